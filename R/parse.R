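# Parsing of fossa names: abbreviations ("pocdf", "cprl-f", "sdf2") and full
# English names (canonical spellings plus the attested variants).

# full-name variants accepted on input but never emitted
.fossa_name_variants <- c(
  "prezygapophyseal parapodiapophyseal fossa" = "prpadf",
  "spinodiapophyseal fossa 1"                 = "sdf1",
  "spinodiapophyseal fossa 2"                 = "sdf2"
)

#' Parse a fossa name
#'
#' Accepts an abbreviation or a full name and returns the corresponding
#' `fossa_name`. Abbreviations are tokenized greedily, two-letter codes
#' (pa, po, pr) before one-letter codes (c, d, s), and must end in "f";
#' a "-f" suffix routes to an intralaminar fossa whose lamina label is
#' validated against the lamina catalogue. `parse_name` inverts
#' [abbreviate_name()] on every catalogue member, and additionally accepts
#' attested synonym-level spellings (e.g. "prezygapophyseal
#' parapodiapophyseal fossa", "prcpaf") that are never emitted.
#'
#' @param text A single name or abbreviation.
#' @return A `fossa_name` object.
#' @examples
#' parse_name("pocdf")
#' parse_name("spol-f")
#' parse_name("postzygapophyseal centrodiapophyseal fossa")
#' @export
parse_name <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  raw <- gsub("\\s+", " ", trimws(tolower(text)))
  if (!nzchar(raw)) stop("unparseable name: empty input", call. = FALSE)

  if (raw %in% c("sdf1", "sdf2"))
    return(new_fossa_name(special = raw))

  # intralaminar abbreviation: "<lamina>-f"
  if (grepl("-f$", raw)) {
    lab <- sub("-f$", "", raw)
    if (!lab %in% lamina_catalogue()$abbreviation)
      stop("unparseable name: unknown lamina label '", lab, "'", call. = FALSE)
    return(new_fossa_name(special = "intralaminar", parent_lamina = lab))
  }

  # full names
  if (grepl(" ", raw) || grepl("fossa$", raw)) {
    if (raw %in% names(.fossa_name_variants))
      return(parse_name(.fossa_name_variants[[raw]]))
    # "<lamina full name> fossa" -> intralaminar
    cat <- lamina_catalogue()
    i <- match(raw, paste(cat$full_name, "fossa"))
    if (!is.na(i))
      return(new_fossa_name(special = "intralaminar",
                            parent_lamina = cat$abbreviation[i]))
    i <- match(raw, paste(names(.lamina_name_variants), "fossa"))
    if (!is.na(i))
      return(new_fossa_name(special = "intralaminar",
                            parent_lamina = .lamina_name_variants[[i]]))
    hit <- .full_name_index()[[raw]]
    if (!is.null(hit)) return(parse_name(hit))
    stop("unparseable name: '", text, "' is not a recognized fossa name",
         call. = FALSE)
  }

  # abbreviation grammar: tokens then trailing "f"
  if (!grepl("f$", raw))
    stop("unparseable name: '", text, "' lacks the terminal 'f'", call. = FALSE)
  body <- sub("f$", "", raw)
  codes <- character(0)
  while (nzchar(body)) {
    two <- substr(body, 1, 2)
    one <- substr(body, 1, 1)
    if (two %in% c("pa", "po", "pr")) {
      codes <- c(codes, two); body <- substring(body, 3)
    } else if (one %in% c("c", "d", "s")) {
      codes <- c(codes, one); body <- substring(body, 2)
    } else {
      stop("unparseable name: unknown token at '", body, "' in '", text, "'",
           call. = FALSE)
    }
  }
  if (length(codes) < 2 || length(codes) > 3)
    stop("unparseable name: '", text, "' is not a bipartite or tripartite ",
         "abbreviation", call. = FALSE)
  if (anyDuplicated(codes))
    stop("impossible combination: a landmark can only be used once to define ",
         "a fossa", call. = FALSE)

  n <- length(codes)
  primary <- codes[n]
  secondary <- codes[n - 1]
  tertiary <- if (n == 3) codes[1] else NULL

  if (!primary %in% c("d", "pr", "po", "pa"))
    stop("impossible combination: ", primary, " cannot act as a primary ",
         "landmark", call. = FALSE)
  if (!secondary %in% c("s", "c", "pa"))
    stop("impossible combination: ", secondary, " cannot act as a secondary ",
         "landmark", call. = FALSE)
  if (!is.null(tertiary) && !tertiary %in% c("pa", "pr", "po"))
    stop("impossible combination: ", tertiary, " cannot act as a tertiary ",
         "landmark", call. = FALSE)

  # note: "prcpaf" (tertiary pr over the promoted-primary pa) passes these
  # checks and is parsed as a synonym-level extension of pacprf, though it is
  # excluded from every catalogue and never emitted
  msg <- roles_incompatibility(primary, secondary, tertiary)
  if (!is.null(msg))
    stop("impossible combination: ", msg, call. = FALSE)

  new_fossa_name(primary = primary, secondary = secondary, tertiary = tertiary)
}

.full_name_cache <- new.env(parent = emptyenv())

.full_name_index <- function() {
  if (is.null(.full_name_cache$idx)) {
    cat <- enumerate_catalogue("table1")
    idx <- list()
    for (nm in cat$names) idx[[nm$full_name]] <- nm$abbreviation
    padf <- new_fossa_name(primary = "d", secondary = "pa")
    idx[[padf$full_name]] <- padf$abbreviation
    .full_name_cache$idx <- idx
  }
  .full_name_cache$idx
}
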