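#' Anatomical landmarks of the vertebral neural arch
#'
#' Six loci anchor the fossa nomenclature: the three processes that define the
#' zygodiapophyseal table (diapophysis, prezygapophysis, postzygapophysis) act
#' as primary landmarks; the neural spine and centrum orient a fossa above or
#' below that table as secondary landmarks; and the parapophysis, normally a
#' tertiary landmark, can be promoted to a secondary or primary landmark in
#' middle and posterior dorsal vertebrae where it carries its own laminae.
#'
#' @return A data frame with one row per landmark and columns `code`,
#'   `full_name`, `primary`, `secondary`, `tertiary` (logical role flags).
#' @examples
#' landmarks()
#' @export
landmarks <- function() {
  data.frame(
    code      = c("c", "d", "pa", "po", "pr", "s"),
    full_name = c("centrum", "diapophysis", "parapophysis",
                  "postzygapophysis", "prezygapophysis", "neural spine"),
    primary   = c(FALSE, TRUE,  TRUE,  TRUE,  TRUE,  FALSE),
    secondary = c(TRUE,  FALSE, TRUE,  FALSE, FALSE, TRUE),
    tertiary  = c(FALSE, FALSE, TRUE,  TRUE,  TRUE,  FALSE),
    stringsAsFactors = FALSE
  )
}

.landmark_codes <- c("c", "d", "pa", "po", "pr", "s")

#' @rdname landmarks
#' @param code Landmark code(s), e.g. `"pr"`.
#' @export
landmark_full_name <- function(code) {
  lm <- landmarks()
  i <- match(code, lm$code)
  if (anyNA(i)) stop("unknown landmark code: ", paste(code[is.na(i)], collapse = ", "))
  lm$full_name[i]
}

# combining forms used when building full fossa names
.secondary_form <- c(c = "centro", s = "spino", pa = "para")
.primary_form   <- c(d = "diapophyseal", pr = "prezygapophyseal",
                     po = "postzygapophyseal", pa = "parapophyseal")
.tertiary_form  <- c(pa = "parapophyseal", pr = "prezygapophyseal",
                     po = "postzygapophyseal")

check_landmark_codes <- function(codes) {
  bad <- setdiff(codes, .landmark_codes)
  if (length(bad))
    stop("unknown landmark code: ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(codes)
}
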