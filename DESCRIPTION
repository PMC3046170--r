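Package: fossanom
Title: Landmark-Based Nomenclature for Vertebral Neural Arch Fossae
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An executable naming engine for the lamina-bounded fossae of
    saurischian (sauropod and theropod) vertebral neural arches. Composes,
    validates, parses and enumerates fossa names from anatomical landmarks
    (centrum, diapophysis, parapophysis, zygapophyses, neural spine); models
    a vertebra as per-view embedded lamina graphs and names their bounded
    faces, including the special cases (parapophyseal promotion, the
    epipophyseal-prezygapophyseal lamina and sdf1/sdf2, intralaminar "-f"
    fossae); translates five legacy fossa terminologies through a packaged
    concordance; scores fossa complexity above and below the zygodiapophyseal
    table; and exports presence/absence character matrices (TSV, NEXUS) for
    phylogenetic analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
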