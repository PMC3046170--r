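# fossanom

Landmark-based nomenclature for the neural arch fossae of saurischian
dinosaur vertebrae, as an executable naming engine.

Sauropod and theropod vertebrae carry large, usually pneumatic fossae
walled by bony laminae. The laminae have a settled landmark-based
nomenclature; the fossae historically did not, so the same concavity can
appear in the literature under half a dozen incompatible terms, and the
structures have been hard to use as phylogenetic characters. `fossanom`
implements a landmark-based system for the fossae: every named fossa points
to the processes at its corners rather than the laminae at its sides.

The grammar uses six landmarks. The diapophysis (d), prezygapophysis (pr)
and postzygapophysis (po) define the zygodiapophyseal table and act as
**primary** landmarks (d taking precedence); the neural spine (s) and
centrum (c) are **secondary** landmarks orienting a fossa above or below
the table; the parapophysis (pa) is normally a **tertiary** landmark and is
promoted to secondary or primary in dorsal vertebrae where it develops its
own laminae. A name is the concatenation tertiary + secondary + primary +
"f": a fossa cornered by the prezygapophysis, centrum and diapophysis is
the *prezygapophyseal centrodiapophyseal fossa*, `prcdf`. Special cases are
covered: the eprl subdivisions `sdf1`/`sdf2`, intralaminar fossae of
divided laminae (`cprl-f`), and bipartite-only naming for sacral vertebrae.

The package provides:

* `compose_name()`, `parse_name()`, `abbreviate_name()`, `expand_name()`,
  `enumerate_catalogue()` — the grammar, with validation of impossible
  landmark combinations, and deterministic catalogues (6+6 base names,
  8+7 with parapophyseal promotion, the 16 attested concordance names);
* `vertebra_graph()`, `make_archetype()`, `enumerate_faces()`,
  `assign_fossa_names()` — a vertebra as per-view embedded lamina graphs
  whose bounded faces are enumerated from the rotation system and named
  automatically, including all special cases;
* `translate_term()`, `reverse_translate()`, `count_terms()` — a packaged
  concordance with five legacy terminologies (Hatcher 1901, Osborn & Mook
  1921, Welles 1984, Bonaparte 1999, Harris 2006);
* `complexity_score()`, `zone_of()` — unique-fossa counts above and below
  the zygodiapophyseal table for morphospace comparison;
* `export_character_matrix()` — presence/absence character matrices
  (TSV or NEXUS) for phylogenetic analysis;
* `run_cli()` and the script `inst/cli/fossanom` — a command-line front
  end (`name`, `parse`, `catalogue`, `translate`, `analyze`, `complexity`,
  `matrix`, `archetype`).

## A worked example

Compose a name from landmarks, then let the graph model name a complex
dorsal vertebra:

```r
library(fossanom)

compose_name(c("c", "d", "pr"))
#> prcdf	prezygapophyseal centrodiapophyseal fossa
#>   primary = d, secondary = c, tertiary = pr

named <- assign_fossa_names(make_archetype("dorsal_complex"))
named[named$chart == "lateral", c("abbreviation", "boundary_laminae")]
#>   abbreviation boundary_laminae
#> 1        prsdf   prdl,spdl,sprl
#> 2        pocdf   cpol,pcdl,podl
#> 3        pacdf   pcdl,pcpl,ppdl
#> 4       pacprf   acpl,cprl,prpl
#> 5       prpadf   ppdl,prdl,prpl
#> 6         cpaf        acpl,pcpl
#> 7        posdf   podl,spdl,spol
```

The four parapophyseal fossae (`prpadf`, `pacprf`, `pacdf`, `cpaf`) are
exactly the ones created when the parapophysis rises onto the neural arch
and gains its own laminae — two of them require the promotion rules, since
one face never touches the zygodiapophyseal table and the other touches no
ordinary secondary landmark.

Complexity scoring follows the unique-fossa rule (midline fossae count
once; one member of each pair counts; a divided midline fossa counts
twice):

```r
inv <- new_fossa_inventory(data.frame(
  abbreviation = c("sprf", "spof", "prsdf", "posdf"),
  laterality   = c("midline", "midline", "paired", "paired"),
  divided      = FALSE))
complexity_score(inv)
#> Fossa complexity: 4 unique fossae above the table, 0 below
```

Marking the `sprf` divided raises the count to 5. Legacy terms translate
as sets, preserving historical ambiguity:

```r
translate_term("infradiapophyseal fossa", "harris2006")
#> [1] "cdf"   "pacdf"
```

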