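---
title: "Naming neural arch fossae: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Naming neural arch fossae: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fossanom)
```

## The problem

The neural arches of sauropod and other saurischian vertebrae carry large
external concavities — fossae, usually pneumatic in origin — that are walled
by bony laminae. The laminae have a stable, landmark-based nomenclature; the
fossae they bound historically did not, which left potentially homologous
structures described under incompatible ad-hoc terms and kept them out of
phylogenetic character matrices. This package implements a landmark-based
naming system for those fossae as executable code: a grammar that composes,
validates and parses names; a graph model of the vertebra whose bounded
faces *are* the fossae; a concordance to five legacy terminologies; a
complexity score for morphospace work; and presence/absence character-matrix
export.

## The naming grammar

Six landmarks participate. The diapophysis (d), prezygapophysis (pr) and
postzygapophysis (po) define the zygodiapophyseal table and act as *primary*
landmarks; the neural spine (s) and centrum (c) orient a fossa above or
below that table as *secondary* landmarks; the parapophysis (pa) is normally
a *tertiary* landmark but is promoted in middle and posterior dorsal
vertebrae where it develops its own laminae.

`compose_name()` assigns roles to a landmark set in a fixed order:

1. **Primary**: d if present (it is the "primary" primary landmark);
   otherwise a lone zygapophysis; otherwise pa, but only when no table
   landmark is present at all (yielding cpaf).
2. **Secondary**: s, else c, else pa when a table primary is present but
   neither s nor c is (yielding padf, prpadf).
3. **Tertiary**: the remaining landmark, if any.
4. **Symmetric flank**: the full sets {s,d,pr,po} and {c,d,pr,po} name the
   *undivided* sdf and cdf — both zygapophyses flank the fossa, and no
   tertiary is assigned.
5. **Compatibility**: tertiary pr never combines with primary po and vice
   versa; pa never combines with secondary s or primary po; secondary pa
   occurs only under primary d. These explicit rules are the minimal
   generalization that reproduces the attested tripartite set
   {pacdf, prcdf, pocdf, prsdf, posdf, pacprf}: the source material names
   only example exclusions, so combinations joining opposite ends of the
   vertebra (e.g. pacpof) are treated as impossible even where not
   explicitly listed.

The abbreviation is tertiary + secondary + primary codes plus "f"
(`prcdf`); the full name uses the combining forms spino-/centro-/para- for
the secondary landmark and a separate leading word for the tertiary.

Two families of names live outside the role grammar. When the
epipophyseal-prezygapophyseal lamina (eprl) divides the spinodiapophyseal
fossa, the resulting upper and lower fossae touch three primary landmarks
at once and are named sdf1 (spine side) and sdf2 (diapophysis side); the
landmark sets {s,pr,po} and {d,pr,po} are therefore only nameable in eprl
context. A fossa between the two rami of a divided lamina takes the lamina
name plus "-f" (cprl-f), never a landmark compound, which would collide
with an existing fossa name.

Spelling follows the abbreviations-list forms; attested variant spellings
("prezygapophyseal parapodiapophyseal fossa", the figure-list abbreviation
"prcpaf", "parapodiapophyseal lamina") are accepted by `parse_name()` but
never emitted, and "prcpaf" is excluded from every catalogue because its
systematic status is unresolved.

### Catalogues

`enumerate_catalogue()` builds three deterministic catalogues: `base`
(6 bipartite + 6 tripartite names, no parapophyseal promotion), `extended`
(plus cpaf, padf, prpadf: 8 + 7), and `table1` (the sixteen names attested
in the published concordance: extended minus padf plus sdf1/sdf2). Ordering
— bipartite and special names before tripartite, then lexicographic — is a
package convention chosen for reproducible output; the source implies no
order.

## The vertebra as embedded lamina graphs

A vertebra is modeled as up to three planar *charts* (lateral, anterior,
posterior views) because the naming system itself is view-oriented: fossae
seen laterally are diapophyseal, those seen anteriorly or posteriorly are
pre- or postzygapophyseal. Only the left side is drawn laterally; bilateral
symmetry is declared, not modeled.

Each chart is a connected multigraph with a *rotation system*: the cyclic
order of incident edges at every node, plus one directed edge designated as
lying on the unbounded face. Standard face traversal then enumerates the
bounded faces — the fossae — and for a connected chart their number is
always E − V + 1. No automatic planar embedding is computed: archetypes
derive their rotation systems from hard-coded schematic drawings, and user
files must supply rotation and outer witness explicitly.

Conventions worth noting:

* **Structural table-margin edge.** In the anterior/posterior views the
  spinal fossa (sprf/spof) and the central fossa (cprf/cpof) are separated
  by the zygapophyses and the roof of the neural canal, not by a named
  lamina. The frontal charts therefore contain one structural, non-lamina
  edge joining the left and right zygapophyses. Every other edge carries at
  least one lamina label.
* **Pass-through parapophysis.** A parapophysis of degree 2 (the simple
  dorsal condition, where it merely interrupts the old acdl path as
  acpl + ppdl) is invisible to naming: the fossa configuration is unchanged
  until the parapophysis develops its own laminae. This is implemented as
  the effective-landmark rule: degree-2 pa nodes are excluded from a face's
  landmark set.
* **Conjoined laminae** are edges carrying several lamina labels. Naming
  depends only on the face's landmark set, so different conjunction
  patterns of the eprl yield the same sdf1/sdf2 names.
* **Divided laminae** appear as two parallel edges with the same label and
  complementary ramus tags; only the face *between* the rami takes the
  intralaminar "-f" name. Whether a face bounded by one ramus plus other
  laminae should ever take that name is not settled in the source; we do
  not guess. The division of each divisible lamina is expressed in the
  chart where its intralaminar fossa is observed (cprl in the anterior
  chart, cpol and spol in the posterior chart, the rest laterally).
* **Ties and failures.** The chart's view supplies a pr-vs-po preference
  used only to break a genuine primary tie; sets such as {c,pr,po} are
  rejected as impossible rather than tie-broken. Faces that cannot take a
  valid name are reported with an unnamed-reason, never raised as errors; a
  face is atomic, so irregular subfossae are out of the data model. A face
  touching {s,d,pr} and {po} with a partial spdl and no eprl is reported
  unnamed rather than silently assimilated to the symmetric-flank sdf,
  which applies to the exact four-landmark set only.
* **Sacral mode** truncates tripartite names to their bipartite base, since
  fusion obliterates the landmarks that justify tertiary precision.
* **Epipophysis.** The eprl's posterior endpoint, the epipophysis, is
  modeled as part of the postzygapophysis node: the source never grants it
  landmark status.

### Archetypes

`make_archetype()` builds five deterministic configurations — cervical
(with and without eprl), simple and complex dorsal, and reduced caudal —
from fixed schematic drawings; options add an spdl or divide attested-
divisible laminae. These archetypes emulate the canonical laminar
topologies and serve as generators for tests: what they do *not* emulate is
metric shape, left/right asymmetry, bifid neural spines' metapophyseal
webbing, irregular subfossae, or intermediate/partial lamina development.
Passing tests on archetypes therefore demonstrate correctness of the
combinatorial naming machinery, not coverage of all real specimens; real
vertebrae enter through the JSON reader with their own embeddings.

### Numerical and degenerate-input choices

Rotation orders for archetypes are derived by sorting edge directions
counterclockwise at each node (bent laminae use their control point); the
outer face is identified at build time by the signed area of each face
polygon. The face traversal itself is purely combinatorial; there are no
tolerances. Degenerate inputs (rotation omitting an incident edge,
disconnected charts, unknown lamina labels, witness not on any face) are
rejected with specific errors at validation time.

The test suite cross-checks the traversal against an independent brute-force
oracle: all simple cycles of a chart are enumerated by subset search, and
the E − V + 1 atomic regions are selected greedily by enclosed polygon area
under GF(2) independence. Greedy-by-area is used deliberately: a non-facial
cycle encloses two or more faces and so always has larger area than each of
them, whereas greedy-by-*length* (a minimum cycle basis) can prefer a
shortcut cycle — in the dorsal configuration the triangle cprl/prdl/pcdl is
shorter than the prcdf face it spans — so cycle length does not
characterize the faces, but enclosed area does.

## Legacy concordance

The packaged concordance table (one row per authority/term/modern-name
triple) preserves legacy ambiguity as sets in both directions; no
disambiguation by vertebral position is attempted, and no fuzzy matching is
offered. Source cells joining two terms (with "+" or ";") yield one row per
term with the same modern target. Three source terms are shipped as notes,
not entries, because they do not name landmark-bounded fossae
(`concordance_notes()`). Per-authority distinct-term counts reproduce the
published header totals for four authorities; the fifth (Welles) prints a
header total of nine against seven tabulated terms plus one footnote
exclusion — `count_terms()` reports table content, and the discrepancy is
documented rather than resolved.

## Complexity scoring

`complexity_score()` counts *unique* fossae above and below the
zygodiapophyseal table: midline fossae and one member of each left/right
pair weigh 1, and a midline fossa divided by a prespinal/postspinal lamina
weighs 2. Bilateral division of a paired fossa does not double-count — the
division rule is read as addressing midline division only. Intralaminar
fossae of table-plane laminae (prdl-f, podl-f, eprl-f) have no intrinsic
zone; they default below the table, configurable via `table_plane =
"above"`, since the morphospace convention does not rule on them.
Inventories containing both the undivided sdf and its subdivisions
sdf1/sdf2 for one position are rejected as inconsistent. The worked
four-vs-five-squares example and the archetype-derived hand counts are
reproduced in the test suite and the acceptance script.

## Character-matrix export

Characters are presence/absence only (no ordered-multistate scheme is
invented), one per catalogue name per position class. Position classes are
fixed at cervical/dorsal/caudal; finer serial positions stay in metadata
rather than multiplying into characters, to avoid column explosion. A class
never scored for a taxon codes "?" throughout. The NEXUS writer emits a
standard DATA block (symbols "01", missing "?"), and the test suite
round-trips it through an independent parser (`ape::read.nexus.data`)
checking that taxa and character counts survive.

## Problem sizes

All checks run at desk scale: charts have at most ~14 edges, the
brute-force region oracle is applied to charts of at most 12 edges, the
randomized property tests use 200 perturbed archetypes under a fixed seed,
and the whole suite completes in well under a minute per module. These
sizes were chosen because the naming machinery is combinatorial and its
behavior is fully exercised by small graphs; nothing in the implementation
depends on scale.

## Known limitations

* No inference of laminae from images or meshes, and no automatic planar
  embedding: the user supplies the topology.
* Centrum fossae and foramina (pleurocoels) are outside the system — they
  are not bounded by landmarks.
* Irregular subfossae within a face are not modeled; a face is atomic.
* The morphospace figures of the source are read off a plot rather than
  printed, so per-taxon square counts are not reproduction targets; only
  the counting rule and its worked example are.
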