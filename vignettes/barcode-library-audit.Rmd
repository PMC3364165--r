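---
title: "Auditing a DNA barcode reference library: methods and design"
author: "barcodeAudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing a DNA barcode reference library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A DNA barcode reference library links voucher specimens — identified by
taxonomists — to sequences of the ~658-bp 5′ (Folmer) fragment of the
mitochondrial COI gene. Before such a library can be trusted for
identification it has to be audited: Are conspecific sequences tightly
clustered? Is every species separated from its nearest non-conspecific
by a clear "barcode gap"? Do any nominal species hide deeply divergent
clusters suggesting cryptic species complexes? Are any vouchers probably
misidentified, i.e. sequenced into another species' cluster? This
package implements that audit, from FASTA/TSV input to per-species and
per-family report tables, together with a fully controlled simulator of
barcode libraries so every stage can be validated against known truth.

## Distance model

All divergences are Kimura 2-parameter (K2P) distances computed under
*pairwise deletion*: for each pair of sequences, only sites where both
carry a concrete base (A, C, G, T) are compared; IUPAC ambiguity codes,
N, gaps and uncovered frame positions are excluded per pair. With
transition proportion $P$ and transversion proportion $Q$ over the $n$
compared sites,

$$ d \;=\; -\tfrac12 \ln(1 - 2P - Q) \;-\; \tfrac14 \ln(1 - 2Q). $$

Two numerical choices matter:

* **Minimum overlap** (`min_overlap`, default 100 sites). A distance
  over too few shared sites is noise; genuine barcode pairs share far
  more (the shortest meaningful records are ~314-bp and the standard
  short amplicon is a 325-bp 5′ fragment). Pairs below the minimum are
  *undefined*, not zero and not an error.
* **Saturation**. When $1-2P-Q \le 0$ or $1-2Q \le 0$ the logarithms
  are undefined; such pairs (in practice: across families) are stored
  as undefined and excluded from summaries with a warning, rather than
  being reported as infinite.

Sequences are anchored on the fixed 658-site barcode coordinate frame
(1-based, 5′ fragments anchored at site 1). Multiple sequence alignment
is deliberately out of scope: barcode records of this marker are
screened for indels, so every surviving record lives on the common frame
and column identity is positional identity.

## Quality screening

Each sequence is translated in the reading frame (offset 0, 1 or 2)
that minimizes in-frame stop codons under the invertebrate
mitochondrial genetic code (ties to the smallest offset; real COI has a
fixed frame, so the minimal-stop frame is the biological one whenever
the sequence is genuine). The screen reports
`stop_codon` (pseudogene/chimera evidence), `indel` (internal gap),
`too_short` (below `min_len`, default 300 sites) or `pass`; only
passing sequences enter the distance matrix.

## The audit statistics

For every species with the specimens in the distance matrix:

* **MXID** — maximum intraspecific K2P distance (undefined for
  singletons), plus the mean of all intraspecific pairs.
* **MNID** — minimum distance from any member to any specimen of
  another species within the *MNID scope*, along with that nearest
  neighbor's label. The scope defaults to congeners (`genus`) and may
  be widened to `family` or `all`; MNID can only shrink as the scope
  widens. The restriction reflects how summary tables in this field
  report "–" for families with a single barcoded species; whether such
  tables used genus or family scope is not documented anywhere we know
  of, so both are supported and neither is asserted as canonical.
* **Haplotype clusters at `t_split`** — single-linkage clusters using
  strict linkage $d < t_{split}$ (default 0.050), so distinct clusters
  are separated by at least 5.0%. Single linkage is chosen because the
  field's informal practice — reading clusters off an NJ tree — has no
  reproducible definition; strict single linkage is the closest
  deterministic formalization.

Three flags, all with strict inequalities:

| flag | condition | default threshold | meaning |
|---|---|---|---|
| `deep_divergence` | MXID > `t_deep` | 0.022 | intraspecific variation above the ~2.2% level repeatedly found to delimit insect species |
| `multi_cluster` | ≥ 2 clusters at `t_split` | 0.050 | putative cryptic complex |
| `gap_overlap` | MXID > MNID | — | the local barcode gap fails |

The 2.2% flag uses strict ">" (report prose in this field says
"greater than", even where table headers print "≥"); the threshold is
configurable for users who prefer the other convention.

## Trees and monophyly

Neighbor joining uses the Studier–Keppler criterion
$Q(i,j) = (r-2)\,d(i,j) - R_i - R_j$, with two determinism guarantees
the standard implementations do not give: ties in $Q$ (and in midpoint
rooting) are broken by the lexicographically smallest pair of ids, and
negative branch lengths are retained rather than clamped. NJ is exact
on additive matrices — leaf-to-leaf path lengths reproduce the input —
which is the property the test suite verifies. Because para- versus
polyphyly depends on a root and no rooting convention is standard for
barcode NJ trees, trees are midpoint-rooted by default (outgroup
rooting can be applied with `ape::root` before classification). A
species with leaf set $L$ is *monophyletic* if some clade equals $L$;
otherwise, with $I$ the intruding leaves under the MRCA of $L$,
*paraphyletic* if $I$ itself is exactly one clade and *polyphyletic*
otherwise; this is one defensible formalization of labels that are
usually assigned by eye. Audit trees are built per family by default:
between-family distances routinely saturate, and NJ requires a complete
matrix.

## Identification rules

* **Assignment**: a query is compared against all expert-identified,
  QC-passing references. With $S$ the set of species holding a
  reference strictly closer than `t_assign` (default 0.020, the <2%
  rule used when propagating names to morphologically unidentifiable
  specimens): one species → assigned with confidence "propagated";
  several → ambiguous; none → unassigned, a candidate for a provisional
  name.
* **Provisional names** follow the convention genus + " sp." +
  taxonomist initials + serial (e.g. *Heptagenia* sp.LJ1); a registry
  issues the smallest free serial and can reserve previously published
  variants (including the spaced form "Acerpenna sp. CHU1").
* **Discordance screen**: a specimen is flagged as a candidate
  misidentification iff its nearest neighbor lies strictly closer than
  `t_assign` *and* carries a different label, *and* its nearest
  conspecific is farther than `t_split` (vacuously true for
  singletons). The screen mirrors the workflow in which barcode
  clusters contradicting morphological identifications trigger
  re-examination of the voucher; `auditLibrary(correctDiscordant =
  TRUE)` emulates the outcome of that re-examination by relabeling
  flagged specimens to their nearest neighbor's species.
* **Diagnostic characters**: a (position, state) pair is diagnostic for
  a species within a comparison set iff every member with data at the
  position shows the state and no member of the other species does.
  Missing data make a position undiagnosable for that specimen only;
  `minCoverage` guards against claiming fixation from a single
  observation.

## The simulator

`simulateReferenceLibrary()` builds libraries by star radiation with
telescoping depths: one random stop-free codon-wise ancestor per
family; genus ancestors at depth
$(d_{genus}-d_{inter})/2$ below it; species ancestors at
$(d_{inter}-d_{intra})/2$ below their genus; specimens at
$d_{intra}/2$ below their species (or cryptic-cluster) ancestor. Two
tips radiating from a common ancestor at depth $t/2$ sit at expected
pairwise distance $t$, so the *expected pairwise* K2P distance equals
`intra_depth` (0.02) within species, `split_depth` (0.08) across
cryptic clusters, `inter_depth` (0.12) across congeners and
`between_genus_depth` (0.30) across genera of a family — calibrated to
the ~2% intraspecific / ~12.5% congeneric means reported for large
mayfly COI libraries. Substitutions follow a per-site continuous-time
K2P process with transition/transversion ratio `kappa` (default 3);
any substitution creating an in-frame stop codon is redrawn (purifying
selection), so clean simulator output passes QC at 100%. A fifth of
species (floor rule) are cryptic complexes of 2–3 clusters; a fraction
of sequences becomes 5′ 325-bp fragments; `misid_count` specimens get
their *metadata label* swapped to a congener while the sequence is
untouched, giving ground truth for the discordance screen. All
randomness flows from one seed; identical seeds give byte-identical
output.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: coalescent genealogies (star radiation has no
within-species topology), among-site rate variation and codon-position
effects, base-composition bias, geographic structure, sequencing error
other than uniform N-masking, and real taxonomic error modes beyond
clean label swaps.

## Choices made where the design was open

* Expected intraspecific distance (0.02) equals the assignment
  threshold (0.020) under the default calibration. Consequences are
  visible in the end-to-end tests: the audit makes no wrong or
  ambiguous assignments, but a minority of queries whose nearest
  conspecific sits just above 2% remain conservatively unassigned, and
  MXID — a maximum over all intraspecific pairs — exceeds the 2.2% flag
  threshold for essentially every 10-specimen species, so the
  deep-divergence flag is a sensitive screen rather than a precise
  cryptic-species detector at these settings. The cryptic-complex truth
  set is recovered exactly by the `multi_cluster` flag after the
  discordance corrections.
* Fragment fraction defaults to 0.10: libraries built from fresh
  material are dominated by full-length reads, with a minority of
  short 5′ amplicons from degraded or historical material.
* Genetic code: invertebrate mitochondrial (translation table 5; stops
  TAA/TAG only). The reading frame is chosen per sequence by minimal
  stops because anchors may start mid-codon in edge cases.
* Degenerate inputs: all-zero trees root on the edge of the
  lexicographically first leaf; equidistant NJ inputs resolve by the
  id tie-break with zero-length internal branches; a two-specimen
  "tree" is a single edge and is handled by the caller rather than NJ.

## Problem sizes

The shipped tests run the audit end-to-end on the default 20-species ×
10-specimen library (200 sequences, ~20k distance pairs, a few
seconds), verify NJ exactness on 100 random additive matrices of 5–8
taxa, compare the monophyly classifier against brute-force clade
enumeration on 200 random trees of up to 32 leaves, and check the
diagnostic finder against a brute-force site scan on 50 small random
libraries. These sizes were chosen as the smallest that exercise every
code path with non-trivial structure.

## Limitations

Distances other than K2P (p-distance, TN93, GTR) are out of scope, as
are alignment, bootstrap support, likelihood/Bayesian trees, fetching
records from BOLD or GenBank, and any nomenclatural interpretation of
the flags: a `multi_cluster` species is a hypothesis to examine, not a
species-level decision.
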