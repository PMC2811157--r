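---
title: "Methods: phosphosite conservation scoring and motif annotation"
author: "phosphocons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phosphosite conservation scoring and motif annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphocons)
```

## The model

`phosphocons` scores how strongly evolution has preserved a mapped human
phosphorylation site across a panel of vertebrate ortholog families. The
working assumption is the standard one for short linear motifs: a
functional phospho-acceptor and its kinase-recognition context sit under
purifying selection, so the 11-residue stretch centered on the
phospho-residue (five flanking residues on each side) diverges more slowly
than the protein background.

For each site and each species the package extracts the aligned −5/+5
window around the phospho-residue and computes

* a **central conservation flag** — the ortholog residue conserves the
  center iff it is identical, or both residues lie in {S, T}. Serine and
  threonine are interchangeable acceptors for Ser/Thr kinases, so S↔T
  exchanges count as conserved; replacement by tyrosine switches the
  required kinase chemistry and counts as loss, as does a gap or any other
  residue. A seed tyrosine is conserved only by tyrosine.
* a **window score** — the fraction of comparable flanking positions whose
  ortholog residue is identical to the seed residue. If the center is lost
  the whole window scores 0: a window around a vanished acceptor is not a
  phosphosite, however similar its flanks.

The site-level summary is the arithmetic mean of the per-species window
scores over species that actually have sequence data, together with the
fraction of those species conserving the center. Both quantities feed the
display convention of the network figure: the central bar height is the
central conservation rate, the flank bar height is the mean window score.

### Missing data semantics

Three states are kept distinct end to end, because they mean different
things biologically:

| state | meaning | effect |
|---|---|---|
| gap `-` | the aligner inferred a deletion | comparable, never identical (a substitution) |
| unknown `X` | sequence data unretrievable | removed from the denominator |
| species absent | no ortholog in the panel | per-species state `NA`, excluded from the mean |

A window whose **central** ortholog residue is unknown reports
`Incomplete`, as does the degenerate case of a conserved center with zero
comparable flanks — a score of 1.0 over an empty flank set would claim
evidence that does not exist. Windows truncate at sequence termini: the
denominator shrinks rather than being padded, which is why near-terminal
sites produce per-species scores in multiples of 1/8 or 1/9.

### Splice variants

Ortholog families may carry several splice variants per species. The
per-species score uses the variant that maximizes the window score —
i.e. the most favorable ortholog evidence — with a deterministic
tie-break: higher central conservation, then longer ungapped sequence,
then lexicographically smallest variant id. Averaging across variants was
the main alternative; it conflates isoform absence of an exon with
sequence divergence, so the maximum was chosen. Scoring only a canonical
variant was rejected because canonical flags are annotation artifacts that
differ across species.

### Aggregation choices

The mean excludes the seed's self-comparison by default (it is always 1.0
and only inflates the score); `include_self = TRUE` reproduces the
"over all species" reading used by tabulations that include the human row.
Species with `NA` or `Incomplete` state are excluded from the denominator
rather than imputed.

## Coordinates

Sites are reported in 1-based residue coordinates on the ungapped human
seed ("Ser139"), which is how the field writes sites. Alignment columns
are also 1-based, the idiomatic R convention; `map_position_to_column()`
converts between the two, and all oracles and tests use the same
convention.

## Motif annotation and the selection filter

Kinase consensus motifs are offset-indexed allowed-residue sets around the
center, loaded from an editable YAML library. Only the ATM/ATR ([S/T]Q)
and Plk1 ([D/E]X[S/T]) consensuses are fixed points of the method; the
CDK ([S/T]P, strict variant with +3 K/R), Polo-box-domain docking
(S-[pS/pT]-P) and minimal Chk1/2 (−3 R) entries follow Scansite-style
consensus literature and are deliberately kept in the config file rather
than the code, since reasonable practitioners tune them. Full
position-weight-matrix predictors (Scansite scoring, NetworKIN context
models) are out of scope; their output can be supplied as an
external-predictions table and is consumed as annotations with provenance
`predicted`. Kinases known from curation are never displaced by
predictions: prediction fires only for sites with no known kinase.

Motif conservation of a seed-matching motif is the fraction of non-seed
species with sequence data whose selected-variant window also satisfies
the motif; required slots landing on gaps or unknown residues count as
failure (the consensus cannot be confirmed there).

`filter_recurrent_conserved()` retains sites that are (i) observed at
least `min_observations` times (default 2), (ii) centrally conserved, and
(iii) carry the named consensus conserved, where (ii) and (iii) use a
single 0–1 threshold with default 1 — the criterion must hold in *every*
scored species. The threshold is exposed because the minimum level of
conservation that counts as "evolutionarily conserved" is a judgment
call; the default is the strictest reading and therefore the most
conservative site list.

## The simulator

`simulate_family()` generates the statistical structure the analysis
assumes, so every stage is testable without external databases:

* **Star phylogeny.** Each non-seed species evolves independently from the
  root. Because the score aggregates independent per-species comparisons
  to the seed, lineage correlation would not change its expectation, and
  independence keeps the oracle analytic: the expected window score of a
  constrained site is `1 − p_sub_neutral × constraint_factor`, of a
  neutral flank `1 − p_sub_neutral`.
* **Substitution-only default.** Columns are preserved, so the emitted
  family is already aligned and scorer correctness is isolated from
  aligner behavior. An optional gap mode (`p_gap_segment`) writes internal
  deletion segments to exercise gap scoring; truncation (`p_truncation`)
  masks a terminal stretch as `X` to exercise the `Incomplete` path.
* **Site classes.** True sites evolve at
  `p_sub_neutral × constraint_factor` throughout their window and their
  centers flip only S↔T (the permitted exchange); decoy sites evolve
  neutrally with unconstrained centers. Substitutions draw uniformly from
  the 19 non-identical residues.

Defaults mirror the study conditions of the analysis the package
implements: 11 vertebrate species, window flank 5, and the calibration
point `p_sub_neutral = 0.3`, `constraint_factor = 0.2` with 5 true + 5
decoy sites on a 400-residue protein. `p_species_missing = 0.15` and
`p_truncation = 0.05` approximate the ortholog dropout and partial gene
models seen in genome-database panels; `n_variants_per_species = 1` keeps
the analytic oracle exact (variant selection is exercised explicitly in
tests). The test suite verifies rate recovery and true/decoy separation
over 200 seeded replicates of this configuration — sizes chosen so the
binomial 3-SD bands are tight while the whole suite stays fast.

What the simulator does **not** emulate: indel evolution (gaps are
injected, not evolved), phylogenetic correlation between lineages,
compositional bias, alignment error, and kinase-motif co-evolution.
Passing tests therefore demonstrate that the scoring arithmetic, missing
data handling and filter logic are correct under the assumed generative
model — not that real alignments are free of aligner artifacts, which on
real data should be inspected per family.

## Numerical and formatting choices

* Scores are exact rationals (k/n with n ≤ 10) computed in double
  precision; no rounding occurs before output.
* Conservation tables print three decimals on the 0–1 scale with literal
  `NA` / `Incomplete` tokens; write∘read is the identity at the printed
  precision.
* JSON network export is lossless and `export` ∘ `import` is the exact
  identity; GraphML embeds the per-site records as a JSON string vertex
  attribute for interoperability.
* All randomness flows through a single integer seed per simulation; two
  runs of the pipeline on the same inputs and seed are byte-identical,
  including the SVG figure.

## Known limitations

* The mean window score weights all species equally; it is not a
  tree-aware (rate4site-style) conservation estimate, and close sister
  species (mouse/rat) are effectively double-counted.
* Gap-heavy windows conflate deletion with divergence by design; families
  with poor alignments will read as unconserved.
* The consensus-motif fallback is far coarser than full kinase-specificity
  predictors and should be treated as a screen, not an assignment.
* Edges of the network are curated input; the package performs no
  interaction inference.
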