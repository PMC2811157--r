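# phosphocons

Cross-species conservation scoring and kinase-motif annotation of mapped
phosphorylation sites.

## The problem

Phosphoproteomics and curated databases place thousands of in vivo
phosphorylation sites on human proteins, but give little guidance on which
sites are functionally important. One strong signal is purifying selection:
a site that matters tends to keep both its phospho-acceptor residue and its
surrounding kinase-recognition context across distant vertebrates.
`phosphocons` is for computational biologists who have (i) a table of mapped
human phosphosites, (ii) pre-aligned ortholog families for each protein
(e.g. MAFFT alignments of Ensembl orthologs, including splice variants), and
optionally (iii) a curated list of signaling interactions and external
kinase predictions — and who want per-site conservation scores, consensus
motif annotations, a filtered list of recurrent conserved kinase-consensus
sites, and an annotated, exportable signaling network.

## The statistic

The conservation unit is the 11-mer window centered on the phospho-residue:
five flanking residues on each side. For a site at seed position *p* and a
species *s* with aligned ortholog residues, the per-species window score is

```
           # identical comparable flanks
w_s(p) = ---------------------------------   if the central S/T/Y is conserved,
              # comparable flanks
w_s(p) = 0                                   if the central residue is lost,
```

where a flank is *comparable* when the seed holds a residue there and the
ortholog holds a residue or an alignment gap (a gap counts as a
substitution; an unknown residue `X` is excluded from the denominator).
S↔T exchanges of the central residue count as conserved (both are
phospho-acceptors for S/T kinases); replacement by Y or anything else does
not, and a seed Y is conserved only by Y. Windows truncate at sequence
termini — a site three residues from the C-terminus has 8 comparable flanks,
so its per-species scores are multiples of 1/8. The site-level score is the
arithmetic mean of w_s over species with sequence data (species without an
ortholog report `NA`; windows whose central residue is unretrievable report
`Incomplete`), with the best-scoring splice variant chosen per species.

On top of the scores, sites are annotated with consensus motifs
([S/T]Q for ATM/ATR, [S/T]P for CDKs, [D/E]X[S/T] for Plk1, S-[pS/pT]-P for
Plk1 Polo-box-domain docking, all editable in a YAML library), and a
selection filter retains sites that are recurrent (observed ≥ 2 times),
have a conserved phospho-acceptor, and carry a conserved consensus motif.

## Worked example

Simulate a small ortholog family with two constrained and two decoy sites,
then score one site:

```r
library(phosphocons)
cfg <- simulation_config(n_species = 6, seq_length = 150,
                         n_true_sites = 2, n_decoy_sites = 2,
                         p_species_missing = 0.1, p_truncation = 0.2,
                         seed = 3)
sim <- simulate_family(cfg)
sim$family
#> <ortholog_family> SIMPROT: 5 sequences x 150 columns, 5/6 species (seed H.sap)

s <- summarize_site(sim$family, sim$sites$position[1])
s
#> <conservation_summary> SIMPROT S11: mean window 0.900, central rate 1.000
s$species_scores
#>   species  variant  status window_score central_conserved n_comparable_flanks
#> 1   H.sap variant1 numeric          1.0              TRUE                  10
#> 2   M.mul variant1 numeric          0.8              TRUE                  10
#> 3   M.mus variant1 numeric          1.0              TRUE                  10
#> 4   R.nor     <NA>      NA           NA                NA                  NA
#> 5   B.tau variant1 numeric          0.8              TRUE                  10
#> 6   C.fam variant1 numeric          1.0              TRUE                  10
```

R.nor drew no ortholog, so it is `NA` and excluded; the remaining
non-seed species average to a mean window conservation of 0.900, and every
ortholog kept the central S (central rate 1.000).

The recurrent-conserved-consensus filter on the bundled synthetic
FHA-domain fixture retains exactly the three planted Plk1-consensus sites:

```r
fx <- synthetic_chk2_fha()
summ <- lapply(seq_len(nrow(fx$sites)), function(i)
  summarize_site(fx$family, fx$sites$position[i]))
ann <- lapply(seq_len(nrow(fx$sites)), function(i)
  annotate_site(fx$sites[i, ], fx$family))
filter_recurrent_conserved(fx$sites, ann, summ)$position
#> [1] 164 205 210
```

`run_full()` (or the `exec/phosphocons` command-line wrapper) composes the
whole pipeline — conservation table, annotations, filtered site list,
GraphML/JSON network exports, a bar-summary figure, and a run manifest —
deterministically for a fixed seed.

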