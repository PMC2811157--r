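#' Synthetic DNA-damage-response phosphosite roster
#'
#' A deterministic synthetic stand-in for a manually curated collection of
#' in vivo mapped phosphosites on the core human DNA damage response (DDR)
#' network: 244 sites over 33 proteins, mirroring the size and structure of
#' such curations (S/T/Y residues, known upstream kinases where curated,
#' observation counts, provenance tags).  Positions and annotations are
#' generated in code and carry no experimental meaning.
#'
#' @return Site `data.frame` with 244 rows over 33 distinct proteins, in
#'   the schema of [read_site_table()].
#' @export
synthetic_ddr_sites <- function() {
  proteins <- c("ATM", "ATR", "ATRIP", "CHEK1", "CHEK2", "TP53BP1", "MDC1",
                "H2AFX", "BRCA1", "BARD1", "NBN", "MRE11A", "RAD50", "RAD51",
                "TP53", "MDM2", "CDC25A", "CDC25B", "CDC25C", "WEE1", "PLK1",
                "CCNB1", "CDK1", "CDK2", "CCNA2", "CLSPN", "TOPBP1", "RPA2",
                "SMC1A", "FANCD2", "EXO1", "BLM", "PRKDC")
  n_per <- rep(7L, length(proteins))
  extra <- 244L - sum(n_per)
  n_per[seq_len(extra)] <- n_per[seq_len(extra)] + 1L
  residues <- c("S", "T", "S", "Y", "T", "S", "S", "T")
  kinase_pool <- c("ATM", "ATR", "CDK1", "CDK2", "CHK1", "CHK2", "PLK1", "")
  sources <- c("Phospho.ELM", "Phosphosite", "PBD-proteomics")
  rows <- list()
  for (i in seq_along(proteins)) {
    for (j in seq_len(n_per[i])) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = proteins[i],
        position = 15L + 23L * (j - 1L) + ((i * 7L) %% 12L),
        residue = residues[(i + j) %% length(residues) + 1L],
        known_kinases = kinase_pool[(i * 3L + j) %% length(kinase_pool) + 1L],
        observation_count = 1L + (i + 2L * j) %% 5L,
        source = sources[(i + j) %% length(sources) + 1L],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Synthetic curated edge list for the DDR network
#'
#' A small set of established signaling interactions among the proteins of
#' [synthetic_ddr_sites()], for assembling and exporting demonstration
#' networks.  Curated input, never inferred.
#'
#' @return Edge `data.frame` with columns `from`, `to`, `label`.
#' @export
synthetic_ddr_edges <- function() {
  data.frame(
    from = c("ATM", "ATM", "ATR", "ATM", "TP53BP1", "CHEK2", "CHEK1",
             "CDK1", "PLK1", "PLK1", "MDC1"),
    to = c("CHEK2", "H2AFX", "CHEK1", "TP53BP1", "CHEK2", "CDC25C",
           "CDC25A", "CCNB1", "TP53BP1", "CHEK2", "H2AFX"),
    label = c("phosphorylation", "phosphorylation", "phosphorylation",
              "recruitment", "scaffold", "phosphorylation",
              "phosphorylation", "complex", "docking", "phosphorylation",
              "binding"),
    stringsAsFactors = FALSE)
}

#' Synthetic Chk2 FHA-domain phosphopeptide fixture
#'
#' A constructed stand-in for an in vitro phosphopeptide mapping of an
#' FHA-domain-containing checkpoint kinase: a synthetic 230-residue seed, a
#' small ortholog family, and a site list in which exactly three sites
#' (Ser-164, Thr-205, Ser-210) are observed at least twice, carry a fully
#' conserved phospho-acceptor, and carry a fully conserved Plk1
#' \[D/E\]X\[S/T\] consensus.  Every other site fails exactly one criterion
#' of [filter_recurrent_conserved()]: observed once, consensus absent from
#' the seed, phospho-acceptor lost in one species, or consensus residue
#' lost in one species.
#'
#' @return List with `sites` (site `data.frame`), `family`
#'   (`ortholog_family`) and `expected_positions` (`c(164, 205, 210)`).
#' @export
synthetic_chk2_fha <- function() {
  protein <- "CHK2"
  species <- default_species()
  set.seed(20100126L)
  seed_seq <- simulate_root_sequence(230L)
  plk1 <- kinase_motif("Plk1", central = c("S", "T"), slots = list(`-2` = c("D", "E")))
  atm <- kinase_motif("ATM/ATR", central = c("S", "T"), slots = list(`+1` = "Q"))

  # the three retained sites: recurrent, conserved, conserved Plk1 consensus
  seed_seq <- plant_site(seed_seq, 164L, plk1, central = "S")
  seed_seq <- plant_site(seed_seq, 205L, plk1, central = "T")
  seed_seq <- plant_site(seed_seq, 210L, plk1, central = "S")
  # decoys, one failed criterion each
  seed_seq <- plant_site(seed_seq, 68L, atm, central = "T")     # no [D/E]X[S/T]
  seed_seq <- sub_residue(seed_seq, 66L, "L")                   # ensure -2 not D/E
  seed_seq <- plant_site(seed_seq, 100L, plk1, central = "S")   # observed once
  seed_seq <- plant_site(seed_seq, 120L, plk1, central = "S")   # motif lost in M.mus
  seed_seq <- plant_site(seed_seq, 140L, plk1, central = "S")   # center lost in M.mus

  orth <- function(edits = list()) {
    s <- seed_seq
    for (e in edits) s <- sub_residue(s, e[[1]], e[[2]])
    s
  }
  members <- data.frame(
    species = c("H.sap", "M.mus", "R.nor", "X.tro"),
    variant = "variant1", is_seed = c(TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  sequences <- c(
    seed_seq,
    orth(list(list(30L, "G"), list(118L, "A"), list(140L, "A"))),  # M.mus
    orth(list(list(55L, "N"))),                                    # R.nor
    orth(list(list(80L, "K"), list(225L, "V"))))                   # X.tro
  fam <- new_ortholog_family(protein, sequences, members, species)

  sites <- data.frame(
    protein_id = protein,
    position = c(68L, 100L, 120L, 140L, 164L, 205L, 210L),
    residue = c("T", "S", "S", "S", "S", "T", "S"),
    known_kinases = c("ATM", "", "", "", "", "", ""),
    observation_count = c(4L, 1L, 2L, 2L, 3L, 2L, 2L),
    source = "synthetic",
    stringsAsFactors = FALSE)
  list(sites = sites, family = fam,
       expected_positions = c(164L, 205L, 210L))
}

sub_residue <- function(sequence, position, residue) {
  substr(sequence, position, position) <- residue
  sequence
}
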