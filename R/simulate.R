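#' Simulation configuration for synthetic ortholog families
#'
#' Defines the star-phylogeny evolution model used by [simulate_family()]:
#' every non-seed species derives independently from a common root sequence;
#' each position substitutes with probability `p_sub_neutral` per lineage,
#' except positions inside a true phosphosite's -5/+5 window, which
#' substitute with probability `p_sub_neutral * constraint_factor`
#' (purifying constraint).  True-site central residues substitute only
#' within \{S,T\} (the interchangeable phospho-acceptor rule); decoy sites
#' evolve neutrally with unconstrained centers.
#'
#' @param n_species Number of species including the seed (default 11, the
#'   high-coverage vertebrate panel).
#' @param seq_length Root sequence length in residues (>= 11).
#' @param n_true_sites,n_decoy_sites Numbers of constrained and neutral
#'   phosphosites to plant; all site positions are kept pairwise >= 11
#'   residues apart so windows never overlap.
#' @param p_sub_neutral Per-position substitution probability per lineage.
#' @param constraint_factor Multiplier applied to `p_sub_neutral` inside
#'   true-site windows (<= 1; 0 freezes the windows).
#' @param p_species_missing Probability that a non-seed species has no
#'   ortholog (scored `NA` downstream).
#' @param p_truncation Probability that a non-seed sequence is truncated
#'   near a site; truncated residues are recorded as `X` (sequence data
#'   unavailable), which maps to the `Incomplete` state downstream.
#' @param n_variants_per_species Splice variants simulated per species.
#' @param p_gap_segment Probability that a non-seed variant carries one
#'   internal deletion (a gap segment `-`, scored as substitutions).
#' @param planted_motif Optional [kinase_motif] planted at every true site
#'   (e.g. the ATM/ATR consensus); `NULL` plants a bare S/T center.
#' @param species Species codes, length `n_species`; first is the seed.
#' @param seed Integer RNG seed.
#' @return A validated `simulation_config` object.
#' @export
#' @examples
#' cfg <- simulation_config(n_species = 4, seq_length = 120,
#'                          n_true_sites = 2, n_decoy_sites = 2, seed = 1)
#' sim <- simulate_family(cfg)
#' sim$truth
simulation_config <- function(n_species = 11,
                              seq_length = 400,
                              n_true_sites = 5,
                              n_decoy_sites = 5,
                              p_sub_neutral = 0.3,
                              constraint_factor = 0.2,
                              p_species_missing = 0.15,
                              p_truncation = 0.05,
                              n_variants_per_species = 1,
                              p_gap_segment = 0,
                              planted_motif = NULL,
                              species = NULL,
                              seed = 1) {
  if (is.null(species)) {
    base <- default_species()
    species <- if (n_species <= length(base)) base[seq_len(n_species)]
               else c(base, sprintf("Sp.%02d", seq_len(n_species - length(base))))
  }
  cfg <- list(n_species = as.integer(n_species),
              seq_length = as.integer(seq_length),
              n_true_sites = as.integer(n_true_sites),
              n_decoy_sites = as.integer(n_decoy_sites),
              p_sub_neutral = p_sub_neutral,
              constraint_factor = constraint_factor,
              p_species_missing = p_species_missing,
              p_truncation = p_truncation,
              n_variants_per_species = as.integer(n_variants_per_species),
              p_gap_segment = p_gap_segment,
              planted_motif = planted_motif,
              species = species,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  probs <- c(cfg$p_sub_neutral, cfg$p_species_missing, cfg$p_truncation,
             cfg$p_gap_segment)
  if (any(probs < 0 | probs > 1))
    stop_pc("all probabilities must lie in [0,1]", "invalid_config")
  if (cfg$constraint_factor < 0 || cfg$constraint_factor > 1)
    stop_pc("constraint_factor must lie in [0,1]", "invalid_config")
  if (cfg$seq_length < 11L)
    stop_pc("seq_length must be >= 11", "invalid_config")
  if (cfg$n_species < 1L || length(cfg$species) != cfg$n_species)
    stop_pc("species list must have length n_species (>= 1)", "invalid_config")
  if (cfg$n_true_sites < 0L || cfg$n_decoy_sites < 0L ||
      cfg$n_true_sites + cfg$n_decoy_sites < 1L)
    stop_pc("need at least one site (true + decoy >= 1)", "invalid_config")
  if (cfg$n_variants_per_species < 1L)
    stop_pc("n_variants_per_species must be >= 1", "invalid_config")
  n_sites <- cfg$n_true_sites + cfg$n_decoy_sites
  # windows must fit (positions 6..L-5) and never overlap (pairwise >= 11)
  if (cfg$seq_length - 10L < (n_sites - 1L) * 11L + 1L)
    stop_pc(sprintf("seq_length %d too short for %d non-overlapping 11-mer windows",
                    cfg$seq_length, n_sites), "invalid_config")
  if (!is.null(cfg$planted_motif) && !inherits(cfg$planted_motif, "kinase_motif"))
    stop_pc("planted_motif must be a kinase_motif or NULL", "invalid_config")
  invisible(cfg)
}

#' Simulate a root protein sequence
#'
#' Draws a sequence over the 20 amino acids, uniform unless a composition
#' vector is supplied.  Deterministic for a fixed seed.
#'
#' @param length Sequence length in residues (>= 11).
#' @param composition Optional named probability vector over the 20 residues.
#' @param seed Optional integer seed applied before drawing.
#' @return Single protein sequence string.
#' @export
simulate_root_sequence <- function(length, composition = NULL, seed = NULL) {
  if (length < 11L)
    stop_pc("root sequence length must be >= 11", "invalid_config")
  if (!is.null(seed)) set.seed(seed)
  prob <- NULL
  if (!is.null(composition)) {
    if (is.null(names(composition)) || !all(names(composition) %in% AMINO_ACIDS))
      stop_pc("composition must be named by the 20 amino acids", "invalid_config")
    prob <- composition[AMINO_ACIDS]
    prob[is.na(prob)] <- 0
  }
  paste(sample(AMINO_ACIDS, length, replace = TRUE, prob = prob),
        collapse = "")
}

#' Plant a phosphosite motif into a sequence
#'
#' Rewrites the central residue (to `central`, or the first allowed central
#' residue of the motif) and every residue named by the motif's required
#' slots; no other position is touched.
#'
#' @param sequence Protein sequence string.
#' @param position 1-based position of the phospho-acceptor.
#' @param motif A [kinase_motif]; `NULL` plants only the central residue.
#' @param central Central residue to plant; must be allowed by the motif.
#' @return The rewritten sequence.
#' @export
#' @examples
#' plant_site(strrep("A", 11), 6, kinase_motif("ATM/ATR", c("S","T"),
#'                                             list(`+1` = "Q")))
plant_site <- function(sequence, position, motif = NULL, central = NULL) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (position < 1L || position > n)
    stop_pc(sprintf("site position %s outside sequence of length %d",
                    format(position), n), "invalid_position")
  allowed_central <- if (is.null(motif)) c("S", "T") else motif$central
  central <- central %||% allowed_central[1]
  if (!central %in% allowed_central)
    stop_pc(sprintf("central residue %s not allowed by motif", central),
            "invalid_config")
  chars[position] <- central
  if (!is.null(motif) && length(motif$slots)) {
    for (i in seq_along(motif$slots)) {
      off <- as.integer(names(motif$slots)[i])
      j <- position + off
      if (j < 1L || j > n)
        stop_pc(sprintf("motif offset %+d falls outside sequence at position %d",
                        off, position), "invalid_position")
      if (!chars[j] %in% motif$slots[[i]]) chars[j] <- motif$slots[[i]][1]
    }
  }
  paste(chars, collapse = "")
}

# Draw non-overlapping site positions with full windows inside the sequence.
draw_site_positions <- function(n_sites, seq_length) {
  lo <- 6L; hi <- seq_length - 5L
  for (i in seq_len(2000L)) {
    pos <- sort(sample(lo:hi, n_sites))
    if (n_sites == 1L || all(diff(pos) >= 11L)) return(pos)
  }
  # guaranteed-feasible deterministic fallback (validated in config)
  seq(lo, by = 11L, length.out = n_sites)
}

# Evolve one lineage from the seed: vector of per-position substitution
# probabilities; true centers flip S<->T, others draw uniformly from the 19
# non-identical residues.
evolve_lineage <- function(seed_chars, p_vec, true_centers) {
  hit <- stats::runif(length(seed_chars)) < p_vec
  out <- seed_chars
  for (j in which(hit)) {
    if (j %in% true_centers) {
      out[j] <- if (seed_chars[j] == "S") "T" else "S"
    } else {
      out[j] <- sample(setdiff(AMINO_ACIDS, seed_chars[j]), 1L)
    }
  }
  out
}

#' Simulate an aligned ortholog family with planted phosphosites
#'
#' Generates a star-phylogeny family under the model described in
#' [simulation_config()]: a root sequence with `n_true_sites` constrained
#' sites (optionally carrying a planted kinase motif) and `n_decoy_sites`
#' neutral sites, then one aligned ortholog per (species, variant).  The
#' substitution-only model preserves alignment columns, so the emitted
#' family is already aligned; optional gap segments (`p_gap_segment`) and
#' truncation to `X` exercise gap and missing-data handling.
#'
#' @param config A [simulation_config()].
#' @param protein_id Protein identifier for the family.
#' @return A list with elements `family` (an `ortholog_family`), `sites`
#'   (a phosphosite `data.frame`, see [read_site_table()]) and `truth`
#'   (a `data.frame` with site id, class, planted motif, and per-species
#'   realized substitution counts inside the window).
#' @export
simulate_family <- function(config, protein_id = "SIMPROT") {
  validate_simulation_config(config)
  set.seed(config$seed)
  L <- config$seq_length
  n_sites <- config$n_true_sites + config$n_decoy_sites

  root <- simulate_root_sequence(L)
  pos <- draw_site_positions(n_sites, L)
  cls <- rep(c("constrained", "neutral"),
             c(config$n_true_sites, config$n_decoy_sites))
  cls <- cls[sample.int(n_sites)]
  seed_seq <- root
  for (k in seq_len(n_sites)) {
    motif_k <- if (cls[k] == "constrained") config$planted_motif else NULL
    seed_seq <- plant_site(seed_seq, pos[k], motif_k,
                           central = sample(c("S", "T"), 1L))
  }
  seed_chars <- strsplit(seed_seq, "")[[1]]
  true_pos <- pos[cls == "constrained"]

  # per-position substitution probability: constrained inside true windows
  p_vec <- rep(config$p_sub_neutral, L)
  for (p in true_pos) {
    win <- max(1L, p - 5L):min(L, p + 5L)
    p_vec[win] <- config$p_sub_neutral * config$constraint_factor
  }

  species <- config$species
  seed_species <- species[1]
  seqs <- list()
  meta <- list()
  sub_counts <- matrix(NA_integer_, nrow = n_sites,
                       ncol = length(species) - 1L,
                       dimnames = list(NULL, setdiff(species, seed_species)))

  seqs[[paste(protein_id, seed_species, "variant1", sep = "|")]] <- seed_seq
  meta[[1]] <- data.frame(species = seed_species, variant = "variant1",
                          is_seed = TRUE, stringsAsFactors = FALSE)

  for (sp in setdiff(species, seed_species)) {
    if (stats::runif(1) < config$p_species_missing) next
    for (v in seq_len(config$n_variants_per_species)) {
      chars <- evolve_lineage(seed_chars, p_vec, true_pos)
      # optional internal deletion segment
      if (config$p_gap_segment > 0 && stats::runif(1) < config$p_gap_segment) {
        glen <- sample(1:5, 1L)
        gstart <- sample.int(L - glen + 1L, 1L)
        chars[gstart:(gstart + glen - 1L)] <- GAP_CHAR
      }
      # truncation near a random site: mask from the nearer terminus into
      # the site's window with X (sequence data unavailable)
      if (stats::runif(1) < config$p_truncation) {
        s <- sample(pos, 1L)
        cut <- s + sample(-5:5, 1L)
        cut <- min(max(cut, 1L), L)
        if (s <= L - s) chars[1:cut] <- UNKNOWN_CHAR
        else chars[cut:L] <- UNKNOWN_CHAR
      }
      if (v == 1L) {
        for (k in seq_len(n_sites)) {
          win <- max(1L, pos[k] - 5L):min(L, pos[k] + 5L)
          sub_counts[k, sp] <- sum(chars[win] != seed_chars[win] &
                                     chars[win] != UNKNOWN_CHAR)
        }
      }
      key <- paste(protein_id, sp, paste0("variant", v), sep = "|")
      seqs[[key]] <- paste(chars, collapse = "")
      meta[[length(meta) + 1L]] <-
        data.frame(species = sp, variant = paste0("variant", v),
                   is_seed = FALSE, stringsAsFactors = FALSE)
    }
  }

  members <- do.call(rbind, meta)
  fam <- new_ortholog_family(protein_id,
                             sequences = unlist(seqs),
                             members = members,
                             species_list = species)

  central <- seed_chars[pos]
  sites <- data.frame(protein_id = protein_id,
                      position = pos,
                      residue = central,
                      known_kinases = "",
                      observation_count = 1L + stats::rpois(n_sites, 2),
                      source = "synthetic",
                      stringsAsFactors = FALSE)

  truth <- data.frame(site_id = sprintf("%s_%s%d", protein_id, central, pos),
                      protein_id = protein_id,
                      position = pos,
                      class = cls,
                      planted_motif = if (is.null(config$planted_motif)) "none"
                                      else ifelse(cls == "constrained",
                                                  config$planted_motif$name,
                                                  "none"),
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(sub_counts, check.names = FALSE))

  list(family = fam, sites = sites, truth = truth)
}
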