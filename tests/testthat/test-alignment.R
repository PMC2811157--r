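test_that("seed positions map to alignment columns through gaps", {
  fam <- fam_from_seqs("P1", c("H.sap|variant1" = strrep("A", 15),
                               "M.mus|variant1" = strrep("A", 15)))
  expect_identical(map_position_to_column(fam, 12), 12L)

  gapped <- fam_from_seqs("P1", c("H.sap|variant1" = "--MK-S",
                                  "M.mus|variant1" = "AAMKAS"))
  expect_identical(map_position_to_column(gapped, 3), 6L)
  expect_identical(map_position_to_column(gapped, 1), 3L)
  expect_error(map_position_to_column(gapped, 0), class = "invalid_position")
  expect_error(map_position_to_column(gapped, 4), class = "invalid_position")

  set.seed(101)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    chars <- sample(c(AAS, "-"), n, replace = TRUE, prob = c(rep(1, 20), 6))
    if (!any(chars != "-")) chars[1] <- "M"
    seed <- paste(chars, collapse = "")
    f <- fam_from_seqs("P1", c("H.sap|variant1" = seed,
                               "M.mus|variant1" = paste(
                                 sample(AAS, n, replace = TRUE), collapse = "")))
    pos <- sample(sum(chars != "-"), 1)
    expect_identical(map_position_to_column(f, pos), oracle_column(seed, pos))
  }
})

test_that("windows truncate at termini and preserve gap vs unknown states", {
  seqs <- c("H.sap|variant1" = "MKLSTQAAAHWMCDE",
            "M.mus|variant1" = "MKLSTQAAAHWMCDE")
  fam <- fam_from_seqs("P1", seqs)
  # site 5 residues from the C-terminus (position 11 of 15): 5 N + 4 C flanks
  w <- extract_window(fam, "M.mus", column = map_position_to_column(fam, 11))
  expect_identical(nrow(w$flanks), 9L)
  expect_identical(sum(w$flanks$offset < 0), 5L)
  expect_identical(sum(w$flanks$offset > 0), 4L)
  # window center always carries the seed phospho-residue
  expect_identical(w$central_pair[["seed"]], "W")

  gap_orth <- fam_from_seqs("P1", c("H.sap|variant1" = "MKLSTQAAAHW",
                                    "M.mus|variant1" = "M----------"))
  wg <- extract_window(gap_orth, "M.mus", column = 6)
  expect_identical(wg$flanks$orth,
                   ifelse(wg$flanks$offset == -5, "M", "-"))
  expect_identical(wg$central_pair[["orth"]], "-")

  expect_error(extract_window(fam, "D.rer", column = 6),
               class = "species_missing")
})

test_that("extracted windows equal a brute-force scan of simulated alignments", {
  cfg <- simulation_config(n_species = 8, seq_length = 180, n_true_sites = 2,
                           n_decoy_sites = 2, seed = 21, p_truncation = 0.25,
                           p_gap_segment = 0.25)
  sim <- simulate_family(cfg)
  fam <- sim$family
  seed_aln <- family_seed(fam)
  for (p in sim$sites$position) {
    col <- map_position_to_column(fam, p)
    for (sp in setdiff(family_species(fam), "H.sap")) {
      w <- extract_window(fam, sp, column = col)
      got <- window_conservation(w)
      want <- oracle_species_score(seed_aln,
                                   fam$sequences[fam$members$species == sp][1],
                                   p)
      expect_identical(got$status, want$status)
      if (want$status == "numeric") {
        expect_equal(got$window_score, want$score)
        expect_identical(got$central_conserved, want$central)
        expect_identical(got$n_comparable_flanks, want$n_comp)
      }
    }
  }
})

test_that("variant selection maximizes window evidence with deterministic ties", {
  # single variant: returned as-is
  fam1 <- fam_from_seqs("P1", c("H.sap|variant1" = "AAAAASQAAAA",
                                "M.mus|variant1" = "AAAAASQAAAA"))
  expect_identical(select_variant(fam1, "M.mus", 6), "variant1")

  # variant A scores 0.9 (1 flank substitution), B scores 0.6 (4)
  fam2 <- fam_from_seqs("P1", c(
    "H.sap|variant1" = "AAAAASQAAAA",
    "M.mus|variantA" = "AAAAASQAAAG",
    "M.mus|variantB" = "GGAAASQAAGG"))
  expect_identical(select_variant(fam2, "M.mus", 6), "variantA")

  # randomized 3-variant families agree with exhaustive oracle enumeration
  set.seed(77)
  for (i in 1:30) {
    seed <- paste(sample(AAS, 15, replace = TRUE), collapse = "")
    seed <- plant_site(seed, 8)
    variants <- lapply(1:3, function(v) {
      chars <- strsplit(seed, "")[[1]]
      idx <- sample(15, sample(0:6, 1))
      chars[idx] <- sample(c(AAS, "-", "X"), length(idx), replace = TRUE)
      paste(chars, collapse = "")
    })
    names(variants) <- paste0("M.mus|variant", 1:3)
    fam <- fam_from_seqs("P1", c(c("H.sap|variant1" = seed), unlist(variants)))
    picked <- select_variant(fam, "M.mus", 8)
    # oracle: exhaustive enumeration with the documented ordering
    stats <- lapply(1:3, function(v) {
      sc <- oracle_species_score(seed, variants[[v]], 8)
      c(num = as.numeric(sc$status == "numeric"),
        score = if (sc$status == "numeric") sc$score else -1,
        central = if (sc$status == "numeric") as.numeric(sc$central) else -1,
        len = sum(strsplit(variants[[v]], "")[[1]] != "-"))
    })
    km <- do.call(rbind, stats)
    ord <- order(-km[, "num"], -km[, "score"], -km[, "central"], -km[, "len"],
                 paste0("variant", 1:3))
    expect_identical(picked, paste0("variant", ord[1]))
  }

  # permutation invariance of input order
  fam_rev <- fam_from_seqs("P1", c(
    "M.mus|variantB" = "GGAAASQAAGG",
    "M.mus|variantA" = "AAAAASQAAAG",
    "H.sap|variant1" = "AAAAASQAAAA"), seed_key = "H.sap|variant1")
  expect_identical(select_variant(fam_rev, "M.mus", 6),
                   select_variant(fam2, "M.mus", 6))
})
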