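test_that("motif construction validates offsets and residue sets", {
  expect_error(kinase_motif("bad", central = "A"), class = "invalid_motif")
  expect_error(kinase_motif("bad", central = "S", slots = list(`0` = "Q")),
               class = "invalid_motif")
  expect_error(kinase_motif("bad", central = "S", slots = list(`+6` = "Q")),
               class = "invalid_motif")
  expect_error(kinase_motif("bad", central = "S", slots = list(`+1` = "B")),
               class = "invalid_motif")
  m <- kinase_motif("ATM/ATR", c("T", "S"), list(`+1` = "Q"))
  expect_identical(m$central, c("S", "T"))
})

test_that("the default library carries the documented consensus set", {
  lib <- default_motif_library()
  expect_setequal(names(lib), c("ATM/ATR", "CDK", "CDK-strict", "Plk1",
                                "PBD-docking", "Chk1/2"))
  expect_identical(lib[["ATM/ATR"]]$central, c("S", "T"))
  expect_identical(lib[["ATM/ATR"]]$slots[["+1"]], "Q")
  expect_identical(lib[["CDK"]]$slots[["+1"]], "P")
  expect_setequal(lib[["CDK-strict"]]$slots[["+3"]], c("K", "R"))
  expect_setequal(lib[["Plk1"]]$slots[["-2"]], c("D", "E"))
  expect_identical(lib[["PBD-docking"]]$slots[["-1"]], "S")
  expect_identical(lib[["PBD-docking"]]$slots[["+1"]], "P")
  expect_identical(lib[["PBD-docking"]]$kinase, "PBD")
  expect_identical(lib[["Chk1/2"]]$slots[["-3"]], "R")
})

test_that("match_motif applies the consensus at a position", {
  lib <- default_motif_library()
  # ATM/ATR [ST]Q context
  expect_true(match_motif("AGQLSQEYAA", 5, lib[["ATM/ATR"]]))
  expect_false(match_motif("AGQLSAEYAA", 5, lib[["ATM/ATR"]]))
  # S-pS-P context: both the minimal CDK consensus and the PBD docking motif
  pep <- "PFIVPSSPTEQEGRY"
  expect_true(match_motif(pep, 7, lib[["CDK"]]))
  expect_true(match_motif(pep, 7, lib[["PBD-docking"]]))
  # S followed by Q is not a CDK site
  expect_false(match_motif("AAAASQAAAA", 5, lib[["CDK"]]))
  # required slot outside the sequence fails the match
  expect_false(match_motif("SP", 1, lib[["Plk1"]]))
  expect_error(match_motif("AAAA", 9, lib[["CDK"]]), class = "invalid_position")
})

test_that("matching is invariant to changes outside required slots", {
  set.seed(55)
  lib <- default_motif_library()
  for (i in 1:200) {
    m <- lib[[sample(length(lib), 1)]]
    seq <- paste(sample(AAS, 15, replace = TRUE), collapse = "")
    pos <- sample(6:10, 1)
    base <- match_motif(seq, pos, m)
    expect_identical(base, oracle_match_motif(seq, pos, m))
    touched <- pos + c(0L, if (length(m$slots)) as.integer(names(m$slots)))
    free <- setdiff(seq_len(15), touched)
    chars <- strsplit(seq, "")[[1]]
    chars[sample(free, 3)] <- sample(AAS, 3, replace = TRUE)
    expect_identical(match_motif(paste(chars, collapse = ""), pos, m), base)
  }
})

test_that("annotation keeps known kinases and predicts only when unknown", {
  fx <- synthetic_chk2_fha()
  sites <- fx$sites

  # T68 has a known kinase: provenance known, regardless of motifs
  a68 <- annotate_site(sites[1, ], fx$family)
  expect_identical(a68$assigned_kinases$kinase, "ATM")
  expect_identical(a68$assigned_kinases$provenance, "known")
  expect_true("ATM/ATR" %in% a68$matched_motifs)

  # S164 has none: the Plk1 consensus match is predicted
  a164 <- annotate_site(sites[sites$position == 164, ], fx$family)
  expect_true("Plk1" %in% a164$assigned_kinases$kinase)
  expect_true(all(a164$assigned_kinases$provenance == "predicted"))
  expect_equal(a164$motif_conservation[["Plk1"]], 1.0)

  # external predictions are merged as predicted annotations
  preds <- data.frame(protein_id = "CHK2", position = 164L,
                      kinase = "PLK3", score = 0.8, stringsAsFactors = FALSE)
  a_ext <- annotate_site(sites[sites$position == 164, ], fx$family,
                         external_predictions = preds)
  expect_true("PLK3" %in% a_ext$assigned_kinases$kinase)

  expect_error(annotate_site(data.frame(protein_id = "OTHER", position = 5,
                                        residue = "S", known_kinases = "",
                                        observation_count = 1,
                                        source = "x"), fx$family),
               class = "input_error")
})

test_that("a frozen planted consensus is fully conserved across species", {
  plk <- kinase_motif("Plk1", c("S", "T"), list(`-2` = c("D", "E")))
  cfg <- simulation_config(n_species = 8, seq_length = 200, n_true_sites = 2,
                           n_decoy_sites = 0, constraint_factor = 0,
                           p_species_missing = 0, p_truncation = 0,
                           planted_motif = plk, seed = 33)
  sim <- simulate_family(cfg)
  for (i in seq_len(nrow(sim$sites))) {
    a <- annotate_site(sim$sites[i, ], sim$family)
    expect_true("Plk1" %in% a$matched_motifs)
    expect_equal(a$motif_conservation[["Plk1"]], 1.0)
  }
})

test_that("the recurrent-conserved-consensus filter selects exactly the planted sites", {
  fx <- synthetic_chk2_fha()
  summ <- lapply(seq_len(nrow(fx$sites)), function(i)
    summarize_site(fx$family, fx$sites$position[i], fx$sites$residue[i]))
  ann <- lapply(seq_len(nrow(fx$sites)), function(i)
    annotate_site(fx$sites[i, ], fx$family))

  kept <- filter_recurrent_conserved(fx$sites, ann, summ)
  expect_identical(kept$position, fx$expected_positions)

  # observed-once site is dropped even though fully conserved with motif
  a100 <- ann[[which(fx$sites$position == 100)]]
  expect_true("Plk1" %in% a100$matched_motifs)
  expect_equal(a100$motif_conservation[["Plk1"]], 1.0)
  expect_false(100 %in% kept$position)

  # recurrent site without the seed consensus is dropped
  expect_false(68 %in% kept$position)

  # raising min_observations never adds sites (monotonicity)
  for (mo in 1:5) {
    k <- filter_recurrent_conserved(fx$sites, ann, summ,
                                    min_observations = mo)
    if (mo > 1)
      expect_true(all(k$position %in% prev$position))
    prev <- k
  }

  # lowering the conservation threshold recovers the partially conserved decoys
  k0 <- filter_recurrent_conserved(fx$sites, ann, summ,
                                   conservation_threshold = 0.6)
  expect_true(all(c(120, 140, 164, 205, 210) %in% k0$position))

  expect_error(filter_recurrent_conserved(fx$sites, ann, summ,
                                          motif_name = "NoSuch"),
               class = "config_error")
})
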