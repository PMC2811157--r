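# Independent brute-force oracles and small in-code fixtures.
# The oracles deliberately re-derive each quantity with plain loops over the
# raw aligned strings so they share no code with the implementation.

AAS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Build an ortholog_family through the public FASTA interface.
# seqs: named character vector "species|variantN" -> aligned sequence.
fam_from_seqs <- function(protein, seqs, seed_key = names(seqs)[1],
                          species_list = default_species()) {
  path <- tempfile(fileext = ".fasta")
  lines <- unlist(lapply(names(seqs), function(k) {
    hdr <- paste0(">", protein, "|", k, if (k == seed_key) "|seed" else "")
    c(hdr, seqs[[k]])
  }))
  writeLines(lines, path)
  read_family(path, species_list = species_list)
}

# Brute-force: 1-based alignment column of the position-th seed residue.
oracle_column <- function(seed_aln, position) {
  chars <- strsplit(seed_aln, "")[[1]]
  seen <- 0L
  for (j in seq_along(chars)) {
    if (chars[j] != "-") {
      seen <- seen + 1L
      if (seen == position) return(j)
    }
  }
  stop("position beyond seed")
}

# Brute-force per-species window score from the raw aligned strings.
# Returns list(status, score, central, n_comp).  Mirrors the scoring rules
# by explicit case analysis.
oracle_species_score <- function(seed_aln, orth_aln, position, flank = 5L) {
  sc <- strsplit(seed_aln, "")[[1]]
  oc <- strsplit(orth_aln, "")[[1]]
  res_cols <- which(sc != "-")
  center <- res_cols[position]
  k <- match(center, res_cols)
  flank_cols <- c()
  for (d in seq_len(flank)) {
    if (k - d >= 1) flank_cols <- c(flank_cols, res_cols[k - d])
    if (k + d <= length(res_cols)) flank_cols <- c(flank_cols, res_cols[k + d])
  }
  if (oc[center] == "X") return(list(status = "Incomplete"))
  seed_c <- sc[center]; orth_c <- oc[center]
  central_ok <- (seed_c == orth_c) ||
    (seed_c %in% c("S", "T") && orth_c %in% c("S", "T"))
  n_comp <- 0L; n_id <- 0L
  for (j in flank_cols) {
    if (oc[j] == "X") next
    n_comp <- n_comp + 1L
    if (oc[j] != "-" && oc[j] == sc[j]) n_id <- n_id + 1L
  }
  if (!central_ok)
    return(list(status = "numeric", score = 0, central = FALSE,
                n_comp = n_comp))
  if (n_comp == 0L) return(list(status = "Incomplete"))
  list(status = "numeric", score = n_id / n_comp, central = TRUE,
       n_comp = n_comp)
}

# Brute-force motif slot checker over a character vector.
oracle_match_motif <- function(sequence, position, motif) {
  chars <- strsplit(sequence, "")[[1]]
  if (!chars[position] %in% motif$central) return(FALSE)
  offs <- if (length(motif$slots)) as.integer(names(motif$slots)) else integer(0)
  for (i in seq_along(offs)) {
    j <- position + offs[i]
    if (j < 1 || j > length(chars)) return(FALSE)
    if (!chars[j] %in% motif$slots[[i]]) return(FALSE)
  }
  TRUE
}

# Construct a site_window directly (the documented structure), for unit
# tests of window_conservation in isolation from alignment extraction.
make_window <- function(seed_center, orth_center, flank_seed, flank_orth,
                        species = "M.mus") {
  n <- length(flank_seed)
  offs <- setdiff(seq(-ceiling(n / 2), ceiling(n / 2)), 0)[seq_len(n)]
  structure(list(species = species, variant = "variant1",
                 central_column = NA_integer_,
                 central_pair = c(seed = seed_center, orth = orth_center),
                 flanks = data.frame(offset = offs, seed = flank_seed,
                                     orth = flank_orth,
                                     stringsAsFactors = FALSE)),
            class = "site_window")
}

# Draw a random site_window with gaps/unknowns sprinkled on the ortholog.
random_window <- function() {
  n_fl <- sample(0:10, 1)
  fs <- sample(AAS, n_fl, replace = TRUE)
  fo <- vapply(fs, function(r) {
    u <- runif(1)
    if (u < 0.45) r
    else if (u < 0.8) sample(AAS, 1)
    else if (u < 0.9) "-"
    else "X"
  }, "", USE.NAMES = FALSE)
  sc <- sample(c("S", "T", "Y"), 1)
  oc <- sample(c(AAS, "-", "X"), 1)
  make_window(sc, oc, fs, fo)
}

# Brute-force score of a constructed site_window.
oracle_window_score <- function(w) {
  if (w$central_pair[["orth"]] == "X") return(list(status = "Incomplete"))
  seed_c <- w$central_pair[["seed"]]; orth_c <- w$central_pair[["orth"]]
  central_ok <- (seed_c == orth_c) ||
    (seed_c %in% c("S", "T") && orth_c %in% c("S", "T"))
  n_comp <- 0L; n_id <- 0L
  for (i in seq_len(nrow(w$flanks))) {
    o <- w$flanks$orth[i]
    if (o == "X") next
    n_comp <- n_comp + 1L
    if (o != "-" && o == w$flanks$seed[i]) n_id <- n_id + 1L
  }
  if (!central_ok)
    return(list(status = "numeric", score = 0, central = FALSE))
  if (n_comp == 0L) return(list(status = "Incomplete"))
  list(status = "numeric", score = n_id / n_comp, central = TRUE)
}

# Hand-built summary/annotation records for network-layer tests.
make_species_score <- function(species, status = "numeric", score = NA_real_,
                               central = NA, n_comp = NA_integer_) {
  structure(list(species = species, variant = "variant1", status = status,
                 window_score = score, central_conserved = central,
                 n_comparable_flanks = n_comp),
            class = "species_score")
}

make_summary <- function(protein, position, residue = "S",
                         scores = list(), include_self = FALSE) {
  site_summary(scores, include_self = include_self,
               protein_id = protein, position = position, residue = residue)
}

make_annotation <- function(protein, position, residue = "S",
                            kinases = character(), provenance = character(),
                            motifs = character(), mc = numeric(),
                            pbd = FALSE) {
  structure(list(protein_id = protein, position = as.integer(position),
                 residue = residue, matched_motifs = motifs,
                 assigned_kinases = data.frame(kinase = kinases,
                                               provenance = provenance,
                                               stringsAsFactors = FALSE),
                 pbd_site = pbd,
                 motif_conservation = stats::setNames(mc, names(mc)),
                 library_motifs = names(default_motif_library())),
            class = "site_annotation")
}

# Random small network for export round-trip fuzzing.
random_network <- function() {
  n_prot <- sample(1:4, 1)
  prots <- paste0("P", seq_len(n_prot))
  sites <- do.call(rbind, lapply(prots, function(p) {
    k <- sample(1:3, 1)
    data.frame(protein_id = p, position = sort(sample(10:300, k)),
               residue = sample(c("S", "T", "Y"), k, replace = TRUE),
               known_kinases = sample(c("", "ATM", "PLK1;CDK1"), k,
                                      replace = TRUE),
               observation_count = sample(1:5, k, replace = TRUE),
               source = "synthetic", stringsAsFactors = FALSE)
  }))
  summaries <- lapply(seq_len(nrow(sites)), function(i) {
    sp <- sample(default_species()[-1], 3)
    make_summary(sites$protein_id[i], sites$position[i], sites$residue[i],
                 scores = lapply(sp, function(s)
                   make_species_score(s, score = round(runif(1), 3),
                                      central = TRUE, n_comp = 8L)))
  })
  annotations <- lapply(seq_len(nrow(sites)), function(i)
    make_annotation(sites$protein_id[i], sites$position[i],
                    sites$residue[i],
                    kinases = "CDK1", provenance = "predicted",
                    motifs = "CDK", mc = c(CDK = round(runif(1), 3)),
                    pbd = runif(1) < 0.3))
  edges <- if (n_prot >= 2)
    data.frame(from = prots[1], to = prots[2], label = "interaction",
               stringsAsFactors = FALSE)
  else NULL
  build_network(sites, summaries, annotations, edges)
}
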