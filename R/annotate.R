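# Does a motif hold in one species' extracted window?  Required slots are
# looked up by seed-relative offset; a slot absent from the window (seed
# terminus), or holding a gap or unknown residue, fails the motif.
motif_holds_in_window <- function(window, motif) {
  orth_c <- window$central_pair[["orth"]]
  if (!orth_c %in% motif$central) return(FALSE)
  for (i in seq_along(motif$slots)) {
    off <- as.integer(names(motif$slots)[i])
    j <- match(off, window$flanks$offset)
    if (is.na(j)) return(FALSE)
    if (!window$flanks$orth[j] %in% motif$slots[[i]]) return(FALSE)
  }
  TRUE
}

#' Annotate a phosphosite with kinase motifs and docking-site predictions
#'
#' Known upstream kinases from the site record are always retained with
#' provenance `known`.  When no kinase is known, the site is assigned the
#' kinases of the consensus motifs matching the seed sequence (plus any
#' rows of `external_predictions` for the site, e.g. NetworKIN-style
#' output) with provenance `predicted`.  For each motif matching the seed,
#' motif conservation is the fraction of non-seed species present in the
#' family whose selected-variant window also satisfies the motif (required
#' slots landing on gaps or unknown residues count as failure).
#'
#' @param site One site: a single-row `data.frame` (see
#'   [read_site_table()]) or an equivalent list.
#' @param family The site's `ortholog_family`.
#' @param library A `motif_library` (default [default_motif_library()]).
#' @param external_predictions Optional `data.frame` with columns
#'   `protein_id`, `position`, `kinase` (and optionally `score`), consumed
#'   as predicted annotations.
#' @param flank Flank width (default 5).
#' @return A `site_annotation`: list with the site reference,
#'   `matched_motifs`, `assigned_kinases` (`data.frame` of kinase +
#'   provenance), `pbd_site`, and named `motif_conservation` fractions.
#' @export
annotate_site <- function(site, family, library = default_motif_library(),
                          external_predictions = NULL, flank = 5L) {
  site <- as.list(site)
  if (!identical(site$protein_id, family$protein_id))
    stop_pc(sprintf("site protein %s does not match family %s",
                    site$protein_id, family$protein_id), "input_error")
  seed_ungapped <- family_seed(family, ungapped = TRUE)
  position <- as.integer(site$position)
  matched <- names(library)[vapply(library, function(m)
    match_motif(seed_ungapped, position, m), NA)]

  column <- map_position_to_column(family, position)
  seed_sp <- family$members$species[family_seed_index(family)]
  present <- setdiff(intersect(family$species_list, family_species(family)),
                     seed_sp)
  motif_cons <- vapply(matched, function(nm) {
    m <- library[[nm]]
    if (!length(present)) return(NA_real_)
    holds <- vapply(present, function(sp) {
      v <- select_variant(family, sp, column, flank)
      motif_holds_in_window(extract_window(family, sp, v, column, flank), m)
    }, NA)
    mean(holds)
  }, 0)

  known <- split_kinases(site$known_kinases)[[1]]
  if (length(known)) {
    assigned <- data.frame(kinase = known, provenance = "known",
                           stringsAsFactors = FALSE)
  } else {
    pred <- unique(vapply(library[matched], `[[`, "", "kinase"))
    pred <- setdiff(pred, "PBD")
    if (!is.null(external_predictions)) {
      hit <- external_predictions$protein_id == site$protein_id &
        as.integer(external_predictions$position) == position
      pred <- unique(c(pred, external_predictions$kinase[hit]))
    }
    assigned <- data.frame(kinase = pred,
                           provenance = rep("predicted", length(pred)),
                           stringsAsFactors = FALSE)
  }
  pbd_motifs <- names(library)[vapply(library, function(m)
    identical(m$kinase, "PBD"), NA)]
  structure(list(protein_id = site$protein_id, position = position,
                 residue = site$residue,
                 matched_motifs = matched,
                 assigned_kinases = assigned,
                 pbd_site = any(matched %in% pbd_motifs),
                 motif_conservation = motif_cons,
                 library_motifs = names(library)),
            class = "site_annotation")
}

site_key <- function(protein_id, position) paste(protein_id, position, sep = "@")

#' Filter recurrent, conserved kinase-consensus sites
#'
#' Retains sites that were (i) observed at least `min_observations` times,
#' (ii) have an evolutionarily conserved phospho-acceptor
#' (central conservation rate >= `conservation_threshold`), and (iii) carry
#' the named consensus motif on the seed with motif conservation >=
#' `conservation_threshold`.  The default threshold of 1 requires the
#' criterion in every scored species.  Output order equals input order.
#'
#' @param sites Site `data.frame` (see [read_site_table()]).
#' @param annotations List of `site_annotation`, covering all sites.
#' @param summaries List of `conservation_summary`, covering all sites.
#' @param min_observations Minimum observation count (default 2).
#' @param motif_name Consensus motif to require (default `"Plk1"`,
#'   the \[D/E\]X\[S/T\] consensus).
#' @param conservation_threshold Fraction of scored species required to
#'   conserve the phospho-acceptor and the motif (default 1).
#' @return The retained subset of `sites`.
#' @export
filter_recurrent_conserved <- function(sites, annotations, summaries,
                                       min_observations = 2L,
                                       motif_name = "Plk1",
                                       conservation_threshold = 1.0) {
  if (!length(annotations))
    stop_pc("no annotations supplied", "input_error")
  if (!motif_name %in% annotations[[1]]$library_motifs)
    stop_pc(sprintf("unknown motif name '%s' (library has: %s)", motif_name,
                    paste(annotations[[1]]$library_motifs, collapse = ", ")),
            "config_error")
  ann_keys <- vapply(annotations, function(a) site_key(a$protein_id, a$position), "")
  sum_keys <- vapply(summaries, function(s) site_key(s$protein_id, s$position), "")
  keep <- vapply(seq_len(nrow(sites)), function(i) {
    key <- site_key(sites$protein_id[i], sites$position[i])
    ai <- match(key, ann_keys); si <- match(key, sum_keys)
    if (is.na(ai) || is.na(si))
      stop_pc(sprintf("site %s lacks annotation or summary coverage", key),
              "input_error")
    if (sites$observation_count[i] < min_observations) return(FALSE)
    rate <- summaries[[si]]$central_conservation_rate
    if (is.na(rate) || rate < conservation_threshold) return(FALSE)
    mc <- annotations[[ai]]$motif_conservation
    if (!motif_name %in% names(mc)) return(FALSE)  # motif absent from seed
    !is.na(mc[[motif_name]]) && mc[[motif_name]] >= conservation_threshold
  }, NA)
  sites[keep, , drop = FALSE]
}
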