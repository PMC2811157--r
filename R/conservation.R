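#' Central phospho-acceptor conservation rule
#'
#' S and T are interchangeable phospho-acceptors: the central residue is
#' conserved iff the ortholog residue is identical, or both residues lie in
#' \{S, T\}.  Replacement by Y (or any other residue), a gap, or an unknown
#' residue breaks conservation; a seed Y is conserved only by Y.
#'
#' @param seed_residue Seed phospho-residue, one of S/T/Y.
#' @param ortholog_residue Aligned ortholog residue, `-` for gap, `X` for
#'   unknown.
#' @return Logical scalar.
#' @export
#' @examples
#' central_conserved("S", "T")  # TRUE: S<->T permitted
#' central_conserved("S", "Y")  # FALSE: S/T -> Y not permitted
central_conserved <- function(seed_residue, ortholog_residue) {
  if (!seed_residue %in% c("S", "T", "Y"))
    stop_pc(sprintf("seed residue must be S, T or Y (got '%s')", seed_residue),
            "invalid_residue")
  if (identical(seed_residue, ortholog_residue)) return(TRUE)
  all(c(seed_residue, ortholog_residue) %in% c("S", "T"))
}

#' Score the conservation of one species' site window
#'
#' Computes the per-species window conservation of a [extract_window()]
#' result.  Comparable flanks are pairs where the seed holds a residue and
#' the ortholog holds a residue or a gap (an ortholog gap counts as a
#' non-conserved comparable position; an unknown `X` is excluded from the
#' denominator).  The score is identical flanks / comparable flanks.  If
#' the central phospho-acceptor is not conserved the score is 0 (numeric),
#' mirroring the convention that loss of the phospho-residue zeroes the
#' site.  An unknown central residue, or a conserved center with zero
#' comparable flanks, yields status `Incomplete`.
#'
#' @param window A `site_window`.
#' @return A `species_score`: list with `species`, `status`
#'   (`"numeric"`/`"Incomplete"`), `window_score`, `central_conserved`, and
#'   `n_comparable_flanks`.
#' @export
window_conservation <- function(window) {
  stopifnot(inherits(window, "site_window"))
  seed_c <- window$central_pair[["seed"]]
  orth_c <- window$central_pair[["orth"]]
  fl <- window$flanks
  comparable <- fl$orth != UNKNOWN_CHAR
  identical_fl <- comparable & fl$orth == fl$seed & fl$orth != GAP_CHAR
  n_comp <- sum(comparable)

  res <- list(species = window$species, variant = window$variant,
              status = "numeric", window_score = NA_real_,
              central_conserved = NA, n_comparable_flanks = n_comp)
  if (orth_c == UNKNOWN_CHAR) {
    res$status <- "Incomplete"
    return(structure(res, class = "species_score"))
  }
  cc <- central_conserved(seed_c, orth_c)
  res$central_conserved <- cc
  if (!cc) {
    res$window_score <- 0
  } else if (n_comp == 0L) {
    # no flank evidence at all: do not report 1.0 over an empty set
    res$status <- "Incomplete"
    res$central_conserved <- NA
  } else {
    res$window_score <- sum(identical_fl) / n_comp
  }
  structure(res, class = "species_score")
}

# Score one declared species for a site, resolving variant choice and the
# NA (species absent) state.
score_species <- function(family, species, column, flank = 5L) {
  if (!species %in% family_species(family)) {
    return(structure(list(species = species, variant = NA_character_,
                          status = "NA", window_score = NA_real_,
                          central_conserved = NA,
                          n_comparable_flanks = NA_integer_),
                     class = "species_score"))
  }
  v <- select_variant(family, species, column, flank)
  window_conservation(extract_window(family, species, v, column, flank))
}

species_scores_df <- function(scores) {
  do.call(rbind, lapply(scores, function(s)
    data.frame(species = s$species, variant = s$variant, status = s$status,
               window_score = s$window_score,
               central_conserved = s$central_conserved,
               n_comparable_flanks = s$n_comparable_flanks,
               stringsAsFactors = FALSE)))
}

#' Aggregate per-species scores into a site-level conservation summary
#'
#' The site-level mean window conservation is the arithmetic mean of the
#' numeric per-species window scores; `NA` and `Incomplete` species are
#' excluded, as is the seed's self-comparison unless `include_self = TRUE`.
#' The central conservation rate is the fraction of numeric species whose
#' central phospho-acceptor is conserved.  With no numeric species both
#' aggregates are `NA`.
#'
#' @param scores List of `species_score` objects (at most one per species).
#' @param include_self Include the seed species' self-comparison row in the
#'   aggregates (default `FALSE`).
#' @param seed_species Species code of the seed (default `"H.sap"`).
#' @param protein_id,position,residue Site identity carried on the summary.
#' @return A `conservation_summary`: list with the site reference, the
#'   per-species score table, `mean_window_conservation` and
#'   `central_conservation_rate`.
#' @export
site_summary <- function(scores, include_self = FALSE,
                         seed_species = "H.sap",
                         protein_id = NA_character_,
                         position = NA_integer_, residue = NA_character_) {
  df <- species_scores_df(scores)
  if (anyDuplicated(df$species))
    stop_pc("duplicate species in score list", "input_error")
  agg <- df
  if (!include_self) agg <- agg[agg$species != seed_species, , drop = FALSE]
  num <- agg[agg$status == "numeric", , drop = FALSE]
  mean_cons <- if (nrow(num)) mean(num$window_score) else NA_real_
  central_rate <- if (nrow(num)) mean(num$central_conserved) else NA_real_
  structure(list(protein_id = protein_id, position = position,
                 residue = residue, species_scores = df,
                 mean_window_conservation = mean_cons,
                 central_conservation_rate = central_rate,
                 include_self = include_self),
            class = "conservation_summary")
}

#' @export
print.conservation_summary <- function(x, ...) {
  cat(sprintf("<conservation_summary> %s %s%s: mean window %.3f, central rate %s\n",
              x$protein_id, x$residue %||% "", x$position,
              x$mean_window_conservation,
              ifelse(is.na(x$central_conservation_rate), "NA",
                     sprintf("%.3f", x$central_conservation_rate))))
  invisible(x)
}

#' Summarize the conservation of one mapped site across a family
#'
#' Convenience wrapper: maps the seed position to its alignment column,
#' scores every declared species (choosing the best splice variant per
#' species) and aggregates with [site_summary()].
#'
#' @param family An `ortholog_family`.
#' @param position 1-based seed residue position.
#' @param residue Expected seed residue (S/T/Y); checked against the seed
#'   sequence if supplied.
#' @param flank Flank width (default 5).
#' @param include_self Passed to [site_summary()].
#' @return A `conservation_summary`.
#' @export
summarize_site <- function(family, position, residue = NULL, flank = 5L,
                           include_self = FALSE) {
  column <- map_position_to_column(family, position)
  seed_res <- substr(family_seed(family), column, column)
  if (!is.null(residue) && !identical(residue, seed_res))
    stop_pc(sprintf("site %s/%d: seed residue is %s, site table says %s",
                    family$protein_id, position, seed_res, residue),
            "input_error")
  seed_sp <- family$members$species[family_seed_index(family)]
  scores <- lapply(family$species_list, function(sp)
    score_species(family, sp, column, flank))
  site_summary(scores, include_self = include_self, seed_species = seed_sp,
               protein_id = family$protein_id, position = position,
               residue = seed_res)
}
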