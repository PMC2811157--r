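#' Map a seed residue position to an alignment column
#'
#' Converts a 1-based residue index on the ungapped human seed sequence
#' (the coordinate system in which phosphosites are reported, e.g.
#' "Ser139") to the 1-based alignment column holding that residue.
#'
#' @param family An `ortholog_family`.
#' @param position 1-based residue index on the ungapped seed.
#' @return 1-based alignment column index.
#' @export
map_position_to_column <- function(family, position) {
  seed <- strsplit(family_seed(family), "")[[1]]
  is_res <- seed != GAP_CHAR
  n_res <- sum(is_res)
  if (length(position) != 1L || is.na(position) || position < 1L ||
      position > n_res)
    stop_pc(sprintf("position %s outside ungapped seed of length %d",
                    format(position), n_res), "invalid_position")
  which(cumsum(is_res) == position & is_res)[1]
}

# Alignment columns of seed residues at offsets -flank..-1, +1..+flank
# relative to the residue in `column`.  Offsets beyond the seed termini are
# absent (never padded).
seed_flank_columns <- function(seed_chars, column, flank) {
  res_cols <- which(seed_chars != GAP_CHAR)
  k <- match(column, res_cols)
  if (is.na(k))
    stop_pc(sprintf("column %d does not hold a seed residue", column),
            "invalid_position")
  offs <- setdiff(seq(-flank, flank), 0L)
  idx <- k + offs
  keep <- idx >= 1L & idx <= length(res_cols)
  data.frame(offset = offs[keep], column = res_cols[idx[keep]])
}

#' Extract the -flank/+flank site window for one ortholog
#'
#' Pairs the seed residues around an alignment column with the residues of
#' one (species, variant) sequence at the same columns.  Windows are
#' truncated at the seed termini (the denominator shrinks; no phantom
#' positions), and gap (`-`) versus unknown (`X`) states on the ortholog
#' side are preserved distinctly.
#'
#' @param family An `ortholog_family`.
#' @param species Species code; must be present in the family (a missing
#'   species raises a `species_missing` condition, mapped to `NA` by the
#'   scoring layer).
#' @param variant Variant id; default: first variant of the species.
#' @param column 1-based alignment column of the phospho-residue (from
#'   [map_position_to_column()]).
#' @param flank Flank width in seed residues (default 5).
#' @return A `site_window`: list with `species`, `variant`, `central_pair`
#'   (seed and ortholog central residues) and `flanks` (data.frame with
#'   `offset`, `seed`, `orth`).
#' @export
extract_window <- function(family, species, variant = NULL, column, flank = 5L) {
  if (!species %in% family_species(family))
    stop_pc(sprintf("species %s absent from family %s",
                    species, family$protein_id), "species_missing")
  variant <- variant %||% family_variants(family, species)[1]
  seq_chars <- strsplit(family_sequence(family, species, variant), "")[[1]]
  seed_chars <- strsplit(family_seed(family), "")[[1]]
  if (column < 1L || column > family$alignment_length)
    stop_pc(sprintf("column %d outside alignment of %d columns",
                    column, family$alignment_length), "invalid_position")
  fl <- seed_flank_columns(seed_chars, column, flank)
  structure(list(species = species, variant = variant,
                 central_column = column,
                 central_pair = c(seed = seed_chars[column],
                                  orth = seq_chars[column]),
                 flanks = data.frame(offset = fl$offset,
                                     seed = seed_chars[fl$column],
                                     orth = seq_chars[fl$column],
                                     stringsAsFactors = FALSE)),
            class = "site_window")
}

#' Select the best splice variant of a species for a site
#'
#' Scores every variant's window and returns the one with the most
#' favorable ortholog evidence: highest window conservation score, with
#' ties broken by higher central-residue conservation, then longer ungapped
#' sequence, then lexicographically smallest variant id.  Numeric scores
#' outrank `Incomplete`.
#'
#' @param family An `ortholog_family`.
#' @param species Species code (must be present).
#' @param column Alignment column of the phospho-residue.
#' @param flank Flank width (default 5).
#' @return Variant id (character scalar).
#' @export
select_variant <- function(family, species, column, flank = 5L) {
  variants <- family_variants(family, species)
  if (!length(variants))
    stop_pc(sprintf("species %s absent from family %s",
                    species, family$protein_id), "species_missing")
  if (length(variants) == 1L) return(variants)
  key <- lapply(variants, function(v) {
    w <- extract_window(family, species, v, column, flank)
    sc <- window_conservation(w)
    seq <- family_sequence(family, species, v)
    ungapped <- nchar(gsub("-", "", seq, fixed = TRUE))
    c(numeric_status = as.numeric(sc$status == "numeric"),
      score = if (sc$status == "numeric") sc$window_score else -1,
      central = if (sc$status == "numeric") as.numeric(sc$central_conserved) else -1,
      len = ungapped)
  })
  km <- do.call(rbind, key)
  ord <- order(-km[, "numeric_status"], -km[, "score"], -km[, "central"],
               -km[, "len"], variants)
  variants[ord[1]]
}
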