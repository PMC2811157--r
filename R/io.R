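#' Read a phosphosite table
#'
#' Expects a UTF-8 TSV with a header row and columns `protein_id`,
#' `position`, `residue`, `known_kinases`, `observation_count`, `source`.
#' Multiple known kinases are semicolon-separated and all retained.  Rows
#' are validated (position >= 1, residue in S/T/Y, observation_count >= 0);
#' malformed rows raise a parse error naming the row and field rather than
#' being coerced.
#'
#' @param path Path to the TSV.
#' @return A `data.frame`, one validated row per input row, order preserved.
#' @export
read_site_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("protein_id", "position", "residue", "known_kinases",
                "observation_count", "source")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_pc(sprintf("site table %s: missing column(s): %s",
                    path, paste(missing, collapse = ", ")), "parse_error")
  pos <- suppressWarnings(as.integer(df$position))
  obs <- suppressWarnings(as.integer(df$observation_count))
  for (i in seq_len(nrow(df))) {
    if (is.na(pos[i]) || pos[i] < 1L)
      stop_pc(sprintf("site table row %d: field 'position' must be a positive integer (got '%s')",
                      i, df$position[i]), "parse_error")
    if (!df$residue[i] %in% c("S", "T", "Y"))
      stop_pc(sprintf("site table row %d: field 'residue' must be S, T or Y (got '%s')",
                      i, df$residue[i]), "parse_error")
    if (is.na(obs[i]) || obs[i] < 0L)
      stop_pc(sprintf("site table row %d: field 'observation_count' must be a non-negative integer (got '%s')",
                      i, df$observation_count[i]), "parse_error")
  }
  data.frame(protein_id = df$protein_id, position = pos,
             residue = df$residue, known_kinases = df$known_kinases,
             observation_count = obs, source = df$source,
             stringsAsFactors = FALSE)
}

#' Write a phosphosite table
#' @param sites Site `data.frame` as returned by [read_site_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Split a known-kinases field into kinase names
#' @param x Character vector of semicolon-separated kinase lists.
#' @return List of character vectors (empty for blank fields).
#' @export
split_kinases <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(v) v[nzchar(trimws(v))])
}

#' Read an aligned ortholog family from multi-FASTA
#'
#' Headers follow `proteinID|species|variantN`, with `|seed` appended to the
#' (single) seed record.  All records must share the alignment length and
#' carry species tags from `species_list`.
#'
#' @param path Aligned multi-FASTA path (gap character `-`, unknown `X`).
#' @param species_list Declared species codes (default [default_species()]).
#' @return An `ortholog_family`.
#' @export
read_family <- function(path, species_list = default_species()) {
  aln <- Biostrings::readAAStringSet(path)
  if (!length(aln)) stop_pc(sprintf("empty FASTA: %s", path), "parse_error")
  headers <- names(aln)
  parts <- strsplit(headers, "|", fixed = TRUE)
  n_fields <- vapply(parts, length, 1L)
  if (any(n_fields < 3L))
    stop_pc(sprintf("family %s: malformed header(s): %s", path,
                    paste(headers[n_fields < 3L], collapse = "; ")),
            "parse_error")
  protein <- unique(vapply(parts, `[[`, "", 1L))
  if (length(protein) != 1L)
    stop_pc(sprintf("family %s: multiple protein ids (%s)",
                    path, paste(protein, collapse = ", ")), "parse_error")
  members <- data.frame(
    species = vapply(parts, `[[`, "", 2L),
    variant = vapply(parts, `[[`, "", 3L),
    is_seed = vapply(parts, function(p) length(p) >= 4L && p[[4L]] == "seed",
                     NA),
    stringsAsFactors = FALSE)
  new_ortholog_family(protein, as.character(aln), members, species_list)
}

#' Write an aligned ortholog family to multi-FASTA
#' @param family An `ortholog_family`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_family <- function(family, path) {
  headers <- paste(family$protein_id, family$members$species,
                   family$members$variant, sep = "|")
  headers[family$members$is_seed] <-
    paste0(headers[family$members$is_seed], "|seed")
  aln <- Biostrings::AAStringSet(family$sequences)
  names(aln) <- headers
  Biostrings::writeXStringSet(aln, path, width = 80L)
  invisible(path)
}

format_score <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else formatC(v, format = "f", digits = 3)
  }, "")
}

#' Write a per-species conservation table
#'
#' One row per site: protein, position, residue, one column per declared
#' species holding the window score (0-1, three decimals), `NA` (no
#' sequence for that species) or `Incomplete` (residue unretrievable), a
#' column `M` with the mean window conservation over scored species, and a
#' column `N` with the central-residue conservation rate.
#'
#' @param summaries List of `conservation_summary` objects
#'   (see [site_summary()]).
#' @param path Output TSV path.
#' @param species Declared species columns (default: from the summaries).
#' @return `path`, invisibly.
#' @export
write_conservation_table <- function(summaries, path, species = NULL) {
  if (!length(summaries)) stop_pc("no summaries to write", "serialization_error")
  species <- species %||% summaries[[1]]$species_scores$species
  rows <- lapply(summaries, function(s) {
    sc <- s$species_scores
    vals <- vapply(species, function(sp) {
      i <- match(sp, sc$species)
      if (is.na(i) || sc$status[i] == "NA") return("NA")
      if (sc$status[i] == "Incomplete") return("Incomplete")
      v <- sc$window_score[i]
      if (is.na(v) || v < 0 || v > 1)
        stop_pc(sprintf("site %s/%d: species %s score outside [0,1]",
                        s$protein_id, s$position, sp), "serialization_error")
      format_score(v)
    }, "")
    for (col in c("mean_window_conservation", "central_conservation_rate")) {
      v <- s[[col]]
      if (!is.na(v) && (v < 0 || v > 1))
        stop_pc(sprintf("site %s/%d: %s outside [0,1]",
                        s$protein_id, s$position, col), "serialization_error")
    }
    c(protein_id = s$protein_id, position = as.character(s$position),
      residue = s$residue, vals,
      M = format_score(s$mean_window_conservation),
      N = format_score(s$central_conservation_rate))
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a per-species conservation table
#'
#' Inverse of [write_conservation_table()].  Numeric cells become scores,
#' `NA` / `Incomplete` tokens become the corresponding states.
#'
#' @param path Conservation TSV path.
#' @return A `data.frame` with character species columns (`"NA"`,
#'   `"Incomplete"`, or a formatted score) and numeric `M`/`N`.
#' @export
read_conservation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  required <- c("protein_id", "position", "residue", "M", "N")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_pc(sprintf("conservation table %s: missing column(s): %s",
                    path, paste(missing, collapse = ", ")), "parse_error")
  df$position <- as.integer(df$position)
  species_cols <- setdiff(names(df), required)
  for (col in c(species_cols, "M", "N")) {
    vals <- df[[col]]
    ok <- vals %in% c("NA", "Incomplete") |
      !is.na(suppressWarnings(as.numeric(vals)))
    if (!all(ok))
      stop_pc(sprintf("conservation table %s: bad value '%s' in column %s",
                      path, vals[!ok][1], col), "parse_error")
    num <- suppressWarnings(as.numeric(vals))
    if (any(!is.na(num) & (num < 0 | num > 1)))
      stop_pc(sprintf("conservation table %s: column %s outside [0,1]",
                      path, col), "parse_error")
  }
  df$M <- suppressWarnings(as.numeric(df$M))
  df$N <- suppressWarnings(as.numeric(df$N))
  df
}

#' Read a signaling edge list
#'
#' TSV with columns `proteinA`, `proteinB` and optional `label` describing
#' established (curated) signaling interactions; edges are an input, never
#' inferred.
#'
#' @param path Edge-list TSV path.
#' @return `data.frame` with columns `from`, `to`, `label`.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("proteinA", "proteinB") %in% names(df)))
    stop_pc(sprintf("edge list %s: need columns proteinA, proteinB", path),
            "parse_error")
  data.frame(from = df$proteinA, to = df$proteinB,
             label = if ("label" %in% names(df)) df$label else "",
             stringsAsFactors = FALSE)
}
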