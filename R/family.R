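#' Ortholog family container
#'
#' An `ortholog_family` holds a protein's aligned sequences across species
#' and splice variants.  Exactly one member is the seed (the human sequence
#' on which phosphosites were mapped); all members share the alignment
#' length.  Gap columns use `-`; unretrievable residues use `X`.
#'
#' @name ortholog_family
#' @keywords internal
NULL

new_ortholog_family <- function(protein_id, sequences, members, species_list) {
  stopifnot(is.character(sequences), nrow(members) == length(sequences))
  lens <- unname(nchar(sequences))
  if (length(unique(lens)) != 1L)
    stop_pc(sprintf("family %s: ragged alignment (lengths %s)",
                    protein_id, paste(unique(lens), collapse = ", ")),
            "alignment_error")
  if (sum(members$is_seed) != 1L)
    stop_pc(sprintf("family %s: expected exactly one seed record, found %d",
                    protein_id, sum(members$is_seed)), "seed_error")
  bad_sp <- setdiff(members$species, species_list)
  if (length(bad_sp))
    stop_pc(sprintf("family %s: unknown species tag(s): %s",
                    protein_id, paste(bad_sp, collapse = ", ")),
            "unknown_species")
  if (anyDuplicated(paste(members$species, members$variant)))
    stop_pc(sprintf("family %s: duplicate (species, variant) member",
                    protein_id), "duplicate_member")
  structure(list(protein_id = protein_id,
                 sequences = toupper(unname(sequences)),
                 members = members,
                 species_list = species_list,
                 alignment_length = lens[1]),
            class = "ortholog_family")
}

#' @export
print.ortholog_family <- function(x, ...) {
  cat(sprintf("<ortholog_family> %s: %d sequences x %d columns, %d/%d species (seed %s)\n",
              x$protein_id, length(x$sequences), x$alignment_length,
              length(unique(x$members$species)), length(x$species_list),
              x$members$species[x$members$is_seed]))
  invisible(x)
}

family_seed_index <- function(family) which(family$members$is_seed)

#' Seed (human) aligned sequence of a family
#' @param family An `ortholog_family`.
#' @param ungapped Drop gap columns?
#' @return Sequence string.
#' @export
family_seed <- function(family, ungapped = FALSE) {
  s <- family$sequences[family_seed_index(family)]
  if (ungapped) gsub("-", "", s, fixed = TRUE) else s
}

#' Species present in a family
#' @param family An `ortholog_family`.
#' @return Character vector of species codes with at least one member.
#' @export
family_species <- function(family) unique(family$members$species)

#' Variants of a species within a family
#' @param family An `ortholog_family`.
#' @param species Species code.
#' @return Character vector of variant ids (possibly empty).
#' @export
family_variants <- function(family, species) {
  sort(family$members$variant[family$members$species == species])
}

family_sequence <- function(family, species, variant) {
  i <- which(family$members$species == species & family$members$variant == variant)
  if (!length(i))
    stop_pc(sprintf("family %s: no member %s|%s", family$protein_id,
                    species, variant), "species_missing")
  family$sequences[i]
}
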