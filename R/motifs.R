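#' Kinase consensus motif
#'
#' A motif is an offset-indexed set of allowed residues around a central
#' phospho-acceptor, e.g. the ATM/ATR consensus \[ST\]Q (central S or T, +1
#' glutamine) or the Plk1 consensus \[D/E\]X\[S/T\] (aspartate/glutamate at
#' -2, central S or T).  Offsets are relative to the phospho-residue and must
#' lie within -5..+5, the same window the conservation score uses.
#'
#' @param name Motif name (used as annotation key).
#' @param central Allowed central residues, a subset of `c("S","T","Y")`.
#' @param slots Named list mapping offsets (as names, e.g. `"+1"`, `"-2"`) to
#'   character vectors of allowed residues.  May be empty.
#' @param kinase Display kinase/class this motif predicts (defaults to
#'   `name`).
#' @return An object of class `kinase_motif`.
#' @export
#' @examples
#' atm <- kinase_motif("ATM/ATR", central = c("S", "T"), slots = list(`+1` = "Q"))
#' match_motif("AAAASQAAAA", 5, atm)
kinase_motif <- function(name, central, slots = list(), kinase = name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  central <- unique(toupper(central))
  if (length(central) == 0L || !all(central %in% c("S", "T", "Y")))
    stop_pc("motif central set must be a non-empty subset of S/T/Y",
            "invalid_motif")
  if (length(slots)) {
    offs <- suppressWarnings(as.integer(names(slots)))
    if (anyNA(offs) || any(offs < -5L | offs > 5L) || any(offs == 0L))
      stop_pc(sprintf("motif '%s': slot offsets must be non-zero integers in -5..+5",
                      name), "invalid_motif")
    if (anyDuplicated(offs))
      stop_pc(sprintf("motif '%s': duplicate slot offsets", name), "invalid_motif")
    slots <- lapply(slots, function(x) unique(toupper(x)))
    if (any(vapply(slots, length, 1L) == 0L) ||
        !all(unlist(slots) %in% AMINO_ACIDS))
      stop_pc(sprintf("motif '%s': allowed-residue sets must be non-empty amino acids",
                      name), "invalid_motif")
    slots <- slots[order(offs)]
    names(slots) <- sprintf("%+d", sort(offs))
  }
  structure(list(name = name, central = sort(central), slots = slots,
                 kinase = kinase),
            class = "kinase_motif")
}

#' @export
print.kinase_motif <- function(x, ...) {
  slot_txt <- if (length(x$slots)) {
    paste(vapply(seq_along(x$slots), function(i)
      sprintf("%s:[%s]", names(x$slots)[i], paste(x$slots[[i]], collapse = "/")),
      ""), collapse = " ")
  } else "(no flank constraints)"
  cat(sprintf("<kinase_motif> %s  central [%s]  %s\n",
              x$name, paste(x$central, collapse = "/"), slot_txt))
  invisible(x)
}

motif_offsets <- function(motif) {
  if (!length(motif$slots)) integer(0) else as.integer(names(motif$slots))
}

#' Default motif library
#'
#' Loads the motif library shipped with the package
#' (`inst/extdata/motif_library.yaml`): ATM/ATR (\[ST\]Q), minimal and strict
#' CDK consensus, Plk1 (\[D/E\]X\[S/T\]), the Plk1 PBD docking consensus
#' (S-\[pS/pT\]-P) and a minimal Chk1/2 basophilic consensus.  Edit a copy of
#' the YAML file and load it with [read_motif_library()] to override.
#'
#' @return A named list of [kinase_motif] objects (class `motif_library`).
#' @export
default_motif_library <- function() {
  read_motif_library(system.file("extdata", "motif_library.yaml",
                                 package = "phosphocons", mustWork = TRUE))
}

#' Read a motif library from a YAML config file
#'
#' Each entry gives `central` (allowed central residues), optionally `kinase`
#' (display class) and `slots`, a map from signed offset to allowed residues.
#'
#' @param path Path to a YAML motif config.
#' @return A named list of [kinase_motif] objects (class `motif_library`).
#' @export
read_motif_library <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stop_pc("empty motif library", "invalid_motif")
  lib <- lapply(names(raw), function(nm) {
    entry <- raw[[nm]]
    slots <- entry$slots %||% list()
    slots <- lapply(slots, function(x) as.character(unlist(x)))
    kinase_motif(nm, central = as.character(unlist(entry$central)),
                 slots = slots, kinase = entry$kinase %||% nm)
  })
  names(lib) <- names(raw)
  structure(lib, class = "motif_library")
}

#' Match a kinase motif at a position of an ungapped sequence
#'
#' Returns `TRUE` iff the residue at `position` is in the motif's central set
#' and every required flank slot whose offset lies inside the sequence holds
#' an allowed residue.  A required slot falling outside the sequence fails
#' the match (the consensus cannot be confirmed).
#'
#' @param sequence Ungapped protein sequence (single string).
#' @param position 1-based residue index of the candidate phospho-acceptor.
#' @param motif A [kinase_motif].
#' @return Logical scalar.
#' @export
match_motif <- function(sequence, position, motif) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            inherits(motif, "kinase_motif"))
  n <- nchar(sequence)
  if (length(position) != 1L || is.na(position) || position < 1L || position > n)
    stop_pc(sprintf("position %s outside sequence of length %d",
                    format(position), n), "invalid_position")
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (!chars[position] %in% motif$central) return(FALSE)
  for (i in seq_along(motif$slots)) {
    off <- as.integer(names(motif$slots)[i])
    j <- position + off
    if (j < 1L || j > n) return(FALSE)
    if (!chars[j] %in% motif$slots[[i]]) return(FALSE)
  }
  TRUE
}
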