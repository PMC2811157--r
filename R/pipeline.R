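#' Generate a synthetic fixture directory
#'
#' Simulates `n_proteins` ortholog families under `config` (per-protein
#' seeds are derived as `config$seed + i - 1`) and writes the aligned
#' family FASTAs (`families/<protein>.fasta`), the phosphosite table
#' (`sites.tsv`) and the truth table (`truth.tsv`).  Idempotent for a fixed
#' seed; the output directory is created if missing.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory.
#' @param n_proteins Number of independent families to simulate.
#' @return Named list of output paths, invisibly.
#' @export
run_simulate <- function(config, out_dir, n_proteins = 1L) {
  fam_dir <- file.path(out_dir, "families")
  dir.create(fam_dir, recursive = TRUE, showWarnings = FALSE)
  all_sites <- list(); all_truth <- list()
  for (i in seq_len(n_proteins)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    pid <- sprintf("SIM%02d", i)
    sim <- simulate_family(cfg, protein_id = pid)
    write_family(sim$family, file.path(fam_dir, paste0(pid, ".fasta")))
    all_sites[[i]] <- sim$sites
    all_truth[[i]] <- sim$truth
  }
  sites_path <- file.path(out_dir, "sites.tsv")
  truth_path <- file.path(out_dir, "truth.tsv")
  write_site_table(do.call(rbind, all_sites), sites_path)
  utils::write.table(do.call(rbind, all_truth), truth_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(list(family_dir = fam_dir, sites = sites_path,
                 truth = truth_path))
}

load_families <- function(site_tab, family_dir, species) {
  proteins <- unique(site_tab$protein_id)
  fams <- lapply(proteins, function(p) {
    path <- file.path(family_dir, paste0(p, ".fasta"))
    if (!file.exists(path))
      stop_pc(sprintf("protein %s: family FASTA not found at %s", p, path),
              "io_error")
    read_family(path, species_list = species)
  })
  names(fams) <- proteins
  fams
}

summarize_all <- function(site_tab, families, flank, include_self) {
  lapply(seq_len(nrow(site_tab)), function(i) {
    s <- summarize_site(families[[site_tab$protein_id[i]]],
                        site_tab$position[i],
                        residue = site_tab$residue[i],
                        flank = flank, include_self = include_self)
    message(sprintf("conserve: %s %s%d mean=%s central=%s",
                    s$protein_id, s$residue, s$position,
                    format_score(s$mean_window_conservation),
                    format_score(s$central_conservation_rate)))
    s
  })
}

#' Compute and write the per-species conservation table
#'
#' Reads the phosphosite table and the per-protein family FASTAs, scores
#' every site, and writes a conservation table (one species column each
#' plus the mean `M` and central-rate `N` columns).  Emits one log line per
#' site.
#'
#' @param site_table Path to the phosphosite TSV.
#' @param family_dir Directory of `<protein>.fasta` aligned families.
#' @param out_dir Output directory (created if missing).
#' @param species Declared species codes.
#' @param flank Flank width (default 5).
#' @param include_self Include the seed self-comparison in the aggregates.
#' @return The list of `conservation_summary` objects, invisibly.
#' @export
run_conserve <- function(site_table, family_dir, out_dir,
                         species = default_species(), flank = 5L,
                         include_self = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  site_tab <- read_site_table(site_table)
  families <- load_families(site_tab, family_dir, species)
  summaries <- summarize_all(site_tab, families, flank, include_self)
  write_conservation_table(summaries, file.path(out_dir, "conservation.tsv"),
                           species = species)
  invisible(summaries)
}

annotations_df <- function(annotations) {
  do.call(rbind, lapply(annotations, function(a) {
    data.frame(
      protein_id = a$protein_id, position = a$position, residue = a$residue,
      matched_motifs = paste(a$matched_motifs, collapse = ";"),
      kinases = paste(sprintf("%s:%s", a$assigned_kinases$kinase,
                              a$assigned_kinases$provenance), collapse = ";"),
      pbd_site = a$pbd_site,
      motif_conservation = paste(sprintf("%s=%s", names(a$motif_conservation),
                                         format_score(a$motif_conservation)),
                                 collapse = ";"),
      stringsAsFactors = FALSE)
  }))
}

#' Run the full annotation pipeline
#'
#' Composes the stages end to end: conservation scoring, motif/kinase
#' annotation, the recurrent-conserved-consensus filter, network assembly,
#' and export.  Writes `conservation.tsv`, `annotations.tsv`,
#' `filtered_sites.tsv`, `network.json`, `network.graphml`, a bar-summary
#' figure, and a run manifest (`manifest.json`: configuration echo, package
#' version, seed).  Deterministic for fixed inputs; inputs are never
#' mutated.
#'
#' @inheritParams run_conserve
#' @param edge_list Optional path to an edge-list TSV of established
#'   signaling interactions.
#' @param motif_library A `motif_library` or path to a motif YAML
#'   (default: the shipped library).
#' @param external_predictions Optional path to a kinase-prediction TSV
#'   (`protein_id`, `position`, `kinase`, `score`), consumed as
#'   annotations.
#' @param min_observations,motif_name,conservation_threshold Passed to
#'   [filter_recurrent_conserved()].
#' @param groups Optional named vector mapping protein to module group.
#' @param figure_format Figure extension: `"svg"`, `"png"` or `"pdf"`.
#' @param seed Integer seed recorded in the manifest and set before the
#'   run (the pipeline itself is deterministic; the seed pins any future
#'   stochastic stage).
#' @return Named list of output paths, invisibly.
#' @export
run_full <- function(site_table, family_dir, out_dir, edge_list = NULL,
                     motif_library = NULL, external_predictions = NULL,
                     species = default_species(), flank = 5L,
                     include_self = FALSE, min_observations = 2L,
                     motif_name = "Plk1", conservation_threshold = 1.0,
                     groups = NULL, figure_format = "svg", seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  if (is.null(motif_library)) motif_library <- default_motif_library()
  if (is.character(motif_library))
    motif_library <- read_motif_library(motif_library)
  preds <- if (!is.null(external_predictions))
    utils::read.delim(external_predictions, stringsAsFactors = FALSE)
  else NULL

  site_tab <- read_site_table(site_table)
  families <- load_families(site_tab, family_dir, species)
  summaries <- summarize_all(site_tab, families, flank, include_self)
  annotations <- lapply(seq_len(nrow(site_tab)), function(i)
    annotate_site(site_tab[i, ], families[[site_tab$protein_id[i]]],
                  library = motif_library, external_predictions = preds,
                  flank = flank))
  filtered <- filter_recurrent_conserved(site_tab, annotations, summaries,
                                         min_observations = min_observations,
                                         motif_name = motif_name,
                                         conservation_threshold = conservation_threshold)
  edges <- if (!is.null(edge_list)) read_edge_list(edge_list) else NULL
  network <- withCallingHandlers(
    build_network(site_tab, summaries, annotations, edges, groups = groups),
    warning = function(w) {
      message("network: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  paths <- list(
    conservation = file.path(out_dir, "conservation.tsv"),
    annotations = file.path(out_dir, "annotations.tsv"),
    filtered = file.path(out_dir, "filtered_sites.tsv"),
    network_json = file.path(out_dir, "network.json"),
    network_graphml = file.path(out_dir, "network.graphml"),
    figure = file.path(out_dir, paste0("network.", figure_format)),
    manifest = file.path(out_dir, "manifest.json"))
  write_conservation_table(summaries, paths$conservation, species = species)
  utils::write.table(annotations_df(annotations), paths$annotations,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  write_site_table(filtered, paths$filtered)
  export_network(network, paths$network_json, "json")
  export_network(network, paths$network_graphml, "graphml")
  render_summary_plot(network, paths$figure)

  manifest <- list(
    package = "phosphocons",
    version = as.character(utils::packageVersion("phosphocons")),
    seed = seed,
    config = list(site_table = site_table, family_dir = family_dir,
                  edge_list = edge_list %||% NA,
                  species = species, flank = flank,
                  include_self = include_self,
                  min_observations = min_observations,
                  motif_name = motif_name,
                  conservation_threshold = conservation_threshold),
    n_sites = nrow(site_tab),
    n_filtered = nrow(filtered),
    n_nodes = length(network$nodes),
    n_edges = nrow(network$edges))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(paths)
}
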