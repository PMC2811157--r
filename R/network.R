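#' Kinase class display palette
#'
#' Display classes and colors for the annotated network: CDK yellow,
#' ATM/ATR red, CHK1/2 orange, PLK1 blue, other known kinases dark grey,
#' unknown light grey, and PBD docking sites green.
#'
#' @return Named character vector of colors.
#' @export
kinase_class_palette <- function() {
  c("CDK" = "#E8C50A", "ATM/ATR" = "#CC3333", "CHK1/2" = "#E68A00",
    "PLK1" = "#3366CC", "other-known" = "#555555", "unknown" = "#C8C8C8",
    "PBD" = "#33A02C")
}

kinase_display_class <- function(assigned) {
  if (is.null(assigned) || !nrow(assigned)) return("unknown")
  classify <- function(k) {
    k <- toupper(k)
    if (grepl("CDK|CDC2|CDK1|CDK2", k)) return("CDK")
    if (grepl("ATM|ATR", k)) return("ATM/ATR")
    if (grepl("CHK|CHEK", k)) return("CHK1/2")
    if (grepl("PLK", k)) return("PLK1")
    "other"
  }
  cls <- vapply(assigned$kinase, classify, "", USE.NAMES = FALSE)
  hit <- cls[cls != "other"]
  if (length(hit)) return(hit[1])
  if (any(assigned$provenance == "known")) "other-known" else "unknown"
}

#' Assemble the annotated phosphorylation site network
#'
#' Builds one node per protein appearing in the site table, each carrying
#' its sites in position order with the two bar heights of the display
#' convention: the central bar is the central-residue conservation rate and
#' the flank bar is the mean window conservation.  Edges (established
#' signaling interactions, an input, never inferred) are copied after
#' endpoint validation; an edge naming an unknown protein is dropped with a
#' warning.
#'
#' @param sites Site `data.frame`.
#' @param summaries List of `conservation_summary`, covering all sites.
#' @param annotations List of `site_annotation`, covering all sites.
#' @param edges Optional edge `data.frame` (`from`, `to`, optional `label`).
#' @param groups Optional named character vector mapping protein to module
#'   group (e.g. checkpoint / cell cycle), carried as a node attribute.
#' @return A `site_network`.
#' @export
build_network <- function(sites, summaries, annotations, edges = NULL,
                          groups = NULL) {
  sum_keys <- vapply(summaries, function(s) site_key(s$protein_id, s$position), "")
  ann_keys <- vapply(annotations, function(a) site_key(a$protein_id, a$position), "")
  proteins <- unique(sites$protein_id)
  nodes <- lapply(proteins, function(p) {
    rows <- which(sites$protein_id == p)
    rows <- rows[order(sites$position[rows])]
    site_entries <- lapply(rows, function(i) {
      key <- site_key(p, sites$position[i])
      si <- match(key, sum_keys); ai <- match(key, ann_keys)
      if (is.na(si) || is.na(ai))
        stop_pc(sprintf("site %s lacks summary or annotation", key),
                "input_error")
      s <- summaries[[si]]; a <- annotations[[ai]]
      list(position = sites$position[i],
           residue = sites$residue[i],
           observation_count = sites$observation_count[i],
           central_height = s$central_conservation_rate,
           flank_height = s$mean_window_conservation,
           kinase_class = kinase_display_class(a$assigned_kinases),
           kinases = a$assigned_kinases,
           matched_motifs = a$matched_motifs,
           motif_conservation = as.list(a$motif_conservation),
           pbd_site = a$pbd_site)
    })
    list(protein_id = p,
         group = if (!is.null(groups) && p %in% names(groups)) groups[[p]]
                 else NA_character_,
         sites = site_entries)
  })
  names(nodes) <- proteins
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        label = character(), stringsAsFactors = FALSE)
  } else {
    if (!"label" %in% names(edges)) edges$label <- ""
    ok <- edges$from %in% proteins & edges$to %in% proteins
    if (any(!ok)) {
      bad <- edges[!ok, , drop = FALSE]
      warning(sprintf("dropping %d edge(s) referencing unknown protein(s): %s",
                      nrow(bad),
                      paste(paste(bad$from, bad$to, sep = "-"), collapse = ", ")),
              call. = FALSE)
      edges <- edges[ok, , drop = FALSE]
    }
    edges <- data.frame(from = edges$from, to = edges$to, label = edges$label,
                        stringsAsFactors = FALSE)
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges,
                 palette = as.list(kinase_class_palette())),
            class = "site_network")
}

#' @export
print.site_network <- function(x, ...) {
  cat(sprintf("<site_network> %d proteins, %d sites, %d edges\n",
              length(x$nodes),
              sum(vapply(x$nodes, function(n) length(n$sites), 1L)),
              nrow(x$edges)))
  invisible(x)
}

network_to_list <- function(network) {
  list(nodes = lapply(unname(network$nodes), function(n) {
    n$sites <- lapply(n$sites, function(s) {
      s$kinases <- list(kinase = as.list(s$kinases$kinase),
                        provenance = as.list(s$kinases$provenance))
      s$matched_motifs <- as.list(s$matched_motifs)
      s
    })
    n
  }),
  edges = list(from = as.list(network$edges$from),
               to = as.list(network$edges$to),
               label = as.list(network$edges$label)),
  palette = network$palette)
}

network_from_list <- function(x) {
  nodes <- lapply(x$nodes, function(n) {
    n$group <- n$group %||% NA_character_
    n$sites <- lapply(n$sites, function(s) {
      s$kinases <- data.frame(
        kinase = as.character(unlist(s$kinases$kinase)),
        provenance = as.character(unlist(s$kinases$provenance)),
        stringsAsFactors = FALSE)
      s$matched_motifs <- as.character(unlist(s$matched_motifs))
      s$motif_conservation <- as.list(s$motif_conservation)
      s
    })
    n
  })
  names(nodes) <- vapply(nodes, `[[`, "", "protein_id")
  edges <- data.frame(from = as.character(unlist(x$edges$from)),
                      to = as.character(unlist(x$edges$to)),
                      label = as.character(unlist(x$edges$label)),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, palette = x$palette),
            class = "site_network")
}

#' Export a site network
#'
#' JSON export is lossless (nodes, per-site attributes, kinase classes,
#' palette and edges) and [import_network()] inverts it exactly.  GraphML
#' export writes one vertex per protein with the per-site records embedded
#' as a JSON string attribute (`sites_json`), suitable for Cytoscape-style
#' tools.
#'
#' @param network A `site_network`.
#' @param path Output path.
#' @param format `"json"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("json", "graphml")) {
  if (!inherits(network, "site_network"))
    stop_pc("not a site_network", "input_error")
  format <- tryCatch(match.arg(format),
                     error = function(e) stop_pc(
                       sprintf("unknown export format '%s'", format[1]),
                       "config_error"))
  if (format == "json") {
    jsonlite::write_json(network_to_list(network), path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null",
                         pretty = TRUE)
  } else {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    if (length(network$nodes)) {
      g <- igraph::add_vertices(
        g, length(network$nodes),
        name = vapply(network$nodes, `[[`, "", "protein_id"),
        group = vapply(network$nodes, function(n)
          ifelse(is.na(n$group), "", n$group), ""),
        n_sites = vapply(network$nodes, function(n) length(n$sites), 1L),
        sites_json = vapply(network$nodes, function(n)
          as.character(jsonlite::toJSON(n$sites, auto_unbox = TRUE,
                                        digits = NA, null = "null",
                                        na = "null")), ""))
      if (nrow(network$edges)) {
        idx <- rbind(match(network$edges$from, igraph::V(g)$name),
                     match(network$edges$to, igraph::V(g)$name))
        g <- igraph::add_edges(g, as.vector(idx),
                               label = network$edges$label)
      }
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import a site network from JSON
#' @param path JSON path written by [export_network()].
#' @return A `site_network`.
#' @export
import_network <- function(path) {
  network_from_list(jsonlite::read_json(path))
}

#' Render the per-protein conservation bar summary
#'
#' One panel per protein; each site is a column of two bars: the central
#' bar (central phospho-acceptor conservation rate) and the flank bar
#' (mean window conservation), colored by assigned kinase class; PBD
#' docking sites carry a green marker.  The device is chosen from the file
#' extension (`.svg`, `.png`, `.pdf`).  The network is never mutated.
#'
#' @param network A `site_network`.
#' @param path Output figure path.
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
render_summary_plot <- function(network, path, width = 10, height = 7) {
  rows <- list()
  for (n in network$nodes) {
    for (s in n$sites) {
      lab <- paste0(s$residue, s$position)
      rows[[length(rows) + 1L]] <- data.frame(
        protein = n$protein_id, site = lab, position = s$position,
        bar = c("central", "flank"),
        height = c(s$central_height %||% NA_real_,
                   s$flank_height %||% NA_real_),
        kinase_class = s$kinase_class, pbd = s$pbd_site,
        stringsAsFactors = FALSE)
    }
  }
  pal <- unlist(network$palette)
  if (length(rows)) {
    df <- do.call(rbind, rows)
    df$site <- factor(df$site, levels = unique(df$site[order(df$position)]))
    df$fill_class <- ifelse(df$bar == "central", df$kinase_class, "flankbar")
    fills <- c(pal, flankbar = "#9A9A9A")
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$site, y = .data$height,
                                          fill = .data$fill_class,
                                          group = .data$bar)) +
      ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                        width = 0.7, na.rm = TRUE) +
      ggplot2::geom_point(data = df[df$pbd & df$bar == "central", ,
                                    drop = FALSE],
                          ggplot2::aes(y = 1.05), color = pal[["PBD"]],
                          shape = 18, size = 2, show.legend = FALSE) +
      ggplot2::scale_fill_manual(values = fills, name = "kinase class",
                                 breaks = names(pal)) +
      ggplot2::scale_y_continuous(limits = c(0, 1.1),
                                  breaks = c(0, 0.5, 1)) +
      ggplot2::facet_wrap(~protein, scales = "free_x") +
      ggplot2::labs(x = NULL, y = "conservation") +
      ggplot2::theme_bw(base_size = 9) +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                         hjust = 1))
  } else {
    p <- ggplot2::ggplot() + ggplot2::theme_void()
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         svg = grDevices::svg(path, width = width, height = height),
         png = grDevices::png(path, width = width * 100,
                              height = height * 100, res = 100),
         pdf = grDevices::pdf(path, width = width, height = height),
         stop_pc(sprintf("unsupported figure format '.%s'", ext),
                 "config_error"))
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}
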