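two_protein_inputs <- function() {
  sites <- data.frame(protein_id = c("ATM", "CHEK2", "CHEK2"),
                      position = c(1981L, 205L, 68L),
                      residue = c("S", "T", "T"),
                      known_kinases = c("", "PLK1", "ATM"),
                      observation_count = c(2L, 2L, 4L),
                      source = "synthetic", stringsAsFactors = FALSE)
  summaries <- lapply(seq_len(nrow(sites)), function(i)
    make_summary(sites$protein_id[i], sites$position[i], sites$residue[i],
                 scores = list(make_species_score("M.mus", score = 0.875,
                                                  central = TRUE,
                                                  n_comp = 8L))))
  annotations <- lapply(seq_len(nrow(sites)), function(i)
    make_annotation(sites$protein_id[i], sites$position[i],
                    sites$residue[i],
                    kinases = if (nzchar(sites$known_kinases[i]))
                      sites$known_kinases[i] else character(),
                    provenance = if (nzchar(sites$known_kinases[i]))
                      "known" else character(),
                    pbd = sites$position[i] == 205))
  list(sites = sites, summaries = summaries, annotations = annotations)
}

test_that("network assembly validates edges and orders sites by position", {
  x <- two_protein_inputs()
  edges <- data.frame(from = "ATM", to = "CHEK2", label = "phosphorylation",
                      stringsAsFactors = FALSE)
  net <- build_network(x$sites, x$summaries, x$annotations, edges)
  expect_identical(length(net$nodes), 2L)
  expect_identical(nrow(net$edges), 1L)
  # sites attached in position order within a node
  chk2 <- net$nodes[["CHEK2"]]
  expect_identical(vapply(chk2$sites, `[[`, 1L, "position"), c(68L, 205L))
  # display heights follow the central/flank bar convention
  expect_equal(chk2$sites[[2]]$central_height, 1.0)
  expect_equal(chk2$sites[[2]]$flank_height, 0.875)
  expect_identical(chk2$sites[[2]]$kinase_class, "PLK1")
  expect_identical(chk2$sites[[1]]$kinase_class, "ATM/ATR")
  expect_identical(net$nodes[["ATM"]]$sites[[1]]$kinase_class, "unknown")

  bad_edges <- rbind(edges, data.frame(from = "ATM", to = "GHOST",
                                       label = "x"))
  expect_warning(net2 <- build_network(x$sites, x$summaries, x$annotations,
                                       bad_edges),
                 regexp = "GHOST")
  expect_identical(nrow(net2$edges), 1L)
})

test_that("node count equals distinct proteins of a large synthetic roster", {
  sites <- synthetic_ddr_sites()
  summaries <- lapply(seq_len(nrow(sites)), function(i)
    make_summary(sites$protein_id[i], sites$position[i], sites$residue[i],
                 scores = list(make_species_score("M.mus", score = 1,
                                                  central = TRUE,
                                                  n_comp = 10L))))
  annotations <- lapply(seq_len(nrow(sites)), function(i)
    make_annotation(sites$protein_id[i], sites$position[i],
                    sites$residue[i]))
  net <- build_network(sites, summaries, annotations,
                       synthetic_ddr_edges())
  expect_identical(length(net$nodes), length(unique(sites$protein_id)))
  expect_identical(length(net$nodes), 33L)
  expect_identical(sum(vapply(net$nodes, function(n) length(n$sites), 1L)),
                   244L)
  expect_identical(nrow(net$edges), nrow(synthetic_ddr_edges()))
})

test_that("JSON export/import is the identity, GraphML is well-formed", {
  set.seed(808)
  for (i in 1:10) {
    net <- random_network()
    path <- tempfile(fileext = ".json")
    export_network(net, path, "json")
    back <- import_network(path)
    expect_equal(back, net)
    # a second export of the re-imported network is byte-identical
    path2 <- tempfile(fileext = ".json")
    export_network(back, path2, "json")
    expect_identical(readLines(path2), readLines(path))
  }

  x <- two_protein_inputs()
  net <- build_network(x$sites, x$summaries, x$annotations,
                       data.frame(from = "ATM", to = "CHEK2", label = "p"))
  gpath <- tempfile(fileext = ".graphml")
  export_network(net, gpath, "graphml")
  doc <- xml2::read_xml(gpath)
  expect_identical(xml2::xml_name(doc), "graphml")
  g <- igraph::read_graph(gpath, format = "graphml")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  expect_setequal(igraph::V(g)$name, c("ATM", "CHEK2"))

  # empty network exports validly in both formats
  empty <- build_network(x$sites[0, ], list(), list())
  epath <- tempfile(fileext = ".json")
  export_network(empty, epath, "json")
  expect_identical(length(import_network(epath)$nodes), 0L)
  egml <- tempfile(fileext = ".graphml")
  export_network(empty, egml, "graphml")
  expect_silent(xml2::read_xml(egml))

  expect_error(export_network(net, tempfile(), "dot"), class = "config_error")
})

test_that("plot rendering is deterministic and never mutates the network", {
  x <- two_protein_inputs()
  net <- build_network(x$sites, x$summaries, x$annotations)
  before <- serialize(net, NULL)
  p1 <- tempfile(fileext = ".svg"); p2 <- tempfile(fileext = ".svg")
  render_summary_plot(net, p1)
  render_summary_plot(net, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_identical(serialize(net, NULL), before)

  # empty network still renders a canvas
  empty <- build_network(x$sites[0, ], list(), list())
  pe <- tempfile(fileext = ".svg")
  render_summary_plot(empty, pe)
  expect_true(file.size(pe) > 0)
})
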