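test_that("collapse matches the hand-enumerated example", {
  edges <- tibble::tibble(node_a = c(1L, 2L, 1L), node_b = c(3L, 3L, 2L))
  membership <- c("1" = "F1", "2" = "F1", "3" = "F2")
  meta <- collapse_to_meta(edges, membership)
  expect_equal(meta$edges$weight, 2L)
  expect_equal(meta$edges$from, "F1")
  expect_equal(meta$edges$to, "F2")
  expect_equal(meta$nodes$intra_edges[meta$nodes$family == "F1"], 1L)
  expect_equal(sum(meta$edges$weight) + sum(meta$nodes$intra_edges), 3L)
  expect_equal(meta$nodes$size, c(2L, 1L))

  intra_only <- tibble::tibble(node_a = 1L, node_b = 2L)
  m2 <- collapse_to_meta(intra_only, membership)
  expect_equal(nrow(m2$edges), 0)

  expect_error(collapse_to_meta(tibble::tibble(node_a = 9L, node_b = 1L),
                                membership), "9")
})

test_that("collapse conservation holds on random graphs vs the oracle", {
  withr::with_seed(33, {
    for (i in 1:200) {
      n <- sample(5:15, 1)
      n_fam <- sample(2:4, 1)
      membership <- setNames(paste0("F", sample(n_fam, n, replace = TRUE)),
                             seq_len(n))
      pairs <- t(combn(n, 2))
      take <- sample(nrow(pairs), sample(3:min(12, nrow(pairs)), 1))
      edges <- tibble::tibble(node_a = pairs[take, 1],
                              node_b = pairs[take, 2])
      meta <- collapse_to_meta(edges, membership)
      expect_equal(sum(meta$edges$weight) + sum(meta$nodes$intra_edges),
                   nrow(edges))
      orc <- oracle_collapse(edges, membership)
      for (fam in names(orc$intra)) {
        expect_equal(meta$nodes$intra_edges[meta$nodes$family == fam],
                     as.integer(orc$intra[[fam]]))
      }
      for (k in names(orc$inter)) {
        fams <- strsplit(k, "~")[[1]]
        w <- meta$edges$weight[meta$edges$from == fams[1] &
                                 meta$edges$to == fams[2]]
        expect_equal(w, as.integer(orc$inter[[k]]))
      }
    }
  })
})

test_that("the synthetic chaperome corpus yields a connected 10-family
           ME meta-network", {
  corpus <- synthetic_interactome_corpus()
  ont <- read_mi_obo(extdata("psimi_subset_synthetic.obo"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mitab(corpus$records, path)
  rec <- read_evidence(path, corpus$mapping,
                       node_filter = corpus$node_universe)
  tiers <- build_tiers(rec, ont)
  me <- tier_edges(tiers, "ME")
  meta <- collapse_to_meta(me, corpus$membership)
  expect_equal(nrow(meta$nodes), 10)
  g <- igraph::graph_from_data_frame(meta$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = meta$nodes$family)
  expect_equal(igraph::count_components(g), 1)
})

test_that("layout is deterministic and respects simple geometry", {
  path_net <- structure(list(
    nodes = tibble::tibble(family = c("A", "B", "C"), size = 1L,
                           intra_edges = 0L, value = 0),
    edges = tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                           weight = c(1L, 1L))),
    class = "family_meta_network")
  l1 <- layout_meta(path_net, seed = 1)
  l2 <- layout_meta(path_net, seed = 1)
  expect_identical(l1$nodes[, c("x", "y")], l2$nodes[, c("x", "y")])
  # B sits between A and C: the stress of the found layout beats swapping
  # B with either terminus (geodesic target distances 1,1,2)
  stress <- function(xy) {
    target <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
    d <- as.matrix(dist(xy))
    sum((d - target)^2 / target^2 / 2, na.rm = TRUE)
  }
  xy <- as.matrix(l1$nodes[, c("x", "y")])
  expect_lt(stress(xy), stress(xy[c(2, 1, 3), ]))
  expect_lt(stress(xy), stress(xy[c(1, 3, 2), ]))

  tri <- structure(list(
    nodes = tibble::tibble(family = c("A", "B", "C"), size = 1L,
                           intra_edges = 0L, value = 0),
    edges = tibble::tibble(from = c("A", "A", "B"), to = c("B", "C", "C"),
                           weight = c(2L, 2L, 2L))),
    class = "family_meta_network")
  lt <- layout_meta(tri)
  d <- as.numeric(dist(as.matrix(lt$nodes[, c("x", "y")])))
  expect_lt((max(d) - min(d)) / mean(d), 0.05)

  single <- structure(list(
    nodes = tibble::tibble(family = "A", size = 1L, intra_edges = 0L,
                           value = 0),
    edges = tibble::tibble(from = character(0), to = character(0),
                           weight = integer(0))),
    class = "family_meta_network")
  ls <- layout_meta(single)
  expect_equal(c(ls$nodes$x, ls$nodes$y), c(0, 0))
})

test_that("the topographic surface follows its closed form", {
  one <- structure(list(
    nodes = tibble::tibble(family = "A", size = 1L, intra_edges = 0L,
                           value = 2.5, x = 0, y = 0),
    edges = tibble::tibble(from = character(0), to = character(0),
                           weight = integer(0))),
    class = "family_meta_network")
  surf <- topographic_surface(one, bandwidth = 0.5, grid_n = 41)
  expect_equal(max(surf$z), 2.5, tolerance = 1e-6)
  # decays to (numerically) zero far away from every node
  expect_lt(abs(surface_at(one, 5, 5, bandwidth = 0.5)), 1e-6 * 2.5)

  two <- structure(list(
    nodes = tibble::tibble(family = c("A", "B"), size = 1L, intra_edges = 0L,
                           value = c(1, -1), x = c(-5, 5), y = c(0, 0)),
    edges = tibble::tibble(from = "A", to = "B", weight = 1L)),
    class = "family_meta_network")
  expect_equal(surface_at(two, c(-5, 5), c(0, 0), bandwidth = 1),
               c(1, -1), tolerance = 1e-6)
  s2 <- topographic_surface(two, bandwidth = 1, grid_n = 61)
  expect_gt(max(s2$z), 0.9)
  expect_lt(min(s2$z), -0.9)

  # linear in the values; flat when all values are zero
  s2b <- topographic_surface(two, values = c(A = 3, B = -3), bandwidth = 1,
                             grid_n = 61)
  expect_equal(s2b$z, 3 * s2$z, tolerance = 1e-9)
  s0 <- topographic_surface(two, values = c(A = 0, B = 0), bandwidth = 1)
  expect_true(all(s0$z == 0))
  expect_error(topographic_surface(two, bandwidth = -1), "positive")
})

test_that("meta-networks round-trip through GraphML, JSON and CSV", {
  net <- structure(list(
    nodes = tibble::tibble(family = c("A", "B", "C"), size = c(3L, 2L, 1L),
                           intra_edges = c(1L, 0L, 0L),
                           value = c(0.5, -0.2, 0)),
    edges = tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                           weight = c(4L, 1L))),
    class = "family_meta_network")
  net <- layout_meta(net)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_meta_network(net, gml, format = "graphml")
  back <- read_meta_network(gml, format = "graphml")
  expect_equal(back$nodes$family, net$nodes$family)
  expect_equal(back$nodes$size, net$nodes$size)
  expect_equal(back$nodes$value, net$nodes$value)
  expect_equal(back$nodes$x, net$nodes$x, tolerance = 1e-9)
  expect_equal(back$edges, net$edges)

  js <- withr::local_tempfile(fileext = ".json")
  export_meta_network(net, js, format = "json")
  bj <- read_meta_network(js, format = "json")
  expect_equal(bj$edges, net$edges)
  expect_equal(bj$nodes$value, net$nodes$value)

  cs <- withr::local_tempfile(fileext = ".csv")
  export_meta_network(net, cs, format = "csv")
  edge_back <- readr::read_csv(cs, show_col_types = FALSE)
  expect_equal(as.integer(edge_back$weight), net$edges$weight)
  expect_error(export_meta_network(net, cs, format = "dot"), "arg")
})
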