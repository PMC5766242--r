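mi_ont <- read_mi_obo(extdata("psimi_subset_synthetic.obo"))

test_that("the OBO reader assigns minimum-depth levels", {
  expect_s3_class(mi_ont, "mi_ontology")
  expect_equal(mi_level(mi_ont, "MI:0001"), 0)
  expect_equal(mi_level(mi_ont, "MI:0045"), 1)
  expect_equal(mi_level(mi_ont, "MI:0004"), 3)
  expect_equal(mi_level(mi_ont, c("MI:0006", "MI:0007")), c(5, 5))
  expect_error(mi_level(mi_ont, "MI:9999"), "unknown")
})

test_that("up-propagation is the identity at level, walks chains, and is
           idempotent", {
  expect_equal(up_propagate(mi_ont, "MI:0004", 3), "MI:0004")
  expect_equal(up_propagate(mi_ont, "MI:0006", 3), "MI:0004")
  expect_equal(up_propagate(mi_ont, "MI:0006", 0), "MI:0001")
  anc <- up_propagate(mi_ont, "MI:0397", 2)
  expect_equal(anc, "MI:0090")
  expect_equal(up_propagate(mi_ont, anc, 2), anc)
  expect_error(up_propagate(mi_ont, "MI:0045", 3), "shallower")
})

test_that("multi-parent terms up-propagate along the shallower path", {
  dag <- simulate_mi_ontology(4, branching = 2, dag_crosslink = TRUE)
  leaf <- names(dag$parents)[length(dag$parents)]
  expect_length(dag$parents[[leaf]], 2)
  # oracle: enumerate all root-ward paths, take the minimum-length one
  paths <- list()
  walk <- function(term, acc) {
    ps <- dag$parents[[term]]
    if (length(ps) == 0) {
      paths[[length(paths) + 1]] <<- acc
    } else {
      for (p in ps) walk(p, c(acc, p))
    }
  }
  walk(leaf, leaf)
  best <- paths[[which.min(lengths(paths))]]
  lv <- dag$levels[[leaf]]
  expect_equal(up_propagate(dag, leaf, lv - 1), best[2])
})

test_that("effective methods keep same-level distinct ids and collapse
           nested annotations", {
  expect_equal(effective_methods(c("MI:0019", "MI:0006"), mi_ont), "MI:0019")
  expect_setequal(effective_methods(c("MI:0006", "MI:0007"), mi_ont),
                  c("MI:0006", "MI:0007"))
  expect_equal(effective_methods("MI:0004", mi_ont), "MI:0004")
  # deep chain collapses to the shallowest representative
  expect_equal(effective_methods(c("MI:0004", "MI:0019", "MI:0006"), mi_ont),
               "MI:0004")
  expect_error(effective_methods("MI:4242", mi_ont), "MI:4242")
})

test_that("curation levels follow the eight-row table", {
  cases <- list(
    list(pm = c("P1", "P2"), me = "MI:0004", lev = "L1",
         tiers = c("SE", "ME")),
    list(pm = c("P1", "P2"), me = "MI:0018", lev = "L2",
         tiers = c("SE", "ME")),
    list(pm = "P1", me = "MI:0018", lev = "L3", tiers = "SE"),
    list(pm = "P1", me = "MI:0096", lev = "L4", tiers = "SE"),
    list(pm = c("P1", "P2"), me = c("MI:0006", "MI:0007"), lev = "L5",
         tiers = c("SE", "ME", "MM")),
    list(pm = "P1", me = c("MI:0006", "MI:0007"), lev = "L6",
         tiers = c("SE", "ME", "MM")),
    list(pm = c("P1", "P2"), me = c("MI:0018", "MI:0004"), lev = "L7",
         tiers = c("SE", "ME", "MM")),
    list(pm = "P1", me = c("MI:0018", "MI:0004"), lev = "L8",
         tiers = c("SE", "ME", "MM")))
  for (cs in cases) {
    res <- classify_edge(cs$pm, cs$me, mi_ont)
    expect_equal(res$curation_level, cs$lev)
    expect_setequal(res$tiers, cs$tiers)
  }
  # nested methods with one pmid fall back to single-method single-pub
  res <- classify_edge("P1", c("MI:0019", "MI:0006"), mi_ont)
  expect_equal(res$curation_level, "L4")
  expect_equal(res$n_effective, 1)
})

test_that("evidence reading maps, filters and counts", {
  mapping <- tibble::tibble(uniprot = c("U1", "U2", "U3", "U9"),
                            entrez_id = c(11L, 12L, 13L, 99L))
  rec <- tibble::tibble(
    id_a = c("U1", "U1", "U2", "U9", "U1", "UX"),
    id_b = c("U2", "U2", "U3", "U1", "U3", "U2"),
    method = "MI:0096",
    pmid = c("1", "1", "2", "3", "4", "5"),
    source_db = "IntAct",
    interaction_type = c("MI:0915", "MI:0915", "MI:0915", "MI:0915",
                         "MI:0914", "MI:0915"))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(rec, path)
  out <- read_evidence(path, mapping, node_filter = c(11, 12, 13))
  # U9 pair dropped by filter, MI:0914 dropped by type, UX unmapped;
  # the duplicated U1-U2 row is kept (dedup happens at edge level)
  expect_equal(nrow(out), 3)
  expect_equal(sum(out$node_a == 11 & out$node_b == 12), 2)
  log <- attr(out, "parse_log")
  expect_equal(log$n_nonphysical, 1)
  expect_equal(log$n_unmapped, 1)
  expect_equal(log$n_outside_filter, 1)
})

test_that("tier construction matches the generator's ground truth", {
  corpus <- simulate_ppi_corpus(ppi_corpus_spec(n_pairs = 500, n_nodes = 80,
                                                seed = 6))
  tiers <- build_tiers(corpus$records, mi_ont)
  got <- setNames(tiers$summary$n_edges, tiers$summary$tier)
  want <- setNames(corpus$expected_counts$n_edges,
                   corpus$expected_counts$tier)
  expect_equal(got[c("SE", "ME", "MM")], want[c("SE", "ME", "MM")])
  # per-edge tier flags agree with the profile bookkeeping
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  m <- match(key(corpus$truth$node_a, corpus$truth$node_b),
             key(tiers$edges$node_a, tiers$edges$node_b))
  expect_false(anyNA(m))
  expect_equal(tiers$edges$me[m], corpus$truth$me)
  expect_equal(tiers$edges$mm[m], corpus$truth$mm)
})

test_that("tiers are nested and classification ignores record order", {
  corpus <- simulate_ppi_corpus(ppi_corpus_spec(n_pairs = 120, seed = 2))
  tiers <- build_tiers(corpus$records, mi_ont)
  e <- tiers$edges
  expect_true(all(e$me[e$mm]))
  expect_true(all(e$se[e$me]))
  n <- tiers$summary$n_edges
  expect_true(n[3] <= n[2] && n[2] <= n[1])

  shuffled <- corpus$records[withr::with_seed(1, sample(nrow(corpus$records))), ]
  doubled <- rbind(corpus$records, corpus$records)
  t2 <- build_tiers(shuffled, mi_ont)
  t3 <- build_tiers(doubled, mi_ont)
  expect_equal(t2$edges, tiers$edges)
  expect_equal(t3$edges, tiers$edges)
})

test_that("single-evidence corpora produce an empty ME tier", {
  profiles <- tibble::tibble(name = "single", prob = 1, n_pmids = 1L,
                             methods = list("MI:0096"), n_effective = 1L)
  corpus <- simulate_ppi_corpus(ppi_corpus_spec(n_pairs = 50,
                                                profiles = profiles,
                                                seed = 3))
  tiers <- build_tiers(corpus$records, mi_ont)
  expect_equal(tiers$summary$n_edges, c(50L, 0L, 0L))

  # all pairs with two distinct same-level methods: MM equals SE
  profiles2 <- tibble::tibble(name = "pair", prob = 1, n_pmids = 1L,
                              methods = list(c("MI:0006", "MI:0007")),
                              n_effective = 2L)
  corpus2 <- simulate_ppi_corpus(ppi_corpus_spec(n_pairs = 50,
                                                 profiles = profiles2,
                                                 seed = 3))
  tiers2 <- build_tiers(corpus2$records, mi_ont)
  expect_equal(tiers2$summary$n_edges, c(50L, 50L, 50L))
})
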