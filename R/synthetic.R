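#' Specification of a synthetic multi-tissue cohort
#'
#' Validated parameter bundle for [simulate_cohort()]. The defaults define
#' the reference simulation used throughout the tests: 5 tissues with 30
#' tumor and 30 normal samples each, 10 families of 12 genes carrying
#' programmed log2 effects of -2, -1, 0, +1, +2 (two families per level)
#' plus a null background, negative-binomial counts with moderate
#' overdispersion, and mild tissue-specific baseline variation.
#'
#' @param n_tissues Number of tissue cohorts.
#' @param samples_per_arm Samples per condition per tissue (>= 2).
#' @param genes_per_family Genes per functional family.
#' @param delta Family-by-tissue matrix of log2 effects applied to tumor
#'   samples; default two families at each of -2, -1, 0, +1, +2, constant
#'   across tissues.
#' @param n_background Null background genes (never in a family). The
#'   default keeps the family genes a small fraction (~2%) of the
#'   simulated transcriptome, as the chaperome is of the genome, so that
#'   programmed family effects cannot distort library sizes enough to
#'   leak composition artifacts into null genes.
#' @param dispersion Negative-binomial size parameter (> 0).
#' @param baseline_log2_range Range of per-gene baseline log2 mean counts.
#' @param lib_factor_range Per-sample library-size multipliers.
#' @param tissue_effect_sd SD of per-(gene, tissue) baseline log2 wobble.
#' @param gene_jitter_sd SD of per-gene jitter around the family effect.
#' @param seed Integer seed.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_tissues = 5, samples_per_arm = 30,
                        genes_per_family = 12, delta = NULL,
                        n_background = 4880, dispersion = 10,
                        baseline_log2_range = c(3, 9),
                        lib_factor_range = c(0.8, 1.2),
                        tissue_effect_sd = 0.2, gene_jitter_sd = 0,
                        seed = 1) {
  if (is.null(delta)) {
    levels <- rep(c(-2, -1, 0, 1, 2), each = 2)
    delta <- matrix(levels, nrow = 10, ncol = n_tissues,
                    dimnames = list(sprintf("F%02d", 1:10),
                                    sprintf("T%02d", seq_len(n_tissues))))
  }
  if (!is.matrix(delta) || is.null(rownames(delta))) {
    abort("invalid spec field `delta`: need a named family x tissue matrix")
  }
  if (ncol(delta) != n_tissues) {
    abort("invalid spec field `delta`: column count must equal n_tissues")
  }
  if (samples_per_arm < 2) abort("invalid spec field `samples_per_arm`: >= 2")
  if (dispersion <= 0) abort("invalid spec field `dispersion`: must be > 0")
  if (genes_per_family < 2) {
    abort("invalid spec field `genes_per_family`: >= 2")
  }
  structure(list(
    n_tissues = n_tissues, samples_per_arm = samples_per_arm,
    genes_per_family = genes_per_family, delta = delta,
    n_background = n_background, dispersion = dispersion,
    baseline_log2_range = baseline_log2_range,
    lib_factor_range = lib_factor_range,
    tissue_effect_sd = tissue_effect_sd, gene_jitter_sd = gene_jitter_sd,
    seed = as.integer(seed)), class = "cohort_spec")
}

#' Simulate a multi-tissue tumor/normal count cohort
#'
#' Draws negative-binomial counts around per-gene baselines; tumor samples
#' of tissue t shift the mean of every gene in family f by the programmed
#' log2 effect `delta[f, t]` (optionally jittered per gene). The returned
#' truth table records the programmed effects, making the cohort a ground
#' truth for effect-recovery tests. Fixed seed, identical output.
#'
#' @param spec A [cohort_spec()].
#' @return List: `counts` (integer matrix), `annotation` (tibble),
#'   `truth` (tibble family/tissue/delta), `gene_families` (tibble),
#'   `sets` (family `gene_set_collection`), `background_genes`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  families <- rownames(spec$delta)
  tissues <- colnames(spec$delta)
  n_fam_genes <- length(families) * spec$genes_per_family
  gene_ids <- c(501000L + seq_len(n_fam_genes),
                601000L + seq_len(spec$n_background))
  fam_of_gene <- c(rep(families, each = spec$genes_per_family),
                   rep(NA_character_, spec$n_background))
  n_genes <- length(gene_ids)

  annotation <- purrr::map_dfr(tissues, function(ti) {
    tibble::tibble(
      sample_id = c(sprintf("%s_tumor_%02d", ti, seq_len(spec$samples_per_arm)),
                    sprintf("%s_normal_%02d", ti, seq_len(spec$samples_per_arm))),
      tissue = ti,
      condition = rep(c("tumor", "normal"), each = spec$samples_per_arm))
  })

  counts <- with_seed(spec$seed, {
    base_log2 <- runif(n_genes, spec$baseline_log2_range[1],
                       spec$baseline_log2_range[2])
    jitter <- if (spec$gene_jitter_sd > 0) {
      stats::rnorm(n_genes, 0, spec$gene_jitter_sd)
    } else {
      numeric(n_genes)
    }
    out <- matrix(0L, n_genes, nrow(annotation),
                  dimnames = list(as.character(gene_ids),
                                  annotation$sample_id))
    for (ti in tissues) {
      t_wobble <- stats::rnorm(n_genes, 0, spec$tissue_effect_sd)
      idx <- which(annotation$tissue == ti)
      for (i in idx) {
        is_tumor <- annotation$condition[i] == "tumor"
        eff <- numeric(n_genes)
        if (is_tumor) {
          in_fam <- !is.na(fam_of_gene)
          eff[in_fam] <- spec$delta[fam_of_gene[in_fam], ti] +
            jitter[in_fam]
        }
        lib <- runif(1, spec$lib_factor_range[1], spec$lib_factor_range[2])
        mu <- lib * 2^(base_log2 + t_wobble + eff)
        out[, i] <- rnbinom(n_genes, mu = mu, size = spec$dispersion)
      }
    }
    storage.mode(out) <- "integer"
    out
  })
  truth <- tibble::as_tibble(as.data.frame.table(spec$delta,
                                                 stringsAsFactors = FALSE))
  names(truth) <- c("family", "tissue", "delta")
  gene_families <- tibble::tibble(
    entrez_id = gene_ids[!is.na(fam_of_gene)],
    family = fam_of_gene[!is.na(fam_of_gene)])
  sets <- new_gene_set_collection(
    split(gene_families$entrez_id, gene_families$family),
    name = "simulated_families")
  list(counts = counts, annotation = annotation, truth = truth,
       gene_families = gene_families, sets = sets,
       background_genes = gene_ids[is.na(fam_of_gene)])
}

#' Simulate a rooted PSI-MI-style ontology
#'
#' A balanced tree of the requested depth and branching factor (term ids
#' `T<level>_<index>`); with `dag_crosslink = TRUE` the deepest-last term
#' gains a second parent one level above its first parent's level, giving a
#' deterministic multi-parent case for up-propagation tests.
#'
#' @param depth Number of levels including the root (>= 2).
#' @param branching Children per term.
#' @param dag_crosslink Add one multi-parent cross-link.
#' @return An `mi_ontology`.
#' @export
simulate_mi_ontology <- function(depth, branching = 2, dag_crosslink = FALSE) {
  if (depth < 2) abort("depth must be at least 2")
  parents <- list("T0_1" = character(0))
  prev <- "T0_1"
  for (lvl in seq_len(depth - 1)) {
    ids <- sprintf("T%d_%d", lvl, seq_len(length(prev) * branching))
    for (k in seq_along(ids)) {
      parents[[ids[k]]] <- prev[((k - 1) %/% branching) + 1]
    }
    prev <- ids
  }
  if (dag_crosslink && depth >= 3) {
    leaf <- prev[length(prev)]
    # second parent two levels up: a grandparent-level term from another
    # subtree, so the two root-ward paths have different lengths
    upper <- names(parents)[startsWith(names(parents),
                                       sprintf("T%d_", depth - 3))]
    parents[[leaf]] <- unique(c(parents[[leaf]], upper[1]))
  }
  new_mi_ontology(parents)
}

#' Specification of a synthetic PPI evidence corpus
#'
#' Each simulated pair draws one evidence profile; a profile fixes the
#' number of supporting publications, the raw method annotations (terms of
#' the shipped synthetic PSI-MI subset) and - as generator bookkeeping -
#' the number of *effective* methods those annotations collapse to, from
#' which the expected SE/ME/MM membership follows analytically.
#'
#' @param n_nodes Size of the node pool.
#' @param n_pairs Number of distinct interacting pairs.
#' @param profiles Tibble `name`, `prob`, `n_pmids`, `methods` (list
#'   column), `n_effective`; defaults cover single evidence, multi-PMID,
#'   distinct same-level methods, nested methods collapsing to one, and a
#'   binary method.
#' @param nodes Optional explicit node-id pool overriding `n_nodes`.
#' @param seed Integer seed.
#' @return A list of class `ppi_corpus_spec`.
#' @export
ppi_corpus_spec <- function(n_nodes = 60, n_pairs = 200, profiles = NULL,
                            nodes = NULL, seed = 1) {
  if (!is.null(nodes)) n_nodes <- length(nodes)
  if (is.null(profiles)) {
    profiles <- tibble::tibble(
      name = c("single", "multi_pub", "distinct_methods", "nested_methods",
               "binary_single"),
      prob = c(0.4, 0.2, 0.2, 0.1, 0.1),
      n_pmids = c(1L, 2L, 1L, 1L, 1L),
      methods = list("MI:0096", "MI:0004", c("MI:0006", "MI:0007"),
                     c("MI:0019", "MI:0006"), "MI:0018"),
      n_effective = c(1L, 1L, 2L, 1L, 1L))
  }
  if (abs(sum(profiles$prob) - 1) > 1e-8) {
    abort("invalid spec field `profiles`: probabilities must sum to 1")
  }
  max_pairs <- n_nodes * (n_nodes - 1) / 2
  if (n_pairs > max_pairs) {
    abort("invalid spec field `n_pairs`: exceeds the number of node pairs")
  }
  structure(list(n_nodes = n_nodes, n_pairs = n_pairs, profiles = profiles,
                 nodes = nodes, seed = as.integer(seed)),
            class = "ppi_corpus_spec")
}

#' Simulate a PPI evidence corpus with known tier composition
#'
#' Draws distinct node pairs and per-pair evidence profiles, emits raw
#' evidence records (one row per method-publication combination) and the
#' analytically expected SE/ME/MM edge counts as ground truth for the
#' curation pipeline.
#'
#' @param spec A [ppi_corpus_spec()].
#' @return List: `records` (tibble compatible with [build_tiers()]),
#'   `truth` (per-pair tibble with expected tier flags), `expected_counts`
#'   (tibble tier/n_edges).
#' @export
simulate_ppi_corpus <- function(spec = ppi_corpus_spec()) {
  nodes <- if (!is.null(spec$nodes)) {
    as.integer(spec$nodes)
  } else {
    301000L + seq_len(spec$n_nodes)
  }
  all_pairs <- utils::combn(nodes, 2)
  drawn <- with_seed(stream_seed(spec$seed, 8L), {
    list(pairs = sample(ncol(all_pairs), spec$n_pairs),
         prof = sample(nrow(spec$profiles), spec$n_pairs, replace = TRUE,
                       prob = spec$profiles$prob))
  })
  records <- list()
  truth <- vector("list", spec$n_pairs)
  for (i in seq_len(spec$n_pairs)) {
    pr <- spec$profiles[drawn$prof[i], ]
    pair <- all_pairs[, drawn$pairs[i]]
    pmids <- sprintf("3%07d", i * 10 + seq_len(pr$n_pmids))
    methods <- pr$methods[[1]]
    combos <- expand.grid(method = methods, pmid = pmids,
                          stringsAsFactors = FALSE)
    records[[i]] <- tibble::tibble(
      node_a = pair[1], node_b = pair[2],
      method = combos$method, pmid = combos$pmid,
      source_db = c("BioGRID", "IntAct", "DIP", "MINT")[(i %% 4) + 1],
      interaction_type = "MI:0915")
    truth[[i]] <- tibble::tibble(
      node_a = pair[1], node_b = pair[2], profile = pr$name,
      se = TRUE,
      me = pr$n_pmids > 1 || pr$n_effective > 1,
      mm = pr$n_effective > 1)
  }
  truth <- dplyr::bind_rows(truth)
  expected <- tibble::tibble(
    tier = c("SE", "ME", "MM"),
    n_edges = c(sum(truth$se), sum(truth$me), sum(truth$mm)))
  list(records = dplyr::bind_rows(records), truth = truth,
       expected_counts = expected)
}

#' Write evidence records as a MITAB-like TSV
#'
#' @param records Evidence tibble with either UniProt columns
#'   (`id_a`/`id_b`) or Entrez columns (`node_a`/`node_b`, converted
#'   through `mapping`).
#' @param path Output path.
#' @param mapping Optional `uniprot`/`entrez_id` tibble for conversion.
#' @return `path`, invisibly.
#' @export
write_mitab <- function(records, path, mapping = NULL) {
  if (!is.null(mapping) && "node_a" %in% names(records)) {
    rev_map <- setNames(mapping$uniprot, as.character(mapping$entrez_id))
    records <- dplyr::mutate(records,
                             id_a = rev_map[as.character(.data$node_a)],
                             id_b = rev_map[as.character(.data$node_b)],
                             .keep = "unused", .before = 1)
  }
  need <- c("id_a", "id_b", "method", "pmid", "source_db", "interaction_type")
  readr::write_tsv(records[, need], path)
  invisible(path)
}

#' Synthetic stand-in for the curated chaperome interaction corpus
#'
#' Deterministic evidence corpus over the synthetic chaperome whose curated
#' tiers reproduce the documented structure of the expert-curated chaperome
#' interactome: 666 SE edges over 220 nodes, of which 222 edges over 128
#' nodes carry multiple evidence (ME) and 132 edges over 96 nodes multiple
#' distinct methods (MM). Gene membership interleaves the 10 families so
#' the ME meta-network is a single connected component covering all
#' families. Evidence profiles exercise every curation level class:
#' same-level distinct coimmunoprecipitation variants (L6), binary/non-binary
#' method mixes (L8), multi-publication single-method edges (L1, L2),
#' single-evidence edges (L3, L4) and nested method annotations that
#' collapse under up-propagation (L4). A few decoy records (non-physical
#' type, unmapped accession, non-chaperome partner) exercise the read
#' filters without affecting the counts.
#'
#' @return List: `records` (UniProt-level MITAB-style tibble), `mapping`
#'   (`uniprot`/`entrez_id`), `node_universe` (chaperome Entrez ids),
#'   `membership` (tibble `entrez_id`/`family`),
#'   `expected_counts` (tibble tier/n_edges/n_nodes).
#' @export
synthetic_interactome_corpus <- function() {
  chap <- synthetic_chaperome_table()
  # interleave families round-robin so consecutive ranks hit all families
  by_fam <- split(seq_len(nrow(chap)), chap$level1)[unique(chap$level1)]
  max_n <- max(lengths(by_fam))
  order_idx <- unlist(lapply(seq_len(max_n), function(r) {
    vapply(by_fam, function(i) if (length(i) >= r) i[r] else NA_integer_,
           integer(1))
  }), use.names = FALSE)
  order_idx <- order_idx[!is.na(order_idx)]
  L <- chap$entrez_id[order_idx]

  edges <- list()
  add_edges <- function(is, js, profile) {
    for (k in seq_along(is)) {
      edges[[length(edges) + 1]] <<- list(a = L[is[k]], b = L[js[k]],
                                          profile = profile)
    }
  }
  # MM tier: 96-cycle + 36 chords over the first 96 genes (132 edges)
  add_edges(1:95, 2:96, "coip_pair")
  add_edges(96, 1, "coip_pair")
  add_edges(1:4, 3:6, "coip_pair")          # chords 1..4
  add_edges(5:36, 7:38, "binary_mix")       # chords 5..36
  # ME-only: 32 attachments of new nodes + 58 chords (90 edges)
  add_edges(96 + (1:32), 1:32, "multi_pub")
  add_edges(1:28, 4:31, "multi_pub")        # offset 3
  add_edges(29:58, 32:61, "binary_multi_pub")
  # SE-only: 92 attachments + 352 chords (444 edges)
  add_edges(128 + (1:92), 1:92, "single")
  add_edges(1:92, 5:96, "single")           # offset 4
  add_edges(1:91, 6:96, "single")           # offset 5
  add_edges(1:25, 7:31, "single")           # offset 6, part
  add_edges(26:90, 32:96, "binary_single")  # offset 6, rest (65)
  add_edges(1:15, 8:22, "binary_single")    # offset 7, part
  add_edges(16:79, 23:86, "nested")         # offset 7, rest (64)

  profiles <- list(
    coip_pair = list(methods = c("MI:0006", "MI:0007"), n_pmids = 1L),
    binary_mix = list(methods = c("MI:0018", "MI:0019"), n_pmids = 1L),
    multi_pub = list(methods = "MI:0004", n_pmids = 2L),
    binary_multi_pub = list(methods = "MI:0018", n_pmids = 2L),
    single = list(methods = "MI:0096", n_pmids = 1L),
    binary_single = list(methods = "MI:0018", n_pmids = 1L),
    nested = list(methods = c("MI:0019", "MI:0006"), n_pmids = 1L))

  mapping <- synthetic_id_mapping(chap$entrez_id)
  to_uni <- setNames(mapping$uniprot, as.character(mapping$entrez_id))
  sources <- c("BioGRID", "IntAct", "DIP", "MINT")
  rows <- vector("list", length(edges))
  for (k in seq_along(edges)) {
    e <- edges[[k]]
    pr <- profiles[[e$profile]]
    pmids <- sprintf("2%07d", k * 10 + seq_len(pr$n_pmids))
    combos <- expand.grid(method = pr$methods, pmid = pmids,
                          stringsAsFactors = FALSE)
    rows[[k]] <- tibble::tibble(
      id_a = to_uni[as.character(e$a)], id_b = to_uni[as.character(e$b)],
      method = combos$method, pmid = combos$pmid,
      source_db = sources[(k %% 4) + 1],
      interaction_type = "MI:0915")
  }
  records <- dplyr::bind_rows(rows)
  # decoys: wrong interaction type, unmapped accession, non-chaperome partner
  extra_map <- tibble::tibble(uniprot = "P900001", entrez_id = 900001L)
  mapping <- dplyr::bind_rows(mapping, extra_map)
  decoys <- tibble::tibble(
    id_a = c(to_uni[as.character(L[221])], to_uni[as.character(L[1])],
             to_uni[as.character(L[2])]),
    id_b = c(to_uni[as.character(L[222])], "Q999999", "P900001"),
    method = "MI:0096",
    pmid = c("29999991", "29999992", "29999993"),
    source_db = "IntAct",
    interaction_type = c("MI:0914", "MI:0915", "MI:0915"))
  records <- dplyr::bind_rows(records, decoys)

  keys <- vapply(edges, function(e) {
    paste(min(e$a, e$b), max(e$a, e$b), sep = "|")
  }, character(1))
  stopifnot(!anyDuplicated(keys), length(edges) == 666)

  list(records = records, mapping = mapping,
       node_universe = chap$entrez_id,
       membership = tibble::tibble(entrez_id = chap$entrez_id,
                                   family = chap$level1),
       expected_counts = tibble::tibble(
         tier = c("SE", "ME", "MM"),
         n_edges = c(666L, 222L, 132L),
         n_nodes = c(220L, 128L, 96L)))
}
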