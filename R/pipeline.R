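#' Assemble and validate a pipeline configuration
#'
#' Collects the file paths and parameters of a full profiling run. All
#' referenced paths must exist at validation time; parameters default to
#' the analysis conventions used throughout the package (100 permutations,
#' Step-2 threshold 1e-4, alpha 0.05).
#'
#' @param counts,annotation Count matrix and sample annotation TSVs.
#' @param ontology_table Chaperome annotation TSV.
#' @param mitab,obo,id_mapping Optional curation inputs; all three must be
#'   given for the curation and meta-network stages to run.
#' @param n_perm,p_threshold,alpha,family_level,min_per_arm,seed Parameters.
#' @param render Also render figure files (PNG).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, annotation, ontology_table,
                            mitab = NULL, obo = NULL, id_mapping = NULL,
                            n_perm = 100, p_threshold = 1e-4, alpha = 0.05,
                            family_level = NULL, min_per_arm = 2, seed = 1,
                            render = FALSE) {
  paths <- list(counts = counts, annotation = annotation,
                ontology_table = ontology_table, mitab = mitab, obo = obo,
                id_mapping = id_mapping)
  curation_given <- !vapply(paths[c("mitab", "obo", "id_mapping")],
                            is.null, logical(1))
  if (any(curation_given) && !all(curation_given)) {
    abort("curation needs all of `mitab`, `obo` and `id_mapping`")
  }
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("config path `%s` does not exist: %s", nm, p))
    }
  }
  structure(list(paths = paths, n_perm = n_perm, p_threshold = p_threshold,
                 alpha = alpha, family_level = family_level,
                 min_per_arm = min_per_arm, seed = as.integer(seed),
                 render = isTRUE(render),
                 curation = all(curation_given)),
            class = "pipeline_config")
}

#' Write a self-contained synthetic demo input bundle
#'
#' Simulates a small cohort and interaction corpus, writes every input file
#' the pipeline reads, and returns a ready [pipeline_config()]. Used by the
#' examples and the end-to-end determinism checks.
#'
#' @param dir Directory for the input files.
#' @param seed Integer seed for the simulated cohort.
#' @param spec Optional [cohort_spec()] override.
#' @param render Forwarded to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
demo_config <- function(dir, seed = 1, spec = NULL, render = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- spec %||% cohort_spec(n_tissues = 3, samples_per_arm = 12,
                                n_background = 300, seed = seed)
  sim <- simulate_cohort(spec)
  write_counts(sim$counts, sim$annotation,
               file.path(dir, "counts.tsv"), file.path(dir, "annotation.tsv"))
  fam_tbl <- dplyr::mutate(sim$gene_families,
                           symbol = paste0("G", .data$entrez_id),
                           level1 = .data$family, role = "chaperone",
                           atp = "dependent")
  readr::write_tsv(
    fam_tbl[, c("symbol", "entrez_id", "level1", "role", "atp")],
    file.path(dir, "ontology.tsv"))
  corpus <- simulate_ppi_corpus(
    ppi_corpus_spec(nodes = sim$gene_families$entrez_id, n_pairs = 200,
                    seed = seed))
  mapping <- synthetic_id_mapping(unique(c(corpus$records$node_a,
                                           corpus$records$node_b)))
  write_mitab(corpus$records, file.path(dir, "evidence.tsv"),
              mapping = mapping)
  readr::write_tsv(mapping, file.path(dir, "id_mapping.tsv"))
  synthetic_psimi_obo(file.path(dir, "psimi.obo"))
  pipeline_config(
    counts = file.path(dir, "counts.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    ontology_table = file.path(dir, "ontology.tsv"),
    mitab = file.path(dir, "evidence.tsv"),
    obo = file.path(dir, "psimi.obo"),
    id_mapping = file.path(dir, "id_mapping.tsv"),
    seed = seed, render = render)
}

#' Run the full profiling pipeline
#'
#' Normalisation (logCPM + per-tissue centering), gene-set analysis,
#' Meta-PCA fitting and scoring with polar summaries,
#' differential-expression testing, evidence curation and the family
#' meta-network with its topographic surface, all written as plain-text
#' artifacts plus a provenance record (config digest, seed, package
#' version). A stage failure halts the run with a stage-named error;
#' artifacts of completed stages remain on disk.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisible list of the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  results$normalize <- stage("normalize", {
    inp <- read_counts(config$paths$counts, config$paths$annotation)
    expr <- center_genes(log_cpm(inp$counts), inp$annotation,
                         scope = "per-tissue")
    out <- tibble::tibble(entrez_id = rownames(expr))
    out <- dplyr::bind_cols(out, tibble::as_tibble(expr))
    readr::write_tsv(out, file.path(out_dir, "logcpm_centered.tsv"))
    list(expr = expr, annotation = inp$annotation)
  })
  expr <- results$normalize$expr
  annotation <- results$normalize$annotation

  results$ontology <- stage("ontology", {
    ont <- read_chaperome_ontology(config$paths$ontology_table,
                                   family_level = config$family_level)
    sets <- family_gene_sets(ont)
    write_gene_sets(sets, file.path(out_dir, "family_sets.json"))
    list(ontology = ont, sets = sets)
  })
  sets <- results$ontology$sets

  results$gsa <- stage("gsa", {
    gsa <- run_gsa(expr, annotation, sets, n_perm = config$n_perm,
                   seed = config$seed, min_per_arm = config$min_per_arm)
    readr::write_tsv(gsa, file.path(out_dir, "gsa.tsv"))
    readr::write_tsv(gsa_group_means(gsa),
                     file.path(out_dir, "gsa_group_means.tsv"))
    gsa
  })

  results$metapca <- stage("metapca", {
    fit <- fit_metapca(expr, annotation, sets,
                       p_threshold = config$p_threshold,
                       min_per_arm = config$min_per_arm)
    write_metapca(fit, file.path(out_dir, "metapca.json"))
    scores <- score_samples(expr, fit, annotation)
    readr::write_tsv(scores, file.path(out_dir, "mscores.tsv"))
    polar <- polar_summary(scores)
    readr::write_tsv(polar, file.path(out_dir, "polar_summary.tsv"))
    list(fit = fit, scores = scores, polar = polar)
  })

  results$de <- stage("de", {
    tissues <- select_paired_tissues(annotation,
                                     min_per_arm = config$min_per_arm)
    de <- purrr::map_dfr(tissues, function(ti) {
      ann <- annotation[annotation$tissue == ti, ]
      res <- de_test(expr[, ann$sample_id, drop = FALSE], ann$condition)
      dplyr::mutate(res, tissue = ti, .before = 1)
    })
    readr::write_tsv(de, file.path(out_dir, "de.tsv"))
    fracs <- purrr::map_dfr(tissues, function(ti) {
      sub <- de[de$tissue == ti, ]
      purrr::map_dfr(names(sets), function(fam) {
        tibble::tibble(tissue = ti, set = fam,
                       de_fraction = de_fraction(
                         sub, intersect(sets[[fam]], sub$gene_id),
                         alpha = config$alpha))
      })
    })
    readr::write_tsv(fracs, file.path(out_dir, "de_fractions.tsv"))
    list(de = de, fractions = fracs)
  })

  if (config$curation) {
    results$curation <- stage("curation", {
      ontology <- read_mi_obo(config$paths$obo)
      mapping <- readr::read_tsv(config$paths$id_mapping,
                                 show_col_types = FALSE)
      records <- read_evidence(config$paths$mitab, mapping)
      tiers <- build_tiers(records, ontology)
      write_tiers(tiers, out_dir)
      list(tiers = tiers, ontology = ontology)
    })

    results$metanetwork <- stage("metanetwork", {
      me <- tier_edges(results$curation$tiers, "ME")
      nodes <- unique(c(me$node_a, me$node_b))
      membership <- setNames(rep("all", length(nodes)), nodes)
      # prefer family membership when the expression families cover the nodes
      fam_map <- unlist(lapply(names(sets), function(f) {
        setNames(rep(f, length(sets[[f]])), as.character(sets[[f]]))
      }))
      if (all(as.character(nodes) %in% names(fam_map))) {
        membership <- fam_map[as.character(nodes)]
      }
      meta <- collapse_to_meta(me, membership)
      values <- dplyr::summarise(
        dplyr::group_by(results$metapca$scores, .data$family),
        value = mean(.data$mscore[.data$condition == "tumor"]) -
          mean(.data$mscore[.data$condition == "normal"]),
        .groups = "drop")
      names(values)[2] <- "value"
      meta <- set_meta_values(meta, values)
      meta$nodes$value[is.na(meta$nodes$value)] <- 0
      meta <- layout_meta(meta, seed = config$seed)
      export_meta_network(meta, file.path(out_dir, "meta_network.graphml"),
                          format = "graphml")
      export_meta_network(meta, file.path(out_dir, "meta_network.json"),
                          format = "json")
      surface <- topographic_surface(meta)
      readr::write_tsv(surface, file.path(out_dir, "surface.tsv"))
      list(meta = meta, surface = surface)
    })
  }

  if (config$render) {
    stage("render", {
      render_reports(results, out_dir)
    })
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("chaperoscope")),
    seed = config$seed,
    n_perm = config$n_perm,
    p_threshold = config$p_threshold,
    alpha = config$alpha,
    config_digest = config_digest(config))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

# FNV-1a digest of the serialized configuration (provenance only).
config_digest <- function(config) {
  bytes <- as.integer(charToRaw(paste(
    utils::capture.output(utils::str(config)), collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Render figure files for pipeline results
#'
#' Writes the signed-score heatmap, one polar plot, the meta-network and
#' the topographic surface as PNG files. Skips figures whose inputs are
#' absent from `results`.
#'
#' @param results The list returned by [run_pipeline()].
#' @param out_dir Output directory.
#' @param width,height,dpi Device settings.
#' @return Invisible character vector of files written.
#' @export
render_reports <- function(results, out_dir, width = 7, height = 6,
                           dpi = 150) {
  written <- character(0)
  save_png <- function(plot, name) {
    path <- file.path(out_dir, name)
    grDevices::png(path, width = width * dpi, height = height * dpi,
                   res = dpi)
    print(plot)
    grDevices::dev.off()
    written <<- c(written, path)
  }
  if (!is.null(results$gsa)) {
    save_png(autoplot(results$gsa), "gsa_heatmap.png")
  }
  if (!is.null(results$metapca)) {
    save_png(autoplot(results$metapca$polar), "polar.png")
  }
  if (!is.null(results$metanetwork)) {
    save_png(autoplot(results$metanetwork$meta), "meta_network.png")
    save_png(autoplot(results$metanetwork$surface), "surface.png")
  }
  invisible(written)
}
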