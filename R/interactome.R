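#' Read a PSI-MI ontology from an OBO file
#'
#' Minimal OBO reader covering `[Term]` stanzas with `id`, `name` and `is_a`
#' tags (obsolete terms are skipped). The PSI-MI vocabulary is formally a
#' DAG; the term level used throughout curation is the minimum depth from a
#' root, and up-propagation follows a minimum-depth path.
#'
#' @param path Path to an OBO file.
#' @return An object of class `mi_ontology`: `parents` (named list),
#'   `term_names`, `levels` (named integer, roots at 0), `roots`.
#' @export
read_mi_obo <- function(path) {
  lines <- readLines(path)
  terms <- list()
  current <- NULL
  in_term <- FALSE
  flush <- function() {
    if (!is.null(current) && !isTRUE(current$obsolete) &&
        !is.null(current$id)) {
      terms[[current$id]] <<- current
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      current <- list(parents = character(0))
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      flush()
      current <- NULL
      in_term <- FALSE
    } else if (in_term && !is.null(current)) {
      if (startsWith(ln, "id:")) {
        current$id <- trimws(sub("^id:", "", ln))
      } else if (startsWith(ln, "name:")) {
        current$name <- trimws(sub("^name:", "", ln))
      } else if (startsWith(ln, "is_a:")) {
        parent <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
        current$parents <- c(current$parents, parent)
      } else if (startsWith(ln, "is_obsolete:") && grepl("true", ln)) {
        current$obsolete <- TRUE
      }
    }
  }
  flush()
  parents <- lapply(terms, `[[`, "parents")
  parents <- lapply(parents, function(p) intersect(p, names(terms)))
  term_names <- vapply(terms, function(t) t$name %||% t$id, character(1))
  new_mi_ontology(parents, term_names)
}

#' Construct a PSI-MI ontology object from a parent map
#'
#' @param parents Named list: term id -> character vector of parent ids
#'   (empty for roots).
#' @param term_names Optional named character vector of term labels.
#' @return An `mi_ontology` object with levels assigned (minimum depth).
#' @export
new_mi_ontology <- function(parents, term_names = NULL) {
  ids <- names(parents)
  roots <- ids[lengths(parents) == 0]
  if (length(roots) == 0) abort("ontology has no root term")
  levels <- setNames(rep(NA_integer_, length(ids)), ids)
  levels[roots] <- 0L
  frontier <- roots
  depth <- 0L
  while (length(frontier) > 0) {
    depth <- depth + 1L
    nxt <- ids[vapply(parents, function(p) any(p %in% frontier), logical(1))]
    nxt <- nxt[is.na(levels[nxt])]
    levels[nxt] <- depth
    frontier <- nxt
    if (depth > length(ids)) abort("cycle detected in ontology")
  }
  if (anyNA(levels)) {
    abort(paste0("term(s) not reachable from a root: ",
                 paste(ids[is.na(levels)], collapse = ", ")))
  }
  structure(list(parents = parents,
                 term_names = term_names %||% setNames(ids, ids),
                 levels = levels, roots = roots),
            class = "mi_ontology")
}

#' @export
print.mi_ontology <- function(x, ...) {
  cat("<mi_ontology> ", length(x$parents), " terms, max level ",
      max(x$levels), "\n", sep = "")
  invisible(x)
}

#' Ontology level of a term
#'
#' @param ontology An `mi_ontology`.
#' @param term Term id(s).
#' @return Integer level(s); roots are at level 0.
#' @export
mi_level <- function(ontology, term) {
  lv <- ontology$levels[term]
  if (anyNA(lv)) {
    abort(paste0("unknown term(s): ",
                 paste(term[is.na(lv)], collapse = ", ")))
  }
  unname(lv)
}

#' Up-propagate a term to a shallower ontology level
#'
#' Walks root-ward to the ancestor at exactly `target_level`. At each step
#' the parent of minimum level is taken (ties broken by term id), i.e. a
#' minimum-depth path, which handles multi-parent DAG terms
#' deterministically.
#'
#' @param ontology An `mi_ontology`.
#' @param term Term id.
#' @param target_level Integer level, at most the term's level.
#' @return Ancestor term id at `target_level` (the term itself when already
#'   there).
#' @export
up_propagate <- function(ontology, term, target_level) {
  lv <- mi_level(ontology, term)
  if (target_level > lv) {
    abort(sprintf("term %s is at level %d, shallower than target %d",
                  term, lv, target_level))
  }
  current <- term
  while (mi_level(ontology, current) > target_level) {
    pars <- ontology$parents[[current]]
    if (length(pars) == 0) {
      abort(sprintf("no ancestor of %s at level %d (malformed ontology)",
                    term, target_level))
    }
    plv <- ontology$levels[pars]
    pars <- pars[order(plv, pars)]
    current <- pars[1]
  }
  current
}

# All ancestors of a term (including itself), via every parent path.
mi_lineage <- function(ontology, term) {
  seen <- character(0)
  frontier <- term
  while (length(frontier) > 0) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(ontology$parents[frontier])), seen)
  }
  seen
}

#' Is a detection method binary?
#'
#' A method counts as binary when its up-propagated lineage (itself or any
#' ancestor) meets the configured binary branch set. The default branch is
#' the protein complementation assay family (MI:0090, which covers the
#' two-hybrid methods).
#'
#' @param ontology An `mi_ontology`.
#' @param term Method term id(s).
#' @param binary_terms Term ids defining the binary branches.
#' @return Logical vector.
#' @export
is_binary_method <- function(ontology, term, binary_terms = c("MI:0090")) {
  vapply(term, function(t) {
    length(intersect(mi_lineage(ontology, t), binary_terms)) > 0
  }, logical(1))
}

#' Deduplicate method annotations by level-matched up-propagation
#'
#' Two methods at the same ontology level with different ids are different
#' evidence; when levels differ, the deeper term is up-propagated to the
#' shallower level and dropped if it lands on the same id (the deeper
#' annotation is then just a refinement of the same experiment class). The
#' result is the maximal set of pairwise-distinct methods.
#'
#' @param methods Character vector of method term ids.
#' @param ontology An `mi_ontology`.
#' @return Sorted character vector of effective methods.
#' @export
effective_methods <- function(methods, ontology) {
  methods <- unique(as.character(methods))
  mi_level(ontology, methods) # validates
  kept <- methods[order(ontology$levels[methods], methods)]
  changed <- TRUE
  while (changed && length(kept) > 1) {
    changed <- FALSE
    for (i in seq_along(kept)) {
      for (j in seq_along(kept)) {
        if (i == j) next
        a <- kept[j]
        b <- kept[i]
        la <- ontology$levels[[a]]
        lb <- ontology$levels[[b]]
        if (la > lb && up_propagate(ontology, a, lb) == b) {
          kept <- setdiff(kept, a)
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  sort(kept)
}

#' Classify one interaction's evidence into a curation level
#'
#' Applies the eight-level curation table on the effective method count
#' (after ontology deduplication), binary-method membership and the number
#' of supporting publications, then derives the tier memberships:
#' single-evidence (SE, always), multiple-evidence (ME, more than one PMID
#' or more than one effective method) and multiple-method (MM, more than
#' one effective method).
#'
#' @param pmids Publication ids supporting the edge.
#' @param methods Raw method term ids.
#' @param ontology An `mi_ontology`.
#' @param binary_terms Binary branch configuration.
#' @return List `curation_level` (`"L1"`..`"L8"`), `tiers`,
#'   `effective_methods`, `n_effective`, `n_pmids`, `n_binary`.
#' @export
classify_edge <- function(pmids, methods, ontology,
                          binary_terms = c("MI:0090")) {
  pmids <- unique(as.character(pmids))
  if (length(pmids) == 0 || length(methods) == 0) {
    abort("an edge needs at least one PMID and one method")
  }
  eff <- effective_methods(methods, ontology)
  n_eff <- length(eff)
  n_pm <- length(pmids)
  n_binary <- sum(is_binary_method(ontology, eff, binary_terms))
  level <- if (n_eff == 1) {
    if (n_binary >= 1) {
      if (n_pm > 1) "L2" else "L3"
    } else {
      if (n_pm > 1) "L1" else "L4"
    }
  } else {
    if (n_binary >= 1) {
      if (n_pm > 1) "L7" else "L8"
    } else {
      if (n_pm > 1) "L5" else "L6"
    }
  }
  tiers <- c("SE",
             if (n_pm > 1 || n_eff > 1) "ME",
             if (n_eff > 1) "MM")
  list(curation_level = level, tiers = tiers, effective_methods = eff,
       n_effective = n_eff, n_pmids = n_pm, n_binary = n_binary)
}

#' Read interaction evidence records from MITAB-like files
#'
#' Expects tab-separated files with header columns `id_a`, `id_b`, `method`,
#' `pmid`, `source_db`, `interaction_type`, identifiers given as UniProt
#' accessions. Records are mapped to Entrez through `id_mapping`
#' (columns `uniprot`, `entrez_id`); unmapped or malformed rows are dropped
#' and counted. Only records typed as PSI-MI 'physical association'
#' (MI:0915; optionally its descendants) survive, and an optional node
#' filter restricts to pairs inside a gene universe.
#'
#' @param paths One or more MITAB-like TSV paths.
#' @param id_mapping Tibble `uniprot`, `entrez_id`.
#' @param node_filter Optional Entrez-id universe; both partners must be in.
#' @param physical_term Accepted interaction-type term (default `MI:0915`).
#' @param include_descendants Accept descendants of `physical_term` too
#'   (requires `ontology`).
#' @param ontology `mi_ontology`, only needed for descendant matching.
#' @return Tibble `node_a`, `node_b`, `method`, `pmid`, `source_db`,
#'   `interaction_type` with attribute `parse_log` (per-source counts).
#' @export
read_evidence <- function(paths, id_mapping, node_filter = NULL,
                          physical_term = "MI:0915",
                          include_descendants = FALSE, ontology = NULL) {
  raw <- purrr::map_dfr(paths, function(p) {
    readr::read_tsv(p, show_col_types = FALSE,
                    col_types = readr::cols(.default = "c"))
  })
  need <- c("id_a", "id_b", "method", "pmid", "source_db", "interaction_type")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("evidence file missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  n_total <- nrow(raw)
  malformed <- rowSums(is.na(raw[, need]) | raw[, need] == "") > 0
  raw <- raw[!malformed, ]
  if (include_descendants) {
    if (is.null(ontology)) abort("descendant matching needs `ontology`")
    keep_type <- vapply(raw$interaction_type, function(t) {
      t %in% names(ontology$levels) &&
        physical_term %in% mi_lineage(ontology, t)
    }, logical(1))
  } else {
    keep_type <- raw$interaction_type == physical_term
  }
  n_nonphysical <- sum(!keep_type)
  raw <- raw[keep_type, ]
  map <- setNames(as.integer(id_mapping$entrez_id), id_mapping$uniprot)
  ea <- map[raw$id_a]
  eb <- map[raw$id_b]
  mapped <- !is.na(ea) & !is.na(eb)
  n_unmapped <- sum(!mapped)
  out <- tibble::tibble(node_a = ea[mapped], node_b = eb[mapped],
                        method = raw$method[mapped],
                        pmid = raw$pmid[mapped],
                        source_db = raw$source_db[mapped],
                        interaction_type = raw$interaction_type[mapped])
  n_outside <- 0L
  if (!is.null(node_filter)) {
    node_filter <- as.integer(node_filter)
    inside <- out$node_a %in% node_filter & out$node_b %in% node_filter
    n_outside <- sum(!inside)
    out <- out[inside, ]
  }
  attr(out, "parse_log") <- list(
    n_total = n_total, n_malformed = sum(malformed),
    n_nonphysical = n_nonphysical, n_unmapped = n_unmapped,
    n_outside_filter = n_outside, n_kept = nrow(out),
    per_source = table(out$source_db))
  out
}

#' Build the SE/ME/MM interactome tiers
#'
#' Groups evidence records by unordered node pair, classifies each pair's
#' pooled evidence into a curation level and emits the three nested tiers:
#' every curated edge belongs to SE; ME keeps edges with multiple PMIDs or
#' multiple effective methods; MM keeps edges with multiple effective
#' methods. Self-interactions (homodimers) are retained unless
#' `drop_self = TRUE`.
#'
#' @param records Evidence tibble from [read_evidence()] (or the synthetic
#'   corpus generator).
#' @param ontology An `mi_ontology`.
#' @param binary_terms Binary branch configuration.
#' @param drop_self Drop self-interactions.
#' @return An object of class `chap_tiers`: `edges` (one row per unordered
#'   pair with level, tiers and evidence) and `summary` (tier edge/node
#'   counts).
#' @export
build_tiers <- function(records, ontology, binary_terms = c("MI:0090"),
                        drop_self = FALSE) {
  if (nrow(records) == 0) abort("no evidence records")
  a <- pmin(records$node_a, records$node_b)
  b <- pmax(records$node_a, records$node_b)
  if (drop_self) {
    keep <- a != b
    records <- records[keep, ]
    a <- a[keep]
    b <- b[keep]
  }
  key <- paste(a, b, sep = "|")
  groups <- split(seq_len(nrow(records)), key)
  edges <- purrr::map_dfr(names(groups), function(k) {
    idx <- groups[[k]]
    cls <- classify_edge(records$pmid[idx], records$method[idx], ontology,
                         binary_terms)
    nodes <- as.integer(strsplit(k, "|", fixed = TRUE)[[1]])
    tibble::tibble(
      node_a = nodes[1], node_b = nodes[2],
      curation_level = cls$curation_level,
      n_pmids = cls$n_pmids,
      pmids = paste(sort(unique(records$pmid[idx])), collapse = ";"),
      raw_methods = paste(sort(unique(records$method[idx])), collapse = ";"),
      effective_methods = paste(cls$effective_methods, collapse = ";"),
      n_effective = cls$n_effective,
      n_binary = cls$n_binary,
      se = TRUE,
      me = "ME" %in% cls$tiers,
      mm = "MM" %in% cls$tiers)
  })
  edges <- dplyr::arrange(edges, .data$node_a, .data$node_b)
  summary <- purrr::map_dfr(c("se", "me", "mm"), function(tier) {
    sub <- edges[edges[[tier]], ]
    tibble::tibble(tier = toupper(tier), n_edges = nrow(sub),
                   n_nodes = length(unique(c(sub$node_a, sub$node_b))))
  })
  structure(list(edges = edges, summary = summary), class = "chap_tiers")
}

#' @export
print.chap_tiers <- function(x, ...) {
  cat("<chap_tiers>\n")
  print(x$summary)
  invisible(x)
}

#' Edge table of one tier
#'
#' @param tiers A `chap_tiers` object.
#' @param tier `"SE"`, `"ME"` or `"MM"`.
#' @return Edge tibble restricted to the tier.
#' @export
tier_edges <- function(tiers, tier = c("SE", "ME", "MM")) {
  tier <- match.arg(tier)
  tiers$edges[tiers$edges[[tolower(tier)]], ]
}

#' Write per-tier edge tables and a JSON summary
#'
#' @param tiers A `chap_tiers` object.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_tiers <- function(tiers, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (tier in c("SE", "ME", "MM")) {
    readr::write_tsv(tier_edges(tiers, tier),
                     file.path(out_dir, paste0(tolower(tier), "_chap.tsv")))
  }
  stats <- split(tiers$summary[, c("n_edges", "n_nodes")], tiers$summary$tier)
  jsonlite::write_json(lapply(stats, as.list), file.path(out_dir, "tiers.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
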