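#' Collapse a gene-level network into family meta-nodes and meta-edges
#'
#' Every network node is mapped to its functional family; edges inside a
#' family are recorded as the meta-node's intra-family count, edges between
#' two families are bundled into one meta-edge whose weight is the number of
#' underlying edges. Families present in the membership but without network
#' nodes appear as isolated meta-nodes of size 0, so the full family
#' repertoire is always drawn. Conservation holds by construction: meta-edge
#' weights plus intra-family counts sum to the number of source edges.
#'
#' @param edges Tibble with `node_a`, `node_b` (gene ids).
#' @param membership Named vector gene id -> family label, or a tibble with
#'   `entrez_id` and `family` columns.
#' @return Object of class `family_meta_network`: `nodes` (family, size,
#'   intra_edges, value) and `edges` (from, to, weight).
#' @export
collapse_to_meta <- function(edges, membership) {
  if (is.data.frame(membership)) {
    membership <- setNames(membership$family,
                           as.character(membership$entrez_id))
  }
  nodes <- unique(c(edges$node_a, edges$node_b))
  fam <- membership[as.character(nodes)]
  if (anyNA(fam)) {
    abort(paste0("unannotated network node(s): ",
                 paste(nodes[is.na(fam)], collapse = ", ")))
  }
  families <- sort(unique(unname(membership)))
  fa <- membership[as.character(edges$node_a)]
  fb <- membership[as.character(edges$node_b)]
  intra <- table(factor(fa[fa == fb], levels = families))
  inter <- data.frame(
    from = pmin(fa, fb)[fa != fb],
    to = pmax(fa, fb)[fa != fb])
  meta_edges <- if (nrow(inter) > 0) {
    agg <- dplyr::count(inter, .data$from, .data$to, name = "weight")
    tibble::as_tibble(agg)
  } else {
    tibble::tibble(from = character(0), to = character(0),
                   weight = integer(0))
  }
  sizes <- table(factor(fam, levels = families))
  meta_nodes <- tibble::tibble(
    family = families,
    size = as.integer(sizes[families]),
    intra_edges = as.integer(intra[families]),
    value = NA_real_)
  stopifnot(sum(meta_edges$weight) + sum(meta_nodes$intra_edges) ==
              nrow(edges))
  structure(list(nodes = meta_nodes, edges = meta_edges),
            class = "family_meta_network")
}

#' @export
print.family_meta_network <- function(x, ...) {
  cat("<family_meta_network> ", nrow(x$nodes), " meta-nodes, ",
      nrow(x$edges), " meta-edges\n", sep = "")
  invisible(x)
}

#' Attach per-family values (M-scores or delta-GSA) to meta-nodes
#'
#' @param meta A `family_meta_network`.
#' @param values Tibble `family`, `value` (or named numeric vector).
#' @return The network with the `value` column filled.
#' @export
set_meta_values <- function(meta, values) {
  if (!is.data.frame(values)) {
    values <- tibble::tibble(family = names(values),
                             value = as.numeric(values))
  }
  idx <- match(meta$nodes$family, values$family)
  meta$nodes$value <- values$value[idx]
  meta
}

#' Force-directed layout of a family meta-network
#'
#' Kamada-Kawai layout with edge target distances set to the inverse
#' meta-edge weight, so strongly coupled families sit closer. The
#' deterministic circular initialisation makes coordinates reproducible;
#' disconnected meta-networks are handled component-wise by the layout
#' engine (noted with a message). A single meta-node is placed at the
#' origin.
#'
#' @param meta A `family_meta_network`.
#' @param seed Unused by the deterministic initialisation; kept in the
#'   signature for pipeline provenance.
#' @return The network with `x`, `y` columns on `nodes`.
#' @export
layout_meta <- function(meta, seed = 1) {
  n <- nrow(meta$nodes)
  if (n == 1) {
    meta$nodes$x <- 0
    meta$nodes$y <- 0
    return(meta)
  }
  g <- meta_igraph(meta)
  if (igraph::count_components(g) > 1) {
    message("meta-network is disconnected; components laid out independently")
  }
  init <- igraph::layout_in_circle(g)
  wts <- if (nrow(meta$edges) > 0) 1 / meta$edges$weight else NULL
  coords <- igraph::layout_with_kk(g, coords = init, weights = wts)
  meta$nodes$x <- coords[, 1]
  meta$nodes$y <- coords[, 2]
  meta
}

# igraph view of a meta-network (vertices = families).
meta_igraph <- function(meta) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(meta$nodes), name = meta$nodes$family,
                            size = meta$nodes$size,
                            intra_edges = meta$nodes$intra_edges,
                            value = meta$nodes$value)
  if (nrow(meta$edges) > 0) {
    g <- igraph::add_edges(
      g, rbind(match(meta$edges$from, meta$nodes$family),
               match(meta$edges$to, meta$nodes$family)),
      weight = meta$edges$weight)
  }
  g
}

#' Topographic surface over a laid-out meta-network
#'
#' Builds the z(x, y) landscape as a Gaussian radial-basis mixture centered
#' on the meta-node coordinates with the family values as amplitudes:
#' `z = sum_f value_f * exp(-d_f^2 / (2 bw^2))`. The surface is linear in
#' the values and decays to zero away from all nodes.
#'
#' @param meta A laid-out `family_meta_network` with values set (or pass
#'   `values`).
#' @param values Optional per-family values overriding `nodes$value`.
#' @param bandwidth Kernel bandwidth; default 0.25 x the median inter-node
#'   distance. Must be positive.
#' @param grid_n Grid resolution per axis (default 60).
#' @return Tibble of class `chap_surface` with `x`, `y`, `z`; attributes
#'   `bandwidth` and `nodes`.
#' @export
topographic_surface <- function(meta, values = NULL, bandwidth = NULL,
                                grid_n = 60) {
  nodes <- meta$nodes
  if (!all(c("x", "y") %in% names(nodes))) {
    abort("layout the meta-network first (layout_meta)")
  }
  if (!is.null(values)) {
    nodes <- set_meta_values(meta, values)$nodes
  }
  if (anyNA(nodes$value)) abort("every family needs a value for the surface")
  if (is.null(bandwidth)) {
    d <- dist(cbind(nodes$x, nodes$y))
    bandwidth <- if (length(d) == 0) 1 else 0.25 * stats::median(d)
    if (bandwidth == 0) bandwidth <- 1
  }
  if (bandwidth <= 0) abort("bandwidth must be positive")
  pad <- 3 * bandwidth
  gx <- seq(min(nodes$x) - pad, max(nodes$x) + pad, length.out = grid_n)
  gy <- seq(min(nodes$y) - pad, max(nodes$y) + pad, length.out = grid_n)
  grid <- expand.grid(x = gx, y = gy)
  z <- numeric(nrow(grid))
  for (i in seq_len(nrow(nodes))) {
    d2 <- (grid$x - nodes$x[i])^2 + (grid$y - nodes$y[i])^2
    z <- z + nodes$value[i] * exp(-d2 / (2 * bandwidth^2))
  }
  out <- tibble::as_tibble(cbind(grid, z = z))
  attr(out, "bandwidth") <- bandwidth
  attr(out, "nodes") <- nodes
  class(out) <- c("chap_surface", class(out))
  out
}

#' Evaluate the surface at arbitrary points
#'
#' Closed-form evaluation of the same Gaussian mixture used by
#' [topographic_surface()], e.g. at the meta-node centers.
#'
#' @param meta Laid-out meta-network with values.
#' @param px,py Coordinates to evaluate at.
#' @param bandwidth Kernel bandwidth.
#' @return Numeric vector of z values.
#' @export
surface_at <- function(meta, px, py, bandwidth) {
  nodes <- meta$nodes
  vapply(seq_along(px), function(i) {
    sum(nodes$value * exp(-((px[i] - nodes$x)^2 + (py[i] - nodes$y)^2) /
                            (2 * bandwidth^2)))
  }, numeric(1))
}

#' Export a meta-network
#'
#' `graphml` (via igraph, round-trippable), `json` (full fidelity) or `csv`
#' (edge list with weights).
#'
#' @param meta A `family_meta_network`.
#' @param path Output file path.
#' @param format `"graphml"`, `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_meta_network <- function(meta, path,
                                format = c("graphml", "json", "csv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- meta_igraph(meta)
    if ("x" %in% names(meta$nodes)) {
      igraph::V(g)$x <- meta$nodes$x
      igraph::V(g)$y <- meta$nodes$y
    }
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "json") {
    jsonlite::write_json(list(nodes = meta$nodes, edges = meta$edges),
                         path, digits = NA, na = "null")
  } else {
    readr::write_csv(meta$edges, path)
  }
  invisible(path)
}

#' Read a meta-network back from GraphML or JSON
#'
#' @param path File path.
#' @param format `"graphml"` or `"json"`.
#' @return A `family_meta_network`.
#' @export
read_meta_network <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- tibble::tibble(
      family = igraph::V(g)$name,
      size = as.integer(igraph::V(g)$size),
      intra_edges = as.integer(igraph::V(g)$intra_edges),
      value = suppressWarnings(as.numeric(igraph::V(g)$value)))
    if ("x" %in% igraph::vertex_attr_names(g)) {
      nodes$x <- igraph::V(g)$x
      nodes$y <- igraph::V(g)$y
    }
    el <- igraph::as_edgelist(g)
    edges <- if (nrow(el) > 0) {
      tibble::tibble(from = pmin(el[, 1], el[, 2]),
                     to = pmax(el[, 1], el[, 2]),
                     weight = as.integer(igraph::E(g)$weight))
    } else {
      tibble::tibble(from = character(0), to = character(0),
                     weight = integer(0))
    }
    edges <- dplyr::arrange(edges, .data$from, .data$to)
  } else {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    nodes <- tibble::as_tibble(raw$nodes)
    edges <- tibble::as_tibble(raw$edges)
    if (nrow(edges) == 0) {
      edges <- tibble::tibble(from = character(0), to = character(0),
                              weight = integer(0))
    }
    edges$weight <- as.integer(edges$weight)
    nodes$size <- as.integer(nodes$size)
    nodes$intra_edges <- as.integer(nodes$intra_edges)
    nodes$value <- as.numeric(nodes$value)
  }
  structure(list(nodes = nodes, edges = edges),
            class = "family_meta_network")
}
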