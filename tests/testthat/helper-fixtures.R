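# Shared fixture builders. Everything is generated in code; nothing binary.

extdata <- function(name) {
  system.file("extdata", name, package = "chaperoscope")
}

# Small expression matrix with named genes/samples.
toy_expr <- function(n_genes = 20, n_samples = 12, seed = 1,
                     shift_genes = NULL, shift = 0) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                dimnames = list(paste0("g", seq_len(n_genes)),
                                paste0("s", seq_len(n_samples))))
    cond <- rep(c("tumor", "normal"), each = n_samples / 2)
    if (!is.null(shift_genes)) {
      m[shift_genes, cond == "tumor"] <-
        m[shift_genes, cond == "tumor"] + shift
    }
    list(expr = m, condition = cond)
  })
}

# Annotation for a single-tissue toy matrix.
toy_annotation <- function(expr, condition, tissue = "T01") {
  tibble::tibble(sample_id = colnames(expr), tissue = tissue,
                 condition = condition)
}

# Write an ontology tibble to a temp TSV and return the path.
write_temp_ontology <- function(tbl) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(tbl, path)
  path
}

# Brute-force maxmean straight from the definition (independent of the
# package implementation).
oracle_maxmean <- function(scores) {
  pos <- scores[scores > 0]
  neg <- scores[scores < 0]
  s_pos <- sum(pos) / length(scores)
  s_neg <- sum(neg) / length(scores)
  if (s_pos >= abs(s_neg)) s_pos else s_neg
}

# Brute-force Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Brute-force silhouette widths for a labelled point set.
oracle_silhouette <- function(points, labels) {
  d <- as.matrix(dist(points))
  vapply(seq_len(nrow(points)), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1) return(0)
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(k) {
      mean(d[i, labels == k])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# Brute-force meta-network collapse: classify each edge by its endpoint
# families and tally.
oracle_collapse <- function(edges, membership) {
  fa <- membership[as.character(edges$node_a)]
  fb <- membership[as.character(edges$node_b)]
  intra <- table(fa[fa == fb])
  inter_keys <- paste(pmin(fa, fb)[fa != fb], pmax(fa, fb)[fa != fb],
                      sep = "~")
  list(intra = intra, inter = table(inter_keys))
}
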