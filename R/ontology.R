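#' Load a chaperome functional gene ontology table
#'
#' Reads a tab-delimited annotation table of chaperome (or proteasome) genes
#' carrying HGNC symbol, Entrez id, up to six functional-ontology levels of
#' increasing detail, the chaperone/co-chaperone role and the ATP-dependence
#' flag. The table is validated: Entrez ids must be unique, role and ATP flags
#' must come from their controlled vocabularies, co-chaperones must carry
#' `atp = "not-applicable"`, and every gene must be labelled at the canonical
#' family level.
#'
#' @param path Path to a TSV file with columns `symbol`, `entrez_id`,
#'   `level1` ... (`level6` optional), `role`, `atp`.
#' @param family_level Integer ontology level used as the family partition.
#'   Default `NULL` auto-detects the shallowest level at which every gene has
#'   a non-empty label (for the shipped chaperome table this is the 10-family
#'   partition).
#' @return A tibble of class `chap_ontology` with attribute `family_level`.
#' @export
#' @examples
#' chap <- read_chaperome_ontology(
#'   system.file("extdata", "chaperome_synthetic.tsv", package = "chaperoscope"))
#' nrow(chap)
read_chaperome_ontology <- function(path, family_level = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  required <- c("symbol", "entrez_id", "role", "atp")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("ontology table is missing required column(s): ",
                 paste(missing, collapse = ", ")), class = "chap_format_error")
  }
  level_cols <- grep("^level[1-6]$", names(tbl), value = TRUE)
  if (length(level_cols) == 0) {
    abort("ontology table needs at least one `level1`..`level6` column",
          class = "chap_format_error")
  }
  tbl$entrez_id <- suppressWarnings(as.integer(tbl$entrez_id))
  if (anyNA(tbl$entrez_id)) {
    abort("entrez_id column contains non-integer values",
          class = "chap_format_error")
  }
  dup <- unique(tbl$entrez_id[duplicated(tbl$entrez_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate Entrez id(s) in ontology table: ",
                 paste(dup, collapse = ", ")), class = "chap_validation_error")
  }
  bad_role <- setdiff(unique(tbl$role), c("chaperone", "co-chaperone"))
  if (length(bad_role) > 0) {
    abort(paste0("role must be 'chaperone' or 'co-chaperone'; found: ",
                 paste(bad_role, collapse = ", ")),
          class = "chap_validation_error")
  }
  bad_atp <- setdiff(unique(tbl$atp),
                     c("dependent", "independent", "not-applicable"))
  if (length(bad_atp) > 0) {
    abort(paste0("atp must be 'dependent', 'independent' or 'not-applicable';",
                 " found: ", paste(bad_atp, collapse = ", ")),
          class = "chap_validation_error")
  }
  offend <- tbl$symbol[tbl$role == "co-chaperone" & tbl$atp != "not-applicable"]
  if (length(offend) > 0) {
    abort(paste0("co-chaperones must have atp = 'not-applicable': ",
                 paste(offend, collapse = ", ")),
          class = "chap_validation_error")
  }
  if (is.null(family_level)) {
    family_level <- detect_family_level(tbl, level_cols)
  }
  fam_col <- paste0("level", family_level)
  if (!fam_col %in% names(tbl)) {
    abort(sprintf("ontology table has no column `%s`", fam_col),
          class = "chap_format_error")
  }
  unlabelled <- tbl$symbol[is.na(tbl[[fam_col]]) | tbl[[fam_col]] == ""]
  if (length(unlabelled) > 0) {
    abort(paste0("genes without a label at level ", family_level, ": ",
                 paste(unlabelled, collapse = ", ")),
          class = "chap_validation_error")
  }
  out <- tibble::as_tibble(tbl)
  class(out) <- c("chap_ontology", class(out))
  attr(out, "family_level") <- as.integer(family_level)
  out
}

# Shallowest level at which every gene carries a non-empty label. The shipped
# chaperome table is fully labelled at level 1 (the 10-family partition) and
# only partially at deeper levels.
detect_family_level <- function(tbl, level_cols) {
  for (lev in sort(as.integer(sub("level", "", level_cols)))) {
    col <- tbl[[paste0("level", lev)]]
    if (!anyNA(col) && all(col != "")) {
      return(lev)
    }
  }
  abort("no ontology level labels every gene; pass `family_level` explicitly",
        class = "chap_validation_error")
}

#' Build the family gene-set collection from an ontology table
#'
#' Partitions genes into functional families by one ontology level. On the
#' shipped chaperome table at the canonical level this yields the 10 families
#' (sHSP, HSP40, HSP70, HSP90, HSP60, HSP100, PFD, TPR, ER, MITO).
#'
#' @param ontology A `chap_ontology` tibble.
#' @param family_level Ontology level; defaults to the level detected at load.
#' @return A named list of integer Entrez-id vectors of class
#'   `gene_set_collection`.
#' @export
family_gene_sets <- function(ontology, family_level = NULL) {
  family_level <- family_level %||% attr(ontology, "family_level")
  fam_col <- paste0("level", family_level)
  if (!fam_col %in% names(ontology)) {
    abort(sprintf("ontology has no column `%s`", fam_col))
  }
  labels <- ontology[[fam_col]]
  offenders <- ontology$symbol[is.na(labels) | labels == ""]
  if (length(offenders) > 0) {
    abort(paste0("genes without a family label at level ", family_level, ": ",
                 paste(offenders, collapse = ", ")))
  }
  sets <- split(ontology$entrez_id, labels)
  new_gene_set_collection(sets, name = paste0("families_level", family_level))
}

#' Functional subsets of the chaperome
#'
#' Returns the four functional subsets used for differential-expression
#' fractions: chaperones, co-chaperones, ATP-dependent chaperones and
#' ATP-independent chaperones. The two ATP subsets partition the chaperones.
#'
#' @param ontology A `chap_ontology` tibble with `role` and `atp` columns.
#' @return A `gene_set_collection` with sets `chaperones`, `co-chaperones`,
#'   `atp-dependent`, `atp-independent`.
#' @export
functional_subsets <- function(ontology) {
  bad <- ontology$symbol[ontology$role == "chaperone" &
                           ontology$atp == "not-applicable"]
  if (length(bad) > 0) {
    abort(paste0("chaperones must be ATP-dependent or -independent: ",
                 paste(bad, collapse = ", ")),
          class = "chap_validation_error")
  }
  sets <- list(
    "chaperones"      = ontology$entrez_id[ontology$role == "chaperone"],
    "co-chaperones"   = ontology$entrez_id[ontology$role == "co-chaperone"],
    "atp-dependent"   = ontology$entrez_id[ontology$atp == "dependent"],
    "atp-independent" = ontology$entrez_id[ontology$atp == "independent"]
  )
  new_gene_set_collection(sets, name = "functional_subsets")
}

new_gene_set_collection <- function(sets, name) {
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty) > 0) {
    abort(paste0("empty gene set(s): ", paste(empty, collapse = ", ")))
  }
  structure(sets, name = name, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> ", attr(x, "name"), "\n", sep = "")
  sizes <- lengths(x)
  for (nm in names(sizes)) cat("  ", nm, ": ", sizes[[nm]], " genes\n", sep = "")
  invisible(x)
}

#' Write or read a gene-set collection as JSON
#'
#' The on-disk form is a JSON object mapping set label to an array of Entrez
#' ids, the interchange format used by the command-line tools.
#'
#' @param sets A `gene_set_collection` (or plain named list of id vectors).
#' @param path Output (or input) file path.
#' @return `write_gene_sets` returns `path` invisibly; `read_gene_sets`
#'   returns a `gene_set_collection`.
#' @export
write_gene_sets <- function(sets, path) {
  jsonlite::write_json(lapply(unclass(sets), as.integer), path)
  invisible(path)
}

#' @rdname write_gene_sets
#' @export
read_gene_sets <- function(path) {
  sets <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_gene_set_collection(lapply(sets, as.integer), name = basename(path))
}
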