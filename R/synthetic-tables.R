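# Synthetic stand-ins for the curated chaperome/proteasome ontology tables.
# The real expert-curated gene lists are distributed as spreadsheets outside
# this package; these deterministic tables reproduce their documented
# structure (332 chaperome genes in 10 functional families; 88 chaperones =
# 50 ATP-dependent + 38 ATP-independent; 244 co-chaperones; 43 proteasome
# genes) with synthetic symbols and Entrez-style ids, and back every test
# and example that needs an ontology table.

#' Synthetic chaperome annotation table
#'
#' Deterministic 332-gene stand-in for the curated chaperome functional
#' ontology: 10 families (sHSP, HSP40, HSP70, HSP90, HSP60, HSP100, PFD,
#' TPR, ER, MITO) at level 1, a two-way subdivision at level 2, 88
#' chaperones (50 ATP-dependent, 38 ATP-independent) and 244 co-chaperones.
#' Symbols and Entrez ids are synthetic.
#'
#' @return Tibble with columns `symbol`, `entrez_id`, `level1`, `level2`,
#'   `level3`, `role`, `atp`.
#' @export
synthetic_chaperome_table <- function() {
  fam <- list(
    # family, total size, n chaperones, chaperone atp flag
    list("sHSP",   10L, 10L, "independent"),
    list("HSP40",  50L,  0L, NA),
    list("HSP70",  25L, 18L, "dependent"),
    list("HSP90",  25L, 15L, "dependent"),
    list("HSP60",  20L, 12L, "dependent"),
    list("HSP100", 10L,  5L, "dependent"),
    list("PFD",    10L, 10L, "independent"),
    list("TPR",   120L,  0L, NA),
    list("ER",     40L, 10L, "independent"),
    list("MITO",   22L,  8L, "independent"))
  rows <- purrr::map_dfr(fam, function(f) {
    n <- f[[2]]
    n_chap <- f[[3]]
    role <- c(rep("chaperone", n_chap), rep("co-chaperone", n - n_chap))
    atp <- c(rep(f[[4]], n_chap), rep("not-applicable", n - n_chap))
    tibble::tibble(
      symbol = sprintf("%s%03d", gsub("[^A-Z0-9]", "", toupper(f[[1]])),
                       seq_len(n)),
      level1 = f[[1]],
      level2 = paste0(f[[1]], "_", rep(c("A", "B"), length.out = n)),
      level3 = ifelse(seq_len(n) <= 3, paste0(f[[1]], "_core"), NA_character_),
      role = role,
      atp = atp)
  })
  rows$entrez_id <- 101000L + seq_len(nrow(rows))
  rows[, c("symbol", "entrez_id", "level1", "level2", "level3", "role", "atp")]
}

#' Synthetic proteasome annotation table
#'
#' Deterministic 43-gene stand-in for the proteasome complex gene family
#' (HGNC family 690 structure: 20S alpha/beta, 19S ATPase and non-ATPase
#' subunits, activators, inhibitor). Symbols follow the PSM* naming scheme;
#' ids are synthetic. Role/ATP columns are placeholders satisfying the
#' shared table schema.
#'
#' @return Tibble with the same columns as [synthetic_chaperome_table()].
#' @export
synthetic_proteasome_table <- function() {
  groups <- list(
    list("PSMA", 7L, "20S_alpha"),
    list("PSMB", 11L, "20S_beta"),
    list("PSMC", 6L, "19S_ATPase"),
    list("PSMD", 14L, "19S_non_ATPase"),
    list("PSME", 4L, "activator"),
    list("PSMF", 1L, "inhibitor"))
  rows <- purrr::map_dfr(groups, function(g) {
    tibble::tibble(symbol = sprintf("%s%d", g[[1]], seq_len(g[[2]])),
                   level1 = "Proteasome",
                   level2 = g[[3]],
                   level3 = NA_character_,
                   role = "co-chaperone",
                   atp = "not-applicable")
  })
  rows$entrez_id <- 201000L + seq_len(nrow(rows))
  rows[, c("symbol", "entrez_id", "level1", "level2", "level3", "role", "atp")]
}

#' Write an annotation table as shipped TSV
#'
#' @param table Tibble from one of the synthetic table generators.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ontology_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' Synthetic PSI-MI ontology subset (OBO text)
#'
#' A small, hand-assembled subset of the PSI-MI controlled vocabulary
#' covering the interaction-detection branches used by the evidence
#' generators (affinity chromatography with its coimmunoprecipitation
#' children, the protein complementation / two-hybrid branch, biophysical
#' methods) and the interaction-type branch with 'physical association'.
#' Real MI ids are used so configurations read naturally; the file is a
#' synthetic subset, not the full released ontology.
#'
#' @param path Optional path; when given the OBO text is written there.
#' @return The OBO text lines (invisibly when `path` is given).
#' @export
synthetic_psimi_obo <- function(path = NULL) {
  terms <- list(
    c("MI:0001", "interaction detection method", NA),
    c("MI:0045", "experimental interaction detection", "MI:0001"),
    c("MI:0063", "interaction prediction", "MI:0001"),
    c("MI:0401", "biochemical", "MI:0045"),
    c("MI:0090", "protein complementation assay", "MI:0045"),
    c("MI:0013", "biophysical", "MI:0045"),
    c("MI:0004", "affinity chromatography technology", "MI:0401"),
    c("MI:0096", "pull down", "MI:0004"),
    c("MI:0019", "coimmunoprecipitation", "MI:0004"),
    c("MI:0006", "anti bait coimmunoprecipitation", "MI:0019"),
    c("MI:0007", "anti tag coimmunoprecipitation", "MI:0019"),
    c("MI:0018", "two hybrid", "MI:0090"),
    c("MI:0397", "two hybrid array", "MI:0018"),
    c("MI:0071", "molecular sieving", "MI:0013"),
    c("MI:0038", "dynamic light scattering", "MI:0013"),
    c("MI:0190", "interaction type", NA),
    c("MI:0914", "association", "MI:0190"),
    c("MI:0915", "physical association", "MI:0914"),
    c("MI:0407", "direct interaction", "MI:0915"))
  lines <- c("format-version: 1.2",
             "ontology: mi (synthetic subset)", "")
  for (t in terms) {
    lines <- c(lines, "[Term]",
               paste0("id: ", t[1]),
               paste0("name: ", t[2]),
               if (!is.na(t[3])) paste0("is_a: ", t[3], " ! parent"),
               "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Synthetic UniProt-to-Entrez mapping for a gene universe
#'
#' Deterministic one-to-one accession mapping used by the evidence
#' generators and fixtures.
#'
#' @param entrez_ids Integer gene ids.
#' @return Tibble `uniprot`, `entrez_id`.
#' @export
synthetic_id_mapping <- function(entrez_ids) {
  entrez_ids <- as.integer(entrez_ids)
  tibble::tibble(uniprot = sprintf("P%06d", entrez_ids %% 1000000L),
                 entrez_id = entrez_ids)
}
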