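#' Published four-database testis expression summaries
#'
#' Per-gene, per-database testis TPM together with the maximum and median
#' TPM over all other tissues, as published for the nine C2H2 zinc-finger
#' genes called testis-specific in all four public expression databases
#' (HPA, ENCODE, GTEx, Illumina Body Map). These printed summaries are the
#' inputs for reproducing the nine-gene consensus without access to the
#' full database exports.
#'
#' @return Data frame with columns `gene`, `database`, `target_tpm`,
#'   `max_other`, `median_other` (36 rows: 9 genes x 4 databases).
#' @export
published_testis_summaries <- function() {
  utils::read.delim(system.file("extdata", "testis_four_db_summaries.tsv",
                                package = "tissuespec"),
                    stringsAsFactors = FALSE)
}

#' Published GePIA normal/tumor testis medians
#'
#' Median transcription levels (TPM) of 25 testis-specific C2H2 genes in
#' normal testis versus testicular germ cell tumor samples, as reported by
#' the GePIA resource (GTEx normals vs TCGA tumors).
#'
#' @return Data frame with columns `gene`, `normal_median_tpm`,
#'   `tumor_median_tpm` (25 rows).
#' @export
gepia_testis_medians <- function() {
  utils::read.delim(system.file("extdata", "gepia_testis_medians.tsv",
                                package = "tissuespec"),
                    stringsAsFactors = FALSE)
}

#' Rebuild per-database mini-panels from printed summaries
#'
#' Converts a summary table (gene, database, target TPM, max-other TPM)
#' into one two-column [expression_panel()] per database: the target
#' tissue and a synthetic "other_max" pseudo-tissue holding the published
#' maximum over all other tissues. Screening such a panel applies exactly
#' the published floor-and-fold rule, because the inverted specificity
#' ratio only depends on the maximum of the other tissues. The published
#' medians are not representable in a two-column panel (summaries
#' recomputed from a mini-panel report the max in the median slot); read
#' the `median_other` column of the summary table directly when the
#' median matters.
#'
#' @param summaries data frame like [published_testis_summaries()].
#' @param target_tissue_label label for the target column (default
#'   "testis").
#' @return Named list of [expression_panel()], one per database.
#' @export
summaries_to_minipanels <- function(summaries,
                                    target_tissue_label = "testis") {
  need <- c("gene", "database", "target_tpm", "max_other")
  if (!all(need %in% names(summaries)))
    stop("summaries must have columns: ", paste(need, collapse = ", "))
  panels <- list()
  for (db in unique(summaries$database)) {
    d <- summaries[summaries$database == db, ]
    vals <- cbind(d$target_tpm, d$max_other)
    panels[[db]] <- expression_panel(
      vals, gene_ids = d$gene,
      tissue_labels = c(target_tissue_label, "other_max"),
      database_name = db)
  }
  panels
}
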