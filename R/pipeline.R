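#' End-to-end tissue-specificity screen across databases
#'
#' Runs the full screening funnel over one panel per database: optional
#' restriction to a gene family, the per-database floor-and-fold screen,
#' the Venn partition of the per-database specific sets, the cross-database
#' consensus fold filter, and the per-database summary table for the genes
#' that survive. With a single panel the consensus is that panel's specific
#' set.
#'
#' @param panels named list of [expression_panel()] (>= 1).
#' @param target_tissue tissue to screen for (must be present in every
#'   panel).
#' @param family optional [gene_family()] restriction applied to every
#'   panel first.
#' @param config a [screen_config()].
#' @param min_fold cross-database consensus fold threshold, strict
#'   (default 1.5).
#' @param out_dir optional directory; when given, all intermediate tables
#'   are written there as TSV together with a JSON manifest.
#' @param seed recorded in the manifest for provenance (the screen itself
#'   is deterministic).
#' @return Object of class `screen_pipeline`: list with `screens` (per
#'   database), `partition` ([intersect_gene_sets()] result, or NULL for
#'   one database), `core` (genes specific in every database), `records`
#'   (consensus records for the core), `consensus` (core genes passing the
#'   fold filter), `summary_table`, `funnel` (record counts per stage).
#' @export
run_screen_pipeline <- function(panels, target_tissue, family = NULL,
                                config = screen_config(), min_fold = 1.5,
                                out_dir = NULL, seed = NULL) {
  if (!length(panels)) stop("stage screen: need at least one panel")
  if (is.null(names(panels)) || any(!nzchar(names(panels))))
    names(panels) <- vapply(panels, `[[`, "", "database_name")
  if (!is.null(family))
    panels <- lapply(panels, subset_to_family, family = family)
  screens <- lapply(panels, function(p) {
    if (!target_tissue %in% p$tissue_labels)
      stop("stage screen [", p$database_name, "]: unknown target tissue '",
           target_tissue, "'")
    screen_panel(p, config, target_tissue = target_tissue)
  })
  sets <- lapply(screens, specific_genes, tissue = target_tissue)
  if (length(panels) >= 2) {
    partition <- intersect_gene_sets(sets)
    core <- consensus_core(partition)
  } else {
    partition <- NULL
    core <- sort(sets[[1]])
  }
  summaries_by_db <- lapply(panels, function(p)
    lapply(intersect(core, p$gene_ids), function(g)
      summarize_gene(p, g, target_tissue)))
  records <- consensus_records(summaries_by_db)
  consensus <- consensus_fold_filter(records, min_fold = min_fold)
  tab <- build_summary_table(records[records$gene %in% consensus, ,
                                     drop = FALSE])
  funnel <- data.frame(
    database = names(panels),
    genes_in = vapply(panels, function(p) length(p$gene_ids), 0L),
    candidates = vapply(screens, nrow, 0L),
    specific = vapply(sets, length, 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- structure(list(screens = screens, partition = partition,
                        core = core, records = records,
                        consensus = consensus, summary_table = tab,
                        funnel = funnel, target_tissue = target_tissue,
                        config = config, min_fold = min_fold),
                   class = "screen_pipeline")
  if (!is.null(out_dir)) write_screen_outputs(out, out_dir, seed)
  out
}

#' @export
print.screen_pipeline <- function(x, ...) {
  cat(sprintf("Screening funnel for tissue '%s' over %d database(s)\n",
              x$target_tissue, nrow(x$funnel)))
  print(x$funnel, row.names = FALSE)
  cat(sprintf("  specific in every database: %d gene(s)\n", length(x$core)))
  cat(sprintf("  consensus after > %g-fold filter: %d gene(s)%s\n",
              x$min_fold, length(x$consensus),
              if (length(x$consensus))
                paste0(" (", paste(x$consensus, collapse = ", "), ")")
              else ""))
  invisible(x)
}

write_screen_outputs <- function(x, out_dir, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (db in names(x$screens))
    write_screen_tsv(x$screens[[db]],
                     file.path(out_dir, paste0("screen_", db, ".tsv")))
  if (!is.null(x$partition))
    write_venn_tsv(x$partition, file.path(out_dir, "venn_regions.tsv"))
  utils::write.table(x$summary_table,
                     file.path(out_dir, "consensus_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$funnel, file.path(out_dir, "funnel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(x$consensus, file.path(out_dir, "consensus_genes.txt"))
  write_manifest(file.path(out_dir, "manifest.json"),
                 list(stage = "screen", target_tissue = x$target_tissue,
                      config = unclass(x$config), min_fold = x$min_fold,
                      databases = names(x$screens), seed = seed))
  invisible(out_dir)
}

#' qPCR validation pipeline: quantification plus cohort statistics
#'
#' Normalizes a Cq table against the reference genes, joins the sample
#' metadata, and runs the tumor-versus-normal comparisons.
#'
#' @param cq_data long-format Cq data frame (`sample_id`, `gene`, `cq`).
#' @param metadata sample metadata (`sample_id`, `state`, `histology`,
#'   `patient_id`).
#' @param reference_genes reference labels (default 18S and GAPDH).
#' @param genes genes to analyze; default all non-reference genes.
#' @param normal_group normal-side definition, see [run_cohort_analysis()].
#' @param out_dir optional output directory for TSV reports + manifest.
#' @param seed recorded in the manifest.
#' @return Object of class `validation_pipeline`: list with `levels`
#'   (relative levels) and `comparisons` (cohort test results).
#' @export
run_validation_pipeline <- function(cq_data, metadata,
                                    reference_genes = c("18S", "GAPDH"),
                                    genes = NULL,
                                    normal_group = "pooled",
                                    out_dir = NULL, seed = NULL) {
  levels <- quantify_plate(cq_data, reference_genes = reference_genes)
  comparisons <- run_cohort_analysis(levels, metadata, genes = genes,
                                     normal_group = normal_group)
  out <- structure(list(levels = levels, comparisons = comparisons),
                   class = "validation_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(as.data.frame(levels),
                       file.path(out_dir, "relative_levels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(comparisons),
                       file.path(out_dir, "cohort_comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(file.path(out_dir, "manifest.json"),
                   list(stage = "validation",
                        reference_genes = reference_genes,
                        normal_group = normal_group, seed = seed))
  }
  out
}

#' @export
print.validation_pipeline <- function(x, ...) {
  print(x$levels)
  print(x$comparisons)
  invisible(x)
}

write_manifest <- function(path, fields) {
  fields$package_version <- as.character(utils::packageVersion("tissuespec"))
  fields$r_version <- paste(R.version$major, R.version$minor, sep = ".")
  jsonlite::write_json(fields, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
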