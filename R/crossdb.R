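#' Venn partition of per-database gene sets
#'
#' Partitions the union of the input sets into the 2^D - 1 regions of the
#' D-set Venn diagram: each gene is assigned to the region of exactly the
#' databases that contain it. The all-databases region is the consensus
#' core.
#'
#' @param per_db_sets named list (>= 2 entries) of character vectors of gene
#'   IDs, one per database.
#' @return A `venn_partition`: list with `database_names` and `region_sets`,
#'   a named list keyed by `+`-joined database subsets (e.g. `"HPA+GTEx"`),
#'   covering every non-empty subset, values sorted character vectors.
#' @export
intersect_gene_sets <- function(per_db_sets) {
  if (length(per_db_sets) < 2) stop("need at least 2 databases")
  if (is.null(names(per_db_sets)) || any(!nzchar(names(per_db_sets))))
    names(per_db_sets) <- paste0("db", seq_along(per_db_sets))
  dbs <- names(per_db_sets)
  D <- length(dbs)
  all_genes <- unique(unlist(per_db_sets, use.names = FALSE))
  membership <- vapply(per_db_sets, function(s) all_genes %in% s,
                       logical(length(all_genes)))
  if (length(all_genes) == 1) membership <- matrix(membership, nrow = 1)
  subset_key <- function(mask) paste(dbs[mask], collapse = "+")
  regions <- list()
  for (code in seq_len(2^D - 1)) {
    mask <- as.logical(bitwAnd(code, 2^(seq_len(D) - 1)))
    regions[[subset_key(mask)]] <- character(0)
  }
  if (length(all_genes)) {
    codes <- as.integer(membership %*% 2^(seq_len(D) - 1))
    for (code in unique(codes)) {
      mask <- as.logical(bitwAnd(code, 2^(seq_len(D) - 1)))
      regions[[subset_key(mask)]] <- sort(all_genes[codes == code])
    }
  }
  structure(list(database_names = dbs, region_sets = regions),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition over", length(x$database_names), "databases:",
      paste(x$database_names, collapse = ", "), "\n")
  sizes <- vapply(x$region_sets, length, 0L)
  for (k in names(sizes)[sizes > 0])
    cat(sprintf("  [%s] %d gene(s)\n", k, sizes[k]))
  core <- consensus_core(x)
  cat("  consensus core:", length(core), "gene(s)\n")
  invisible(x)
}

#' Genes present in every database of a partition
#'
#' @param partition a `venn_partition`.
#' @return Sorted character vector of core gene IDs.
#' @export
consensus_core <- function(partition) {
  stopifnot(inherits(partition, "venn_partition"))
  partition$region_sets[[paste(partition$database_names, collapse = "+")]]
}

#' Cross-database consensus records
#'
#' Assembles, for each gene, its per-database summaries and the minimum
#' target/max-other fold across databases (a zero `max_other` counts as
#' infinite fold). Genes missing from any database cannot be consensus
#' candidates and are excluded (reported in the `missing` attribute).
#'
#' @param summaries_by_db named list, one entry per database, each a list of
#'   `gene_tissue_summary` objects.
#' @return Data frame of class `consensus_records` with one row per gene
#'   present everywhere: `gene`, `min_fold_across_dbs`, and per-database
#'   `target`/`max_other`/`median_other` columns.
#' @export
consensus_records <- function(summaries_by_db) {
  stopifnot(length(summaries_by_db) >= 1)
  dbs <- names(summaries_by_db)
  if (is.null(dbs)) stop("summaries_by_db must be named by database")
  per_db <- lapply(summaries_by_db, function(lst) {
    data.frame(gene = vapply(lst, `[[`, "", "gene"),
               target = vapply(lst, `[[`, 0, "target_tpm"),
               max_other = vapply(lst, `[[`, 0, "max_other"),
               median_other = vapply(lst, `[[`, 0, "median_other"),
               stringsAsFactors = FALSE)
  })
  common <- Reduce(intersect, lapply(per_db, `[[`, "gene"))
  all_ids <- unique(unlist(lapply(per_db, `[[`, "gene")))
  missing <- lapply(dbs, function(d) setdiff(all_ids, per_db[[d]]$gene))
  names(missing) <- dbs
  folds <- sapply(per_db, function(df) {
    df <- df[match(common, df$gene), ]
    ifelse(df$max_other == 0, Inf, df$target / df$max_other)
  })
  if (length(common) == 1) folds <- matrix(folds, nrow = 1)
  out <- data.frame(gene = common,
                    min_fold_across_dbs =
                      if (length(common)) apply(folds, 1, min) else numeric(0),
                    stringsAsFactors = FALSE)
  for (d in dbs) {
    df <- per_db[[d]][match(common, per_db[[d]]$gene), ]
    out[[paste0(d, ".target")]] <- df$target
    out[[paste0(d, ".max_other")]] <- df$max_other
    out[[paste0(d, ".median_other")]] <- df$median_other
  }
  structure(out, class = c("consensus_records", "data.frame"),
            databases = dbs, missing = missing)
}

#' Consensus fold filter
#'
#' Keeps genes whose testis/other fold exceeds `min_fold` in every database,
#' i.e. whose minimum fold across databases is strictly greater than
#' `min_fold` (the default; set `strict = FALSE` for an inclusive bound).
#'
#' @param records a `consensus_records` data frame (or anything with columns
#'   `gene` and `min_fold_across_dbs`).
#' @param min_fold fold threshold (default 1.5).
#' @param strict use strict `>` (default) or inclusive `>=`.
#' @return Character vector of retained gene IDs.
#' @export
consensus_fold_filter <- function(records, min_fold = 1.5, strict = TRUE) {
  keep <- if (strict) records$min_fold_across_dbs > min_fold
          else records$min_fold_across_dbs >= min_fold
  records$gene[keep]
}

#' Format a summary cell as "target (max/median)"
#'
#' Reproduces the compact report layout used for per-database testis
#' summaries: target TPM followed by the max and median over other tissues
#' in brackets. Numbers keep their shortest round-tripping decimal form.
#'
#' @param target,max_other,median_other numeric scalars.
#' @return A character scalar like `"109.3 (6.5/0.3)"`.
#' @export
format_summary_cell <- function(target, max_other, median_other) {
  sprintf("%s (%s/%s)", format_tpm(target), format_tpm(max_other),
          format_tpm(median_other))
}

#' Parse a "target (max/median)" cell
#'
#' @param cell character scalar in the format written by
#'   [format_summary_cell()].
#' @return Named numeric vector `c(target, max_other, median_other)`.
#' @export
parse_summary_cell <- function(cell) {
  m <- regmatches(cell, regexec(
    "^\\s*([0-9.eE+-]+)\\s*\\(\\s*([0-9.eE+-]+)\\s*/\\s*([0-9.eE+-]+)\\s*\\)\\s*$",
    cell))[[1]]
  if (length(m) != 4) stop("unparseable summary cell: '", cell, "'")
  v <- as.numeric(m[2:4])
  stats::setNames(v, c("target", "max_other", "median_other"))
}

#' Per-database summary table for consensus genes
#'
#' One row per gene, one formatted `"T (M/m)"` cell per database.
#'
#' @param records a `consensus_records` data frame.
#' @return Data frame: `gene` plus one character column per database.
#' @export
build_summary_table <- function(records) {
  dbs <- attr(records, "databases")
  out <- data.frame(gene = records$gene, stringsAsFactors = FALSE)
  for (d in dbs) {
    out[[d]] <- mapply(format_summary_cell,
                       records[[paste0(d, ".target")]],
                       records[[paste0(d, ".max_other")]],
                       records[[paste0(d, ".median_other")]])
  }
  out
}

#' Write Venn regions as TSV
#'
#' @param partition a `venn_partition`.
#' @param path output path.
#' @export
write_venn_tsv <- function(partition, path) {
  df <- data.frame(region = names(partition$region_sets),
                   n = vapply(partition$region_sets, length, 0L),
                   genes = vapply(partition$region_sets, paste, "",
                                  collapse = ","),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
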