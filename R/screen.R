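#' Screening configuration
#'
#' Thresholds for the tissue-specificity screen. A gene is called specific
#' to a tissue when its TPM there is at least `tpm_min` and every other
#' tissue lies at least `fold_min`-fold below it. The fold condition is
#' applied through the inverted ratio (max over other tissues of
#' other/target), which is well defined even when other tissues are silent:
#' specific means `inv_ratio <= inv_ratio_max`, with `inv_ratio_max =
#' 1/fold_min` unless overridden. `active_tpm` is the separate floor used
#' only for counting in how many tissues a gene is transcribed at all.
#'
#' Both boundary comparisons are inclusive: a gene at exactly `tpm_min` TPM
#' or at exactly the fold boundary passes.
#'
#' @param tpm_min TPM floor for candidacy (default 5).
#' @param fold_min minimum target/other fold (default 3; must exceed 1).
#' @param inv_ratio_max cap on the inverted ratio; defaults to `1/fold_min`.
#' @param active_tpm floor for "transcribed" counting (default 3).
#' @return A `screen_config` list.
#' @export
screen_config <- function(tpm_min = 5, fold_min = 3,
                          inv_ratio_max = 1 / fold_min, active_tpm = 3) {
  stopifnot(tpm_min > 0, fold_min > 1, inv_ratio_max >= 0, active_tpm >= 0)
  structure(list(tpm_min = tpm_min, fold_min = fold_min,
                 inv_ratio_max = inv_ratio_max, active_tpm = active_tpm),
            class = "screen_config")
}

#' Inverted tissue-specificity ratio
#'
#' For a vector of per-tissue TPM values and a target tissue, returns the
#' maximum over all non-target tissues of `other / target`. Inverting the
#' fold this way avoids division by zero when a gene is silent everywhere
#' outside the target tissue: the ratio is then 0, the strongest possible
#' evidence of specificity. A gene is `fold_min`-fold specific exactly when
#' this ratio is at most `1/fold_min`.
#'
#' @param values numeric vector of TPM across tissues (length >= 2).
#' @param target_index position of the target tissue in `values`.
#' @return The inverted ratio, a dimensionless number >= 0.
#' @examples
#' inverse_specificity_ratio(c(76.4, 11.1, 4.25, 1.0, 4.25), 1)  # ~0.145
#' @export
inverse_specificity_ratio <- function(values, target_index) {
  if (length(values) < 2) stop("need at least 2 tissues")
  if (target_index < 1 || target_index > length(values))
    stop("target_index out of range")
  target <- values[target_index]
  if (!is.finite(target) || target <= 0)
    stop("target tissue TPM must be positive; the ratio is undefined at 0")
  max(values[-target_index]) / target
}

#' Decide tissue specificity for one gene summary
#'
#' @param summary a `gene_tissue_summary` from [summarize_gene()].
#' @param config a [screen_config()].
#' @return `TRUE` iff `target_tpm >= tpm_min` and the inverted ratio
#'   `max_other/target_tpm` is at most `inv_ratio_max`.
#' @export
is_tissue_specific <- function(summary, config = screen_config()) {
  stopifnot(inherits(summary, "gene_tissue_summary"))
  if (summary$target_tpm < config$tpm_min) return(FALSE)
  summary$max_other / summary$target_tpm <= config$inv_ratio_max
}

#' Screen an expression panel for tissue-specific genes
#'
#' Applies the two-rule screen (TPM floor, then inverted fold ratio) to
#' every gene, either for one target tissue or across all tissues. Only
#' genes passing the `tpm_min` floor in a tissue yield a record for that
#' tissue; the `specific` flag then reports the fold condition.
#'
#' @param panel an [expression_panel()] with >= 2 tissues.
#' @param config a [screen_config()].
#' @param target_tissue optional tissue label; when omitted, every tissue
#'   is scanned.
#' @return An object of class `specificity_screen`: a data frame with
#'   columns `gene`, `symbol`, `tissue`, `target_tpm`, `max_other`,
#'   `median_other`, `inv_ratio`, `specific`, plus attributes `config` and
#'   `database_name`.
#' @export
screen_panel <- function(panel, config = screen_config(), target_tissue = NULL) {
  stopifnot(inherits(panel, "expression_panel"), inherits(config, "screen_config"))
  if (length(panel$tissue_labels) < 2)
    stop("screening needs at least 2 tissues")
  if (!is.null(target_tissue)) {
    if (!target_tissue %in% panel$tissue_labels)
      stop("unknown target_tissue: ", target_tissue)
    tissues <- target_tissue
  } else {
    tissues <- panel$tissue_labels
  }
  rows <- vector("list", length(tissues))
  for (k in seq_along(tissues)) {
    ti <- match(tissues[k], panel$tissue_labels)
    target <- panel$values[, ti]
    cand <- which(target >= config$tpm_min)
    if (!length(cand)) next
    others <- panel$values[cand, -ti, drop = FALSE]
    max_other <- apply(others, 1, max)
    median_other <- apply(others, 1, stats::median)
    inv_ratio <- max_other / target[cand]
    rows[[k]] <- data.frame(
      gene = panel$gene_ids[cand],
      symbol = panel$gene_symbols[cand],
      tissue = tissues[k],
      target_tpm = unname(target[cand]),
      max_other = unname(max_other),
      median_other = unname(median_other),
      inv_ratio = unname(inv_ratio),
      specific = unname(inv_ratio <= config$inv_ratio_max),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), symbol = character(),
                      tissue = character(), target_tpm = numeric(),
                      max_other = numeric(), median_other = numeric(),
                      inv_ratio = numeric(), specific = logical(),
                      stringsAsFactors = FALSE)
  structure(out, class = c("specificity_screen", "data.frame"),
            config = config, database_name = panel$database_name)
}

#' @export
print.specificity_screen <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Tissue-specificity screen of '%s' (floor %g TPM, fold >= %g)\n",
              attr(x, "database_name"), cfg$tpm_min, cfg$fold_min))
  cat(sprintf("  %d candidate (gene, tissue) records, %d specific\n",
              nrow(x), sum(x$specific)))
  sp <- x[x$specific, , drop = FALSE]
  if (nrow(sp)) {
    tab <- sort(table(sp$tissue), decreasing = TRUE)
    cat("  specific genes per tissue:",
        paste(sprintf("%s=%d", names(utils::head(tab, 8)), utils::head(tab, 8)),
              collapse = ", "),
        if (length(tab) > 8) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
summary.specificity_screen <- function(object, ...) {
  sp <- object[object$specific, , drop = FALSE]
  structure(list(n_candidates = nrow(object), n_specific = nrow(sp),
                 per_tissue = table(factor(sp$tissue)),
                 config = attr(object, "config"),
                 database_name = attr(object, "database_name")),
            class = "summary.specificity_screen")
}

#' @export
print.summary.specificity_screen <- function(x, ...) {
  cat(sprintf("Screen of '%s': %d candidates, %d specific calls\n",
              x$database_name, x$n_candidates, x$n_specific))
  if (length(x$per_tissue)) print(x$per_tissue)
  invisible(x)
}

#' Specific gene set from a screen
#'
#' @param screen a `specificity_screen`.
#' @param tissue optional tissue restriction.
#' @return Character vector of gene IDs flagged specific.
#' @export
specific_genes <- function(screen, tissue = NULL) {
  stopifnot(inherits(screen, "specificity_screen"))
  sp <- screen[screen$specific, , drop = FALSE]
  if (!is.null(tissue)) sp <- sp[sp$tissue == tissue, , drop = FALSE]
  unique(sp$gene)
}

#' Count transcribed genes per tissue
#'
#' Counts, per tissue, how many genes reach at least `active_tpm` TPM
#' (boundary inclusive).
#'
#' @param panel an [expression_panel()].
#' @param config a [screen_config()]; only `active_tpm` is used.
#' @return Named integer vector over tissues.
#' @export
count_active <- function(panel, config = screen_config()) {
  stopifnot(inherits(panel, "expression_panel"))
  counts <- colSums(panel$values >= config$active_tpm)
  stats::setNames(as.integer(counts), panel$tissue_labels)
}

#' Write screen records as TSV
#'
#' @param screen a `specificity_screen`.
#' @param path output path.
#' @export
write_screen_tsv <- function(screen, path) {
  utils::write.table(as.data.frame(screen), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
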