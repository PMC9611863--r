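#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent groups. The statistic is U for
#' the first group (number of (a, b) pairs with a < b, counting ties as
#' half). The p-value is exact by enumeration when the combined sample size
#' is at most 12 and there are no ties; otherwise the normal approximation
#' with midrank tie correction and continuity correction is used. The
#' computation is delegated to [stats::wilcox.test()] with the switch made
#' explicit here so the exact/approximate rule is deterministic.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param exact_max combined size up to which the exact null distribution is
#'   enumerated (default 12).
#' @return List with `statistic` (U of `a`), `p_value`, `exact` (logical),
#'   `n_a`, `n_b`.
#' @export
mann_whitney <- function(a, b, exact_max = 12) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  has_ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- (length(a) + length(b) <= exact_max) && !has_ties
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = use_exact,
                                            correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       exact = use_exact, n_a = length(a), n_b = length(b))
}

#' Wilcoxon signed-rank test for paired samples (two-sided)
#'
#' Tests symmetry of within-pair differences about zero. Zero differences
#' are uninformative and dropped, as in the classical procedure. The
#' statistic is V, the sum of the ranks of the positive differences (so all
#' differences positive gives the maximal V = n(n+1)/2). Exact p by sign
#' enumeration for at most `exact_max` informative pairs without tied
#' absolute differences; normal approximation with tie and continuity
#' correction otherwise. All differences zero is degenerate: p = 1 with
#' `degenerate = TRUE`.
#'
#' @param x,y paired numeric vectors of equal length, or `y = NULL` to
#'   treat `x` as the differences.
#' @param exact_max informative-pair count up to which the exact
#'   distribution is used (default 12).
#' @return List with `statistic` (V), `p_value`, `exact`, `n_pairs`
#'   (informative pairs), `degenerate`.
#' @export
wilcoxon_paired <- function(x, y = NULL, exact_max = 12) {
  d <- if (is.null(y)) as.numeric(x) else {
    stopifnot(length(x) == length(y))
    as.numeric(x) - as.numeric(y)
  }
  if (!length(d)) stop("need at least one pair")
  d <- d[d != 0]
  if (!length(d))
    return(list(statistic = 0, p_value = 1, exact = TRUE, n_pairs = 0L,
                degenerate = TRUE))
  has_ties <- anyDuplicated(abs(d)) > 0
  use_exact <- length(d) <= exact_max && !has_ties
  ht <- suppressWarnings(stats::wilcox.test(d, mu = 0, exact = use_exact,
                                            correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       exact = use_exact, n_pairs = length(d), degenerate = FALSE)
}

#' Ratio of group medians
#'
#' Fold change reported as median(a) / median(b). A zero denominator median
#' yields `Inf` with a flag rather than an error, mirroring how suppressed
#' tumors can silence a gene completely.
#'
#' @param group_a,group_b numeric vectors (typically normal and tumor
#'   levels).
#' @return List with `fold` and `zero_denominator`.
#' @examples
#' median_fold_change(93.0, 0.93)$fold   # 100
#' @export
median_fold_change <- function(group_a, group_b) {
  ma <- stats::median(as.numeric(group_a))
  mb <- stats::median(as.numeric(group_b))
  if (mb == 0) return(list(fold = Inf, zero_denominator = TRUE))
  list(fold = ma / mb, zero_denominator = FALSE)
}

#' Tumor-versus-normal cohort analysis
#'
#' For each gene, compares relative expression between tumor and normal
#' samples: unpaired Mann-Whitney tests per histology stratum (germ,
#' non-germ, and all samples pooled), and a Wilcoxon signed-rank test over
#' patients contributing both a tumor and an adjacent-normal sample. The
#' "normal" side pools healthy controls with adjacent-normal tissue by
#' default (`normal_group = "pooled"`); set `"control"` or
#' `"adjacent_normal"` to restrict it. Comparisons with fewer than two
#' samples on either side are skipped and listed in the `skipped`
#' attribute.
#'
#' @param levels data frame of relative levels (`sample_id`, `gene`,
#'   `level`), e.g. from [quantify_plate()].
#' @param metadata sample metadata data frame (`sample_id`, `state`,
#'   `histology`, `patient_id`).
#' @param genes genes to analyze; default all genes in `levels`.
#' @param normal_group which normal samples form the comparison group.
#' @return Data frame of class `cohort_comparison`: `gene`, `stratum`,
#'   `test`, `n_normal`, `n_tumor`, `statistic`, `p_value`, `median_fold`
#'   (normal/tumor).
#' @export
run_cohort_analysis <- function(levels, metadata, genes = NULL,
                                normal_group = c("pooled", "control",
                                                 "adjacent_normal")) {
  normal_group <- match.arg(normal_group)
  if (is.null(genes)) genes <- sort(unique(levels$gene))
  miss <- setdiff(levels$sample_id, metadata$sample_id)
  if (length(miss))
    stop("metadata missing for sample(s): ", paste(miss, collapse = ", "))
  md <- metadata[match(levels$sample_id, metadata$sample_id), ]
  levels$state <- md$state
  levels$histology <- md$histology
  levels$patient_id <- md$patient_id
  normal_states <- switch(normal_group,
                          pooled = c("control", "adjacent_normal"),
                          control = "control",
                          adjacent_normal = "adjacent_normal")
  rows <- list(); skipped <- character(0)
  strata <- list(all = function(h) rep(TRUE, length(h)),
                 germ = function(h) !is.na(h) & h == "germ",
                 non_germ = function(h) !is.na(h) & h == "non_germ")
  for (g in genes) {
    lg <- levels[levels$gene == g, ]
    for (st in names(strata)) {
      in_st <- strata[[st]](lg$histology)
      # controls (histology NA) belong to the normal side of every stratum
      nrm <- lg$level[(in_st | lg$state == "control") &
                        lg$state %in% normal_states]
      tum <- lg$level[in_st & lg$state == "tumor"]
      if (length(nrm) < 2 || length(tum) < 2) {
        skipped <- c(skipped, sprintf("%s/%s: n_normal=%d n_tumor=%d",
                                      g, st, length(nrm), length(tum)))
        next
      }
      mw <- mann_whitney(nrm, tum)
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, stratum = st, test = "mann_whitney",
        n_normal = length(nrm), n_tumor = length(tum),
        statistic = mw$statistic, p_value = mw$p_value,
        median_fold = median_fold_change(nrm, tum)$fold,
        stringsAsFactors = FALSE)
    }
    # paired subset: patients with one tumor and one adjacent-normal sample
    pl <- lg[!is.na(lg$patient_id), ]
    nrm_p <- pl[pl$state == "adjacent_normal", ]
    tum_p <- pl[pl$state == "tumor", ]
    pts <- intersect(nrm_p$patient_id, tum_p$patient_id)
    if (length(pts) >= 2) {
      xn <- nrm_p$level[match(pts, nrm_p$patient_id)]
      xt <- tum_p$level[match(pts, tum_p$patient_id)]
      wx <- wilcoxon_paired(xn, xt)
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, stratum = "paired", test = "wilcoxon_paired",
        n_normal = length(pts), n_tumor = length(pts),
        statistic = wx$statistic, p_value = wx$p_value,
        median_fold = median_fold_change(xn, xt)$fold,
        stringsAsFactors = FALSE)
    } else if (nrow(pl)) {
      skipped <- c(skipped, sprintf("%s/paired: %d complete pair(s)",
                                    g, length(pts)))
    }
  }
  out <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
         else data.frame(gene = character(), stratum = character(),
                         test = character(), n_normal = integer(),
                         n_tumor = integer(), statistic = numeric(),
                         p_value = numeric(), median_fold = numeric(),
                         stringsAsFactors = FALSE)
  structure(out, class = c("cohort_comparison", "data.frame"),
            normal_group = normal_group, skipped = skipped)
}

#' @export
print.cohort_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Cohort comparison (%d test(s); normal side = %s)\n",
              nrow(x), attr(x, "normal_group")))
  if (nrow(x)) {
    df <- as.data.frame(x)
    df$p_value <- signif(df$p_value, digits)
    df$median_fold <- signif(df$median_fold, digits)
    df$statistic <- signif(df$statistic, digits)
    print(df, row.names = FALSE)
  }
  sk <- attr(x, "skipped")
  if (length(sk)) cat("skipped:", paste(sk, collapse = "; "), "\n")
  invisible(x)
}
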