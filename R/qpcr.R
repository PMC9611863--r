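#' Aggregate technical qPCR replicates
#'
#' Technical replicates are averaged on the Cq scale (arithmetic mean of
#' cycle numbers), the conventional order of operations. The replicate
#' spread (max - min) is reported; a spread above `max_spread` cycles is
#' flagged as noisy but is not fatal.
#'
#' @param cqs numeric vector of replicate Cq values (>= 1, each in (0, 45)).
#' @param max_spread spread flagging threshold in cycles (default 0.5).
#' @return List with `mean_cq`, `spread`, `n`, `flagged`.
#' @export
aggregate_replicates <- function(cqs, max_spread = 0.5) {
  cqs <- as.numeric(cqs)
  if (!length(cqs)) stop("empty replicate list")
  if (any(!is.finite(cqs)) || any(cqs <= 0) || any(cqs >= 45))
    stop("Cq values must be finite and in (0, 45)")
  spread <- max(cqs) - min(cqs)
  list(mean_cq = mean(cqs), spread = spread, n = length(cqs),
       flagged = spread > max_spread)
}

#' Reference-normalized relative expression level
#'
#' Converts a target Cq and a set of reference-gene Cqs into a relative
#' abundance: the target abundance `eff^-Cq` divided by the geometric mean
#' of the reference abundances. On the Cq scale that is
#' `eff^(mean(reference_cqs) - target_cq)`; with the default amplification
#' efficiency of 2 (100% per cycle), one cycle of difference is a two-fold
#' change.
#'
#' @param target_cq aggregated Cq of the target gene.
#' @param reference_cqs numeric vector (>= 1, typically 2: 18S and GAPDH) of
#'   aggregated reference-gene Cqs.
#' @param efficiency amplification factor per cycle, default 2.
#' @return Relative level, a positive dimensionless number.
#' @examples
#' relative_level(22, c(22, 22))   # 1
#' relative_level(23, c(22, 22))   # 0.5
#' relative_level(22, c(20, 24))   # 1: only the reference mean matters
#' @export
relative_level <- function(target_cq, reference_cqs, efficiency = 2) {
  if (!length(reference_cqs)) stop("empty reference Cq list")
  stopifnot(is.finite(target_cq), all(is.finite(reference_cqs)),
            efficiency > 1)
  efficiency^(mean(reference_cqs) - target_cq)
}

#' Quantify a qPCR plate against reference genes
#'
#' Takes long-format replicate measurements, aggregates replicates per
#' (sample, gene), and normalizes every non-reference gene to the geometric
#' mean abundance of the reference genes within the same sample. Samples
#' missing any reference gene cannot be normalized and are skipped (listed
#' in the `skipped` attribute).
#'
#' @param cq_data data frame with columns `sample_id`, `gene`, `cq`;
#'   repeated (sample, gene) rows are technical replicates.
#' @param reference_genes character vector of reference gene labels,
#'   default `c("18S", "GAPDH")`.
#' @param efficiency amplification factor per cycle, default 2.
#' @param max_spread replicate-spread flag threshold, default 0.5 cycles.
#' @return Data frame of class `relative_levels`: `sample_id`, `gene`,
#'   `level`, `mean_cq`, `spread_flagged`, with attributes
#'   `reference_genes` and `skipped`.
#' @export
quantify_plate <- function(cq_data, reference_genes = c("18S", "GAPDH"),
                           efficiency = 2, max_spread = 0.5) {
  need <- c("sample_id", "gene", "cq")
  if (!all(need %in% names(cq_data)))
    stop("cq_data must have columns: ", paste(need, collapse = ", "))
  if (length(reference_genes) < 1) stop("at least one reference gene required")
  agg <- lapply(split(cq_data, list(cq_data$sample_id, cq_data$gene),
                      drop = TRUE),
                function(d) {
                  a <- aggregate_replicates(d$cq, max_spread)
                  data.frame(sample_id = d$sample_id[1], gene = d$gene[1],
                             mean_cq = a$mean_cq, flagged = a$flagged,
                             stringsAsFactors = FALSE)
                })
  agg <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  rows <- list(); skipped <- character(0)
  for (s in unique(agg$sample_id)) {
    d <- agg[agg$sample_id == s, ]
    ref <- d[d$gene %in% reference_genes, ]
    if (length(unique(ref$gene)) < length(reference_genes)) {
      skipped <- c(skipped, s)
      next
    }
    targets <- d[!d$gene %in% reference_genes, , drop = FALSE]
    if (!nrow(targets)) next
    rows[[s]] <- data.frame(
      sample_id = s, gene = targets$gene,
      level = relative_level_vec(targets$mean_cq, ref$mean_cq, efficiency),
      mean_cq = targets$mean_cq, spread_flagged = targets$flagged,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
         else data.frame(sample_id = character(), gene = character(),
                         level = numeric(), mean_cq = numeric(),
                         spread_flagged = logical(), stringsAsFactors = FALSE)
  if (length(skipped))
    message("skipped ", length(skipped),
            " sample(s) missing a reference gene: ",
            paste(skipped, collapse = ", "))
  structure(out, class = c("relative_levels", "data.frame"),
            reference_genes = reference_genes, skipped = skipped)
}

relative_level_vec <- function(target_cqs, reference_cqs, efficiency = 2) {
  vapply(target_cqs, relative_level, 0, reference_cqs = reference_cqs,
         efficiency = efficiency)
}

#' @export
print.relative_levels <- function(x, ...) {
  cat(sprintf("Relative qPCR levels: %d (sample, gene) values, %d gene(s), normalized to %s\n",
              nrow(x), length(unique(x$gene)),
              paste(attr(x, "reference_genes"), collapse = " & ")))
  if (length(attr(x, "skipped")))
    cat("  skipped samples:", paste(attr(x, "skipped"), collapse = ", "), "\n")
  invisible(x)
}

#' Read a long-format Cq table
#'
#' Expects a TSV with header `sample_id<TAB>gene<TAB>cq`; repeated rows are
#' technical replicates.
#'
#' @param path path to the TSV.
#' @return Data frame with those three columns.
#' @export
read_cq_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "cq")
  if (!all(need %in% names(df)))
    stop("Cq table must have columns: ", paste(need, collapse = ", "))
  df$cq <- as.numeric(df$cq)
  df
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `state` (control / adjacent_normal /
#' tumor), `histology` (germ / non_germ, may be NA for controls) and
#' optional `patient_id` pairing key.
#'
#' @param path path to the TSV.
#' @return Data frame of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("sample_id", "state", "histology")
  if (!all(need %in% names(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  ok <- df$state %in% c("control", "adjacent_normal", "tumor")
  if (any(!ok))
    stop("unknown state value(s): ", paste(unique(df$state[!ok]), collapse = ", "))
  if (!"patient_id" %in% names(df)) df$patient_id <- NA_character_
  df
}
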