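#' Spearman correlation matrix across genes
#'
#' Midrank-based Spearman correlation of every gene pair, computed over
#' samples (columns). A constant gene has no defined rank correlation; its
#' correlations are recorded as 0 and the gene is listed in the
#' `constant_genes` attribute so the matrix stays complete for clustering.
#'
#' @param sample_matrix numeric genes x samples matrix with >= 2 gene rows
#'   and >= 3 sample columns; row names label the genes.
#' @return Correlation matrix of class `correlation_matrix` (symmetric,
#'   unit diagonal, entries in \[-1, 1\]).
#' @export
spearman_matrix <- function(sample_matrix) {
  sample_matrix <- as.matrix(sample_matrix)
  if (ncol(sample_matrix) < 3) stop("need at least 3 samples")
  if (nrow(sample_matrix) < 2) stop("need at least 2 genes")
  if (is.null(rownames(sample_matrix)))
    rownames(sample_matrix) <- paste0("g", seq_len(nrow(sample_matrix)))
  const <- apply(sample_matrix, 1, function(r) max(r) == min(r))
  rho <- suppressWarnings(stats::cor(t(sample_matrix), method = "spearman"))
  rho[is.na(rho)] <- 0
  diag(rho) <- 1
  rho <- (rho + t(rho)) / 2  # kill <1e-15 asymmetry from midranks
  structure(rho, class = c("correlation_matrix", class(rho)),
            constant_genes = rownames(sample_matrix)[const])
}

#' Sign-blind correlation distance
#'
#' Converts a correlation matrix into the distance d = 1 - |rho|. Strong
#' correlation of either sign maps to a small distance: genes moving
#' together and genes moving in strict opposition are both "close", which
#' is the intended reading for transcriptional consistency. d lies in
#' \[0, 1\] with a zero diagonal.
#'
#' @param rho a correlation matrix (e.g. from [spearman_matrix()]).
#' @return A symmetric distance matrix with the same labels.
#' @export
correlation_distance <- function(rho) {
  rho <- unclass(as.matrix(rho))
  if (any(abs(rho) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  d <- 1 - abs(rho)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering of a precomputed distance matrix under complete
#' linkage (inter-cluster distance = maximum pairwise distance), via
#' [stats::hclust()]. Complete-linkage merge heights are monotone
#' non-decreasing, so the dendrogram has no inversions.
#'
#' @param d symmetric distance matrix (or `dist`) with zero diagonal.
#' @return An `hclust` object.
#' @export
hcluster <- function(d) {
  dd <- if (inherits(d, "dist")) d else stats::as.dist(d)
  if (attr(dd, "Size") < 2) stop("need at least 2 items to cluster")
  stats::hclust(dd, method = "complete")
}

#' Cophenetic correlation of a dendrogram
#'
#' Pearson correlation between the original pairwise distances and the
#' cophenetic distances (the merge height at which each pair first joins).
#' 1 means the tree reproduces the distances exactly (ultrametric input).
#' Degenerate inputs where either set of distances is constant have no
#' defined correlation and are flagged.
#'
#' @param d the distance matrix (or `dist`) the tree was built from.
#' @param hc the `hclust` tree.
#' @return List with `correlation` and `degenerate`.
#' @export
cophenetic_correlation <- function(d, hc) {
  dd <- if (inherits(d, "dist")) d else stats::as.dist(d)
  cd <- stats::cophenetic(hc)
  if (stats::sd(dd) == 0 || stats::sd(cd) == 0)
    return(list(correlation = NA_real_, degenerate = TRUE))
  list(correlation = stats::cor(as.numeric(dd), as.numeric(cd)),
       degenerate = FALSE)
}

#' Choose the number of clusters by mean silhouette width
#'
#' Cuts the tree at each k in `k_range`, scores the partition by the mean
#' silhouette width on the precomputed distance
#' ([cluster::silhouette()]), and returns the k with the highest mean
#' width. Ties (within `tie_tol`) break to the smallest k.
#'
#' @param d distance matrix (or `dist`).
#' @param hc `hclust` tree over the same items.
#' @param k_range candidate cluster counts, default `2:10`, clipped to
#'   `[2, n - 1]`.
#' @param tie_tol absolute tolerance within which two widths count as tied
#'   (default 1e-8).
#' @return List with `k`, `widths` (named mean silhouette per candidate k).
#' @export
select_k <- function(d, hc, k_range = 2:10, tie_tol = 1e-8) {
  dd <- if (inherits(d, "dist")) d else stats::as.dist(d)
  n <- attr(dd, "Size")
  k_range <- sort(unique(k_range[k_range >= 2 & k_range <= n - 1]))
  if (!length(k_range)) stop("k_range has no feasible value in [2, n-1]")
  widths <- vapply(k_range, function(k) {
    sil <- cluster::silhouette(stats::cutree(hc, k = k), dd)
    mean(sil[, "sil_width"])
  }, 0)
  names(widths) <- k_range
  best <- k_range[which(widths >= max(widths) - tie_tol)[1]]
  list(k = best, widths = widths)
}

#' Cut a dendrogram into k clusters
#'
#' @param hc `hclust` tree.
#' @param k number of clusters, in `[1, n]`.
#' @return Named integer vector of cluster labels.
#' @export
cut_clusters <- function(hc, k) {
  n <- length(hc$labels %||% hc$order)
  if (k < 1 || k > n) stop("k must lie in [1, ", n, "]")
  stats::cutree(hc, k = k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Transcription-consistency clustering of a sample matrix
#'
#' The full co-expression workflow: Spearman correlation across samples,
#' sign-blind 1 - |rho| distance, complete-linkage dendrogram, cophenetic
#' diagnostic, silhouette-based cluster-count selection, and the final cut.
#'
#' @param sample_matrix genes x samples matrix (>= 2 genes, >= 3 samples).
#' @param k fixed number of clusters; `NULL` (default) selects k by mean
#'   silhouette over `k_range`.
#' @param k_range candidate cluster counts when `k` is `NULL`.
#' @return Object of class `coexpression_clusters`: list with `rho`,
#'   `dist`, `tree`, `k`, `clusters`, `silhouette_widths`,
#'   `cophenetic_correlation`, `constant_genes`.
#' @export
coexpression_clusters <- function(sample_matrix, k = NULL, k_range = 2:10) {
  rho <- spearman_matrix(sample_matrix)
  d <- correlation_distance(rho)
  hc <- hcluster(d)
  widths <- NULL
  if (is.null(k)) {
    sel <- select_k(d, hc, k_range)
    k <- sel$k; widths <- sel$widths
  }
  structure(list(rho = rho, dist = d, tree = hc, k = k,
                 clusters = cut_clusters(hc, k),
                 silhouette_widths = widths,
                 cophenetic_correlation =
                   cophenetic_correlation(d, hc)$correlation,
                 constant_genes = attr(rho, "constant_genes")),
            class = "coexpression_clusters")
}

#' @export
print.coexpression_clusters <- function(x, ...) {
  cat(sprintf("Co-expression clustering of %d genes (1 - |Spearman rho| distance, complete linkage)\n",
              nrow(x$rho)))
  cat(sprintf("  k = %d cluster(s); sizes: %s\n", x$k,
              paste(table(x$clusters), collapse = ", ")))
  cat(sprintf("  cophenetic correlation: %.3f\n", x$cophenetic_correlation))
  if (length(x$constant_genes))
    cat("  constant genes (rho set to 0):",
        paste(x$constant_genes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.coexpression_clusters <- function(x, ...) {
  plot(x$tree, ylab = "1 - |Spearman rho| (complete linkage)",
       xlab = "", sub = "", main = "Transcription-consistency dendrogram",
       ...)
  if (x$k > 1 && x$k < nrow(x$rho))
    stats::rect.hclust(x$tree, k = x$k, border = "grey40")
  invisible(x)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are merge-height differences, so root-to-leaf path length
#' equals the final merge height.
#'
#' @param hc `hclust` tree.
#' @param path optional file to write; when `NULL`, the string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  labels <- hc$labels %||% as.character(seq_len(nrow(hc$merge) + 1))
  node_str <- function(i, parent_height) {
    if (i < 0) return(sprintf("%s:%s", labels[-i], format(parent_height)))
    h <- hc$height[i]
    kids <- vapply(hc$merge[i, ], node_str, "", parent_height = h)
    sprintf("(%s,%s):%s", kids[1], kids[2], format(parent_height - h))
  }
  n <- nrow(hc$merge)
  h <- hc$height[n]
  kids <- vapply(hc$merge[n, ], node_str, "", parent_height = h)
  s <- sprintf("(%s,%s);", kids[1], kids[2])
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
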