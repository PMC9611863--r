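# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (loops, full enumeration) and never call
# the implementation under test.

oracle_summary <- function(values, target_idx) {
  others <- sort(values[-target_idx])
  n <- length(others)
  med <- if (n %% 2 == 1) others[(n + 1) / 2]
         else (others[n / 2] + others[n / 2 + 1]) / 2
  list(max_other = others[n], median_other = med)
}

oracle_inv_ratio <- function(values, target_idx) {
  best <- -Inf
  for (i in seq_along(values))
    if (i != target_idx) best <- max(best, values[i] / values[target_idx])
  best
}

# exact two-sided Mann-Whitney p by enumeration of all C(m+n, m)
# assignments of the pooled ranks to group a (distinct values assumed)
oracle_mw_exact <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  us <- apply(combos, 2, function(idx) sum(rank(pooled)[idx]) - m * (m + 1) / 2)
  if (u_obs > m * n / 2) p <- 2 * mean(us >= u_obs) else p <- 2 * mean(us <= u_obs)
  list(u = u_obs, p = min(1, p))
}

# exact two-sided signed-rank p by enumeration of all 2^n sign patterns
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  vs <- apply(signs, 1, function(s) sum(r[s]))
  mu <- n * (n + 1) / 4
  if (v_obs > mu) p <- 2 * mean(vs >= v_obs) else p <- 2 * mean(vs <= v_obs)
  list(v = v_obs, p = min(1, p))
}

# naive O(n^3) complete-linkage agglomeration; returns sorted merge heights
oracle_complete_linkage_heights <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < best) { best <- d; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# pairwise cophenetic distances extracted by replaying the merge sequence
oracle_cophenetic_matrix <- function(hc) {
  n <- nrow(hc$merge) + 1
  out <- matrix(0, n, n)
  merged <- list()
  for (s in seq_len(nrow(hc$merge))) {
    left <- hc$merge[s, 1]; right <- hc$merge[s, 2]
    lm <- if (left < 0) -left else merged[[left]]
    rm_ <- if (right < 0) -right else merged[[right]]
    for (i in lm) for (j in rm_) out[i, j] <- out[j, i] <- hc$height[s]
    merged[[s]] <- c(lm, rm_)
  }
  dimnames(out) <- list(hc$labels, hc$labels)
  out
}

oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# Venn regions by explicit per-gene membership
oracle_venn_region <- function(per_db_sets, gene) {
  names(per_db_sets)[vapply(per_db_sets, function(s) gene %in% s, TRUE)]
}

adjusted_rand <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  choose2 <- function(x) sum(choose(x, 2))
  sum_ij <- choose2(tab); sum_a <- choose2(rowSums(tab))
  sum_b <- choose2(colSums(tab)); nc2 <- choose(sum(tab), 2)
  exp_idx <- sum_a * sum_b / nc2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# shared tiny fixture: the published nine-gene four-database summaries
published_minipanels <- function() {
  summaries_to_minipanels(published_testis_summaries())
}
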