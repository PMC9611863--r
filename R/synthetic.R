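#' Run an expression with a local, restorable RNG seed
#'
#' All generators are pure functions of (config, seed): they seed the RNG
#' locally and restore the caller's RNG state on exit.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate multi-database expression panels with planted specific genes
#'
#' Emulates several correlated databases measuring the same genes across
#' the same tissues: a shared log-normal background (heavy right tail, as
#' in real TPM data), per-database multiplicative log-normal jitter, and a
#' configurable number of planted target-tissue-specific genes. Planting is
#' enforced by construction after the jitter: in every database, a planted
#' gene's target-tissue TPM is set to
#' `max(5, specific_fold * max(other tissues)) * U(1, 1.3)`, so the planted
#' set is recoverable exactly by a `specific_fold`-fold screen and the
#' recovery tests are sharp rather than probabilistic.
#'
#' @param n_genes total genes per panel (default 100).
#' @param n_tissues tissues per panel (default 20).
#' @param n_databases number of pseudo-databases (default 4).
#' @param n_specific planted target-specific genes (default 9, as many as
#'   the consensus screen is expected to recover).
#' @param bg_meanlog,bg_sdlog log-normal background parameters on the
#'   natural-log scale (defaults 0.5 and 1.0).
#' @param specific_fold planted target/other fold, > 1 (default 10).
#' @param background_max_fold cap on the target/other fold of background
#'   genes (default 1.5, half the default 3-fold screen threshold): a
#'   background gene whose jittered target-tissue value exceeds this fold
#'   over its other tissues is pulled back under the cap, so the planted
#'   set is recovered exactly, never probabilistically.
#' @param cross_db_noise_sd log-scale sd of the between-database jitter
#'   (default 0.2).
#' @param target_tissue_label label of the planted tissue (default
#'   "testis").
#' @param seed integer seed.
#' @return List with `panels` (named list of [expression_panel()]),
#'   `truth` (character vector of planted gene IDs), and `config`.
#' @export
generate_panels <- function(n_genes = 100, n_tissues = 20, n_databases = 4,
                            n_specific = 9, bg_meanlog = 0.5, bg_sdlog = 1.0,
                            specific_fold = 10, background_max_fold = 1.5,
                            cross_db_noise_sd = 0.2,
                            target_tissue_label = "testis", seed = 1) {
  stopifnot(n_specific <= n_genes, specific_fold > 1, bg_sdlog >= 0,
            cross_db_noise_sd >= 0, n_tissues >= 2, n_databases >= 1,
            background_max_fold > 0, background_max_fold < specific_fold)
  config <- list(n_genes = n_genes, n_tissues = n_tissues,
                 n_databases = n_databases, n_specific = n_specific,
                 bg_meanlog = bg_meanlog, bg_sdlog = bg_sdlog,
                 specific_fold = specific_fold,
                 background_max_fold = background_max_fold,
                 cross_db_noise_sd = cross_db_noise_sd,
                 target_tissue_label = target_tissue_label, seed = seed)
  with_seed(seed, {
    gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
    symbols <- sprintf("SYM%04d", seq_len(n_genes))
    tissues <- c(target_tissue_label,
                 sprintf("tissue%02d", seq_len(n_tissues - 1)))
    planted <- gene_ids[seq_len(n_specific)]
    base <- matrix(stats::rlnorm(n_genes * n_tissues, bg_meanlog, bg_sdlog),
                   n_genes, n_tissues)
    panels <- list()
    for (d in seq_len(n_databases)) {
      jitter <- matrix(stats::rlnorm(n_genes * n_tissues, 0,
                                     cross_db_noise_sd),
                       n_genes, n_tissues)
      vals <- base * jitter
      for (i in seq_len(n_genes)) {
        mo <- max(vals[i, -1])
        if (i <= n_specific) {
          vals[i, 1] <- max(5, specific_fold * mo) * stats::runif(1, 1, 1.3)
          if (!is.finite(vals[i, 1]))
            stop("infeasible panel config: planted value not finite")
        } else if (vals[i, 1] > background_max_fold * mo) {
          # pull stray background genes back under the fold cap
          vals[i, 1] <- background_max_fold * mo * stats::runif(1, 0.5, 1)
        }
      }
      panels[[sprintf("DB%d", d)]] <- expression_panel(
        vals, gene_ids = gene_ids, tissue_labels = tissues,
        gene_symbols = symbols, database_name = sprintf("DB%d", d))
    }
    list(panels = panels, truth = planted, config = config)
  })
}

#' Simulate a qPCR tumor/normal cohort with planted suppression
#'
#' Emulates a testis cohort measured by qPCR: two reference genes at a
#' common base Cq plus a per-sample loading shift (which the geometric-mean
#' normalization must cancel), target genes whose Cq encodes a true
#' relative level with log-normal biological spread, and planted genes
#' suppressed `suppression_fold`-fold in germ-histology tumor samples.
#' Default arm sizes mirror a realistic orchiectomy series: 2 healthy
#' controls, 27 germ tumors with 7 adjacent normals (6 patient pairs), and
#' 4 non-germ tumors with 4 adjacent normals (3 pairs).
#'
#' @param n_control healthy control samples (histology NA).
#' @param n_tumor_germ,n_adjacent_germ germ-histology arm sizes.
#' @param n_tumor_nongerm,n_adjacent_nongerm non-germ arm sizes.
#' @param n_pairs_germ,n_pairs_nongerm patients contributing a
#'   tumor/adjacent pair (must not exceed the smaller arm).
#' @param target_genes genes with planted suppression in germ tumors.
#' @param null_genes genes with no planted effect.
#' @param suppression_fold fold suppression (>= 1) applied to
#'   `target_genes` in germ tumors (default 50).
#' @param base_level normal-tissue relative level of every gene (default 1).
#' @param bio_sdlog2 biological spread of true levels in log2 units
#'   (default 0.5).
#' @param cq_noise_sd technical replicate noise, cycles (default 0.1).
#' @param n_replicates technical replicates per well (default 3).
#' @param reference_cq_base base Cq of the reference genes (default 15).
#' @param reference_genes reference gene labels (default 18S, GAPDH).
#' @param seed integer seed.
#' @return List with `cq_data` (long-format sample_id/gene/cq), `metadata`
#'   (sample_id/state/histology/patient_id), `truth` (sample_id/gene/
#'   true_level), `config`.
#' @export
generate_qpcr_cohort <- function(n_control = 2,
                                 n_tumor_germ = 27, n_adjacent_germ = 7,
                                 n_tumor_nongerm = 4, n_adjacent_nongerm = 4,
                                 n_pairs_germ = 6, n_pairs_nongerm = 3,
                                 target_genes = c("TS1", "TS2"),
                                 null_genes = "NULL1",
                                 suppression_fold = 50,
                                 base_level = 1, bio_sdlog2 = 0.5,
                                 cq_noise_sd = 0.1, n_replicates = 3,
                                 reference_cq_base = 15,
                                 reference_genes = c("18S", "GAPDH"),
                                 seed = 1) {
  stopifnot(suppression_fold >= 1, cq_noise_sd >= 0,
            n_pairs_germ <= min(n_tumor_germ, n_adjacent_germ),
            n_pairs_nongerm <= min(n_tumor_nongerm, n_adjacent_nongerm))
  config <- as.list(environment())
  with_seed(seed, {
    mk <- function(prefix, n) if (n > 0) sprintf("%s%02d", prefix, seq_len(n))
                              else character(0)
    arm <- function(prefix, n, state, histology, pair_prefix, n_pairs) {
      data.frame(sample_id = mk(prefix, n), state = rep(state, n),
                 histology = rep(histology, n),
                 patient_id = c(mk(pair_prefix, n_pairs),
                                rep(NA_character_, n - n_pairs)),
                 stringsAsFactors = FALSE)
    }
    meta <- rbind(
      arm("K", n_control, "control", NA_character_, "", 0),
      arm("GT", n_tumor_germ, "tumor", "germ", "PG", n_pairs_germ),
      arm("GN", n_adjacent_germ, "adjacent_normal", "germ", "PG",
          n_pairs_germ),
      arm("NGT", n_tumor_nongerm, "tumor", "non_germ", "PN",
          n_pairs_nongerm),
      arm("NGN", n_adjacent_nongerm, "adjacent_normal", "non_germ", "PN",
          n_pairs_nongerm))
    genes <- c(target_genes, null_genes)
    cq_rows <- list(); truth_rows <- list()
    for (i in seq_len(nrow(meta))) {
      s <- meta$sample_id[i]
      shift <- stats::rnorm(1, 0, 0.5)  # loading/efficiency offset
      ref_cq <- reference_cq_base + shift
      for (rg in reference_genes)
        cq_rows[[length(cq_rows) + 1]] <- data.frame(
          sample_id = s, gene = rg,
          cq = ref_cq + stats::rnorm(n_replicates, 0, cq_noise_sd),
          stringsAsFactors = FALSE)
      suppressed <- meta$state[i] == "tumor" &&
        identical(meta$histology[i], "germ")
      for (g in genes) {
        lvl <- base_level * 2^stats::rnorm(1, 0, bio_sdlog2)
        if (suppressed && g %in% target_genes) lvl <- lvl / suppression_fold
        cq <- ref_cq - log2(lvl)
        cq_rows[[length(cq_rows) + 1]] <- data.frame(
          sample_id = s, gene = g,
          cq = cq + stats::rnorm(n_replicates, 0, cq_noise_sd),
          stringsAsFactors = FALSE)
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          sample_id = s, gene = g, true_level = lvl,
          stringsAsFactors = FALSE)
      }
    }
    list(cq_data = do.call(rbind, c(cq_rows, list(make.row.names = FALSE))),
         metadata = meta,
         truth = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))),
         config = config)
  })
}

#' Simulate block-correlated gene expression across samples
#'
#' Emulates a genes x samples matrix with planted co-expression blocks:
#' each block shares a latent per-sample factor, and each gene is
#' `within_block_rho * latent + noise_sd * independent noise`. With
#' `noise_sd = 0` the within-block Spearman correlation is exactly 1; the
#' realized correlation rises with `within_block_rho` and falls with
#' `noise_sd`. Setting `anticorrelated_fraction > 0` flips the sign of
#' that fraction of genes in each block, exercising the sign-blind
#' distance.
#'
#' @param block_sizes integer vector of genes per block.
#' @param n_samples number of sample columns (default 50).
#' @param within_block_rho latent-factor loading in (0, 1] (default 0.9).
#' @param noise_sd independent noise sd (default 0.3).
#' @param anticorrelated_fraction fraction of genes per block with flipped
#'   sign (default 0).
#' @param seed integer seed.
#' @return List with `matrix` (genes x samples, rownames `B<block>G<i>`),
#'   `block_labels` (integer vector), `config`.
#' @export
generate_correlated_blocks <- function(block_sizes = c(10, 10),
                                       n_samples = 50,
                                       within_block_rho = 0.9,
                                       noise_sd = 0.3,
                                       anticorrelated_fraction = 0,
                                       seed = 1) {
  stopifnot(within_block_rho > 0, within_block_rho <= 1, noise_sd >= 0,
            all(block_sizes >= 1), n_samples >= 3,
            anticorrelated_fraction >= 0, anticorrelated_fraction <= 1)
  config <- list(block_sizes = block_sizes, n_samples = n_samples,
                 within_block_rho = within_block_rho, noise_sd = noise_sd,
                 anticorrelated_fraction = anticorrelated_fraction,
                 seed = seed)
  with_seed(seed, {
    n_genes <- sum(block_sizes)
    mat <- matrix(0, n_genes, n_samples)
    labels <- integer(n_genes)
    names_out <- character(n_genes)
    row <- 1
    for (b in seq_along(block_sizes)) {
      latent <- stats::rnorm(n_samples)
      n_flip <- floor(block_sizes[b] * anticorrelated_fraction)
      for (i in seq_len(block_sizes[b])) {
        sgn <- if (i <= n_flip) -1 else 1
        mat[row, ] <- sgn * within_block_rho * latent +
          noise_sd * stats::rnorm(n_samples)
        labels[row] <- b
        names_out[row] <- sprintf("B%dG%d", b, i)
        row <- row + 1
      }
    }
    rownames(mat) <- names_out
    colnames(mat) <- sprintf("S%03d", seq_len(n_samples))
    list(matrix = mat, block_labels = labels, config = config)
  })
}
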