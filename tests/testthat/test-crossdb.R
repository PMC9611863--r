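test_that("Venn partition handles the simple documented cases", {
  p <- intersect_gene_sets(list(d1 = "A", d2 = "A"))
  expect_equal(consensus_core(p), "A")
  expect_true(all(lengths(p$region_sets[names(p$region_sets) != "d1+d2"]) == 0))

  p2 <- intersect_gene_sets(list(w = c("A", "B"), x = c("B", "C"),
                                 y = "B", z = c("B", "D")))
  expect_equal(consensus_core(p2), "B")
})

test_that("Venn regions are a disjoint, exhaustive partition matching per-gene membership", {
  set.seed(31)
  genes <- sprintf("G%03d", 1:100)
  sets <- lapply(1:4, function(i) sample(genes, sample(20:60, 1)))
  names(sets) <- c("HPA", "ENCODE", "GTEx", "Illumina")
  p <- intersect_gene_sets(sets)
  expect_length(p$region_sets, 2^4 - 1)

  all_assigned <- unlist(p$region_sets, use.names = FALSE)
  expect_equal(anyDuplicated(all_assigned), 0L)       # pairwise disjoint
  expect_setequal(all_assigned, unique(unlist(sets))) # exhaustive

  # every gene sits in the region of exactly its member databases
  for (g in sample(all_assigned, 30)) {
    region <- names(Filter(function(r) g %in% r, p$region_sets))
    expect_equal(sort(strsplit(region, "+", fixed = TRUE)[[1]]),
                 sort(oracle_venn_region(sets, g)))
  }
  # union over regions containing database d reconstitutes d's input
  for (d in names(sets)) {
    has_d <- vapply(strsplit(names(p$region_sets), "+", fixed = TRUE),
                    function(k) d %in% k, TRUE)
    expect_setequal(unlist(p$region_sets[has_d]), sets[[d]])
  }
  expect_lte(length(consensus_core(p)), min(lengths(sets)))
  expect_error(intersect_gene_sets(list(a = "A")), "at least 2")
})

make_summary <- function(gene, target, max_other, median_other = max_other / 2) {
  structure(list(gene = gene, target_tissue = "testis", target_tpm = target,
                 max_other = max_other, median_other = median_other),
            class = "gene_tissue_summary")
}

test_that("consensus records carry the minimum fold across databases", {
  recs <- consensus_records(list(
    HPA = list(make_summary("ZNF473", 76.4, 11.1),
               make_summary("PRDM9", 7, 0)),
    GTEx = list(make_summary("ZNF473", 49.1, 8.3),
                make_summary("PRDM9", 6.9, 0))))
  zn <- recs[recs$gene == "ZNF473", ]
  expect_equal(zn$min_fold_across_dbs, min(76.4 / 11.1, 49.1 / 8.3))
  # a zero max-other counts as infinite fold
  expect_equal(recs$min_fold_across_dbs[recs$gene == "PRDM9"], Inf)
})

test_that("consensus fold filter is strict, monotone, and excludes missing genes", {
  # published ZNF473 folds: min across the four databases ~ 5.75 -> kept
  s <- published_testis_summaries()
  by_db <- lapply(split(s, s$database), function(d)
    lapply(seq_len(nrow(d)), function(i)
      make_summary(d$gene[i], d$target_tpm[i], d$max_other[i],
                   d$median_other[i])))
  recs <- consensus_records(by_db)
  zn <- recs$min_fold_across_dbs[recs$gene == "ZNF473"]
  expect_equal(zn, min(76.4 / 11.1, 79 / 8, 49.1 / 8.3, 46 / 8))
  expect_true("ZNF473" %in% consensus_fold_filter(recs, 1.5))
  expect_length(consensus_fold_filter(recs, 1.5), 9)

  # exact boundary is dropped under strict, kept when inclusive
  b <- consensus_records(list(a = list(make_summary("G", 3, 2)),
                              b = list(make_summary("G", 4.5, 3))))
  expect_length(consensus_fold_filter(b, 1.5, strict = TRUE), 0)
  expect_equal(consensus_fold_filter(b, 1.5, strict = FALSE), "G")

  # monotone in the threshold; brute-force loop-min cross-check
  set.seed(8)
  genes <- sprintf("G%02d", 1:30)
  dbs <- lapply(1:3, function(i)
    lapply(genes, function(g) make_summary(g, stats::rlnorm(1, 2),
                                           stats::rlnorm(1, 0.5))))
  names(dbs) <- paste0("db", 1:3)
  recs2 <- consensus_records(dbs)
  for (g in genes) {
    folds <- vapply(dbs, function(lst) {
      s1 <- lst[[which(genes == g)]]
      if (s1$max_other == 0) Inf else s1$target_tpm / s1$max_other
    }, 0)
    expect_equal(recs2$min_fold_across_dbs[recs2$gene == g], min(folds))
  }
  f1 <- consensus_fold_filter(recs2, 1.2)
  f2 <- consensus_fold_filter(recs2, 2.0)
  expect_true(all(f2 %in% f1))

  # gene absent from one database is excluded and reported
  part <- consensus_records(list(a = list(make_summary("G1", 10, 1),
                                          make_summary("G2", 10, 1)),
                                 b = list(make_summary("G1", 10, 1))))
  expect_equal(part$gene, "G1")
  expect_equal(attr(part, "missing")$b, "G2")
})

test_that("summary cells format as 'T (M/m)' and round-trip through the parser", {
  expect_equal(format_summary_cell(109.3, 6.5, 0.3), "109.3 (6.5/0.3)")
  expect_equal(format_summary_cell(0, 0, 0), "0 (0/0)")
  set.seed(13)
  for (rep in 1:20) {
    v <- round(stats::rlnorm(3, 2), sample(0:3, 1))
    cell <- format_summary_cell(v[1], v[2], v[3])
    expect_equal(unname(parse_summary_cell(cell)), v)
  }
  expect_error(parse_summary_cell("garbage"), "unparseable")
})

test_that("build_summary_table emits one formatted cell per database", {
  recs <- consensus_records(list(
    GTEx = list(make_summary("ZBTB32", 109.3, 6.5, 0.3)),
    HPA = list(make_summary("ZBTB32", 43.3, 7.5, 0.15))))
  tab <- build_summary_table(recs)
  expect_equal(tab$GTEx, "109.3 (6.5/0.3)")
  expect_equal(tab$HPA, "43.3 (7.5/0.15)")
})
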