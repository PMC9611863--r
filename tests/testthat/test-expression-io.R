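test_that("GCT 1.2 read/write round-trips, including the minimal panel", {
  # minimal 1x1 panel with value 0
  f <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "1\t1", "Name\tDescription\ttestis", "G1\tG1\t0"), f)
  p <- read_gct(f)
  expect_equal(dim(p), c(1L, 1L))
  expect_equal(unname(p$values[1, 1]), 0)

  # round-trip of a synthetic 3x2 panel against the in-memory matrix
  g <- generate_panels(n_genes = 3, n_tissues = 2, n_databases = 1,
                       n_specific = 1, seed = 11)
  p0 <- g$panels[[1]]
  f2 <- withr::local_tempfile(fileext = ".gct")
  write_gct(p0, f2)
  p1 <- read_gct(f2, database_name = p0$database_name)
  expect_equal(p1$values, p0$values)
  expect_equal(p1$gene_ids, p0$gene_ids)
  expect_equal(p1$gene_symbols, p0$gene_symbols)
  expect_equal(p1$tissue_labels, p0$tissue_labels)

  # second round trip is the identity
  f3 <- withr::local_tempfile(fileext = ".gct")
  write_gct(p1, f3)
  expect_identical(readLines(f2), readLines(f3))
})

test_that("malformed GCT inputs are rejected with the offending line", {
  write_gct_lines <- function(lines) {
    f <- tempfile(fileext = ".gct")
    writeLines(lines, f)
    f
  }
  expect_error(read_gct(write_gct_lines(
    c("#1.3", "1\t1", "Name\tDescription\tt1", "G1\tG1\t1"))),
    "line 1.*#1\\.2")
  expect_error(read_gct(write_gct_lines(
    c("#1.2", "2\t1", "Name\tDescription\tt1", "G1\tG1\t1"))),
    "declared 2 genes")
  expect_error(read_gct(write_gct_lines(
    c("#1.2", "2\t1", "Name\tDescription\tt1", "G1\tG1\t1", "G1\tG1\t2"))),
    "duplicate Name entry 'G1'")
  expect_error(read_gct(write_gct_lines(
    c("#1.2", "1\t1", "Name\tDescription\tt1", "G1\tG1\t-3"))),
    "negative TPM")
  expect_error(read_gct(write_gct_lines(
    c("#1.2", "1\t2", "Name\tDescription\tt1\tt2", "G1\tG1\t1\tx"))),
    "non-numeric")
})

test_that("TSV matrix reader handles the contract and round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ttestis", "G1\t5.0"), f)
  p <- read_tsv_matrix(f)
  expect_equal(unname(p$values[1, 1]), 5.0)
  expect_equal(p$gene_symbols, p$gene_ids)

  writeLines(c("gene\ttestis", "G1\t5.0", "G1\t6.0"), f)
  expect_error(read_tsv_matrix(f), "duplicate gene row 'G1'")

  writeLines(c("gene\tt1\tt2", "G1\t1\tfoo"), f)
  expect_error(read_tsv_matrix(f), "row 2, column 3")

  # random 10x5 round trip
  set.seed(42)
  m <- matrix(round(stats::rlnorm(50), 6), 10, 5,
              dimnames = list(sprintf("G%02d", 1:10), sprintf("t%d", 1:5)))
  p0 <- expression_panel(m, database_name = "rt")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_matrix(p0, f2)
  p1 <- read_tsv_matrix(f2)
  expect_equal(p1$values, p0$values)
})

test_that("panels with NA cells follow the na_action flag", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tt1\tt2", "G1\t1\tNA", "G2\t2\t3"), f)
  expect_warning(p <- read_tsv_matrix(f), "dropping 1 gene")
  expect_equal(p$gene_ids, "G2")
  p0 <- read_tsv_matrix(f, na_action = "zero")
  expect_equal(unname(p0$values["G1", "t2"]), 0)
  expect_error(read_tsv_matrix(f, na_action = "error"), "NA values")
})

test_that("subset_to_family intersects by ID and reports unmatched members", {
  g <- generate_panels(n_genes = 40, n_tissues = 4, n_databases = 1,
                       n_specific = 0, seed = 7)
  panel <- g$panels[[1]]

  # family = all genes -> identical panel
  all_fam <- gene_family(panel$gene_ids)
  expect_equal(subset_to_family(panel, all_fam)$values, panel$values)

  # disjoint family -> error
  expect_error(subset_to_family(panel, gene_family(c("X1", "X2"))),
               "vacuous")

  # random 50% family, verified by independent set arithmetic
  set.seed(1)
  members <- sample(c(panel$gene_ids, sprintf("ABS%02d", 1:10)), 25)
  fam <- gene_family(members)
  sub <- subset_to_family(panel, fam)
  expected <- panel$gene_ids[panel$gene_ids %in% members]  # order preserved
  expect_identical(sub$gene_ids, expected)
  expect_setequal(attr(sub, "unmatched"), setdiff(members, panel$gene_ids))
})

test_that("gene family files parse in both accepted layouts", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("ENSG1", "ENSG2"), f)
  fam <- read_gene_family(f)
  expect_setequal(fam$member_ids, c("ENSG1", "ENSG2"))

  writeLines(c("id\tsymbol", "ENSG1\tZNF1", "ENSG2\tZNF2"), f)
  fam2 <- read_gene_family(f)
  expect_equal(unname(fam2$id_to_symbol["ENSG1"]), "ZNF1")
})

test_that("summarize_gene matches the published ZNF473 cell and its oracle", {
  m <- matrix(c(76.4, 11.1, 4.25, 1.0, 4.25), 1,
              dimnames = list("ZNF473", c("testis", paste0("t", 1:4))))
  s <- summarize_gene(expression_panel(m), "ZNF473", "testis")
  expect_equal(s$target_tpm, 76.4)
  expect_equal(s$max_other, 11.1)
  expect_equal(s$median_other, 4.25)

  # two tissues: the single other value is both max and median
  m2 <- matrix(c(5, 5), 1, dimnames = list("G", c("a", "b")))
  s2 <- summarize_gene(expression_panel(m2), "G", "a")
  expect_equal(s2$max_other, 5)
  expect_equal(s2$median_other, 5)

  expect_error(summarize_gene(expression_panel(m), "NOPE", "testis"),
               "unknown gene: NOPE")
  expect_error(summarize_gene(expression_panel(m), "ZNF473", "spleen"),
               "unknown tissue: spleen")
})

test_that("summaries obey permutation and scaling invariances plus the brute-force oracle", {
  set.seed(99)
  for (rep in 1:20) {
    v <- stats::rlnorm(20)
    m <- matrix(v, 1, dimnames = list("G", sprintf("t%02d", 1:20)))
    s <- summarize_gene(expression_panel(m), "G", "t01")
    o <- oracle_summary(v, 1)
    expect_equal(s$max_other, o$max_other)
    expect_equal(s$median_other, o$median_other)

    # permute non-target tissues
    perm <- c(1, sample(2:20))
    mp <- matrix(v[perm], 1, dimnames = list("G", sprintf("t%02d", 1:20)))
    sp <- summarize_gene(expression_panel(mp), "G", "t01")
    expect_equal(sp$max_other, s$max_other)
    expect_equal(sp$median_other, s$median_other)

    # scale by c > 0
    cc <- stats::runif(1, 0.1, 10)
    sc <- summarize_gene(expression_panel(m * cc), "G", "t01")
    expect_equal(sc$target_tpm, cc * s$target_tpm)
    expect_equal(sc$max_other, cc * s$max_other)
    expect_equal(sc$median_other, cc * s$median_other)
  }
})
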