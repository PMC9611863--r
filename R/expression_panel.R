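#' Expression panel: one database's genes-by-tissues TPM matrix
#'
#' An `expression_panel` bundles a non-negative genes x tissues matrix of
#' TPM values with gene identifiers (primary keys, e.g. Ensembl IDs), display
#' symbols, and tissue labels. Gene IDs and tissue labels must be unique;
#' symbols may repeat or be missing. All joins across databases are by ID.
#'
#' @param values numeric matrix, genes in rows, tissues in columns; finite,
#'   non-negative TPM.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#' @param tissue_labels character vector of unique tissue labels, one per
#'   column.
#' @param gene_symbols optional character vector of display symbols parallel
#'   to `gene_ids`; defaults to the IDs.
#' @param database_name label for the source database.
#' @return An object of class `expression_panel`: a list with elements
#'   `values`, `gene_ids`, `gene_symbols`, `tissue_labels`, `database_name`.
#' @examples
#' m <- matrix(c(10, 1, 2, 0.5), 2, 2,
#'             dimnames = list(c("G1", "G2"), c("testis", "liver")))
#' expression_panel(m, database_name = "demo")
#' @export
expression_panel <- function(values, gene_ids = rownames(values),
                             tissue_labels = colnames(values),
                             gene_symbols = NULL,
                             database_name = "unnamed") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) stop("gene_ids are required (or row names on 'values')")
  if (is.null(tissue_labels)) stop("tissue_labels are required (or column names on 'values')")
  gene_ids <- as.character(gene_ids)
  tissue_labels <- as.character(tissue_labels)
  if (is.null(gene_symbols)) gene_symbols <- gene_ids
  gene_symbols <- as.character(gene_symbols)

  if (nrow(values) != length(gene_ids))
    stop("values has ", nrow(values), " rows but ", length(gene_ids), " gene_ids")
  if (ncol(values) != length(tissue_labels))
    stop("values has ", ncol(values), " columns but ", length(tissue_labels),
         " tissue_labels")
  if (length(gene_symbols) != length(gene_ids))
    stop("gene_symbols must be parallel to gene_ids")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene_ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(tissue_labels))
    stop("duplicate tissue_labels: ",
         paste(unique(tissue_labels[duplicated(tissue_labels)]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("non-finite TPM values are not permitted in a panel")
  if (any(values < 0))
    stop("negative TPM values are not permitted in a panel")

  dimnames(values) <- list(gene_ids, tissue_labels)
  structure(
    list(values = values, gene_ids = gene_ids, gene_symbols = gene_symbols,
         tissue_labels = tissue_labels, database_name = as.character(database_name)),
    class = "expression_panel"
  )
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("Expression panel '%s': %d genes x %d tissues (TPM)\n",
              x$database_name, length(x$gene_ids), length(x$tissue_labels)))
  cat("  tissues:", paste(utils::head(x$tissue_labels, 6), collapse = ", "),
      if (length(x$tissue_labels) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.expression_panel <- function(x) dim(x$values)

#' Read a GCT 1.2 expression matrix
#'
#' GCT 1.2 begins with a `#1.2` version line, then a line with row and column
#' counts, then a header `Name<TAB>Description<TAB><tissue labels...>`. The
#' Description column is kept as the gene symbols. Transparent gzip
#' decompression is supported via R's connection machinery.
#'
#' @param path path to a `.gct` (optionally gzipped) file.
#' @param database_name label for the panel; defaults to the file name.
#' @param na_action how to treat NA cells: `"drop"` removes the gene with a
#'   warning, `"zero"` replaces NA by 0, `"error"` aborts.
#' @return An [expression_panel()].
#' @export
read_gct <- function(path, database_name = basename(path),
                     na_action = c("drop", "zero", "error")) {
  na_action <- match.arg(na_action)
  lines <- readLines(path)
  if (length(lines) < 3)
    stop("line 1: not a GCT file (fewer than 3 lines): ", path)
  if (trimws(lines[1]) != "#1.2")
    stop("line 1: expected GCT version line '#1.2', got '", lines[1], "'")
  counts <- strsplit(trimws(lines[2]), "\t")[[1]]
  if (length(counts) < 2 || anyNA(suppressWarnings(as.integer(counts[1:2]))))
    stop("line 2: expected '<n_genes><TAB><n_tissues>', got '", lines[2], "'")
  n_genes <- as.integer(counts[1]); n_tissues <- as.integer(counts[2])
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  if (length(header) < 3 || header[1] != "Name" || header[2] != "Description")
    stop("line 3: header must start with 'Name<TAB>Description'")
  tissues <- header[-(1:2)]
  if (length(tissues) != n_tissues)
    stop("line 3: header declares ", length(tissues),
         " tissues but line 2 declares ", n_tissues)
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_genes)
    stop("line 2: declared ", n_genes, " genes but found ", length(body),
         " data rows")
  fields <- strsplit(body, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, "", 1L)
  syms <- vapply(fields, `[[`, "", 2L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])[1]
    stop("line ", 3 + which(ids == dup)[2], ": duplicate Name entry '", dup, "'")
  }
  vals <- matrix(NA_real_, length(ids), n_tissues)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != n_tissues + 2)
      stop("line ", 3 + i, ": expected ", n_tissues + 2, " fields, found ",
           length(f))
    v <- suppressWarnings(as.numeric(f[-(1:2)]))
    bad <- which(is.na(v) & !(toupper(f[-(1:2)]) %in% c("NA", "NAN", "")))
    if (length(bad))
      stop("line ", 3 + i, ", column ", bad[1] + 2, ": non-numeric value '",
           f[bad[1] + 2], "'")
    vals[i, ] <- v
  }
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("line ", 3 + neg[1, 1], ": negative TPM value ", vals[neg[1, , drop = FALSE]])
  res <- resolve_na(vals, ids, syms, na_action)
  expression_panel(res$vals, gene_ids = res$ids, tissue_labels = tissues,
                   gene_symbols = res$syms, database_name = database_name)
}

resolve_na <- function(vals, ids, syms, na_action) {
  na_rows <- which(apply(vals, 1, anyNA))
  if (length(na_rows)) {
    if (na_action == "error")
      stop("NA values in genes: ", paste(ids[na_rows], collapse = ", "))
    if (na_action == "zero") {
      vals[is.na(vals)] <- 0
    } else {
      warning("dropping ", length(na_rows), " gene(s) with NA values: ",
              paste(utils::head(ids[na_rows], 5), collapse = ", "))
      keep <- setdiff(seq_len(nrow(vals)), na_rows)
      vals <- vals[keep, , drop = FALSE]
      ids <- ids[keep]; syms <- syms[keep]
    }
  }
  list(vals = vals, ids = ids, syms = syms)
}

#' Write a panel as GCT 1.2
#'
#' @param panel an [expression_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(panel, path) {
  stopifnot(inherits(panel, "expression_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#1.2", con)
  writeLines(paste(length(panel$gene_ids), length(panel$tissue_labels), sep = "\t"), con)
  writeLines(paste(c("Name", "Description", panel$tissue_labels), collapse = "\t"), con)
  rows <- paste(panel$gene_ids, panel$gene_symbols,
                apply(panel$values, 1, function(r)
                  paste(format_tpm(r), collapse = "\t")), sep = "\t")
  writeLines(rows, con)
  invisible(path)
}

# shortest decimal representation that round-trips through as.numeric
format_tpm <- function(x) {
  vapply(x, function(v) format(v, digits = 15, scientific = FALSE, trim = TRUE),
         "")
}

#' Read a plain TSV expression matrix
#'
#' First column holds gene IDs, header row holds tissue labels, body is
#' numeric. Symbols default to the IDs.
#'
#' @inheritParams read_gct
#' @return An [expression_panel()].
#' @export
read_tsv_matrix <- function(path, database_name = basename(path),
                            na_action = c("drop", "zero", "error")) {
  na_action <- match.arg(na_action)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("TSV matrix needs a header and at least one row: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  tissues <- header[-1]
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])[1]
    stop("row ", which(ids == dup)[2] + 1, ": duplicate gene row '", dup, "'")
  }
  vals <- matrix(NA_real_, length(ids), length(tissues))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != length(tissues) + 1)
      stop("row ", i + 1, ": expected ", length(tissues) + 1,
           " fields, found ", length(f))
    v <- suppressWarnings(as.numeric(f[-1]))
    bad <- which(is.na(v) & !(toupper(f[-1]) %in% c("NA", "NAN", "")))
    if (length(bad))
      stop("row ", i + 1, ", column ", bad[1] + 1, ": non-numeric cell '",
           f[bad[1] + 1], "'")
    vals[i, ] <- v
  }
  res <- resolve_na(vals, ids, ids, na_action)
  expression_panel(res$vals, gene_ids = res$ids, tissue_labels = tissues,
                   gene_symbols = res$syms, database_name = database_name)
}

#' Write a panel as a plain TSV matrix
#'
#' @inheritParams write_gct
#' @export
write_tsv_matrix <- function(panel, path) {
  stopifnot(inherits(panel, "expression_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", panel$tissue_labels), collapse = "\t"), con)
  rows <- paste(panel$gene_ids,
                apply(panel$values, 1, function(r)
                  paste(format_tpm(r), collapse = "\t")), sep = "\t")
  writeLines(rows, con)
  invisible(path)
}

#' Read a gene-family membership list
#'
#' Accepts one-ID-per-line text or a two-column TSV (id, symbol), with an
#' optional header line starting with "id" or "gene".
#'
#' @param path path to the list.
#' @return A `gene_family` object: list with `member_ids` (character) and
#'   `id_to_symbol` (named character).
#' @export
read_gene_family <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^(id|gene)", lines[1], ignore.case = TRUE) &&
      grepl("\t", lines[1]))
    lines <- lines[-1]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, "", 1L)
  syms <- vapply(fields, function(f) if (length(f) > 1) f[[2]] else f[[1]], "")
  gene_family(ids, syms)
}

#' Construct a gene-family list
#'
#' @param member_ids character vector of member gene IDs (non-empty).
#' @param symbols optional parallel display symbols.
#' @return A `gene_family` object.
#' @export
gene_family <- function(member_ids, symbols = member_ids) {
  member_ids <- as.character(member_ids)
  if (!length(member_ids)) stop("a gene family must have at least one member")
  keep <- !duplicated(member_ids)
  structure(list(member_ids = member_ids[keep],
                 id_to_symbol = stats::setNames(as.character(symbols)[keep],
                                                member_ids[keep])),
            class = "gene_family")
}

#' Restrict a panel to a gene family
#'
#' Keeps panel genes whose ID is in the family, preserving panel order.
#' Family members absent from the panel are reported via an attribute.
#'
#' @param panel an [expression_panel()].
#' @param family a [gene_family()].
#' @return The subset panel, with attribute `unmatched` listing family
#'   members not present in the panel.
#' @export
subset_to_family <- function(panel, family) {
  stopifnot(inherits(panel, "expression_panel"), inherits(family, "gene_family"))
  keep <- panel$gene_ids %in% family$member_ids
  if (!any(keep))
    stop("no panel gene matches the family; the screen would be vacuous")
  out <- expression_panel(panel$values[keep, , drop = FALSE],
                          gene_ids = panel$gene_ids[keep],
                          tissue_labels = panel$tissue_labels,
                          gene_symbols = panel$gene_symbols[keep],
                          database_name = panel$database_name)
  attr(out, "unmatched") <- setdiff(family$member_ids, panel$gene_ids)
  out
}

#' Summarize one gene's expression against all other tissues
#'
#' For a gene and target tissue, reports the target TPM together with the
#' maximum and median TPM over every other tissue. The median of an even
#' count is the mean of the two central values.
#'
#' @param panel an [expression_panel()] with at least two tissues.
#' @param gene gene ID present in the panel.
#' @param target_tissue tissue label present in the panel.
#' @return A `gene_tissue_summary`: list with `gene`, `target_tissue`,
#'   `target_tpm`, `max_other`, `median_other`.
#' @examples
#' m <- matrix(c(76.4, 11.1, 4.25, 1.0, 4.25), 1,
#'             dimnames = list("ZNF473", c("testis", "t1", "t2", "t3", "t4")))
#' summarize_gene(expression_panel(m), "ZNF473", "testis")
#' @export
summarize_gene <- function(panel, gene, target_tissue) {
  stopifnot(inherits(panel, "expression_panel"))
  if (length(panel$tissue_labels) < 2)
    stop("summaries need at least 2 tissues")
  gi <- match(gene, panel$gene_ids)
  if (is.na(gi)) stop("unknown gene: ", gene)
  ti <- match(target_tissue, panel$tissue_labels)
  if (is.na(ti)) stop("unknown tissue: ", target_tissue)
  others <- panel$values[gi, -ti]
  structure(list(gene = gene, target_tissue = target_tissue,
                 target_tpm = unname(panel$values[gi, ti]),
                 max_other = max(others),
                 median_other = stats::median(others)),
            class = "gene_tissue_summary")
}

#' @export
print.gene_tissue_summary <- function(x, ...) {
  cat(sprintf("%s @ %s: %s TPM (max other %s / median other %s)\n",
              x$gene, x$target_tissue, format(x$target_tpm),
              format(x$max_other), format(x$median_other)))
  invisible(x)
}
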