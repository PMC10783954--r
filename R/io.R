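# Readers and writers for the file formats the tool touches, plus input
# alignment. Internally samples are always rows and genes always columns;
# a single `transpose` flag at ingest covers genes x samples sources.

#' Validate an expression matrix
#'
#' Checks the internal contract of an expression matrix: samples as rows,
#' genes as columns, unique non-empty identifiers on both dimensions, and no
#' missing values.
#'
#' @param values a numeric `matrix` or a sparse [Matrix::Matrix] with
#'   row names (sample identifiers) and column names (gene identifiers).
#' @return `values`, invisibly, after validation.
#' @export
validate_expression <- function(values) {
  if (!(is.matrix(values) || methods::is(values, "Matrix"))) {
    stop("expression data must be a matrix or a Matrix sparse matrix")
  }
  sample_ids <- rownames(values)
  gene_ids <- colnames(values)
  if (is.null(sample_ids) || is.null(gene_ids)) {
    stop("expression matrix must carry sample (row) and gene (column) names")
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s) > 0L) {
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "))
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g) > 0L) {
    stop("duplicate gene identifiers: ", paste(dup_g, collapse = ", "))
  }
  if (is.matrix(values)) {
    if (!is.numeric(values)) stop("expression matrix must be numeric")
    if (anyNA(values)) {
      bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "missing value in expression matrix at sample '%s', gene '%s'",
        sample_ids[bad[1L]], gene_ids[bad[2L]]
      ))
    }
  } else if (anyNA(values@x)) {
    stop("missing value in sparse expression matrix")
  }
  invisible(values)
}

#' Read an expression matrix
#'
#' Reads a samples x genes expression matrix from a dense delimited file or
#' from a Matrix Market sparse triplet directory. Dense files carry gene
#' identifiers in the header and sample identifiers in the first column.
#' A sparse directory contains `matrix.mtx` (or a single `*.mtx` file) plus
#' `rows.txt` / `cols.txt` sidecars with one identifier per line; entries
#' absent from the triplet are zeros.
#'
#' @param path path to the CSV/TSV file, or to the directory holding the
#'   `.mtx` triplet and its sidecars.
#' @param format one of `"csv"`, `"tsv"`, `"mtx_dir"`.
#' @param transpose set to `TRUE` when the source stores genes as rows and
#'   samples as columns; the matrix is transposed at ingest so that samples
#'   are rows internally.
#' @return a validated numeric matrix (dense input) or `dgCMatrix` (sparse
#'   input) with samples as rows and genes as columns.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("sample_id,g1,g2", "s1,1,2", "s2,3,4"), f)
#' read_expression(f, "csv")
#' @export
read_expression <- function(path, format = c("csv", "tsv", "mtx_dir"),
                            transpose = FALSE) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    values <- read_mtx_dir(path)
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- if (format == "csv") "," else "\t"
    header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]][-1L]
    dup_h <- unique(header[duplicated(header)])
    if (length(dup_h) > 0L) {
      stop("duplicate gene identifiers: ", paste(dup_h, collapse = ", "))
    }
    dt <- data.table::fread(path, sep = sep, header = TRUE,
                            colClasses = list(character = 1L),
                            data.table = FALSE, na.strings = NULL)
    if (ncol(dt) < 2L) stop("expression table needs an id column and at least one data column")
    ids <- as.character(dt[[1L]])
    values <- as.matrix(dt[, -1L, drop = FALSE])
    if (!is.numeric(values)) {
      bad <- which(is.na(suppressWarnings(
        matrix(as.numeric(values), nrow(values))
      )) | values == "NA", arr.ind = TRUE)
      loc <- if (nrow(bad) > 0L) {
        sprintf(" at row '%s', column '%s'", ids[bad[1L, 1L]],
                colnames(values)[bad[1L, 2L]])
      } else ""
      stop("non-numeric cell in expression table", loc)
    }
    if (anyNA(values)) {
      bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
      stop(sprintf("non-numeric cell in expression table at row '%s', column '%s'",
                   ids[bad[1L]], colnames(values)[bad[2L]]))
    }
    rownames(values) <- ids
  }
  if (isTRUE(transpose)) values <- Matrix::t(values)
  validate_expression(values)
  values
}

read_mtx_dir <- function(path) {
  if (!dir.exists(path)) stop("directory not found: ", path)
  mtx <- file.path(path, "matrix.mtx")
  if (!file.exists(mtx)) {
    cand <- list.files(path, pattern = "\\.mtx$", full.names = TRUE)
    if (length(cand) != 1L) stop("expected exactly one .mtx file in ", path)
    mtx <- cand
  }
  rows_f <- file.path(path, "rows.txt")
  cols_f <- file.path(path, "cols.txt")
  if (!file.exists(rows_f) || !file.exists(cols_f)) {
    stop("mtx directory must contain rows.txt and cols.txt sidecars")
  }
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  row_ids <- readLines(rows_f)
  col_ids <- readLines(cols_f)
  row_ids <- row_ids[nzchar(row_ids)]
  col_ids <- col_ids[nzchar(col_ids)]
  if (length(row_ids) != nrow(m) || length(col_ids) != ncol(m)) {
    stop(sprintf("sidecar lengths (%d rows, %d cols) do not match matrix shape %d x %d",
                 length(row_ids), length(col_ids), nrow(m), ncol(m)))
  }
  dimnames(m) <- list(row_ids, col_ids)
  m
}

#' Write an expression matrix to a delimited file
#'
#' Inverse of [read_expression()] for dense output: the header holds gene
#' identifiers and the first column (named `sample_id`) the sample
#' identifiers. Values are written with 17 significant digits, so doubles
#' round-trip bit-exactly.
#'
#' @param values expression matrix, samples x genes.
#' @param path output file path.
#' @param sep field separator (`","` for CSV, `"\t"` for TSV).
#' @return `path`, invisibly.
#' @export
write_expression <- function(values, path, sep = ",") {
  validate_expression(values)
  values <- as.matrix(values)
  body <- apply(values, 1L, function(row) {
    paste(sprintf("%.17g", row), collapse = sep)
  })
  lines <- c(paste(c("sample_id", colnames(values)), collapse = sep),
             paste(rownames(values), body, sep = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT pathway collection
#'
#' Parses the de facto gene-set exchange format: one tab-separated line per
#' pathway holding its name, a description (discarded), and the member gene
#' identifiers. Duplicate genes within a line are collapsed; lines without
#' any genes are skipped with a warning; duplicate pathway names are an
#' error. Gene identifiers are matched downstream by exact, case-sensitive
#' string comparison.
#'
#' @param path path to the `.gmt` file.
#' @return a named list of character vectors of gene identifiers, in file
#'   order, with a `source_label` attribute naming the file.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)
  lines <- lines[nzchar(lines)]
  pathways <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    name <- fields[1L]
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      warning("pathway '", name, "' has no genes; skipped")
      next
    }
    if (name %in% names(pathways)) {
      stop("duplicate pathway name: ", name)
    }
    pathways[[name]] <- genes
  }
  attr(pathways, "source_label") <- basename(path)
  pathways
}

#' Write a pathway collection to GMT
#'
#' @param pathways named list of character vectors of gene identifiers.
#' @param path output file path.
#' @param descriptions optional character vector of per-pathway descriptions;
#'   defaults to `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(pathways))
  lines <- vapply(seq_along(pathways), function(i) {
    paste(c(names(pathways)[i], descriptions[i], pathways[[i]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a phenotype annotation table
#'
#' Reads a TSV with a `sample_id` key column and one or more discrete
#' annotation columns (phenotype, confounder, ...). All annotation values
#' are kept as character labels; missing labels are an error because the
#' scoring model requires fully observed partitions.
#'
#' @param path path to the TSV file.
#' @return a data.frame with a `sample_id` column and character annotation
#'   columns.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE,
                          na.strings = c("NA", ""))
  if (!"sample_id" %in% colnames(df)) {
    stop("phenotype table must have a 'sample_id' column")
  }
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0L) {
    stop("duplicate sample identifiers in phenotype table: ",
         paste(dup, collapse = ", "))
  }
  for (col in setdiff(colnames(df), "sample_id")) {
    if (anyNA(df[[col]])) {
      stop("missing labels in phenotype column '", col, "'")
    }
  }
  df
}

#' Align expression and phenotype inputs on shared samples
#'
#' Restricts both inputs to the intersection of their sample identifiers, in
#' the expression matrix's order, and reports how many samples were dropped
#' from each side.
#'
#' @param expr expression matrix, samples x genes.
#' @param pheno phenotype data.frame with a `sample_id` column.
#' @return a list with elements `expr`, `pheno`, and `n_dropped` (named
#'   count of samples dropped from each input).
#' @export
align_inputs <- function(expr, pheno) {
  validate_expression(expr)
  shared <- intersect(rownames(expr), pheno$sample_id)
  if (length(shared) == 0L) {
    stop("no samples shared between expression matrix and phenotype table")
  }
  keep <- rownames(expr)[rownames(expr) %in% shared]
  dropped <- c(expression = nrow(expr) - length(keep),
               phenotype = nrow(pheno) - length(keep))
  if (any(dropped > 0L)) {
    message(sprintf("align_inputs: dropped %d expression and %d phenotype samples",
                    dropped[["expression"]], dropped[["phenotype"]]))
  }
  expr <- expr[keep, , drop = FALSE]
  pheno <- pheno[match(keep, pheno$sample_id), , drop = FALSE]
  rownames(pheno) <- NULL
  list(expr = expr, pheno = pheno, n_dropped = dropped)
}
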