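#' Validate a gene-by-sample expression matrix
#'
#' Checks the invariants every downstream step relies on: a numeric matrix
#' with unique, non-empty gene and sample identifiers and finite,
#' non-negative values (TPM-like units).
#'
#' @param x numeric matrix, genes in rows, samples in columns, with dimnames.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression data must be a numeric matrix (genes x samples)")
  }
  gid <- rownames(x)
  sid <- colnames(x)
  if (is.null(gid) || is.null(sid)) {
    stop("expression matrix must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(gid)) {
    stop("duplicate gene identifier: ", gid[duplicated(gid)][1])
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample identifier: ", sid[duplicated(sid)][1])
  }
  if (any(!nzchar(gid)) || any(!nzchar(sid))) {
    stop("empty gene or sample identifier")
  }
  bad <- which(!is.finite(x) | x < 0)
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(x))
    stop(sprintf("negative or non-finite value at gene '%s', sample '%s'",
                 gid[i[1]], sid[i[2]]))
  }
  invisible(x)
}

#' Read a tab-separated expression matrix
#'
#' First column holds gene identifiers, the header row holds sample
#' identifiers, and the body is numeric. Row and column order are preserved.
#'
#' @param path path to a TSV file.
#' @return numeric matrix (genes x samples) with identifiers as dimnames.
#' @export
read_expression_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = NA, stringsAsFactors = FALSE, quote = "",
                   comment.char = "")
  if (ncol(df) < 2) stop("expression file needs a gene column plus >= 1 sample")
  gid <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))))[1]
      stop(sprintf("non-numeric value at row %d, column '%s'",
                   bad, names(body)[j]))
    }
  }
  x <- as.matrix(body)
  rownames(x) <- gid
  validate_expression_matrix(x)
  x
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_tsv()]: UTF-8, tab-separated, Unix newlines,
#' gene identifiers in the first column (`gene_id` header).
#'
#' @param x validated expression matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  validate_expression_matrix(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con, sep = "\n")
  lines <- paste(rownames(x),
                 apply(format(x, trim = TRUE, digits = 15, scientific = FALSE),
                       1, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a sample-annotation table
#'
#' Tab-separated with a header; required columns `sample_id`, `dataset`,
#' `tissue`, `state`; optional `replicate` and `library_size` (positive).
#'
#' @param path path to a TSV file.
#' @return data.frame with one row per sample.
#' @export
read_sample_annotations <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "", comment.char = "")
  validate_sample_annotations(df)
}

#' @rdname read_sample_annotations
#' @param annotations data.frame to validate in place of a file.
#' @export
validate_sample_annotations <- function(annotations) {
  required <- c("sample_id", "dataset", "tissue", "state")
  missing <- setdiff(required, names(annotations))
  if (length(missing)) {
    stop("annotation table missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(annotations$sample_id)) {
    stop("duplicate sample_id: ",
         annotations$sample_id[duplicated(annotations$sample_id)][1])
  }
  for (col in c("tissue", "state")) {
    if (any(is.na(annotations[[col]]) | !nzchar(as.character(annotations[[col]])))) {
      stop("empty value in column '", col, "'")
    }
  }
  if ("library_size" %in% names(annotations)) {
    ls <- suppressWarnings(as.numeric(annotations$library_size))
    if (any(is.na(ls) | ls <= 0)) {
      stop("library_size must be a positive number")
    }
    annotations$library_size <- ls
  }
  annotations
}

#' @rdname read_sample_annotations
#' @param path output path.
#' @export
write_sample_annotations <- function(annotations, path) {
  annotations <- validate_sample_annotations(annotations)
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(annotations, con, sep = "\t", quote = FALSE,
              row.names = FALSE, eol = "\n")
  invisible(path)
}
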