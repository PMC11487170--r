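#' Align a gene-weight matrix and a target dataset through an ortholog map
#'
#' Keeps exactly the one-to-one ortholog pairs whose source gene is a row of
#' `A_source` and whose target gene is a row of `Y_target`, in map order, so
#' both outputs have identical row counts with row i of one matching row i
#' of the other. Pairs absent from either input are dropped silently, with
#' the count recorded.
#'
#' @param A_source gene-weight matrix (genes x patterns) with source gene
#'   ids as rownames.
#' @param Y_target target expression matrix (genes x samples).
#' @param map an [ortholog_map()].
#' @param source which side of `map` holds the source gene ids:
#'   `"species_a"`, `"species_b"`, or `"auto"` to detect it (errors when
#'   both orientations match).
#' @return list with aligned `A` (source-gene rownames), `Y` (target-gene
#'   rownames), `pairs` (the data.frame of pairs used) and `n_dropped`.
#' @export
restrict_to_orthologs <- function(A_source, Y_target, map,
                                  source = c("auto", "species_a", "species_b")) {
  stopifnot(inherits(map, "ortholog_map"))
  source <- match.arg(source)
  src_ids <- rownames(A_source)
  tgt_ids <- rownames(Y_target)
  if (is.null(src_ids) || is.null(tgt_ids)) {
    stop("both matrices need gene rownames")
  }
  if (source == "auto") {
    hits_a <- sum(map$gene_a %in% src_ids)
    hits_b <- sum(map$gene_b %in% src_ids)
    if (hits_a > 0 && hits_b > 0) {
      stop("ambiguous map orientation: source genes match both species; ",
           "state source = 'species_a' or 'species_b'")
    }
    if (hits_a == 0 && hits_b == 0) stop("no ortholog pair overlaps the source genes")
    source <- if (hits_a > 0) "species_a" else "species_b"
  }
  src_col <- if (source == "species_a") map$gene_a else map$gene_b
  tgt_col <- if (source == "species_a") map$gene_b else map$gene_a
  keep <- src_col %in% src_ids & tgt_col %in% tgt_ids
  if (!any(keep)) stop("no ortholog pair present in both datasets")
  n_dropped <- sum(!keep)
  list(A = A_source[src_col[keep], , drop = FALSE],
       Y = Y_target[tgt_col[keep], , drop = FALSE],
       pairs = data.frame(source_gene = src_col[keep],
                          target_gene = tgt_col[keep],
                          stringsAsFactors = FALSE),
       n_dropped = n_dropped)
}

#' Project learned gene weights into a target dataset
#'
#' Scores every target sample for every source pattern by unconstrained
#' per-sample ordinary least squares of expression on the gene-weight
#' matrix (no intercept, no non-negativity constraint): a high score means
#' the sample's expression profile resembles the pattern, and scores may be
#' negative. With `center = TRUE` (default) each gene's mean across target
#' samples is removed from `Y` first; `A` is never altered.
#'
#' @param A_aligned gene-weight matrix, rows aligned with `Y_aligned`.
#' @param Y_aligned target expression, same row count and order.
#' @param center subtract gene means across target samples from `Y`.
#' @return a `pattern_projection`: list with `scores` (patterns x samples),
#'   `source_pattern_ids`, `target_sample_ids`, `n_genes_used`, `center`,
#'   and an initially empty `group_tests` data.frame.
#' @export
project_patterns <- function(A_aligned, Y_aligned, center = TRUE) {
  A <- as.matrix(A_aligned)
  Y <- as.matrix(Y_aligned)
  if (nrow(A) != nrow(Y)) stop("A and Y must have aligned rows")
  if (nrow(A) < 2) stop("projection needs at least 2 shared genes")
  if (nrow(A) < ncol(A)) {
    stop("fewer shared genes (", nrow(A), ") than patterns (", ncol(A), ")")
  }
  qa <- qr(A)
  if (qa$rank < ncol(A)) {
    bad <- colnames(A)[qa$pivot[-seq_len(qa$rank)]] %||%
      qa$pivot[-seq_len(qa$rank)]
    stop("gene-weight matrix is rank deficient on the shared genes; ",
         "collinear pattern(s): ", paste(bad, collapse = ", "))
  }
  if (center) Y <- Y - rowMeans(Y)
  scores <- qr.coef(qa, Y)
  rownames(scores) <- colnames(A)
  colnames(scores) <- colnames(Y)
  structure(list(scores = scores,
                 source_pattern_ids = colnames(A),
                 target_sample_ids = colnames(Y),
                 n_genes_used = nrow(A),
                 center = center,
                 group_tests = empty_group_tests()),
            class = "pattern_projection")
}

empty_group_tests <- function() {
  data.frame(pattern = character(), state_a = character(),
             state_b = character(), tissue = character(),
             n_a = integer(), n_b = integer(), t_statistic = numeric(),
             df = numeric(), p_value = numeric(), stringsAsFactors = FALSE)
}

#' @export
print.pattern_projection <- function(x, ...) {
  cat(sprintf("Pattern projection: %d patterns x %d target samples (%d genes used%s)\n",
              nrow(x$scores), ncol(x$scores), x$n_genes_used,
              if (isTRUE(x$center)) ", gene-centered" else ""))
  if (nrow(x$group_tests)) {
    cat("Group tests:\n")
    print(x$group_tests, row.names = FALSE)
  }
  invisible(x)
}

#' Compare projected scores between two sample groups
#'
#' Two-sided two-sample Student's t-test with the pooled equal-variance
#' estimate on one pattern's projected scores (Welch's form behind
#' `var_equal = FALSE`). Degenerate input with zero pooled variance and
#' equal means yields `t = 0, p = 1`.
#'
#' @param result a `pattern_projection`.
#' @param annotations annotations of the target samples.
#' @param pattern pattern id (or index) to test.
#' @param state_a,state_b state labels of the two groups.
#' @param tissue optional tissue label restricting the comparison.
#' @param var_equal pooled-variance Student's t (default) or Welch.
#' @return the `pattern_projection` with one row appended to
#'   `group_tests`; the row itself is in attribute `"last_test"`.
#' @export
compare_groups <- function(result, annotations, pattern, state_a, state_b,
                           tissue = NULL, var_equal = TRUE) {
  stopifnot(inherits(result, "pattern_projection"))
  annotations <- validate_sample_annotations(annotations)
  idx <- match(result$target_sample_ids, annotations$sample_id)
  if (anyNA(idx)) {
    stop("missing annotation for target sample '",
         result$target_sample_ids[which(is.na(idx))[1]], "'")
  }
  ann <- annotations[idx, , drop = FALSE]
  keep <- if (is.null(tissue)) rep(TRUE, nrow(ann)) else ann$tissue == tissue
  pat <- if (is.numeric(pattern)) result$source_pattern_ids[pattern] else pattern
  if (!pat %in% result$source_pattern_ids) stop("unknown pattern '", pat, "'")
  w <- result$scores[pat, ]
  xa <- w[keep & ann$state == state_a]
  xb <- w[keep & ann$state == state_b]
  if (length(xa) < 2 || length(xb) < 2) {
    stop("both groups need >= 2 samples (got ", length(xa), " and ",
         length(xb), ")")
  }
  if (var_equal) {
    na <- length(xa); nb <- length(xb)
    df <- na + nb - 2
    sp2 <- ((na - 1) * stats::var(xa) + (nb - 1) * stats::var(xb)) / df
    delta <- mean(xa) - mean(xb)
    if (sp2 == 0) {
      tt <- if (delta == 0) 0 else sign(delta) * Inf
    } else {
      tt <- delta / sqrt(sp2 * (1 / na + 1 / nb))
    }
    p <- max(2 * pt(-abs(tt), df), .Machine$double.xmin)
  } else {
    ht <- t.test(xa, xb, var.equal = FALSE)
    tt <- unname(ht$statistic); df <- unname(ht$parameter)
    p <- max(ht$p.value, .Machine$double.xmin)
  }
  row <- data.frame(pattern = pat, state_a = state_a, state_b = state_b,
                    tissue = tissue %||% NA_character_,
                    n_a = length(xa), n_b = length(xb),
                    t_statistic = tt, df = df, p_value = p,
                    stringsAsFactors = FALSE)
  result$group_tests <- rbind(result$group_tests, row)
  attr(result, "last_test") <- row
  result
}
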