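#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("Non-negative matrix factorization (%s)\n",
              if (x$method == "consensus") "split-gene consensus" else
                "multiplicative updates"))
  cat(sprintf("  %d genes x %d samples, k = %d patterns\n",
              length(x$gene_ids), length(x$sample_ids), x$k))
  cat(sprintf("  Frobenius error: %.6g  (seed %d, %d iterations, %s)\n",
              x$frobenius_error, x$seed, x$iterations,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' @export
summary.nmf_fit <- function(object, ...) {
  rel <- if (!is.null(object$X)) {
    object$frobenius_error / max(norm(object$X, "F"), .Machine$double.eps)
  } else NA_real_
  top <- apply(object$P, 1, function(w) object$sample_ids[which.max(w)])
  out <- list(fit = object, relative_error = rel,
              pattern_summary = data.frame(
                pattern = object$pattern_ids,
                max_sample = top,
                weight_sum = rowSums(object$P),
                row.names = NULL))
  class(out) <- "summary.nmf_fit"
  out
}

#' @export
print.summary.nmf_fit <- function(x, ...) {
  print(x$fit)
  if (is.finite(x$relative_error)) {
    cat(sprintf("  Relative error: %.4f\n", x$relative_error))
  }
  cat("\nPattern sample weights:\n")
  print(x$pattern_summary, row.names = FALSE)
  invisible(x)
}

#' Extract the amplitude (gene-weight) matrix
#' @param object an `nmf_fit`.
#' @param ... unused.
#' @return numeric matrix, genes x patterns.
#' @export
coef.nmf_fit <- function(object, ...) object$A

#' @export
fitted.nmf_fit <- function(object, ...) object$A %*% object$P

#' @export
residuals.nmf_fit <- function(object, ...) {
  if (is.null(object$X)) {
    stop("fit was built with keep_x = FALSE; residuals need the training matrix")
  }
  object$X - fitted(object)
}

#' Project a fitted factorization into new expression data
#'
#' Transfer learning: keeps the fitted gene weights fixed and solves for the
#' pattern scores of each new sample by least squares. When `map` is given,
#' rows are first restricted to one-to-one orthologs shared by the fit and
#' the new data (see [restrict_to_orthologs()]).
#'
#' @param object an `nmf_fit`.
#' @param newdata expression matrix of the target dataset.
#' @param map optional [ortholog_map()] for cross-species projection.
#' @param source which side of `map` carries the fit's gene ids
#'   (`"auto"`, `"species_a"` or `"species_b"`).
#' @param center gene-wise centering of the target (see
#'   [project_patterns()]).
#' @param ... unused.
#' @return a `pattern_projection` (see [project_patterns()]).
#' @export
predict.nmf_fit <- function(object, newdata, map = NULL, source = "auto",
                            center = TRUE, ...) {
  A <- object$A
  if (!is.null(map)) {
    al <- restrict_to_orthologs(A, newdata, map, source = source)
    project_patterns(al$A, al$Y, center = center)
  } else {
    shared <- intersect(rownames(A), rownames(newdata))
    if (length(shared) < 2) stop("no shared gene identifiers with newdata")
    project_patterns(A[shared, , drop = FALSE],
                     newdata[shared, , drop = FALSE], center = center)
  }
}

#' Heatmap of sample pattern weights
#'
#' Draws samples x patterns weights on a blue-to-red scale, the layout used
#' to judge tissue / state / sample specificity by eye.
#'
#' @param x an `nmf_fit`.
#' @param ... passed to [graphics::image()].
#' @export
plot.nmf_fit <- function(x, ...) {
  m <- t(x$P)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(64)
  op <- graphics::par(mar = c(6, 6, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m), col = pal,
                  xlab = "", ylab = "", axes = FALSE, ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 2,
                 cex.axis = 0.7)
  invisible(x)
}

#' @export
print.nmf_scan <- function(x, ...) {
  cat("Pattern-count scan:\n")
  for (fit in x) {
    cat(sprintf("  k = %2d  Frobenius error %.6g\n", fit$k,
                fit$frobenius_error))
  }
  invisible(x)
}
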