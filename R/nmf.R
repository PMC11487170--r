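#' TPM-normalize a count matrix
#'
#' Per sample, each gene's count is divided by its length to a rate, and
#' rates are rescaled so every column sums to one million (transcripts per
#' million).
#'
#' @param counts non-negative numeric matrix, genes x samples.
#' @param lengths positive gene lengths, one per row of `counts`.
#' @param unit `"bp"` or `"kb"`; the result is identical either way (the
#'   scale cancels), the flag only documents the input.
#' @return matrix of the same shape whose columns each sum to 1e6.
#' @export
tpm_normalize <- function(counts, lengths, unit = c("bp", "kb")) {
  unit <- match.arg(unit)
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  if (length(lengths) != nrow(counts)) {
    stop("one length per gene required")
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("gene lengths must be positive")
  }
  len_kb <- if (unit == "bp") lengths / 1000 else lengths
  rate <- counts / len_kb
  cs <- colSums(rate)
  if (any(cs == 0)) {
    stop("column '", colnames(counts)[which(cs == 0)[1]] %||% which(cs == 0)[1],
         "' has zero total expression")
  }
  sweep(rate, 2, cs, "/") * 1e6
}

# Shared input checks for the factorization entry points.
check_nmf_input <- function(X, k) {
  validate_expression_matrix(X)
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (k > min(dim(X))) {
    stop("k = ", k, " exceeds min(genes, samples) = ", min(dim(X)))
  }
  k
}

#' Non-negative matrix factorization of an expression matrix
#'
#' Decomposes a non-negative genes x samples matrix `X` into a gene-weight
#' (amplitude) matrix `A` (genes x k) and a sample pattern-weight matrix `P`
#' (k x samples) minimizing the Frobenius loss by multiplicative updates,
#' with multiple seeded restarts. The restart with the lowest reconstruction
#' error wins (ties broken by lowest restart index). Rows of `P` are rescaled
#' to unit maximum with the inverse scale absorbed into `A`, so `A %*% P` is
#' unchanged. Results are fully determined by `(X, k, seed, max_iter, tol,
#' n_restarts)`.
#'
#' @param X validated expression matrix (see [validate_expression_matrix()]).
#' @param k number of patterns, `1 <= k <= min(dim(X))`.
#' @param seed integer seed; every restart derives its own stream from it.
#' @param max_iter maximum multiplicative-update iterations per restart.
#' @param tol convergence threshold on the relative decrease of the
#'   Frobenius error between successive iterations.
#' @param n_restarts number of random restarts.
#' @param log1p factor `log1p(X)` instead of `X`; off by default because the
#'   pipeline feeds TPM directly to the factorizer.
#' @param keep_x keep the training matrix in the fit (needed by
#'   [residuals.nmf_fit()] and [drop_technical_patterns()]).
#' @return an object of class `nmf_fit`: list with `A`, `P`, `k`,
#'   `gene_ids`, `sample_ids`, `frobenius_error`, `seed`, `iterations`,
#'   `converged`, `error_trace`, `restart_errors`.
#' @seealso [nmf_consensus()] for the split-gene consensus mode, [scan_k()]
#'   for a pattern-count scan, [pattern_markers()], [classify_patterns()].
#' @examples
#' X <- outer(c(1, 2, 0), c(3, 1))
#' dimnames(X) <- list(paste0("g", 1:3), paste0("s", 1:2))
#' fit <- nmf(X, k = 1, seed = 1)
#' fit$frobenius_error
#' @export
nmf <- function(X, k, seed = 1L, max_iter = 2000L, tol = 1e-6,
                n_restarts = 3L, log1p = FALSE, keep_x = TRUE) {
  k <- check_nmf_input(X, k)
  Xw <- if (log1p) log1p(X) else X
  scale0 <- sqrt(max(mean(Xw), .Machine$double.eps) / k)
  best <- NULL
  restart_errors <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    init <- with_seed(derive_seed(seed, 1L, r), {
      list(A = matrix(runif(nrow(Xw) * k, 0.1, 1) * scale0, nrow(Xw), k),
           P = matrix(runif(k * ncol(Xw), 0.1, 1) * scale0, k, ncol(Xw)))
    })
    res <- .nmf_mu(Xw, init$A, init$P, as.integer(max_iter), tol)
    restart_errors[r] <- res$frobenius_error
    if (is.null(best) || res$frobenius_error < best$frobenius_error) {
      best <- res
    }
  }
  new_nmf_fit(A = best$A, P = best$P, k = k, X = if (keep_x) Xw else NULL,
              gene_ids = rownames(X), sample_ids = colnames(X),
              frobenius_error = best$frobenius_error, seed = as.integer(seed),
              iterations = best$iterations, converged = best$converged,
              error_trace = best$error_trace, restart_errors = restart_errors,
              method = "mu")
}

# Assemble and normalize a fit: P rows to unit maximum, inverse scale into A.
new_nmf_fit <- function(A, P, k, X, gene_ids, sample_ids, frobenius_error,
                        seed, iterations, converged, error_trace = numeric(),
                        restart_errors = numeric(), method = "mu") {
  s <- apply(P, 1, max)
  pos <- s > 0
  if (any(pos)) {
    P[pos, ] <- P[pos, , drop = FALSE] / s[pos]
    A[, pos] <- sweep(A[, pos, drop = FALSE], 2, s[pos], "*")
  }
  pattern_ids <- paste0("pattern_", seq_len(k))
  dimnames(A) <- list(gene_ids, pattern_ids)
  dimnames(P) <- list(pattern_ids, sample_ids)
  structure(list(A = A, P = P, k = k, gene_ids = gene_ids,
                 sample_ids = sample_ids, pattern_ids = pattern_ids,
                 frobenius_error = frobenius_error, seed = seed,
                 iterations = iterations, converged = converged,
                 error_trace = error_trace, restart_errors = restart_errors,
                 method = method, X = X),
            class = "nmf_fit")
}

#' Split-gene consensus factorization
#'
#' Speeds up and stabilizes factorization of large gene sets by randomly
#' partitioning genes into `n_sets` groups, factorizing each group
#' independently at the same `k`, clustering the `n_sets * k` sample-weight
#' vectors into `k` consensus patterns (average-linkage agglomerative
#' clustering with correlation distance, cut at exactly `k`), averaging each
#' cluster into a consensus `P` (rows rescaled to unit maximum), and solving
#' the final amplitude of every gene by non-negative least squares against
#' the consensus `P`. With `n_sets = 1` this reduces exactly to [nmf()] with
#' the same seed.
#'
#' @inheritParams nmf
#' @param n_sets number of random gene groups.
#' @return an `nmf_fit` (see [nmf()]); `method` is `"consensus"`.
#' @export
nmf_consensus <- function(X, k, n_sets = 24L, seed = 1L, max_iter = 2000L,
                          tol = 1e-6, n_restarts = 3L, log1p = FALSE,
                          keep_x = TRUE) {
  k <- check_nmf_input(X, k)
  n_sets <- as.integer(n_sets)
  if (n_sets < 1) stop("n_sets must be >= 1")
  if (n_sets == 1L) {
    return(nmf(X, k, seed = seed, max_iter = max_iter, tol = tol,
               n_restarts = n_restarts, log1p = log1p, keep_x = keep_x))
  }
  n_genes <- nrow(X)
  if (floor(n_genes / n_sets) < k) {
    stop("gene subsets would have fewer than k genes; use fewer sets")
  }
  groups <- with_seed(derive_seed(seed, 2L),
                      sample(rep_len(seq_len(n_sets), n_genes)))
  Xw <- if (log1p) log1p(X) else X
  P_all <- vector("list", n_sets)
  iters <- 0L
  conv <- TRUE
  for (s in seq_len(n_sets)) {
    sub <- nmf(Xw[groups == s, , drop = FALSE], k,
               seed = derive_seed(seed, 3L, s), max_iter = max_iter,
               tol = tol, n_restarts = n_restarts, keep_x = FALSE)
    P_all[[s]] <- sub$P
    iters <- iters + sub$iterations
    conv <- conv && sub$converged
  }
  P_stack <- do.call(rbind, P_all)
  # correlation distance; constant rows get correlation 0 (maximal distance 1)
  cors <- suppressWarnings(cor(t(P_stack)))
  cors[!is.finite(cors)] <- 0
  d <- as.dist(1 - cors)
  cl <- cutree(hclust(d, method = "average"), k = k)
  P_cons <- t(vapply(seq_len(k), function(j) {
    colMeans(P_stack[cl == j, , drop = FALSE])
  }, numeric(ncol(Xw))))
  smax <- apply(P_cons, 1, max)
  smax[smax == 0] <- 1
  P_cons <- P_cons / smax
  A <- t(apply(Xw, 1, function(y) pracma::lsqnonneg(t(P_cons), y)$x))
  if (k == 1L) A <- matrix(A, ncol = 1L)
  err <- norm(Xw - A %*% P_cons, "F")
  new_nmf_fit(A = A, P = P_cons, k = k, X = if (keep_x) Xw else NULL,
              gene_ids = rownames(X), sample_ids = colnames(X),
              frobenius_error = err, seed = as.integer(seed),
              iterations = iters, converged = conv, method = "consensus")
}

#' Factorize over a range of pattern counts
#'
#' Runs one factorization per `k` in `[k_min, k_max]`, each with its own seed
#' derived from `(seed, k)`, and returns them in order of `k`. Pattern-count
#' selection from the scan is done by [classify_patterns()] plus
#' [select_pattern_count()].
#'
#' @inheritParams nmf
#' @param k_min,k_max inclusive bounds of the scan.
#' @param n_sets passed to [nmf_consensus()]; 1 (default) factorizes all
#'   genes jointly.
#' @param ... further arguments to [nmf()] / [nmf_consensus()].
#' @return an `nmf_scan`: list of `nmf_fit` objects named by `k`.
#' @export
scan_k <- function(X, k_min = 2L, k_max = 10L, seed = 1L, n_sets = 1L, ...) {
  k_min <- as.integer(k_min)
  k_max <- as.integer(k_max)
  if (k_min < 1 || k_min > k_max) stop("need 1 <= k_min <= k_max")
  if (k_max > min(dim(X))) stop("k_max exceeds min(genes, samples)")
  fits <- lapply(k_min:k_max, function(k) {
    nmf_consensus(X, k, n_sets = n_sets, seed = derive_seed(seed, 4L, k), ...)
  })
  names(fits) <- as.character(k_min:k_max)
  structure(fits, class = "nmf_scan")
}

#' Serialize / deserialize a factorization
#'
#' `A` is written with gene rows, `P` with sample columns, plus a JSON
#' sidecar with `k`, `seed`, `frobenius_error`, `iterations`, `converged`
#' and `method`.
#'
#' @param fit an `nmf_fit`.
#' @param prefix path prefix; files `<prefix>_A.tsv`, `<prefix>_P.tsv`,
#'   `<prefix>_meta.json` are produced.
#' @return invisibly, the three paths.
#' @export
write_nmf_fit <- function(fit, prefix) {
  stopifnot(inherits(fit, "nmf_fit"))
  paths <- paste0(prefix, c("_A.tsv", "_P.tsv", "_meta.json"))
  write_weight_tsv(fit$A, "gene_id", paths[1])
  write_weight_tsv(fit$P, "pattern_id", paths[2])
  meta <- list(k = fit$k, seed = fit$seed,
               frobenius_error = fit$frobenius_error,
               iterations = fit$iterations, converged = fit$converged,
               method = fit$method)
  jsonlite::write_json(meta, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_nmf_fit
#' @export
read_nmf_fit <- function(prefix) {
  A <- read_weight_tsv(paste0(prefix, "_A.tsv"))
  P <- read_weight_tsv(paste0(prefix, "_P.tsv"))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  structure(list(A = A, P = P, k = meta$k, gene_ids = rownames(A),
                 sample_ids = colnames(P), pattern_ids = colnames(A),
                 frobenius_error = meta$frobenius_error, seed = meta$seed,
                 iterations = meta$iterations, converged = meta$converged,
                 error_trace = numeric(), restart_errors = numeric(),
                 method = meta$method, X = NULL),
            class = "nmf_fit")
}

write_weight_tsv <- function(m, id_col, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(m)), collapse = "\t"), con, sep = "\n")
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 15,
                                               scientific = FALSE),
                                        collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con, sep = "\n")
  invisible(path)
}

read_weight_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}
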