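test_that("TPM normalization rescales rates to one million per sample", {
  one <- matrix(7, 1, 1, dimnames = list("g", "s"))
  expect_equal(unname(tpm_normalize(one, 500)), matrix(1e6, 1, 1))

  counts <- matrix(c(10, 90), 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_equal(unname(tpm_normalize(counts, c(1000, 1000))[, 1]),
               c(1e5, 9e5))

  counts2 <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_equal(unname(tpm_normalize(counts2, c(1, 2), unit = "kb")[, 1]),
               c(2 / 3, 1 / 3) * 1e6)

  multi <- matrix(runif(30, 1, 100), 10, 3,
                  dimnames = list(paste0("g", 1:10), paste0("s", 1:3)))
  tpm <- tpm_normalize(multi, rep(2, 10))
  expect_equal(colSums(tpm), rep(1e6, 3), ignore_attr = TRUE,
               tolerance = 1e-6)

  expect_error(tpm_normalize(matrix(0, 2, 1), c(1, 1)), "zero total")
  expect_error(tpm_normalize(matrix(1, 2, 1), c(1, -1)), "positive")
})

test_that("rank-1 and zero matrices are factorized exactly", {
  X <- outer(c(1, 2, 0), c(3, 1))
  dimnames(X) <- list(paste0("g", 1:3), paste0("s", 1:2))
  fit <- nmf(X, 1, seed = 1)
  expect_lt(fit$frobenius_error, 1e-6)
  # sample weights proportional to (3, 1)
  expect_equal(fit$P[1, 1] / fit$P[1, 2], 3, tolerance = 1e-6)

  Z <- matrix(0, 4, 3, dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  expect_equal(nmf(Z, 2, seed = 1)$frobenius_error, 0)
})

test_that("multiplicative updates reach the ANLS oracle on rank-3 products", {
  set.seed(7)
  X <- matrix(runif(20 * 3, 0, 2), 20, 3) %*% matrix(runif(3 * 8, 0, 2), 3, 8)
  dimnames(X) <- list(sprintf("g%02d", 1:20), sprintf("s%d", 1:8))
  fit <- nmf(X, 3, seed = 3, n_restarts = 10, max_iter = 5000, tol = 1e-10)
  oracle_err <- anls_oracle(unname(X), 3, n_restarts = 10, seed = 5)
  nx <- norm(X, "F")
  expect_lt(abs(fit$frobenius_error - oracle_err) / nx, 1e-3)
})

test_that("the error trace is monotone non-increasing and A, P non-negative", {
  sim <- simulate_torpor(tiny_scenario(seed = 3))
  X <- sim$expression$species1
  fit <- nmf(X, 4, seed = 2)
  expect_true(all(diff(fit$error_trace) <= 1e-8 * fit$error_trace[-length(fit$error_trace)]))
  expect_true(all(fit$A >= 0))
  expect_true(all(fit$P >= 0))
  expect_true(all(is.finite(fit$A)) && all(is.finite(fit$P)))
})

test_that("the reported error is recomputable and P rows have unit maximum", {
  pl <- planted_two_pattern()
  fit <- nmf(pl$X, 2, seed = 9)
  expect_equal(fit$frobenius_error, norm(pl$X - fit$A %*% fit$P, "F"),
               tolerance = 1e-10)
  expect_equal(unname(apply(fit$P, 1, max)), c(1, 1), tolerance = 1e-12)
})

test_that("factorization is deterministic in (X, k, seed) and picks the best restart", {
  pl <- planted_two_pattern()
  f1 <- nmf(pl$X, 2, seed = 4, n_restarts = 3)
  f2 <- nmf(pl$X, 2, seed = 4, n_restarts = 3)
  expect_identical(f1$A, f2$A)
  expect_identical(f1$P, f2$P)
  expect_equal(f1$frobenius_error, min(f1$restart_errors))
})

test_that("k bounds are enforced", {
  x <- tiny_expression()
  expect_error(nmf(x, 3, seed = 1), "exceeds")
  expect_error(nmf(x, 0, seed = 1), ">= 1")
})

test_that("consensus with one gene set bit-matches the plain factorization", {
  pl <- planted_two_pattern()
  expect_identical(nmf_consensus(pl$X, 2, n_sets = 1, seed = 5),
                   nmf(pl$X, 2, seed = 5))
})

test_that("consensus recovers planted noise-free patterns across gene splits", {
  pl <- planted_two_pattern()
  fit <- nmf_consensus(pl$X, 2, n_sets = 4, seed = 6)
  expect_gte(best_match_correlation(fit$P, pl$P), 0.999)
  # all per-set patterns agree, so exactly k consensus clusters emerge
  expect_equal(fit$k, 2L)
  expect_true(all(fit$A >= 0))
})

test_that("consensus refuses subsets smaller than k", {
  pl <- planted_two_pattern(n_genes = 6)
  expect_error(nmf_consensus(pl$X, 2, n_sets = 5, seed = 1), "fewer sets")
})

test_that("scan_k covers the requested range deterministically", {
  pl <- planted_two_pattern()
  scan <- scan_k(pl$X, 2, 4, seed = 8)
  expect_equal(vapply(scan, `[[`, integer(1), "k"), c(`2` = 2L, `3` = 3L, `4` = 4L))
  single <- scan_k(pl$X, 3, 3, seed = 8)
  expect_length(single, 1L)
  expect_identical(single[["3"]]$A, scan[["3"]]$A)
  scan2 <- scan_k(pl$X, 2, 4, seed = 8)
  expect_equal(vapply(scan, `[[`, numeric(1), "frobenius_error"),
               vapply(scan2, `[[`, numeric(1), "frobenius_error"))
})

test_that("fit serialization round trips", {
  pl <- planted_two_pattern()
  fit <- nmf(pl$X, 2, seed = 5)
  prefix <- file.path(withr::local_tempdir(), "fit")
  write_nmf_fit(fit, prefix)
  back <- read_nmf_fit(prefix)
  expect_equal(back$A, fit$A, tolerance = 1e-12)
  expect_equal(back$P, fit$P, tolerance = 1e-12)
  expect_equal(back$k, fit$k)
  expect_equal(back$frobenius_error, fit$frobenius_error)
})

test_that("fit methods expose coefficients, fitted values and residuals", {
  pl <- planted_two_pattern()
  fit <- nmf(pl$X, 2, seed = 5)
  expect_identical(coef(fit), fit$A)
  expect_equal(fitted(fit), fit$A %*% fit$P, ignore_attr = TRUE)
  expect_equal(residuals(fit), pl$X - fitted(fit), ignore_attr = TRUE)
  expect_output(print(fit), "k = 2 patterns")
  expect_output(print(summary(fit)), "Relative error")
})
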