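test_that("ortholog restriction aligns rows in map order and counts drops", {
  A <- matrix(1:10, 5, 2,
              dimnames = list(paste0("a", 1:5), c("p1", "p2")))
  Y <- matrix(1:15, 5, 3,
              dimnames = list(paste0("b", c(1, 2, 3, 6, 7)), paste0("s", 1:3)))
  map <- ortholog_map("spA", "spB",
                      c("a1", "a2", "a3", "a9"), c("b3", "b1", "b6", "b9"))
  al <- restrict_to_orthologs(A, Y, map, source = "species_a")
  expect_equal(rownames(al$A), c("a1", "a2", "a3"))
  expect_equal(rownames(al$Y), c("b3", "b1", "b6"))
  expect_equal(al$n_dropped, 1L)

  # identity map leaves values untouched up to row order
  idm <- ortholog_map("x", "x2", paste0("a", 1:5), paste0("a", 1:5))
  Y2 <- matrix(runif(10), 5, 2, dimnames = list(paste0("a", 1:5), c("t1", "t2")))
  al2 <- restrict_to_orthologs(A, Y2, idm, source = "species_a")
  expect_equal(al2$A, A[rownames(al2$A), ])
  expect_equal(al2$Y, Y2[rownames(al2$A), ])

  empty <- ortholog_map("spA", "spB", "a9", "b9")
  expect_error(restrict_to_orthologs(A, Y, empty, source = "species_a"),
               "no ortholog pair")
})

test_that("ambiguous map orientation is rejected, explicit orientation accepted", {
  A <- matrix(1, 2, 1, dimnames = list(c("g1", "g2"), "p1"))
  Y <- matrix(1, 2, 2, dimnames = list(c("g2", "g3"), c("s1", "s2")))
  map <- ortholog_map("spA", "spB", c("g1", "g3"), c("g2", "g4"))
  expect_error(restrict_to_orthologs(A, Y, map), "ambiguous")
  al <- restrict_to_orthologs(A, Y, map, source = "species_a")
  expect_equal(al$pairs$source_gene, "g1")
})

test_that("projection scores solve the normal equations", {
  A <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2,
              dimnames = list(paste0("g", 1:3), c("p1", "p2")))
  y <- matrix(c(2, 3, 5), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  pr <- project_patterns(A, y, center = FALSE)
  expect_equal(unname(pr$scores[, 1]), c(2, 3), tolerance = 1e-10)
  # oracle: (A'A)^-1 A'y
  expect_equal(unname(pr$scores[, 1]),
               unname(drop(solve(t(A) %*% A, t(A) %*% y))), tolerance = 1e-10)

  y_orth <- matrix(c(1, 1, -1), 3, 1,
                   dimnames = list(paste0("g", 1:3), "s1"))
  # y orthogonal to both columns
  expect_equal(unname(crossprod(A, y_orth))[, 1], c(0, 0))
  pr0 <- project_patterns(A, y_orth, center = FALSE)
  expect_equal(max(abs(pr0$scores)), 0, tolerance = 1e-10)
})

test_that("projecting Y = A P without centering recovers P exactly", {
  pl <- planted_two_pattern()
  Y <- pl$A %*% pl$P
  dimnames(Y) <- dimnames(pl$X)
  rownames(pl$A) <- rownames(Y)
  colnames(pl$A) <- c("p1", "p2")
  pr <- project_patterns(pl$A, Y, center = FALSE)
  expect_equal(unname(pr$scores), unname(pl$P), tolerance = 1e-8)
})

test_that("projection is linear in the target and matches normal equations broadly", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(6:15, 1); k <- sample(2:4, 1); m <- sample(2:5, 1)
    A <- matrix(runif(n * k, 0, 3), n, k,
                dimnames = list(paste0("g", 1:n), paste0("p", 1:k)))
    Y <- matrix(rnorm(n * m), n, m,
                dimnames = list(paste0("g", 1:n), paste0("s", 1:m)))
    pr <- project_patterns(A, Y, center = FALSE)
    oracle <- solve(t(A) %*% A, t(A) %*% Y)
    expect_equal(unname(pr$scores), unname(oracle), tolerance = 1e-8)
    pr3 <- project_patterns(A, 3 * Y, center = FALSE)
    expect_equal(pr3$scores, 3 * pr$scores, tolerance = 1e-8)
  }
})

test_that("centering removes gene means from the target only", {
  set.seed(3)
  A <- matrix(runif(12), 6, 2,
              dimnames = list(paste0("g", 1:6), c("p1", "p2")))
  Y <- matrix(rnorm(18, mean = 5), 6, 3,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:3)))
  pr <- project_patterns(A, Y, center = TRUE)
  oracle <- solve(t(A) %*% A, t(A) %*% (Y - rowMeans(Y)))
  expect_equal(unname(pr$scores), unname(oracle), tolerance = 1e-10)
})

test_that("rank-deficient or under-determined projections error", {
  A <- matrix(c(1, 2, 3, 2, 4, 6), 3, 2,
              dimnames = list(paste0("g", 1:3), c("p1", "p2")))
  Y <- matrix(1, 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  expect_error(project_patterns(A, Y), "rank deficient")
  A2 <- matrix(1:2, 1, 2, dimnames = list("g1", c("p1", "p2")))
  expect_error(project_patterns(A2, Y[1, , drop = FALSE]), "at least 2|fewer")
})

test_that("group comparison reproduces the pooled t-test closed form", {
  scores <- matrix(c(1, 2, 3, 2, 3, 4), 1, 6,
                   dimnames = list("p1", paste0("s", 1:6)))
  pr <- structure(list(scores = scores, source_pattern_ids = "p1",
                       target_sample_ids = colnames(scores),
                       n_genes_used = 10L, center = TRUE,
                       group_tests = patternTransfer:::empty_group_tests()),
                  class = "pattern_projection")
  ann <- annotations_for(colnames(scores), tissue = "retina",
                         state = rep(c("torpor", "euthermia"), each = 3))
  out <- compare_groups(pr, ann, "p1", "torpor", "euthermia")
  row <- attr(out, "last_test")
  expect_equal(row$t_statistic, -1.224745, tolerance = 1e-6)
  expect_equal(row$df, 4)
  expect_equal(row$p_value, 0.2878641, tolerance = 1e-6)
  oracle <- pooled_t_oracle(c(1, 2, 3), c(2, 3, 4))
  expect_equal(row$t_statistic, oracle$t, tolerance = 1e-12)
  expect_equal(row$p_value, oracle$p, tolerance = 1e-12)
})

test_that("degenerate group comparisons behave as defined", {
  scores <- matrix(c(2, 2, 2, 2), 1, 4,
                   dimnames = list("p1", paste0("s", 1:4)))
  pr <- structure(list(scores = scores, source_pattern_ids = "p1",
                       target_sample_ids = colnames(scores),
                       n_genes_used = 5L, center = TRUE,
                       group_tests = patternTransfer:::empty_group_tests()),
                  class = "pattern_projection")
  ann <- annotations_for(colnames(scores), tissue = "t",
                         state = rep(c("a", "b"), each = 2))
  row <- attr(compare_groups(pr, ann, "p1", "a", "b"), "last_test")
  expect_equal(row$t_statistic, 0)
  expect_equal(row$p_value, 1)

  ann1 <- annotations_for(colnames(scores), tissue = "t",
                          state = c("a", "b", "b", "b"))
  expect_error(compare_groups(pr, ann1, "p1", "a", "b"), ">= 2 samples")
})

test_that("predict on an nmf fit projects through shared genes or a map", {
  pl <- planted_two_pattern()
  fit <- nmf(pl$X, 2, seed = 11)
  Y <- fitted(fit)  # exactly A %*% P, so projection must return P
  pr <- predict(fit, Y, center = FALSE)
  expect_equal(unname(pr$scores), unname(fit$P), tolerance = 1e-8)

  # cross-namespace projection through an ortholog map
  Y2 <- Y
  rownames(Y2) <- paste0("other_", rownames(Y))
  map <- ortholog_map("spA", "spB", rownames(Y), rownames(Y2))
  pr2 <- predict(fit, Y2, map = map, source = "species_a", center = FALSE)
  expect_equal(unname(pr2$scores), unname(fit$P), tolerance = 1e-8)
  expect_equal(pr2$n_genes_used, nrow(Y))
})
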