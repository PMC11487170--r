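make_class_fixture <- function() {
  samples <- paste0("s", 1:4)
  ann <- annotations_for(samples,
                         tissue = c("brain", "brain", "liver", "liver"),
                         state = c("torpor", "torpor", "torpor", "torpor"))
  list(samples = samples, ann = ann)
}

test_that("a one-sample pattern with replicated groups is sample specific", {
  fx <- make_class_fixture()
  P <- rbind(c(1, 0, 0, 0))
  rownames(P) <- "p1"; colnames(P) <- fx$samples
  cl <- classify_patterns(list(P = P, sample_ids = fx$samples), fx$ann)
  expect_equal(cl$category, "sample_specific")
  expect_equal(cl$dominance, 1)
})

test_that("state- and tissue-driven patterns are classified by eta squared", {
  samples <- paste0("s", 1:8)
  ann <- annotations_for(samples,
                         tissue = rep(c("brain", "liver"), each = 4),
                         state = rep(c("euthermia", "torpor"), 4))
  P <- rbind(state = as.numeric(ann$state == "torpor"),
             tissue = as.numeric(ann$tissue == "liver"))
  colnames(P) <- samples
  cl <- classify_patterns(list(P = P, sample_ids = samples), ann)
  expect_equal(cl$category, c("state", "tissue"))
  expect_equal(cl$eta2_state[1], 1)
  expect_equal(cl$eta2_tissue[2], 1)
})

test_that("a single-cell pattern with agreeing replicates is tissue_state", {
  samples <- paste0("s", 1:12)
  ann <- annotations_for(samples,
                         tissue = rep(c("brain", "liver"), each = 6),
                         state = rep(rep(c("euthermia", "torpor"), each = 3), 2))
  cell <- as.numeric(ann$tissue == "brain" & ann$state == "torpor")
  P <- rbind(cellpat = cell)
  colnames(P) <- samples
  cl <- classify_patterns(list(P = P, sample_ids = samples), ann)
  expect_equal(cl$category, "tissue_state")

  # one aberrant sample inflating a cell is not an interaction program
  outlier <- c(0, 0, 0, 1, 0.1, 0.05, rep(0, 6))
  P2 <- rbind(outlier = outlier)
  colnames(P2) <- samples
  cl2 <- classify_patterns(list(P = P2, sample_ids = samples), ann)
  expect_false(cl2$category == "tissue_state")
})

test_that("weights proportional to library size are flagged technical", {
  samples <- paste0("s", 1:6)
  libs <- c(30, 10, 25, 40, 15, 22) * 1e5
  ann <- annotations_for(samples, tissue = rep(c("a", "b"), 3),
                         state = rep(c("x", "y"), each = 3),
                         library_size = libs)
  P <- rbind(tech = libs / max(libs))
  colnames(P) <- samples
  cl <- classify_patterns(list(P = P, sample_ids = samples), ann)
  expect_equal(cl$category, "technical")
  expect_equal(cl$depth_correlation, cor(P[1, ], libs))
  expect_equal(cl$depth_correlation, 1, tolerance = 1e-12)
})

test_that("classification is invariant to sample order and positive rescaling", {
  sim <- simulate_torpor(tiny_scenario(seed = 5))
  fit <- nmf(sim$expression$species1, 4, seed = 2)
  ann <- sim$annotations$species1
  base <- classify_patterns(fit, ann)

  shuffled <- ann[sample(nrow(ann)), ]
  expect_equal(classify_patterns(fit, shuffled), base)

  scaled <- fit
  scaled$P <- fit$P * 37.5
  rescaled <- classify_patterns(scaled, ann)
  expect_equal(rescaled$category, base$category)
  expect_equal(rescaled$dominance, base$dominance, tolerance = 1e-12)
  expect_equal(rescaled$eta2_state, base$eta2_state, tolerance = 1e-12)
})

test_that("classification demands complete annotations", {
  fx <- make_class_fixture()
  P <- rbind(c(1, 0, 0, 0)); colnames(P) <- fx$samples
  expect_error(classify_patterns(list(P = P, sample_ids = fx$samples),
                                 fx$ann[-2, ]), "missing annotation")
})

test_that("pattern-count selection takes the largest clean k", {
  cl <- function(cats, k) {
    df <- data.frame(pattern = paste0("p", seq_along(cats)), category = cats)
    attr(df, "k") <- k
    df
  }
  expect_equal(select_pattern_count(list(
    cl(c("tissue", "state"), 2), cl(c("tissue", "state", "tissue"), 3),
    cl(c("tissue", "state", "tissue", "sample_specific"), 4))), 3L)
  expect_equal(select_pattern_count(lapply(2:10, function(k)
    cl(rep("state", k), k))), 10L)
  # technical patterns do not disqualify a k
  expect_equal(select_pattern_count(list(
    cl(c("tissue", "technical", "state"), 3))), 3L)
  # diffuse unclassified patterns do disqualify a k
  expect_equal(select_pattern_count(list(
    cl(c("tissue", "state"), 2),
    cl(c("tissue", "state", "unclassified"), 3))), 2L)
  expect_error(select_pattern_count(list(
    cl(c("sample_specific", "tissue"), 2))), "replicates")
})

test_that("technical patterns are dropped without touching the rest", {
  pl <- planted_two_pattern()
  A <- cbind(pl$A, tech = runif(nrow(pl$A)))
  P <- rbind(pl$P, runif(ncol(pl$P)))
  rownames(P) <- paste0("p", 1:3); colnames(A) <- paste0("p", 1:3)
  colnames(P) <- sprintf("s%d", seq_len(ncol(P)))
  rownames(A) <- sprintf("g%02d", seq_len(nrow(A)))
  fit <- manual_fit(A, P, X = A %*% P)
  cls <- data.frame(pattern = paste0("p", 1:3),
                    category = c("tissue", "technical", "state"))
  out <- drop_technical_patterns(fit, cls)
  expect_equal(out$k, 2L)
  expect_identical(out$A, A[, c(1, 3)])
  expect_identical(out$P, P[c(1, 3), ])

  none <- data.frame(pattern = paste0("p", 1:3),
                     category = rep("state", 3))
  expect_identical(drop_technical_patterns(fit, none), fit)

  all_tech <- data.frame(pattern = paste0("p", 1:3),
                         category = rep("technical", 3))
  expect_error(drop_technical_patterns(fit, all_tech), "all patterns")
})

test_that("marker distances, assignment and tie-breaks follow the statistic", {
  A <- rbind(exact2 = c(0, 5), uniform = c(3, 5), only1 = c(2, 0),
             mixed = c(1, 4), weak1 = c(0.4, 0.1))
  colnames(A) <- c("p1", "p2")
  mk <- pattern_markers(A)

  # brute-force oracle over the scaled matrix
  S <- sweep(A, 2, apply(A, 2, max), "/")
  D <- sapply(1:2, function(j) {
    e <- rep(0, 2); e[j] <- 1
    apply(S, 1, function(r) sqrt(sum((r - e)^2)))
  })
  oracle_assign <- apply(D, 1, which.min)
  oracle_score <- D[cbind(1:5, oracle_assign)]
  got <- mk[match(rownames(A), mk$gene_id), ]
  expect_equal(got$pattern, colnames(A)[oracle_assign])
  expect_equal(got$marker_score, unname(oracle_score), tolerance = 1e-12)

  # the exact indicator row has distance 0 and rank 1
  expect_equal(mk$marker_score[mk$gene_id == "exact2"], 0)
  expect_equal(mk$rank[mk$gene_id == "exact2"], 1L)
  # within-pattern ranks are ascending in distance
  for (p in unique(mk$pattern)) {
    sub <- mk[mk$pattern == p, ]
    expect_equal(sub$rank, order(sub$marker_score))
    expect_false(is.unsorted(sub$marker_score[order(sub$rank)]))
  }
})

test_that("a uniform scaled row ties to the lowest pattern index", {
  A <- rbind(tie = c(1, 1, 1), top = c(2, 0, 0), other = c(0, 2, 0),
             third = c(0, 0, 2))
  colnames(A) <- paste0("p", 1:3)
  mk <- pattern_markers(A)
  expect_equal(mk$pattern[mk$gene_id == "tie"], "p1")
})

test_that("exclusively loaded genes always sit closest to their own pattern", {
  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    A <- matrix(runif(12 * k, 0.1, 3), 12, k,
                dimnames = list(sprintf("g%02d", 1:12), paste0("p", 1:k)))
    g <- sample(12, 1); j <- sample(k, 1)
    A[g, ] <- 0; A[g, j] <- runif(1, 0.1, 3)
    mk <- pattern_markers(A)
    expect_equal(mk$pattern[mk$gene_id == rownames(A)[g]], paste0("p", j))
  }
})

test_that("marker edge cases error or report unassigned genes", {
  expect_error(pattern_markers(matrix(1, 3, 1)), "k >= 2")
  expect_error(pattern_markers(matrix(0, 3, 2)), "all zero")
  A <- rbind(a = c(1, 0), b = c(0, 0), c = c(0, 1))
  colnames(A) <- paste0("p", 1:2)
  mk <- pattern_markers(A)
  expect_identical(attr(mk, "unassigned"), "b")
  expect_equal(nrow(mk), 2L)
})
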