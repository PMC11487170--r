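# In-code fixtures shared across test files.

tiny_expression <- function(values = matrix(c(1, 3, 2, 4), 2, 2),
                            genes = c("G1", "G2"), samples = c("S1", "S2")) {
  dimnames(values) <- list(genes, samples)
  values
}

# A deterministic low-noise two-pattern dataset with known factors.
planted_two_pattern <- function(n_genes = 40, seed = 42) {
  set.seed(seed)
  P <- rbind(c(1, 0.9, 1, 0.05, 0, 0.1),
             c(0.05, 0, 0.1, 1, 0.95, 1))
  A <- matrix(runif(n_genes * 2, 0, 5), n_genes, 2)
  # make half the genes pattern-exclusive so the factors are identifiable
  A[1:(n_genes / 2), 2] <- 0
  A[(n_genes / 2 + 1):n_genes, 1] <- 0
  X <- A %*% P
  dimnames(X) <- list(sprintf("g%02d", seq_len(n_genes)),
                      sprintf("s%d", seq_len(ncol(P))))
  list(X = X, A = A, P = P)
}

# Minimal annotation table for a fit's samples.
annotations_for <- function(sample_ids, tissue, state,
                            dataset = "d1", library_size = NULL) {
  df <- data.frame(sample_id = sample_ids, dataset = dataset,
                   tissue = tissue, state = state,
                   stringsAsFactors = FALSE)
  if (!is.null(library_size)) df$library_size <- library_size
  df
}

# strip generator bookkeeping attributes before matrix comparisons
unname_attrs <- function(m) {
  attr(m, "baseline") <- NULL
  m
}

# A bare-bones nmf_fit wrapper around explicit A / P matrices.
manual_fit <- function(A, P, X = NULL) {
  structure(list(A = A, P = P, k = ncol(A),
                 gene_ids = rownames(A), sample_ids = colnames(P),
                 pattern_ids = colnames(A),
                 frobenius_error = if (is.null(X)) NA_real_ else
                   norm(X - A %*% P, "F"),
                 seed = 0L, iterations = 0L, converged = TRUE,
                 error_trace = numeric(), restart_errors = numeric(),
                 method = "manual", X = X),
            class = "nmf_fit")
}

# Small fast scenario for pipeline-level tests.
tiny_scenario <- function(seed = 1, ...) {
  torpor_scenario(genes_per_species = 200L, tissues = c("brain", "liver"),
                  states = c("euthermia", "torpor"), replicates = 3L,
                  marker_genes_per_pattern = 8L, seed = seed, ...)
}
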