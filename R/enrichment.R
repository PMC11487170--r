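#' Rank genes by their weight in one pattern
#'
#' Orders genes by descending amplitude in the chosen pattern (pattern
#' weights are non-negative, so the top of the list carries the pattern's
#' program). An optional ortholog map converts identifiers to a reference
#' namespace (e.g. human symbols) first; unmapped genes are dropped and
#' counted. Ties are broken lexicographically by symbol.
#'
#' @param A amplitude matrix (genes x patterns) or an `nmf_fit`.
#' @param pattern pattern id or column index.
#' @param symbol_map optional [ortholog_map()]; identity when absent.
#' @param source which side of `symbol_map` holds the matrix's gene ids
#'   (`"auto"`, `"species_a"`, `"species_b"`).
#' @return data.frame `(symbol, weight)` in ranking order, attribute
#'   `n_dropped`.
#' @export
rank_genes_by_pattern <- function(A, pattern, symbol_map = NULL,
                                  source = "auto") {
  if (inherits(A, "nmf_fit")) A <- A$A
  A <- as.matrix(A)
  pat <- if (is.numeric(pattern)) pattern else match(pattern, colnames(A))
  if (is.na(pat) || pat < 1 || pat > ncol(A)) {
    stop("unknown pattern '", pattern, "'")
  }
  w <- A[, pat]
  if (any(w < 0)) stop("pattern weights must be non-negative")
  symbols <- rownames(A)
  n_dropped <- 0L
  if (!is.null(symbol_map)) {
    stopifnot(inherits(symbol_map, "ortholog_map"))
    if (identical(source, "auto")) {
      hits_a <- sum(symbol_map$gene_a %in% symbols)
      hits_b <- sum(symbol_map$gene_b %in% symbols)
      if (hits_a > 0 && hits_b > 0) {
        stop("ambiguous symbol_map orientation; state source explicitly")
      }
      source <- if (hits_a >= hits_b) "species_a" else "species_b"
    }
    from <- if (source == "species_a") symbol_map$gene_a else symbol_map$gene_b
    to <- if (source == "species_a") symbol_map$gene_b else symbol_map$gene_a
    idx <- match(symbols, from)
    n_dropped <- sum(is.na(idx))
    keep <- !is.na(idx)
    symbols <- to[idx[keep]]
    w <- w[keep]
  }
  if (!length(w)) stop("no genes left after symbol mapping")
  ord <- order(-w, symbols)
  out <- data.frame(symbol = symbols[ord], weight = unname(w[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  out
}

# Enrichment score from hit positions in a ranking of N genes with weights w
# (already exponentiated). The running sum gains w_i / sum(w_hits) at each
# hit and loses 1/(N - N_hits) per miss; its maximum is attained at a hit,
# so only hit positions need evaluating. Positive-score regime: the score is
# the maximal positive deviation, floored at 0.
es_from_positions <- function(positions, w_exp, N) {
  pos <- sort(positions)
  nh <- length(pos)
  tot <- sum(w_exp[pos])
  hit_cum <- if (tot > 0) cumsum(w_exp[pos]) / tot else seq_len(nh) / nh
  miss <- (pos - seq_len(nh)) / (N - nh)
  max(0, max(hit_cum - miss))
}

#' Weighted enrichment score of a gene set in a ranked list
#'
#' The classic weighted running-sum statistic under a positive-only score
#' regime: walking down the ranking, set members ("hits") add their weight
#' (raised to `exponent`) normalized by the total hit weight, non-members
#' subtract `1/(N - N_hits)`; the enrichment score is the maximum of the
#' running sum, floored at zero, so it lies in `[0, 1]`. A set whose hits
#' all carry zero weight falls back to equal hit increments.
#'
#' @param ranked data.frame `(symbol, weight)` from
#'   [rank_genes_by_pattern()], or a named non-negative numeric vector in
#'   ranking order.
#' @param set character vector of member symbols.
#' @param exponent weight exponent (1 = classic weighted scheme).
#' @return the enrichment score.
#' @export
enrichment_score <- function(ranked, set, exponent = 1) {
  rk <- as_ranking(ranked)
  N <- length(rk$weight)
  positions <- which(rk$symbol %in% set)
  if (!length(positions)) stop("gene set has no member in the ranking")
  if (length(positions) == N) {
    stop("gene set covers the whole ranking; the miss decrement is undefined")
  }
  es_from_positions(positions, rk$weight^exponent, N)
}

as_ranking <- function(ranked) {
  if (is.data.frame(ranked)) {
    list(symbol = as.character(ranked$symbol), weight = as.numeric(ranked$weight))
  } else {
    if (is.null(names(ranked))) stop("ranked vector must be named by symbol")
    list(symbol = names(ranked), weight = as.numeric(ranked))
  }
}

#' Positive-score preranked gene-set enrichment test
#'
#' Tests every gene set for concentration near the top of a weight ranking.
#' The null distribution for a set of size m is the enrichment score of
#' `n_perm` random m-gene subsets of the ranking (gene-label permutation,
#' sampled without replacement, seeded); the p-value uses the add-one
#' permutation estimator `p = (1 + #{null >= observed}) / (1 + n_perm)`, so
#' `1/(n_perm + 1) <= p <= 1`. NES is the observed score over the null mean.
#' Benjamini-Hochberg adjustment is applied across the surviving sets of the
#' ranking (i.e. within one pattern).
#'
#' @param ranked ranking as in [enrichment_score()].
#' @param sets named list of gene sets (see [read_gmt()]).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation null.
#' @param min_size,max_size bounds on `|set `\eqn{\cap}` ranking|`; sets
#'   outside are skipped.
#' @param exponent weight exponent.
#' @return data.frame `(set_name, es, nes, p_value, p_adjusted,
#'   set_size_used)`, attributes `n_perm` and `seed`; zero rows (with a
#'   warning) when no set survives the size filter.
#' @export
gsea_pos <- function(ranked, sets, n_perm = 1000L, seed = 1L, min_size = 5L,
                     max_size = 500L, exponent = 1) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) stop("n_perm must be >= 100")
  rk <- as_ranking(ranked)
  N <- length(rk$weight)
  sizes <- vapply(sets, function(s) sum(rk$symbol %in% s), integer(1))
  keep <- sizes >= min_size & sizes <= max_size & sizes < N
  if (!any(keep)) {
    warning("no gene set within the size bounds; empty result")
    out <- data.frame(set_name = character(), es = numeric(), nes = numeric(),
                      p_value = numeric(), p_adjusted = numeric(),
                      set_size_used = integer(), stringsAsFactors = FALSE)
    attr(out, "n_perm") <- n_perm
    attr(out, "seed") <- as.integer(seed)
    return(out)
  }
  sets <- sets[keep]
  sizes <- sizes[keep]
  w_exp <- rk$weight^exponent

  es_obs <- vapply(sets, function(s) {
    es_from_positions(which(rk$symbol %in% s), w_exp, N)
  }, numeric(1))
  # independent permutation null per set (same-size random gene subsets)
  p <- numeric(length(sets))
  nes <- numeric(length(sets))
  for (i in seq_along(sets)) {
    null_es <- with_seed(derive_seed(seed, 5L, i), {
      vapply(seq_len(n_perm), function(j) {
        es_from_positions(sample.int(N, sizes[i]), w_exp, N)
      }, numeric(1))
    })
    p[i] <- (1 + sum(null_es >= es_obs[i])) / (1 + n_perm)
    mu <- mean(null_es)
    nes[i] <- if (mu > 0) es_obs[i] / mu else NA_real_
  }
  out <- data.frame(set_name = names(sets), es = unname(es_obs),
                    nes = unname(nes), p_value = unname(p),
                    p_adjusted = unname(p.adjust(p, method = "BH")),
                    set_size_used = unname(sizes), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- as.integer(seed)
  out
}
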