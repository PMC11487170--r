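#' Classify patterns by what drives their sample weights
#'
#' Operationalizes the visual rule used to screen factorization heatmaps:
#' each pattern is assigned exactly one category by a decision cascade.
#'
#' 1. `technical` if the pattern's sample weights correlate with library
#'    size at `|r| >= tau_depth` (requires `library_size` in the
#'    annotations) — the broad depth-driven patterns seen in real data;
#' 2. `sample_specific` if one sample holds at least `tau_dom` of the total
#'    weight while its tissue-by-state group has replicates (splitting
#'    replicates is over-factorization, not biology);
#' 3. `tissue_state`, `tissue` or `state` by which variance fraction
#'    (eta-squared: between-group over total sum of squares) of the weights
#'    under the metadata grouping reaches `tau_eta`. Interaction is checked
#'    first: a pattern is `tissue_state` when the tissue-by-state cell
#'    grouping explains the weights while neither main effect alone does;
#'    otherwise the larger qualifying main effect decides;
#' 4. `unclassified` otherwise.
#'
#' Eta-squared is the between-group sum of squares over the total sum of
#' squares of the pattern's sample weights; the interaction term is the
#' tissue-by-state cell effect net of both main effects (clamped at 0). The
#' classification is invariant to sample order and to rescaling a pattern's
#' weights by a positive constant.
#'
#' @param fit an `nmf_fit` (or any list with `P` and `sample_ids`).
#' @param annotations sample annotations covering every sample of the fit
#'   (see [read_sample_annotations()]).
#' @param tau_dom dominance threshold for `sample_specific` (default 0.5).
#' @param tau_eta eta-squared threshold for metadata-driven categories
#'   (default 0.5).
#' @param tau_depth absolute library-size correlation threshold for
#'   `technical` (default 0.8).
#' @return a `pattern_classification`: data.frame with one row per pattern
#'   (`pattern`, `category`, `dominance`, `eta2_tissue`, `eta2_state`,
#'   `eta2_interaction`, `depth_correlation`), attribute `k`.
#' @export
classify_patterns <- function(fit, annotations, tau_dom = 0.5, tau_eta = 0.5,
                              tau_depth = 0.8) {
  P <- fit$P
  sample_ids <- fit$sample_ids %||% colnames(P)
  if (ncol(P) < 2) stop("classification needs at least 2 samples")
  annotations <- validate_sample_annotations(annotations)
  idx <- match(sample_ids, annotations$sample_id)
  if (anyNA(idx)) {
    stop("missing annotation for sample '", sample_ids[which(is.na(idx))[1]], "'")
  }
  ann <- annotations[idx, , drop = FALSE]
  tissue <- factor(ann$tissue)
  state <- factor(ann$state)
  cell <- interaction(tissue, state, drop = TRUE)
  libsize <- if ("library_size" %in% names(ann)) ann$library_size else NULL
  group_n <- table(cell)

  ss_between <- function(w, g) {
    mu <- mean(w)
    sum(tapply(w, g, function(v) length(v) * (mean(v) - mu)^2))
  }

  # one tissue-by-state group carries the pattern (its mean weight stands
  # well above every other group's, floor-relative) and its replicates agree
  # (a single aberrant sample inflating the cell does not qualify)
  single_cell_dominant <- function(w, g) {
    m <- sort(tapply(w, g, mean), decreasing = TRUE)
    floor_ <- min(m)
    if ((m[1] - floor_) < 1.5 * (m[2] - floor_)) return(FALSE)
    top <- w[g == names(m)[1]]
    min(top) >= max(top) / 3
  }

  rows <- lapply(seq_len(nrow(P)), function(j) {
    w <- P[j, ]
    tot <- sum(w)
    dominance <- if (tot > 0) max(w) / tot else 0
    sst <- sum((w - mean(w))^2)
    if (sst > 0) {
      eta_t <- ss_between(w, tissue) / sst
      eta_s <- ss_between(w, state) / sst
      eta_cell <- ss_between(w, cell) / sst
      eta_i <- max(0, eta_cell - eta_t - eta_s)
    } else {
      eta_t <- eta_s <- eta_i <- eta_cell <- 0
    }
    depth_r <- if (!is.null(libsize) && sd(w) > 0 && sd(libsize) > 0) {
      cor(w, libsize)
    } else NA_real_
    dom_sample_cell <- cell[which.max(w)]
    category <- if (!is.na(depth_r) && abs(depth_r) >= tau_depth) {
      "technical"
    } else if (dominance >= tau_dom && group_n[[as.character(dom_sample_cell)]] >= 2) {
      "sample_specific"
    } else if (eta_cell >= tau_eta && max(eta_t, eta_s) < tau_eta &&
                 single_cell_dominant(w, cell)) {
      # the tissue-by-state cells explain the weights, neither main effect
      # alone does, and one cell clearly dominates: an interaction-driven
      # pattern rather than a multi-group mixture
      "tissue_state"
    } else if (max(eta_t, eta_s) >= tau_eta) {
      if (eta_t >= eta_s) "tissue" else "state"
    } else {
      "unclassified"
    }
    data.frame(pattern = rownames(P)[j] %||% paste0("pattern_", j),
               category = category, dominance = dominance,
               eta2_tissue = eta_t, eta2_state = eta_s,
               eta2_interaction = eta_i, depth_correlation = depth_r,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "k") <- nrow(P)
  attr(out, "thresholds") <- c(tau_dom = tau_dom, tau_eta = tau_eta,
                               tau_depth = tau_depth)
  class(out) <- c("pattern_classification", "data.frame")
  out
}

#' Select the pattern count from a classified scan
#'
#' The rule of "as many patterns as each remain tissue and/or state
#' specific, but not sample specific": a pattern count qualifies when every
#' one of its patterns is driven by the metadata — category `tissue`,
#' `state` or `tissue_state` — and the largest qualifying `k` wins.
#' Sample-specific patterns (replicate splitting) and diffuse unclassified
#' patterns both disqualify a `k`; `technical` patterns do not — they are
#' removed afterwards by [drop_technical_patterns()], not counted against
#' the model.
#'
#' @param classifications list of [classify_patterns()] results over a scan;
#'   `k` is read from each element's `k` attribute (or the list names).
#' @return the selected integer `k`.
#' @export
select_pattern_count <- function(classifications) {
  ks <- vapply(seq_along(classifications), function(i) {
    as.integer(attr(classifications[[i]], "k") %||%
                 names(classifications)[i])
  }, integer(1))
  if (anyNA(ks)) stop("cannot determine k for every classification")
  ok <- c("tissue", "state", "tissue_state", "technical")
  clean <- vapply(classifications, function(cl) {
    all(cl$category %in% ok)
  }, logical(1))
  if (!any(clean)) {
    stop("no pattern count where every pattern is tissue- and/or ",
         "state-specific; more replicates per tissue/state group are needed")
  }
  max(ks[clean])
}

#' Remove technical patterns from a fit
#'
#' Drops the amplitude columns and weight rows of patterns classified as
#' `technical`, leaving all remaining values untouched (no refit). The
#' reconstruction error is recomputed when the training matrix is stored.
#'
#' @param fit an `nmf_fit`.
#' @param classification the [classify_patterns()] result for `fit`.
#' @return an `nmf_fit` with reduced `k`.
#' @export
drop_technical_patterns <- function(fit, classification) {
  stopifnot(inherits(fit, "nmf_fit"))
  if (nrow(classification) != fit$k) {
    stop("classification does not match the fit (k differs)")
  }
  keep <- classification$category != "technical"
  if (!any(keep)) stop("all patterns are technical; nothing would remain")
  if (all(keep)) return(fit)
  fit$A <- fit$A[, keep, drop = FALSE]
  fit$P <- fit$P[keep, , drop = FALSE]
  fit$k <- sum(keep)
  fit$pattern_ids <- rownames(fit$P)
  if (!is.null(fit$X)) {
    fit$frobenius_error <- norm(fit$X - fit$A %*% fit$P, "F")
  }
  fit
}

#' Pattern-marker genes
#'
#' Ranks genes by how exclusively they load a single pattern: each amplitude
#' column is scaled to unit maximum, and each gene's scaled weight row is
#' compared with every pattern's unit indicator vector by Euclidean
#' distance. A gene is assigned to the pattern whose indicator it is closest
#' to (ties go to the lowest pattern index) and ranked within the pattern by
#' ascending distance, so rank 1 is the most pattern-specific gene.
#'
#' @param fit an `nmf_fit` with `k >= 2`, or an amplitude matrix.
#' @return a `pattern_marker_table`: data.frame `(gene_id, pattern,
#'   marker_score, rank)` with one row per gene carrying any amplitude;
#'   all-zero genes are reported in attribute `unassigned`.
#' @export
pattern_markers <- function(fit) {
  A <- if (inherits(fit, "nmf_fit")) fit$A else as.matrix(fit)
  if (ncol(A) < 2) stop("pattern markers need k >= 2")
  if (all(A == 0)) stop("amplitude matrix is all zero")
  zero_rows <- rowSums(A) == 0
  unassigned <- rownames(A)[zero_rows]
  A <- A[!zero_rows, , drop = FALSE]
  cmax <- apply(A, 2, max)
  cmax[cmax == 0] <- 1
  S <- sweep(A, 2, cmax, "/")
  rs <- rowSums(S^2)
  # squared distance of gene g to indicator e_j: ||s_g||^2 - 2 s_gj + 1
  D2 <- rs - 2 * S + 1
  assigned <- apply(D2, 1, which.min)
  score <- sqrt(pmax(D2[cbind(seq_len(nrow(S)), assigned)], 0))
  out <- data.frame(gene_id = rownames(S),
                    pattern = colnames(S)[assigned],
                    marker_score = score, stringsAsFactors = FALSE)
  out <- out[order(match(out$pattern, colnames(S)), out$marker_score,
                   out$gene_id), , drop = FALSE]
  out$rank <- unlist(lapply(split(seq_len(nrow(out)), out$pattern)[unique(out$pattern)],
                            seq_along), use.names = FALSE)
  rownames(out) <- NULL
  attr(out, "unassigned") <- unassigned
  class(out) <- c("pattern_marker_table", "data.frame")
  out
}
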