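#' Define a synthetic multi-species torpor study
#'
#' Describes the structure the generator emulates: two (or more) species,
#' several tissues, physiological states (euthermia / torpor / interbout
#' arousal), a few replicates per tissue-state group, latent expression
#' programs partially shared across species through one-to-one orthologs,
#' and per-sample sequencing-depth artifacts.
#'
#' `patterns` declares the planted programs, one row per pattern with
#' columns `type` (`"tissue"`, `"state"`, `"tissue_state"` with level
#' `"tissue:state"`, or `"baseline"`), `level`, and `shared` (logical:
#' identical amplitudes on orthologous genes in every species). The default
#' is one pattern per tissue plus one per state, all shared.
#'
#' @param n_species number of species.
#' @param genes_per_species genes per species.
#' @param ortholog_fraction fraction of genes with a one-to-one ortholog in
#'   every other species, in (0, 1].
#' @param tissues,states label vectors.
#' @param replicates samples per tissue-state group.
#' @param patterns planted-pattern table (see Details); `NULL` for the
#'   default tissue + state set.
#' @param effect_size planted amplitude relative to a gene's baseline.
#' @param noise_sd log-scale sd of multiplicative lognormal noise; also
#'   scales the per-sample individual component (see `individual_effect`).
#' @param depth_factor_sd log-scale sd of per-sample depth factors.
#' @param individual_effect strength of each sample's coherent individual
#'   deviation (inter-animal variability), as a multiple of `noise_sd`
#'   relative to baseline; `individual_effect * noise_sd * baseline` is the
#'   typical planted deviation on the affected genes. Zero noise implies no
#'   individual component, so noiseless data equal `A_true %*% P_true`
#'   exactly.
#' @param individual_genes fraction of genes carrying each sample's
#'   individual deviation.
#' @param outlier_samples number of aberrant individuals per species whose
#'   individual deviation is amplified by `outlier_multiplier`; these are
#'   what over-factorization isolates into sample-specific patterns.
#' @param outlier_multiplier amplification of the outlier animals'
#'   deviations.
#' @param marker_genes_per_pattern planted pattern-exclusive genes per
#'   pattern.
#' @param responsive_fraction fraction of non-marker genes additionally
#'   loading one random state-like pattern (non-exclusively).
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of per-gene
#'   baseline expression (TPM-like scale).
#' @param seed integer seed; the simulation is fully determined by it.
#' @return a validated `torpor_scenario` list.
#' @export
torpor_scenario <- function(n_species = 2L, genes_per_species = 2000L,
                            ortholog_fraction = 0.8,
                            tissues = c("brain", "liver", "muscle"),
                            states = c("euthermia", "torpor", "IBA"),
                            replicates = 3L, patterns = NULL,
                            effect_size = 2, noise_sd = 0.1,
                            depth_factor_sd = 0.15,
                            individual_effect = 7, individual_genes = 0.05,
                            outlier_samples = 3L, outlier_multiplier = 3.3,
                            marker_genes_per_pattern = 40L,
                            responsive_fraction = 0.25,
                            baseline_meanlog = 3, baseline_sdlog = 0.7,
                            seed = 1L) {
  if (is.null(patterns)) {
    # the first state is the baseline physiological condition (euthermia) and
    # gets no pattern of its own: one pattern per tissue, one per non-baseline
    # state, plus one tissue-by-state program when the design allows it
    patterns <- data.frame(
      type = c(rep("tissue", length(tissues)),
               rep("state", length(states) - 1)),
      level = c(tissues, states[-1]),
      shared = TRUE, stringsAsFactors = FALSE)
    if (length(tissues) >= 2 && length(states) >= 2) {
      patterns <- rbind(patterns,
                        data.frame(type = "tissue_state",
                                   level = paste(tissues[1], states[2],
                                                 sep = ":"),
                                   shared = TRUE, stringsAsFactors = FALSE))
    }
  }
  sc <- list(n_species = as.integer(n_species),
             genes_per_species = as.integer(genes_per_species),
             ortholog_fraction = ortholog_fraction,
             tissues = tissues, states = states,
             replicates = as.integer(replicates), patterns = patterns,
             effect_size = effect_size, noise_sd = noise_sd,
             depth_factor_sd = depth_factor_sd,
             individual_effect = individual_effect,
             individual_genes = individual_genes,
             outlier_samples = as.integer(outlier_samples),
             outlier_multiplier = outlier_multiplier,
             marker_genes_per_pattern = as.integer(marker_genes_per_pattern),
             responsive_fraction = responsive_fraction,
             baseline_meanlog = baseline_meanlog,
             baseline_sdlog = baseline_sdlog,
             seed = as.integer(seed))
  validate_scenario(sc)
  class(sc) <- "torpor_scenario"
  sc
}

validate_scenario <- function(sc) {
  stopifnot(sc$n_species >= 1, sc$genes_per_species >= 1, sc$replicates >= 1,
            sc$marker_genes_per_pattern >= 0)
  if (!(sc$ortholog_fraction > 0 && sc$ortholog_fraction <= 1)) {
    stop("ortholog_fraction must be in (0, 1]")
  }
  if (anyDuplicated(sc$tissues) || anyDuplicated(sc$states)) {
    stop("tissue and state labels must be unique")
  }
  if (any(!nzchar(sc$tissues)) || any(!nzchar(sc$states))) {
    stop("tissue and state labels must be non-empty")
  }
  p <- sc$patterns
  if (!all(c("type", "level", "shared") %in% names(p))) {
    stop("patterns needs columns type, level, shared")
  }
  if (!all(p$type %in% c("tissue", "state", "tissue_state", "baseline"))) {
    stop("pattern type must be tissue, state, tissue_state or baseline")
  }
  k_true <- nrow(p)
  n_samples <- length(sc$tissues) * length(sc$states) * sc$replicates
  if (k_true > min(sc$genes_per_species, n_samples)) {
    stop("k_true = ", k_true, " exceeds min(genes, samples)")
  }
  if (k_true * sc$marker_genes_per_pattern >
      round(sc$ortholog_fraction * sc$genes_per_species)) {
    stop("not enough ortholog genes for the requested marker count")
  }
  invisible(sc)
}

# planted sample-weight row for one pattern (before jitter)
pattern_base_weights <- function(type, level, modifiers, ann) {
  switch(type,
         baseline = rep(1, nrow(ann)),
         tissue = as.numeric(ann$tissue == level),
         state = modifiers[as.character(ann$tissue)] *
           as.numeric(ann$state == level),
         tissue_state = {
           parts <- strsplit(level, ":", fixed = TRUE)[[1]]
           as.numeric(ann$tissue == parts[1] & ann$state == parts[2])
         },
         stop("unknown pattern type '", type, "'"))
}

#' Generate a synthetic multi-species torpor dataset
#'
#' Builds, per species, expression as `(A_true %*% P_true) * noise * depth`:
#' planted sample weights are (near-)indicator rows over the declared
#' tissue / state / tissue-state groups with a small uniform jitter (state
#' patterns additionally carry a per-tissue response modifier so the planted
#' rows stay linearly independent); gene amplitudes put each gene's
#' lognormal baseline on the tissue (or baseline) patterns, plant
#' `marker_genes_per_pattern` pattern-exclusive marker genes per pattern at
#' `effect_size` times baseline, and let a `responsive_fraction` of the
#' remaining genes load one state-like pattern non-exclusively. Noise is
#' multiplicative lognormal, depth a per-sample lognormal factor. Shared
#' patterns copy their orthologous-gene amplitudes across species, so
#' restricting two species to the ortholog map leaves identical planted
#' amplitudes for shared patterns.
#'
#' @param scenario a [torpor_scenario()].
#' @return a `torpor_simulation`: list with `expression` (named list of
#'   matrices), `annotations` (named list of data.frames, `library_size` =
#'   column sums), `ortholog_maps` (one per species pair), and `truth`
#'   (per-species `A_true`, `P_true`, `markers`, `depth`; plus `patterns`
#'   table with `shared` flags and the `seed`).
#' @export
simulate_torpor <- function(scenario) {
  sc <- validate_scenario(scenario)
  with_seed(sc$seed, simulate_torpor_impl(sc))
}

simulate_torpor_impl <- function(sc) {
  pat <- sc$patterns
  k <- nrow(pat)
  species <- paste0("species", seq_len(sc$n_species))
  n_orth <- round(sc$ortholog_fraction * sc$genes_per_species)
  pattern_ids <- paste0("true_", seq_len(k), "_", pat$type, "_",
                        gsub("[^A-Za-z0-9]", "", pat$level %||% ""))

  ann0 <- expand.grid(replicate = paste0("r", seq_len(sc$replicates)),
                      state = sc$states, tissue = sc$tissues,
                      stringsAsFactors = FALSE)
  ann0 <- ann0[, c("tissue", "state", "replicate")]
  n_samples <- nrow(ann0)

  # per-tissue response modifiers, drawn once per pattern (shared logic)
  modifiers <- lapply(seq_len(k), function(i) {
    setNames(runif(length(sc$tissues), 0.8, 1.2), sc$tissues)
  })

  # marker gene indices (into the ortholog block for shared patterns, the
  # species-private block otherwise) — same indices reused across species so
  # shared markers are orthologous by construction
  n_priv <- sc$genes_per_species - n_orth
  marker_idx <- list()
  orth_pool <- seq_len(n_orth)
  priv_pool <- if (n_priv > 0) n_orth + seq_len(n_priv) else integer()
  for (i in seq_len(k)) {
    m <- sc$marker_genes_per_pattern
    # tissue-by-state programs span few samples; give them a double share of
    # genes so every planted program carries comparable signal
    if (pat$type[i] == "tissue_state") m <- 2L * m
    if (m == 0) { marker_idx[[i]] <- integer(); next }
    pool <- if (!pat$shared[i] && length(priv_pool) >= m) priv_pool else orth_pool
    pick <- sort(sample(pool, m))
    marker_idx[[i]] <- pick
    orth_pool <- setdiff(orth_pool, pick)
    priv_pool <- setdiff(priv_pool, pick)
  }
  all_markers <- unlist(marker_idx)

  baseline_like <- which(pat$type %in% c("tissue", "baseline"))
  state_like <- setdiff(seq_len(k), baseline_like)

  build_amplitudes <- function(gene_ids) {
    n <- length(gene_ids)
    b <- stats::rlnorm(n, sc$baseline_meanlog, sc$baseline_sdlog)
    A <- matrix(0, n, k, dimnames = list(gene_ids, pattern_ids))
    nonmark <- setdiff(seq_len(n), all_markers)
    for (j in baseline_like) {
      A[nonmark, j] <- b[nonmark] * stats::rlnorm(length(nonmark), 0, 0.3)
    }
    if (length(state_like) && sc$responsive_fraction > 0) {
      resp <- nonmark[runif(length(nonmark)) < sc$responsive_fraction]
      if (length(resp)) {
        # balanced allocation, with a double share for tissue-by-state
        # programs (few samples, so more genes for comparable signal)
        pool <- c(state_like,
                  state_like[pat$type[state_like] == "tissue_state"])
        tgt <- rep_len(pool, length(resp))
        A[cbind(resp, tgt)] <- sc$effect_size * b[resp] *
          runif(length(resp), 0.5, 1)
      }
    }
    for (i in seq_len(k)) {
      mk <- marker_idx[[i]]
      mk <- mk[mk <= n]
      if (length(mk)) {
        A[mk, ] <- 0
        # marker genes are the program's most strongly expressed responsive
        # genes (that is how pattern markers are found in real analyses):
        # their baselines sit in the upper tail of the baseline distribution
        b_mk <- exp(sc$baseline_meanlog +
                      (1.3 + abs(stats::rnorm(length(mk), 0, 0.5))) *
                        sc$baseline_sdlog)
        A[mk, i] <- sc$effect_size * b_mk
      }
    }
    attr(A, "baseline") <- b
    A
  }

  expression <- list(); annotations <- list(); truth_species <- list()
  A_first <- NULL
  for (s in seq_along(species)) {
    sp <- species[s]
    gene_ids <- sprintf("%s_g%05d", sp, seq_len(sc$genes_per_species))
    sample_ids <- sprintf("%s_%s_%s_%s", sp, ann0$tissue, ann0$state,
                          ann0$replicate)
    P <- t(vapply(seq_len(k), function(i) {
      pattern_base_weights(pat$type[i], pat$level[i], modifiers[[i]], ann0) +
        runif(n_samples, 0, 0.1)
    }, numeric(n_samples)))
    dimnames(P) <- list(pattern_ids, sample_ids)
    A <- build_amplitudes(gene_ids)
    if (s == 1L) {
      A_first <- A
    } else {
      shared <- which(pat$shared)
      if (length(shared) && n_orth > 0) {
        A[seq_len(n_orth), shared] <- A_first[seq_len(n_orth), shared]
      }
    }
    X <- A %*% P
    # coherent per-sample individuality: each replicate animal deviates on a
    # random gene subset, scaled by noise_sd so noiseless data stay exact
    indiv_amp <- sc$individual_effect * sc$noise_sd
    if (indiv_amp > 0 && sc$individual_genes > 0) {
      b <- attr(A, "baseline")
      n_aff <- max(1L, round(sc$individual_genes * nrow(X)))
      # every animal deviates mildly; a few aberrant individuals per cohort
      # deviate several-fold more strongly (stress, health status), which is
      # what splits replicates into sample-specific patterns when the
      # factorization rank exceeds the number of biological programs
      animal <- runif(n_samples, 0.5, 1.5)
      n_out <- min(sc$outlier_samples, n_samples)
      if (n_out > 0) {
        out_idx <- sample.int(n_samples, n_out)
        animal[out_idx] <- runif(n_out, 0.8, 1.2) * sc$outlier_multiplier
      }
      b_bar <- mean(b)
      for (j in seq_len(n_samples)) {
        aff <- sample.int(nrow(X), n_aff)
        X[aff, j] <- X[aff, j] +
          indiv_amp * animal[j] * b_bar * stats::rlnorm(n_aff, 0, 0.25)
      }
    }
    # TPM-like: equalize structural column totals before depth artifacts,
    # folding the per-column factor into the stored truth so that noiseless
    # data remain exactly A_true %*% P_true
    totals <- colSums(X)
    f <- mean(totals) / totals
    X <- sweep(X, 2, f, "*")
    P <- sweep(P, 2, f, "*")
    noise <- matrix(stats::rlnorm(length(X), 0, sc$noise_sd), nrow(X), ncol(X))
    depth <- stats::rlnorm(n_samples, 0, sc$depth_factor_sd)
    X <- sweep(X * noise, 2, depth, "*")
    ann <- data.frame(sample_id = sample_ids, dataset = sp,
                      tissue = ann0$tissue, state = ann0$state,
                      replicate = ann0$replicate,
                      library_size = colSums(X), stringsAsFactors = FALSE)
    expression[[sp]] <- X
    annotations[[sp]] <- ann
    truth_species[[sp]] <- list(
      A_true = A, P_true = P, depth = setNames(depth, sample_ids),
      markers = setNames(lapply(marker_idx, function(ix) gene_ids[ix]),
                         pattern_ids))
  }

  maps <- list()
  if (sc$n_species >= 2 && n_orth > 0) {
    combs <- utils::combn(seq_along(species), 2)
    for (c_i in seq_len(ncol(combs))) {
      a <- species[combs[1, c_i]]; b2 <- species[combs[2, c_i]]
      maps[[paste(a, b2, sep = ":")]] <- ortholog_map(
        a, b2,
        sprintf("%s_g%05d", a, seq_len(n_orth)),
        sprintf("%s_g%05d", b2, seq_len(n_orth)))
    }
  }

  structure(list(expression = expression, annotations = annotations,
                 ortholog_maps = maps,
                 truth = list(species = truth_species,
                              patterns = cbind(pat, pattern_id = pattern_ids,
                                               stringsAsFactors = FALSE),
                              k_true = k, seed = sc$seed),
                 scenario = sc),
            class = "torpor_simulation")
}

#' @export
print.torpor_simulation <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf("Synthetic torpor study: %d species, %d genes each, %s\n",
              sc$n_species, sc$genes_per_species,
              paste0(length(sc$tissues), " tissues x ", length(sc$states),
                     " states x ", sc$replicates, " replicates")))
  cat(sprintf("  %d planted patterns (%d shared), effect %.2g, noise sd %.2g, depth sd %.2g, seed %d\n",
              x$truth$k_true, sum(sc$patterns$shared), sc$effect_size,
              sc$noise_sd, sc$depth_factor_sd, sc$seed))
  invisible(x)
}

#' Write a simulation as a complete on-disk fixture bundle
#'
#' Emits every file dialect the readers understand: one expression TSV and
#' one annotation TSV per species, an OMA-dialect ortholog file pair per
#' species pair, a GMT of the planted marker sets (first species'
#' namespace), the planted `A_true` / `P_true` matrices as TSV, and a
#' `truth.json` sidecar (shared flags, depth factors, marker ids, seed).
#'
#' @param sim a [simulate_torpor()] result.
#' @param dir output directory.
#' @param overwrite allow writing into a non-empty directory.
#' @return invisibly, a named list of the paths written.
#' @export
write_fixture_bundle <- function(sim, dir, overwrite = FALSE) {
  stopifnot(inherits(sim, "torpor_simulation"))
  if (dir.exists(dir) && length(dir(dir)) > 0 && !overwrite) {
    stop("directory '", dir, "' is not empty; set overwrite = TRUE")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (sp in names(sim$expression)) {
    paths[[paste0(sp, "_expression")]] <-
      write_expression_tsv(sim$expression[[sp]],
                           file.path(dir, paste0(sp, "_expression.tsv")))
    paths[[paste0(sp, "_annotations")]] <-
      write_sample_annotations(sim$annotations[[sp]],
                               file.path(dir, paste0(sp, "_annotations.tsv")))
    tr <- sim$truth$species[[sp]]
    write_weight_tsv(tr$A_true, "gene_id",
                     file.path(dir, paste0(sp, "_A_true.tsv")))
    write_weight_tsv(tr$P_true, "pattern_id",
                     file.path(dir, paste0(sp, "_P_true.tsv")))
  }
  for (nm in names(sim$ortholog_maps)) {
    tag <- gsub(":", "_", nm, fixed = TRUE)
    mp <- file.path(dir, paste0("OrthologousMatrix_", tag, ".txt"))
    ip <- file.path(dir, paste0("Map-SeqNum-ID_", tag, ".txt"))
    write_oma_orthologs(sim$ortholog_maps[[nm]], mp, ip)
    paths[[paste0("oma_", tag)]] <- c(mp, ip)
  }
  sp1 <- names(sim$expression)[1]
  marker_sets <- sim$truth$species[[sp1]]$markers
  marker_sets <- marker_sets[lengths(marker_sets) > 0]
  if (length(marker_sets)) {
    paths$marker_gmt <- write_gmt(marker_sets,
                                  file.path(dir, "planted_marker_sets.gmt"))
  }
  truth_meta <- list(
    seed = sim$truth$seed,
    patterns = sim$truth$patterns,
    depth = lapply(sim$truth$species, `[[`, "depth"),
    markers = lapply(sim$truth$species, `[[`, "markers"))
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(truth_meta, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
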