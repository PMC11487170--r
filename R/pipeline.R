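#' Default pipeline configuration
#'
#' Fills every tunable of [run_pipeline()] with its default. Supply either
#' `scenario` (a [torpor_scenario()], simulated on the fly) or `datasets`
#' (named list of `list(expression =, annotations =)` file paths) plus
#' optional `ortholog_maps` (named `"a:b"`, each
#' `list(matrix =, map =, species_a =, species_b =)` file paths or an
#' [ortholog_map()]).
#'
#' @param ... overrides of the defaults.
#' @return a `run_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(scenario = NULL, datasets = NULL, ortholog_maps = NULL,
              k_min = 2L, k_max = 10L, n_sets = 1L, n_restarts = 3L,
              max_iter = 2000L, tol = 1e-6,
              tau_dom = 0.5, tau_eta = 0.5, tau_depth = 0.8,
              center = TRUE, var_equal = TRUE,
              gmt = NULL, n_perm = 1000L, min_size = 5L, max_size = 500L,
              exponent = 1,
              seed = 1L, out_dir = "pipeline_out", overwrite = FALSE)
  user <- list(...)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, user, keep.null = TRUE)
  if (cfg$k_min > cfg$k_max) stop("k_min must be <= k_max")
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline config from a YAML file
#'
#' @param path YAML file whose keys are [pipeline_config()] fields.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$scenario)) {
    vals$scenario <- do.call(torpor_scenario, vals$scenario)
  }
  do.call(pipeline_config, vals)
}

load_pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$scenario)) {
    sim <- simulate_torpor(cfg$scenario)
    list(expression = sim$expression, annotations = sim$annotations,
         maps = sim$ortholog_maps, sim = sim)
  } else if (!is.null(cfg$datasets)) {
    expr <- lapply(cfg$datasets, function(d) read_expression_tsv(d$expression))
    ann <- lapply(cfg$datasets, function(d) read_sample_annotations(d$annotations))
    maps <- lapply(cfg$ortholog_maps %||% list(), function(m) {
      if (inherits(m, "ortholog_map")) m else {
        read_oma_orthologs(m$matrix, m$map, m$species_a, m$species_b)
      }
    })
    list(expression = expr, annotations = ann, maps = maps, sim = NULL)
  } else {
    stop("config must provide either 'scenario' or 'datasets'")
  }
}

#' Run the full pattern-discovery and transfer pipeline
#'
#' For every dataset: scan pattern counts, classify every pattern at every
#' `k`, select the pattern count (largest `k` with no sample-specific
#' pattern), drop technical patterns, and compute pattern markers. For every
#' ordered dataset pair connected by an ortholog map (both orientations, as
#' in reciprocal cross-species comparisons): restrict to shared orthologs,
#' project the source amplitudes into the target, and t-test every pattern's
#' scores between every pair of target states. When a GMT is supplied, every
#' dataset's pattern weights are tested for gene-set enrichment. All
#' intermediate tables are written as TSV under `out_dir` together with a
#' `manifest.json` recording the seeds, thresholds and counts that fully
#' determine the run.
#'
#' @param config a [pipeline_config()] (or arguments to build one).
#' @param ... overrides when `config` is missing.
#' @return invisibly, a list with the fits, classifications, selected k,
#'   markers, projections, enrichment tables and the manifest; the output
#'   directory path is in `$out_dir`.
#' @export
run_pipeline <- function(config = NULL, ...) {
  cfg <- if (is.null(config)) pipeline_config(...) else config
  stopifnot(inherits(cfg, "run_config"))
  if (dir.exists(cfg$out_dir) && length(dir(cfg$out_dir)) > 0 &&
      !isTRUE(cfg$overwrite)) {
    stop("output directory '", cfg$out_dir, "' is not empty; set overwrite = TRUE")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  inputs <- load_pipeline_inputs(cfg)
  datasets <- names(inputs$expression)
  gmt_sets <- if (is.null(cfg$gmt)) NULL else if (is.character(cfg$gmt)) {
    read_gmt(cfg$gmt)
  } else cfg$gmt

  fits <- list(); classifications <- list(); selected <- list()
  markers <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  for (di in seq_along(datasets)) {
    d <- datasets[di]
    X <- inputs$expression[[d]]
    ann <- inputs$annotations[[d]]
    dseed <- derive_seed(cfg$seed, 10L, di)
    say("[%s] scanning k = %d..%d (seed %d)", d, cfg$k_min, cfg$k_max, dseed)
    scan <- stage("scan_k", scan_k(X, cfg$k_min, cfg$k_max, seed = dseed,
                                   n_sets = cfg$n_sets,
                                   n_restarts = cfg$n_restarts,
                                   max_iter = cfg$max_iter, tol = cfg$tol))
    cls <- stage("classify_patterns", lapply(scan, classify_patterns,
                                             annotations = ann,
                                             tau_dom = cfg$tau_dom,
                                             tau_eta = cfg$tau_eta,
                                             tau_depth = cfg$tau_depth))
    k_sel <- stage("select_pattern_count", select_pattern_count(cls))
    say("[%s] selected k = %d", d, k_sel)
    fit <- scan[[as.character(k_sel)]]
    cls_sel <- cls[[as.character(k_sel)]]
    n_tech <- sum(cls_sel$category == "technical")
    if (n_tech > 0) say("[%s] dropping %d technical pattern(s)", d, n_tech)
    fit <- stage("drop_technical_patterns",
                 drop_technical_patterns(fit, cls_sel))
    mk <- stage("pattern_markers", pattern_markers(fit))

    fits[[d]] <- fit
    classifications[[d]] <- cls
    selected[[d]] <- k_sel
    markers[[d]] <- mk
    prefix <- file.path(cfg$out_dir, d)
    write_nmf_fit(fit, prefix)
    write_classification_tsv(cls_sel, paste0(prefix, "_classification.tsv"))
    write_table_tsv(mk, paste0(prefix, "_pattern_markers.tsv"))
  }

  projections <- list()
  if (length(datasets) >= 2 && length(inputs$maps)) {
    for (src in datasets) for (tgt in setdiff(datasets, src)) {
      map <- inputs$maps[[paste(src, tgt, sep = ":")]]
      side <- "species_a"
      if (is.null(map)) {
        map <- inputs$maps[[paste(tgt, src, sep = ":")]]
        side <- "species_b"
      }
      if (is.null(map)) next
      key <- paste(src, tgt, sep = "_to_")
      al <- stage("restrict_to_orthologs",
                  restrict_to_orthologs(fits[[src]]$A,
                                        inputs$expression[[tgt]],
                                        map, source = side))
      say("[%s] %d ortholog genes used, %d pairs dropped", key,
          nrow(al$A), al$n_dropped)
      pr <- stage("project_patterns",
                  project_patterns(al$A, al$Y, center = cfg$center))
      ann_t <- inputs$annotations[[tgt]]
      states <- unique(ann_t$state)
      if (length(states) >= 2) {
        combs <- utils::combn(states, 2)
        for (pat in pr$source_pattern_ids) {
          for (ci in seq_len(ncol(combs))) {
            pr <- stage("compare_groups",
                        compare_groups(pr, ann_t, pat,
                                       combs[1, ci], combs[2, ci],
                                       var_equal = cfg$var_equal))
          }
        }
      }
      projections[[key]] <- pr
      prefix <- file.path(cfg$out_dir, key)
      write_weight_tsv(pr$scores, "pattern_id", paste0(prefix, "_scores.tsv"))
      write_table_tsv(pr$group_tests, paste0(prefix, "_group_tests.tsv"))
    }
  } else if (length(datasets) >= 2) {
    say("no ortholog maps supplied; projection stage skipped")
  } else {
    say("single dataset; projection stage skipped")
  }

  enrichment <- list()
  if (!is.null(gmt_sets)) {
    universe <- unique(unlist(gmt_sets))
    for (d in datasets) {
      A <- fits[[d]]$A
      sym_map <- NULL
      if (!any(rownames(A) %in% universe)) {
        # gene namespace differs from the GMT; route through an ortholog map
        for (nm in names(inputs$maps)) {
          m <- inputs$maps[[nm]]
          if (any(m$gene_a %in% rownames(A) & m$gene_b %in% universe) ||
              any(m$gene_b %in% rownames(A) & m$gene_a %in% universe)) {
            sym_map <- m
            break
          }
        }
        if (is.null(sym_map)) {
          say("[%s] no symbol mapping into the GMT namespace; enrichment skipped", d)
          next
        }
      }
      res <- lapply(colnames(A), function(pat) {
        ranked <- rank_genes_by_pattern(A, pat, symbol_map = sym_map)
        gs <- stage("gsea_pos",
                    gsea_pos(ranked, gmt_sets, n_perm = cfg$n_perm,
                             seed = derive_seed(cfg$seed, 20L, match(pat, colnames(A))),
                             min_size = cfg$min_size, max_size = cfg$max_size,
                             exponent = cfg$exponent))
        if (nrow(gs)) cbind(pattern = pat, gs, stringsAsFactors = FALSE) else NULL
      })
      res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
      if (!is.null(res)) {
        enrichment[[d]] <- res
        write_table_tsv(res, file.path(cfg$out_dir,
                                       paste0(d, "_enrichment.tsv")))
      }
    }
  }

  manifest <- list(
    package_version = as.character(packageVersion("patternTransfer")),
    seed = cfg$seed,
    dataset_seeds = setNames(lapply(seq_along(datasets), function(i)
      derive_seed(cfg$seed, 10L, i)), datasets),
    parameters = cfg[c("k_min", "k_max", "n_sets", "n_restarts", "max_iter",
                       "tol", "tau_dom", "tau_eta", "tau_depth", "center",
                       "var_equal", "n_perm", "min_size", "max_size",
                       "exponent")],
    selected_k = selected,
    n_genes_used = lapply(projections, `[[`, "n_genes_used"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))

  invisible(list(fits = fits, classifications = classifications,
                 selected_k = selected, markers = markers,
                 projections = projections, enrichment = enrichment,
                 manifest = manifest, sim = inputs$sim,
                 out_dir = cfg$out_dir))
}

write_table_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

write_classification_tsv <- function(cls, path) {
  write_table_tsv(as.data.frame(cls), path)
}
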