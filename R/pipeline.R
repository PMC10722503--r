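#' Pipeline configuration
#'
#' Declares either a synthetic study (via [sim_config()]) or a set of
#' on-disk family tables, together with the analysis settings used by
#' [run_pipeline()].  Exactly one of `synthetic` and `dataset_paths` must be
#' given.
#'
#' @param synthetic A [sim_config()], or `NULL` when reading real tables.
#' @param dataset_paths Named character vector of family-table paths (one
#'   per dataset), or `NULL`.
#' @param breakpoints Interval edges in My; defaults to the synthetic
#'   config's partition when simulating.  Required for real inputs.
#' @param grid A [grid_spec()].  The pipeline default is a thinned version
#'   of the full search grid (`r` step 5e-4, `lambda` step 0.1), which keeps
#'   full five-dataset runs tractable while leaving the rate estimates and
#'   classifications unchanged at the resolutions that matter.
#' @param consensus_mode `"strict"` or `"majority"` (used for reporting;
#'   both are always computed).
#' @param majority_min Votes required for the majority consensus.
#' @param fdr_q Global FDR for the trait screen.
#' @param alpha Significance level for residual flags.
#' @param dr_estimator,dr_eps Per-family rate estimator settings for the
#'   occurrence map (see [family_dr()]).
#' @param out_dir Optional output directory; when set, every stage writes
#'   its table there.
#' @param seed Integer seed for any pipeline-level randomness (the synthetic
#'   config carries its own).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = sim_config(),
                            dataset_paths = NULL,
                            breakpoints = NULL,
                            grid = grid_spec(r_step = 5e-4, lam_step = 0.1),
                            consensus_mode = c("strict", "majority"),
                            majority_min = 4,
                            fdr_q = 0.1,
                            alpha = 0.05,
                            dr_estimator = "stem",
                            dr_eps = 0,
                            out_dir = NULL,
                            seed = 1L) {
  consensus_mode <- match.arg(consensus_mode)
  if (is.null(synthetic) == is.null(dataset_paths)) {
    stop("exactly one of 'synthetic' and 'dataset_paths' must be set",
         call. = FALSE)
  }
  if (!is.null(dataset_paths)) {
    if (is.null(names(dataset_paths)) || any(names(dataset_paths) == "")) {
      stop("'dataset_paths' must be a named vector (dataset id -> path)",
           call. = FALSE)
    }
    missing_files <- dataset_paths[!file.exists(dataset_paths)]
    if (length(missing_files) > 0) {
      stop("family table not found for dataset(s): ",
           paste(names(missing_files), collapse = ", "), call. = FALSE)
    }
    if (is.null(breakpoints)) {
      stop("'breakpoints' are required when reading real family tables; ",
           "supply the interval edges for each dataset", call. = FALSE)
    }
  }
  if (is.null(breakpoints) && !is.null(synthetic)) {
    breakpoints <- synthetic$partition$breakpoints
  }
  structure(
    list(synthetic = synthetic, dataset_paths = dataset_paths,
         partition = interval_partition(breakpoints), grid = grid,
         consensus_mode = consensus_mode, majority_min = majority_min,
         fdr_q = fdr_q, alpha = alpha, dr_estimator = dr_estimator,
         dr_eps = dr_eps, out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  # version-pinned serialization so the hash is stable across sessions
  saveRDS(config, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full classification pipeline
#'
#' Sequences every stage: input assembly (synthetic or from disk), grid
#' maximum-likelihood fits per dataset and geological interval, per-family
#' richness calls, cross-dataset consensus, category counts, the
#' period-independence test, the trait screen, the age comparison, and the
#' occurrence/geography stage.  Deterministic given the configuration; a
#' manifest records the configuration hash and per-stage record counts.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages (default `TRUE`).
#' @return List with elements `tables`, `truth` (synthetic runs only),
#'   `fits` (named `dataset/interval` list), `calls`, `consensus`, `counts`,
#'   `period_tests`, `traits` (synthetic runs only), `ks_ages`, `geo`
#'   (synthetic runs only: cleaned occurrences, grids and range summaries
#'   for poor/high families), and `manifest`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  counts <- list()
  synthetic <- !is.null(config$synthetic)

  say("stage: ingest")
  truth <- NULL
  if (synthetic) {
    sim <- stage("simulate", simulate_families(config$synthetic))
    tables <- sim$tables
    truth <- sim$truth
  } else {
    tables <- stage("ingest", {
      out <- lapply(names(config$dataset_paths), function(id) {
        read_family_table(config$dataset_paths[[id]], id)
      })
      names(out) <- names(config$dataset_paths)
      out
    })
  }
  counts$families <- vapply(tables, nrow, integer(1))

  say("stage: fit")
  part <- config$partition
  fits <- stage("fit", {
    out <- list()
    for (id in names(tables)) {
      tab <- tables[[id]]
      iv <- interval_of(part, tab$age)
      for (k in seq_len(part$n_intervals)) {
        sel <- iv == k
        if (!any(sel)) {
          stop("dataset '", id, "' has no families in interval ", k,
               "; adjust the breakpoints", call. = FALSE)
        }
        out[[paste0(id, "/interval", k)]] <-
          grid_mle(tab$richness[sel], tab$age[sel], grid = config$grid)
      }
    }
    out
  })

  say("stage: classify")
  calls <- stage("classify", {
    out <- lapply(names(tables), function(id) {
      dataset_fits <- fits[paste0(id, "/interval", seq_len(part$n_intervals))]
      classify_richness(tables[[id]], dataset_fits, part)
    })
    do.call(rbind, out)
  })
  counts$calls <- nrow(calls)

  say("stage: consensus")
  consensus <- stage("consensus", {
    consensus_calls(calls, n_datasets = length(tables),
                    majority_min = config$majority_min)
  })
  counts$consensus <- nrow(consensus)
  cat_counts <- category_counts(consensus, "strict")

  say("stage: association")
  period_tests <- stage("period_independence", {
    lapply(split(calls, calls$dataset), function(d) {
      tryCatch(period_independence(d, alpha = config$alpha),
               error = function(e) NULL)  # degenerate tables are possible
    })
  })

  trait_res <- NULL
  if (synthetic) {
    trait_res <- stage("traits", {
      traits_tab <- simulate_traits(truth, config$synthetic$trait_effects,
                                    seed = config$synthetic$seed + 1L)
      cat_of <- stats::setNames(consensus$strict, consensus$family)
      grp <- cat_of[traits_tab$family]
      keep <- !is.na(grp) & grp != "undefined"
      trait_names <- setdiff(names(traits_tab), c("family", "category"))
      tl <- lapply(trait_names, function(tr) {
        split(traits_tab[[tr]][keep], grp[keep])
      })
      names(tl) <- trait_names
      kruskal_dunn(tl, fdr_q = config$fdr_q)
    })
  }

  ks_ages <- stage("ks_ages", {
    med <- tapply(calls$t, calls$family, stats::median)
    lab <- stats::setNames(consensus$strict, consensus$family)[names(med)]
    keep <- !is.na(lab) & lab != "undefined"
    groups <- split(as.numeric(med[keep]), lab[keep])
    if (sum(lengths(groups) > 0) >= 2) ks_median_ages(groups) else NULL
  })

  geo <- NULL
  if (synthetic) {
    geo <- stage("geo", {
      occ_raw <- simulate_occurrences(truth, config$synthetic)
      occ <- clean_occurrences(occ_raw)
      lab <- stats::setNames(consensus$strict, consensus$family)
      ref <- tables[[1]]
      dr <- stats::setNames(
        family_dr(ref$richness, ref$age, config$dr_estimator,
                  eps = config$dr_eps),
        ref$family
      )
      by_cat <- lapply(c(poor = "poor", high = "high"), function(cat) {
        fams <- names(lab)[lab == cat]
        sub <- occ[occ$family %in% fams, , drop = FALSE]
        if (nrow(sub) == 0) return(NULL)
        list(grid = grid_mean_dr(sub, dr),
             summary = realm_biome_summary(sub))
      })
      list(occurrences = occ, rejection_log = attr(occ, "rejection_log"),
           family_dr = dr, by_category = by_cat)
    })
    counts$occurrences <- nrow(geo$occurrences)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("depauperon")),
    r_version = R.version.string,
    config_hash = config_hash(config),
    n_datasets = length(tables),
    n_intervals = part$n_intervals,
    counts = counts,
    stages = c("ingest", "fit", "classify", "consensus", "association",
               if (synthetic) "traits", "ks_ages", if (synthetic) "geo")
  )

  result <- list(
    tables = tables, truth = truth, fits = fits, calls = calls,
    consensus = consensus, counts = cat_counts,
    period_tests = period_tests, traits = trait_res, ks_ages = ks_ages,
    geo = geo, manifest = manifest
  )

  if (!is.null(config$out_dir)) {
    say("stage: write")
    stage("write", write_pipeline_outputs(result, config$out_dir))
  }
  result
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fit_table(result$fits, file.path(dir, "fits.tsv"))
  write_richness_calls(result$calls, result$consensus,
                       file.path(dir, "richness_calls.tsv"))
  utils::write.table(result$counts, file.path(dir, "category_counts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(result$traits)) {
    utils::write.table(result$traits, file.path(dir, "trait_tests.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(result$geo)) {
    for (cat in names(result$geo$by_category)) {
      g <- result$geo$by_category[[cat]]
      if (!is.null(g)) {
        utils::write.table(g$grid,
                           file.path(dir, paste0("grid_dr_", cat, ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
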