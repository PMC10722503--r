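#' Configuration of the synthetic study
#'
#' Bundles every knob of the synthetic-data generator.  The defaults emulate
#' the structure of the real study: 432 families assigned to geological
#' intervals, five age datasets that disagree by a small multiplicative
#' calibration error, clade sizes drawn from the geometric birth-death model
#' at the configured `(r, eps)` per interval, and a known fraction of
#' families forced into genuinely species-poor or species-rich outliers to
#' provide ground truth for recovery checks.
#'
#' @param n_families Number of families (default 432).
#' @param r_true,eps_true Net diversification rate and extinction fraction
#'   per interval (recycled across intervals).
#' @param breakpoints Interval edges in My (see [interval_partition()]).
#' @param age_max Oldest possible crown age in My; ages are uniform within
#'   each interval, the oldest interval capped at `age_max`.
#' @param n_datasets Number of emulated age datasets (default 5).
#' @param age_jitter_sd Standard deviation (log scale) of the multiplicative
#'   lognormal noise that separates the datasets' ages (default 0.05, i.e.
#'   about 5\% calibration disagreement; ages stay positive).
#' @param frac_low,frac_high Fractions of families forced below/above the
#'   stochastic clade-size bounds (defaults 0.10 and 0.05).
#' @param trait_effects Named numeric vector: per-trait shift in mean trait
#'   proportion per category step (poor = -1, predicted = 0, high = +1);
#'   unnamed traits are null.
#' @param n_records_per_family,spread_deg,p_disjunct,dup_rate,bad_name_rate,bad_basis_rate
#'   Occurrence-generator knobs: records per family, Gaussian cluster spread
#'   in degrees, probability a family gets two widely separated clusters,
#'   and the rates at which duplicate rows, genus-only names and
#'   non-accepted basis values are injected to exercise cleaning.
#' @param seed Integer seed; fixes every simulated byte.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_families = 432,
                       r_true = 0.05,
                       eps_true = 0.9,
                       breakpoints = c(66, 145),
                       age_max = 196,
                       n_datasets = 5,
                       age_jitter_sd = 0.05,
                       frac_low = 0.10,
                       frac_high = 0.05,
                       trait_effects = c(animal_pollination = 0.25,
                                         annual_life_history = 0.2,
                                         null_trait = 0),
                       n_records_per_family = 40,
                       spread_deg = 3,
                       p_disjunct = 0.15,
                       dup_rate = 0.05,
                       bad_name_rate = 0.02,
                       bad_basis_rate = 0.02,
                       seed = 1L) {
  partition <- interval_partition(breakpoints)
  n_iv <- partition$n_intervals
  r_true <- rep_len(r_true, n_iv)
  eps_true <- rep_len(eps_true, n_iv)
  if (any(r_true <= 0)) stop("'r_true' must be positive", call. = FALSE)
  if (any(eps_true < 0 | eps_true >= 1)) {
    stop("'eps_true' must lie in [0, 1)", call. = FALSE)
  }
  if (age_max <= max(c(0, partition$breakpoints))) {
    stop("'age_max' must exceed the oldest breakpoint", call. = FALSE)
  }
  stopifnot(n_families >= 1, n_datasets >= 1, age_jitter_sd >= 0,
            frac_low >= 0, frac_high >= 0, frac_low + frac_high < 1)
  structure(
    list(n_families = n_families, r_true = r_true, eps_true = eps_true,
         partition = partition, age_max = age_max, n_datasets = n_datasets,
         age_jitter_sd = age_jitter_sd, frac_low = frac_low,
         frac_high = frac_high, trait_effects = trait_effects,
         n_records_per_family = n_records_per_family, spread_deg = spread_deg,
         p_disjunct = p_disjunct, dup_rate = dup_rate,
         bad_name_rate = bad_name_rate, bad_basis_rate = bad_basis_rate,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# inverse-CDF draw from the geometric distribution on {1, 2, ...} with
# P(N = n) = (1 - beta) beta^(n - 1); platform-stable given the RNG stream
rgeom_beta <- function(u, beta) {
  beta <- rep_len(beta, length(u))
  n <- rep(1, length(u))
  pos <- beta > 0
  n[pos] <- ceiling(log1p(-u[pos]) / log(beta[pos]))
  pmax(1, n)
}

#' Simulate per-dataset family tables with a known truth key
#'
#' Each family gets a true crown age drawn uniformly within its geological
#' interval and a richness drawn from the geometric clade-size distribution
#' at the interval's true `(r, eps)` (inverse-CDF sampling).  A configured
#' fraction of families is then forced into ground-truth outliers: poor
#' families get `n = 1` (eligible only where the true bounds leave room,
#' `k_lower > 3`), rich families get twenty times the upper bound (the
#' upper bound is steeply sensitive to the fitted extinction fraction, so a
#' genuine outlier must sit an order of magnitude above it, as real
#' species-rich families do).  Each of
#' the `n_datasets` emulated studies reports the true age perturbed by
#' multiplicative lognormal noise; richness is a family property and is
#' shared.
#'
#' @param config A [sim_config()].
#' @return List with `tables` (list of per-dataset data frames in the
#'   [read_family_table()] layout plus `dataset`), `truth` (data frame:
#'   `family`, `interval`, `t_true`, `beta_true`, `n`, `true_category` in
#'   `{"low", "predicted", "high"}`), and `config`.
#' @export
simulate_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nf <- config$n_families
  part <- config$partition
  n_iv <- part$n_intervals
  edges <- c(0, part$breakpoints, config$age_max)

  interval <- sample(rep_len(seq_len(n_iv), nf))
  t_true <- stats::runif(nf, edges[interval], edges[interval + 1])
  beta_true <- bd_beta(config$r_true[interval], config$eps_true[interval], t_true)
  n <- rgeom_beta(stats::runif(nf), beta_true)

  bounds <- clade_size_bounds(beta = beta_true)
  true_category <- rep("predicted", nf)
  n_low <- floor(config$frac_low * nf)
  n_high <- floor(config$frac_high * nf)
  # poor outliers need clear headroom below the lower bound (n = 1 at least
  # two units under it); rich outliers are always constructible
  eligible_low <- which(bounds$k_lower > 3)
  if (length(eligible_low) < n_low) {
    warning("only ", length(eligible_low),
            " families have k_lower > 3; fewer poor outliers forced",
            call. = FALSE)
    n_low <- length(eligible_low)
  }
  idx_low <- sample(eligible_low, n_low)
  idx_high <- sample(setdiff(seq_len(nf), idx_low), n_high)
  n[idx_low] <- 1L
  # k_upper scales like 1/(1 - beta), so a fitted extinction fraction on the
  # likelihood ridge can inflate it several-fold; rich outliers are planted
  # a decade above the true bound, matching the orders-of-magnitude excess
  # of genuinely species-rich families
  n[idx_high] <- ceiling(20 * bounds$k_upper[idx_high])
  true_category[idx_low] <- "low"
  true_category[idx_high] <- "high"

  fam <- sprintf("Family%03d", seq_len(nf))
  tables <- lapply(seq_len(config$n_datasets), function(d) {
    jitter <- if (config$age_jitter_sd > 0) {
      exp(stats::rnorm(nf, 0, config$age_jitter_sd))
    } else rep(1, nf)
    data.frame(
      family = fam,
      richness = as.integer(n),
      age = t_true * jitter,
      dataset = sprintf("dataset%d", d),
      age_source = "observed",
      stringsAsFactors = FALSE
    )
  })
  names(tables) <- sprintf("dataset%d", seq_len(config$n_datasets))

  list(
    tables = tables,
    truth = data.frame(
      family = fam, interval = interval, t_true = t_true,
      beta_true = beta_true, n = as.integer(n),
      true_category = true_category, stringsAsFactors = FALSE
    ),
    config = config
  )
}

#' Simulate per-family trait proportions with category-dependent shifts
#'
#' Trait values are proportions in (0, 1) drawn from Beta distributions with
#' fixed concentration; the mean shifts by `trait_effects[trait]` per
#' category step (poor = -1 step, predicted = 0, high = +1), clipped to
#' (0.02, 0.98).  Traits with a zero effect are null.
#'
#' @param truth Truth key from [simulate_families()] (needs `family` and
#'   `true_category`).
#' @param trait_effects Named numeric vector of per-step mean shifts.
#' @param base_mean Baseline mean proportion (default 0.3).
#' @param concentration Beta concentration parameter (default 10).
#' @param seed Integer seed.
#' @return Data frame: `family`, `category`, one column per trait.
#' @export
simulate_traits <- function(truth, trait_effects, base_mean = 0.3,
                            concentration = 10, seed = 1L) {
  stopifnot(all(c("family", "true_category") %in% names(truth)))
  if (is.null(names(trait_effects)) || any(names(trait_effects) == "")) {
    stop("'trait_effects' must be a fully named vector", call. = FALSE)
  }
  set.seed(seed)
  step <- c(low = -1, predicted = 0, high = 1)[truth$true_category]
  out <- data.frame(family = truth$family, category = truth$true_category,
                    stringsAsFactors = FALSE)
  for (tr in names(trait_effects)) {
    mu <- pmin(pmax(base_mean + trait_effects[[tr]] * step, 0.02), 0.98)
    out[[tr]] <- stats::rbeta(nrow(truth), mu * concentration,
                              (1 - mu) * concentration)
  }
  out
}

# synthetic partition of the globe into 8 realms (longitude quadrant x
# hemisphere) and 14 biomes (latitude bands)
synthetic_realm <- function(lon, lat) {
  quad <- pmin(floor((lon + 180) / 90) + 1, 4)
  teow_realms[quad + ifelse(lat >= 0, 4, 0)]
}

synthetic_biome <- function(lat) {
  band <- pmin(floor((lat + 90) / 180 * 14) + 1, 14)
  teow_biomes[band]
}

#' Simulate a Darwin-Core-style occurrence table
#'
#' Each family receives one Gaussian cluster of records around a random
#' center (or two widely separated clusters with probability `p_disjunct`,
#' producing ground-truth disjunct ranges).  Realm and biome labels come
#' from a fixed synthetic partition of the globe (8 longitude/hemisphere
#' realms, 14 latitude-band biomes).  To exercise the cleaning rules,
#' duplicate rows, genus-only names, and non-accepted basis values are
#' injected at the configured rates.
#'
#' @param truth Truth key from [simulate_families()].
#' @param config A [sim_config()] (rates and cluster geometry are read from
#'   it).
#' @param seed Integer seed (defaults to `config$seed + 2`).
#' @return Data frame with columns `species`, `family`, `decimalLongitude`,
#'   `decimalLatitude`, `basisOfRecord`, `realm`, `biome`, plus attribute
#'   `"n_injected"` (named counts of injected dirty rows).
#' @export
simulate_occurrences <- function(truth, config, seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  nrec <- config$n_records_per_family
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    fam <- truth$family[i]
    two <- stats::runif(1) < config$p_disjunct
    centers <- cbind(
      lon = stats::runif(if (two) 2 else 1, -150, 150),
      lat = stats::runif(if (two) 2 else 1, -55, 65)
    )
    if (two) centers[2, ] <- c(
      ifelse(centers[1, 1] < 0, centers[1, 1] + 150, centers[1, 1] - 150),
      -centers[1, 2]
    )
    pick <- sample(nrow(centers), nrec, replace = TRUE)
    lon <- stats::rnorm(nrec, centers[pick, 1], config$spread_deg)
    lat <- stats::rnorm(nrec, centers[pick, 2], config$spread_deg)
    lon <- ((lon + 180) %% 360) - 180
    lat <- pmin(pmax(lat, -89.9), 89.9)
    data.frame(
      species = sprintf("%s sp%02d", sub("Family", "Genus", fam),
                        sample(8, nrec, replace = TRUE)),
      family = fam,
      decimalLongitude = lon,
      decimalLatitude = lat,
      basisOfRecord = "PRESERVED_SPECIMEN",
      stringsAsFactors = FALSE
    )
  })
  occ <- do.call(rbind, rows)

  n <- nrow(occ)
  n_dup <- floor(config$dup_rate * n)
  n_bad_name <- floor(config$bad_name_rate * n)
  n_bad_basis <- floor(config$bad_basis_rate * n)
  if (n_dup > 0) occ <- rbind(occ, occ[sample(n, n_dup), , drop = FALSE])
  if (n_bad_name > 0) {
    i <- sample(nrow(occ), n_bad_name)
    occ$species[i] <- vapply(strsplit(occ$species[i], " "), `[`, "", 1)
  }
  if (n_bad_basis > 0) {
    i <- sample(nrow(occ), n_bad_basis)
    occ$basisOfRecord[i] <- "LIVING_SPECIMEN"
  }
  occ$realm <- synthetic_realm(occ$decimalLongitude, occ$decimalLatitude)
  occ$biome <- synthetic_biome(occ$decimalLatitude)
  rownames(occ) <- NULL
  attr(occ, "n_injected") <- c(duplicates = n_dup, bad_names = n_bad_name,
                               bad_basis = n_bad_basis)
  occ
}

#' Materialize a full synthetic study directory
#'
#' Writes every input the ingestion layer consumes: one family table per
#' dataset, the truth key, a trait table, and an occurrence table, all as
#' delimited text.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of written file paths.
#' @export
write_synthetic_study <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_families(config)
  paths <- character(0)
  for (nm in names(sim$tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.table(sim$tables[[nm]][, c("family", "richness", "age")],
                       p, sep = ",", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "truth.csv")
  utils::write.table(sim$truth, p, sep = ",", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  traits <- simulate_traits(sim$truth, config$trait_effects,
                            seed = config$seed + 1L)
  p <- file.path(dir, "traits.csv")
  utils::write.table(traits, p, sep = ",", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  occ <- simulate_occurrences(sim$truth, config)
  p <- file.path(dir, "occurrences.csv")
  utils::write.table(occ, p, sep = ",", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
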