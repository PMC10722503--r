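#' Partition of geological time into rate-homogeneous intervals
#'
#' Breakpoints come from an external diversification-shift analysis and are
#' consumed as configuration.  Interior breakpoints split the age axis into
#' intervals `(0, b1]`, `(b1, b2]`, ..., `(b_last, Inf)`, numbered from the
#' present backwards.
#'
#' @param breakpoints Numeric vector of interval edges in million years,
#'   strictly positive; accepted in either order and sorted ascending.
#' @return An object of class `interval_partition`.
#' @examples
#' p <- interval_partition(c(66, 145))
#' interval_of(p, c(10, 100, 200))
#' @export
interval_partition <- function(breakpoints = numeric(0)) {
  stopifnot(is.numeric(breakpoints))
  if (anyNA(breakpoints) || any(breakpoints <= 0)) {
    stop("breakpoints must be positive times in My", call. = FALSE)
  }
  bp <- sort(unique(breakpoints))
  structure(list(breakpoints = bp, n_intervals = length(bp) + 1L),
            class = "interval_partition")
}

#' Map ages to interval indices
#'
#' @param partition An [interval_partition()].
#' @param t Ages in million years (> 0).
#' @return Integer interval indices (1 = youngest interval).
#' @export
interval_of <- function(partition, t) {
  stopifnot(inherits(partition, "interval_partition"))
  if (any(t <= 0)) stop("ages must be positive", call. = FALSE)
  findInterval(t, partition$breakpoints, left.open = TRUE) + 1L
}

# widest clade-size bounds over the profile-likelihood region at age t:
# every retained (r, eps) combination contributes a bound pair and the
# union [min k_lower, max k_upper] is taken
widest_bounds <- function(fit, t) {
  pr <- fit$profile
  b <- bd_beta(pr$r, pr$eps, t)
  lb <- log(b)
  c(k_lower = min(log(0.975) / lb + 1), k_upper = max(log(0.025) / lb + 1))
}

#' Classify family richness against the fitted birth-death model
#'
#' For each family, clade-size bounds are evaluated at the family's crown age
#' under every parameter combination retained in the profile-likelihood
#' region of the fit, and the widest resulting interval
#' `[min k_lower, max k_upper]` is used: the family is `low` when its
#' richness falls strictly below `k_lower`, `high` when strictly above
#' `k_upper`, and `predicted` otherwise.  Bounds are compared real-valued,
#' without rounding.
#'
#' @param records Family table for one dataset (columns `family`, `richness`,
#'   `age`, optional `dataset`, `age_source`).
#' @param fits A single `bd_fit` (one interval) or a list of fits indexed by
#'   interval, together with `partition`.
#' @param partition Optional [interval_partition()]; required when `fits` is
#'   a per-interval list.
#' @param include_imputed Set `FALSE` to drop families whose `age_source` is
#'   not `"observed"` (sensitivity analysis on directly dated families only).
#' @return Data frame of richness calls: `family`, `dataset`, `n`, `t`,
#'   `interval`, `k_lower`, `k_upper`, `category` in
#'   `{"low", "predicted", "high"}`.  Families with a missing age are
#'   skipped with a warning.
#' @export
classify_richness <- function(records, fits, partition = NULL,
                              include_imputed = TRUE) {
  stopifnot(is.data.frame(records),
            all(c("family", "richness", "age") %in% names(records)))
  if (inherits(fits, "bd_fit")) {
    fits <- list(fits)
    if (is.null(partition)) partition <- interval_partition()
  }
  stopifnot(inherits(partition, "interval_partition"))
  if (length(fits) != partition$n_intervals) {
    stop("need one fit per interval (", partition$n_intervals, ")", call. = FALSE)
  }

  keep <- rep(TRUE, nrow(records))
  if (!include_imputed && "age_source" %in% names(records)) {
    keep <- records$age_source == "observed"
  }
  missing_age <- is.na(records$age)
  if (any(missing_age & keep)) {
    warning("skipping families without an age: ",
            paste(records$family[missing_age & keep], collapse = ", "),
            call. = FALSE)
  }
  keep <- keep & !missing_age
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) == 0) {
    return(data.frame(family = character(0), dataset = character(0),
                      n = integer(0), t = numeric(0), interval = integer(0),
                      k_lower = numeric(0), k_upper = numeric(0),
                      category = character(0), stringsAsFactors = FALSE))
  }

  iv <- interval_of(partition, rec$age)
  bounds <- t(vapply(seq_len(nrow(rec)), function(i) {
    widest_bounds(fits[[iv[i]]], rec$age[i])
  }, numeric(2)))
  category <- ifelse(rec$richness < bounds[, 1], "low",
                     ifelse(rec$richness > bounds[, 2], "high", "predicted"))
  data.frame(
    family = rec$family,
    dataset = if ("dataset" %in% names(rec)) rec$dataset else NA_character_,
    n = rec$richness,
    t = rec$age,
    interval = iv,
    k_lower = bounds[, 1],
    k_upper = bounds[, 2],
    category = category,
    stringsAsFactors = FALSE
  )
}

#' Cross-dataset consensus of richness calls
#'
#' Aggregates per-dataset richness calls into family-level labels.  The
#' strict consensus requires all `n_datasets` calls to agree (families
#' missing from any dataset are ineligible); the majority consensus requires
#' at least `majority_min` agreeing calls.  Strict labels map `low` to
#' `poor`, `predicted` to `predicted`, `high` to `high`; families without
#' the required agreement are `undefined`.
#'
#' @param calls Data frame of richness calls from [classify_richness()],
#'   stacked over datasets (each family at most once per dataset).
#' @param n_datasets Number of source datasets (default 5).
#' @param majority_min Votes needed for the majority consensus (default 4).
#' @return Data frame with columns `family`, `votes_low`, `votes_predicted`,
#'   `votes_high`, `n_votes`, `strict`, `majority`.
#' @export
consensus_calls <- function(calls, n_datasets = 5, majority_min = 4) {
  stopifnot(all(c("family", "dataset", "category") %in% names(calls)))
  if (any(duplicated(calls[, c("family", "dataset")]))) {
    stop("a family appears more than once in a dataset", call. = FALSE)
  }
  label <- c(low = "poor", predicted = "predicted", high = "high")
  fams <- sort(unique(calls$family))
  votes <- table(factor(calls$family, levels = fams),
                 factor(calls$category, levels = c("low", "predicted", "high")))
  v <- as.data.frame.matrix(votes)
  n_votes <- rowSums(v)
  top <- apply(v, 1, which.max)
  top_votes <- apply(v, 1, max)
  strict <- ifelse(n_votes == n_datasets & top_votes == n_datasets,
                   label[colnames(v)[top]], "undefined")
  majority <- ifelse(top_votes >= majority_min,
                     label[colnames(v)[top]], "undefined")
  data.frame(
    family = fams,
    votes_low = v$low,
    votes_predicted = v$predicted,
    votes_high = v$high,
    n_votes = n_votes,
    strict = unname(strict),
    majority = unname(majority),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Category counts and percentages of consensus families
#'
#' Counts families per consensus category and expresses them as percentages
#' of the classified (non-`undefined`) total, rounded to one decimal place.
#'
#' @param consensus Data frame from [consensus_calls()].
#' @param which Consensus column to tabulate, `"strict"` (default) or
#'   `"majority"`.
#' @return Data frame with columns `category`, `n`, `pct`.
#' @export
category_counts <- function(consensus, which = c("strict", "majority")) {
  which <- match.arg(which)
  lab <- consensus[[which]]
  lab <- lab[lab != "undefined"]
  lev <- c("poor", "predicted", "high")
  n <- as.integer(table(factor(lab, levels = lev)))
  total <- sum(n)
  pct <- if (total > 0) round(100 * n / total, 1) else rep(0, length(lev))
  data.frame(category = lev, n = n, pct = pct, stringsAsFactors = FALSE)
}

#' Independence of richness category and origin interval
#'
#' Tests whether the classification of families is independent of the
#' geological interval in which they originated: a Pearson chi-squared test
#' with Haberman adjusted residuals on the interval-by-category contingency
#' table.
#'
#' @param calls Richness calls from [classify_richness()] (one dataset).
#' @param alpha Two-sided significance level for flagging residuals.
#' @return A `contingency_result`; see [chi2_haberman()].
#' @export
period_independence <- function(calls, alpha = 0.05) {
  stopifnot(all(c("interval", "category") %in% names(calls)))
  tab <- table(interval = calls$interval, category = calls$category)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("need at least two intervals and two categories represented",
         call. = FALSE)
  }
  chi2_haberman(unclass(tab), alpha = alpha)
}

#' Write richness calls and consensus labels as delimited text
#'
#' @param calls Stacked per-dataset calls from [classify_richness()].
#' @param consensus Output of [consensus_calls()].
#' @param path Output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_richness_calls <- function(calls, consensus, path) {
  wide <- stats::reshape(
    calls[, c("family", "dataset", "category")],
    idvar = "family", timevar = "dataset", direction = "wide"
  )
  names(wide) <- sub("^category\\.", "category_", names(wide))
  out <- merge(consensus, wide, by = "family", all.x = TRUE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
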