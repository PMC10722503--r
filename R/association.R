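#' Pearson chi-squared test with Haberman adjusted residuals
#'
#' Computes the uncorrected Pearson chi-squared statistic on a contingency
#' table and, per cell, the Haberman adjusted residual
#' `(O - E) / sqrt(E * (1 - row/N) * (1 - col/N))`, which is approximately
#' standard normal under independence.  Cells whose residual exceeds the
#' two-sided normal critical value at `alpha` are flagged `excess` (positive)
#' or `deficit` (negative).  No continuity correction is applied, and small
#' expected counts raise a warning rather than switching methods.
#'
#' @param observed Matrix of non-negative counts, at least 2 x 2.
#' @param alpha Two-sided significance level for flagging cells
#'   (default 0.05, critical value 1.96).
#' @return An object of class `contingency_result`: list with `observed`,
#'   `expected`, `chi2`, `df`, `p`, `adj_residuals`, `flags` (character
#'   matrix in `{"excess", "deficit", "none"}`), and `critical`.
#' @examples
#' m <- matrix(c(30, 10, 10, 30), 2, 2)
#' chi2_haberman(m)
#' @export
chi2_haberman <- function(observed, alpha = 0.05) {
  observed <- as.matrix(observed)
  if (nrow(observed) < 2 || ncol(observed) < 2) {
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  }
  if (any(observed < 0) || anyNA(observed)) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  if (any(rowSums(observed) == 0) || any(colSums(observed) == 0)) {
    stop("degenerate table: a row or column marginal is zero", call. = FALSE)
  }
  cs <- suppressWarnings(stats::chisq.test(observed, correct = FALSE))
  if (any(cs$expected < 5)) {
    warning("expected counts below 5; chi-squared approximation may be poor",
            call. = FALSE)
  }
  crit <- stats::qnorm(1 - alpha / 2)
  # chisq.test's standardized residuals are exactly Haberman's adjusted
  # residuals: (O - E) / sqrt(E (1 - row/N) (1 - col/N))
  adj <- cs$stdres
  flags <- matrix("none", nrow(observed), ncol(observed),
                  dimnames = dimnames(adj))
  flags[adj > crit] <- "excess"
  flags[adj < -crit] <- "deficit"
  structure(
    list(
      observed = observed,
      expected = cs$expected,
      chi2 = unname(cs$statistic),
      df = unname(cs$parameter),
      p = cs$p.value,
      adj_residuals = adj,
      flags = flags,
      critical = crit
    ),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Pearson chi-squared: X2 = %.4f, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p))
  cat(sprintf("Haberman adjusted residuals (|z| > %.2f flagged):\n", x$critical))
  print(round(x$adj_residuals, 2))
  n_flag <- sum(x$flags != "none")
  cat(sprintf("%d cell(s) flagged excess/deficit\n", n_flag))
  invisible(x)
}

# Dunn's post-hoc z statistics on mean ranks of the pooled sample, with the
# tie-corrected variance; no package in the stack provides this, so it is
# implemented directly.
dunn_pairs <- function(groups) {
  k <- length(groups)
  stopifnot(k >= 2)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), lengths(groups))
  N <- length(x)
  rk <- rank(x)
  rbar <- tapply(rk, g, mean)
  n <- as.numeric(lengths(groups))
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  z <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
    (rbar[i] - rbar[j]) / se
  })
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  data.frame(
    group1 = nm[pairs[1, ]],
    group2 = nm[pairs[2, ]],
    z = as.numeric(z),
    p = 2 * stats::pnorm(-abs(as.numeric(z))),
    stringsAsFactors = FALSE
  )
}

#' Kruskal-Wallis screen with Dunn post-hoc under a global FDR
#'
#' For each trait, a tie-corrected Kruskal-Wallis test compares the
#' distribution of per-family trait values between richness categories.  The
#' trait-level p-values are adjusted together with Benjamini-Hochberg, and a
#' trait is significant when its adjusted p-value is at most `fdr_q`.  For
#' significant traits only, Dunn's pairwise z tests on mean ranks are
#' reported, BH-adjusted within trait.  The realized p-value threshold (the
#' largest raw p-value declared significant) is reported rather than
#' hard-coded.
#'
#' @param traits Named list; each element is one trait, itself a named list
#'   of numeric vectors (one vector of per-family values per category).
#' @param fdr_q Global false discovery rate across traits (default 0.1).
#' @return Data frame with one row per trait (`trait`, `H`, `df`, `p`,
#'   `p_adj`, `significant`) carrying two attributes: `"dunn"` (data frame
#'   of pairwise comparisons for significant traits: `trait`, `group1`,
#'   `group2`, `z`, `p`, `p_adj`) and `"p_threshold"` (realized raw-p
#'   significance threshold, `NA` when nothing is significant).
#' @examples
#' set.seed(1)
#' traits <- list(
#'   shifted = list(poor = rnorm(20, 0), high = rnorm(20, 2)),
#'   null = list(poor = rnorm(20), high = rnorm(20))
#' )
#' kruskal_dunn(traits)
#' @export
kruskal_dunn <- function(traits, fdr_q = 0.1) {
  stopifnot(is.list(traits), length(traits) >= 1)
  if (is.null(names(traits))) names(traits) <- paste0("trait", seq_along(traits))
  res <- lapply(names(traits), function(nm) {
    groups <- traits[[nm]]
    if (length(groups) < 2 || any(lengths(groups) < 1)) {
      stop("trait '", nm, "': need >= 2 non-empty groups", call. = FALSE)
    }
    x <- unlist(groups, use.names = FALSE)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    kw <- stats::kruskal.test(x, g)
    data.frame(trait = nm, H = unname(kw$statistic),
               df = unname(kw$parameter), p = kw$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj <= fdr_q

  p_threshold <- if (any(out$significant)) max(out$p[out$significant]) else NA_real_

  dunn <- NULL
  for (nm in out$trait[out$significant]) {
    d <- dunn_pairs(traits[[nm]])
    d$p_adj <- stats::p.adjust(d$p, method = "BH")
    d <- cbind(trait = nm, d)
    dunn <- rbind(dunn, d)
  }
  if (is.null(dunn)) {
    dunn <- data.frame(trait = character(0), group1 = character(0),
                       group2 = character(0), z = numeric(0), p = numeric(0),
                       p_adj = numeric(0), stringsAsFactors = FALSE)
  }
  attr(out, "dunn") <- dunn
  attr(out, "p_threshold") <- p_threshold
  out
}

#' Pairwise Kolmogorov-Smirnov comparison of median family ages
#'
#' Two-sample KS statistic `D` and asymptotic p-value for every pair of
#' categories, used to ask whether families in different richness categories
#' differ in their (median across datasets) crown age distribution.
#'
#' @param ages_by_category Named list of numeric vectors of median family
#'   ages, one per category.  Empty categories are skipped with a warning.
#' @return Data frame with columns `group1`, `group2`, `D`, `p`, plus an
#'   attribute `"max_D"`, the largest D across pairs.
#' @export
ks_median_ages <- function(ages_by_category) {
  stopifnot(is.list(ages_by_category))
  empty <- lengths(ages_by_category) == 0
  if (any(empty)) {
    warning("empty categories skipped: ",
            paste(names(ages_by_category)[empty], collapse = ", "),
            call. = FALSE)
    ages_by_category <- ages_by_category[!empty]
  }
  if (length(ages_by_category) < 2) {
    stop("need at least two non-empty categories", call. = FALSE)
  }
  nm <- names(ages_by_category)
  pairs <- utils::combn(length(ages_by_category), 2)
  rows <- apply(pairs, 2, function(pr) {
    ks <- suppressWarnings(stats::ks.test(ages_by_category[[pr[1]]],
                                          ages_by_category[[pr[2]]]))
    data.frame(group1 = nm[pr[1]], group2 = nm[pr[2]],
               D = unname(ks$statistic), p = ks$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "max_D") <- max(out$D)
  out
}
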