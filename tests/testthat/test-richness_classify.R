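test_that("interval partitions map ages to the right bins", {
  p <- interval_partition(c(66, 145))
  expect_equal(p$n_intervals, 3L)
  expect_equal(interval_of(p, c(10, 66, 66.1, 145, 150)), c(1L, 1L, 2L, 2L, 3L))
  expect_error(interval_of(p, 0), "positive")
  # no breakpoints: everything is one interval
  p0 <- interval_partition()
  expect_equal(interval_of(p0, c(1, 200)), c(1L, 1L))
})

test_that("families classify against the widest profile-region bounds", {
  # single profile point with eps = 0; at t = log(2)/r, beta = 0.5 so the
  # bounds are (1.0365, 6.3219)
  fit <- fixture_fit(r = 0.1, lam = 0.1)
  t_half <- log(2) / 0.1
  rec <- data.frame(
    family = c("P", "Q", "R"), richness = c(5L, 7L, 1L),
    age = rep(t_half, 3), dataset = "d", age_source = "observed",
    stringsAsFactors = FALSE
  )
  calls <- classify_richness(rec, fit)
  expect_equal(calls$category, c("predicted", "high", "low"))
  expect_equal(calls$k_lower, rep(1.036526, 3), tolerance = 1e-6)
  expect_equal(calls$k_upper, rep(6.321928, 3), tolerance = 1e-6)

  # a two-point profile region takes the union of bounds
  fit2 <- fixture_fit(r = c(0.1, 0.12), lam = c(0.1, 0.12))
  calls2 <- classify_richness(rec[1, ], fit2)
  b_hi <- bd_beta(0.12, 0, t_half)
  expect_equal(calls2$k_upper, log(0.025) / log(b_hi) + 1, tolerance = 1e-9)
  expect_equal(calls2$k_lower, 1.036526, tolerance = 1e-6)
})

test_that("classification is monotone in richness", {
  fit <- fixture_fit(r = c(0.05, 0.06), lam = c(0.5, 0.3))
  ord <- c(low = 1, predicted = 2, high = 3)
  for (t in c(20, 60, 120)) {
    rec <- data.frame(family = sprintf("F%02d", 1:30),
                      richness = as.integer(round(exp(seq(0, 10, length.out = 30)))),
                      age = t, dataset = "d", stringsAsFactors = FALSE)
    cat_seq <- ord[classify_richness(rec, fit)$category]
    expect_true(all(diff(cat_seq) >= 0))
  }
})

test_that("imputed-age families can be excluded on request", {
  fit <- fixture_fit(r = 0.1, lam = 0.1)
  rec <- data.frame(family = c("A", "B"), richness = c(5L, 5L),
                    age = c(10, 10), dataset = "d",
                    age_source = c("observed", "sister_imputed"),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(classify_richness(rec, fit)), 2)
  expect_equal(classify_richness(rec, fit, include_imputed = FALSE)$family, "A")
})

test_that("consensus requires unanimity (strict) or four votes (majority)", {
  mk <- function(fam, cats) {
    data.frame(family = fam, dataset = paste0("d", seq_along(cats)),
               category = cats, stringsAsFactors = FALSE)
  }
  calls <- rbind(
    mk("U", rep("low", 5)),
    mk("V", c(rep("low", 4), "predicted")),
    mk("W", c("low", "low", "predicted", "predicted", "high")),
    mk("X", rep("high", 5)),
    mk("Y", rep("predicted", 4))  # missing from one dataset
  )
  cons <- consensus_calls(calls, n_datasets = 5, majority_min = 4)
  get <- function(f, col) cons[cons$family == f, col]
  expect_equal(get("U", "strict"), "poor")
  expect_equal(get("U", "majority"), "poor")
  expect_equal(get("V", "strict"), "undefined")
  expect_equal(get("V", "majority"), "poor")
  expect_equal(get("W", "strict"), "undefined")
  expect_equal(get("W", "majority"), "undefined")
  expect_equal(get("X", "strict"), "high")
  expect_equal(get("Y", "strict"), "undefined")  # ineligible: 4 of 5 datasets
  expect_equal(get("Y", "majority"), "predicted")

  # permutation invariance over dataset order
  cons2 <- consensus_calls(calls[sample(nrow(calls)), ], 5, 4)
  expect_identical(cons[order(cons$family), ], cons2[order(cons2$family), ])

  expect_error(consensus_calls(rbind(mk("Z", "low"), mk("Z", "low")), 5),
               "more than once")
})

test_that("category counts reproduce printed-style percentages", {
  cons <- data.frame(
    family = sprintf("F%03d", 1:260),
    strict = c(rep("predicted", 161), rep("poor", 75), rep("high", 12),
               rep("undefined", 12)),
    stringsAsFactors = FALSE
  )
  cc <- category_counts(cons)
  expect_equal(cc$n[cc$category == "poor"], 75L)
  expect_equal(cc$pct[cc$category == "poor"], 30.2)
  expect_equal(cc$pct[cc$category == "predicted"], 64.9)
  expect_equal(cc$pct[cc$category == "high"], 4.8)
  # degenerate inputs
  empty <- category_counts(cons[0, ])
  expect_equal(empty$n, c(0L, 0L, 0L))
  all_poor <- category_counts(data.frame(family = "A", strict = "poor"))
  expect_equal(all_poor$pct, c(100, 0, 0))
})

test_that("period independence delegates to the contingency machinery", {
  # perfectly proportional interval x category table: chi2 = 0
  calls <- expand.grid(interval = 1:3, category = c("low", "predicted"),
                       rep = 1:10, stringsAsFactors = FALSE)
  res <- suppressWarnings(period_independence(calls))
  expect_s3_class(res, "contingency_result")
  expect_equal(res$chi2, 0, tolerance = 1e-12)
  expect_true(all(res$flags == "none"))
  expect_error(period_independence(data.frame(interval = 1,
                                              category = "low")),
               "at least two")
})
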