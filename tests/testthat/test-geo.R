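occ_row <- function(species = "Genus species", family = "Fam",
                    lon = 0, lat = 0, basis = "PRESERVED_SPECIMEN",
                    realm = "Neotropic", biome = "biome_07") {
  data.frame(species = species, family = family,
             decimalLongitude = lon, decimalLatitude = lat,
             basisOfRecord = basis, realm = realm, biome = biome,
             stringsAsFactors = FALSE)
}

test_that("occurrence cleaning applies every rule and logs it", {
  occ <- rbind(
    occ_row("Quercus robur", lon = 1),
    occ_row("Quercus robur", lon = 1),                 # exact duplicate
    occ_row("Quercus", lon = 2),                       # genus only
    occ_row("Zea mays", lon = 3),                      # excluded crop
    occ_row("Abies alba", lon = 4, basis = "LIVING_SPECIMEN"),
    occ_row("Abies alba", lon = 400),                  # out of bounds
    occ_row("Abies alba", lon = 5)
  )
  out <- clean_occurrences(occ, exclude_taxa = "Zea mays")
  expect_equal(nrow(out), 2)
  expect_setequal(out$species, c("Quercus robur", "Abies alba"))
  log <- attr(out, "rejection_log")
  expect_equal(unname(log[c("incomplete_name", "out_of_bounds", "bad_basis",
                            "excluded_taxon", "duplicate")]),
               c(1L, 1L, 1L, 1L, 1L))

  # same taxon at different coordinates is not a duplicate
  occ2 <- rbind(occ_row("A b", lon = 1), occ_row("A b", lon = 2))
  expect_equal(nrow(clean_occurrences(occ2)), 2)

  # empty input passes through
  empty <- clean_occurrences(occ[0, ])
  expect_equal(nrow(empty), 0)
  expect_error(clean_occurrences(data.frame(species = "A b")), "missing")
})

test_that("per-family diversification estimators evaluate correctly", {
  expect_equal(family_dr(1, 50), 0)
  expect_equal(family_dr(8, 20), log(8) / 20, tolerance = 1e-12)
  # crown estimator at eps = 0 reduces to log(n/2)/t
  expect_equal(family_dr(100, 50, "crown"), log(50) / 50, tolerance = 1e-12)
  # monotone nondecreasing in n at fixed t, both estimators and eps values
  # (the crown estimator is defined from n = 2, the minimal crown group)
  for (e in c(0, 0.5, 0.9)) {
    r_stem <- family_dr(c(1, 2, 10, 100, 1e4), 30, "stem", eps = e)
    expect_true(all(diff(r_stem) > 0))
    expect_true(all(r_stem >= 0))
    r_crown <- family_dr(c(2, 10, 100, 1e4), 30, "crown", eps = e)
    expect_true(all(diff(r_crown) > 0))
    expect_true(all(r_crown >= 0))
  }
  expect_error(family_dr(1, 30, "crown"), "n >= 2")
  # extinction correction lowers the stem rate for the same data
  expect_lt(family_dr(100, 30, eps = 0.9), family_dr(100, 30, eps = 0))
  expect_error(family_dr(5, -1), "positive")
  expect_error(family_dr(5, 10, eps = 1), "eps")
})

test_that("one-degree grid aggregation uses half-open cells", {
  occ <- rbind(
    occ_row("A b", family = "F1", lon = 10.0, lat = 0.5),   # edge: cell 10
    occ_row("C d", family = "F2", lon = 10.5, lat = 0.1),
    occ_row("E f", family = "F1", lon = 9.999, lat = 0.5),  # cell 9
    occ_row("G h", family = "F1", lon = -0.5, lat = -0.5)   # cell -1,-1
  )
  dr <- c(F1 = 0.0, F2 = 0.2)
  g <- grid_mean_dr(occ, dr)
  cell <- function(lon, lat) g[g$cell_lon == lon & g$cell_lat == lat, ]
  expect_equal(cell(10, 0)$mean_dr, 0.1)     # mean of 0.0 and 0.2
  expect_equal(cell(10, 0)$n_records, 2L)
  expect_equal(cell(9, 0)$mean_dr, 0.0)
  expect_equal(cell(-1, -1)$n_records, 1L)
  # record conservation
  expect_equal(sum(g$n_records), nrow(occ))
  expect_error(grid_mean_dr(occ, dr["F1"]), "no diversification rate")

  # a family spread over many cells carries its own DR everywhere
  occ2 <- do.call(rbind, lapply(1:6, function(i)
    occ_row("A b", family = "F1", lon = i + 0.3, lat = 20.2)))
  g2 <- grid_mean_dr(occ2, c(F1 = 0.123))
  expect_true(all(g2$mean_dr == 0.123))
  expect_equal(nrow(g2), 6)
})

test_that("ascii grid export reproduces cell values", {
  g <- data.frame(cell_lon = c(0, 2), cell_lat = c(0, 1),
                  mean_dr = c(0.1, 0.3), n_records = c(1L, 2L))
  tf <- tempfile(fileext = ".asc")
  write_ascii_grid(g, tf)
  lines <- readLines(tf)
  expect_equal(lines[1], "ncols 3")
  expect_equal(lines[2], "nrows 2")
  vals <- read.table(text = lines[-(1:6)])
  expect_equal(vals[1, 3], 0.3)   # north band, lon 2
  expect_equal(vals[2, 1], 0.1)   # south band, lon 0
  expect_equal(vals[1, 1], -9999)
})

test_that("realm/biome summaries tally presence and classify ranges", {
  # tight single-window family
  local_occ <- do.call(rbind, lapply(1:20, function(i)
    occ_row("A b", family = "Tight", lon = 5 + 0.1 * i, lat = -2 + 0.1 * i,
            realm = "Afrotropic", biome = "biome_03")))
  # family spanning five realms, far-flung
  wide_occ <- do.call(rbind, lapply(1:5, function(i)
    occ_row("C d", family = "Wide", lon = -160 + i * 65, lat = 10 * i - 30,
            realm = teow_realms[i], biome = teow_biomes[i])))
  out <- realm_biome_summary(rbind(local_occ, wide_occ))
  tight <- out[out$family == "Tight", ]
  wide <- out[out$family == "Wide", ]
  expect_equal(tight$n_realms, 1)
  expect_equal(tight$range_class, "highly_localized")
  expect_equal(tight$pattern_class, "continuous")
  expect_equal(wide$n_realms, 5)
  expect_equal(wide$range_class, "cosmopolitan")
  rp <- attr(out, "realm_pct")
  expect_equal(unname(rowSums(rp)), c(100, 100), tolerance = 0.1)
  expect_equal(rp["Tight", "Afrotropic"], 100)
  bp <- attr(out, "biome_pct")
  expect_equal(unname(rowSums(bp)), c(100, 100), tolerance = 0.1)
})

test_that("disjunct ranges are detected by great-circle gaps", {
  # two clusters ~5000 km apart along the equator (45 degrees of longitude)
  cl1 <- do.call(rbind, lapply(1:8, function(i)
    occ_row("A b", family = "Dis", lon = 0 + 0.2 * i, lat = 0.1 * i)))
  cl2 <- do.call(rbind, lapply(1:8, function(i)
    occ_row("A b", family = "Dis", lon = 45 + 0.2 * i, lat = 0.1 * i)))
  out <- realm_biome_summary(rbind(cl1, cl2))
  expect_equal(out$pattern_class, "disjunct")
  # the same points with the gap threshold above the separation: continuous
  out2 <- realm_biome_summary(rbind(cl1, cl2), gap_km = 6000)
  expect_equal(out2$pattern_class, "continuous")
  # unlabeled records trigger the warning path
  cl1$realm[1] <- NA
  expect_warning(realm_biome_summary(rbind(cl1, cl2)), "unlabeled")
})
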