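#' Biogeographic realm and biome labels
#'
#' The eight terrestrial biogeographic realms and fourteen biomes of the
#' Terrestrial Ecoregions of the World scheme, used as the label vocabulary
#' for occurrence summaries.
#'
#' @format Character vectors of length 8 and 14.
#' @name teow_labels
NULL

#' @rdname teow_labels
#' @export
teow_realms <- c(
  "Afrotropic", "Antarctic", "Australasia", "Indomalaya",
  "Nearctic", "Neotropic", "Oceania", "Palearctic"
)

#' @rdname teow_labels
#' @export
teow_biomes <- paste0("biome_", sprintf("%02d", 1:14))

#' Clean georeferenced occurrence records
#'
#' Applies the standard filters to a Darwin-Core-style occurrence table:
#' records must carry a full binomial (genus and epithet), valid coordinates,
#' an accepted basis of record (preserved specimens and literature by
#' default); exact duplicates of the same `(taxon, lon, lat)` are collapsed
#' to the first occurrence, and taxa on an exclusion list (crops, cultivated
#' or garden material) are dropped.  Every rule logs how many records it
#' removed.
#'
#' @param records Data frame with columns `species`, `family`,
#'   `decimalLongitude`, `decimalLatitude`, `basisOfRecord`, and optionally
#'   `realm`, `biome`.
#' @param allowed_basis Accepted values of `basisOfRecord`.
#' @param exclude_taxa Character vector of taxon names to drop.
#' @return The filtered data frame, with an attribute `"rejection_log"`:
#'   named integer vector of removal counts per rule
#'   (`incomplete_name`, `out_of_bounds`, `bad_basis`, `excluded_taxon`,
#'   `duplicate`).
#' @export
clean_occurrences <- function(records,
                              allowed_basis = c("PRESERVED_SPECIMEN",
                                                "LITERATURE",
                                                "MATERIAL_CITATION"),
                              exclude_taxa = character(0)) {
  need <- c("species", "family", "decimalLongitude", "decimalLatitude",
            "basisOfRecord")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    stop("occurrence table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  log <- c(incomplete_name = 0L, out_of_bounds = 0L, bad_basis = 0L,
           excluded_taxon = 0L, duplicate = 0L)
  if (nrow(records) == 0) {
    attr(records, "rejection_log") <- log
    return(records)
  }

  # full binomial: at least two non-empty name parts
  parts <- lengths(strsplit(trimws(as.character(records$species)), "\\s+"))
  ok <- parts >= 2 & !is.na(records$species)
  log["incomplete_name"] <- sum(!ok)
  records <- records[ok, , drop = FALSE]

  lon <- records$decimalLongitude
  lat <- records$decimalLatitude
  ok <- is.finite(lon) & is.finite(lat) &
    lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90
  log["out_of_bounds"] <- sum(!ok)
  records <- records[ok, , drop = FALSE]

  ok <- records$basisOfRecord %in% allowed_basis
  log["bad_basis"] <- sum(!ok)
  records <- records[ok, , drop = FALSE]

  ok <- !(records$species %in% exclude_taxa)
  log["excluded_taxon"] <- sum(!ok)
  records <- records[ok, , drop = FALSE]

  key <- paste(records$species, records$decimalLongitude,
               records$decimalLatitude, sep = "\r")
  ok <- !duplicated(key)
  log["duplicate"] <- sum(!ok)
  records <- records[ok, , drop = FALSE]

  rownames(records) <- NULL
  attr(records, "rejection_log") <- log
  records
}

#' Per-family net diversification rate from richness and age
#'
#' Method-of-moments estimators of the net diversification rate of a clade
#' from its standing richness `n` and age `t`.  The stem estimator is
#' \code{r = log(n(1 - eps) + eps)/t}, which reduces to `log(n)/t` at
#' `eps = 0`; the crown estimator conditions on the basal split into two
#' surviving lineages and reduces to `log(n/2)/t` at `eps = 0`.
#'
#' @param n Species richness (`>= 1`).
#' @param t Clade age in million years (> 0): stem age for the stem
#'   estimator, crown age for the crown estimator.
#' @param estimator `"stem"` (default) or `"crown"`.
#' @param eps Assumed extinction fraction in `[0, 1)` (default 0).
#' @return Numeric vector of rates per million years (non-negative).
#' @examples
#' family_dr(8, 20)                      # log(8)/20
#' family_dr(100, 50, "crown", eps = 0)  # log(50)/50
#' @export
family_dr <- function(n, t, estimator = c("stem", "crown"), eps = 0) {
  estimator <- match.arg(estimator)
  stopifnot(is.numeric(n), is.numeric(t))
  if (any(n < 1)) stop("richness must be >= 1", call. = FALSE)
  if (any(t <= 0)) stop("clade age must be positive", call. = FALSE)
  if (eps < 0 || eps >= 1) stop("'eps' must lie in [0, 1)", call. = FALSE)
  if (estimator == "stem") {
    log(n * (1 - eps) + eps) / t
  } else {
    # crown-clade estimator conditioned on survival of both basal lineages;
    # a crown group has at least two species by definition
    if (any(n < 2)) {
      stop("the crown estimator requires n >= 2", call. = FALSE)
    }
    inner <- n * (1 - eps^2) / 2 + 2 * eps +
      (1 - eps) / 2 * sqrt(n * (n * eps^2 - 8 * eps + 2 * n * eps + n))
    (log(inner) - log(2)) / t
  }
}

#' Mean family diversification rate on a one-degree grid
#'
#' Each occurrence record contributes the diversification rate of its family
#' once; cells are 1 x 1 degree, half-open `[i, i + 1)` in both axes (a
#' record exactly on a cell edge belongs to the cell it opens).  The cell
#' value is the arithmetic mean over contributing records.
#'
#' @param records Cleaned occurrence data frame (see [clean_occurrences()]).
#' @param dr Named numeric vector mapping family name to rate; every family
#'   present in `records` must be covered.
#' @return Data frame with columns `cell_lon`, `cell_lat` (integer cell
#'   origins), `mean_dr`, `n_records`.
#' @export
grid_mean_dr <- function(records, dr) {
  fams <- unique(records$family)
  missing_fam <- setdiff(fams, names(dr))
  if (length(missing_fam) > 0) {
    stop("no diversification rate supplied for: ",
         paste(missing_fam, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0) {
    return(data.frame(cell_lon = integer(0), cell_lat = integer(0),
                      mean_dr = numeric(0), n_records = integer(0)))
  }
  # half-open [i, i+1) cells; the antimeridian wraps into [-180, -179)
  lon <- ifelse(records$decimalLongitude >= 180, -180, records$decimalLongitude)
  lat <- pmin(records$decimalLatitude, 90 - 1e-9)
  cell_lon <- floor(lon)
  cell_lat <- floor(lat)
  val <- unname(dr[records$family])
  key <- paste(cell_lon, cell_lat, sep = ":")
  agg <- tapply(val, key, mean)
  cnt <- tapply(val, key, length)
  parts <- do.call(rbind, strsplit(names(agg), ":", fixed = TRUE))
  out <- data.frame(
    cell_lon = as.integer(parts[, 1]),
    cell_lat = as.integer(parts[, 2]),
    mean_dr = as.numeric(agg),
    n_records = as.integer(cnt)
  )
  out[order(out$cell_lon, out$cell_lat), , drop = FALSE]
}

#' Export a grid as an ASCII raster
#'
#' Writes the cell table from [grid_mean_dr()] in ESRI ASCII grid layout
#' (plain text), covering the bounding box of occupied cells; empty cells
#' get the nodata value.
#'
#' @param grid Data frame from [grid_mean_dr()].
#' @param path Output file path.
#' @param nodata Value used for empty cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  stopifnot(nrow(grid) > 0)
  lon0 <- min(grid$cell_lon); lon1 <- max(grid$cell_lon)
  lat0 <- min(grid$cell_lat); lat1 <- max(grid$cell_lat)
  ncol <- lon1 - lon0 + 1L
  nrow_ <- lat1 - lat0 + 1L
  m <- matrix(nodata, nrow_, ncol)
  # row 1 = northernmost band
  m[cbind(lat1 - grid$cell_lat + 1L, grid$cell_lon - lon0 + 1L)] <- grid$mean_dr
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol), paste("nrows", nrow_),
    paste("xllcorner", lon0), paste("yllcorner", lat0),
    paste("cellsize", 1), paste("NODATA_value", nodata)
  ), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# deterministic subsample used to cap pairwise-distance work for very
# large families (every k-th record, preserving order)
thin_rows <- function(n, cap) {
  if (n <= cap) seq_len(n) else unique(round(seq(1, n, length.out = cap)))
}

#' Realm/biome presence and range summary per family
#'
#' Tallies, per family, the percentage of records in each biogeographic
#' realm and biome, counts the realms/biomes occupied, and applies a
#' deterministic rule set in place of by-eye range assessment:
#' `highly_localized` when all records fit in a single `window_deg` x
#' `window_deg` window; otherwise `localized` with records in one realm,
#' `widespread` with records in `widespread_realms` or more realms, and
#' `cosmopolitan` with `cosmopolitan_realms` or more.  The distribution
#' pattern is `disjunct` when single-linkage clustering of the records on
#' great-circle distance, cut at `gap_km`, yields two or more clusters.
#'
#' @param records Cleaned occurrences with `realm` and `biome` columns;
#'   unlabeled records are counted as unassigned and excluded from the
#'   percentages with a warning.
#' @param realms,biomes Label vocabularies (defaults [teow_realms],
#'   [teow_biomes]).
#' @param window_deg Window size (degrees) for `highly_localized`.
#' @param widespread_realms,cosmopolitan_realms Realm-count thresholds.
#' @param gap_km Great-circle gap (km) defining a disjunction.
#' @param max_points Per-family cap on records used for the pairwise
#'   distance matrix (deterministic thinning).
#' @return Data frame with one row per family: `family`, `n_records`,
#'   `n_realms`, `n_biomes`, `range_class`, `pattern_class`, plus attributes
#'   `"realm_pct"` and `"biome_pct"` (family x label percentage matrices,
#'   rows summing to 100 over labeled records).
#' @export
realm_biome_summary <- function(records,
                                realms = teow_realms, biomes = teow_biomes,
                                window_deg = 10,
                                widespread_realms = 2,
                                cosmopolitan_realms = 4,
                                gap_km = 2000,
                                max_points = 400) {
  need <- c("family", "decimalLongitude", "decimalLatitude", "realm", "biome")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    stop("occurrence table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unlabeled <- is.na(records$realm) | is.na(records$biome)
  if (any(unlabeled)) {
    warning(sum(unlabeled), " unlabeled record(s) excluded from percentages",
            call. = FALSE)
  }
  fams <- sort(unique(records$family))
  realm_pct <- matrix(0, length(fams), length(realms),
                      dimnames = list(fams, realms))
  biome_pct <- matrix(0, length(fams), length(biomes),
                      dimnames = list(fams, biomes))
  rows <- vector("list", length(fams))
  for (fi in seq_along(fams)) {
    rec <- records[records$family == fams[fi], , drop = FALSE]
    lab <- rec[!(is.na(rec$realm) | is.na(rec$biome)), , drop = FALSE]
    if (nrow(lab) > 0) {
      rp <- 100 * table(factor(lab$realm, levels = realms)) / nrow(lab)
      bp <- 100 * table(factor(lab$biome, levels = biomes)) / nrow(lab)
      realm_pct[fi, ] <- as.numeric(rp)
      biome_pct[fi, ] <- as.numeric(bp)
    }
    n_realms <- sum(realm_pct[fi, ] > 0)
    n_biomes <- sum(biome_pct[fi, ] > 0)

    lon <- rec$decimalLongitude
    lat <- rec$decimalLatitude
    lon_span <- diff(range(lon))
    lat_span <- diff(range(lat))
    range_class <- if (lon_span <= window_deg && lat_span <= window_deg) {
      "highly_localized"
    } else if (n_realms >= cosmopolitan_realms) {
      "cosmopolitan"
    } else if (n_realms >= widespread_realms) {
      "widespread"
    } else {
      "localized"
    }

    pattern_class <- "continuous"
    if (nrow(rec) >= 2) {
      idx <- thin_rows(nrow(rec), max_points)
      pts <- cbind(lon[idx], lat[idx])
      d <- geosphere::distm(pts, fun = geosphere::distHaversine) / 1000
      hc <- stats::hclust(stats::as.dist(d), method = "single")
      k <- sum(hc$height > gap_km) + 1L
      if (k >= 2L) pattern_class <- "disjunct"
    }
    rows[[fi]] <- data.frame(
      family = fams[fi], n_records = nrow(rec),
      n_realms = n_realms, n_biomes = n_biomes,
      range_class = range_class, pattern_class = pattern_class,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "realm_pct") <- realm_pct
  attr(out, "biome_pct") <- biome_pct
  out
}
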