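#' Read a family richness/age table
#'
#' Reads a delimited text table (comma or tab, autodetected) with at least the
#' columns `family`, `richness`, and `age`.  Richness cells given as a range
#' (`"10-20"`, `"10–20"`, or `"10 to 20"`) are resolved to their mean,
#' rounded half-up to an integer.  Ages are crown ages in million years.
#'
#' @param path Path to the delimited text file (UTF-8).
#' @param dataset_id Label of the source dataset (e.g. the study the crown
#'   ages come from); stored in the `dataset` column.
#' @return A data frame with columns `family` (character), `richness`
#'   (integer), `age` (numeric, My), `dataset`, and `age_source` (one of
#'   `"observed"`, `"sister_imputed"`, `"stem_imputed"`; read from the file
#'   when an `age_source` column is present, `"observed"` otherwise).
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("family,richness,age",
#'              "Amborellaceae,1,132",
#'              "Poaceae,10-20,75"), tf)
#' read_family_table(tf, "demo")
#' @export
read_family_table <- function(path, dataset_id) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  stopifnot(is.character(dataset_id), length(dataset_id) == 1L)
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, encoding = "UTF-8",
                           comment.char = "", quote = "\"")
  required <- c("family", "richness", "age")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("family table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dup <- unique(raw$family[duplicated(raw$family)])
  if (length(dup) > 0) {
    stop("duplicated family rows within dataset '", dataset_id, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  richness <- parse_richness(as.character(raw$richness))
  age <- as.numeric(raw$age)
  if (anyNA(age)) stop("non-numeric age values in family table", call. = FALSE)
  bad_age <- which(age <= 0)
  if (length(bad_age) > 0) {
    stop("non-positive crown age for: ",
         paste(raw$family[bad_age], collapse = ", "), call. = FALSE)
  }
  src <- if ("age_source" %in% names(raw)) as.character(raw$age_source) else
    rep("observed", nrow(raw))
  ok_src <- c("observed", "sister_imputed", "stem_imputed")
  if (!all(src %in% ok_src)) {
    stop("age_source values must be one of: ", paste(ok_src, collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    family = as.character(raw$family),
    richness = richness,
    age = age,
    dataset = dataset_id,
    age_source = src,
    stringsAsFactors = FALSE
  )
}

#' Write a family table as delimited text
#'
#' Inverse of [read_family_table()]: writing then re-reading reproduces the
#' records.
#'
#' @param records Data frame as returned by [read_family_table()].
#' @param path Output file path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_family_table <- function(records, path, sep = ",") {
  cols <- intersect(c("family", "richness", "age", "age_source"), names(records))
  utils::write.table(records[, cols], path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Resolve richness cells: plain integers pass through; "a-b", "a–b" and
# "a to b" ranges become the mean, rounded half-up.
parse_richness <- function(x) {
  x <- trimws(x)
  rng <- regmatches(
    x,
    regexec("^([0-9]+)\\s*(?:-|–|to)\\s*([0-9]+)$", x)
  )
  out <- vapply(seq_along(x), function(i) {
    if (length(rng[[i]]) == 3L) {
      a <- as.numeric(rng[[i]][2L])
      b <- as.numeric(rng[[i]][3L])
      floor((a + b) / 2 + 0.5)  # round half-up
    } else {
      suppressWarnings(as.numeric(x[i]))
    }
  }, numeric(1))
  if (anyNA(out)) {
    stop("unparseable richness value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  if (any(out < 1)) stop("richness must be >= 1", call. = FALSE)
  as.integer(out)
}

#' Extract family crown ages from an ultrametric tree
#'
#' For every family with two or more assigned tips, the crown age is the
#' height above the present of the most recent common ancestor of its tips.
#' A family represented by a single tip gets its stem age (the height of the
#' node the tip hangs from, i.e. its terminal branch length on an ultrametric
#' tree) and is flagged `stem_imputed`.
#'
#' @param tree An [ape::read.tree()] `phylo` object with branch lengths;
#'   must be ultrametric (relative tip-height spread at most `tol` of tree
#'   depth).
#' @param tip_to_family Data frame with columns `tip` and `family`, or a
#'   named character vector `tip -> family`.  Tips absent from the map are
#'   dropped with a warning.
#' @param tol Relative ultrametricity tolerance (default `1e-6`).
#' @return Data frame with columns `family`, `age`, `age_source`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' extract_crown_ages(tr, data.frame(tip = c("A", "B", "C"),
#'                                   family = c("F", "F", "G")))
#' @export
extract_crown_ages <- function(tree, tip_to_family, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (is.data.frame(tip_to_family)) {
    stopifnot(all(c("tip", "family") %in% names(tip_to_family)))
    map <- stats::setNames(as.character(tip_to_family$family),
                           as.character(tip_to_family$tip))
  } else {
    map <- tip_to_family
  }

  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)  # distance from root
  tip_depth <- depth[seq_len(ntip)]
  total <- max(tip_depth)
  if (total <= 0) stop("tree depth is zero", call. = FALSE)
  if ((max(tip_depth) - min(tip_depth)) / total > tol) {
    stop("tree is not ultrametric within tolerance; ",
         "linearize it before extracting crown ages", call. = FALSE)
  }

  unmapped <- setdiff(tree$tip.label, names(map))
  if (length(unmapped) > 0) {
    warning("tips without a family assignment excluded: ",
            paste(unmapped, collapse = ", "), call. = FALSE)
  }
  fams <- unique(unname(map[intersect(names(map), tree$tip.label)]))
  if (length(fams) == 0) stop("no tips could be assigned to a family", call. = FALSE)

  height <- total - depth  # node height above the present
  rows <- lapply(fams, function(f) {
    tips <- intersect(names(map)[map == f], tree$tip.label)
    if (length(tips) >= 2L) {
      mrca <- ape::getMRCA(tree, tips)
      data.frame(family = f, age = height[mrca], age_source = "observed",
                 stringsAsFactors = FALSE)
    } else {
      tip_id <- match(tips, tree$tip.label)
      parent <- tree$edge[tree$edge[, 2] == tip_id, 1]
      data.frame(family = f, age = height[parent], age_source = "stem_imputed",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Impute missing crown ages from proxy (sister) families
#'
#' Families without an age in a dataset borrow the age of a designated proxy
#' family, typically the sister clade in the reference classification.  The
#' map must be one step deep: a proxy may not itself be a family listed for
#' imputation (chains and cycles are rejected), and every proxy must have an
#' observed age in the dataset.
#'
#' @param records Family table (one dataset) as from [read_family_table()];
#'   families needing imputation are rows with `NA` age or absent rows named
#'   in the map.
#' @param imputation_map Data frame with columns `family`, `proxy`, and
#'   optionally `mode` (`"sister_crown"` default, or `"stem"`).
#' @return The records with every mapped family assigned an age and its
#'   `age_source` set to `sister_imputed` (or `stem_imputed` for mode
#'   `"stem"`).
#' @export
impute_missing_ages <- function(records, imputation_map) {
  if (is.null(imputation_map) || nrow(imputation_map) == 0) return(records)
  stopifnot(all(c("family", "proxy") %in% names(imputation_map)))
  imap <- imputation_map
  if (!"mode" %in% names(imap)) imap$mode <- "sister_crown"
  if (any(imap$family == imap$proxy)) {
    stop("a family cannot be its own age proxy", call. = FALSE)
  }
  chained <- intersect(imap$proxy, imap$family)
  if (length(chained) > 0) {
    stop("imputation chains/cycles are not allowed; proxies that are ",
         "themselves imputed: ", paste(chained, collapse = ", "), call. = FALSE)
  }
  have_age <- records$family[!is.na(records$age)]
  missing_proxy <- setdiff(imap$proxy, have_age)
  if (length(missing_proxy) > 0) {
    stop("proxy families without an observed age: ",
         paste(missing_proxy, collapse = ", "), call. = FALSE)
  }

  for (k in seq_len(nrow(imap))) {
    fam <- imap$family[k]
    proxy_age <- records$age[records$family == imap$proxy[k]][1]
    src <- if (imap$mode[k] == "stem") "stem_imputed" else "sister_imputed"
    i <- which(records$family == fam)
    if (length(i) == 0) {
      records <- rbind(records, data.frame(
        family = fam, richness = NA_integer_, age = proxy_age,
        dataset = records$dataset[1], age_source = src,
        stringsAsFactors = FALSE
      ))
    } else if (is.na(records$age[i])) {
      records$age[i] <- proxy_age
      records$age_source[i] <- src
    }
  }
  records
}

#' Categorize family mating/sexual systems from species proportions
#'
#' A family is `Dioecious` only when every scored species is dioecious;
#' otherwise `SC` when more than 80\% of scored species are self-compatible,
#' `SI` when more than 80\% are self-incompatible or self-sterile, and
#' `SC-SI` when the self-incompatible fraction lies between 20\% and 80\%
#' (boundary values 0.2 and 0.8 fall in `SC-SI`).  Families with no scored
#' species -- or proportions matching none of the rules -- are `Unknown`.
#'
#' @param prop_sc Proportion of scored species that are self-compatible.
#' @param prop_si_or_ss Proportion self-incompatible or self-sterile.
#' @param prop_dioecious Proportion dioecious.
#' @param n_scored Number of species scored per family.
#' @return Character vector of labels in
#'   `{"Dioecious", "SC", "SC-SI", "SI", "Unknown"}`; every family receives
#'   exactly one label.
#' @examples
#' categorize_mating_system(0.4, 0.5, 0, 12)   # "SC-SI"
#' categorize_mating_system(0, 0, 1, 3)        # "Dioecious"
#' @export
categorize_mating_system <- function(prop_sc, prop_si_or_ss, prop_dioecious,
                                     n_scored) {
  k <- max(length(prop_sc), length(prop_si_or_ss), length(prop_dioecious),
           length(n_scored))
  prop_sc <- rep_len(prop_sc, k)
  prop_si <- rep_len(prop_si_or_ss, k)
  prop_d <- rep_len(prop_dioecious, k)
  n <- rep_len(n_scored, k)
  tol <- 1e-8
  if (any(prop_sc + prop_si > 1 + 1e-6, na.rm = TRUE)) {
    stop("prop_sc + prop_si_or_ss exceeds 1", call. = FALSE)
  }
  out <- character(k)
  for (i in seq_len(k)) {
    out[i] <- if (is.na(n[i]) || n[i] == 0) {
      "Unknown"
    } else if (!is.na(prop_d[i]) && prop_d[i] >= 1 - tol) {
      "Dioecious"
    } else if (prop_sc[i] > 0.8 + tol) {
      "SC"
    } else if (prop_si[i] > 0.8 + tol) {
      "SI"
    } else if (prop_si[i] >= 0.2 - tol) {
      "SC-SI"
    } else {
      "Unknown"
    }
  }
  out
}
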