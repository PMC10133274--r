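#' Assemble aggregated weak-supervision examples
#'
#' Groups pixels by (crop, district, year): every yield record that has at
#' least one cultivated pixel becomes one example holding the n x F block of
#' that group's pixel covariates and the single district-level yield label.
#' This is the unit of weak supervision — the label is a mean over the
#' group, never a per-pixel value.
#'
#' @param grids named list (by year) of `feature_grid`s.
#' @param partition a `district_partition` (or named list per period; a
#'   single partition is applied to all years).
#' @param assignments named list (by year) of `crop_assignment`s.
#' @param yields a `yield_table`.
#' @param max_group_pixels cap on pixels per group; oversized groups are
#'   downsampled uniformly without replacement (seeded) with a warning.
#'   `Inf` (default) disables the cap.
#' @param seed seed used only for the downsampling draw.
#' @return list of `agg_example`s, each with fields `crop`, `crop_index`,
#'   `district`, `year`, `features` (n x F), `label`, `n`,
#'   `standardized = FALSE`.
#' @export
build_examples <- function(grids, partition, assignments, yields,
                           max_group_pixels = Inf, seed = 1L) {
  if (max_group_pixels < 1) stop("max_group_pixels must be >= 1 (or Inf)")
  years <- names(grids)
  if (!identical(years, names(assignments)))
    stop("grids and assignments must cover the same years")
  part_for <- function(year) {
    if (inherits(partition, "district_partition")) partition
    else partition[[year]]
  }
  examples <- list()
  skipped <- 0L; capped <- 0L
  rs <- as.integer(seed)
  for (i in seq_len(nrow(yields))) {
    rec <- yields[i, ]
    yr <- as.character(rec$year)
    g <- grids[[yr]]; a <- assignments[[yr]]; p <- part_for(yr)
    if (is.null(g) || is.null(a) || is.null(p))
      stop("no rasters for year ", yr, " referenced by a yield record")
    ci <- match(rec$crop, a$crop_names)
    if (is.na(ci)) stop("crop '", rec$crop, "' absent from crop list")
    px <- which(!is.na(a$assignment) & a$assignment == ci &
                  !is.na(p$assignment) & p$assignment == rec$district &
                  !g$nodata_mask)
    if (length(px) == 0L) { skipped <- skipped + 1L; next }
    if (length(px) > max_group_pixels) {
      capped <- capped + 1L
      px <- with_seed(rs + i, sort(sample(px, max_group_pixels)))
    }
    dm <- dim(g$values)
    feat <- matrix(g$values, dm[1] * dm[2], dm[3])[px, , drop = FALSE]
    examples[[length(examples) + 1L]] <- structure(
      list(crop = rec$crop, crop_index = ci, district = rec$district,
           year = rec$year, features = feat, label = rec$yield,
           n = length(px), pixels = px, standardized = FALSE),
      class = "agg_example")
  }
  if (skipped > 0L)
    warning(skipped, " yield record(s) skipped: no cultivated pixels in group")
  if (capped > 0L)
    warning(capped, " group(s) downsampled to max_group_pixels = ",
            max_group_pixels)
  examples
}

#' Fit a feature/label standardizer
#'
#' Computes per-feature means and standard deviations over all pixel rows of
#' the supplied (training) examples, and mean/sd of the supplied labels.
#' Sample (n-1) standard deviations are used throughout.
#'
#' @param examples list of `agg_example`s (raw physical units).
#' @return A `standardizer` with `feature_means`, `feature_sds`,
#'   `label_mean`, `label_sd`.
#' @export
fit_standardizer <- function(examples) {
  if (length(examples) < 1L) stop("need at least one example")
  x <- do.call(rbind, lapply(examples, `[[`, "features"))
  y <- vapply(examples, `[[`, numeric(1), "label")
  if (length(y) < 2L) stop("need >= 2 labels to standardize the yield")
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  bad <- which(!is.finite(sdv) | sdv <= 0)
  if (length(bad))
    stop("zero variance in feature(s): ", paste(bad, collapse = ", "))
  ls <- sd(y)
  if (!is.finite(ls) || ls <= 0) stop("zero variance in labels")
  structure(list(feature_means = mu, feature_sds = sdv,
                 label_mean = mean(y), label_sd = ls),
            class = "standardizer")
}

#' Apply (or invert) a standardizer
#'
#' Affine per-feature and per-label transform. `direction = "forward"` maps
#' physical units to the zero-mean/unit-sd training scale;
#' `"inverse"` undoes it exactly.
#'
#' @param x list of `agg_example`s, a `feature_grid`, or a numeric matrix of
#'   pixel features.
#' @param standardizer a fitted `standardizer`.
#' @param direction `"forward"` or `"inverse"`.
#' @param what for bare matrices/vectors: `"features"` or `"label"`.
#' @return the transformed object, same shape as the input.
#' @export
apply_standardizer <- function(x, standardizer,
                               direction = c("forward", "inverse"),
                               what = c("features", "label")) {
  direction <- match.arg(direction)
  what <- match.arg(what)
  fwd <- direction == "forward"
  tr_feat <- function(m) {
    if (ncol(m) != length(standardizer$feature_means))
      stop("feature dimension mismatch")
    if (fwd)
      sweep(sweep(m, 2, standardizer$feature_means), 2,
            standardizer$feature_sds, "/")
    else
      sweep(sweep(m, 2, standardizer$feature_sds, "*"), 2,
            standardizer$feature_means, "+")
  }
  tr_lab <- function(v) {
    if (fwd) (v - standardizer$label_mean) / standardizer$label_sd
    else v * standardizer$label_sd + standardizer$label_mean
  }
  if (is.list(x) && length(x) && inherits(x[[1]], "agg_example")) {
    lapply(x, function(ex) {
      ex$features <- tr_feat(ex$features)
      ex$label <- tr_lab(ex$label)
      ex$standardized <- fwd
      ex
    })
  } else if (inherits(x, "feature_grid")) {
    dm <- dim(x$values)
    m <- tr_feat(matrix(x$values, dm[1] * dm[2], dm[3]))
    x$values <- array(m, dm)
    x
  } else if (is.matrix(x)) {
    if (what == "features") tr_feat(x) else tr_lab(x)
  } else if (is.numeric(x)) {
    tr_lab(x)
  } else stop("unsupported input to apply_standardizer")
}

#' Plan district-held-out cross-validation folds
#'
#' Builds `k` folds, each holding out `districts_per_fold` districts drawn
#' from the districts eligible in all periods. Validation examples of a fold
#' are exactly those whose district is held out; its training set never
#' contains them. Districts are drawn without replacement and without reuse
#' across folds until the eligible pool is exhausted, after which the pool
#' resets (so more than `eligible / districts_per_fold` folds are possible).
#'
#' @param examples list of `agg_example`s (used to flag crops with no
#'   validation observation in a fold as unevaluable there).
#' @param k number of folds (>= 2).
#' @param districts_per_fold districts held out per fold (default 4).
#' @param seed integer seed.
#' @param eligible_districts optional explicit pool; defaults to all
#'   districts appearing in `examples`.
#' @return A `fold_plan`: `k`, `folds` (list of district-id vectors),
#'   `eligible_districts`, and `unevaluable` (per fold, crops with no
#'   validation record).
#' @export
split_by_district <- function(examples, k, districts_per_fold = 4L, seed,
                              eligible_districts = NULL) {
  if (k < 2) stop("k must be >= 2")
  dists <- vapply(examples, `[[`, numeric(1), "district")
  crops <- vapply(examples, `[[`, character(1), "crop")
  if (is.null(eligible_districts))
    eligible_districts <- sort(unique(dists))
  if (length(eligible_districts) < districts_per_fold)
    stop("fewer eligible districts than districts_per_fold")
  folds <- with_seed(seed, {
    pool <- sample(eligible_districts)
    out <- vector("list", k)
    for (f in seq_len(k)) {
      if (length(pool) < districts_per_fold)
        pool <- sample(eligible_districts)   # pool reset
      out[[f]] <- sort(pool[seq_len(districts_per_fold)])
      pool <- pool[-seq_len(districts_per_fold)]
    }
    out
  })
  all_crops <- sort(unique(crops))
  unevaluable <- lapply(folds, function(vd) {
    setdiff(all_crops, unique(crops[dists %in% vd]))
  })
  structure(list(k = as.integer(k), folds = folds,
                 eligible_districts = eligible_districts,
                 districts_per_fold = as.integer(districts_per_fold),
                 unevaluable = unevaluable, seed = as.integer(seed)),
            class = "fold_plan")
}
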