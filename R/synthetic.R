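#' @importFrom stats rnorm runif sd dnorm
NULL

# Internal: run a computation under a local, restorable RNG state so that
# generators are bit-reproducible per seed without clobbering the caller's
# stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  # pin the generator kind so results do not depend on ambient RNGkind
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

#' Generate a spatially autocorrelated covariate grid
#'
#' Simulates `n_features` soil-climate-landscape covariates on an `height` x
#' `width` pixel lattice. Each feature starts as white noise, is smoothed
#' with an isotropic Gaussian kernel of standard deviation
#' `correlation_length` (in pixels, reflection padding at the edges), and is
#' then rescaled to mean 0 and standard deviation 1 across the lattice.
#' `correlation_length = 0` leaves the white noise unsmoothed.
#'
#' @param height,width lattice dimensions in pixels (>= 1).
#' @param n_features number of covariates per pixel (default 16).
#' @param correlation_length Gaussian smoothing scale in pixels (>= 0).
#' @param seed integer seed; identical arguments and seed give bit-identical
#'   output.
#' @param year calendar year tag carried as metadata.
#' @param pixel_size numeric length-2 (height_m, width_m) pixel footprint;
#'   default 300 x 500 m.
#' @return A `feature_grid`: list with `year`, `values` (H x W x F array),
#'   `pixel_size`, and `nodata_mask` (H x W logical, all `FALSE` here).
#' @export
generate_feature_grid <- function(height, width, n_features = 16L,
                                  correlation_length = 0, seed,
                                  year = 2013L,
                                  pixel_size = c(300, 500)) {
  if (height < 1 || width < 1) stop("grid dimensions must be >= 1")
  if (n_features < 1) stop("n_features must be >= 1")
  if (correlation_length < 0) stop("correlation_length must be >= 0")
  if (any(pixel_size <= 0)) stop("pixel_size components must be > 0")
  vals <- with_seed(seed, {
    arr <- array(rnorm(height * width * n_features),
                 dim = c(height, width, n_features))
    if (correlation_length > 0) {
      for (f in seq_len(n_features))
        arr[, , f] <- gaussian_blur(arr[, , f, drop = TRUE],
                                    correlation_length)
    }
    arr
  })
  # enforce per-feature mean 0, sd 1 (smoothing shrinks the variance)
  for (f in seq_len(n_features)) {
    v <- vals[, , f]
    vals[, , f] <- (v - mean(v)) / sd(v)
  }
  structure(list(year = as.integer(year), values = vals,
                 pixel_size = pixel_size,
                 nodata_mask = matrix(FALSE, height, width)),
            class = "feature_grid")
}

# Separable Gaussian convolution with reflected edges.
gaussian_blur <- function(m, len) {
  r <- max(1L, ceiling(3 * len))
  k <- dnorm(seq(-r, r), sd = len)
  k <- k / sum(k)
  refl <- function(i, n) {  # reflect any index into 1..n (period 2n-2)
    if (n == 1L) return(rep(1L, length(i)))
    j <- (i - 1L) %% (2L * n - 2L)
    ifelse(j < n, j + 1L, 2L * n - j - 1L)
  }
  blur1 <- function(x) {  # columns of x smoothed
    n <- nrow(x)
    pad <- x[refl(seq.int(1L - r, n + r), n), , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (j in seq_along(k))
      out <- out + k[j] * pad[j:(j + n - 1), , drop = FALSE]
    out
  }
  t(blur1(t(blur1(m))))
}

#' Partition the pixel lattice into districts
#'
#' Nearest-seed (Voronoi-style) partition: `n_districts` seed pixels are
#' drawn uniformly without replacement and every pixel joins the district of
#' its nearest seed (squared Euclidean distance on row/column indices; ties
#' go to the lowest district id). Emulates the large administrative
#' reporting districts over which yields are published.
#'
#' @param grid a `feature_grid` defining the lattice.
#' @param n_districts number of districts, `1 <= n_districts <= H*W`.
#' @param seed integer seed.
#' @param period label for the period these boundaries are valid for.
#' @return A `district_partition`: list with `period`, `assignment`
#'   (H x W integer matrix of district ids 1..n, `NA` for unassigned) and
#'   `district_ids`.
#' @export
generate_districts <- function(grid, n_districts, seed, period = "P1") {
  h <- dim(grid$values)[1]; w <- dim(grid$values)[2]
  if (n_districts < 1 || n_districts > h * w)
    stop("n_districts must be between 1 and the pixel count")
  seeds <- with_seed(seed, sample.int(h * w, n_districts))
  sr <- (seeds - 1L) %% h + 1L
  sc <- (seeds - 1L) %/% h + 1L
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  best <- matrix(1L, h, w)
  bestd <- (rows - sr[1])^2 + (cols - sc[1])^2
  if (n_districts > 1) for (d in 2:n_districts) {
    dd <- (rows - sr[d])^2 + (cols - sc[d])^2
    upd <- dd < bestd
    best[upd] <- d
    bestd[upd] <- dd[upd]
  }
  structure(list(period = period, assignment = best,
                 district_ids = seq_len(n_districts)),
            class = "district_partition")
}

#' Define the synthetic ground truth for per-pixel crop response
#'
#' Draws one smooth response function per crop mapping the F covariates to an
#' expected pixel yield (bushels/acre):
#' `yield_c(x) = max(0, offset_c + gain * x . w_c)`. Crop weight vectors are
#' built as `w_c = sqrt(rho) * w_shared + sqrt(1 - rho) * e_c`, so their
#' pairwise correlation rises with the cross-crop correlation knob `rho`
#' (crops that grow under similar conditions share response structure).
#' The clamp at 0 keeps expected yields physical; with the default offset
#' and gain it is essentially never active.
#'
#' @param n_crops number of crops (>= 1).
#' @param n_features covariate dimension F.
#' @param cross_crop_correlation rho in [0, 1].
#' @param label_noise_sd Gaussian noise sd added to district labels
#'   (bushels/acre, >= 0).
#' @param selection_sharpness softmax sharpness (>= 0) biasing crop
#'   placement toward pixels where the crop's true yield is high; 0 means
#'   placement ignores suitability.
#' @param seed integer seed.
#' @param offset_range uniform range the per-crop offsets are drawn from.
#' @param gain scale of the covariate effect (bushels/acre per sd of the
#'   linear index).
#' @param curvature weight of an optional quadratic term: each crop also
#'   gets a second direction `v_c` (same cross-crop correlation structure)
#'   contributing `curvature * gain * ((x . v_c)^2 - 1)`. 0 (default) keeps
#'   the response linear; positive values give a smooth non-monotone
#'   response surface closer to real yield response.
#' @param crop_names optional character vector of length `n_crops`.
#' @return A `synthetic_truth`: weights (F x C), offsets (C), gain, the three
#'   knobs, and crop names.
#' @export
define_truth <- function(n_crops, n_features = 16L,
                         cross_crop_correlation = 0,
                         label_noise_sd = 0,
                         selection_sharpness = 0,
                         seed,
                         offset_range = c(50, 70),
                         gain = 10,
                         curvature = 0,
                         crop_names = NULL) {
  if (n_crops < 1) stop("n_crops must be >= 1")
  if (cross_crop_correlation < 0 || cross_crop_correlation > 1)
    stop("cross_crop_correlation must lie in [0, 1]")
  if (label_noise_sd < 0) stop("label_noise_sd must be >= 0")
  if (selection_sharpness < 0) stop("selection_sharpness must be >= 0")
  rho <- cross_crop_correlation
  out <- with_seed(seed, {
    draw_cor <- function() {
      shared <- rnorm(n_features, sd = 1 / sqrt(n_features))
      m <- matrix(0, n_features, n_crops)
      for (c in seq_len(n_crops))
        m[, c] <- sqrt(rho) * shared +
          sqrt(1 - rho) * rnorm(n_features, sd = 1 / sqrt(n_features))
      m
    }
    w <- draw_cor()
    v <- draw_cor()
    offs <- runif(n_crops, offset_range[1], offset_range[2])
    list(w = w, v = v, offs = offs)
  })
  if (is.null(crop_names))
    crop_names <- paste0("crop", seq_len(n_crops))
  structure(list(weights = out$w, weights2 = out$v,
                 offsets = out$offs, gain = gain, curvature = curvature,
                 cross_crop_correlation = rho,
                 label_noise_sd = label_noise_sd,
                 selection_sharpness = selection_sharpness,
                 crop_names = crop_names),
            class = "synthetic_truth")
}

#' Evaluate the true expected pixel yields on a grid
#'
#' @param truth a `synthetic_truth`.
#' @param grid a `feature_grid` with matching feature dimension.
#' @return H x W x C array of expected yields (bushels/acre, >= 0).
#' @export
true_yield <- function(truth, grid) {
  dm <- dim(grid$values)
  if (dm[3] != nrow(truth$weights))
    stop("feature dimension of grid and truth differ")
  x <- matrix(grid$values, dm[1] * dm[2], dm[3])
  y <- truth$gain * (x %*% truth$weights)
  cv <- truth$curvature %||% 0
  if (cv > 0)
    y <- y + cv * truth$gain * ((x %*% truth$weights2)^2 - 1)
  y <- sweep(y, 2, truth$offsets, "+")
  y[y < 0] <- 0
  array(y, dim = c(dm[1], dm[2], ncol(truth$weights)))
}

#' Assign crops to cultivated pixels
#'
#' Marks approximately `cultivated_fraction` of the pixels as cultivated
#' (uniform draw) and gives each cultivated pixel exactly one crop, sampled
#' with probability `softmax(selection_sharpness * true_yield)` across crops.
#' Sharpness 0 gives a uniform crop choice; large sharpness concentrates on
#' the argmax-yield crop. This reproduces the central observational confound
#' of the problem: crops are observed only where someone chose to grow them,
#' and that choice favours suitable land.
#'
#' @param grid a `feature_grid`.
#' @param truth a `synthetic_truth` (supplies yields and sharpness).
#' @param cultivated_fraction fraction of pixels cultivated, in [0, 1].
#' @param seed integer seed.
#' @return A `crop_assignment`: `year`, `assignment` (H x W integer crop
#'   index 1..C, `NA` where uncultivated), `crop_names`.
#' @export
assign_crops <- function(grid, truth, cultivated_fraction, seed) {
  if (cultivated_fraction < 0 || cultivated_fraction > 1)
    stop("cultivated_fraction must lie in [0, 1]")
  dm <- dim(grid$values)
  n <- dm[1] * dm[2]
  yt <- matrix(true_yield(truth, grid), n, length(truth$crop_names))
  asg <- with_seed(seed, {
    a <- rep(NA_integer_, n)
    ncult <- round(cultivated_fraction * n)
    if (ncult > 0) {
      cult <- sample.int(n, ncult)
      s <- truth$selection_sharpness
      z <- s * yt[cult, , drop = FALSE]
      z <- z - apply(z, 1, max)          # softmax, overflow-safe
      p <- exp(z); p <- p / rowSums(p)
      u <- runif(ncult)
      cum <- t(apply(p, 1, cumsum))
      pick <- as.integer(1L + rowSums(cum < u))  # inverse-cdf draw per pixel
      pick[pick > ncol(yt)] <- ncol(yt)
      a[cult] <- pick
    }
    a
  })
  structure(list(year = grid$year,
                 assignment = matrix(asg, dm[1], dm[2]),
                 crop_names = truth$crop_names),
            class = "crop_assignment")
}

#' Observe district-level yield labels
#'
#' For every (crop, district) pair with at least one cultivated pixel, emits
#' one record whose yield equals the mean of the true pixel yields over that
#' group plus Gaussian noise (sd `truth$label_noise_sd`), truncated at 0.
#' This is exactly the aggregation assumption under which the model is
#' trained: the published district yield is the mean over the crop's
#' cultivated pixels.
#'
#' @param grid a `feature_grid`.
#' @param partition a `district_partition` on the same lattice.
#' @param assignment a `crop_assignment` for the same year.
#' @param truth a `synthetic_truth`.
#' @param seed integer seed for the label noise.
#' @return A `yield_table` data.frame with columns
#'   `crop`, `year`, `district`, `yield`; (crop, year, district) unique.
#' @export
observe_district_yields <- function(grid, partition, assignment, truth, seed) {
  if (!identical(dim(partition$assignment), dim(assignment$assignment)))
    stop("partition and crop assignment lattices differ")
  yt <- true_yield(truth, grid)
  h <- dim(yt)[1]; w <- dim(yt)[2]
  dist <- as.vector(partition$assignment)
  crop <- as.vector(assignment$assignment)
  recs <- with_seed(seed, {
    out <- list()
    for (ci in seq_along(truth$crop_names)) {
      ymat <- as.vector(yt[, , ci])
      for (d in sort(partition$district_ids)) {
        px <- which(!is.na(crop) & crop == ci & !is.na(dist) & dist == d)
        if (length(px) == 0L) next
        lab <- mean(ymat[px]) +
          if (truth$label_noise_sd > 0) rnorm(1, 0, truth$label_noise_sd) else 0
        out[[length(out) + 1L]] <- data.frame(
          crop = truth$crop_names[ci], year = grid$year,
          district = d, yield = max(0, lab))
      }
    }
    out
  })
  tab <- if (length(recs)) do.call(rbind, recs) else
    data.frame(crop = character(), year = integer(),
               district = integer(), yield = numeric())
  class(tab) <- c("yield_table", "data.frame")
  tab
}

#' Simulate a complete synthetic study bundle
#'
#' Convenience wrapper generating, for each requested year, a covariate grid
#' and crop assignment on a shared district partition, plus the pooled yield
#' table and the ground truth — everything the downstream dataset, training,
#' evaluation and mapping stages consume.
#'
#' @param height,width lattice size.
#' @param n_features covariate dimension (default 16).
#' @param n_crops number of crops.
#' @param n_districts number of districts.
#' @param years integer vector of years to simulate.
#' @param correlation_length spatial smoothing scale (pixels).
#' @param cross_crop_correlation,label_noise_sd,selection_sharpness
#'   ground-truth knobs, see [define_truth()].
#' @param cultivated_fraction fraction of pixels cultivated each year.
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @param crop_names optional crop names.
#' @param ... further arguments passed to [define_truth()]
#'   (`offset_range`, `gain`).
#' @return list with `grids` (per year), `partition`, `assignments`
#'   (per year), `yields` (pooled `yield_table`), `truth`, `seed`.
#' @export
simulate_bundle <- function(height = 32, width = 32, n_features = 16L,
                            n_crops = 6L, n_districts = 12L,
                            years = 2013:2015,
                            correlation_length = 2,
                            cross_crop_correlation = 0.5,
                            label_noise_sd = 0,
                            selection_sharpness = 0,
                            cultivated_fraction = 0.5,
                            seed = 1L, crop_names = NULL, ...) {
  base <- as.integer(seed) %% 1000000L
  truth <- define_truth(n_crops, n_features,
                        cross_crop_correlation, label_noise_sd,
                        selection_sharpness, seed = base + 11L,
                        crop_names = crop_names, ...)
  grids <- list(); assignments <- list(); ytabs <- list()
  g0 <- generate_feature_grid(height, width, n_features,
                              correlation_length, seed = base + 23L,
                              year = years[1])
  partition <- generate_districts(g0, n_districts, seed = base + 31L)
  for (i in seq_along(years)) {
    g <- generate_feature_grid(height, width, n_features,
                               correlation_length,
                               seed = base + 23L + 101L * (i - 1L),
                               year = years[i])
    a <- assign_crops(g, truth, cultivated_fraction,
                      seed = base + 57L + 101L * (i - 1L))
    y <- observe_district_yields(g, partition, a, truth,
                                 seed = base + 83L + 101L * (i - 1L))
    grids[[i]] <- g; assignments[[i]] <- a; ytabs[[i]] <- y
  }
  names(grids) <- names(assignments) <- as.character(years)
  yields <- do.call(rbind, ytabs)
  class(yields) <- c("yield_table", "data.frame")
  list(grids = grids, partition = partition, assignments = assignments,
       yields = yields, truth = truth, seed = seed)
}
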