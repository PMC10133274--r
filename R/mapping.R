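#' Predict suitability maps for every crop
#'
#' Applies the fitted model to each year's covariate grid and averages the
#' per-pixel predictions across years, giving one map per crop that
#' represents the current predicted state of land suitability (expected
#' attainable yield, bushels/acre). A pixel that is nodata in any year is
#' nodata in the average (propagation, not skipping).
#'
#' @param model fitted `multicrop_model`.
#' @param feature_grids_by_year list of `feature_grid`s on one lattice.
#' @return named list (by crop) of `suitability_map`s: `crop`, `values`
#'   (H x W, `NA` = nodata), `years_averaged`, `mask_applied`, `nodata`.
#' @export
predict_suitability <- function(model, feature_grids_by_year) {
  if (length(feature_grids_by_year) < 1L) stop("need at least one year")
  dims <- lapply(feature_grids_by_year, function(g) dim(g$values))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("all yearly grids must share one lattice")
  h <- dims[[1]][1]; w <- dims[[1]][2]
  C <- model$config$output_dim
  acc <- array(0, c(h, w, C))
  for (g in feature_grids_by_year) {
    yr <- predict_pixel_yield(model, g)   # NA where nodata
    acc <- acc + yr                        # NA propagates
  }
  acc <- acc / length(feature_grids_by_year)
  years <- vapply(feature_grids_by_year, `[[`, integer(1), "year")
  out <- lapply(seq_len(C), function(c) {
    structure(list(crop = model$crop_names[c], values = acc[, , c],
                   years_averaged = years, mask_applied = FALSE,
                   nodata = -9999), class = "suitability_map")
  })
  names(out) <- model$crop_names
  out
}

#' Apply an external validity mask to a suitability map
#'
#' Pixels where the mask is `FALSE` (e.g. regions unable to grow sufficient
#' vegetation, per an external vegetation-index product) become nodata.
#' Unmasked values are never altered.
#'
#' @param map a `suitability_map`.
#' @param mask_raster H x W logical (or 0/1 numeric) matrix, `TRUE` = keep.
#' @return the masked `suitability_map` with `mask_applied = TRUE`.
#' @export
apply_mask <- function(map, mask_raster) {
  if (!identical(dim(map$values), dim(mask_raster)))
    stop("mask lattice does not match map")
  keep <- mask_raster > 0
  v <- map$values
  v[!keep] <- NA_real_
  map$values <- v
  map$mask_applied <- TRUE
  map
}

#' Summarise a suitability map over zones
#'
#' Mean predicted yield and pixel count per zone of a zone partition
#' (e.g. growing-season-length polygons rasterized onto the model lattice).
#' Zones with no valid (non-nodata) pixel are omitted.
#'
#' @param map a `suitability_map`.
#' @param zone_partition H x W integer matrix of zone ids (`NA` = no zone),
#'   or a `district_partition`.
#' @return A `zone_summary` data.frame: `zone`, `mean_yield`, `n_pixels`.
#' @export
summarize_by_zone <- function(map, zone_partition) {
  z <- if (inherits(zone_partition, "district_partition"))
    zone_partition$assignment else zone_partition
  if (!identical(dim(map$values), dim(z)))
    stop("zone lattice does not match map")
  ok <- !is.na(map$values) & !is.na(z)
  if (!any(ok))
    return(structure(data.frame(zone = integer(), mean_yield = numeric(),
                                n_pixels = integer()),
                     class = c("zone_summary", "data.frame")))
  agg <- tapply(map$values[ok], z[ok], mean)
  cnt <- tapply(map$values[ok], z[ok], length)
  out <- data.frame(zone = as.integer(names(agg)),
                    mean_yield = as.numeric(agg),
                    n_pixels = as.integer(cnt))
  out <- out[order(out$zone), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("zone_summary", "data.frame")
  out
}

#' Compare predicted suitability on cultivated vs uncultivated pixels
#'
#' For each crop, the mean predicted yield over the pixels where the crop
#' inventory says it was cultivated versus over all other valid pixels. If
#' crop placement favours suitable land, the cultivated mean should exceed
#' the uncultivated one — the quantitative form of overlaying the crop
#' inventory on the suitability maps as a sanity check.
#'
#' @param maps named list of `suitability_map`s (one per crop).
#' @param crop_assignment a `crop_assignment` on the same lattice.
#' @return An `overlay_summary` data.frame: `crop`, `mean_cultivated`,
#'   `n_cultivated`, `mean_uncultivated`, `n_uncultivated`. Crops never
#'   cultivated report `NA`/0 on the cultivated side.
#' @export
overlay_inventory <- function(maps, crop_assignment) {
  rows <- lapply(names(maps), function(cr) {
    map <- maps[[cr]]
    if (!identical(dim(map$values), dim(crop_assignment$assignment)))
      stop("assignment lattice does not match map")
    ci <- match(cr, crop_assignment$crop_names)
    valid <- !is.na(map$values)
    cult <- valid & !is.na(crop_assignment$assignment) &
      crop_assignment$assignment == if (is.na(ci)) -1L else ci
    unc <- valid & !cult
    data.frame(
      crop = cr,
      mean_cultivated = if (any(cult)) mean(map$values[cult]) else NA_real_,
      n_cultivated = sum(cult),
      mean_uncultivated = if (any(unc)) mean(map$values[unc]) else NA_real_,
      n_uncultivated = sum(unc))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("overlay_summary", "data.frame")
  out
}
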