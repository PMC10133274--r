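#' @importFrom utils read.csv write.csv
NULL

# Raster I/O. Rasters are written as 32-bit-float TIFF with the values
# affinely rescaled into [0,1]; the offset/scale, nodata value, band names
# and pixel footprint live in a JSON sidecar (<path>.json). Reading undoes
# the rescale, so round-trip fidelity is at float32-quantization level.
# Nodata pixels are stored as the sentinel (default -9999) and come back
# as NA.

#' Write a raster to 32-bit-float TIFF (+ JSON sidecar)
#'
#' @param values H x W matrix or H x W x B array; `NA` = nodata.
#' @param path output path (`.tif`); a `<path>.json` sidecar is written too.
#' @param nodata sentinel stored for nodata pixels (default -9999).
#' @param band_names optional character vector, one per band.
#' @param pixel_size optional (height_m, width_m) metadata.
#' @param year optional year metadata.
#' @return `path`, invisibly.
#' @export
write_raster_tiff <- function(values, path, nodata = -9999,
                              band_names = NULL, pixel_size = NULL,
                              year = NULL) {
  v <- values
  v[is.na(v)] <- nodata
  vmin <- min(v); vmax <- max(v)
  scale <- if (vmax > vmin) vmax - vmin else 1
  vs <- (v - vmin) / scale
  # one TIFF directory (page) per band; single-band rasters stay plain
  if (length(dim(vs)) == 3L)
    tiff::writeTIFF(lapply(seq_len(dim(vs)[3]),
                           function(b) vs[, , b, drop = TRUE]),
                    path, bits.per.sample = 32L)
  else
    tiff::writeTIFF(vs, path, bits.per.sample = 32L)
  meta <- list(nodata = nodata, value_offset = vmin, value_scale = scale,
               dim = dim(v), band_names = band_names,
               pixel_size = pixel_size, year = year,
               indexing = "row-major, 0-based in exported tables")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a raster written by [write_raster_tiff()]
#'
#' @param path path to the `.tif` (sidecar `<path>.json` must exist).
#' @return H x W matrix or H x W x B array with `NA` where nodata, plus
#'   attributes `band_names`, `pixel_size`, `year`.
#' @export
read_raster_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- suppressWarnings(tiff::readTIFF(path, all = TRUE))
  v <- if (length(v) == 1L) v[[1]]
  else array(unlist(v), c(dim(v[[1]]), length(v)))
  v <- v * meta$value_scale + meta$value_offset
  tol <- max(1e-3, meta$value_scale * 2^-22)
  v[abs(v - meta$nodata) < tol] <- NA_real_
  attr(v, "band_names") <- meta$band_names
  attr(v, "pixel_size") <- meta$pixel_size
  attr(v, "year") <- meta$year
  v
}

#' Write a feature grid as a long-format CSV
#'
#' Columns `pixel_id,row,col,year,x1..xF`; row-major, 0-based pixel ids.
#'
#' @param grid a `feature_grid`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  dm <- dim(grid$values)
  h <- dm[1]; w <- dm[2]
  # row-major pixel id: id = row * W + col (0-based)
  rows <- rep(seq_len(h) - 1L, each = w)
  cols <- rep(seq_len(w) - 1L, times = h)
  x <- matrix(grid$values, h * w, dm[3])
  # arrays are column-major in memory; emit rows in row-major id order
  m <- x[cols * h + rows + 1L, , drop = FALSE]
  df <- data.frame(pixel_id = rows * w + cols, row = rows, col = cols,
                   year = grid$year)
  feat <- as.data.frame(m)
  names(feat) <- paste0("x", seq_len(dm[3]))
  write.csv(cbind(df, feat), path, row.names = FALSE)
  invisible(path)
}

#' Read a feature grid from the long CSV written by [write_grid_csv()]
#'
#' @param path CSV path.
#' @param pixel_size pixel footprint metadata to attach.
#' @return a `feature_grid`.
#' @export
read_grid_csv <- function(path, pixel_size = c(300, 500)) {
  df <- read.csv(path)
  h <- max(df$row) + 1L; w <- max(df$col) + 1L
  fcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  fcols <- fcols[order(as.integer(sub("x", "", fcols)))]
  vals <- array(NA_real_, c(h, w, length(fcols)))
  idx <- cbind(df$row + 1L, df$col + 1L)
  for (f in seq_along(fcols))
    vals[cbind(idx, f)] <- df[[fcols[f]]]
  structure(list(year = as.integer(df$year[1]), values = vals,
                 pixel_size = pixel_size,
                 nodata_mask = is.na(vals[, , 1])),
            class = "feature_grid")
}

#' Write / read district yield tables
#'
#' CSV with header `crop,year,district,yield` (bushels/acre).
#'
#' @param yields a `yield_table`.
#' @param path CSV path.
#' @return `path` (write) or a `yield_table` (read).
#' @export
write_yield_csv <- function(yields, path) {
  write.csv(as.data.frame(yields)[, c("crop", "year", "district", "yield")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_yield_csv
#' @export
read_yield_csv <- function(path) {
  df <- read.csv(path, colClasses = c(crop = "character"))
  need <- c("crop", "year", "district", "yield")
  if (!all(need %in% names(df)))
    stop("yield CSV must have columns ", paste(need, collapse = ","))
  if (anyDuplicated(df[, c("crop", "year", "district")]))
    stop("(crop, year, district) must be unique")
  if (any(df$yield < 0)) stop("yields must be >= 0")
  class(df) <- c("yield_table", "data.frame")
  df
}

#' Serialize a fold plan to JSON (and back)
#'
#' @param plan a `fold_plan`.
#' @param path JSON path.
#' @return `path` (write) or a `fold_plan` (read).
#' @export
write_fold_plan <- function(plan, path) {
  jsonlite::write_json(
    list(k = plan$k, districts_per_fold = plan$districts_per_fold,
         seed = plan$seed, eligible_districts = plan$eligible_districts,
         folds = plan$folds, unevaluable = plan$unevaluable),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(list(k = x$k,
                 folds = lapply(x$folds, function(f) unlist(f)),
                 eligible_districts = unlist(x$eligible_districts),
                 districts_per_fold = x$districts_per_fold,
                 unevaluable = lapply(x$unevaluable, function(u)
                   as.character(unlist(u))),
                 seed = x$seed),
            class = "fold_plan")
}

#' Save / load a fitted model directory
#'
#' The directory holds `config.yaml`, `crops.json`, `standardizer.json`,
#' the weights as a flat little-endian float64 stream `weights.bin`, and a
#' `manifest.json` with the layer shapes and byte order.
#'
#' @param model a `multicrop_model`.
#' @param dir directory to create/overwrite.
#' @return `dir` (save) or a `multicrop_model` (load).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(model$config), file.path(dir, "config.yaml"))
  jsonlite::write_json(model$crop_names, file.path(dir, "crops.json"))
  jsonlite::write_json(lapply(unclass(model$standardizer), as.numeric),
                       file.path(dir, "standardizer.json"), digits = NA)
  shapes <- lapply(model$weights$W, dim)
  con <- file(file.path(dir, "weights.bin"), "wb")
  on.exit(close(con))
  for (l in seq_along(model$weights$W)) {
    writeBin(as.numeric(model$weights$W[[l]]), con, size = 8,
             endian = "little")
    writeBin(as.numeric(model$weights$b[[l]]), con, size = 8,
             endian = "little")
  }
  jsonlite::write_json(
    list(layers = shapes, dtype = "float64", endian = "little",
         order = "column-major, W then b per layer",
         training_log = model$training_log),
    file.path(dir, "manifest.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$hidden_dims <- as.integer(unlist(cfg$hidden_dims))
  class(cfg) <- "model_config"
  crops <- unlist(jsonlite::read_json(file.path(dir, "crops.json"),
                                      simplifyVector = TRUE))
  stdl <- jsonlite::read_json(file.path(dir, "standardizer.json"),
                              simplifyVector = TRUE)
  std <- structure(stdl, class = "standardizer")
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  con <- file(file.path(dir, "weights.bin"), "rb")
  on.exit(close(con))
  W <- list(); b <- list()
  for (l in seq_along(man$layers)) {
    d <- as.integer(unlist(man$layers[[l]]))
    W[[l]] <- matrix(readBin(con, "numeric", d[1] * d[2], size = 8,
                             endian = "little"), d[1], d[2])
    b[[l]] <- readBin(con, "numeric", d[2], size = 8, endian = "little")
  }
  structure(list(config = cfg, weights = list(W = W, b = b),
                 crop_names = crops, standardizer = std,
                 training_log = as.numeric(unlist(man$training_log))),
            class = "multicrop_model")
}
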