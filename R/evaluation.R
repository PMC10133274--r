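#' Mean absolute error
#'
#' @param predictions,labels equal-length numeric vectors (physical units).
#' @return scalar MAE.
#' @export
mae <- function(predictions, labels) {
  if (length(predictions) == 0L || length(predictions) != length(labels))
    stop("predictions and labels must be non-empty and of equal length")
  mean(abs(predictions - labels))
}

#' District-held-out k-fold cross-validation
#'
#' For each fold of the plan, trains on the examples of all non-held-out
#' districts and evaluates per-crop MAE on the held-out districts' labels
#' against the aggregated district predictions (all in bushels/acre). In
#' `"multi"` mode one joint model serves every crop; in `"single"` mode one
#' independent single-output model is trained per crop on that crop's
#' records only (same architecture otherwise). A crop with no validation
#' observation in a fold — or, in single mode, no training observation — is
#' excluded from that fold's statistics, so its `n_val_sets` is less than k.
#'
#' The standardizer is fitted on each fold's training examples only, unless
#' `global_standardize = TRUE`, which standardizes once on all examples
#' before splitting (faster, but leaks validation statistics into training).
#'
#' @param examples list of `agg_example`s in physical units.
#' @param fold_plan a `fold_plan` from [split_by_district()].
#' @param config a `model_config` (multi mode uses it as-is; single mode
#'   copies it with `output_dim = 1`).
#' @param mode `"multi"` or `"single"`.
#' @param global_standardize logical, see Details.
#' @param verbose print per-fold progress.
#' @return A `cv_result`: data.frame `summary` with one row per crop
#'   (`crop`, `mae_mean`, `mae_sd`, `n_val_sets`, `relative_error_pct`),
#'   plus `per_fold` (crop x fold MAE matrix), `fold_plan`, `mode`, and
#'   `yield_range` (per-crop max - min of observed labels over the whole
#'   dataset, the denominator of the relative error).
#' @export
crossval <- function(examples, fold_plan, config,
                     mode = c("multi", "single"),
                     global_standardize = FALSE, verbose = FALSE) {
  mode <- match.arg(mode)
  crops_all <- sort(unique(vapply(examples, `[[`, character(1), "crop")))
  dists <- vapply(examples, `[[`, numeric(1), "district")
  labels_by_crop <- split(vapply(examples, `[[`, numeric(1), "label"),
                          vapply(examples, `[[`, character(1), "crop"))
  yrange <- vapply(labels_by_crop, function(v) diff(range(v)), numeric(1))
  glob_std <- if (global_standardize) fit_standardizer(examples) else NULL

  per_fold <- matrix(NA_real_, length(crops_all), fold_plan$k,
                     dimnames = list(crops_all, NULL))
  for (f in seq_len(fold_plan$k)) {
    vd <- fold_plan$folds[[f]]
    is_val <- dists %in% vd
    tr <- examples[!is_val]; va <- examples[is_val]
    if (length(tr) == 0L || length(va) == 0L) next
    std <- if (global_standardize) glob_std else fit_standardizer(tr)
    va_crops <- vapply(va, `[[`, character(1), "crop")
    if (mode == "multi") {
      cfg <- config
      cfg$seed <- config$seed + f   # independent init/shuffle per fold
      fit <- train(tr, cfg, crop_names = crops_all_padded(crops_all, cfg),
                   standardizer = std)
      for (cr in intersect(crops_all, unique(va_crops))) {
        sub <- va[va_crops == cr]
        preds <- vapply(sub, function(ex) predict_example(fit, ex),
                        numeric(1))
        labs <- vapply(sub, `[[`, numeric(1), "label")
        per_fold[cr, f] <- mae(preds, labs)
      }
    } else {
      tr_crops <- vapply(tr, `[[`, character(1), "crop")
      for (cr in intersect(crops_all, unique(va_crops))) {
        tr_c <- tr[tr_crops == cr]
        if (length(tr_c) == 0L) next  # crop unlearnable in this fold
        cfg <- config
        cfg$output_dim <- 1L
        cfg$seed <- config$seed + f
        fit <- train(tr_c, cfg, crop_names = cr, standardizer = std)
        sub <- va[va_crops == cr]
        preds <- vapply(sub, function(ex) predict_example(fit, ex),
                        numeric(1))
        labs <- vapply(sub, `[[`, numeric(1), "label")
        per_fold[cr, f] <- mae(preds, labs)
      }
    }
    if (verbose) message("fold ", f, "/", fold_plan$k, " done")
  }
  n_val <- rowSums(!is.na(per_fold))
  mae_mean <- ifelse(n_val > 0, rowMeans(per_fold, na.rm = TRUE), NA_real_)
  mae_sd <- apply(per_fold, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) >= 2) sd(v) else NA_real_
  })
  rel <- ifelse(yrange[crops_all] > 0,
                100 * mae_mean / yrange[crops_all], NA_real_)
  structure(list(
    summary = data.frame(crop = crops_all, mae_mean = mae_mean,
                         mae_sd = mae_sd, n_val_sets = n_val,
                         relative_error_pct = rel, row.names = NULL),
    per_fold = per_fold, fold_plan = fold_plan, mode = mode,
    yield_range = yrange), class = "cv_result")
}

# pad the crop list to the configured output width (unused heads get
# placeholder names; they receive no gradient)
crops_all_padded <- function(crops, cfg) {
  if (length(crops) < cfg$output_dim)
    c(crops, paste0("unused", seq_len(cfg$output_dim - length(crops))))
  else crops[seq_len(cfg$output_dim)]
}

#' Compare multi-crop and single-crop cross-validation results
#'
#' Per-crop fold-reduction factor: single-crop `mae_mean` divided by
#' multi-crop `mae_mean`. Ratios above 1 indicate the multi-crop model is
#' more accurate for that crop. Crops unevaluable in either result are
#' omitted, with a note.
#'
#' @param cv_multi,cv_single `cv_result`s over the same fold plan.
#' @return A `comparison_report` data.frame: `crop`, `mae_multi`,
#'   `mae_single`, `fold_reduction`.
#' @export
compare_models <- function(cv_multi, cv_single) {
  sm <- cv_multi$summary; ss <- cv_single$summary
  common <- intersect(sm$crop[!is.na(sm$mae_mean)],
                      ss$crop[!is.na(ss$mae_mean)])
  missing <- setdiff(union(sm$crop, ss$crop), common)
  if (length(missing))
    message("omitted (unevaluable in one result): ",
            paste(missing, collapse = ", "))
  mm <- sm$mae_mean[match(common, sm$crop)]
  ms <- ss$mae_mean[match(common, ss$crop)]
  out <- data.frame(crop = common, mae_multi = mm, mae_single = ms,
                    fold_reduction = ms / mm)
  class(out) <- c("comparison_report", "data.frame")
  out
}
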