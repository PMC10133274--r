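#' Model configuration
#'
#' Defaults follow the reference architecture for 16 soil-climate-landscape
#' covariates and 9 crops: hidden layers of 256, 512 and 256 rectified-linear
#' units, dropout applied to each hidden layer, L1 objective minimised with
#' the Adam optimizer. `dropout_rate` is the probability that a hidden unit
#' is *dropped* during training (inverted scaling at train time, identity at
#' inference); the heavy default regularises the small weakly-labelled
#' training sets this model is meant for, but recovery experiments on clean
#' synthetic data should set it to 0.
#'
#' @param input_dim covariate dimension F.
#' @param hidden_dims integer vector of hidden-layer widths.
#' @param output_dim number of crops C.
#' @param dropout_rate drop probability in [0, 1).
#' @param learning_rate Adam step size.
#' @param lr_decay inverse-time decay: the step size at epoch e is
#'   `learning_rate / (1 + lr_decay * (e - 1))`. The L1 objective has a
#'   constant-magnitude subgradient near its optimum, so a fixed Adam step
#'   oscillates; decay makes late epochs settle. 0 disables.
#' @param beta1,beta2,epsilon Adam moment coefficients and stabiliser.
#' @param epochs passes over the training examples.
#' @param batch_groups aggregated examples per optimizer step.
#' @param weight_by_pixels if `TRUE`, a batch's loss weights each example by
#'   its pixel count n instead of equally.
#' @param seed seed controlling initialisation, shuffling and dropout.
#' @return a `model_config` list.
#' @export
model_config <- function(input_dim = 16L,
                         hidden_dims = c(256L, 512L, 256L),
                         output_dim = 9L,
                         dropout_rate = 0.95,
                         learning_rate = 1e-3,
                         lr_decay = 0.02,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                         epochs = 300L,
                         batch_groups = 8L,
                         weight_by_pixels = FALSE,
                         seed = 1L) {
  stopifnot(input_dim >= 1, all(hidden_dims >= 1), output_dim >= 1,
            dropout_rate >= 0, dropout_rate < 1, epochs >= 1,
            batch_groups >= 1, learning_rate > 0)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 output_dim = as.integer(output_dim),
                 dropout_rate = dropout_rate,
                 activation = "relu", optimizer = "adam",
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 epochs = as.integer(epochs),
                 batch_groups = as.integer(batch_groups),
                 weight_by_pixels = isTRUE(weight_by_pixels),
                 seed = as.integer(seed)),
            class = "model_config")
}

# He-style variance-scaled symmetric initialisation.
init_weights <- function(config) {
  dims <- c(config$input_dim, config$hidden_dims, config$output_dim)
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1L)) {
    W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1L],
                           sd = sqrt(2 / dims[l])),
                     dims[l], dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  list(W = W, b = b)
}

# Forward pass caching pre-activations and dropout masks for backprop.
# `features` is n x F on the standardized scale.
nn_forward <- function(weights, config, features, training = FALSE) {
  L <- length(weights$W)
  a <- features
  zs <- vector("list", L); as <- vector("list", L + 1L)
  masks <- vector("list", L)
  as[[1L]] <- a
  p <- if (training) config$dropout_rate else 0
  for (l in seq_len(L)) {
    z <- a %*% weights$W[[l]]
    z <- sweep(z, 2, weights$b[[l]], "+")
    zs[[l]] <- z
    if (l < L) {
      a <- pmax(z, 0)
      if (p > 0) {
        m <- matrix(runif(length(a)) >= p, nrow(a), ncol(a))
        a <- a * m / (1 - p)
        masks[[l]] <- m
      }
    } else a <- z
    as[[l + 1L]] <- a
  }
  list(out = a, zs = zs, as = as, masks = masks)
}

# Backprop of d(loss)/d(out) through the cached forward pass.
nn_backward <- function(weights, config, cache, dout) {
  L <- length(weights$W)
  dW <- vector("list", L); db <- vector("list", L)
  delta <- dout
  p <- config$dropout_rate
  for (l in seq.int(L, 1L)) {
    dW[[l]] <- crossprod(cache$as[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(weights$W[[l]])
      if (!is.null(cache$masks[[l - 1L]]))
        delta <- delta * cache$masks[[l - 1L]] / (1 - p)
      delta <- delta * (cache$zs[[l - 1L]] > 0)
    }
  }
  list(W = dW, b = db)
}

#' Per-pixel forward pass
#'
#' Runs the network on an n x F block of standardized pixel covariates and
#' returns the n x C per-pixel yield predictions (standardized scale).
#' Dropout is active only when `training = TRUE`; inference is deterministic
#' given the weights.
#'
#' @param model a `multicrop_model` (or a bare list with `weights` and
#'   `config`).
#' @param features n x F numeric matrix, standardized.
#' @param training logical; enable dropout.
#' @return n x C matrix of per-pixel predictions.
#' @export
forward_pixels <- function(model, features, training = FALSE) {
  if (!is.matrix(features)) features <- matrix(features, nrow = 1L)
  if (ncol(features) != model$config$input_dim)
    stop("feature width ", ncol(features), " does not match input_dim ",
         model$config$input_dim)
  nn_forward(model$weights, model$config, features, training)$out
}

#' Aggregate per-pixel predictions to a district yield
#'
#' The averaging head of the method: the predicted district yield for the
#' observed crop is the arithmetic mean of that crop's per-pixel predictions
#' over the group's cultivated pixels,
#' `y_hat = (1/n) * sum_i pixel_preds[i, crop]`.
#'
#' @param pixel_preds n x C matrix of per-pixel predictions.
#' @param crop_index column (1-based) of the observed crop.
#' @return scalar predicted district yield.
#' @export
aggregate_prediction <- function(pixel_preds, crop_index) {
  if (!is.matrix(pixel_preds)) pixel_preds <- matrix(pixel_preds, nrow = 1L)
  if (nrow(pixel_preds) < 1L) stop("no pixels to aggregate")
  if (crop_index < 1L || crop_index > ncol(pixel_preds))
    stop("crop_index out of range")
  mean(pixel_preds[, crop_index])
}

#' One-hot crop indicator
#'
#' @param crop_index observed crop (1-based).
#' @param n_crops total number of crops C.
#' @return length-C vector with a single 1 at `crop_index`.
#' @export
crop_indicator <- function(crop_index, n_crops) {
  v <- numeric(n_crops)
  v[crop_index] <- 1
  v
}

#' Indicator-masked L1 loss
#'
#' `Loss = I_observed^T E`, where E stacks the per-crop absolute errors
#' between aggregated predictions and district yields. Because only one
#' crop's yield is observed per example, the one-hot indicator zeroes the
#' error of every unobserved crop exactly: the loss equals
#' `|y_hat_c - y_c|` for the observed crop c alone.
#'
#' @param aggregated_preds length-C vector of aggregated predictions.
#' @param observed_label the observed district yield. Either a scalar (the
#'   usual case: only the observed crop's label exists) or a length-C vector
#'   of per-crop labels of which only the indicated entry is used.
#' @param indicator one-hot length-C vector (see [crop_indicator()]).
#' @return scalar loss, >= 0.
#' @export
masked_l1_loss <- function(aggregated_preds, observed_label, indicator) {
  C <- length(aggregated_preds)
  if (length(indicator) != C || any(!indicator %in% c(0, 1)) ||
      sum(indicator) != 1)
    stop("indicator must be one-hot of length ", C)
  labels <- if (length(observed_label) == 1L)
    rep(observed_label, C) else observed_label
  if (length(labels) != C) stop("label length must be 1 or C")
  E <- abs(aggregated_preds - labels)
  sum(indicator * E)
}

#' Train the multi-crop model on aggregated examples
#'
#' Minimises the indicator-masked aggregated L1 loss with Adam. Each
#' optimizer step averages the per-example masked loss over a batch of
#' `batch_groups` examples (optionally weighting by pixel count); one
#' example contributes gradient only to the observed crop's output head and
#' to the shared layers. Features and labels are standardized internally
#' with a standardizer fitted on the supplied examples unless one is given
#' (pass the training-fold standardizer to avoid leakage in
#' cross-validation).
#'
#' @param examples list of `agg_example`s in physical units
#'   (or pre-standardized; see `standardizer`).
#' @param config a `model_config`.
#' @param crop_names character vector naming the C outputs; defaults to the
#'   crops present in `examples` (padded to `output_dim`).
#' @param standardizer optional pre-fitted `standardizer`. If the examples
#'   are already standardized (`standardized = TRUE`), it is required and
#'   used only for inverse transforms at prediction time.
#' @param verbose print the epoch loss every 50 epochs.
#' @return a `multicrop_model` with `config`, `weights`, `crop_names`,
#'   `standardizer` and `training_log` (mean masked loss per epoch,
#'   standardized scale).
#' @export
train <- function(examples, config, crop_names = NULL,
                  standardizer = NULL, verbose = FALSE) {
  if (length(examples) < 1L) stop("need at least one training example")
  if (is.null(crop_names)) {
    crop_names <- sort(unique(vapply(examples, `[[`, character(1), "crop")))
    if (length(crop_names) < config$output_dim)
      crop_names <- c(crop_names,
                      paste0("unused", seq_len(config$output_dim -
                                                 length(crop_names))))
  }
  if (length(crop_names) != config$output_dim)
    stop("length(crop_names) must equal output_dim")
  already_std <- isTRUE(examples[[1]]$standardized)
  if (already_std) {
    if (is.null(standardizer))
      stop("pre-standardized examples need their standardizer")
  } else {
    if (is.null(standardizer)) standardizer <- fit_standardizer(examples)
    examples <- apply_standardizer(examples, standardizer, "forward")
  }
  # map each example's crop onto the model's output columns
  cidx <- match(vapply(examples, `[[`, character(1), "crop"), crop_names)
  if (anyNA(cidx)) stop("example crop not in crop_names")

  n_ex <- length(examples)
  px_w <- vapply(examples, `[[`, numeric(1), "n")
  model <- with_seed(config$seed, {
    weights <- init_weights(config)
    m <- lapply(weights$W, function(w) w * 0); mb <- lapply(weights$b, function(b) b * 0)
    v <- lapply(weights$W, function(w) w * 0); vb <- lapply(weights$b, function(b) b * 0)
    t_step <- 0L
    log_ <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n_ex)
      ep_loss <- 0
      for (b0 in seq(1L, n_ex, by = config$batch_groups)) {
        idx <- ord[b0:min(b0 + config$batch_groups - 1L, n_ex)]
        # stack the batch's pixel blocks into one matrix: one forward and
        # one backward pass per optimizer step
        feats <- do.call(rbind, lapply(examples[idx], `[[`, "features"))
        ns <- vapply(examples[idx], `[[`, numeric(1), "n")
        grp <- rep(seq_along(idx), times = ns)
        labs <- vapply(examples[idx], `[[`, numeric(1), "label")
        cache <- nn_forward(weights, config, feats,
                            training = config$dropout_rate > 0)
        gmeans <- rowsum(cache$out, grp) / ns          # G x C group means
        agg <- gmeans[cbind(seq_along(idx), cidx[idx])]
        err <- agg - labs
        if (any(!is.finite(err)))
          stop("non-finite loss at epoch ", ep, ", example ",
               idx[which(!is.finite(err))[1]])
        wt <- if (config$weight_by_pixels) ns else rep(1, length(idx))
        wsum <- sum(wt)
        # d|agg_g - y_g|/d pixel_pred[i, c_g] = sign(err_g)/n_g for pixels
        # of group g, exactly 0 for every other output column
        dout <- matrix(0, nrow(cache$out), ncol(cache$out))
        dout[cbind(seq_len(nrow(dout)), cidx[idx][grp])] <-
          (wt * sign(err) / ns)[grp]
        g <- nn_backward(weights, config, cache, dout)
        gW <- g$W; gb <- g$b
        ep_loss <- ep_loss + sum(abs(err))
        t_step <- t_step + 1L
        lr <- config$learning_rate /
          (1 + (config$lr_decay %||% 0) * (ep - 1L))
        for (l in seq_along(weights$W)) {
          gWl <- gW[[l]] / wsum; gbl <- gb[[l]] / wsum
          m[[l]] <- config$beta1 * m[[l]] + (1 - config$beta1) * gWl
          v[[l]] <- config$beta2 * v[[l]] + (1 - config$beta2) * gWl^2
          mb[[l]] <- config$beta1 * mb[[l]] + (1 - config$beta1) * gbl
          vb[[l]] <- config$beta2 * vb[[l]] + (1 - config$beta2) * gbl^2
          mhat <- m[[l]] / (1 - config$beta1^t_step)
          vhat <- v[[l]] / (1 - config$beta2^t_step)
          mbh <- mb[[l]] / (1 - config$beta1^t_step)
          vbh <- vb[[l]] / (1 - config$beta2^t_step)
          weights$W[[l]] <- weights$W[[l]] - lr * mhat / (sqrt(vhat) + config$epsilon)
          weights$b[[l]] <- weights$b[[l]] - lr * mbh / (sqrt(vbh) + config$epsilon)
        }
      }
      log_[ep] <- ep_loss / n_ex
      if (verbose && ep %% 50L == 0L)
        message("epoch ", ep, " mean masked L1 loss ", signif(log_[ep], 4))
    }
    list(weights = weights, log_ = log_)
  })
  structure(list(config = config, weights = model$weights,
                 crop_names = crop_names, standardizer = standardizer,
                 training_log = model$log_),
            class = "multicrop_model")
}

#' Predict per-pixel yields over a grid, in physical units
#'
#' Standardizes the grid's covariates with the model's stored standardizer,
#' runs the network without dropout, and inverse-standardizes the outputs to
#' bushels/acre. Nodata pixels propagate as `NA`.
#'
#' @param model a fitted `multicrop_model`.
#' @param feature_grid a `feature_grid` in raw (generation) units.
#' @return H x W x C array of predicted yields (bushels/acre; may be
#'   negative — map export clamps at 0).
#' @export
predict_pixel_yield <- function(model, feature_grid) {
  if (is.null(model$standardizer))
    stop("model has no standardizer; cannot predict in physical units")
  dm <- dim(feature_grid$values)
  x <- matrix(feature_grid$values, dm[1] * dm[2], dm[3])
  xs <- apply_standardizer(x, model$standardizer, "forward")
  out <- forward_pixels(model, xs, training = FALSE)
  out <- apply_standardizer(out, model$standardizer, "inverse",
                            what = "label")
  arr <- array(out, dim = c(dm[1], dm[2], ncol(out)))
  nod <- which(feature_grid$nodata_mask)
  if (length(nod))
    for (c in seq_len(dim(arr)[3])) {
      sl <- arr[, , c]; sl[nod] <- NA_real_; arr[, , c] <- sl
    }
  arr
}

#' Predict the district-level yield for one aggregated example
#'
#' Convenience composition of the forward pass, the averaging head and the
#' inverse label standardization: the model's estimate of the example's
#' district yield, in bushels/acre.
#'
#' @param model fitted `multicrop_model`.
#' @param example an `agg_example` in physical units.
#' @return scalar predicted district yield (bushels/acre).
#' @export
predict_example <- function(model, example) {
  xs <- apply_standardizer(example$features, model$standardizer, "forward")
  preds <- forward_pixels(model, xs, training = FALSE)
  ci <- match(example$crop, model$crop_names)
  if (is.na(ci)) stop("crop '", example$crop, "' unknown to model")
  agg <- aggregate_prediction(preds, ci)
  apply_standardizer(agg, model$standardizer, "inverse", what = "label")
}
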