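#' Training configuration for the multi-view VAE
#'
#' Defaults mirror the protocol the package implements end-to-end: a random
#' 20% test split, a hyperparameter search space of \{1,2,3\} MLP layers,
#' \{32,48,64,128,256\} hidden units and \{32,48,64,128,256\} latent
#' dimensions, and adaptive-moment stochastic gradient descent (learning
#' rate 1e-3, batch size 64, up to 500 epochs with early stopping on a
#' 50-epoch validation-loss plateau).
#'
#' @param test_fraction proportion of subjects held out for testing.
#' @param latent_dim shared latent dimension D.
#' @param n_layers,hidden_units encoder/decoder MLP depth and width.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param val_fraction fraction of the training subjects carved out for the
#'   early-stopping validation loss.
#' @param patience epochs without validation improvement before stopping.
#' @param seed integer; fixes initialization, data order and noise draws.
#' @return list of class `train_config`.
#' @export
train_config <- function(test_fraction = 0.2, latent_dim = 32, n_layers = 2,
                         hidden_units = 64, epochs = 500, batch_size = 64,
                         learning_rate = 1e-3, val_fraction = 0.1,
                         patience = 50, seed = 1) {
  cfg <- list(test_fraction = test_fraction, latent_dim = as.integer(latent_dim),
              n_layers = as.integer(n_layers),
              hidden_units = as.integer(hidden_units),
              epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              learning_rate = learning_rate, val_fraction = val_fraction,
              patience = as.integer(patience), seed = as.integer(seed))
  assert_that(cfg$test_fraction > 0 && cfg$test_fraction < 1,
              "test_fraction must lie in (0, 1)")
  assert_that(cfg$val_fraction >= 0 && cfg$val_fraction < 1,
              "val_fraction must lie in [0, 1)")
  assert_that(cfg$epochs >= 1 && cfg$batch_size >= 1 && cfg$latent_dim >= 1,
              "epochs, batch_size and latent_dim must be positive")
  structure(cfg, class = "train_config")
}

#' Random train/test split of subject indices
#'
#' @param n_subjects number of subjects (>= 5).
#' @param test_fraction held-out proportion; `round(n * fraction)` subjects.
#' @param seed integer seed.
#' @return list with disjoint, exhaustive `train` and `test` index vectors.
#' @export
split_train_test <- function(n_subjects, test_fraction = 0.2, seed = 1) {
  assert_that(n_subjects >= 5, "need at least 5 subjects")
  n_test <- round(n_subjects * test_fraction)
  if (n_test < 1 || n_test >= n_subjects) {
    stop_mvfuse("test_fraction ", test_fraction,
                " yields an empty train or test set for n = ", n_subjects)
  }
  test <- with_seed(seed, sort(sample.int(n_subjects, n_test)))
  list(train = setdiff(seq_len(n_subjects), test), test = test)
}

#' Fit a per-view min-max scaler on training subjects
#'
#' The Bernoulli cross-entropy reconstruction term is only finite for inputs
#' in \[0, 1\], so every view is min-max scaled with statistics computed on
#' the training subjects only. Constant features map to 0.5 and out-of-range
#' test values are clipped to \[0, 1\] at application time.
#'
#' @param train_views named list of subject x P_m training matrices.
#' @return object of class `mv_scaler`.
#' @export
fit_scaler <- function(train_views) {
  assert_that(length(train_views) >= 1, "at least one view required")
  stats_ <- lapply(train_views, function(x) {
    x <- as.matrix(x)
    list(min = apply(x, 2, min), max = apply(x, 2, max))
  })
  structure(list(stats = stats_, view_names = names(train_views)),
            class = "mv_scaler")
}

#' @rdname fit_scaler
#' @param scaler an `mv_scaler` from [fit_scaler()].
#' @param views named list of matrices to transform (same views and widths
#'   as at fit time).
#' @return list of scaled matrices with entries in \[0, 1\].
#' @export
apply_scaler <- function(scaler, views) {
  stopifnot(inherits(scaler, "mv_scaler"))
  out <- vector("list", length(views))
  names(out) <- names(views)
  for (v in names(views)) {
    st <- scaler$stats[[v]]
    if (is.null(st)) stop_mvfuse("scaler has no view named '", v, "'")
    x <- as.matrix(views[[v]])
    assert_that(ncol(x) == length(st$min), "feature width changed since fit")
    rng <- st$max - st$min
    const <- rng <= 0
    rng[const] <- 1
    sc <- sweep(sweep(x, 2, st$min), 2, rng, "/")
    sc[, const] <- 0.5
    out[[v]] <- clamp(sc, 0, 1)
  }
  out
}

#' Train the multi-view VAE with product-of-experts fusion
#'
#' Minimizes the negative evidence lower bound (summed per-view Bernoulli
#' cross-entropy plus the KL divergence of the fused posterior from the
#' standard-normal prior) by minibatch Adam. A validation slice of the
#' supplied subjects provides the early-stopping loss; the parameters
#' returned are the ones from the best validation epoch. Fully reproducible
#' under `config$seed`.
#'
#' @param train_views named list of subject x P_m matrices already scaled to
#'   \[0, 1\] (see [fit_scaler()]).
#' @param config a [train_config()].
#' @param view_specs optional list of [view_spec()]s; by default every view
#'   uses `config$n_layers` and `config$hidden_units`.
#' @param verbose print the loss every 50 epochs.
#' @return list with `params` (an `mvae_params`), `trace` (data frame of
#'   per-epoch mean training and validation loss) and `config`.
#' @export
train_mvae <- function(train_views, config = train_config(),
                       view_specs = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  assert_that(length(train_views) >= 1, "at least one view required")
  assert_that(!is.null(names(train_views)) && all(nzchar(names(train_views))),
              "views must be named")
  n <- nrow(train_views[[1]])
  for (v in train_views) {
    assert_that(nrow(v) == n, "views must be row-aligned")
    assert_that(all(v >= 0 & v <= 1), "views must be scaled to [0, 1]")
  }
  view_specs <- view_specs %||% lapply(names(train_views), function(nm) {
    view_spec(nm, ncol(train_views[[nm]]),
              n_layers = config$n_layers, hidden_units = config$hidden_units)
  })
  params <- mvae_init(view_specs, config$latent_dim, seed = config$seed)
  specs <- params$view_specs
  n_val <- floor(n * config$val_fraction)
  idx <- with_seed(config$seed + 1L, sample.int(n))
  val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer()
  fit_idx <- setdiff(idx, val_idx)
  fit_views <- lapply(train_views, function(v) v[fit_idx, , drop = FALSE])
  val_views <- lapply(train_views, function(v) v[val_idx, , drop = FALSE])
  n_fit <- length(fit_idx)
  theta <- params$theta
  state <- adam_init(theta)
  trace <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric())
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  with_seed(config$seed + 2L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n_fit)
      starts <- seq(1, n_fit, by = config$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        batch <- ord[s:min(s + config$batch_size - 1, n_fit)]
        xb <- lapply(fit_views, function(v) v[batch, , drop = FALSE])
        eps <- matrix(rnorm(length(batch) * config$latent_dim),
                      length(batch), config$latent_dim)
        bp <- mvae_backprop(theta, specs, config$latent_dim, xb, eps)
        if (!is.finite(bp$loss)) {
          stop_mvfuse("non-finite loss at epoch ", epoch,
                      ", batch starting at ", s)
        }
        epoch_loss <- epoch_loss + bp$loss
        upd <- adam_step(theta, bp$grads, state, lr = config$learning_rate)
        theta <- upd$theta
        state <- upd$state
      }
      train_loss <- epoch_loss / n_fit
      val_loss <- if (length(val_idx)) {
        ev <- mvae_backprop(theta, specs, config$latent_dim, val_views,
                            matrix(0, length(val_idx), config$latent_dim),
                            want_grads = FALSE)
        ev$loss / length(val_idx)
      } else train_loss
      trace <- rbind(trace, data.frame(epoch = epoch, train_loss = train_loss,
                                       val_loss = val_loss))
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, theta = theta, epoch = epoch)
      }
      if (verbose && epoch %% 50 == 0) {
        message(sprintf("epoch %d: train %.4f, val %.4f",
                        epoch, train_loss, val_loss))
      }
      if (epoch - best$epoch >= config$patience) break
    }
  })
  params$theta <- best$theta
  list(params = params, trace = trace, config = config)
}

#' Extract fused latent representations
#'
#' Encodes each view, fuses the posteriors by product of experts and returns
#' the fused posterior mean per subject — the noise-free latent features the
#' regression head consumes. Deterministic given the parameters.
#'
#' @param params a trained `mvae_params`.
#' @param views named list of scaled matrices matching the training views.
#' @return N x D matrix of fused posterior means.
#' @export
extract_latents <- function(params, views) {
  stopifnot(inherits(params, "mvae_params"))
  missing_views <- setdiff(names(params$view_specs), names(views))
  if (length(missing_views)) {
    stop_mvfuse("views absent from input: ",
                paste(missing_views, collapse = ", "))
  }
  posts <- lapply(names(params$view_specs), function(v) {
    mvae_encode(params, views[[v]], v)
  })
  poe_fuse(posts)$mean
}

#' Fit the linear regression head on latent features
#'
#' Ordinary least squares of the phenotype on the latent features plus an
#' intercept. If the design is rank-deficient (possible when D approaches
#' the training size) the fit falls back to ridge regression with penalty
#' 1e-6 and a warning.
#'
#' @param latents_train N x D latent matrix.
#' @param y_train numeric phenotype vector.
#' @return object of class `mv_head` with `coef` (intercept first) and
#'   `ridge` flag.
#' @export
fit_head <- function(latents_train, y_train) {
  x <- cbind(1, as.matrix(latents_train))
  y <- as.numeric(y_train)
  assert_that(nrow(x) == length(y), "latents and phenotype must align")
  qrd <- qr(x)
  if (qrd$rank < ncol(x) || nrow(x) <= ncol(x)) {
    warning("rank-deficient latent design; falling back to ridge (1e-6)",
            call. = FALSE)
    xtx <- crossprod(x) + diag(1e-6, ncol(x))
    beta <- solve(xtx, crossprod(x, y))
    return(structure(list(coef = drop(beta), ridge = TRUE), class = "mv_head"))
  }
  beta <- qr.coef(qrd, y)
  structure(list(coef = unname(beta), ridge = FALSE), class = "mv_head")
}

#' @rdname fit_head
#' @param head an `mv_head`.
#' @param latents latent matrix to predict for.
#' @return numeric vector of predictions.
#' @export
predict_head <- function(head, latents) {
  stopifnot(inherits(head, "mv_head"))
  drop(cbind(1, as.matrix(latents)) %*% head$coef)
}

#' @export
predict.mv_head <- function(object, latents, ...) predict_head(object, latents)

#' Regression evaluation metrics
#'
#' Computes mean absolute error, mean absolute percentage error
#' (`mean(|y - yhat| / y) * 100`, signed denominator), root mean squared
#' error and the R-squared score `1 - SS_res / SS_tot`. MAPE is `NA` with a
#' flag when any observed value is zero.
#'
#' @param y observed phenotype values.
#' @param y_hat predictions of equal length.
#' @return list of class `prediction_report` with `mae`, `mape`, `rmse`,
#'   `r2`, `mape_defined` and a `pairs` data frame of (y, y_hat).
#' @examples
#' evaluate_predictions(c(1, 2, 3), c(2, 2, 2))
#' @export
evaluate_predictions <- function(y, y_hat) {
  y <- as.numeric(y)
  y_hat <- as.numeric(y_hat)
  assert_that(length(y) == length(y_hat), "y and y_hat must have equal length")
  assert_that(length(y) >= 1, "empty input")
  err <- y - y_hat
  mape_defined <- all(y != 0)
  structure(list(
    mae = mean(abs(err)),
    mape = if (mape_defined) mean(abs(err) / y) * 100 else NA_real_,
    rmse = sqrt(mean(err^2)),
    r2 = 1 - sum(err^2) / sum((y - mean(y))^2),
    mape_defined = mape_defined,
    pairs = data.frame(y = y, y_hat = y_hat)
  ), class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("prediction_report: MAE %.4g, MAPE %s, RMSE %.4g, R2 %.4f\n",
              x$mae,
              if (x$mape_defined) sprintf("%.2f%%", x$mape) else "undefined",
              x$rmse, x$r2))
  invisible(x)
}

#' Hyperparameter grid search
#'
#' Trains one model per grid point and selects the configuration with the
#' highest R-squared on an inner validation split carved from the training
#' subjects (20% by default), so the held-out test set is never used for
#' selection. Failed grid points are recorded and skipped.
#'
#' @param train_views named list of scaled training views.
#' @param y_train training phenotype vector.
#' @param space list with vectors `n_layers`, `hidden_units`, `latent_dim`;
#'   defaults to the full search space of [train_config()].
#' @param base_config a [train_config()] supplying every other setting.
#' @param inner_fraction validation fraction for model selection.
#' @return list with `best_config`, `results` (one row per grid point,
#'   sorted by decreasing R-squared) and `best_index` into the sorted table.
#' @export
grid_search <- function(train_views, y_train,
                        space = list(n_layers = c(1, 2, 3),
                                     hidden_units = c(32, 48, 64, 128, 256),
                                     latent_dim = c(32, 48, 64, 128, 256)),
                        base_config = train_config(),
                        inner_fraction = 0.2) {
  assert_that(length(space$n_layers) >= 1 && length(space$hidden_units) >= 1 &&
                length(space$latent_dim) >= 1, "search space must be nonempty")
  n <- nrow(train_views[[1]])
  sp <- split_train_test(n, inner_fraction, seed = base_config$seed + 7L)
  inner_train <- lapply(train_views, function(v) v[sp$train, , drop = FALSE])
  inner_val <- lapply(train_views, function(v) v[sp$test, , drop = FALSE])
  y_in <- y_train[sp$train]
  y_val <- y_train[sp$test]
  grid <- expand.grid(n_layers = space$n_layers,
                      hidden_units = space$hidden_units,
                      latent_dim = space$latent_dim)
  results <- data.frame(grid, r2 = NA_real_, rmse = NA_real_, mae = NA_real_,
                        mape = NA_real_, failed = FALSE)
  for (i in seq_len(nrow(grid))) {
    cfg <- base_config
    cfg$n_layers <- as.integer(grid$n_layers[i])
    cfg$hidden_units <- as.integer(grid$hidden_units[i])
    cfg$latent_dim <- as.integer(grid$latent_dim[i])
    res <- tryCatch({
      fit <- train_mvae(inner_train, cfg)
      z_in <- extract_latents(fit$params, inner_train)
      z_val <- extract_latents(fit$params, inner_val)
      head <- suppressWarnings(fit_head(z_in, y_in))
      evaluate_predictions(y_val, predict_head(head, z_val))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      results$failed[i] <- TRUE
    } else {
      results$r2[i] <- res$r2
      results$rmse[i] <- res$rmse
      results$mae[i] <- res$mae
      results$mape[i] <- res$mape
    }
  }
  if (all(results$failed)) stop_mvfuse("every grid point failed")
  results <- results[order(-results$r2, na.last = TRUE), ]
  rownames(results) <- NULL
  best <- results[1, ]
  best_config <- base_config
  best_config$n_layers <- as.integer(best$n_layers)
  best_config$hidden_units <- as.integer(best$hidden_units)
  best_config$latent_dim <- as.integer(best$latent_dim)
  list(best_config = best_config, results = results, best_index = 1L)
}
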