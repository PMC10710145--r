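test_that("train/test split partitions the subjects", {
  sp <- split_train_test(10, 0.2, seed = 1)
  expect_length(sp$test, 2)
  expect_length(sp$train, 8)
  expect_setequal(c(sp$train, sp$test), 1:10)
  expect_identical(sp, split_train_test(10, 0.2, seed = 1))
  expect_false(identical(sp$test, split_train_test(10, 0.2, seed = 2)$test))
  expect_error(split_train_test(10, 0.01), "empty")
})

test_that("min-max scaler follows its stated conventions", {
  tr <- list(v = cbind(a = c(1, 2, 3), b = c(5, 5, 5)))
  sc <- fit_scaler(tr)
  out <- apply_scaler(sc, tr)$v
  expect_equal(out[, "a"], c(0, 0.5, 1))
  expect_equal(out[, "b"], c(0.5, 0.5, 0.5))   # constant feature convention
  te <- apply_scaler(sc, list(v = cbind(a = c(0, 4), b = c(5, 9))))$v
  expect_equal(te[, "a"], c(0, 1))             # clipped to the train range
})

test_that("training reduces the loss and is reproducible", {
  qv <- quick_views(n = 150, seed = 6)
  fit <- train_mvae(qv$scaled, quick_cfg())
  expect_lt(tail(fit$trace$train_loss, 1), fit$trace$train_loss[1])
  fit2 <- train_mvae(qv$scaled, quick_cfg())
  expect_equal(fit$trace, fit2$trace, tolerance = 1e-6)
  ## trained weights reconstruct better than the untrained initialization
  raw <- mvae_init(fit$params$view_specs, quick_cfg()$latent_dim,
                   seed = quick_cfg()$seed)
  recon_err <- function(params) {
    z <- extract_latents(params, qv$scaled)
    sum(vapply(names(qv$scaled), function(v) {
      sum((qv$scaled[[v]] - mvae_decode(params, z, v))^2)
    }, 0))
  }
  expect_lt(recon_err(fit$params), recon_err(raw))
})

test_that("extracted latents are deterministic with the configured width", {
  qv <- quick_views(n = 120, seed = 2)
  fit <- train_mvae(qv$scaled, quick_cfg())
  z <- extract_latents(fit$params, qv$scaled)
  expect_equal(dim(z), c(120L, 8L))
  expect_identical(z, extract_latents(fit$params, qv$scaled))
  expect_error(extract_latents(fit$params, qv$scaled["view1"]), "absent")
})

test_that("regression head is exact least squares with ridge fallback", {
  set.seed(7)
  z <- matrix(rnorm(50 * 3), 50, 3)
  beta <- c(2, 1, -1, 0.5)
  y <- drop(cbind(1, z) %*% beta)
  h <- fit_head(z, y)
  expect_equal(max(abs(y - predict_head(h, z))), 0, tolerance = 1e-8)
  ## intercept-only behaviour
  h0 <- suppressWarnings(fit_head(matrix(0, 50, 2), y))
  expect_equal(unname(predict_head(h0, matrix(0, 4, 2))), rep(mean(y), 4),
               tolerance = 1e-6)   # ridge fallback shrinks by its 1e-6 penalty
  ## normal-equations oracle
  yn <- y + rnorm(50)
  hn <- fit_head(z, yn)
  d <- cbind(1, z)
  expect_equal(hn$coef, drop(solve(t(d) %*% d, t(d) %*% yn)),
               tolerance = 1e-8)
  ## rank-deficient design falls back to ridge with a warning
  expect_warning(fit_head(matrix(rnorm(4 * 6), 4, 6), rnorm(4)), "ridge")
})

test_that("evaluation metrics match their definitions", {
  perfect <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$mape, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2, 1)

  r <- evaluate_predictions(c(1, 2, 3), c(2, 2, 2))
  expect_equal(r$mae, 2 / 3)
  expect_equal(r$mape, (1 + 0 + 1 / 3) / 3 * 100)
  expect_equal(r$rmse, sqrt(2 / 3))
  expect_equal(r$r2, 0)

  ## metrics recomputable from the stored pairs
  again <- evaluate_predictions(r$pairs$y, r$pairs$y_hat)
  expect_identical(r$mae, again$mae)
  expect_identical(r$rmse, again$rmse)

  zero <- evaluate_predictions(c(0, 1), c(1, 1))
  expect_false(zero$mape_defined)
  expect_true(is.na(zero$mape))
  expect_equal(zero$mae, 0.5)
})

test_that("grid search selects the argmax of its own table", {
  qv <- quick_views(n = 120, seed = 9)
  y <- drop(qv$latent %*% c(1, -1, 0.5)) + rnorm(120, 0, 0.2)
  gs <- grid_search(qv$scaled, y,
                    space = list(n_layers = 1, hidden_units = c(8, 16),
                                 latent_dim = 8),
                    base_config = quick_cfg())
  expect_equal(nrow(gs$results), 2)
  expect_equal(gs$results$r2[1], max(gs$results$r2, na.rm = TRUE))
  expect_equal(gs$best_config$hidden_units, gs$results$hidden_units[1])
  single <- grid_search(qv$scaled, y,
                        space = list(n_layers = 1, hidden_units = 16,
                                     latent_dim = 8),
                        base_config = quick_cfg())
  expect_equal(nrow(single$results), 1)
})

test_that("the model is equivariant to feature order within a view", {
  ## permuting a view's features together with the matching first-layer
  ## encoder rows and final-layer decoder columns leaves every latent and
  ## every reconstruction unchanged
  qv <- quick_views(n = 100, dims = c(10, 8), seed = 5)
  fit <- train_mvae(qv$scaled, quick_cfg())
  perm <- rev(seq_len(10))
  p2 <- fit$params
  p2$theta[["view1.enc.1.W"]] <- p2$theta[["view1.enc.1.W"]][perm, ]
  p2$theta[["view1.out.1.W"]] <- p2$theta[["view1.out.1.W"]][, perm]
  p2$theta[["view1.out.1.b"]] <- p2$theta[["view1.out.1.b"]][perm]
  sv2 <- qv$scaled
  sv2$view1 <- sv2$view1[, perm]
  z1 <- extract_latents(fit$params, qv$scaled)
  z2 <- extract_latents(p2, sv2)
  expect_equal(z1, z2, tolerance = 1e-12)
  xh1 <- mvae_decode(fit$params, z1, "view1")
  xh2 <- mvae_decode(p2, z2, "view1")
  expect_equal(xh1[, perm], xh2, tolerance = 1e-12)
})

test_that("training quality is insensitive to feature order", {
  qv <- quick_views(n = 100, dims = c(10, 8), seed = 5)
  y <- drop(qv$latent %*% c(1, 0.5, -0.5)) + rnorm(100, 0, 0.2)
  run <- function(views) {
    sv <- apply_scaler(fit_scaler(views), views)
    fit <- train_mvae(sv, quick_cfg())
    z <- extract_latents(fit$params, sv)
    h <- fit_head(z, y)
    evaluate_predictions(y, predict_head(h, z))$r2
  }
  r1 <- run(qv$raw)
  v2 <- qv$raw
  v2$view1 <- v2$view1[, rev(seq_len(10))]
  r2 <- run(v2)
  ## a new random initialization meets a permuted input: same quality level
  expect_lt(abs(r1 - r2), 0.15)
})
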