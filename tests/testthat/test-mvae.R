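zero_params <- function(specs, d) {
  p <- mvae_init(specs, d, seed = 1)
  p$theta <- lapply(p$theta, function(x) x * 0)
  p
}

test_that("encoder with zero weights yields the unit Gaussian posterior", {
  p <- zero_params(list(view_spec("a", 4, 1, 6)), 3)
  post <- mvae_encode(p, matrix(runif(8), 2, 4), "a")
  expect_equal(post$mean, matrix(0, 2, 3))
  expect_equal(exp(post$log_variance), matrix(1, 2, 3))
  ## identical subjects get identical posteriors
  p2 <- mvae_init(list(view_spec("a", 4, 2, 6)), 3, seed = 9)
  x <- matrix(rep(runif(4), each = 2), 2, 4)
  post2 <- mvae_encode(p2, x, "a")
  expect_equal(post2$mean[1, ], post2$mean[2, ])
  expect_error(mvae_encode(p2, matrix(0, 2, 5), "a"), "features")
})

test_that("decoder with zero weights outputs one half everywhere", {
  p <- zero_params(list(view_spec("a", 4, 1, 6)), 3)
  xh <- mvae_decode(p, matrix(rnorm(6), 2, 3), "a")
  expect_equal(xh, matrix(0.5, 2, 4))
  p2 <- mvae_init(list(view_spec("a", 4, 1, 6)), 3, seed = 2)
  z <- matrix(rnorm(6), 2, 3)
  expect_identical(mvae_decode(p2, z, "a"), mvae_decode(p2, z, "a"))
  expect_error(mvae_decode(p2, matrix(0, 2, 4), "a"), "latent width")
})

test_that("product of experts fuses by precision weighting", {
  one <- gaussian_posterior(c(1, -2), c(0, 0))
  expect_equal(poe_fuse(list(one)), one)
  two <- poe_fuse(list(gaussian_posterior(0, 0), gaussian_posterior(0, 0)))
  expect_equal(exp(two$log_variance), matrix(0.5, 1, 1))
  ab <- poe_fuse(list(gaussian_posterior(1, 0), gaussian_posterior(3, 0)))
  expect_equal(ab$mean, matrix(2, 1, 1))
  expect_equal(exp(ab$log_variance), matrix(0.5, 1, 1))
  expect_error(poe_fuse(list(gaussian_posterior(c(1, 2), c(0, 0)),
                             gaussian_posterior(1, 0))), "mismatched")
})

test_that("fused Gaussian equals the renormalized density product", {
  set.seed(33)
  for (i in 1:50) {
    m <- sample(2:3, 1)
    means <- rnorm(m, 0, 2)
    vars <- exp(rnorm(m, 0, 0.7))
    fused <- poe_fuse(lapply(seq_len(m), function(j) {
      gaussian_posterior(means[j], log(vars[j]))
    }))
    err <- poe_grid_supnorm(means, vars, drop(fused$mean),
                            drop(exp(fused$log_variance)))
    expect_lt(err, 1e-6)
  }
})

test_that("fusion is permutation-invariant and contracts variance", {
  set.seed(4)
  posts <- lapply(1:3, function(i) {
    gaussian_posterior(matrix(rnorm(10), 2, 5), matrix(rnorm(10), 2, 5))
  })
  f1 <- poe_fuse(posts)
  f2 <- poe_fuse(posts[c(3, 1, 2)])
  expect_equal(f1, f2, tolerance = 1e-12)
  for (p in posts) {
    expect_true(all(exp(f1$log_variance) <= exp(p$log_variance) + 1e-12))
  }
  same <- poe_fuse(list(posts[[1]], posts[[1]], posts[[1]]))
  expect_equal(exp(same$log_variance), exp(posts[[1]]$log_variance) / 3,
               tolerance = 1e-12)
})

test_that("optional prior expert tightens the product", {
  p <- gaussian_posterior(2, log(4))
  f <- poe_fuse(list(p), include_prior = TRUE)
  ## N(2,4) * N(0,1): precision 1/4 + 1 = 5/4
  expect_equal(drop(exp(f$log_variance)), 4 / 5)
  expect_equal(drop(f$mean), 2 * (1 / 4) / (5 / 4))
})

test_that("reparameterization is the location-scale transform", {
  post <- gaussian_posterior(c(0, 5), log(c(4, 1)))
  expect_equal(reparameterize(post, c(0, 0)), post$mean)
  expect_equal(drop(reparameterize(post, c(1, -1))), c(2, 4))
  set.seed(10)
  draws <- replicate(2e5, reparameterize(post, rnorm(2))[1])
  expect_equal(mean(draws), 0, tolerance = 0.02)
  expect_equal(var(draws), 4, tolerance = 0.05)
})

test_that("closed-form KL matches direct evaluation and Monte Carlo", {
  expect_equal(kl_to_standard_normal(gaussian_posterior(c(0, 0), c(0, 0))), 0)
  expect_equal(kl_to_standard_normal(gaussian_posterior(1, 0)), 0.5)
  set.seed(12)
  for (i in 1:5) {
    mu <- rnorm(3)
    v <- exp(rnorm(3, 0, 0.5))
    closed <- kl_to_standard_normal(gaussian_posterior(mu, log(v)))
    mc <- kl_mc(mu, v, n_samples = 4e5)
    expect_equal(closed, mc, tolerance = 0.02)
  }
  ## nonnegativity, zero only at the prior
  set.seed(13)
  kls <- replicate(50, kl_to_standard_normal(
    gaussian_posterior(rnorm(4), rnorm(4))))
  expect_true(all(kls > 0))
})

test_that("negative ELBO decomposes and hits its floors", {
  fusedprior <- gaussian_posterior(matrix(0, 2, 3), matrix(0, 2, 3))
  x <- matrix(c(0, 1, 1, 0), 2, 2)
  perfect <- negative_elbo(list(x), list(x), fusedprior)
  expect_lt(perfect$reconstruction / length(x), 1e-5)
  expect_equal(perfect$kl, 0)

  half <- matrix(0.5, 2, 2)
  floorv <- negative_elbo(list(half), list(half), fusedprior)
  expect_equal(floorv$reconstruction, -log(0.5) * length(half))

  set.seed(3)
  xs <- matrix(runif(6), 2, 3)
  xh <- matrix(runif(6), 2, 3)
  fused <- gaussian_posterior(matrix(rnorm(4), 2, 2), matrix(rnorm(4), 2, 2))
  out <- negative_elbo(list(xs), list(xh), fused)
  expect_equal(out$total, out$reconstruction + out$kl, tolerance = 1e-10)
  expect_error(negative_elbo(list(xs), list(xh + 2), fused), "\\[0, 1\\]")
})

test_that("analytic gradients match finite differences end to end", {
  set.seed(42)
  specs <- list(view_spec("a", 5, 2, 7), view_spec("b", 4, 1, 6))
  p <- mvae_init(specs, 3, seed = 3)
  n <- 6
  views <- list(a = matrix(runif(n * 5), n), b = matrix(runif(n * 4), n))
  eps <- matrix(rnorm(n * 3), n)
  bp <- mvfuse:::mvae_backprop(p$theta, p$view_specs, 3, views, eps)
  worst <- 0
  for (nm in names(p$theta)) {
    for (k in sample(seq_along(p$theta[[nm]]),
                     min(3, length(p$theta[[nm]])))) {
      h <- 1e-5
      tp <- p$theta; tp[[nm]][k] <- tp[[nm]][k] + h
      tm <- p$theta; tm[[nm]][k] <- tm[[nm]][k] - h
      lp <- mvfuse:::mvae_backprop(tp, p$view_specs, 3, views, eps,
                                   want_grads = FALSE)$loss
      lm_ <- mvfuse:::mvae_backprop(tm, p$view_specs, 3, views, eps,
                                    want_grads = FALSE)$loss
      g_num <- (lp - lm_) / (2 * h)
      g_an <- bp$grads[[nm]][k]
      worst <- max(worst, abs(g_num - g_an) /
                     max(1e-8, abs(g_num) + abs(g_an)))
    }
  }
  expect_lt(worst, 1e-4)
})
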