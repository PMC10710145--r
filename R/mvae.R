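#' Declare one input view of the multi-view autoencoder
#'
#' @param name view label (e.g. `"WGS"`, `"DXA"`).
#' @param input_dim number of features in the view.
#' @param n_layers encoder/decoder MLP depth (1, 2 or 3 in the default
#'   search space).
#' @param hidden_units width of each hidden layer.
#' @return list of class `view_spec`.
#' @export
view_spec <- function(name, input_dim, n_layers = 2, hidden_units = 64) {
  assert_that(input_dim >= 1 && n_layers >= 1 && hidden_units >= 1,
              "view dimensions must be positive")
  structure(list(name = name, input_dim = input_dim,
                 n_layers = as.integer(n_layers),
                 hidden_units = as.integer(hidden_units)),
            class = "view_spec")
}

#' Initialize multi-view VAE parameters
#'
#' Each view gets an MLP encoder (ReLU hidden layers, then separate linear
#' heads for the posterior mean and log-variance) and an MLP decoder ending
#' in a logistic sigmoid, so reconstructions live in (0, 1) as the Bernoulli
#' cross-entropy reconstruction term requires. Weights are fan-in-scaled
#' Gaussian draws under `seed`; log-variance head outputs are clamped to
#' \[-10, 10\] before exponentiation for numerical stability.
#'
#' @param view_specs list of [view_spec()]s (names taken from the specs).
#' @param latent_dim dimension D of the shared latent space.
#' @param seed integer initialization seed.
#' @return object of class `mvae_params` holding the flat weight list plus
#'   architecture metadata sufficient to reload it bit-identically.
#' @export
mvae_init <- function(view_specs, latent_dim, seed = 1) {
  if (inherits(view_specs, "view_spec")) view_specs <- list(view_specs)
  assert_that(length(view_specs) >= 1, "at least one view required")
  names(view_specs) <- vapply(view_specs, function(s) s$name, "")
  assert_that(!anyDuplicated(names(view_specs)), "view names must be unique")
  structure(
    list(view_specs = view_specs, latent_dim = as.integer(latent_dim),
         seed = as.integer(seed),
         theta = init_theta(view_specs, latent_dim, seed)),
    class = "mvae_params"
  )
}

#' @export
print.mvae_params <- function(x, ...) {
  cat(sprintf("mvae_params: %d view(s) [%s], latent dim %d, %d weight arrays\n",
              length(x$view_specs), paste(names(x$view_specs), collapse = ", "),
              x$latent_dim, length(x$theta)))
  invisible(x)
}

#' Per-subject diagonal-Gaussian posterior
#'
#' @param mean N x D matrix (or length-D vector) of posterior means.
#' @param log_variance matching matrix/vector of log variances.
#' @return object of class `gaussian_posterior`.
#' @export
gaussian_posterior <- function(mean, log_variance) {
  mean <- rbind(mean)[, , drop = FALSE]
  if (is.vector(log_variance)) log_variance <- rbind(log_variance)
  assert_that(all(dim(mean) == dim(log_variance)),
              "mean and log_variance shapes must match")
  assert_that(all(is.finite(mean)) && all(is.finite(log_variance)),
              "posterior parameters must be finite")
  structure(list(mean = unname(mean), log_variance = unname(log_variance)),
            class = "gaussian_posterior")
}

#' Encode one view to its Gaussian posterior
#'
#' @param params trained or initialized [mvae_init()] parameters.
#' @param x subject x P_m feature matrix, scaled to \[0, 1\].
#' @param view the view name.
#' @return a [gaussian_posterior()] with one row per subject.
#' @export
mvae_encode <- function(params, x, view) {
  stopifnot(inherits(params, "mvae_params"))
  spec <- params$view_specs[[view]]
  if (is.null(spec)) stop_mvfuse("unknown view: ", view)
  x <- rbind(x)[, , drop = FALSE]
  if (ncol(x) != spec$input_dim) {
    stop_mvfuse("view '", view, "' expects ", spec$input_dim,
                " features, got ", ncol(x))
  }
  e <- enc_forward(params$theta, spec, x)
  gaussian_posterior(e$mu, e$lv)
}

#' Decode latent variables back to one view's feature space
#'
#' @param params [mvae_init()] parameters.
#' @param z subject x D latent matrix.
#' @param view the view name.
#' @return reconstruction matrix with entries in (0, 1).
#' @export
mvae_decode <- function(params, z, view) {
  stopifnot(inherits(params, "mvae_params"))
  spec <- params$view_specs[[view]]
  if (is.null(spec)) stop_mvfuse("unknown view: ", view)
  z <- rbind(z)[, , drop = FALSE]
  if (ncol(z) != params$latent_dim) {
    stop_mvfuse("latent width ", ncol(z), " does not match D = ",
                params$latent_dim)
  }
  dec_forward(params$theta, spec, z)$xhat
}

#' Product-of-experts fusion of Gaussian posteriors
#'
#' The product of diagonal Gaussian densities is again Gaussian: per latent
#' dimension the precisions add, and the fused mean is the precision-weighted
#' mean of the expert means. The fused variance is therefore no larger than
#' any expert's, and with a single expert the input is returned unchanged.
#'
#' @param posteriors list of [gaussian_posterior()]s with equal dimensions,
#'   one per view.
#' @param include_prior if TRUE, a unit-Gaussian expert is added to the
#'   product (the Wu-Goodman convention); default FALSE, multiplying only
#'   the view posteriors.
#' @return fused [gaussian_posterior()].
#' @examples
#' a <- gaussian_posterior(1, 0)  # N(1, 1)
#' b <- gaussian_posterior(3, 0)  # N(3, 1)
#' poe_fuse(list(a, b))           # N(2, 0.5)
#' @export
poe_fuse <- function(posteriors, include_prior = FALSE) {
  if (inherits(posteriors, "gaussian_posterior")) posteriors <- list(posteriors)
  assert_that(length(posteriors) >= 1, "at least one posterior required")
  dims <- vapply(posteriors, function(p) ncol(p$mean), 0L)
  if (length(unique(dims)) != 1) {
    stop_mvfuse("posteriors have mismatched latent dimensions: ",
                paste(dims, collapse = ", "))
  }
  if (include_prior) {
    prior <- gaussian_posterior(posteriors[[1]]$mean * 0,
                                posteriors[[1]]$log_variance * 0)
    posteriors <- c(posteriors, list(prior))
  }
  prec <- lapply(posteriors, function(p) exp(-p$log_variance))
  tsum <- Reduce(`+`, prec)
  mu <- Reduce(`+`, Map(function(p, t) p$mean * t, posteriors, prec)) / tsum
  gaussian_posterior(mu, -log(tsum))
}

#' Reparameterized Gaussian sample
#'
#' `z = mean + sqrt(variance) * noise`, the change of variables that lets
#' gradients flow through the sampling step.
#'
#' @param posterior a [gaussian_posterior()].
#' @param noise standard-normal draws with the posterior's shape.
#' @return matrix of samples, same shape as the posterior mean.
#' @export
reparameterize <- function(posterior, noise) {
  stopifnot(inherits(posterior, "gaussian_posterior"))
  if (is.vector(noise)) noise <- rbind(noise)
  assert_that(all(dim(noise) == dim(posterior$mean)),
              "noise shape must match the posterior")
  z <- posterior$mean + exp(posterior$log_variance / 2) * noise
  dimnames(z) <- NULL
  z
}

#' Closed-form KL divergence to the standard normal prior
#'
#' For a diagonal Gaussian the divergence is
#' `0.5 * sum_d (mu_d^2 + sigma_d^2 - log sigma_d^2 - 1)`, which is zero
#' exactly at the prior and positive elsewhere.
#'
#' @param posterior a [gaussian_posterior()].
#' @return nonnegative numeric vector, one value per subject (row).
#' @export
kl_to_standard_normal <- function(posterior) {
  stopifnot(inherits(posterior, "gaussian_posterior"))
  v <- exp(posterior$log_variance)
  0.5 * rowSums(posterior$mean^2 + v - posterior$log_variance - 1)
}

#' Negative evidence lower bound of the multi-view VAE
#'
#' The training loss: summed Bernoulli cross-entropy between each view and
#' its reconstruction plus the summed KL divergence of the fused posterior
#' from the standard-normal prior. Reconstructions are clipped to
#' \[1e-7, 1 - 1e-7\] before the logs.
#'
#' @param views list of subject x P_m matrices scaled to \[0, 1\].
#' @param reconstructions matching list of decoder outputs in \[0, 1\].
#' @param fused the fused [gaussian_posterior()].
#' @return list with `total`, `reconstruction` and `kl` (total =
#'   reconstruction + kl).
#' @export
negative_elbo <- function(views, reconstructions, fused) {
  assert_that(length(views) == length(reconstructions),
              "one reconstruction per view required")
  eps <- 1e-7
  recon <- 0
  for (i in seq_along(views)) {
    x <- as.matrix(views[[i]])
    xh <- as.matrix(reconstructions[[i]])
    assert_that(all(dim(x) == dim(xh)), "view/reconstruction shape mismatch")
    if (any(xh < 0 | xh > 1)) {
      stop_mvfuse("reconstructions must lie in [0, 1]")
    }
    xh <- clamp(xh, eps, 1 - eps)
    recon <- recon - sum(x * log(xh) + (1 - x) * log(1 - xh))
  }
  kl <- sum(kl_to_standard_normal(fused))
  list(total = recon + kl, reconstruction = recon, kl = kl)
}
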