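## Internal multilayer-perceptron machinery for the multi-view VAE.
## Parameters live in a flat named list of matrices/vectors ("theta") so the
## Adam update is a simple loop; names follow <view>.<part>.<layer>.<W|b>.

LOGVAR_CLAMP <- 10   # log-variance head clamped to [-10, 10] before exp()

relu <- function(x) (x > 0) * x

param_name <- function(view, part, layer, what) {
  paste(view, part, layer, what, sep = ".")
}

## He-style fan-in scaled Gaussian init for one affine layer
init_layer <- function(n_in, n_out, gain = 2) {
  list(
    W = matrix(rnorm(n_in * n_out, 0, sqrt(gain / n_in)), n_in, n_out),
    b = numeric(n_out)
  )
}

## Build the flat parameter list for all views under the run seed.
init_theta <- function(view_specs, latent_dim, seed) {
  with_seed(seed, {
    theta <- list()
    for (spec in view_specs) {
      v <- spec$name
      dims <- c(spec$input_dim, rep(spec$hidden_units, spec$n_layers))
      for (l in seq_len(spec$n_layers)) {
        lay <- init_layer(dims[l], dims[l + 1])
        theta[[param_name(v, "enc", l, "W")]] <- lay$W
        theta[[param_name(v, "enc", l, "b")]] <- lay$b
      }
      h <- spec$hidden_units
      mu <- init_layer(h, latent_dim, gain = 1)
      lv <- init_layer(h, latent_dim, gain = 1)
      theta[[param_name(v, "mu", 1, "W")]] <- mu$W
      theta[[param_name(v, "mu", 1, "b")]] <- mu$b
      theta[[param_name(v, "lv", 1, "W")]] <- lv$W
      theta[[param_name(v, "lv", 1, "b")]] <- lv$b
      ddims <- c(latent_dim, rep(spec$hidden_units, spec$n_layers))
      for (l in seq_len(spec$n_layers)) {
        lay <- init_layer(ddims[l], ddims[l + 1])
        theta[[param_name(v, "dec", l, "W")]] <- lay$W
        theta[[param_name(v, "dec", l, "b")]] <- lay$b
      }
      out <- init_layer(spec$hidden_units, spec$input_dim, gain = 1)
      theta[[param_name(v, "out", 1, "W")]] <- out$W
      theta[[param_name(v, "out", 1, "b")]] <- out$b
    }
    theta
  })
}

affine <- function(x, w, b) sweep(x %*% w, 2, b, "+")

## Encoder forward pass; caches post-activation layers for backprop.
enc_forward <- function(theta, spec, x) {
  v <- spec$name
  hs <- vector("list", spec$n_layers + 1)
  as <- vector("list", spec$n_layers)
  hs[[1]] <- x
  for (l in seq_len(spec$n_layers)) {
    as[[l]] <- affine(hs[[l]],
                      theta[[param_name(v, "enc", l, "W")]],
                      theta[[param_name(v, "enc", l, "b")]])
    hs[[l + 1]] <- relu(as[[l]])
  }
  top <- hs[[spec$n_layers + 1]]
  mu <- affine(top, theta[[param_name(v, "mu", 1, "W")]],
               theta[[param_name(v, "mu", 1, "b")]])
  lv_raw <- affine(top, theta[[param_name(v, "lv", 1, "W")]],
                   theta[[param_name(v, "lv", 1, "b")]])
  lv <- clamp(lv_raw, -LOGVAR_CLAMP, LOGVAR_CLAMP)
  list(mu = mu, lv = lv, lv_raw = lv_raw, hs = hs, as = as)
}

## Decoder forward pass; final logistic keeps reconstructions in (0, 1).
dec_forward <- function(theta, spec, z) {
  v <- spec$name
  hs <- vector("list", spec$n_layers + 1)
  as <- vector("list", spec$n_layers)
  hs[[1]] <- z
  for (l in seq_len(spec$n_layers)) {
    as[[l]] <- affine(hs[[l]],
                      theta[[param_name(v, "dec", l, "W")]],
                      theta[[param_name(v, "dec", l, "b")]])
    hs[[l + 1]] <- relu(as[[l]])
  }
  a_out <- affine(hs[[spec$n_layers + 1]],
                  theta[[param_name(v, "out", 1, "W")]],
                  theta[[param_name(v, "out", 1, "b")]])
  list(xhat = logistic(a_out), a_out = a_out, hs = hs, as = as)
}

## Backprop a gradient through a ReLU trunk; fills `grads` (an environment)
## and returns the gradient at the trunk input.
trunk_backward <- function(theta, grads, view, part, hs, as, d_top) {
  n_layers <- length(as)
  d <- d_top
  for (l in rev(seq_len(n_layers))) {
    d <- d * (as[[l]] > 0)
    wn <- param_name(view, part, l, "W")
    bn <- param_name(view, part, l, "b")
    grads[[wn]] <- grads[[wn]] + crossprod(hs[[l]], d)
    grads[[bn]] <- grads[[bn]] + colSums(d)
    d <- d %*% t(theta[[wn]])
  }
  d
}

## One forward+backward pass over a batch. Returns the summed loss, its
## decomposition, and gradients for every entry of theta.
## `eps` is the reparameterization noise (B x D), drawn by the caller.
mvae_backprop <- function(theta, view_specs, latent_dim, views, eps,
                          want_grads = TRUE) {
  m <- length(view_specs)
  encs <- vector("list", m)
  for (i in seq_len(m)) {
    encs[[i]] <- enc_forward(theta, view_specs[[i]], views[[i]])
  }
  tprec <- lapply(encs, function(e) exp(-e$lv))
  tsum <- Reduce(`+`, tprec)
  s_z <- 1 / tsum
  mu_z <- Reduce(`+`, Map(function(e, tp) e$mu * tp, encs, tprec)) * s_z
  z <- mu_z + sqrt(s_z) * eps
  kl <- 0.5 * sum(mu_z^2 + s_z - log(s_z) - 1)
  decs <- vector("list", m)
  recon <- 0
  eps_c <- 1e-7
  for (i in seq_len(m)) {
    decs[[i]] <- dec_forward(theta, view_specs[[i]], z)
    xh <- clamp(decs[[i]]$xhat, eps_c, 1 - eps_c)
    x <- views[[i]]
    recon <- recon - sum(x * log(xh) + (1 - x) * log(1 - xh))
  }
  loss <- recon + kl
  if (!want_grads) {
    return(list(loss = loss, recon = recon, kl = kl, mu_z = mu_z, s_z = s_z))
  }
  grads <- new.env(parent = emptyenv())
  for (nm in names(theta)) grads[[nm]] <- theta[[nm]] * 0
  dz <- 0
  for (i in seq_len(m)) {
    spec <- view_specs[[i]]
    v <- spec$name
    ## d(BCE)/d(a_out) = xhat - x (exact off the clipping region)
    d_out <- decs[[i]]$xhat - views[[i]]
    wn <- param_name(v, "out", 1, "W")
    bn <- param_name(v, "out", 1, "b")
    top <- decs[[i]]$hs[[spec$n_layers + 1]]
    grads[[wn]] <- grads[[wn]] + crossprod(top, d_out)
    grads[[bn]] <- grads[[bn]] + colSums(d_out)
    d_top <- d_out %*% t(theta[[wn]])
    dz <- dz + trunk_backward(theta, grads, v, "dec",
                              decs[[i]]$hs, decs[[i]]$as, d_top)
  }
  d_mu_z <- dz + mu_z
  d_s_z <- dz * eps / (2 * sqrt(s_z)) + 0.5 * (1 - 1 / s_z)
  for (i in seq_len(m)) {
    spec <- view_specs[[i]]
    v <- spec$name
    e <- encs[[i]]
    tp <- tprec[[i]]
    d_mu_m <- d_mu_z * tp * s_z
    d_t_m <- d_mu_z * (e$mu - mu_z) * s_z - d_s_z * s_z^2
    d_lv_m <- -d_t_m * tp
    d_lv_m[abs(e$lv_raw) > LOGVAR_CLAMP] <- 0   # clamp is flat outside
    top <- e$hs[[spec$n_layers + 1]]
    for (head in list(list(part = "mu", d = d_mu_m),
                      list(part = "lv", d = d_lv_m))) {
      wn <- param_name(v, head$part, 1, "W")
      bn <- param_name(v, head$part, 1, "b")
      grads[[wn]] <- grads[[wn]] + crossprod(top, head$d)
      grads[[bn]] <- grads[[bn]] + colSums(head$d)
    }
    d_top <- d_mu_m %*% t(theta[[param_name(v, "mu", 1, "W")]]) +
      d_lv_m %*% t(theta[[param_name(v, "lv", 1, "W")]])
    trunk_backward(theta, grads, v, "enc", e$hs, e$as, d_top)
  }
  list(loss = loss, recon = recon, kl = kl,
       grads = as.list(grads), mu_z = mu_z, s_z = s_z)
}

## Adam state and update (bias-corrected first/second moments).
adam_init <- function(theta) {
  list(m = lapply(theta, function(x) x * 0),
       v = lapply(theta, function(x) x * 0),
       t = 0L)
}

adam_step <- function(theta, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(theta)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    theta[[nm]] <- theta[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(theta = theta, state = state)
}
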