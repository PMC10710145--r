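#' Simulate biallelic SNP genotypes under Hardy-Weinberg equilibrium
#'
#' Draws each genotype as the sum of two independent Bernoulli alleles at the
#' variant's minor-allele frequency, optionally with two subpopulations whose
#' allele frequencies are shifted apart (a simple, controllable analogue of
#' F_ST-like structure for exercising population-stratification PCs).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_snps number of variants.
#' @param maf_range length-2 numeric, per-SNP MAFs are drawn uniformly from
#'   this interval; both ends must lie in (0, 0.5].
#' @param subpop_fraction fraction of subjects assigned to the second
#'   subpopulation; 0 disables structure.
#' @param maf_divergence allele-frequency gap between the two subpopulations;
#'   each gets the base frequency shifted by +/- `maf_divergence / 2`,
#'   clipped to (0.01, 0.99).
#' @param missing_rate proportion of calls set to missing uniformly at
#'   random (default 0).
#' @param seed integer seed; fully determines the output.
#' @return a [genotype_matrix()]; when structure is enabled the subpopulation
#'   labels are attached as attribute `"subpop"`. Variants are assigned
#'   synthetic chromosomes (1..22 in blocks) with ascending positions.
#' @examples
#' g <- simulate_genotypes(50, 20, maf_range = c(0.1, 0.5), seed = 1)
#' @export
simulate_genotypes <- function(n_subjects, n_snps, maf_range = c(0.05, 0.5),
                               subpop_fraction = 0, maf_divergence = 0,
                               missing_rate = 0, seed = 1) {
  assert_that(n_subjects >= 2, "n_subjects must be >= 2")
  assert_that(length(maf_range) == 2 && maf_range[1] <= maf_range[2],
              "maf_range must be an increasing pair")
  if (maf_range[1] <= 0) {
    stop_mvfuse("maf_range lower bound must be > 0, got ", maf_range[1])
  }
  if (maf_range[2] > 0.5) {
    stop_mvfuse("maf_range upper bound must be <= 0.5, got ", maf_range[2])
  }
  assert_that(subpop_fraction >= 0 && subpop_fraction <= 1,
              "subpop_fraction must be in [0,1]")
  with_seed(seed, {
    maf <- runif(n_snps, maf_range[1], maf_range[2])
    n2 <- round(n_subjects * subpop_fraction)
    subpop <- c(rep(1L, n_subjects - n2), rep(2L, n2))
    ## per-subject-per-SNP allele frequency
    shift <- maf_divergence / 2
    p1 <- clamp(maf - shift, 0.01, 0.99)
    p2 <- clamp(maf + shift, 0.01, 0.99)
    pmat <- rbind(p1, p2)[subpop, , drop = FALSE]
    counts <- matrix(
      rbinom(n_subjects * n_snps, size = 2L, prob = pmat),
      nrow = n_subjects, ncol = n_snps
    )
    if (missing_rate > 0) {
      miss <- runif(n_subjects * n_snps) < missing_rate
      counts[miss] <- NA_real_
    }
    per_chr <- ceiling(n_snps / 22)
    chrom <- as.character(rep(seq_len(22), each = per_chr)[seq_len(n_snps)])
    pos <- integer(n_snps)
    for (chr in unique(chrom)) {
      k <- sum(chrom == chr)
      pos[chrom == chr] <- seq(10000L, by = 10000L, length.out = k)
    }
    g <- genotype_matrix(counts, chromosome = chrom, position = pos)
    attr(g, "maf") <- maf
    attr(g, "subpop") <- subpop
    g
  })
}

#' Simulate a quantitative phenotype from genotypes and covariates
#'
#' Generates `y_i = intercept + sum_c alpha_c v_c(i) + sum_j beta_j g_ij +
#' eps_i` with Gaussian noise, i.e. the additive linear model the association
#' score test assumes, generalized to a sparse set of causal variants.
#' Missing genotype calls at causal variants are mean-imputed per variant
#' before the linear predictor is formed.
#'
#' @param genotypes a [genotype_matrix()].
#' @param causal_index integer indices of causal variants (may be empty).
#' @param causal_effects numeric effects, one per causal variant
#'   (phenotype units per minor allele).
#' @param covariates N x C numeric matrix (may be NULL for none).
#' @param covariate_effects numeric vector of length C.
#' @param intercept scalar baseline.
#' @param noise_sd standard deviation of the Gaussian error.
#' @param seed integer seed for the noise draw.
#' @return numeric vector of length N, named by subject id.
#' @export
simulate_phenotype <- function(genotypes, causal_index = integer(),
                               causal_effects = numeric(),
                               covariates = NULL, covariate_effects = numeric(),
                               intercept = 0, noise_sd = 1, seed = 1) {
  n <- nrow(genotypes$counts)
  s <- ncol(genotypes$counts)
  causal_index <- as.integer(causal_index)
  if (length(causal_index) &&
      (min(causal_index) < 1L || max(causal_index) > s)) {
    stop_mvfuse("causal_index out of range 1..", s)
  }
  assert_that(length(causal_index) == length(causal_effects),
              "one effect per causal variant required")
  y <- rep(intercept, n)
  if (!is.null(covariates) && length(covariate_effects)) {
    covariates <- as.matrix(covariates)
    assert_that(nrow(covariates) == n && ncol(covariates) == length(covariate_effects),
                "covariate dimensions not conformable")
    y <- y + drop(covariates %*% covariate_effects)
  }
  if (length(causal_index)) {
    gsub_ <- impute_mean(genotypes$counts[, causal_index, drop = FALSE])
    y <- y + drop(gsub_ %*% causal_effects)
  }
  y <- with_seed(seed, y + rnorm(n, 0, noise_sd))
  names(y) <- genotypes$subject_ids
  y
}

#' Simulate multi-view features from a shared low-dimensional latent factor
#'
#' Draws a standard-Gaussian latent matrix Z (N x d_true) and, for each view
#' m, returns `Z %*% L_m + E_m`, the linear-Gaussian factor structure the
#' multi-view autoencoder assumes across views. Loadings can be supplied
#' explicitly to construct, e.g., complementary designs where each view
#' observes a different latent subspace.
#'
#' @param n_subjects number of subjects.
#' @param latent_dim_true dimension of the shared factor.
#' @param view_dims integer vector of per-view feature counts.
#' @param loadings_sd sd of the Gaussian loadings (ignored for views whose
#'   loadings are supplied).
#' @param view_noise_sd sd of per-view additive Gaussian noise.
#' @param seed integer seed.
#' @param loadings optional list of d_true x P_m loading matrices, one per
#'   view (entries may be NULL to keep the random default for that view).
#' @return list with `views` (named list of N x P_m matrices), `latent_true`
#'   (N x d_true) and `loadings` (list of d_true x P_m matrices).
#' @export
simulate_multiview <- function(n_subjects, latent_dim_true, view_dims,
                               loadings_sd = 1, view_noise_sd = 0.3,
                               seed = 1, loadings = NULL) {
  assert_that(n_subjects >= 1 && latent_dim_true >= 1 && all(view_dims >= 1),
              "all dimensions must be >= 1")
  m <- length(view_dims)
  with_seed(seed, {
    z <- matrix(rnorm(n_subjects * latent_dim_true), n_subjects, latent_dim_true)
    l_list <- vector("list", m)
    views <- vector("list", m)
    for (i in seq_len(m)) {
      p <- view_dims[i]
      l <- loadings[[i]] %||%
        matrix(rnorm(latent_dim_true * p, 0, loadings_sd), latent_dim_true, p)
      assert_that(nrow(l) == latent_dim_true && ncol(l) == p,
                  "supplied loadings have wrong shape")
      e <- if (view_noise_sd > 0) {
        matrix(rnorm(n_subjects * p, 0, view_noise_sd), n_subjects, p)
      } else 0
      views[[i]] <- z %*% l + e
      l_list[[i]] <- l
    }
    names(views) <- paste0("view", seq_len(m))
    list(views = views, latent_true = z, loadings = l_list)
  })
}

#' Configuration for a synthetic radiogenomic-style study
#'
#' Bundles every knob of the generator: cohort size, variant panel, causal
#' architecture, covariate effects, and the shared-latent multi-view feature
#' model. The defaults emulate the data model the pipeline is designed for: a
#' mid-sized single-sex cohort with age/weight/height covariates, a sparse
#' causal SNP set, and two feature views (a 196-feature imaging-like view and
#' a 256-feature genotype-derived view) driven by a common low-dimensional
#' factor that also loads on the phenotype.
#'
#' @param n_subjects,n_snps cohort and panel size.
#' @param maf_range pair in (0, 0.5]; per-SNP MAFs drawn uniformly.
#' @param n_causal number of causal SNPs (<= n_snps).
#' @param causal_effect_sd sd of the Gaussian causal-effect draws
#'   (phenotype units per allele).
#' @param covariate_effects length-3 effects for age, weight, height.
#' @param noise_sd residual phenotype sd.
#' @param n_views,latent_dim_true,loadings_sd,view_noise_sd,view_dims
#'   multi-view factor model; `view_dims` must have `n_views` entries.
#' @param latent_effects phenotype loading on each true latent dimension
#'   (vector of length `latent_dim_true`; zeros disconnect views from the
#'   phenotype).
#' @param intercept phenotype baseline.
#' @param subpop_fraction,maf_divergence optional two-subpopulation
#'   structure; `subpop_fraction = 0` disables it.
#' @param missing_rate genotype missing-call rate.
#' @param seed integer; fully determines the study.
#' @return a list of class `sim_study_config`.
#' @export
sim_config <- function(n_subjects = 400, n_snps = 2000,
                       maf_range = c(0.05, 0.5), n_causal = 5,
                       causal_effect_sd = 0.5,
                       covariate_effects = c(0.02, 0.01, 0.01),
                       noise_sd = 1, n_views = 2, latent_dim_true = 4,
                       loadings_sd = 1, view_noise_sd = 0.3,
                       view_dims = c(196, 256),
                       latent_effects = rep(0.5, latent_dim_true),
                       intercept = 10, subpop_fraction = 0,
                       maf_divergence = 0, missing_rate = 0, seed = 1) {
  cfg <- list(
    n_subjects = n_subjects, n_snps = n_snps, maf_range = maf_range,
    n_causal = n_causal, causal_effect_sd = causal_effect_sd,
    covariate_effects = covariate_effects, noise_sd = noise_sd,
    n_views = n_views, latent_dim_true = latent_dim_true,
    loadings_sd = loadings_sd, view_noise_sd = view_noise_sd,
    view_dims = view_dims, latent_effects = latent_effects,
    intercept = intercept, subpop_fraction = subpop_fraction,
    maf_divergence = maf_divergence, missing_rate = missing_rate,
    seed = seed
  )
  assert_that(cfg$n_causal <= cfg$n_snps, "n_causal must be <= n_snps")
  assert_that(length(cfg$view_dims) == cfg$n_views,
              "view_dims must have n_views entries")
  assert_that(length(cfg$latent_effects) == cfg$latent_dim_true,
              "latent_effects must have latent_dim_true entries")
  assert_that(all(cfg$maf_range > 0) && all(cfg$maf_range <= 0.5),
              "maf_range must lie in (0, 0.5]")
  structure(cfg, class = "sim_study_config")
}

#' Generate a complete synthetic study
#'
#' Runs the three simulators under per-stage seeds derived from
#' `config$seed`: genotypes under HWE, covariates (age/weight/height
#' analogues), a shared latent factor with its feature views, and a phenotype
#' linear in the causal SNPs, the covariates and (by default) the latent
#' factor, so that both the association stage and the multi-view fusion stage
#' carry recoverable signal.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_study` with elements `genotypes`,
#'   `covariates`, `phenotype`, `causal_index`, `causal_effects`, `views`,
#'   `latent_true`, `loadings`, `config`.
#' @examples
#' study <- make_study(sim_config(n_subjects = 60, n_snps = 50,
#'                                view_dims = c(8, 10), seed = 7))
#' length(study$phenotype)
#' @export
make_study <- function(config) {
  stopifnot(inherits(config, "sim_study_config"))
  g <- simulate_genotypes(
    config$n_subjects, config$n_snps, config$maf_range,
    subpop_fraction = config$subpop_fraction,
    maf_divergence = config$maf_divergence,
    missing_rate = config$missing_rate,
    seed = derive_seed(config$seed, "genotypes")
  )
  ## age/weight/height analogues on realistic adult-male scales
  covariates <- with_seed(derive_seed(config$seed, "covariates"), {
    cbind(
      age = round(runif(config$n_subjects, 20, 51)),
      weight = rnorm(config$n_subjects, 83, 16.7),
      height = rnorm(config$n_subjects, 175, 6.9)
    )
  })
  rownames(covariates) <- g$subject_ids
  mv <- simulate_multiview(
    config$n_subjects, config$latent_dim_true, config$view_dims,
    loadings_sd = config$loadings_sd, view_noise_sd = config$view_noise_sd,
    seed = derive_seed(config$seed, "views")
  )
  cc <- with_seed(derive_seed(config$seed, "causal"), {
    idx <- if (config$n_causal > 0) {
      sort(sample.int(config$n_snps, config$n_causal))
    } else integer()
    eff <- rnorm(length(idx), 0, config$causal_effect_sd)
    list(index = idx, effects = eff)
  })
  y <- simulate_phenotype(
    g, cc$index, cc$effects, covariates, config$covariate_effects,
    intercept = config$intercept, noise_sd = config$noise_sd,
    seed = derive_seed(config$seed, "phenotype")
  )
  y <- y + drop(mv$latent_true %*% config$latent_effects)
  structure(
    list(genotypes = g, covariates = covariates, phenotype = y,
         causal_index = cc$index, causal_effects = cc$effects,
         views = mv$views, latent_true = mv$latent_true,
         loadings = mv$loadings, config = config),
    class = "sim_study"
  )
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "sim_study: %d subjects, %d SNPs (%d causal), %d views (%s features)\n",
    length(x$phenotype), ncol(x$genotypes$counts), length(x$causal_index),
    length(x$views), paste(vapply(x$views, ncol, 0L), collapse = "+")
  ))
  invisible(x)
}
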