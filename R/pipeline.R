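#' Configuration of the end-to-end pipeline
#'
#' Collects file paths, quality-control thresholds, the association stage
#' settings and the training configuration. All randomness flows from
#' `seed`, expanded into per-stage seeds, so any stage can be rerun in
#' isolation from the written manifest.
#'
#' @param genotype_path delimited additive table or VCF of genotypes.
#' @param view_paths named character vector of per-view feature tables
#'   (may be empty; the genotype-derived view is always built).
#' @param phenotype_path table with subject id, phenotype and covariate
#'   columns.
#' @param output_dir directory for all artifacts (created if needed).
#' @param phenotype_column name of the phenotype column.
#' @param covariate_columns names of covariate columns (default age,
#'   weight, height).
#' @param thresholds a [qc_thresholds()].
#' @param top_k variants kept as the genotype-derived view.
#' @param n_pcs genotype principal components used as covariates.
#' @param train a [train_config()].
#' @param use_wgs_view include the genotype-derived view in the model
#'   (disable to fit an imaging-only model; with a single view the
#'   product-of-experts model reduces to a standard VAE).
#' @param seed global integer seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotype_path, view_paths = character(),
                            phenotype_path, output_dir,
                            phenotype_column = "phenotype",
                            covariate_columns = c("age", "weight", "height"),
                            thresholds = qc_thresholds(), top_k = 256,
                            n_pcs = 10, train = train_config(),
                            use_wgs_view = TRUE, seed = 1) {
  structure(list(
    genotype_path = genotype_path, view_paths = view_paths,
    phenotype_path = phenotype_path, output_dir = output_dir,
    phenotype_column = phenotype_column,
    covariate_columns = covariate_columns, thresholds = thresholds,
    top_k = as.integer(top_k), n_pcs = as.integer(n_pcs), train = train,
    use_wgs_view = isTRUE(use_wgs_view), seed = as.integer(seed)
  ), class = "pipeline_config")
}

config_digest <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Executes quality control, genotype PCA, the covariate-adjusted
#' score-test association scan, top-k variant selection, per-view min-max
#' scaling, multi-view VAE training with product-of-experts fusion, the
#' linear regression head, held-out evaluation and leave-one-out
#' feature importance. Writes the association table, selected variants,
#' model archive, metrics report, importance ranking and a manifest
#' recording the seed and a config hash.
#'
#' @param config a [pipeline_config()].
#' @return list with `metrics` (test-set [evaluate_predictions()] report),
#'   `association` table, `selected` variant ids, `importance` ranking,
#'   `model` (trained `mvae_params`), `head`, `scaler`, `split`, and the
#'   output `dir`; all also persisted under `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_mvfuse("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  genotypes <- stage("read", read_genotypes(config$genotype_path))
  pheno_tab <- stage("read", {
    tab <- utils::read.table(config$phenotype_path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    rownames(tab) <- as.character(tab[[1]])
    tab
  })
  extra_views <- lapply(config$view_paths, read_feature_table)

  ## subject alignment by id intersection across every input
  geno_counts <- genotypes$counts
  aligned <- stage("align", do.call(align_subjects, c(
    list(geno_counts, pheno_tab), unname(extra_views))))
  common <- rownames(aligned[[1]])
  genotypes <- subset_genotypes(genotypes,
                                subjects = match(common, genotypes$subject_ids))
  pheno_tab <- aligned[[2]]
  extra_views <- lapply(seq_along(extra_views), function(i) aligned[[i + 2]])
  names(extra_views) <- names(config$view_paths)

  qc <- stage("qc", qc_filter(genotypes, config$thresholds))
  genotypes <- qc$genotypes
  ## QC may drop subjects; keep every table aligned
  keep <- match(genotypes$subject_ids, common)
  pheno_tab <- pheno_tab[keep, , drop = FALSE]
  extra_views <- lapply(extra_views, function(v) v[keep, , drop = FALSE])

  phenotype <- as.numeric(pheno_tab[[config$phenotype_column]])
  base_cov <- as.matrix(pheno_tab[, config$covariate_columns, drop = FALSE])

  pcs <- stage("pca", genotype_pca(genotypes,
                                   k = min(config$n_pcs,
                                           nrow(genotypes$counts) - 1,
                                           ncol(genotypes$counts))))
  covariates <- covariate_set(cbind(base_cov, pcs))

  assoc <- stage("gwas", run_gwas(genotypes, phenotype, covariates))
  assoc_sorted <- assoc[order(assoc$p), ]
  utils::write.table(
    data.frame(assoc_sorted[, c("variant_id", "chrom", "pos")],
               signif(assoc_sorted[, c("U", "V", "T", "p")], 10)),
    file.path(config$output_dir, "association.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  sel <- stage("select", select_top_k(assoc, genotypes,
                                      k = min(config$top_k, nrow(assoc))))
  writeLines(sel$variant_ids,
             file.path(config$output_dir, "selected_variants.txt"))

  views <- extra_views
  if (config$use_wgs_view) {
    wgs <- sel$features
    rownames(wgs) <- genotypes$subject_ids
    views <- c(list(WGS = wgs), views)
  }
  assert_that(length(views) >= 1, "no views configured")

  n <- length(phenotype)
  split <- split_train_test(n, config$train$test_fraction,
                            seed = derive_seed(config$seed, "split"))
  train_views_raw <- lapply(views, function(v) v[split$train, , drop = FALSE])
  test_views_raw <- lapply(views, function(v) v[split$test, , drop = FALSE])
  scaler <- fit_scaler(train_views_raw)
  train_views <- apply_scaler(scaler, train_views_raw)
  test_views <- apply_scaler(scaler, test_views_raw)

  tcfg <- config$train
  tcfg$seed <- derive_seed(config$seed, "train")
  fit <- stage("train", train_mvae(train_views, tcfg))

  z_train <- extract_latents(fit$params, train_views)
  z_test <- extract_latents(fit$params, test_views)
  head_fit <- stage("head",
                    suppressWarnings(fit_head(z_train, phenotype[split$train])))
  metrics <- evaluate_predictions(phenotype[split$test],
                                  predict_head(head_fit, z_test))

  imp <- stage("importance",
               loo_importance(fit$params, head_fit, test_views,
                              phenotype[split$test]))
  utils::write.table(
    data.frame(imp$ranking[, c("view", "feature")],
               signif(imp$ranking[, c("baseline_mae", "zeroed_mae", "delta")],
                      10)),
    file.path(config$output_dir, "importance.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  saveRDS(list(params = fit$params, head = head_fit, scaler = scaler),
          file.path(config$output_dir, "model.rds"))
  jsonlite::write_json(
    list(mae = metrics$mae, mape = metrics$mape, rmse = metrics$rmse,
         r2 = metrics$r2, n_train = length(split$train),
         n_test = length(split$test)),
    file.path(config$output_dir, "metrics.json"),
    auto_unbox = TRUE, digits = 10, na = "null")
  jsonlite::write_json(
    list(seed = config$seed, config_md5 = config_digest(config),
         n_subjects = n, n_variants_post_qc = ncol(genotypes$counts),
         views = names(views), package_version = "0.1.0"),
    file.path(config$output_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA)

  list(metrics = metrics, association = assoc, selected = sel$variant_ids,
       importance = imp, model = fit$params, head = head_fit,
       scaler = scaler, split = split, trace = fit$trace,
       dir = config$output_dir)
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Convenience wrapper for generating end-to-end test inputs: writes the
#' genotype table, one table per view, and a phenotype + covariate table.
#'
#' @param study a [make_study()] result.
#' @param dir output directory.
#' @return named list of written paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(genotypes = file.path(dir, "genotypes.tsv"))
  write_genotypes(study$genotypes, paths$genotypes)
  for (v in names(study$views)) {
    x <- study$views[[v]]
    rownames(x) <- study$genotypes$subject_ids
    colnames(x) <- paste0(v, "_f", seq_len(ncol(x)))
    paths[[v]] <- file.path(dir, paste0(v, ".tsv"))
    write_feature_table(x, paths[[v]])
  }
  ptab <- data.frame(subject_id = study$genotypes$subject_ids,
                     phenotype = signif(unname(study$phenotype), 10),
                     signif(study$covariates, 10), check.names = FALSE)
  paths$phenotype <- file.path(dir, "phenotype.tsv")
  utils::write.table(ptab, paths$phenotype, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
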