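#' Genotype principal components for population stratification
#'
#' Standard Price-style genotype PCA: missing calls are mean-imputed per
#' variant, each variant is centered at twice its allele frequency estimate
#' and scaled by `sqrt(2 p (1 - p))`, and the top-k left singular directions
#' give per-subject PC scores. Monomorphic variants (zero variance) are
#' skipped. Signs are fixed so that each component's largest-magnitude
#' variant loading is positive, making scores deterministic.
#'
#' @param genotypes a post-QC [genotype_matrix()].
#' @param k number of components (<= min(N, S)).
#' @return N x k matrix of PC scores (columns `PC1..PCk`).
#' @export
genotype_pca <- function(genotypes, k = 10) {
  x <- impute_mean(genotypes$counts)
  p_hat <- colMeans(x) / 2
  keep <- p_hat > 0 & p_hat < 1 & apply(x, 2, stats::sd) > 0
  if (!any(keep)) stop_mvfuse("genotype matrix has zero variance")
  x <- x[, keep, drop = FALSE]
  p_hat <- p_hat[keep]
  x <- sweep(x, 2, 2 * p_hat)
  x <- sweep(x, 2, sqrt(2 * p_hat * (1 - p_hat)), "/")
  assert_that(k <= min(dim(x)), "k must be <= min(N, S)")
  sv <- svd(x, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, 0)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k) %*% diag(flip, k)
  dimnames(scores) <- list(genotypes$subject_ids, paste0("PC", seq_len(k)))
  scores
}

#' Bundle covariates for association testing
#'
#' @param matrix N x C numeric matrix with no missing entries.
#' @param names column names (default taken from the matrix).
#' @return list of class `covariate_set`.
#' @export
covariate_set <- function(matrix, names = colnames(matrix)) {
  matrix <- as.matrix(matrix)
  assert_that(!anyNA(matrix), "covariates must have no missing entries")
  assert_that(ncol(matrix) >= 1, "at least one covariate required")
  names <- names %||% paste0("cov", seq_len(ncol(matrix)))
  colnames(matrix) <- names
  structure(list(matrix = matrix, names = names), class = "covariate_set")
}

#' Residualize a vector (or matrix of columns) against covariates
#'
#' Least-squares residuals after regressing on the covariates plus an
#' intercept. Residuals are orthogonal to every covariate column and sum to
#' (numerically) zero. This is the covariate adjustment applied to both the
#' phenotype and each genotype column before the score test.
#'
#' @param values numeric vector of length N, or an N x m matrix whose
#'   columns are residualized jointly (one QR factorization).
#' @param covariates a [covariate_set()], a plain N x C matrix, or NULL for
#'   intercept-only adjustment (mean removal).
#' @return residuals with the shape of `values`.
#' @export
residualize <- function(values, covariates = NULL) {
  v <- as.matrix(values)
  x <- if (is.null(covariates)) {
    matrix(numeric(), nrow(v), 0)
  } else if (inherits(covariates, "covariate_set")) {
    covariates$matrix
  } else {
    as.matrix(covariates)
  }
  assert_that(nrow(v) == nrow(x), "values and covariates must be row-aligned")
  assert_that(nrow(v) > ncol(x) + 1, "need N > C + 1 subjects")
  design <- cbind(`(intercept)` = 1, x)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop_mvfuse("rank-deficient covariates; offending column(s): ",
                paste(bad, collapse = ", "))
  }
  res <- qr.resid(qrd, v)
  if (is.vector(values)) drop(res) else res
}

#' Score test for association between adjusted phenotype and genotype
#'
#' Given covariate-adjusted residuals of the phenotype and of one genotype
#' column, computes the score statistic
#' `U = sum(y_res * g_res)`, `V = (1/N) sum(y_res^2) sum(g_res^2)`,
#' `T = U^2 / V`, with the p-value from the upper tail of the chi-square
#' distribution on 1 degree of freedom (equivalently a two-sided normal test
#' on `U / sqrt(V)`).
#'
#' @param y_res,g_res numeric residual vectors of equal length (N >= 3).
#' @return list with `U`, `V`, `T`, `p` and a logical `degenerate` flag set
#'   when either residual vector has zero variance (then `p = 1`).
#' @examples
#' score_test(c(1, -1, 0), c(1, 0, -1))
#' @export
score_test <- function(y_res, g_res) {
  n <- length(y_res)
  assert_that(n == length(g_res), "residual vectors must have equal length")
  assert_that(n >= 3, "need at least 3 subjects")
  ssy <- sum(y_res^2)
  ssg <- sum(g_res^2)
  if (ssy <= 0 || ssg <= 0) {
    return(list(U = 0, V = 0, T = 0, p = 1, degenerate = TRUE))
  }
  u <- sum(y_res * g_res)
  v <- ssy * ssg / n
  t <- u^2 / v
  list(U = u, V = v, T = t,
       p = stats::pchisq(t, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Genome-wide association scan with covariate adjustment
#'
#' Residualizes the phenotype once and every (mean-imputed) genotype column
#' against the same covariates, then applies the score test per variant.
#'
#' @param genotypes a post-QC [genotype_matrix()].
#' @param phenotype numeric vector of length N.
#' @param covariates a [covariate_set()] (typically age/weight/height plus
#'   genotype PCs).
#' @return data frame of class `association_table` with columns
#'   `variant_id`, `chrom`, `pos`, `U`, `V`, `T`, `p`, `degenerate`,
#'   one row per variant (input order).
#' @export
run_gwas <- function(genotypes, phenotype, covariates) {
  n <- nrow(genotypes$counts)
  assert_that(length(phenotype) == n, "phenotype length must match subjects")
  g <- impute_mean(genotypes$counts)
  y_res <- residualize(as.numeric(phenotype), covariates)
  g_res <- residualize(g, covariates)
  ssy <- sum(y_res^2)
  ssg <- colSums(g_res^2)
  u <- drop(crossprod(g_res, y_res))
  v <- ssy * ssg / n
  degenerate <- ssg <= 1e-12 | ssy <= 1e-12
  t <- ifelse(degenerate, 0, u^2 / pmax(v, .Machine$double.xmin))
  p <- ifelse(degenerate, 1, stats::pchisq(t, df = 1, lower.tail = FALSE))
  out <- data.frame(
    variant_id = genotypes$variant_ids,
    chrom = genotypes$chromosome,
    pos = genotypes$position,
    U = ifelse(degenerate, 0, u),
    V = ifelse(degenerate, 0, v),
    T = t, p = p, degenerate = degenerate,
    stringsAsFactors = FALSE
  )
  class(out) <- c("association_table", "data.frame")
  out
}

#' Select the top-k variants by association p-value
#'
#' The k variants with smallest p are returned, ties broken by ascending
#' (chromosome, position); the feature matrix contains their mean-imputed
#' genotype columns in selection order, ready to serve as the
#' genotype-derived view.
#'
#' @param table an association table from [run_gwas()].
#' @param genotypes the matching [genotype_matrix()].
#' @param k number of variants to keep (default 256).
#' @return list with `variant_ids` and the N x k `features` matrix.
#' @export
select_top_k <- function(table, genotypes, k = 256) {
  assert_that(nrow(table) >= 1, "association table is empty")
  if (k > nrow(table)) {
    stop_mvfuse("k = ", k, " exceeds table size ", nrow(table))
  }
  chrom_key <- suppressWarnings(as.numeric(table$chrom))
  if (anyNA(chrom_key)) chrom_key <- xtfrm(table$chrom)
  ord <- order(table$p, chrom_key, table$pos)
  sel <- ord[seq_len(k)]
  ids <- table$variant_id[sel]
  cols <- match(ids, genotypes$variant_ids)
  assert_that(!anyNA(cols), "association table ids not found in genotypes")
  features <- impute_mean(genotypes$counts[, cols, drop = FALSE])
  colnames(features) <- ids
  list(variant_ids = ids, features = features)
}
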