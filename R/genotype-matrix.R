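#' Construct a genotype matrix
#'
#' Container for additive-coded genotypes: an N x S matrix of minor-allele
#' counts in \{0, 1, 2\} (NA = missing call) with per-variant chromosome and
#' position metadata. This is the object every quality-control and
#' association function in the package consumes.
#'
#' @param counts numeric matrix, subjects in rows, variants in columns;
#'   entries 0/1/2 or NA.
#' @param subject_ids character vector of unique subject identifiers
#'   (default `"S1".."SN"`).
#' @param variant_ids character vector of unique variant identifiers
#'   (default `"snp1".."snpS"`).
#' @param chromosome per-variant chromosome label.
#' @param position per-variant 1-based coordinate; must be nondecreasing
#'   within each chromosome.
#' @return an object of class `genotype_matrix` with elements `counts`,
#'   `subject_ids`, `variant_ids`, `chromosome`, `position`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 1), 2, 2))
#' dim(g$counts)
#' @export
genotype_matrix <- function(counts, subject_ids = NULL, variant_ids = NULL,
                            chromosome = NULL, position = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  n <- nrow(counts)
  s <- ncol(counts)
  ok <- counts[!is.na(counts)]
  if (length(ok) && !all(ok %in% c(0, 1, 2))) {
    stop_mvfuse("genotype counts must be 0, 1, 2 or NA")
  }
  subject_ids <- subject_ids %||% paste0("S", seq_len(n))
  variant_ids <- variant_ids %||% paste0("snp", seq_len(s))
  assert_that(!anyDuplicated(subject_ids), "subject ids must be unique")
  assert_that(!anyDuplicated(variant_ids), "variant ids must be unique")
  assert_that(length(subject_ids) == n, "subject_ids length mismatch")
  assert_that(length(variant_ids) == s, "variant_ids length mismatch")
  chromosome <- as.character(chromosome %||% rep("1", s))
  position <- as.integer(position %||% seq_len(s))
  assert_that(length(chromosome) == s && length(position) == s,
              "variant metadata length mismatch")
  for (chr in unique(chromosome)) {
    if (is.unsorted(position[chromosome == chr])) {
      stop_mvfuse("positions must be nondecreasing within chromosome ", chr)
    }
  }
  dimnames(counts) <- list(subject_ids, variant_ids)
  structure(
    list(counts = counts, subject_ids = subject_ids,
         variant_ids = variant_ids, chromosome = chromosome,
         position = position),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d variants (%.2f%% missing)\n",
              nrow(x$counts), ncol(x$counts),
              100 * mean(is.na(x$counts))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

## Subset keeping metadata in sync (internal).
subset_genotypes <- function(g, subjects = NULL, variants = NULL) {
  subjects <- subjects %||% seq_len(nrow(g$counts))
  variants <- variants %||% seq_len(ncol(g$counts))
  genotype_matrix(
    g$counts[subjects, variants, drop = FALSE],
    subject_ids = g$subject_ids[subjects],
    variant_ids = g$variant_ids[variants],
    chromosome = g$chromosome[variants],
    position = g$position[variants]
  )
}

## Per-variant mean imputation of missing calls (internal; standard GWAS
## default, keeps the allele-frequency expectation).
impute_mean <- function(counts) {
  if (!anyNA(counts)) return(counts)
  mu <- colMeans(counts, na.rm = TRUE)
  idx <- which(is.na(counts), arr.ind = TRUE)
  counts[idx] <- mu[idx[, 2L]]
  counts
}
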