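#' Per-variant and per-subject genotype missing rates
#'
#' @param genotypes a [genotype_matrix()].
#' @return list with `variant` and `subject` proportions of missing calls,
#'   named by the corresponding ids.
#' @export
compute_missing_rates <- function(genotypes) {
  m <- is.na(genotypes$counts)
  assert_that(length(m) > 0, "empty genotype matrix")
  list(
    variant = colMeans(m),
    subject = rowMeans(m)
  )
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Exact two-sided test for deviation from HWE genotype proportions at a
#' biallelic variant, conditioning on the observed allele counts: the
#' p-value is the summed conditional probability of every heterozygote count
#' (with the same sample size and allele counts) whose probability does not
#' exceed that of the observed count. Probabilities follow the standard
#' recurrence over heterozygote counts (Wigginton-style), so the test is
#' exact for any sample size.
#'
#' @param n_AA count of major-allele homozygotes.
#' @param n_Aa count of heterozygotes.
#' @param n_aa count of minor-allele homozygotes.
#' @return p-value in (0, 1].
#' @examples
#' hwe_exact_p(50, 21, 29)
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "genotype counts must be nonnegative integers")
  n <- sum(counts)
  if (n < 1) stop_mvfuse("at least one subject required")
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa
  n_rare <- min(n_rare, 2 * n - n_rare)
  if (n_rare == 0) return(1)           # monomorphic: single attainable table
  ## attainable heterozygote counts share the parity of the rare-allele count
  het_max <- min(n_rare, 2 * n - n_rare)
  hets <- seq(n_rare %% 2, het_max, by = 2)
  ## unnormalized recurrence P(h+2)/P(h) = 4 hom_rare(h) hom_com(h) /
  ## ((h+2)(h+1)), accumulated in log space so large n cannot overflow
  lp <- numeric(length(hets))
  if (length(hets) > 1) {
    for (i in seq_len(length(hets) - 1)) {
      h <- hets[i]
      hom_rare <- (n_rare - h) / 2
      hom_com <- n - h - hom_rare
      lp[i + 1] <- lp[i] +
        log(4 * hom_rare * hom_com) - log((h + 2) * (h + 1))
    }
  }
  probs <- exp(lp - max(lp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

#' Minor allele frequency of one genotype column
#'
#' @param genotype_column numeric vector of additive genotype calls
#'   (0/1/2, NA = missing).
#' @return frequency of the less common allele among non-missing calls,
#'   in \[0, 0.5\].
#' @export
compute_maf <- function(genotype_column) {
  g <- genotype_column[!is.na(genotype_column)]
  if (!length(g)) stop_mvfuse("all genotype calls missing")
  af <- sum(g) / (2 * length(g))
  min(af, 1 - af)
}

#' Variant and subject quality-control thresholds
#'
#' Defaults follow the usual GWAS pass: drop variants with more than 5%
#' missing calls, HWE exact-test p below 1e-4 or MAF below 5%, and subjects
#' with more than 20% missing calls.
#'
#' @param variant_missing_max,hwe_p_min,maf_min,subject_missing_max
#'   thresholds, all in \[0, 1\].
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(variant_missing_max = 0.05, hwe_p_min = 1e-4,
                          maf_min = 0.05, subject_missing_max = 0.20) {
  th <- list(variant_missing_max = variant_missing_max,
             hwe_p_min = hwe_p_min, maf_min = maf_min,
             subject_missing_max = subject_missing_max)
  assert_that(all(unlist(th) >= 0) && all(unlist(th) <= 1),
              "thresholds must lie in [0, 1]")
  structure(th, class = "qc_thresholds")
}

#' Apply variant and subject quality control
#'
#' Subjects with excessive missingness are dropped first; variant statistics
#' (missing rate, HWE exact p, MAF) are then computed on the retained
#' subjects and variants failing any rule are removed. A variant failing
#' several rules appears once in the report with all reasons recorded.
#'
#' @param genotypes a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list with the filtered `genotypes` and a `report` data frame
#'   (`id`, `type`, `reasons`, one row per removed subject or variant).
#' @export
qc_filter <- function(genotypes, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  rates <- compute_missing_rates(genotypes)
  keep_subj <- rates$subject <= thresholds$subject_missing_max
  report <- data.frame(id = character(), type = character(),
                       reasons = character(), stringsAsFactors = FALSE)
  if (any(!keep_subj)) {
    report <- rbind(report, data.frame(
      id = genotypes$subject_ids[!keep_subj], type = "subject",
      reasons = "missing_rate", stringsAsFactors = FALSE
    ))
    genotypes <- subset_genotypes(genotypes, subjects = which(keep_subj))
  }
  counts <- genotypes$counts
  vmiss <- colMeans(is.na(counts))
  maf <- apply(counts, 2, function(g) {
    if (all(is.na(g))) 0 else compute_maf(g)
  })
  hwe <- apply(counts, 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(0)
    hwe_exact_p(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  fail_miss <- vmiss > thresholds$variant_missing_max
  fail_hwe <- hwe < thresholds$hwe_p_min
  fail_maf <- maf < thresholds$maf_min
  fail_any <- fail_miss | fail_hwe | fail_maf
  if (any(fail_any)) {
    reasons <- vapply(which(fail_any), function(j) {
      paste(c("missing_rate", "hwe", "maf")[
        c(fail_miss[j], fail_hwe[j], fail_maf[j])], collapse = ",")
    }, "")
    report <- rbind(report, data.frame(
      id = genotypes$variant_ids[fail_any], type = "variant",
      reasons = reasons, stringsAsFactors = FALSE
    ))
  }
  if (all(fail_any)) stop_mvfuse("quality control removed every variant")
  genotypes <- subset_genotypes(genotypes, variants = which(!fail_any))
  list(genotypes = genotypes, report = report)
}
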