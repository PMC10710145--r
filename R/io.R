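## Delimited dialect used throughout: tab-separated, UTF-8, "NA" for missing,
## header row of feature/variant names, first column the subject id.

#' Read a genotype matrix from disk
#'
#' Two formats are supported: a delimited additive-coding table (subjects x
#' variants, entries 0/1/2/NA, first column subject id) and VCF, where GT
#' fields are mapped to alternate-allele counts (`0/1` -> 1, `1/1` -> 2,
#' `./.` -> missing; phased separators handled). VCF parsing uses the vcfR
#' package.
#'
#' @param path file path.
#' @param format `"delimited"` or `"vcf"` (default guessed from the
#'   extension).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "delimited", "vcf")) {
  format <- match.arg(format)
  assert_that(file.exists(path), paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "delimited"
  }
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  assert_that(ncol(tab) >= 2, "genotype table needs an id column and variants")
  ids <- as.character(tab[[1]])
  counts <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(counts) <- "double"
  bad <- which(!(is.na(counts) | counts %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_mvfuse(sprintf(
      "invalid genotype value %s at row %d (subject %s), column %s",
      counts[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]],
      colnames(counts)[bad[1, 2]]))
  }
  genotype_matrix(counts, subject_ids = ids, variant_ids = colnames(counts))
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_mvfuse("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))
  ## rows = variants, columns = subjects; map GT strings to allele counts
  count_alt <- function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles != "0")
  }
  counts <- t(apply(gt, c(1, 2), count_alt))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(
    fix[is.na(ids) | ids == ".", "CHROM"], ":",
    fix[is.na(ids) | ids == ".", "POS"])
  genotype_matrix(counts,
                  subject_ids = colnames(gt),
                  variant_ids = unname(ids),
                  chromosome = unname(fix[, "CHROM"]),
                  position = as.integer(fix[, "POS"]))
}

#' Write a genotype matrix as a delimited additive table
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  tab <- data.frame(subject_id = genotypes$subject_ids,
                    genotypes$counts, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits an uncompressed VCFv4.2 file with GT-only FORMAT fields
#' (synthetic REF/ALT alleles A/B), sufficient for round-tripping additive
#' genotype counts through standard VCF tooling.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output file (conventionally `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=mvfuse",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$subject_ids), collapse = "\t")
  ), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_along(genotypes$variant_ids)) {
    g <- genotypes$counts[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    writeLines(paste(c(genotypes$chromosome[j], genotypes$position[j],
                       genotypes$variant_ids[j], "A", "B", ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a subject-by-feature table
#'
#' Expects a header row of feature names with the subject id in the first
#' column; rejects duplicate subject ids.
#'
#' @param path file path.
#' @return numeric matrix with subject ids as row names, column order as in
#'   the file.
#' @export
read_feature_table <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    stop_mvfuse("duplicate subject ids in ", path, ": ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  x <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- ids
  x
}

#' Write a subject-by-feature table
#'
#' @param x numeric matrix with subject ids as row names.
#' @param path output file.
#' @param digits significant digits for floating-point text (fixed so
#'   outputs are byte-reproducible).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, digits = 10) {
  tab <- data.frame(subject_id = rownames(x) %||% paste0("S", seq_len(nrow(x))),
                    signif(as.matrix(x), digits), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align multiple subject-indexed inputs by id intersection
#'
#' Subjects absent from any input are dropped with a message reporting the
#' count; an empty intersection is an error.
#'
#' @param ... named matrices/data frames with subject ids as row names, or
#'   vectors named by subject id.
#' @return list of the inputs restricted to the common subjects, in a
#'   common order.
#' @export
align_subjects <- function(...) {
  inputs <- list(...)
  assert_that(length(inputs) >= 2, "need at least two inputs to align")
  ids <- lapply(inputs, function(x) {
    if (is.matrix(x) || is.data.frame(x)) rownames(x) else names(x)
  })
  assert_that(!any(vapply(ids, is.null, TRUE)), "all inputs need subject ids")
  common <- Reduce(intersect, ids)
  if (!length(common)) stop_mvfuse("no subjects shared across inputs")
  dropped <- sum(vapply(ids, function(i) length(setdiff(i, common)), 0L))
  if (dropped > 0) {
    message(dropped, " subject record(s) absent from some input were dropped")
  }
  lapply(inputs, function(x) {
    if (is.matrix(x) || is.data.frame(x)) x[common, , drop = FALSE]
    else x[common]
  })
}
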