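# GenotypeMatrix container and VCF input.
#
# Dosages are stored individuals x variants as minor-allele counts in
# [0, 2]; missing genotypes are mean-imputed at load time (imputation to the
# variant mean preserves the allele frequency and keeps the SKAT kernel
# well defined), so downstream code never sees NA.

#' Construct a genotype matrix
#'
#' @param dosages numeric matrix, `N` individuals x `M` variants, entries in
#'   `[0, 2]` (minor-allele counts; fractional values arise only from
#'   mean-imputed missing genotypes).
#' @param positions integer vector of 1-based base-pair coordinates, sorted
#'   non-decreasing (ties are permitted only for split multi-allelic
#'   records).
#' @param chrom single chromosome name.
#' @param sample_ids optional individual identifiers (default `S1..SN`).
#' @param variant_ids optional variant identifiers.
#' @param flip_to_minor if `TRUE` (default), columns whose allele frequency
#'   exceeds 0.5 are flipped (`d -> 2 - d`) so dosages always count the
#'   minor allele; this makes the container invariant to allele labelling
#'   of the source.
#' @param drop_monomorphic if `TRUE` (default), columns with no minor
#'   alleles observed are removed.
#' @return an object of class `genotype_matrix` with elements `dosages`,
#'   `positions`, `chrom`, `maf`, `sample_ids`, `variant_ids`.
#' @export
genotype_matrix <- function(dosages, positions, chrom = "chr",
                            sample_ids = NULL, variant_ids = NULL,
                            flip_to_minor = TRUE, drop_monomorphic = TRUE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages); m <- ncol(dosages)
  if (length(positions) != m)
    stop_winsig("positions length must equal the number of variant columns",
                "winsig_bad_argument")
  if (m > 1 && any(diff(positions) < 0))
    stop_winsig("positions must be sorted in ascending order",
                "winsig_bad_argument")
  if (anyNA(dosages)) {
    cm <- colMeans(dosages, na.rm = TRUE)
    idx <- which(is.na(dosages), arr.ind = TRUE)
    dosages[idx] <- cm[idx[, 2L]]
  }
  if (any(dosages < 0 | dosages > 2))
    stop_winsig("dosages must lie in [0, 2]", "winsig_bad_argument")
  p <- colMeans(dosages) / 2
  if (flip_to_minor && any(p > 0.5)) {
    flip <- p > 0.5
    dosages[, flip] <- 2 - dosages[, flip]
    p[flip] <- 1 - p[flip]
  }
  maf <- pmin(p, 1 - p)
  sample_ids <- sample_ids %||% paste0("S", seq_len(n))
  variant_ids <- variant_ids %||% paste0(chrom, ":", positions)
  keep <- rep(TRUE, m)
  if (drop_monomorphic) keep <- maf > 0
  structure(
    list(dosages = dosages[, keep, drop = FALSE],
         positions = as.numeric(positions)[keep],
         chrom = chrom,
         maf = unname(maf[keep]),
         sample_ids = as.character(sample_ids),
         variant_ids = as.character(variant_ids)[keep]),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d variants on %s\n",
              nrow(x$dosages), ncol(x$dosages), x$chrom))
  cat(sprintf("  positions %s..%s; MAF median %.4g, %.1f%% below 0.01\n",
              format(x$positions[1], big.mark = ","),
              format(tail(x$positions, 1), big.mark = ","),
              stats::median(x$maf), 100 * mean(x$maf < 0.01)))
  invisible(x)
}

#' Number of individuals / variants
#' @param g a `genotype_matrix`.
#' @return integer count.
#' @export
n_individuals <- function(g) nrow(g$dosages)

#' @rdname n_individuals
#' @export
n_variants <- function(g) ncol(g$dosages)

#' Read a VCF into a genotype matrix of minor-allele dosages
#'
#' Parses diploid GT fields with [VariantAnnotation::readVcf()].
#' Multi-allelic records are split into one bi-allelic dosage column per
#' alternate allele.  Missing genotypes are mean-imputed; sites where no
#' minor allele is observed are excluded.  Dosage columns are flipped where
#' necessary so that entries always count the minor allele, making the
#' result invariant to REF/ALT labelling.
#'
#' @param vcf_path path to a plain or bgzipped VCF.
#' @param region optional `"chrom:start-end"` string restricting the
#'   variants retained (filtered after parsing; no index required).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(vcf_path, region = NULL) {
  if (!file.exists(vcf_path))
    stop_winsig(sprintf("VCF not found: %s", vcf_path), "winsig_io")
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "unknown")
  if (nrow(vcf) == 0L)
    stop_winsig("VCF contains no variant records", "winsig_empty_region")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt))
    stop_winsig("VCF has no GT field", "winsig_io")
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)

  if (length(unique(chrom)) > 1L) {
    # process one contig at a time and bind; positions restart per contig
    stop_winsig("multi-contig VCFs must be read one region at a time",
                "winsig_bad_argument")
  }
  if (!is.null(region)) {
    reg <- parse_region(region)
    keep <- (chrom == reg$chrom) & pos >= reg$start & pos <= reg$end
    if (!any(keep))
      stop_winsig(sprintf("no variants in region %s", region),
                  "winsig_empty_region")
    gt <- gt[keep, , drop = FALSE]
    pos <- pos[keep]; chrom <- chrom[keep]; n_alt <- n_alt[keep]
  }

  cols <- vector("list", sum(n_alt))
  out_pos <- numeric(sum(n_alt))
  out_id <- character(sum(n_alt))
  k <- 0L
  for (j in seq_len(nrow(gt))) {
    for (a in seq_len(n_alt[j])) {
      k <- k + 1L
      cols[[k]] <- gt_to_dosage(gt[j, ], allele = a)
      out_pos[k] <- pos[j]
      out_id[k] <- sprintf("%s:%d_%d", chrom[j], pos[j], a)
    }
  }
  genotype_matrix(do.call(cbind, cols), out_pos, chrom = chrom[1],
                  sample_ids = colnames(gt), variant_ids = out_id)
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L)
    stop_winsig("region must look like 'chrom:start-end'",
                "winsig_bad_argument")
  list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}

# Count occurrences of `allele` in diploid GT strings.  The common diploid
# cases go through a dictionary; anything else (multi-allelic, haploid-coded)
# falls back to tokenising.  Missing alleles yield NA (mean-imputed later).
gt_to_dosage <- function(gt_row, allele = 1L) {
  a <- as.character(allele)
  dict_keys <- c("0/0", "0|0", "0/1", "1/0", "0|1", "1|0", "1/1", "1|1",
                 "./.", ".|.", ".")
  dict_vals <- c(0, 0, 1, 1, 1, 1, 2, 2, NA, NA, NA)
  d <- dict_vals[match(gt_row, dict_keys)]
  if (a != "1") d[] <- NA  # dictionary only encodes allele 1
  miss <- is.na(d) & !gt_row %in% c("./.", ".|.", ".")
  if (any(miss)) {
    toks <- strsplit(gt_row[miss], "[/|]")
    if (any(lengths(toks) != 2L))
      stop_winsig("non-diploid GT encountered", "winsig_bad_ploidy")
    d[miss] <- vapply(toks, function(t) {
      if (any(t == ".")) return(NA_real_)
      sum(t == a)
    }, numeric(1))
  }
  d
}
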