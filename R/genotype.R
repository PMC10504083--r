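#' Construct a genotype matrix object
#'
#' Container for a samples x variants dosage matrix (entries 0/1/2/NA, the
#' count of the counted allele) plus per-variant metadata. On the X
#' chromosome, hemizygous males are expected to carry dosages in \{0, 2\}
#' (the single allele counted twice), mirroring the convention of coding the
#' minor-allele count as 0 or 2 for males.
#'
#' @param dosages Numeric matrix, samples in rows (rownames = sample ids),
#'   variants in columns (colnames = variant ids).
#' @param variants data.frame with columns `id`, `chrom` (1-22 or "X"),
#'   `pos` (1-based), `ref`, `alt`; optional `annotation_class`. `maf` and
#'   `missing_rate` are (re)computed from the dosages.
#' @param samples Optional data.frame with column `sample_id` and optional
#'   `sex` (0 = male, 1 = female).
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, samples = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages))) stop("dosage rownames (sample ids) required")
  if (is.null(colnames(dosages))) colnames(dosages) <- variants$id
  if (!identical(colnames(dosages), as.character(variants$id)))
    stop("dosage columns and variant table out of order")
  if (any(!is.na(dosages) & !(dosages %in% c(0, 1, 2))))
    stop("dosages must be 0, 1, 2 or NA")
  variants$maf <- variant_maf(dosages)
  variants$missing_rate <- colMeans(is.na(dosages))
  if (is.null(samples)) samples <- data.frame(sample_id = rownames(dosages))
  structure(list(dosages = dosages, variants = variants,
                 sample_ids = rownames(dosages), samples = samples),
            class = "genotype_matrix")
}

variant_maf <- function(dosages) {
  f <- colMeans(dosages, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "samples x", ncol(x$dosages),
      "variants;", sum(x$variants$chrom == "X"), "on X\n")
  invisible(x)
}

#' Read genotypes from PLINK or VCF
#'
#' PLINK input is a `.bed`/`.bim`/`.fam` trio given by its common prefix
#' (bed v1.00 magic bytes, SNP-major). VCF input (v4.2, GT field) is parsed
#' with the vcfR package; non-biallelic records are dropped with a warning.
#' By default the counted allele is the minor allele recomputed from the
#' data: variants whose loaded allele frequency exceeds 0.5 are flipped
#' (dosage -> 2 - dosage, ref/alt labels swapped).
#'
#' @param path PLINK prefix (no extension) or VCF file path.
#' @param format `"plink"` or `"vcf"`.
#' @param count `"minor"` (default) or `"alt"`: which allele the dosage counts.
#' @return A [genotype_matrix()]. The number of dropped non-biallelic records
#'   is attached as attribute `n_dropped_multiallelic`.
#' @export
read_genotypes <- function(path, format = c("plink", "vcf"),
                           count = c("minor", "alt")) {
  format <- match.arg(format)
  count <- match.arg(count)
  g <- switch(format, plink = read_plink(path), vcf = read_vcf(path))
  if (count == "minor") {
    f <- colMeans(g$dosages, na.rm = TRUE) / 2
    flip <- which(!is.na(f) & f > 0.5)
    if (length(flip)) {
      g$dosages[, flip] <- 2 - g$dosages[, flip]
      tmp <- g$variants$ref[flip]
      g$variants$ref[flip] <- g$variants$alt[flip]
      g$variants$alt[flip] <- tmp
      g$variants$maf <- variant_maf(g$dosages)
    }
  }
  g
}

read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim"); fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing PLINK file: ", f)
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              colClasses = c("character", "character", "numeric",
                                             "integer", "character", "character"))
  n <- nrow(fam_df); m <- nrow(bim_df)
  raw <- readBin(bed, what = "raw", n = 3 + ceiling(n / 4) * m)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file (bad magic bytes): ", bed)
  if (raw[3] != as.raw(0x01)) stop("only SNP-major bed files are supported")
  body <- raw[-(1:3)]
  if (length(body) != ceiling(n / 4) * m)
    stop("bed file size inconsistent with fam/bim sample and variant counts")
  ## 2-bit codes per sample: 00 hom A1, 01 missing, 10 het, 11 hom A2;
  ## dosage counts A1
  lut <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  bpv <- ceiling(n / 4)
  ints <- as.integer(body)
  codes <- matrix(0L, nrow = 4 * bpv, ncol = m)
  block <- matrix(ints, nrow = bpv, ncol = m)
  for (k in 0:3) codes[seq_len(bpv) * 4 - 3 + k, ] <- (block %/% 4^k) %% 4
  dos <- matrix(lut[codes[seq_len(n), , drop = FALSE] + 1L], nrow = n, ncol = m)
  rownames(dos) <- as.character(fam_df$V2)
  colnames(dos) <- bim_df$V2
  variants <- data.frame(id = bim_df$V2, chrom = norm_chrom(bim_df$V1),
                         pos = bim_df$V4, ref = bim_df$V6, alt = bim_df$V5,
                         stringsAsFactors = FALSE)
  sex <- fam_df$V5  # PLINK: 1 male, 2 female, 0 unknown
  samples <- data.frame(sample_id = as.character(fam_df$V2),
                        sex = ifelse(sex == 2, 1L, ifelse(sex == 1, 0L, NA_integer_)))
  g <- genotype_matrix(dos, variants, samples)
  attr(g, "n_dropped_multiallelic") <- 0L
  g
}

read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required to read VCF files")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)  # single-record VCF
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT)
  n_drop <- sum(multi)
  if (n_drop > 0) {
    warning(n_drop, " non-biallelic record(s) dropped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_real_)
    al <- strsplit(x, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    s <- sum(al == "1")
    if (length(al) == 1) 2 * s else s  # haploid calls coded 0/2
  }
  dos <- t(apply(gt, 1, function(r) vapply(r, count_alt, numeric(1))))
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  dos <- matrix(as.numeric(dos), nrow = ncol(gt), ncol = nrow(gt), byrow = TRUE,
                dimnames = list(colnames(gt), ids))
  variants <- data.frame(id = ids, chrom = norm_chrom(fix$CHROM),
                         pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  g <- genotype_matrix(dos, variants)
  attr(g, "n_dropped_multiallelic") <- n_drop
  g
}

norm_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x))
  x[x %in% c("23")] <- "X"
  x
}

#' Write a genotype matrix as a PLINK bed/bim/fam trio
#'
#' The counted allele is written as A1 (bim column 5).
#'
#' @param g A [genotype_matrix()].
#' @param prefix Output path prefix (writes `prefix.bed/.bim/.fam`).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  n <- nrow(g$dosages); m <- ncol(g$dosages)
  sex <- if ("sex" %in% names(g$samples)) g$samples$sex else rep(NA_integer_, n)
  fam <- data.frame(fid = g$sample_ids, iid = g$sample_ids, pat = 0, mat = 0,
                    sex = ifelse(is.na(sex), 0L, ifelse(sex == 1, 2L, 1L)),
                    phe = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = g$variants$chrom, id = g$variants$id, cm = 0,
                    pos = g$variants$pos, a1 = g$variants$alt, a2 = g$variants$ref)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  code <- matrix(1L, n, m)  # 01 = missing
  code[!is.na(g$dosages) & g$dosages == 2] <- 0L
  code[!is.na(g$dosages) & g$dosages == 1] <- 2L
  code[!is.na(g$dosages) & g$dosages == 0] <- 3L
  bpv <- ceiling(n / 4)
  pad <- 4 * bpv - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, m))
  idx <- seq(1, 4 * bpv, by = 4)
  bytes <- code[idx, , drop = FALSE] + 4L * code[idx + 1, , drop = FALSE] +
    16L * code[idx + 2, , drop = FALSE] + 64L * code[idx + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

#' Genotype quality-control filter
#'
#' Applies, in order: sample missingness, variant missingness, minor allele
#' frequency and exact Hardy-Weinberg filters, with the strict inequalities
#' as thresholds (remove if missing rate > 5%, MAF < 5%, HWE p < 5e-7 by
#' default). Variant statistics are recomputed after sample removal. On the
#' X chromosome the HWE test uses females only; if no sex information is
#' available it is taken from [infer_sex()].
#'
#' @param g A [genotype_matrix()].
#' @param sample_miss,var_miss,maf_min,hwe_p_min Thresholds.
#' @param sex Optional 0/1 vector named by sample id (0 = male, 1 = female).
#' @return List with `genotypes` (filtered) and `report` (a `qc_report`:
#'   per-rule removal counts and the thresholds used; serializable with
#'   [write_qc_report()]).
#' @export
qc_filter <- function(g, sample_miss = 0.05, var_miss = 0.05,
                      maf_min = 0.05, hwe_p_min = 5e-7, sex = NULL) {
  if (nrow(g$dosages) == 0 || ncol(g$dosages) == 0) stop("empty genotype matrix")
  n0 <- nrow(g$dosages); m0 <- ncol(g$dosages)
  smiss <- rowMeans(is.na(g$dosages))
  drop_s <- smiss > sample_miss
  dos <- g$dosages[!drop_s, , drop = FALSE]
  vmiss <- colMeans(is.na(dos))
  maf <- variant_maf(dos)
  is_x <- g$variants$chrom == "X"
  if (is.null(sex) && "sex" %in% names(g$samples))
    sex <- stats::setNames(g$samples$sex, g$samples$sample_id)
  if (any(is_x) && is.null(sex)) {
    sc <- infer_sex(g)
    sex <- stats::setNames(ifelse(sc$call == "female", 1L,
                                  ifelse(sc$call == "male", 0L, NA_integer_)),
                           sc$sample_id)
  }
  hwe_rows <- rep(TRUE, nrow(dos))
  hwe_p <- vapply(seq_len(ncol(dos)), function(j) {
    keep <- hwe_rows
    if (is_x[j]) keep <- !is.na(sex[rownames(dos)]) & sex[rownames(dos)] == 1
    d <- dos[keep, j]
    d <- d[!is.na(d)]
    if (length(d) == 0) return(1.0)
    hwe_exact(sum(d == 0), sum(d == 1), sum(d == 2))
  }, numeric(1))
  fail_miss <- vmiss > var_miss
  fail_maf <- !fail_miss & maf < maf_min
  fail_hwe <- !fail_miss & !fail_maf & hwe_p < hwe_p_min
  keep_v <- !(fail_miss | fail_maf | fail_hwe)
  if (!any(keep_v)) stop("all variants removed by QC; review thresholds")
  out <- genotype_matrix(dos[, keep_v, drop = FALSE],
                         g$variants[keep_v, , drop = FALSE],
                         g$samples[!drop_s, , drop = FALSE])
  report <- structure(list(
    thresholds = list(sample_miss = sample_miss, var_miss = var_miss,
                      maf_min = maf_min, hwe_p_min = hwe_p_min),
    n_samples_in = n0, n_samples_removed_missing = sum(drop_s),
    n_samples_retained = n0 - sum(drop_s),
    n_variants_in = m0,
    n_variants_removed_missing = sum(fail_miss),
    n_variants_removed_maf = sum(fail_maf),
    n_variants_removed_hwe = sum(fail_hwe),
    n_variants_retained = sum(keep_v),
    kinship_method = "correlation-based (simplified, not KING)",
    pca_method = "SVD of standardized dosages (simplified, not EIGENSTRAT)"),
    class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report: samples", x$n_samples_in, "->", x$n_samples_retained,
      "; variants", x$n_variants_in, "->", x$n_variants_retained, "\n")
  cat("  removed: missing", x$n_variants_removed_missing,
      "| maf", x$n_variants_removed_maf, "| hwe", x$n_variants_removed_hwe, "\n")
  invisible(x)
}

#' Serialize a QC report to JSON
#' @param report A `qc_report` from [qc_filter()].
#' @param path Output file path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Infer sample sex from X-chromosome heterozygosity
#'
#' Computes the heterozygosity rate across non-missing X-chromosome variants
#' per sample. Hemizygous males (dosage coded 0/2) show near-zero
#' heterozygosity. Samples below `het_male_max` are called male, above
#' `het_female_min` female, and in the dead zone (or with fewer than
#' `min_x_variants` non-missing X genotypes) ambiguous.
#'
#' @param g A [genotype_matrix()] with X-chromosome variants.
#' @param het_male_max,het_female_min Dead-zone boundaries.
#' @param min_x_variants Minimum informative X variants per sample.
#' @return data.frame with `sample_id`, `x_heterozygosity`, `call`.
#' @export
infer_sex <- function(g, het_male_max = 0.02, het_female_min = 0.15,
                      min_x_variants = 20) {
  xv <- g$variants$chrom == "X"
  if (!any(xv)) stop("no X-chromosome variants available for sex inference")
  dx <- g$dosages[, xv, drop = FALSE]
  n_obs <- rowSums(!is.na(dx))
  het <- rowSums(dx == 1, na.rm = TRUE) / pmax(n_obs, 1)
  call <- ifelse(n_obs < min_x_variants, "ambiguous",
                 ifelse(het < het_male_max, "male",
                        ifelse(het > het_female_min, "female", "ambiguous")))
  data.frame(sample_id = g$sample_ids, x_heterozygosity = het, call = call,
             stringsAsFactors = FALSE)
}

## mean-impute missing dosages and standardize columns; zero-variance
## columns are dropped (used for PCA, kinship and LD only)
standardize_dosages <- function(dosages, drop_constant = TRUE) {
  X <- dosages
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  X <- scale(X)
  sdv <- attr(X, "scaled:scale")
  if (drop_constant && any(sdv == 0 | is.na(sdv)))
    X <- X[, sdv > 0 & !is.na(sdv), drop = FALSE]
  X
}

#' Genetic principal components
#'
#' PCs of the column-standardized (mean-imputed) dosage matrix via SVD.
#' Returned scores are orthogonal with unit variance; each component's sign
#' is fixed so that its largest-magnitude variant loading is positive.
#'
#' @param g A [genotype_matrix()].
#' @param k Number of components.
#' @return samples x k matrix of PC scores.
#' @export
genetic_pcs <- function(g, k = 10) {
  if (k < 1) stop("k must be at least 1")
  X <- standardize_dosages(g$dosages)
  if (k > min(dim(X))) stop("k exceeds matrix dimensions")
  sv <- svd(X, nu = k, nv = k)
  rank <- sum(sv$d > sv$d[1] * 1e-8)
  if (k > rank) stop("k = ", k, " exceeds rank ", rank, " of the genotype matrix")
  flip <- vapply(seq_len(k), function(i) {
    v <- sv$v[, i]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE], 2, flip, `*`)
  scores <- scores * sqrt(nrow(X) - 1)
  rownames(scores) <- g$sample_ids
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Prune related samples by correlation-based kinship
#'
#' Pairwise kinship is estimated as half the correlation between samples'
#' (mean-imputed) genotype vectors (a simplified stand-in for pedigree-aware
#' estimators; duplicates score about 0.5, parent-offspring about 0.25).
#' Pairs above `threshold` are broken greedily: one member of each related
#' pair is removed by a seeded random choice until no pair remains.
#'
#' @param g A [genotype_matrix()] with at least two samples.
#' @param threshold Kinship above which a pair counts as related
#'   (default 0.177, the usual first/second-degree boundary).
#' @param seed Integer seed for the random member choice.
#' @return Character vector of retained sample ids.
#' @export
kinship_prune <- function(g, threshold = 0.177, seed = 1) {
  if (nrow(g$dosages) < 2) stop("at least two samples required")
  X <- g$dosages
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  kin <- stats::cor(t(X)) / 2
  diag(kin) <- 0
  rownames(kin) <- colnames(kin) <- rownames(X)
  keep <- rownames(kin)
  rng <- local_rng(seed)
  repeat {
    sub <- kin[keep, keep, drop = FALSE]
    hits <- which(sub > threshold, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    if (nrow(hits) == 0) break
    pair <- keep[hits[1, ]]
    drop <- pair[1 + (rng() > 0.5)]
    keep <- setdiff(keep, drop)
  }
  keep
}

## small deterministic RNG helper that does not disturb the global stream
local_rng <- function(seed) {
  env <- new.env()
  env$state <- seed
  function() {
    env$state <- (1103515245 * env$state + 12345) %% 2^31
    env$state / 2^31
  }
}
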