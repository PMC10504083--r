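#' Construct an expression matrix object
#'
#' Genes x samples abundance matrix with a measurement level and a
#' processing-stage tag. Stages advance only forward through
#' raw -> normalized -> residualized -> zscored.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). NA marks missing.
#' @param level `"protein"` or `"transcript"`.
#' @param stage Processing stage tag.
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, level = c("protein", "transcript"),
                              stage = c("raw", "normalized", "residualized", "zscored")) {
  level <- match.arg(level)
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry gene (row) and sample (column) names")
  structure(list(values = values, gene_ids = rownames(values),
                 sample_ids = colnames(values), level = level, stage = stage),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix (", x$level, ", stage ", x$stage, "): ",
      nrow(x$values), " genes x ", ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

.stage_order <- c(raw = 1, normalized = 2, residualized = 3, zscored = 4)

advance_stage <- function(e, to) {
  if (.stage_order[to] < .stage_order[e$stage])
    stop("stage transitions only move forward (", e$stage, " -> ", to, ")")
  e$stage <- to
  e
}

require_stage <- function(e, stages) {
  if (!e$stage %in% stages)
    stop("operation requires stage ", paste(stages, collapse = " or "),
         ", got ", e$stage)
  invisible(e)
}

#' Remove genes with excessive missingness
#'
#' Genes missing in more than `max_missing` of the samples are removed
#' (strict inequality: a gene missing in exactly the threshold fraction is
#' retained).
#'
#' @param e A raw-stage [expression_matrix()].
#' @param max_missing Maximum tolerated missing fraction (default 0.5).
#' @return Filtered [expression_matrix()].
#' @export
filter_missing <- function(e, max_missing = 0.5) {
  require_stage(e, "raw")
  frac <- rowMeans(is.na(e$values))
  keep <- frac <= max_missing
  if (!any(keep)) stop("no genes survive the missingness filter")
  expression_matrix(e$values[keep, , drop = FALSE], e$level, e$stage)
}

#' Total-abundance normalization for proteomics
#'
#' Divides each sample's abundances by that sample's total over non-missing
#' proteins (correcting loading differences), then log2 transforms. Output
#' is invariant to per-sample positive rescaling of the input.
#'
#' @param e A raw-stage [expression_matrix()] of positive abundances.
#' @return Normalized-stage [expression_matrix()]; missing values stay missing.
#' @export
normalize_protein <- function(e) {
  require_stage(e, "raw")
  if (any(e$values <= 0, na.rm = TRUE)) stop("abundances must be positive")
  totals <- colSums(e$values, na.rm = TRUE)
  vals <- log2(sweep(e$values, 2, totals, `/`))
  out <- expression_matrix(vals, e$level, "raw")
  advance_stage(out, "normalized")
}

#' Iterative PCA-based sample outlier removal
#'
#' Repeatedly computes the first two principal components across samples and
#' removes samples lying more than `sd_cut` standard deviations from the
#' mean on either, until no sample is removed. Missing values are gene-mean
#' imputed for the PCA only.
#'
#' @param e A normalized-stage [expression_matrix()] with at least 10 samples.
#' @param sd_cut Standard-deviation cutoff (default 4).
#' @param max_iter Iteration cap; exceeding it is treated as non-convergence.
#' @return List with `expression` (filtered matrix) , `removed` (sample ids)
#'   and `iterations`.
#' @export
remove_outlier_samples <- function(e, sd_cut = 4, max_iter = 20) {
  require_stage(e, c("normalized", "residualized"))
  if (ncol(e$values) < 10) stop("at least 10 samples required")
  vals <- e$values
  removed <- character(0)
  it <- 0
  repeat {
    it <- it + 1
    if (it > max_iter) stop("outlier removal did not converge in ", max_iter, " iterations")
    X <- vals
    if (anyNA(X)) {
      mu <- rowMeans(X, na.rm = TRUE)
      idx <- which(is.na(X), arr.ind = TRUE)
      X[idx] <- mu[idx[, 1]]
    }
    pc <- stats::prcomp(t(X), center = TRUE, scale. = FALSE, rank. = 2)
    out <- rep(FALSE, ncol(vals))
    for (j in 1:2) {
      s <- pc$x[, j]
      out <- out | abs(s - mean(s)) > sd_cut * stats::sd(s)
    }
    if (!any(out)) break
    removed <- c(removed, colnames(vals)[out])
    vals <- vals[, !out, drop = FALSE]
  }
  list(expression = expression_matrix(vals, e$level, e$stage),
       removed = removed, iterations = it)
}

## design matrix for a covariate subset of a sample table; categorical
## columns one-hot encoded dropping the first level
covariate_design <- function(s, covariates, data_only = FALSE) {
  miss <- setdiff(covariates, names(s))
  if (length(miss)) stop("covariates absent from sample table: ",
                         paste(miss, collapse = ", "))
  df <- s[, covariates, drop = FALSE]
  for (cl in names(df)) if (is.character(df[[cl]])) df[[cl]] <- factor(df[[cl]])
  stats::model.matrix(~ ., data = df)
}

#' Regress covariate effects out of an expression matrix
#'
#' Removes the effects of nuisance covariates (batch, age, post-mortem
#' interval, diagnosis, ...) by per-gene OLS, returning residuals plus the
#' gene mean. Sex is a protected variable and must not appear in the
#' covariate list. Genes with missing values are fitted on their non-missing
#' samples (pairwise exclusion).
#'
#' @param e A normalized-stage (or raw, for pre-normalized input)
#'   [expression_matrix()].
#' @param s Sample table (data.frame) with `sample_id` plus covariate columns,
#'   rows matching the expression samples.
#' @param covariates Character vector of covariate column names.
#' @return Residualized-stage [expression_matrix()].
#' @export
regress_out <- function(e, s, covariates) {
  require_stage(e, c("raw", "normalized"))
  if (any(tolower(covariates) == "sex"))
    stop("sex is a protected variable and cannot be regressed out")
  s <- s[match(e$sample_ids, s$sample_id), , drop = FALSE]
  X <- covariate_design(s, covariates)
  Y <- e$values
  Q <- qr.Q(qr(X))
  has_na <- apply(Y, 1, anyNA)
  res <- Y
  if (any(!has_na)) {
    Yc <- Y[!has_na, , drop = FALSE]
    res[!has_na, ] <- Yc - (Yc %*% Q) %*% t(Q) + rowMeans(Yc)
  }
  for (i in which(has_na)) {
    ok <- !is.na(Y[i, ])
    fit <- ols_fit(X[ok, , drop = FALSE], Y[i, ok])
    res[i, ok] <- fit$residuals + mean(Y[i, ok])
  }
  out <- expression_matrix(res, e$level, e$stage)
  out$stage <- "residualized"
  out
}

#' Estimate surrogate variables protecting the sex effect
#'
#' Hidden-factor estimation by residual SVD with permutation-based
#' (parallel-analysis) component selection. The expression matrix is first
#' residualized on the protected primary variable (sex), so every returned
#' surrogate variable is orthogonal to the sex indicator by construction;
#' the SVD of the sex-residual matrix then yields candidate factors, and a
#' component is kept while its singular value exceeds the `quantile` of the
#' corresponding singular values from `n_perm` row-wise permutations of the
#' residual matrix. `n_sv` overrides the automatic selection with a fixed
#' count.
#'
#' @param e A residualized-stage [expression_matrix()].
#' @param s Sample table with a 0/1 `sex` column (0 = male, 1 = female).
#' @param n_sv Optional fixed number of surrogate variables.
#' @param n_perm Number of permutations (default 20).
#' @param quantile Null-quantile used as the keep threshold (default 0.95).
#' @param seed Integer seed for the permutations.
#' @return samples x k matrix of surrogate variables (orthonormal columns;
#'   may have zero columns), with attribute `method`.
#' @export
estimate_svs <- function(e, s, n_sv = NULL, n_perm = 20, quantile = 0.95, seed = 1) {
  require_stage(e, "residualized")
  s <- s[match(e$sample_ids, s$sample_id), , drop = FALSE]
  sex <- s$sex
  if (anyNA(sex)) stop("sex must be non-missing for all samples")
  if (min(table(sex)) < 3) stop("at least 3 samples per sex required")
  Y <- e$values
  if (anyNA(Y)) {
    mu <- rowMeans(Y, na.rm = TRUE)
    idx <- which(is.na(Y), arr.ind = TRUE)
    Y[idx] <- mu[idx[, 1]]
  }
  X <- cbind(1, sex)
  Q <- qr.Q(qr(X))
  R <- Y - (Y %*% Q) %*% t(Q)
  sv <- svd(R)
  kmax <- min(nrow(R), ncol(R) - 2L)  # two dimensions consumed by the protected design
  if (is.null(n_sv)) {
    old <- get_seed_state()
    set.seed(seed)
    dperm <- matrix(0, n_perm, length(sv$d))
    for (b in seq_len(n_perm)) {
      Rp <- t(apply(R, 1, sample))
      Rp <- Rp - (Rp %*% Q) %*% t(Q)
      dperm[b, ] <- svd(Rp, nu = 0, nv = 0)$d
    }
    restore_seed_state(old)
    thr <- apply(dperm, 2, stats::quantile, probs = quantile)
    keep <- sv$d > thr
    k <- if (all(keep)) kmax else (which(!keep)[1] - 1L)
    k <- min(k, kmax)
  } else {
    k <- min(n_sv, kmax)
  }
  svs <- sv$v[, seq_len(k), drop = FALSE]
  rownames(svs) <- e$sample_ids
  if (k > 0) colnames(svs) <- paste0("SV", seq_len(k))
  attr(svs, "method") <- if (is.null(n_sv)) "residual-svd permutation" else "residual-svd fixed-k"
  svs
}

get_seed_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
restore_seed_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Z-score transform each gene
#'
#' Centers and scales each gene to mean 0, SD 1 (for cross-dataset
#' comparability). Zero-variance genes are dropped with a warning.
#'
#' @param e A residualized-stage [expression_matrix()].
#' @return Z-scored [expression_matrix()].
#' @export
zscore_expression <- function(e) {
  require_stage(e, "residualized")
  mu <- rowMeans(e$values, na.rm = TRUE)
  sdv <- apply(e$values, 1, stats::sd, na.rm = TRUE)
  drop <- sdv == 0 | is.na(sdv)
  if (any(drop)) warning(sum(drop), " zero-variance gene(s) dropped")
  vals <- (e$values - mu) / sdv
  out <- expression_matrix(vals[!drop, , drop = FALSE], e$level, "residualized")
  advance_stage(out, "zscored")
}

#' Filter and normalize a transcript count matrix
#'
#' Removes transcripts expressed below `cpm_min` counts per million in at
#' least `frac` of the samples within every clinical-diagnosis group (a
#' transcript is kept if any diagnosis group passes), then normalizes to
#' log2(CPM + 0.5). The sex effect is untouched.
#'
#' @param counts Non-negative integer matrix, transcripts x samples.
#' @param s Sample table with `sample_id` and `diagnosis` columns.
#' @param cpm_min CPM threshold (default 1).
#' @param frac Within-group fraction (default 0.5).
#' @return Normalized-stage transcript [expression_matrix()].
#' @export
prepare_transcripts <- function(counts, s, cpm_min = 1, frac = 0.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample(s) with zero library size: ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  s <- s[match(colnames(counts), s$sample_id), , drop = FALSE]
  cpm <- sweep(counts, 2, lib, `/`) * 1e6
  groups <- split(seq_len(ncol(counts)), s$diagnosis)
  ## removed only when every diagnosis group has >= frac of samples below cpm_min
  saved <- Reduce(`|`, lapply(groups, function(idx)
    rowMeans(cpm[, idx, drop = FALSE] < cpm_min) < frac))
  if (!any(saved)) stop("no transcripts survive the CPM filter")
  vals <- log2(cpm[saved, , drop = FALSE] + 0.5)
  out <- expression_matrix(vals, "transcript", "raw")
  advance_stage(out, "normalized")
}

#' Collapse isoforms to one row per gene
#'
#' Keeps the isoform with the highest mean abundance per gene; ties are
#' broken lexicographically by isoform id. Row names of the result are gene
#' ids.
#'
#' @param e An [expression_matrix()] whose rows are isoforms.
#' @param mapping data.frame with columns `isoform_id`, `gene_id`.
#' @return [expression_matrix()] with one row per gene.
#' @export
select_isoform <- function(e, mapping) {
  mapping <- mapping[match(e$gene_ids, mapping$isoform_id), , drop = FALSE]
  if (anyNA(mapping$gene_id)) stop("isoforms missing from mapping")
  means <- rowMeans(e$values, na.rm = TRUE)
  ord <- order(mapping$gene_id, -means, mapping$isoform_id)
  first <- !duplicated(mapping$gene_id[ord])
  chosen <- sort(ord[first])
  vals <- e$values[chosen, , drop = FALSE]
  rownames(vals) <- mapping$gene_id[chosen]
  expression_matrix(vals, e$level, e$stage)
}

#' Read / write expression TSV
#'
#' First column is the gene id, remaining columns are samples; "NA" marks
#' missing values.
#'
#' @param path TSV file path.
#' @param level,stage Tags for the constructed matrix.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, level = "protein", stage = "raw") {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  expression_matrix(vals, level, stage)
}

#' @rdname read_expression_tsv
#' @param e An [expression_matrix()] to write.
#' @export
write_expression_tsv <- function(e, path) {
  df <- data.frame(gene_id = e$gene_ids, e$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
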