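#' Ordinary least squares with full inference
#'
#' Fits `response ~ design` by QR decomposition and returns coefficients,
#' standard errors, t statistics and two-sided p-values. The design matrix is
#' expected to carry its own intercept column. Rank deficiency is detected
#' from the pivoted QR (relative tolerance 1e-10) and reported as an error
#' naming the offending columns rather than silently dropping them.
#'
#' @param design Numeric matrix, n rows (observations) by p columns. Must
#'   include an intercept column and contain no missing values.
#' @param response Numeric vector of length n, no missing values.
#' @return An object of class `ols_fit`: a list with `coefficients`,
#'   `standard_errors`, `t_statistics`, `p_values`, `residuals`, `fitted`,
#'   `dof` (n - p) and `n`.
#' @export
ols_fit <- function(design, response) {
  design <- as.matrix(design)
  response <- as.numeric(response)
  n <- nrow(design)
  p <- ncol(design)
  if (length(response) != n) stop("design and response dimensions differ")
  if (anyNA(design) || anyNA(response)) stop("missing values are not allowed in ols_fit")
  if (n <= p) stop("ols_fit requires more observations than design columns (n = ",
                   n, ", p = ", p, ")")
  qx <- qr(design, tol = 1e-10)
  if (qx$rank < p) {
    cn <- colnames(design)
    if (is.null(cn)) cn <- paste0("column", seq_len(p))
    bad <- cn[qx$pivot[(qx$rank + 1L):p]]
    stop("collinear design: rank ", qx$rank, " < ", p,
         "; offending columns: ", paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qx, response)
  res <- qr.resid(qx, response)
  dof <- n - p
  sigma2 <- sum(res^2) / dof
  ## (X'X)^{-1} from the pivoted R factor
  R <- qr.R(qx)
  xtx_inv_piv <- chol2inv(R)
  xtx_inv <- matrix(NA_real_, p, p)
  xtx_inv[qx$pivot, qx$pivot] <- xtx_inv_piv
  se <- sqrt(sigma2 * diag(xtx_inv))
  tstat <- coef / se
  pval <- 2 * stats::pt(-abs(tstat), df = dof)
  structure(list(coefficients = coef, standard_errors = se,
                 t_statistics = tstat, p_values = pval,
                 residuals = res, fitted = response - res,
                 dof = dof, n = n),
            class = "ols_fit")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values. Missing inputs propagate as missing and are
#' excluded from the effective number of tests.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Vector of BH-adjusted values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) < 1) stop("empty p-value vector")
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Storey's pi1 (1 - pi0) estimate
#'
#' Estimates the proportion of true alternatives among a vector of p-values.
#' pi0 is estimated on the lambda grid 0.05, 0.10, ..., 0.95 as
#' \#\{p > lambda\} / (m (1 - lambda)), smoothed with a natural cubic spline
#' and evaluated at the largest lambda, then clipped to \[0, 1\]. With fewer
#' than 50 p-values the spline is unstable, so a conservative fixed-lambda
#' (0.5) estimate is used with a warning. If the spline fit fails the same
#' fixed-lambda fallback applies.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param method `"smoother"` (default) or `"fixed"` (pi0 at lambda = 0.5).
#' @return pi1 in \[0, 1\].
#' @export
storey_pi1 <- function(p_values, method = c("smoother", "fixed")) {
  method <- match.arg(method)
  if (length(p_values) == 0) stop("empty p-value vector")
  if (anyNA(p_values)) p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0) stop("no non-missing p-values")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  pi0_at <- function(lam) sum(p_values > lam) / (m * (1 - lam))
  if (m < 50 && method == "smoother") {
    warning("fewer than 50 p-values; using conservative fixed-lambda pi0 estimate")
    method <- "fixed"
  }
  if (method == "fixed") {
    pi0 <- pi0_at(0.5)
  } else {
    lam <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lam, pi0_at, numeric(1))
    pi0 <- tryCatch({
      sp <- stats::smooth.spline(lam, pi0_l, df = 3)
      stats::predict(sp, x = max(lam))$y
    }, error = function(e) pi0_at(0.5))
  }
  pi0 <- min(max(pi0, 0), 1)
  1 - pi0
}

#' Fisher's exact test for a 2x2 table
#'
#' Returns the sample odds ratio ad/bc (Inf when bc = 0 with ad > 0), the
#' two-sided p-value obtained by summing hypergeometric probabilities no
#' larger than that of the observed table, and the conditional-likelihood 95%
#' confidence interval (both taken from [stats::fisher.test()]). The
#' alternative "doubling" two-sided rule is not used.
#'
#' @param table 2x2 matrix, or vector `c(a, b, c, d)` read row-wise, of
#'   non-negative integer counts.
#' @return List with `odds_ratio` (sample OR), `p` (two-sided) and `ci95`
#'   (length-2 vector; conditional likelihood bounds).
#' @export
fisher_exact_or <- function(table) {
  tab <- matrix(as.numeric(table), 2, 2, byrow = is.null(dim(table)))
  if (any(tab < 0) || anyNA(tab)) stop("counts must be non-negative")
  if (sum(tab) == 0) stop("all-zero table")
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  or <- if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * cc)
  ft <- stats::fisher.test(tab)
  list(odds_ratio = or, p = ft$p.value, ci95 = as.numeric(ft$conf.int))
}

#' Genomic inflation factor (lambda) from p-values
#'
#' Median-based inflation: lambda = median(qchisq(p, 1, lower = FALSE)) /
#' qchisq(0.5, 1). Zero p-values are clamped to the smallest positive double
#' with a warning. Also returns expected/observed -log10 p pairs for a QQ
#' plot.
#'
#' @param p_values Numeric vector of p-values in (0, 1\].
#' @return List with `lambda` and `qq` (data.frame with columns `expected`,
#'   `observed`, sorted by expected).
#' @export
qq_lambda <- function(p_values) {
  if (length(p_values) == 0) stop("empty p-value vector")
  p <- p_values[!is.na(p_values)]
  if (length(p) == 0) stop("no non-missing p-values")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("p-values of 0 clamped to smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  m <- length(p)
  obs <- sort(-log10(p))
  expd <- sort(-log10(stats::ppoints(m)))
  list(lambda = lambda, qq = data.frame(expected = expd, observed = obs))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact test on genotype counts by full enumeration of all heterozygote
#' counts compatible with the observed allele-count margin; the two-sided
#' p-value sums the probabilities of all outcomes no more probable than the
#' observed one. Monomorphic variants return p = 1. On the X chromosome the
#' test should be run on females only (males are hemizygous).
#'
#' @param n_hom_ref,n_het,n_hom_alt Non-negative genotype counts.
#' @return Exact p-value in \[0, 1\].
#' @export
hwe_exact <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (anyNA(counts) || any(counts < 0)) stop("genotype counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("total genotype count is zero")
  ## rare-allele count determines the enumeration margin
  n_alt <- 2 * n_hom_alt + n_het
  n_ref <- 2 * n_hom_ref + n_het
  rare <- min(n_alt, n_ref)
  if (rare == 0) return(1.0)  # monomorphic
  hets <- seq(rare %% 2, rare, by = 2)
  ## log-probabilities of each compatible het count under the exact HWE
  ## conditional distribution
  logp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_common <- n - h - hom_rare
    lgamma(n + 1) - lgamma(hom_rare + 1) - lgamma(h + 1) - lgamma(hom_common + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- n_het
  p_obs <- prob[hets == obs]
  if (length(p_obs) != 1) stop("observed heterozygote count incompatible with allele margin")
  sum(prob[prob <= p_obs * (1 + 1e-12)])
}
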