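#' Cis SNP-based heritability by single-component REML
#'
#' Fits y = mu + g + e with g ~ N(0, sigma_g^2 K), K = X X' / m on
#' standardized cis dosages. The intercept is projected out and the
#' restricted likelihood is profiled over h2 = sigma_g^2 / (sigma_g^2 +
#' sigma_e^2) on a grid with local refinement, using one eigendecomposition
#' of the projected kernel. The p-value comes from the likelihood-ratio test
#' against h2 = 0 with the boundary mixture 0.5 chi2_0 + 0.5 chi2_1; the
#' `heritable` flag uses p < 0.01.
#'
#' @param g_window samples x variants dosage matrix (cis window).
#' @param expression Numeric expression vector aligned to the samples.
#' @param stratum Label recorded in the result (`"joint"`, `"male"`, `"female"`).
#' @param p_min Heritability significance threshold (default 0.01).
#' @return List of class `heritability_result`: `stratum`, `h2`, `p`,
#'   `loglik`, `heritable`.
#' @export
cis_heritability <- function(g_window, expression, stratum = "joint", p_min = 0.01) {
  y <- as.numeric(expression)
  n <- length(y)
  if (n < 50) stop("at least 50 samples required")
  if (anyNA(y)) stop("missing expression values not supported")
  if (stats::sd(y) == 0) stop("constant expression vector")
  X <- standardize_dosages(as.matrix(g_window))
  if (ncol(X) < 2) stop("at least 2 polymorphic cis variants required")
  m <- ncol(X)
  K <- tcrossprod(X) / m
  ## REML: project out the intercept, eigendecompose the projected kernel
  P <- diag(n) - matrix(1 / n, n, n)
  ed <- eigen(P %*% K %*% P, symmetric = TRUE)
  keep <- seq_len(n - 1)  # drop the null direction consumed by the mean
  lam <- pmax(ed$values[keep], 0)
  v <- as.numeric(crossprod(ed$vectors[, keep], y - mean(y)))
  nr <- n - 1
  negll <- function(h2) {
    d <- h2 * lam + (1 - h2)
    s2 <- mean(v^2 / d)
    0.5 * (nr * log(s2) + sum(log(d)) + nr)
  }
  grid <- seq(0, 0.99, by = 0.01)
  vals <- vapply(grid, negll, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- min(grid[min(length(grid), i + 1)], 0.9999)
  opt <- stats::optimize(negll, c(lo, hi))
  h2 <- if (opt$objective < vals[i]) opt$minimum else grid[i]
  ll <- -min(opt$objective, vals[i])
  lrt <- max(0, 2 * (ll - (-negll(0))))
  p <- if (lrt <= 0) 1 else 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  structure(list(stratum = stratum, h2 = h2, p = p, loglik = ll,
                 heritable = p < p_min),
            class = "heritability_result")
}

#' Train cis expression-prediction weights
#'
#' Fits ridge (a BLUP-equivalent shrinkage fit), lasso and elastic net
#' (glmnet, penalty chosen by inner cross-validation) and scores each by
#' out-of-fold R-squared on `folds` outer folds with a fixed seed; the
#' best-performing model's weights are kept.
#'
#' @param g_window samples x variants dosage matrix (cis window).
#' @param expression Numeric expression vector.
#' @param folds Outer fold count (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param stratum Label recorded in the result.
#' @return List of class `weight_model`: `stratum`, `weights` (named by
#'   variant), `model` (ridge_blup / lasso / elastic_net), `cv_r2`,
#'   `cv_r2_all`, `folds`, `seed`.
#' @export
train_weights <- function(g_window, expression, folds = 5, seed = 1,
                          stratum = "joint") {
  y <- as.numeric(expression)
  n <- length(y)
  if (n < folds) stop("fewer samples than folds")
  X <- as.matrix(g_window)
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  alphas <- c(ridge_blup = 0, lasso = 1, elastic_net = 0.5)
  old <- get_seed_state(); on.exit(restore_seed_state(old))
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  r2 <- vapply(alphas, function(a) {
    pred <- rep(NA_real_, n)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      cv <- glmnet::cv.glmnet(X[tr, , drop = FALSE], y[tr], alpha = a, nfolds = 5)
      pred[!tr] <- as.numeric(stats::predict(cv, X[!tr, , drop = FALSE], s = "lambda.min"))
    }
    if (stats::sd(pred) == 0) return(0)
    stats::cor(pred, y)^2
  }, numeric(1))
  best <- names(alphas)[which.max(r2)]
  cv <- glmnet::cv.glmnet(X, y, alpha = alphas[[best]], nfolds = 5)
  w <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
  names(w) <- colnames(X)
  structure(list(stratum = stratum, weights = w, model = best,
                 cv_r2 = unname(r2[best]), cv_r2_all = r2,
                 folds = folds, seed = seed),
            class = "weight_model")
}

#' Summary-statistic PWAS association
#'
#' Combines expression-prediction weights with GWAS z-scores:
#' z = w'z / sqrt(w' R w) with a ridge stabilizer (0.01 added to the
#' diagonal of the LD matrix R); two-sided normal p. Variants are harmonized
#' between the weight model and the GWAS table by id and alleles: records
#' with swapped A1/A2 get their z sign flipped, strand-ambiguous (A/T, C/G)
#' variants are dropped by default, and unmatched variants are dropped with
#' a count.
#'
#' @param w A [train_weights()] model with attached variant alleles
#'   (attribute `alleles`: data.frame `id`, `a1`, `a2`), or a named weight
#'   vector.
#' @param gwas data.frame with columns `SNP`, `A1`, `A2`, `Z`.
#' @param R LD (correlation) matrix named by variant id.
#' @param drop_ambiguous Drop strand-ambiguous variants (default TRUE).
#' @param lambda Diagonal stabilizer (default 0.01).
#' @return List of class `pwas_record`: `z`, `p`, `n_variants`, `n_dropped`.
#' @export
pwas_assoc <- function(w, gwas, R, drop_ambiguous = TRUE, lambda = 0.01) {
  weights <- if (inherits(w, "weight_model")) w$weights else w
  alleles <- if (inherits(w, "weight_model")) attr(w, "alleles") else NULL
  if (all(weights == 0)) stop("all weights are zero")
  ids <- names(weights)
  gi <- match(ids, gwas$SNP)
  matched <- !is.na(gi)
  z <- rep(NA_real_, length(ids))
  z[matched] <- gwas$Z[gi[matched]]
  flip_dropped <- 0L
  if (!is.null(alleles)) {
    ai <- match(ids, alleles$id)
    a1 <- toupper(alleles$a1[ai]); a2 <- toupper(alleles$a2[ai])
    g1 <- toupper(gwas$A1[gi]); g2 <- toupper(gwas$A2[gi])
    amb <- matched & ((a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
                        (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C"))
    if (drop_ambiguous && any(amb)) {
      flip_dropped <- sum(amb)
      matched <- matched & !amb
    }
    same <- matched & a1 == g1 & a2 == g2
    swapped <- matched & a1 == g2 & a2 == g1
    z[swapped] <- -z[swapped]
    mismatch <- matched & !same & !swapped
    matched <- matched & !mismatch
  }
  keep <- matched & weights != 0
  if (!any(keep)) stop("no usable variant after harmonization")
  ids_k <- ids[keep]
  wv <- weights[keep]
  Rk <- R[ids_k, ids_k, drop = FALSE] + diag(lambda, sum(keep))
  denom <- as.numeric(t(wv) %*% Rk %*% wv)
  if (denom <= 0) stop("non-positive weighted LD quadratic form")
  zp <- sum(wv * z[keep]) / sqrt(denom)
  structure(list(z = zp, p = 2 * stats::pnorm(-abs(zp)),
                 n_variants = sum(keep),
                 n_dropped = length(ids) - sum(keep),
                 n_ambiguous_dropped = flip_dropped),
            class = "pwas_record")
}

#' Colocalization priors
#'
#' @param p1,p2 Per-variant prior probability of association with trait 1 /
#'   trait 2 (default 1e-4 each).
#' @param p12 Per-variant prior probability of association with both
#'   (default 1e-5).
#' @return List of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  if (any(c(p1, p2, p12) <= 0) || any(c(p1, p2, p12) >= 1))
    stop("priors must lie in (0, 1)")
  if (p12 > min(p1, p2)) stop("p12 must not exceed min(p1, p2)")
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## log(exp(a) - exp(b)) for a >= b
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Approximate-Bayes-factor colocalization
#'
#' Wakefield log-ABFs per variant, log ABF = 0.5 (log(1 - r) + r z^2) with
#' r = W / (W + se^2), summed per single-causal-variant hypothesis:
#' L1 = sum BF1, L2 = sum BF2, L4 = sum BF1 BF2, L3 = L1 L2 - L4. Posterior
#' probabilities PP0..PP4 are proportional to (1, p1 L1, p2 L2, p1 p2 L3,
#' p12 L4). The prior effect SD defaults to 0.15 (quantitative traits; use
#' 0.2 for binary traits).
#'
#' @param beta1,se1 Per-variant effect and standard error for trait 1.
#' @param beta2,se2 Same for trait 2 (same variant order).
#' @param priors A [coloc_priors()].
#' @param sd_prior1,sd_prior2 Prior effect SDs (default 0.15).
#' @param variant_ids Optional ids; checked for consistency of the two traits
#'   when given as a 2-column matrix/data.frame.
#' @return List of class `coloc_result`: `pp` (named vector PP0..PP4 summing
#'   to 1), `n_variants`, `best`.
#' @export
coloc_abf <- function(beta1, se1, beta2, se2, priors = coloc_priors(),
                      sd_prior1 = 0.15, sd_prior2 = 0.15, variant_ids = NULL) {
  k <- length(beta1)
  if (k < 2) stop("at least 2 variants required")
  if (length(se1) != k || length(beta2) != k || length(se2) != k)
    stop("mismatched variant lists between traits")
  if (any(se1 <= 0) || any(se2 <= 0)) stop("standard errors must be positive")
  labf <- function(beta, se, sdp) {
    r <- sdp^2 / (sdp^2 + se^2)
    0.5 * (log1p(-r) + r * (beta / se)^2)
  }
  l1 <- labf(beta1, se1, sd_prior1)
  l2 <- labf(beta2, se2, sd_prior2)
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  lh <- c(h0 = 0,
          h1 = log(priors$p1) + s1,
          h2 = log(priors$p2) + s2,
          h3 = log(priors$p1) + log(priors$p2) + logdiffexp(s1 + s2, s12),
          h4 = log(priors$p12) + s12)
  pp <- exp(lh - logsumexp(lh))
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP", 0:4)
  structure(list(pp = pp, n_variants = k,
                 best = names(pp)[which.max(pp)]),
            class = "coloc_result")
}

#' Classify sex-specific causal proteins
#'
#' A gene is called `female_only` when the female PWAS is FDR-significant
#' (q < `fdr`), the female colocalization PP4 exceeds `pp4_min`, and the
#' male PWAS is either absent (not heritable in males, or untested) or has
#' raw p > 0.05; `male_only` is symmetric. `both` requires the q and PP4
#' conditions in both sexes; everything else is `neither`.
#'
#' @param pwas data.frame with columns `gene_id`, `stratum` (male/female),
#'   `z`, `p`, `q` (one row per gene and stratum; genes not heritable in a
#'   stratum simply carry no row there).
#' @param coloc data.frame with columns `gene_id`, `stratum`, `pp4`.
#' @param fdr PWAS FDR threshold (default 0.05).
#' @param pp4_min Colocalization threshold (default 0.75).
#' @param block_p Raw-p threshold in the other sex above which the
#'   single-sex call survives (default 0.05).
#' @return data.frame per gene: `gene_id`, `classification`, per-stratum
#'   support columns.
#' @export
classify_sex_specific <- function(pwas, coloc, fdr = 0.05, pp4_min = 0.75,
                                  block_p = 0.05) {
  if (any(duplicated(pwas[, c("gene_id", "stratum")])))
    stop("duplicate PWAS records per gene/stratum")
  if (any(duplicated(coloc[, c("gene_id", "stratum")])))
    stop("duplicate colocalization records per gene/stratum")
  genes <- unique(c(pwas$gene_id, coloc$gene_id))
  get1 <- function(df, gid, st, col) {
    v <- df[[col]][df$gene_id == gid & df$stratum == st]
    if (length(v) == 0) NA_real_ else v
  }
  out <- do.call(rbind, lapply(genes, function(gid) {
    fq <- get1(pwas, gid, "female", "q"); fp <- get1(pwas, gid, "female", "p")
    mq <- get1(pwas, gid, "male", "q"); mp <- get1(pwas, gid, "male", "p")
    f4 <- get1(coloc, gid, "female", "pp4"); m4 <- get1(coloc, gid, "male", "pp4")
    f_pass <- !is.na(fq) && fq < fdr && !is.na(f4) && f4 > pp4_min
    m_pass <- !is.na(mq) && mq < fdr && !is.na(m4) && m4 > pp4_min
    m_quiet <- is.na(mp) || mp > block_p
    f_quiet <- is.na(fp) || fp > block_p
    cls <- if (f_pass && m_pass) "both"
    else if (f_pass && m_quiet) "female_only"
    else if (m_pass && f_quiet) "male_only"
    else "neither"
    data.frame(gene_id = gid, classification = cls,
               female_q = fq, female_pp4 = f4, male_q = mq, male_pp4 = m4,
               female_p = fp, male_p = mp, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Intersect an external causal-gene list with sex-biased hit sets
#'
#' @param causal data.frame with `gene_id` and `trait`.
#' @param sexde_hits Character vector of genes with sex-biased expression.
#' @param sbqtl_genes Character vector of genes with sb-QTLs.
#' @return data.frame per trait: counts and percentages of causal genes with
#'   sex-biased expression, sb-QTLs, either, and both; plus a `TOTAL` row.
#' @export
intersect_causal_sets <- function(causal, sexde_hits, sbqtl_genes) {
  if (nrow(causal) == 0) stop("empty causal gene list")
  per <- function(df) {
    g <- unique(df$gene_id)
    n <- length(g)
    n_de <- sum(g %in% sexde_hits)
    n_qtl <- sum(g %in% sbqtl_genes)
    n_either <- sum(g %in% union(sexde_hits, sbqtl_genes))
    n_both <- sum(g %in% intersect(sexde_hits, sbqtl_genes))
    data.frame(n_causal = n, n_sexde = n_de, pct_sexde = 100 * n_de / n,
               n_sbqtl = n_qtl, pct_sbqtl = 100 * n_qtl / n,
               n_either = n_either, n_both = n_both)
  }
  traits <- split(causal, causal$trait)
  out <- do.call(rbind, lapply(traits, per))
  out <- cbind(trait = names(traits), out)
  tot <- per(causal); tot <- cbind(trait = "TOTAL", tot)
  out <- rbind(out, tot)
  rownames(out) <- NULL
  out
}
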