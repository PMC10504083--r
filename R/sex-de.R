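## Frisch-Waugh-Lovell helpers shared by all scans: residualize the
## response, the predictor(s) and the target regressor on the fixed
## covariate block once, then solve the small remaining regression in
## closed form. Identical to the full per-test OLS, but vectorizable
## across thousands of gene-variant pairs.

## orthonormal basis of the column space of X
proj_basis <- function(X) qr.Q(qr(as.matrix(X)))

## residualize columns of M (n x k) on the basis Q
resid_cols <- function(M, Q) M - Q %*% (t(Q) %*% M)

## vectorized single-predictor OLS after residualization:
## y and x are n-vectors already residualized on a p-column block
fwl_single <- function(xr, Yr_rows, n, p_block) {
  ## Yr_rows: tests x n matrix (one row per test), xr: n x tests matrix
  cross <- colSums(xr * t(Yr_rows))
  gg <- colSums(xr^2)
  yy <- rowSums(Yr_rows^2)
  dof <- n - p_block - 1L
  beta <- cross / gg
  rss <- pmax(yy - cross^2 / gg, 0)
  se <- sqrt(rss / dof / gg)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df = dof)
  data.frame(beta = beta, se = se, p = p)
}

#' Scan for sex-differential expression
#'
#' Per-gene linear regression of expression on sex with surrogate variables
#' as covariates; Benjamini-Hochberg adjustment across genes. Direction
#' labels follow the male = 0 / female = 1 coding: a positive sex
#' coefficient means higher expression in females.
#'
#' @param e A zscored- or residualized-stage [expression_matrix()].
#' @param s Sample table with `sample_id` and 0/1 `sex`.
#' @param svs Optional samples x k surrogate-variable matrix from
#'   [estimate_svs()] (rows aligned to samples).
#' @param fdr FDR threshold used for the `significant` flag (default 0.05).
#' @param gene_coords Optional data.frame (`gene_id`, `chrom`, ...) used to
#'   fill the `chromosome` column.
#' @return data.frame of per-gene records: `gene_id`, `beta_sex`, `se`, `p`,
#'   `q`, `direction`, `significant`, `chromosome`.
#' @export
sexdiff_scan <- function(e, s, svs = NULL, fdr = 0.05, gene_coords = NULL) {
  require_stage(e, c("residualized", "zscored"))
  s <- s[match(e$sample_ids, s$sample_id), , drop = FALSE]
  sex <- as.numeric(s$sex)
  if (anyNA(sex)) stop("sex must be non-missing")
  if (length(unique(sex)) < 2) stop("both sexes must be present")
  n <- length(sex)
  X0 <- cbind(intercept = rep(1, n))
  if (!is.null(svs) && ncol(svs) > 0) X0 <- cbind(X0, svs[e$sample_ids, , drop = FALSE])
  Q <- proj_basis(X0)
  Y <- e$values
  has_na <- apply(Y, 1, anyNA)
  out <- data.frame(gene_id = e$gene_ids, beta_sex = NA_real_, se = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  xr <- as.numeric(resid_cols(matrix(sex, ncol = 1), Q))
  if (any(!has_na)) {
    Yr <- resid_cols(t(Y[!has_na, , drop = FALSE]), Q)
    st <- fwl_single(matrix(xr, n, sum(!has_na)), t(Yr), n, ncol(X0))
    out[!has_na, c("beta_sex", "se", "p")] <- st
  }
  for (i in which(has_na)) {
    ok <- !is.na(Y[i, ])
    fit <- ols_fit(cbind(X0[ok, , drop = FALSE], sex = sex[ok]), Y[i, ok])
    j <- length(fit$coefficients)
    out[i, c("beta_sex", "se", "p")] <- list(fit$coefficients[j],
                                             fit$standard_errors[j], fit$p_values[j])
  }
  out$q <- bh_fdr(out$p)
  out$direction <- ifelse(out$beta_sex > 0, "higher_in_females", "higher_in_males")
  out$significant <- !is.na(out$q) & out$q < fdr
  out$chromosome <- if (!is.null(gene_coords))
    gene_coords$chrom[match(out$gene_id, gene_coords$gene_id)] else NA_character_
  out
}

#' Per-chromosome composition of significant genes
#'
#' @param records Output of [sexdiff_scan()] (uses the `significant` flag).
#' @param gene_coords data.frame with `gene_id`, `chrom`.
#' @return data.frame per chromosome: `chrom`, `n_tested`, `n_significant`,
#'   `proportion`; attribute `share_of_hits_on_X` gives the X fraction among
#'   all hits.
#' @export
chromosome_composition <- function(records, gene_coords) {
  chrom <- gene_coords$chrom[match(records$gene_id, gene_coords$gene_id)]
  if (anyNA(chrom)) {
    warning(sum(is.na(chrom)), " gene(s) without chromosome mapping excluded")
    records <- records[!is.na(chrom), , drop = FALSE]
    chrom <- chrom[!is.na(chrom)]
  }
  tab <- stats::aggregate(list(n_tested = records$gene_id),
                          by = list(chrom = chrom), FUN = length)
  sig <- tapply(records$significant, chrom, sum)
  tab$n_significant <- as.integer(sig[tab$chrom])
  tab$proportion <- ifelse(tab$n_tested > 0, tab$n_significant / tab$n_tested, 0)
  n_hits <- sum(tab$n_significant)
  attr(tab, "share_of_hits_on_X") <-
    if (n_hits > 0) sum(tab$n_significant[tab$chrom == "X"]) / n_hits else 0
  tab
}

#' Cross-level (protein vs transcript) concordance of sex effects
#'
#' Among genes measured at both levels: counts significant at both, the
#' percentage with concordant effect direction among those, Storey's pi1 of
#' the transcript p-values restricted to the protein hits, and (optionally)
#' the mean per-gene Pearson correlation between paired expression matrices.
#'
#' @param protein_records,mrna_records Outputs of [sexdiff_scan()].
#' @param paired_protein,paired_mrna Optional paired [expression_matrix()]
#'   objects sharing samples, for the per-gene correlation summary.
#' @return List with `n_overlap_genes`, `n_both_significant`,
#'   `percent_concordant_direction`, `pi1_protein_to_mrna`,
#'   `mean_mrna_protein_correlation`.
#' @export
cross_level_concordance <- function(protein_records, mrna_records,
                                    paired_protein = NULL, paired_mrna = NULL) {
  shared <- intersect(protein_records$gene_id, mrna_records$gene_id)
  if (length(shared) == 0) stop("no genes shared between the two levels")
  pr <- protein_records[match(shared, protein_records$gene_id), ]
  mr <- mrna_records[match(shared, mrna_records$gene_id), ]
  both <- pr$significant & mr$significant
  conc <- if (any(both))
    100 * mean(sign(pr$beta_sex[both]) == sign(mr$beta_sex[both])) else NA_real_
  hits <- pr$significant
  pi1 <- if (any(hits)) suppressWarnings(storey_pi1(mr$p[hits])) else NA_real_
  mean_cor <- NA_real_
  if (!is.null(paired_protein) && !is.null(paired_mrna)) {
    gshared <- intersect(intersect(paired_protein$gene_ids, paired_mrna$gene_ids), shared)
    sshared <- intersect(paired_protein$sample_ids, paired_mrna$sample_ids)
    cors <- vapply(gshared, function(gid)
      suppressWarnings(stats::cor(paired_protein$values[gid, sshared],
                                  paired_mrna$values[gid, sshared],
                                  use = "pairwise.complete.obs")), numeric(1))
    mean_cor <- mean(cors, na.rm = TRUE)
  }
  list(n_overlap_genes = length(shared), n_both_significant = sum(both),
       percent_concordant_direction = conc, pi1_protein_to_mrna = pi1,
       mean_mrna_protein_correlation = mean_cor)
}

#' Fisher enrichment of a hit set across categories
#'
#' One 2x2 table per category (hit / non-hit x in / out of category) tested
#' with [fisher_exact_or()]; BH adjustment across categories. Uncategorized
#' ids form their own class. A degenerate cell yields an infinite sample OR
#' with a one-sided (lower-bounded) confidence interval.
#'
#' @param hit_ids Character vector of hits (must be a subset of the
#'   background).
#' @param background_ids Character vector, the test universe.
#' @param categories data.frame with columns `id`, `category`.
#' @return data.frame per category: `category`, `n_hit_in`, `n_hit_out`,
#'   `n_bg_in`, `n_bg_out`, `odds_ratio`, `ci_low`, `ci_high`, `p`, `q`.
#' @export
enrichment_fisher <- function(hit_ids, background_ids, categories) {
  if (!all(hit_ids %in% background_ids)) stop("hits must be a subset of the background")
  cat_of <- categories$category[match(background_ids, categories$id)]
  cat_of[is.na(cat_of)] <- "uncategorized"
  is_hit <- background_ids %in% hit_ids
  out <- do.call(rbind, lapply(sort(unique(cat_of)), function(ct) {
    inc <- cat_of == ct
    a <- sum(is_hit & inc); b <- sum(is_hit & !inc)
    cc <- sum(!is_hit & inc); d <- sum(!is_hit & !inc)
    ft <- fisher_exact_or(matrix(c(a, b, cc, d), 2, 2, byrow = TRUE))
    data.frame(category = ct, n_hit_in = a, n_hit_out = b, n_bg_in = cc,
               n_bg_out = d, odds_ratio = ft$odds_ratio,
               ci_low = ft$ci95[1], ci_high = ft$ci95[2], p = ft$p,
               stringsAsFactors = FALSE)
  }))
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}
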