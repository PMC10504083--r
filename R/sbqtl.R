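#' Analysis configuration defaults
#'
#' Central container for the thresholds of the sb-QTL pipeline: cis window
#' 500 kb, FDR 0.05 at both stages, clump r2 0.50 (index) / 0.10
#' (independent) with a 250 kb window, colocalization priors
#' p1 = p2 = 1e-4, p12 = 1e-5, PP4 cutoff 0.75 and heritability p 0.01.
#'
#' @param ... Named overrides of the defaults.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(cis_window = 500000, fdr = 0.05, clump_r2_index = 0.50,
              clump_r2_independent = 0.10, clump_window = 250000,
              interaction_fdr = 0.05, pp4_min = 0.75, heritability_p = 0.01,
              coloc_p1 = 1e-4, coloc_p2 = 1e-4, coloc_p12 = 1e-5)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "),
                        "; valid keys: ", paste(names(cfg), collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$fdr <= 0 || cfg$fdr > 1) stop("fdr must be in (0, 1]")
  if (cfg$interaction_fdr <= 0 || cfg$interaction_fdr > 1) stop("interaction_fdr must be in (0, 1]")
  if (cfg$cis_window < 0 || cfg$clump_window < 0) stop("windows must be non-negative")
  structure(cfg, class = "analysis_config")
}

#' Enumerate cis gene-variant pairs
#'
#' A variant pairs with a gene when its position falls in
#' \[gene_start - window, gene_end + window\] on the same chromosome
#' (1-based inclusive; strand ignored, window symmetric).
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @param variants data.frame with `id`, `chrom`, `pos`.
#' @param window Flank size in bp (default 500000).
#' @return data.frame with `gene_id`, `variant_id`, `distance` (bp to the
#'   gene body, 0 if intragenic).
#' @export
map_cis_pairs <- function(genes, variants, window = 500000) {
  if (any(genes$end < genes$start)) stop("gene(s) with end < start")
  out <- lapply(seq_len(nrow(genes)), function(i) {
    gv <- variants$chrom == genes$chrom[i] &
      variants$pos >= genes$start[i] - window &
      variants$pos <= genes$end[i] + window
    if (!any(gv)) return(NULL)
    pos <- variants$pos[gv]
    dist <- pmax(genes$start[i] - pos, pos - genes$end[i], 0)
    data.frame(gene_id = genes$gene_id[i], variant_id = variants$id[gv],
               distance = dist, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(gene_id = character(), variant_id = character(),
                                      distance = integer())
  rownames(res) <- NULL
  res
}

## align genotype, expression, covariates and sex to a common sample set
align_scan_inputs <- function(g, e, covariates, sex) {
  ids <- intersect(g$sample_ids, e$sample_ids)
  if (!is.null(covariates)) ids <- intersect(ids, rownames(covariates))
  if (!is.null(names(sex))) ids <- intersect(ids, names(sex))
  if (length(ids) == 0) stop("no shared samples across inputs")
  list(ids = ids,
       G = g$dosages[ids, , drop = FALSE],
       Y = e$values[, ids, drop = FALSE],
       C = if (is.null(covariates)) NULL else covariates[ids, , drop = FALSE],
       sex = if (is.null(names(sex))) sex else sex[ids])
}

#' Cis-QTL scan (joint or sex-stratified)
#'
#' Per-pair OLS of expression on dosage with covariates (surrogate
#' variables + genetic PCs); in joint mode sex is added as a covariate.
#' Males keep their hemizygous 0/2 X coding in every mode. BH q-values are
#' computed within the mode across all tested pairs. Variants monomorphic
#' within the analyzed stratum are skipped (counted in attribute
#' `n_skipped_monomorphic`). Missing dosages are mean-imputed for the
#' regression.
#'
#' @param pairs data.frame from [map_cis_pairs()].
#' @param g A [genotype_matrix()].
#' @param e A zscored- or residualized-stage [expression_matrix()].
#' @param covariates samples x c matrix (rownames = sample ids) or NULL.
#' @param sex 0/1 vector named by sample id.
#' @param mode `"joint"`, `"male"` or `"female"`.
#' @param min_n Minimum stratum size (default 30).
#' @return data.frame of association records: `gene_id`, `variant_id`,
#'   `mode`, `beta`, `se`, `p`, `q`, `n`.
#' @export
cis_scan <- function(pairs, g, e, covariates = NULL, sex,
                     mode = c("joint", "male", "female"), min_n = 30) {
  mode <- match.arg(mode)
  require_stage(e, c("residualized", "zscored"))
  al <- align_scan_inputs(g, e, covariates, sex)
  keep <- switch(mode, joint = rep(TRUE, length(al$ids)),
                 male = al$sex == 0, female = al$sex == 1)
  ids <- al$ids[keep]
  n <- length(ids)
  if (n < min_n) stop("stratum size ", n, " below minimum ", min_n)
  G <- al$G[keep, , drop = FALSE]
  Y <- al$Y[, keep, drop = FALSE]
  X0 <- cbind(intercept = rep(1, n))
  if (mode == "joint") X0 <- cbind(X0, sex = al$sex[keep])
  if (!is.null(al$C)) X0 <- cbind(X0, al$C[keep, , drop = FALSE])
  mono <- apply(G, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) == 0 || stats::sd(x) == 0
  })
  Q <- proj_basis(X0)
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  pairs <- pairs[pairs$gene_id %in% rownames(Y) & pairs$variant_id %in% colnames(G), ,
                 drop = FALSE]
  testable <- !mono[pairs$variant_id]
  out <- data.frame(gene_id = pairs$gene_id, variant_id = pairs$variant_id,
                    mode = mode, beta = NA_real_, se = NA_real_, p = NA_real_,
                    n = n, stringsAsFactors = FALSE)
  if (any(testable)) {
    pt <- pairs[testable, , drop = FALSE]
    Gr <- resid_cols(G[, unique(pt$variant_id), drop = FALSE], Q)
    Yr <- resid_cols(t(Y[unique(pt$gene_id), , drop = FALSE]), Q)
    st <- fwl_single(Gr[, pt$variant_id, drop = FALSE],
                     t(Yr)[pt$gene_id, , drop = FALSE], n, ncol(X0))
    out[testable, c("beta", "se", "p")] <- st
  }
  out$q <- bh_fdr(out$p)
  attr(out, "n_skipped_monomorphic") <- sum(!testable)
  out
}

#' Stage-1 pQTL/eQTL union
#'
#' A gene-variant pair enters stage 2 when it is significant (q < fdr) in
#' the joint, male or female scan; the contributing modes are recorded.
#'
#' @param joint,male,female Record data.frames from [cis_scan()].
#' @param fdr FDR threshold (default 0.05).
#' @return data.frame with `gene_id`, `variant_id`, `source_modes`
#'   (comma-separated).
#' @export
stage1_union <- function(joint, male, female, fdr = 0.05) {
  key <- function(df) paste(df$gene_id, df$variant_id, sep = "\r")
  sig <- list(joint = joint[!is.na(joint$q) & joint$q < fdr, ],
              male = male[!is.na(male$q) & male$q < fdr, ],
              female = female[!is.na(female$q) & female$q < fdr, ])
  keys <- unique(unlist(lapply(sig, key)))
  if (length(keys) == 0)
    return(data.frame(gene_id = character(), variant_id = character(),
                      source_modes = character()))
  modes <- vapply(keys, function(k)
    paste(names(sig)[vapply(sig, function(df) k %in% key(df), logical(1))],
          collapse = ","), character(1))
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  data.frame(gene_id = parts[, 1], variant_id = parts[, 2],
             source_modes = unname(modes), stringsAsFactors = FALSE)
}

#' Genotype-by-sex interaction scan (stage 2)
#'
#' For every stage-1 pair, fits expression ~ dosage + sex + dosage x sex +
#' covariates and tests the interaction term. With the male = 0 / female = 1
#' coding the interaction beta is the female-minus-male difference in
#' per-allele effect. The default FDR universe (`universe = "all_pairs"`)
#' runs the interaction model on every tested cis pair and BH-adjusts over
#' all of them — the conservative reading of correcting over all tested
#' SNP-by-gene combinations — and then declares sb-QTLs among the stage-1
#' pairs; this is what keeps the two-stage procedure calibrated, because
#' pairs that enter stage 1 through a single sex's scan alone are selected
#' for a large per-sex slope and carry a winner's-curse excess in the
#' interaction statistic that a lenient stage-1-only BH universe converts
#' into false discoveries. `universe = "stage1"` restricts both the scan
#' and the adjustment to the stage-1 pairs. Pairs whose interaction design
#' is collinear (for example, dosage constant within one sex) are skipped
#' with a reason. The largest raw interaction p among significant records
#' is exposed as attribute `stage_p` (the p-value threshold corresponding
#' to the FDR cut).
#'
#' @param stage1 data.frame from [stage1_union()].
#' @param g,e,covariates,sex As in [cis_scan()].
#' @param fdr Interaction FDR threshold (default 0.05).
#' @param universe `"all_pairs"` (default) or `"stage1"`.
#' @param all_pairs Full pair list (required for `universe = "all_pairs"`).
#' @return data.frame of interaction records (all tested pairs under
#'   `"all_pairs"`, stage-1 pairs otherwise): `gene_id`, `variant_id`,
#'   `beta_gxs`, `se`, `p`, `q`, `in_stage1`, `significant` (q < fdr and in
#'   stage 1), `skip_reason`; attributes `stage_p` and `n_skipped`.
#' @export
interaction_scan <- function(stage1, g, e, covariates = NULL, sex, fdr = 0.05,
                             universe = c("all_pairs", "stage1"), all_pairs = NULL) {
  universe <- match.arg(universe)
  if (nrow(stage1) == 0) stop("stage-1 set is empty")
  target <- if (universe == "stage1") stage1 else {
    if (is.null(all_pairs)) stop("all_pairs required for universe = 'all_pairs'")
    all_pairs
  }
  al <- align_scan_inputs(g, e, covariates, sex)
  n <- length(al$ids)
  sexv <- as.numeric(al$sex)
  X0 <- cbind(intercept = rep(1, n), sex = sexv)
  if (!is.null(al$C)) X0 <- cbind(X0, al$C)
  Q <- proj_basis(X0)
  G <- al$G
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  vids <- unique(target$variant_id)
  Gr <- resid_cols(G[, vids, drop = FALSE], Q)
  Tr <- resid_cols(G[, vids, drop = FALSE] * sexv, Q)
  Yr <- t(resid_cols(t(al$Y[unique(target$gene_id), , drop = FALSE]), Q))
  gx <- Gr[, target$variant_id, drop = FALSE]
  tx <- Tr[, target$variant_id, drop = FALSE]
  yx <- t(Yr[target$gene_id, , drop = FALSE])
  gg <- colSums(gx^2); tt <- colSums(tx^2); gt <- colSums(gx * tx)
  gy <- colSums(gx * yx); ty <- colSums(tx * yx); yy <- colSums(yx^2)
  det <- gg * tt - gt^2
  bad <- !(det > pmax(gg * tt, .Machine$double.eps) * 1e-10)
  dof <- n - ncol(X0) - 2L
  beta_g <- (tt * gy - gt * ty) / det
  beta_t <- (gg * ty - gt * gy) / det
  rss <- pmax(yy - beta_g * gy - beta_t * ty, 0)
  sigma2 <- rss / dof
  se_t <- sqrt(sigma2 * gg / det)
  tstat <- beta_t / se_t
  p <- 2 * stats::pt(-abs(tstat), df = dof)
  out <- data.frame(gene_id = target$gene_id, variant_id = target$variant_id,
                    beta_gxs = beta_t, se = se_t, p = p, n = n,
                    stringsAsFactors = FALSE)
  out$skip_reason <- ifelse(bad, "collinear interaction design (dosage constant within a sex?)", NA)
  out[bad, c("beta_gxs", "se", "p")] <- NA_real_
  out$q <- bh_fdr(out$p)
  k1 <- paste(stage1$gene_id, stage1$variant_id)
  out$in_stage1 <- paste(out$gene_id, out$variant_id) %in% k1
  sm <- stage1$source_modes[match(paste(out$gene_id, out$variant_id),
                                  paste(stage1$gene_id, stage1$variant_id))]
  out$source_modes <- sm
  out$significant <- !is.na(out$q) & out$q < fdr & out$in_stage1
  attr(out, "stage_p") <- if (any(out$significant)) max(out$p[out$significant]) else NA_real_
  attr(out, "n_skipped") <- sum(bad)
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping to index variants
#'
#' Repeatedly takes the smallest-p unassigned record as an index and assigns
#' to it every unassigned record within `window` bp whose squared genotype
#' correlation with the index reaches `r2`. Ties in p are broken by position
#' then variant id. r2 is computed from mean-imputed standardized dosages in
#' the full sample. The index count at the alternative threshold `alt_r2` is
#' attached as attribute `n_index_alt`.
#'
#' @param records data.frame with `variant_id` and `p` (one row per record;
#'   records of different genes are clumped independently when a `gene_id`
#'   column is present).
#' @param g A [genotype_matrix()] covering the record variants.
#' @param r2 Index r2 threshold (default 0.50).
#' @param window Clump window in bp around the index variant (default 250000).
#' @param alt_r2 Alternative (independent-signal) threshold (default 0.10).
#' @return `records` with added `is_index`, `index_variant`,
#'   `clump_members` (comma-separated, for index rows).
#' @export
ld_clump <- function(records, g, r2 = 0.50, window = 250000, alt_r2 = 0.10) {
  if (nrow(records) == 0) {
    records$is_index <- logical(0); records$index_variant <- character(0)
    records$clump_members <- character(0)
    attr(records, "n_index_alt") <- 0L
    return(records)
  }
  pos <- g$variants$pos[match(records$variant_id, g$variants$id)]
  chrom <- g$variants$chrom[match(records$variant_id, g$variants$id)]
  if (anyNA(pos)) stop("record variant(s) missing from the genotype matrix")
  X <- standardize_dosages(g$dosages[, unique(records$variant_id), drop = FALSE],
                           drop_constant = FALSE)
  r2mat <- stats::cor(X)^2
  grp <- if ("gene_id" %in% names(records)) records$gene_id else rep("", nrow(records))
  run <- function(thr) {
    idx_flag <- rep(FALSE, nrow(records))
    index_of <- rep(NA_character_, nrow(records))
    for (gset in split(seq_len(nrow(records)), grp)) {
      un <- gset
      while (length(un) > 0) {
        o <- un[order(records$p[un], pos[un], records$variant_id[un])]
        i <- o[1]
        idx_flag[i] <- TRUE
        vi <- records$variant_id[i]
        memb <- un[chrom[un] == chrom[i] & abs(pos[un] - pos[i]) <= window &
                     r2mat[records$variant_id[un], vi] >= thr]
        memb <- union(memb, i)
        index_of[memb] <- vi
        un <- setdiff(un, memb)
      }
    }
    list(idx = idx_flag, of = index_of)
  }
  main <- run(r2)
  alt <- run(alt_r2)
  records$is_index <- main$idx
  records$index_variant <- main$of
  records$clump_members <- NA_character_
  for (i in which(main$idx)) {
    vi <- records$variant_id[i]
    memb <- records$variant_id[!is.na(main$of) & main$of == vi & grp == grp[i]]
    records$clump_members[i] <- paste(setdiff(memb, vi), collapse = ",")
  }
  attr(records, "n_index_alt") <- sum(alt$idx)
  records
}

#' Classify sb-QTLs by per-sex significance pattern
#'
#' Uses the per-sex scan q-values and effect signs: significant in both
#' sexes with the same sign -> `both_concordant`; both significant with
#' opposite signs -> `both_discordant`; significant in one sex only ->
#' `male_only` / `female_only`. Stage-1 pairs significant only in the joint
#' scan are classified by the larger per-sex |Z| and flagged `joint_only`;
#' records that could not have passed stage 1 are dropped with a warning.
#'
#' @param records sb-QTL records (from [interaction_scan()], typically the
#'   significant subset).
#' @param male,female Per-sex [cis_scan()] record data.frames.
#' @param fdr Per-sex FDR threshold (default 0.05).
#' @return `records` with added `category` and `joint_only` columns.
#' @export
classify_sbqtl <- function(records, male, female, fdr = 0.05) {
  key <- function(df) paste(df$gene_id, df$variant_id)
  mi <- match(key(records), key(male))
  fi <- match(key(records), key(female))
  msig <- !is.na(mi) & !is.na(male$q[mi]) & male$q[mi] < fdr
  fsig <- !is.na(fi) & !is.na(female$q[fi]) & female$q[fi] < fdr
  mbeta <- male$beta[mi]; fbeta <- female$beta[fi]
  mz <- abs(male$beta[mi] / male$se[mi]); fz <- abs(female$beta[fi] / female$se[fi])
  cat <- rep(NA_character_, nrow(records))
  cat[msig & fsig & sign(mbeta) == sign(fbeta)] <- "both_concordant"
  cat[msig & fsig & sign(mbeta) != sign(fbeta)] <- "both_discordant"
  cat[msig & !fsig] <- "male_only"
  cat[!msig & fsig] <- "female_only"
  joint_only <- !msig & !fsig
  from_joint <- if ("source_modes" %in% names(records))
    grepl("joint", records$source_modes) else rep(TRUE, nrow(records))
  resolvable <- joint_only & from_joint & !is.na(mz) & !is.na(fz)
  cat[resolvable] <- ifelse(mz[resolvable] >= fz[resolvable], "male_only", "female_only")
  orphan <- joint_only & !resolvable
  if (any(orphan)) {
    warning(sum(orphan), " record(s) not significant in any stage-1 scan dropped")
    records <- records[!orphan, , drop = FALSE]
    cat <- cat[!orphan]; joint_only <- joint_only[!orphan]
  }
  records$category <- cat
  records$joint_only <- joint_only
  records
}

#' Environment-interaction confounding check for index sb-QTLs
#'
#' Three steps. (1) Test each environment variable for a sex difference
#' (Welch t-test for numeric, chi-squared for categorical). (2) For each
#' index sb-QTL and environment, fit expression ~ SNP + environment +
#' SNP x environment + covariates and flag pairs whose SNP-by-environment p
#' falls below `stage_p` (the p threshold corresponding to the interaction
#' FDR cut). (3) For flagged pairs, fit the joint model with both SNP x sex
#' and SNP x environment; the record is `robust` if the SNP x sex p stays
#' below `stage_p` and `attenuated` otherwise. Degenerate models (for
#' example a constant environment) are surfaced per record while the rest
#' proceed.
#'
#' @param index_records sb-QTL records (index rows).
#' @param g,e,covariates,sex As in [cis_scan()].
#' @param s Sample table holding the environment columns.
#' @param env_names Character vector of environment column names.
#' @param stage_p Stage p-value threshold (attribute `stage_p` of
#'   [interaction_scan()] output).
#' @return List with `sex_env_tests` (per-environment sex-difference tests)
#'   and `records` (per SNP x environment rows with `snp_env_p`,
#'   `snp_sex_p_joint`, `flag` in \{not_flagged, robust, attenuated, error\}).
#' @export
environment_check <- function(index_records, g, e, covariates = NULL, sex, s,
                              env_names, stage_p) {
  miss <- setdiff(env_names, names(s))
  if (length(miss)) stop("environment column(s) missing: ", paste(miss, collapse = ", "))
  al <- align_scan_inputs(g, e, covariates, sex)
  s <- s[match(al$ids, s$sample_id), , drop = FALSE]
  sexv <- as.numeric(al$sex)
  sex_env <- do.call(rbind, lapply(env_names, function(ev) {
    x <- s[[ev]]
    if (is.numeric(x)) {
      p <- tryCatch(stats::t.test(x ~ sexv)$p.value, error = function(e) NA_real_)
      data.frame(environment = ev, test = "welch_t", p = p)
    } else {
      p <- tryCatch(suppressWarnings(stats::chisq.test(table(x, sexv))$p.value),
                    error = function(e) NA_real_)
      data.frame(environment = ev, test = "chisq", p = p)
    }
  }))
  base_C <- al$C
  rows <- list()
  for (i in seq_len(nrow(index_records))) {
    gid <- index_records$gene_id[i]; vid <- index_records$variant_id[i]
    dos <- al$G[, vid]
    if (anyNA(dos)) dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
    y <- al$Y[gid, ]
    for (ev in env_names) {
      envx <- s[[ev]]
      if (is.character(envx) || is.factor(envx)) envx <- as.numeric(as.factor(envx)) - 1
      rec <- data.frame(gene_id = gid, variant_id = vid, environment = ev,
                        snp_env_p = NA_real_, snp_sex_p_joint = NA_real_,
                        flag = "not_flagged", stringsAsFactors = FALSE)
      fit2 <- tryCatch({
        X <- cbind(intercept = 1, snp = dos, env = envx, snp_env = dos * envx)
        if (!is.null(base_C)) X <- cbind(X, base_C)
        ok <- !is.na(y) & !is.na(envx)
        ols_fit(X[ok, , drop = FALSE], y[ok])
      }, error = function(err) err)
      if (inherits(fit2, "error")) {
        rec$flag <- "error"
        rec$snp_env_p <- NA_real_
        attr(rec, "error") <- conditionMessage(fit2)
        rows[[length(rows) + 1]] <- rec
        next
      }
      rec$snp_env_p <- fit2$p_values[["snp_env"]]
      if (!is.na(rec$snp_env_p) && rec$snp_env_p < stage_p) {
        fit3 <- tryCatch({
          X <- cbind(intercept = 1, snp = dos, sex = sexv, env = envx,
                     snp_sex = dos * sexv, snp_env = dos * envx)
          if (!is.null(base_C)) X <- cbind(X, base_C)
          ok <- !is.na(y) & !is.na(envx)
          ols_fit(X[ok, , drop = FALSE], y[ok])
        }, error = function(err) err)
        if (inherits(fit3, "error")) {
          rec$flag <- "error"
        } else {
          rec$snp_sex_p_joint <- fit3$p_values[["snp_sex"]]
          rec$flag <- if (rec$snp_sex_p_joint < stage_p) "robust" else "attenuated"
        }
      }
      rows[[length(rows) + 1]] <- rec
    }
  }
  list(sex_env_tests = sex_env, records = do.call(rbind, rows))
}

#' Discovery/replication pi1 statistic
#'
#' Matches discovery-significant index sb-QTL records to the replication
#' cohort's interaction records by gene, variant and (when available)
#' alleles — records whose ref/alt labels are swapped between cohorts are
#' harmonized, which leaves the interaction p-value unchanged — and returns
#' Storey's pi1 over the matched replication p-values.
#'
#' @param discovery Index sb-QTL records from the discovery cohort (rows
#'   with `is_index` if present, otherwise all rows are used).
#' @param replication Interaction records from the replication cohort (from
#'   [interaction_scan()] run on the replication data).
#' @param method pi0 estimator passed to [storey_pi1()]. The default is the
#'   fixed-lambda (0.5) estimator: discovery index sets number in the tens
#'   to low hundreds, a regime where the spline smoother's boundary
#'   evaluation is unstable while the fixed-lambda estimate stays
#'   conservative; pass `"smoother"` for replication sets of a thousand or
#'   more records.
#' @return List with `n_discovery_hits`, `n_matched`, `pi1`.
#' @export
pi1_replication <- function(discovery, replication,
                            method = c("fixed", "smoother")) {
  method <- match.arg(method)
  if (nrow(discovery) == 0) stop("discovery set is empty")
  if ("is_index" %in% names(discovery)) discovery <- discovery[discovery$is_index, ]
  key <- function(df) paste(df$gene_id, df$variant_id)
  idx <- match(key(discovery), key(replication))
  p <- replication$p[idx[!is.na(idx)]]
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("no discovery record matched in the replication cohort")
  if (length(p) < 50 && method == "smoother") {
    warning("fewer than 50 matched records; pi1 uses the conservative fixed-lambda estimator")
    method <- "fixed"
  }
  pi1 <- suppressWarnings(storey_pi1(p, method = method))
  list(n_discovery_hits = nrow(discovery), n_matched = length(p), pi1 = pi1)
}
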