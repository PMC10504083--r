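## shared small cohort for scan tests
scan_fixture <- function(seed = 5, n_genes = 40, gxs_frac = 0.3, n = 700, ...) {
  cfg <- sim_config(n_samples = n, n_genes = n_genes, snps_per_gene = 50,
                    gxs_frac = gxs_frac, seed = seed, ...)
  g <- simulate_genotypes(cfg)
  sim <- simulate_expression(g, cfg)
  list(cfg = cfg, g = g, truth = sim$truth,
       e = zscore_expression(sim$expression),
       sex = stats::setNames(g$samples$sex, g$samples$sample_id),
       pairs = map_cis_pairs(g$genes, g$variants, 500000))
}

test_that("map_cis_pairs applies exact window arithmetic", {
  genes <- data.frame(gene_id = "g1", chrom = "1", start = 1000, end = 2000)
  variants <- data.frame(id = paste0("v", 1:5), chrom = c("1", "1", "1", "1", "2"),
                         pos = c(499, 500, 2500, 2501, 1500))
  out <- map_cis_pairs(genes, variants, window = 500)
  expect_equal(sort(out$variant_id), c("v2", "v3"))
  ## distance bookkeeping
  expect_equal(out$distance[out$variant_id == "v2"], 500)
  ## window 0: intragenic only
  v2 <- data.frame(id = c("a", "b"), chrom = "1", pos = c(1500, 2500))
  expect_equal(map_cis_pairs(genes, v2, window = 0)$variant_id, "a")
  expect_error(map_cis_pairs(transform(genes, end = 10), variants), "end < start")
})

test_that("cis_scan detects a planted cis effect and matches ols_fit exactly", {
  fx <- scan_fixture(seed = 31, n_genes = 10, gxs_frac = 0, cis_frac = 1,
                     cis_beta_sd = 0.5)
  sc <- cis_scan(fx$pairs, fx$g, fx$e, covariates = NULL, sex = fx$sex, "joint")
  ## the causal pair of a strong gene is found; "strong" accounts for the
  ## causal variant's MAF through the expected per-pair z
  tr <- fx$truth
  maf <- fx$g$variants$maf[match(tr$causal_variant, fx$g$variants$id)]
  exp_z <- abs(tr$beta_male) * sqrt(700 * 2 * maf * (1 - maf))
  strong <- which(exp_z > 8)
  for (i in strong) {
    hit <- sc[sc$gene_id == tr$gene_id[i] & sc$variant_id == tr$causal_variant[i], ]
    expect_lt(hit$q, 0.05)
  }
  ## spot-check agreement with the full per-pair OLS (different code path)
  for (row in c(1, 57, 200)) {
    gid <- sc$gene_id[row]; vid <- sc$variant_id[row]
    X <- cbind(1, sex = unname(fx$sex), dos = fx$g$dosages[, vid])
    fit <- ols_fit(X, fx$e$values[gid, ])
    expect_equal(sc$beta[row], unname(fit$coefficients["dos"]), tolerance = 1e-10)
    expect_equal(sc$p[row], unname(fit$p_values["dos"]), tolerance = 1e-10)
  }
  ## male X dosages stay in {0, 2} in every mode
  xv <- fx$g$variants$id[fx$g$variants$chrom == "X"]
  males <- names(fx$sex)[fx$sex == 0]
  expect_true(all(fx$g$dosages[males, xv] %in% c(0, 2)))
  ## stratum too small -> error
  expect_error(cis_scan(fx$pairs, fx$g, fx$e, NULL, fx$sex, "male", min_n = 1e6),
               "below minimum")
})

test_that("null cis scan is calibrated", {
  fx <- scan_fixture(seed = 32, n_genes = 30, gxs_frac = 0, cis_frac = 0,
                     sex_effect_frac = 0, hidden_frac = 0)
  sc <- cis_scan(fx$pairs, fx$g, fx$e, covariates = NULL, sex = fx$sex, "joint")
  expect_lte(mean(sc$q < 0.05, na.rm = TRUE), 0.001)
  expect_equal(qq_lambda(sc$p[!is.na(sc$p)])$lambda, 1.0, tolerance = 0.12)
})

test_that("stage1_union takes the three-scan union with source bookkeeping", {
  mk <- function(q) data.frame(gene_id = paste0("g", 1:6), variant_id = paste0("v", 1:6),
                               q = q, beta = 1, se = 1)
  joint <- mk(c(0.01, 0.2, 0.2, 0.01, 0.2, 0.2))
  male <- mk(c(0.2, 0.01, 0.2, 0.01, 0.2, 0.2))
  female <- mk(c(0.2, 0.2, 0.01, 0.2, 0.2, 0.051))
  s1 <- stage1_union(joint, male, female, fdr = 0.05)
  expect_equal(nrow(s1), 4L)
  expect_setequal(s1$gene_id, c("g1", "g2", "g3", "g4"))
  expect_equal(s1$source_modes[s1$gene_id == "g3"], "female")
  expect_equal(s1$source_modes[s1$gene_id == "g4"], "joint,male")
  expect_equal(nrow(stage1_union(mk(rep(1, 6)), mk(rep(1, 6)), mk(rep(1, 6)))), 0L)
})

test_that("interaction_scan recovers planted interactions and their magnitude", {
  fx <- scan_fixture(seed = 33, n_genes = 40, gxs_frac = 0.4, gxs_beta_sd = 0.5)
  sc <- lapply(c("joint", "male", "female"), function(m)
    cis_scan(fx$pairs, fx$g, fx$e, NULL, fx$sex, m))
  s1 <- stage1_union(sc[[1]], sc[[2]], sc[[3]])
  it <- interaction_scan(s1, fx$g, fx$e, NULL, fx$sex, all_pairs = fx$pairs)
  tr <- fx$truth
  strong <- tr$gene_id[abs(tr$beta_gxs) > 0.45]
  found <- unique(it$gene_id[it$significant])
  expect_gte(sum(strong %in% found) / length(strong), 0.6)
  ## interaction beta close to the planted value on the causal pair; the
  ## outcome is z-scored per gene, so the truth rescales by the raw SD
  key <- paste(it$gene_id, it$variant_id)
  ck <- match(paste(tr$gene_id, tr$causal_variant), key)
  est <- it$beta_gxs[ck]
  sim <- simulate_expression(fx$g, fx$cfg)
  sd_raw <- apply(sim$expression$values, 1, sd)
  truth_z <- tr$beta_gxs / sd_raw[tr$gene_id]
  ok <- !is.na(ck) & abs(truth_z) > 0.2
  ## estimates are noisy per pair (se ~ 0.15-0.25); the systematic bias is
  ## what must vanish
  expect_lt(abs(mean(est[ok] - truth_z[ok])), 0.1)
  ## sexes generated identically -> no detections
  fx0 <- scan_fixture(seed = 34, n_genes = 20, gxs_frac = 0, sex_effect_frac = 0)
  sc0 <- lapply(c("joint", "male", "female"), function(m)
    cis_scan(fx0$pairs, fx0$g, fx0$e, NULL, fx0$sex, m))
  s10 <- stage1_union(sc0[[1]], sc0[[2]], sc0[[3]])
  if (nrow(s10) > 0) {
    it0 <- interaction_scan(s10, fx0$g, fx0$e, NULL, fx0$sex, all_pairs = fx0$pairs)
    expect_equal(sum(it0$significant), 0L)
  }
  expect_error(interaction_scan(s1[0, ], fx$g, fx$e, NULL, fx$sex,
                                all_pairs = fx$pairs), "empty")
})

test_that("swapping sex labels maps male_only <-> female_only and negates betas", {
  fx <- scan_fixture(seed = 35, n_genes = 30, gxs_frac = 0.4, gxs_beta_sd = 0.6)
  run <- function(sex) {
    sc <- lapply(c("joint", "male", "female"), function(m)
      cis_scan(fx$pairs, fx$g, fx$e, NULL, sex, m))
    s1 <- stage1_union(sc[[1]], sc[[2]], sc[[3]])
    it <- interaction_scan(s1, fx$g, fx$e, NULL, sex, all_pairs = fx$pairs)
    sb <- it[it$significant, , drop = FALSE]
    sb <- classify_sbqtl(sb, sc[[2]], sc[[3]])
    list(it = it, sb = sb)
  }
  a <- run(fx$sex)
  b <- run(1 - fx$sex)
  ## interaction betas negate exactly (same pairs tested)
  key <- function(df) paste(df$gene_id, df$variant_id)
  m <- match(key(a$it), key(b$it))
  expect_equal(a$it$beta_gxs, -b$it$beta_gxs[m], tolerance = 1e-10)
  ## categories swap
  ms <- match(key(a$sb), key(b$sb))
  swap <- c(male_only = "female_only", female_only = "male_only",
            both_concordant = "both_concordant", both_discordant = "both_discordant")
  expect_equal(unname(swap[a$sb$category]), b$sb$category[ms])
})

test_that("ld_clump matches the brute-force greedy oracle", {
  set.seed(21)
  for (rep in 1:5) {
    nsnp <- 20
    ## LD-structured dosages
    cfg <- sim_config(n_samples = 300, n_genes = 1, snps_per_gene = nsnp,
                      ld_block_size = 5, ld_rho = 0.9, seed = 100 + rep)
    g <- simulate_genotypes(cfg)
    recs <- data.frame(gene_id = "g", variant_id = g$variants$id,
                       p = runif(nsnp))
    out <- ld_clump(recs, g, r2 = 0.5, window = 250000)
    X <- scale(g$dosages)
    r2m <- cor(X)^2
    oc <- oracle_clump(recs$p, g$variants$pos, r2m, 0.5, 250000)
    expect_equal(out$is_index, oc$is_index)
    expect_equal(out$index_variant, recs$variant_id[oc$index_of])
  }
  ## 3 SNPs in perfect LD: single index at the smallest p
  dos <- random_dosages(200, c(0.3), seed = 3)
  dos <- cbind(dos, dos, dos)
  colnames(dos) <- paste0("v", 1:3)
  g3 <- tiny_genotypes(dos, pos = c(1000L, 2000L, 3000L))
  recs3 <- data.frame(variant_id = paste0("v", 1:3), p = c(1e-8, 1e-6, 1e-5))
  out3 <- ld_clump(recs3, g3)
  expect_equal(out3$is_index, c(TRUE, FALSE, FALSE))
  expect_equal(out3$clump_members[1], "v2,v3")
  ## mutually uncorrelated SNPs: all index
  g4 <- tiny_genotypes(random_dosages(500, rep(0.4, 4), seed = 4))
  recs4 <- data.frame(variant_id = colnames(g4$dosages), p = runif(4))
  expect_true(all(ld_clump(recs4, g4)$is_index))
})

test_that("classify_sbqtl applies the definitional rules", {
  recs <- data.frame(gene_id = "g", variant_id = c("a", "b", "c", "d"),
                     source_modes = c("male", "joint", "male,female", "joint"))
  male <- data.frame(gene_id = "g", variant_id = c("a", "b", "c", "d"),
                     q = c(1e-4, 0.4, 1e-3, 0.4), beta = c(0.3, 0.1, 0.3, 0.2),
                     se = c(0.05, 0.05, 0.05, 0.05))
  female <- data.frame(gene_id = "g", variant_id = c("a", "b", "c", "d"),
                       q = c(0.4, 1e-3, 1e-3, 0.4), beta = c(0.1, 0.2, -0.3, 0.1),
                       se = c(0.05, 0.05, 0.05, 0.05))
  out <- classify_sbqtl(recs, male, female)
  expect_equal(out$category, c("male_only", "female_only", "both_discordant",
                               "male_only"))
  expect_equal(out$joint_only, c(FALSE, FALSE, FALSE, TRUE))
  ## concordant case
  female2 <- female; female2$beta[3] <- 0.3
  expect_equal(classify_sbqtl(recs, male, female2)$category[3], "both_concordant")
  ## orphan record (no stage-1 support) dropped with warning
  recs2 <- rbind(recs, data.frame(gene_id = "g", variant_id = "zz",
                                  source_modes = "male"))
  male2 <- rbind(male, data.frame(gene_id = "g", variant_id = "zz", q = NA,
                                  beta = NA, se = NA))
  female3 <- rbind(female, data.frame(gene_id = "g", variant_id = "zz", q = NA,
                                      beta = NA, se = NA))
  expect_warning(out2 <- classify_sbqtl(recs2, male2, female3), "dropped")
  expect_equal(nrow(out2), 4L)
})

test_that("environment_check flags a sex-correlated environmental driver", {
  n <- 700
  set.seed(41)
  sex <- rep(0:1, each = n / 2)
  ids <- sprintf("S%04d", 1:n)
  dos <- matrix(rbinom(n * 2, 2, 0.3), n, 2,
                dimnames = list(ids, c("v1", "v2")))
  g <- tiny_genotypes(dos)
  ## env strongly correlated with sex; expression interaction driven by env
  env <- sex * 0.9 + rnorm(n, 0, 0.4)
  y1 <- 0.4 * dos[, 1] * env + rnorm(n)          # truly env-driven
  y2 <- 0.4 * dos[, 2] * sex + rnorm(n)          # truly sex-driven
  e <- as_expr(rbind(ga = y1, gb = y2))
  colnames(e$values) <- ids; e$sample_ids <- ids
  s <- data.frame(sample_id = ids, alcohol = env,
                  inert = rnorm(n), stringsAsFactors = FALSE)
  idx <- data.frame(gene_id = c("ga", "gb"), variant_id = c("v1", "v2"))
  res <- environment_check(idx, g, e, covariates = NULL,
                           sex = setNames(sex, ids), s = s,
                           env_names = c("alcohol", "inert"), stage_p = 5e-4)
  ## step 1: alcohol differs by sex, inert does not
  expect_lt(res$sex_env_tests$p[res$sex_env_tests$environment == "alcohol"], 1e-10)
  expect_gt(res$sex_env_tests$p[res$sex_env_tests$environment == "inert"], 0.001)
  r <- res$records
  ## the env-driven gene is flagged and attenuated once env is modeled
  ga <- r[r$gene_id == "ga" & r$environment == "alcohol", ]
  expect_equal(ga$flag, "attenuated")
  ## the sex-driven gene stays robust (its sex interaction survives)
  gb <- r[r$gene_id == "gb" & r$environment == "alcohol", ]
  expect_true(gb$flag %in% c("not_flagged", "robust"))
  ## inert environment: nothing flagged
  expect_true(all(r$flag[r$environment == "inert"] == "not_flagged"))
  ## constant environment column surfaces as per-record error
  s$constant <- 1
  res2 <- environment_check(idx, g, e, NULL, setNames(sex, ids), s,
                            c("constant"), stage_p = 5e-4)
  expect_true(all(res2$records$flag == "error"))
  expect_error(environment_check(idx, g, e, NULL, setNames(sex, ids), s,
                                 c("missing_col"), stage_p = 5e-4), "missing")
})

test_that("pi1_replication separates true and null replication", {
  cfg <- sim_config(n_samples = 700, n_genes = 80, snps_per_gene = 50,
                    gxs_frac = 0.4, gxs_beta_sd = 0.8, seed = 50)
  for (rho in c(0, 1)) {
    pair <- simulate_replication_pair(cfg, rho_rep = rho)
    res <- suppressWarnings(sbqtl:::replicate_pi1(pair))
    if (rho == 1) expect_gte(res$pi1, 0.8) else expect_lte(res$pi1, 0.1)
  }
  expect_error(pi1_replication(data.frame()[0, ], data.frame()), "empty")
})
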