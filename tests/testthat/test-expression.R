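sample_table <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             sex = rep(c(0L, 1L), length.out = n),
             age = round(runif(n, 60, 95)),
             post_mortem_interval = runif(n, 2, 20),
             batch = sample(c("b1", "b2", "b3"), n, replace = TRUE),
             diagnosis = sample(c("normal", "AD", "other"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

test_that("filter_missing applies the strict 50% rule", {
  set.seed(1)
  vals <- matrix(rnorm(10 * 100), 10, 100)
  vals[1, 1:51] <- NA   # 51% -> removed
  vals[2, 1:50] <- NA   # exactly 50% -> retained
  vals[3, 1:80] <- NA
  vals[4, 1:60] <- NA
  e <- as_expr(vals, stage = "raw")
  out <- filter_missing(e)
  expect_equal(nrow(out$values), 7L)
  expect_false("g001" %in% out$gene_ids)
  expect_true("g002" %in% out$gene_ids)
})

test_that("normalize_protein is scale invariant and matches hand computation", {
  vals <- matrix(c(1, 3, 2, 6), 2, 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  e <- expression_matrix(vals, "protein", "raw")
  out <- normalize_protein(e)
  expect_equal(unname(out$values),
               matrix(log2(c(0.25, 0.75, 0.25, 0.75)), 2, 2))
  expect_equal(out$stage, "normalized")
  ## doubling one sample's values changes nothing
  vals2 <- vals; vals2[, 2] <- vals2[, 2] * 2
  out2 <- normalize_protein(expression_matrix(vals2, "protein", "raw"))
  expect_equal(out2$values, out$values)
  ## missing stays missing; nonpositive errors
  vals3 <- vals; vals3[1, 1] <- NA
  expect_true(is.na(normalize_protein(expression_matrix(vals3, "protein", "raw"))$values[1, 1]))
  vals4 <- vals; vals4[1, 1] <- 0
  expect_error(normalize_protein(expression_matrix(vals4, "protein", "raw")), "positive")
})

test_that("remove_outlier_samples removes a planted extreme sample and is a fixed point", {
  set.seed(5)
  vals <- matrix(rnorm(50 * 40), 50, 40)
  vals[, 7] <- vals[, 7] + 10  # 10-SD shift on the dominant axis
  e <- as_expr(vals, stage = "residualized")
  res <- remove_outlier_samples(e, sd_cut = 4)
  expect_true("S007" %in% res$removed)
  ## homogeneous matrix: nothing removed, idempotent
  res2 <- remove_outlier_samples(res$expression, sd_cut = 4)
  expect_equal(length(res2$removed), 0L)
  expect_equal(res2$expression$values, res$expression$values)
})

test_that("regress_out removes covariate effects and guards sex", {
  n <- 80
  s <- sample_table(n, seed = 2)
  batch_eff <- c(b1 = 0, b2 = 3, b3 = -2)[s$batch]
  vals <- matrix(rep(batch_eff, each = 5), 5, n, byrow = FALSE)
  vals <- t(t(matrix(0, 5, n)) + batch_eff)  # pure batch effect
  rownames(vals) <- sprintf("g%03d", 1:5); colnames(vals) <- s$sample_id
  e <- expression_matrix(vals, "protein", "raw")
  out <- regress_out(e, s, c("batch"))
  expect_lt(max(apply(out$values, 1, sd)), 1e-8)
  expect_equal(out$stage, "residualized")
  ## residuals uncorrelated with covariates
  set.seed(3)
  vals2 <- matrix(rnorm(5 * n), 5, n,
                  dimnames = list(sprintf("g%03d", 1:5), s$sample_id))
  out2 <- regress_out(expression_matrix(vals2, "protein", "raw"), s,
                      c("age", "post_mortem_interval", "batch"))
  for (i in 1:5) {
    expect_lt(abs(cor(out2$values[i, ], s$age)), 1e-8)
    expect_lt(abs(cor(out2$values[i, ], s$post_mortem_interval)), 1e-8)
  }
  ## covariate orthogonal to expression leaves values unchanged
  valso <- matrix(rnorm(3 * n), 3, n,
                  dimnames = list(sprintf("g%03d", 1:3), s$sample_id))
  covo <- s; covo$ortho <- as.numeric(residuals(lm(rnorm(n) ~ t(valso))))
  out3 <- regress_out(expression_matrix(valso, "protein", "raw"), covo, "ortho")
  expect_equal(out3$values, valso, tolerance = 1e-8)
  expect_error(regress_out(e, s, c("batch", "sex")), "protected")
})

test_that("estimate_svs recovers a planted factor, protects sex, nulls out noise", {
  n <- 150; ng <- 200
  s <- sample_table(n, seed = 4)
  set.seed(4)
  ## pure noise -> k near 0
  e0 <- as_expr(matrix(rnorm(ng * n), ng, n,
                       dimnames = list(NULL, s$sample_id)))
  sv0 <- estimate_svs(e0, s, seed = 1)
  expect_lte(ncol(sv0), 1)
  ## planted hidden factor on 30% of genes
  fac <- rnorm(n)
  load <- ifelse(runif(ng) < 0.3, rnorm(ng, 0, 1), 0)
  vals <- matrix(rnorm(ng * n), ng, n) + outer(load, fac)
  e1 <- as_expr(vals)
  colnames(e1$values) <- s$sample_id; e1$sample_ids <- s$sample_id
  sv1 <- estimate_svs(e1, s, seed = 1)
  expect_gte(ncol(sv1), 1)
  expect_gt(abs(cor(sv1[, 1], fac)), 0.8)
  ## protection: all SVs orthogonal to the (centered) sex indicator
  sexc <- s$sex - mean(s$sex)
  expect_lt(max(abs(crossprod(sv1, sexc))), 1e-8)
  ## a factor equal to sex itself is not captured
  vals2 <- matrix(rnorm(ng * n), ng, n) + outer(load, as.numeric(s$sex))
  e2 <- as_expr(vals2)
  colnames(e2$values) <- s$sample_id; e2$sample_ids <- s$sample_id
  sv2 <- estimate_svs(e2, s, seed = 1)
  if (ncol(sv2) > 0)
    expect_lt(max(abs(cor(sv2, s$sex))), 0.3)
  ## fixed-k override
  svf <- estimate_svs(e1, s, n_sv = 5, seed = 1)
  expect_equal(ncol(svf), 5L)
})

test_that("zscore_expression standardizes rows and drops constants", {
  set.seed(6)
  vals <- matrix(rnorm(6 * 30, mean = 5, sd = 3), 6, 30)
  vals[6, ] <- 2
  e <- as_expr(vals)
  expect_warning(out <- zscore_expression(e), "zero-variance")
  expect_equal(nrow(out$values), 5L)
  expect_lt(max(abs(rowMeans(out$values))), 1e-8)
  expect_equal(apply(out$values, 1, sd), rep(1, 5), tolerance = 1e-8,
               ignore_attr = TRUE)
  ## affine invariance
  e2 <- as_expr(vals[1:5, ] * 7 - 3)
  expect_equal(zscore_expression(e2)$values, out$values, ignore_attr = TRUE)
  expect_equal(out$stage, "zscored")
})

test_that("prepare_transcripts honors the per-diagnosis CPM rule and log2 CPM", {
  s <- data.frame(sample_id = c("a", "b", "c", "d"),
                  diagnosis = c("normal", "normal", "AD", "AD"))
  counts <- rbind(
    t1 = c(0, 0, 0, 0),          # zero everywhere -> removed
    t2 = c(500, 600, 0, 0),      # passes in 'normal' only -> retained
    t3 = c(0, 0, 0, 1),          # below 1 CPM in >= 50% of both groups -> removed
    t4 = c(300, 300, 300, 300))  # passes everywhere
  colnames(counts) <- s$sample_id
  lib <- colSums(counts)
  out <- prepare_transcripts(counts, s)
  expect_equal(sort(rownames(out$values)), c("t2", "t4"))
  ## hand-computed log2(CPM + 0.5)
  expect_equal(out$values["t4", "a"], log2(300 / lib[["a"]] * 1e6 + 0.5))
  expect_equal(out$values["t2", "c"], log2(0 + 0.5))
  expect_equal(out$level, "transcript")
  counts0 <- counts; counts0[, 2] <- 0
  expect_error(prepare_transcripts(counts0, s), "zero library")
})

test_that("select_isoform keeps the most abundant isoform with lexicographic ties", {
  vals <- rbind(i1 = rep(5, 4), i2 = rep(7, 4), i3 = rep(3, 4),
                i4 = rep(3, 4), i5 = rep(2, 4))
  colnames(vals) <- sprintf("S%03d", 1:4)
  e <- as_expr(vals)
  map <- data.frame(isoform_id = c("i1", "i2", "i3", "i4", "i5"),
                    gene_id = c("gA", "gA", "gB", "gB", "gC"))
  out <- select_isoform(e, map)
  expect_equal(sort(rownames(out$values)), c("gA", "gB", "gC"))
  expect_equal(unname(out$values["gA", 1]), 7)  # max rule
  expect_equal(unname(out$values["gB", 1]), 3)  # tie -> i3 (lexicographic)
  expect_equal(unname(out$values["gC", 1]), 2)  # single isoform unchanged
})

test_that("stage transitions only move forward", {
  e <- as_expr(matrix(rnorm(20), 4, 5), stage = "residualized")
  z <- zscore_expression(e)
  expect_error(normalize_protein(z), "stage")
  expect_error(filter_missing(z), "stage")
})
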