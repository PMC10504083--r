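test_that("cis_heritability recovers planted variance fractions", {
  set.seed(61)
  n <- 700; m <- 50
  X <- random_dosages(n, runif(m, 0.1, 0.5), seed = 61)
  Xs <- scale(X)
  for (h2 in c(0, 0.25, 0.5)) {
    b <- rnorm(m, 0, sqrt(h2 / m))
    gval <- as.numeric(Xs %*% b)
    y <- gval + rnorm(n, 0, sqrt(1 - h2))
    res <- cis_heritability(X, y)
    expect_lt(abs(res$h2 - h2), 0.15)
  }
  ## null: significance rate controlled
  sig <- replicate(60, {
    y <- rnorm(n)
    cis_heritability(X, y)$p < 0.01
  })
  mc_se <- sqrt(0.01 * 0.99 / 60)
  expect_lte(mean(sig), 0.01 + 2 * mc_se + 1 / 60)
  expect_error(cis_heritability(X[1:10, ], rnorm(10)), "at least 50")
  expect_error(cis_heritability(X, rep(1, n)), "constant")
})

test_that("train_weights concentrates weight on the causal SNP", {
  set.seed(62)
  n <- 400; m <- 30
  X <- random_dosages(n, runif(m, 0.2, 0.5), seed = 62)
  y <- X[, 5] + rnorm(n, 0, 0.4)
  w <- train_weights(X, y, seed = 3)
  expect_equal(which.max(abs(w$weights)), 5L)
  expect_gt(w$cv_r2, 0.5)
  expect_equal(w$model, names(which.max(w$cv_r2_all)))
  ## null gene: negligible predictive accuracy
  w0 <- train_weights(X, rnorm(n), seed = 3)
  expect_lte(w0$cv_r2, 0.05)
  ## duplicated causal SNPs: ridge splits, lasso concentrates; predictions agree
  X2 <- cbind(X[, 1:10], dup1 = X[, 5], dup2 = X[, 5])
  colnames(X2) <- paste0("s", seq_len(ncol(X2)))
  y2 <- X[, 5] + rnorm(n, 0.0, 0.2)
  ridge <- glmnet::cv.glmnet(X2, y2, alpha = 0)
  lasso <- glmnet::cv.glmnet(X2, y2, alpha = 1)
  pr <- predict(ridge, X2, s = "lambda.min")
  pl <- predict(lasso, X2, s = "lambda.min")
  expect_gt(cor(pr, pl), 0.99)
  expect_error(train_weights(X[1:3, ], rnorm(3), folds = 5), "fewer samples")
})

test_that("pwas_assoc combines weights and GWAS z-scores with LD", {
  ## single variant: z passes through
  gw <- data.frame(SNP = "v1", A1 = "G", A2 = "A", Z = 5)
  r <- pwas_assoc(c(v1 = 1), gw, matrix(1, 1, 1, dimnames = list("v1", "v1")),
                  lambda = 0)
  expect_equal(r$z, 5.0)
  ## two perfectly correlated variants: w'z = 4, w'Rw = 1
  gw2 <- data.frame(SNP = c("v1", "v2"), A1 = "G", A2 = "A", Z = c(4, 4))
  R2 <- matrix(1, 2, 2, dimnames = list(c("v1", "v2"), c("v1", "v2")))
  r2 <- pwas_assoc(c(v1 = 0.5, v2 = 0.5), gw2, R2, lambda = 0)
  expect_equal(r2$z, 4.0)
  r2s <- pwas_assoc(c(v1 = 0.5, v2 = 0.5), gw2, R2)  # with default stabilizer
  expect_equal(r2s$z, 4.0, tolerance = 0.03)
  ## allele harmonization: swapped alleles flip the z sign
  w <- structure(list(weights = c(v1 = 1), stratum = "joint"), class = "weight_model")
  attr(w, "alleles") <- data.frame(id = "v1", a1 = "G", a2 = "A")
  gw3 <- data.frame(SNP = "v1", A1 = "A", A2 = "G", Z = 5)
  r3 <- pwas_assoc(w, gw3, matrix(1, 1, 1, dimnames = list("v1", "v1")), lambda = 0)
  expect_equal(r3$z, -5.0)
  ## strand-ambiguous variants dropped
  w2 <- structure(list(weights = c(v1 = 1, v2 = 1)), class = "weight_model")
  attr(w2, "alleles") <- data.frame(id = c("v1", "v2"), a1 = c("A", "G"),
                                    a2 = c("T", "A"))
  gw4 <- data.frame(SNP = c("v1", "v2"), A1 = c("A", "G"), A2 = c("T", "A"),
                    Z = c(3, 2))
  R4 <- diag(2); dimnames(R4) <- list(c("v1", "v2"), c("v1", "v2"))
  r4 <- pwas_assoc(w2, gw4, R4, lambda = 0)
  expect_equal(r4$n_ambiguous_dropped, 1L)
  expect_equal(r4$z, 2.0)
  expect_error(pwas_assoc(c(v1 = 0), gw, matrix(1, 1, 1)), "zero")
})

test_that("pwas type-I error is nominal under a null GWAS", {
  set.seed(63)
  n <- 500; m <- 20
  X <- random_dosages(n, runif(m, 0.2, 0.5), seed = 63)
  colnames(X) <- paste0("v", 1:m)
  R <- cor(X)
  hits <- replicate(400, {
    z <- rnorm(m)  # independent null GWAS z (LD-free approximation at the null)
    ## null z with LD structure: draw from N(0, R)
    z <- as.numeric(t(chol(R + diag(1e-8, m))) %*% rnorm(m))
    w <- rnorm(m) * rbinom(m, 1, 0.3)
    if (all(w == 0)) w[1] <- 1
    names(w) <- colnames(X)
    gw <- data.frame(SNP = colnames(X), A1 = "G", A2 = "A", Z = z)
    pwas_assoc(w, gw, R, lambda = 0)$p < 0.05
  })
  mc_se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(mean(hits) - 0.05), 3 * mc_se)
})

test_that("coloc_abf ranks hypotheses correctly and posteriors sum to one", {
  ## shared single causal variant, peak z = 8
  se <- rep(0.05, 10)
  beta <- c(8 * 0.05, rnorm(9, 0, 0.01))
  res <- coloc_abf(beta, se, beta, se)
  expect_gt(res$pp["PP4"], 0.95)
  expect_equal(sum(res$pp), 1, tolerance = 1e-10)
  ## no signal anywhere: PP0 dominates
  res0 <- coloc_abf(rep(0, 5), rep(0.1, 5), rep(0, 5), rep(0.1, 5))
  expect_equal(res0$best, "PP0")
  ## two distinct causal variants: PP3 dominates
  b1 <- c(0.4, rep(0, 8), 0); b2 <- c(0, rep(0, 8), 0.4)
  res3 <- coloc_abf(b1, rep(0.05, 10), b2, rep(0.05, 10))
  expect_equal(res3$best, "PP3")
  expect_error(coloc_abf(1, 1, 1, 1), "at least 2")
  expect_error(coloc_abf(c(1, 1), c(1, -1), c(1, 1), c(1, 1)), "positive")
  expect_error(coloc_abf(c(1, 1), c(1, 1), c(1, 1, 1), c(1, 1, 1)), "mismatch")
  expect_error(coloc_priors(p1 = 1e-6, p12 = 1e-4), "p12")
})

test_that("classify_sex_specific applies the definitional rule symmetrically", {
  pw <- data.frame(gene_id = c("g1", "g1", "g2", "g2", "g3"),
                   stratum = c("female", "male", "female", "male", "female"),
                   z = c(4, 0.8, 4, 2.2, 4),
                   p = c(1e-4, 0.4, 1e-4, 0.03, 1e-4),
                   q = c(0.01, 0.6, 0.01, 0.2, 0.01))
  cl <- data.frame(gene_id = c("g1", "g2", "g3"), stratum = "female",
                   pp4 = c(0.9, 0.9, 0.9))
  out <- classify_sex_specific(pw, cl)
  expect_equal(out$classification[out$gene_id == "g1"], "female_only")
  ## male nominally significant blocks the female-only call
  expect_equal(out$classification[out$gene_id == "g2"], "neither")
  ## absent male record (not heritable) does not block
  expect_equal(out$classification[out$gene_id == "g3"], "female_only")
  ## label symmetry: swap strata, calls swap
  pw2 <- transform(pw, stratum = ifelse(stratum == "female", "male", "female"))
  cl2 <- transform(cl, stratum = "male")
  out2 <- classify_sex_specific(pw2, cl2)
  expect_equal(out2$classification[out2$gene_id == "g1"], "male_only")
  expect_error(classify_sex_specific(rbind(pw, pw[1, ]), cl), "duplicate")
})

test_that("intersect_causal_sets computes exact overlap percentages", {
  causal <- data.frame(gene_id = sprintf("g%02d", 1:20),
                       trait = rep(c("t1", "t2"), each = 10))
  hits <- sprintf("g%02d", c(1:6, 11, 12))  # 8 overlapping genes
  out <- intersect_causal_sets(causal, hits, character(0))
  tot <- out[out$trait == "TOTAL", ]
  expect_equal(tot$n_sexde, 8)
  expect_equal(tot$pct_sexde, 40)
  expect_equal(out$pct_sexde[out$trait == "t1"], 60)
  ## disjoint and identical sets
  expect_equal(intersect_causal_sets(causal, "zzz", "zzz")[3, "n_either"], 0)
  expect_equal(intersect_causal_sets(causal, causal$gene_id,
                                     character(0))[3, "pct_sexde"], 100)
  expect_error(intersect_causal_sets(causal[0, ], hits, hits), "empty")
})
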