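## Small deterministic fixtures shared across test files.

## tiny genotype matrix with explicit dosages
tiny_genotypes <- function(dosages, chrom = NULL, pos = NULL) {
  n <- nrow(dosages); m <- ncol(dosages)
  if (is.null(rownames(dosages))) rownames(dosages) <- sprintf("S%03d", seq_len(n))
  if (is.null(colnames(dosages))) colnames(dosages) <- sprintf("v%03d", seq_len(m))
  variants <- data.frame(id = colnames(dosages),
                         chrom = if (is.null(chrom)) rep("1", m) else chrom,
                         pos = if (is.null(pos)) seq_len(m) * 1000L else pos,
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(dosages, variants)
}

## random genotype dosages at given MAFs, Hardy-Weinberg, no LD
random_dosages <- function(n, mafs, seed = 1) {
  withr::with_seed(seed, {
    sapply(mafs, function(p) stats::rbinom(n, 2, p))
  })
}

## expression matrix wrapper for a plain numeric matrix
as_expr <- function(values, level = "protein", stage = "residualized") {
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  e <- expression_matrix(values, level, "raw")
  e$stage <- stage
  e
}

## brute-force greedy clumping oracle (independent of ld_clump's code path)
oracle_clump <- function(p, pos, r2mat, r2, window) {
  nr <- length(p)
  assigned <- rep(FALSE, nr)
  is_index <- rep(FALSE, nr)
  index_of <- rep(NA_integer_, nr)
  while (!all(assigned)) {
    un <- which(!assigned)
    o <- un[order(p[un], pos[un])]
    i <- o[1]
    is_index[i] <- TRUE
    memb <- un[abs(pos[un] - pos[i]) <= window & r2mat[un, i] >= r2]
    memb <- union(memb, i)
    index_of[memb] <- i
    assigned[memb] <- TRUE
  }
  list(is_index = is_index, index_of = index_of)
}

## exact BH step-up oracle, written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

## exact hypergeometric two-sided Fisher oracle by full enumeration
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

## exact HWE enumeration oracle
oracle_hwe_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_bb + n_ab
  rare <- min(na, 2 * n - na)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  num <- vapply(hets, function(h) {
    hr <- (rare - h) / 2; hc <- n - h - hr
    exp(lgamma(n + 1) - lgamma(hr + 1) - lgamma(h + 1) - lgamma(hc + 1) + h * log(2))
  }, numeric(1))
  probs <- num / sum(num)
  p_obs <- probs[hets == n_ab]
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}
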