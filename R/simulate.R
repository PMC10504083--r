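#' Simulation configuration
#'
#' Defines the generative model used throughout the test bench: a cohort of
#' `n_samples` donors (balanced sexes), `n_genes` genes each with
#' `snps_per_gene` cis variants in LD blocks (latent-Gaussian blocks of size
#' `ld_block_size` with correlation `ld_rho`, thresholded to Hardy-Weinberg
#' genotypes at a MAF drawn uniformly from `maf_range`), a fraction of genes
#' on the X chromosome (hemizygous males coded 0/2), and expression built
#' gene by gene as
#' cis effect x dosage + sex effect + interaction x dosage x sex +
#' hidden-factor loadings + noise. Sparsity and scale of each effect class
#' are configurable; hidden factors are drawn independent of sex so that
#' surrogate-variable protection is testable. A sparse set of genes carries
#' protein-to-trait effects (shared, female-only or male-only) used by the
#' GWAS simulator.
#'
#' @param n_samples Cohort size (default 700, balanced sexes).
#' @param n_genes Number of genes (default 100).
#' @param snps_per_gene Cis variants per gene (default 50).
#' @param maf_range Uniform MAF range (default c(0.05, 0.5)).
#' @param ld_block_size,ld_rho LD block size (default 10) and within-block
#'   latent correlation (default 0.8).
#' @param fraction_x_genes Fraction of genes placed on X (default 0.1).
#' @param sex_effect_sd,sex_effect_frac Sex main-effect scale (SD units,
#'   default 0.5) and fraction of affected genes (default 0.15).
#' @param cis_beta_sd,cis_frac Cis effect scale (default 0.5) and fraction of
#'   genes with a causal cis variant (default 0.4).
#' @param gxs_beta_sd,gxs_frac Genotype-by-sex interaction scale (default
#'   0.4) and fraction of genes with an interaction (default 0.1; these
#'   genes also carry the cis effect at the same variant).
#' @param n_hidden,hidden_loading_sd,hidden_frac Hidden confounding factors
#'   (default 3), loading scale (default 0.4) and fraction of genes loaded
#'   (default 0.3).
#' @param noise_sd Residual noise SD (default 1).
#' @param trait_frac,trait_effect_sd Fraction of genes with a
#'   protein-to-trait effect (default 0.05) and its scale (default 0.3).
#' @param gwas_n GWAS cohort size (default 20000).
#' @param n_replication Replication cohort size (default `n_samples`).
#' @param seed Mandatory integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_samples = 700, n_genes = 100, snps_per_gene = 50,
                       maf_range = c(0.05, 0.5), ld_block_size = 10, ld_rho = 0.8,
                       fraction_x_genes = 0.1,
                       sex_effect_sd = 0.5, sex_effect_frac = 0.15,
                       cis_beta_sd = 0.5, cis_frac = 0.4,
                       gxs_beta_sd = 0.4, gxs_frac = 0.1,
                       n_hidden = 3, hidden_loading_sd = 0.4, hidden_frac = 0.3,
                       noise_sd = 1, trait_frac = 0.05, trait_effect_sd = 0.3,
                       gwas_n = 20000, n_replication = n_samples, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("invalid MAF range")
  fr <- c(fraction_x_genes, sex_effect_frac, cis_frac, gxs_frac, hidden_frac, trait_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  structure(as.list(environment()), class = "sim_config")
}

## deterministic sub-seed derivation, kept below 2^31
sub_seed <- function(seed, tag) {
  (as.numeric(seed) * 1009 + tag * 7919) %% 2147483647
}

## latent-Gaussian haplotype block: n x m alleles with block correlation rho
sim_haplotypes <- function(n, mafs, block_size, rho) {
  m <- length(mafs)
  nb <- ceiling(m / block_size)
  lat <- matrix(stats::rnorm(n * m), n, m)
  shared <- matrix(stats::rnorm(n * nb), n, nb)
  bidx <- rep(seq_len(nb), each = block_size)[seq_len(m)]
  lat <- sqrt(rho) * shared[, bidx, drop = FALSE] + sqrt(1 - rho) * lat
  thr <- stats::qnorm(mafs)
  alle <- sweep(lat, 2, thr, `<`)
  storage.mode(alle) <- "integer"
  alle
}

#' Simulate an LD-structured genotype cohort
#'
#' Lays genes on chromosomes 1-22 plus X (gene bodies 10 kb, spaced 2 Mb),
#' places `snps_per_gene` variants across each gene's cis window, and draws
#' genotypes from thresholded latent Gaussians with block LD at
#' Hardy-Weinberg frequencies. Females receive two independent haplotypes
#' everywhere; on the X chromosome males are hemizygous and their single
#' allele is counted twice (dosage 0/2). The variant layout (positions,
#' MAFs, block structure) is a function of the seed's layout stream, so
#' repeated cohorts drawn with `cohort` tags share variants.
#'
#' @param cfg A [sim_config()].
#' @param n Cohort size override (default `cfg$n_samples`).
#' @param cohort Integer tag separating sample draws that share a layout.
#' @param id_prefix Sample-id prefix.
#' @return A [genotype_matrix()] with a `genes` element (data.frame
#'   `gene_id`, `chrom`, `start`, `end`) and per-sample `sex` in `samples`.
#' @export
simulate_genotypes <- function(cfg, n = cfg$n_samples, cohort = 0L,
                               id_prefix = "S") {
  old <- get_seed_state(); on.exit(restore_seed_state(old))
  ## layout stream: identical across cohorts with the same cfg seed
  set.seed(sub_seed(cfg$seed, 1))
  ng <- cfg$n_genes; mpg <- cfg$snps_per_gene
  n_x <- round(cfg$fraction_x_genes * ng)
  chroms <- c(rep(as.character(rep_len(1:22, max(ng - n_x, 1))[seq_len(ng - n_x)]), 1),
              rep("X", n_x))
  starts <- integer(ng)
  for (ch in unique(chroms)) {
    i <- which(chroms == ch)
    starts[i] <- 1000000 + (seq_along(i) - 1) * 2000000
  }
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(ng)), chrom = chroms,
                      start = starts, end = starts + 10000,
                      stringsAsFactors = FALSE)
  mafs <- stats::runif(ng * mpg, cfg$maf_range[1], cfg$maf_range[2])
  offsets <- sort(sample(seq(-450000, 460000, by = 200), mpg))
  vpos <- as.vector(vapply(seq_len(ng), function(i) genes$start[i] + offsets,
                           numeric(mpg)))
  variants <- data.frame(id = sprintf("rs%05d", seq_len(ng * mpg)),
                         chrom = rep(genes$chrom, each = mpg),
                         pos = as.integer(vpos),
                         ref = "A", alt = "G",
                         gene_id = rep(genes$gene_id, each = mpg),
                         stringsAsFactors = FALSE)
  site_types <- c("intergenic", "intronic", "exonic", "UTR", "ncRNA")
  variants$annotation_class <- sample(site_types, ng * mpg, replace = TRUE,
                                      prob = c(0.4, 0.35, 0.1, 0.1, 0.05))
  ## cohort stream: sample-level randomness
  set.seed(sub_seed(cfg$seed, 100 + cohort))
  sex <- sample(rep(c(0L, 1L), length.out = n))
  dos <- matrix(0L, n, ng * mpg)
  for (i in seq_len(ng)) {
    cols <- ((i - 1) * mpg + 1):(i * mpg)
    h1 <- sim_haplotypes(n, mafs[cols], cfg$ld_block_size, cfg$ld_rho)
    h2 <- sim_haplotypes(n, mafs[cols], cfg$ld_block_size, cfg$ld_rho)
    d <- h1 + h2
    if (genes$chrom[i] == "X") d[sex == 0, ] <- 2L * h1[sex == 0, , drop = FALSE]
    dos[, cols] <- d
  }
  rownames(dos) <- sprintf("%s%05d", id_prefix, seq_len(n) + cohort * 100000)
  colnames(dos) <- variants$id
  samples <- data.frame(sample_id = rownames(dos), sex = sex,
                        stringsAsFactors = FALSE)
  g <- genotype_matrix(dos, variants, samples)
  g$genes <- genes
  g
}

#' Simulate expression with known truth
#'
#' Builds each gene's expression as beta_cis x dosage + beta_sex x sex +
#' beta_gxs x dosage x sex + hidden-factor loadings + Gaussian noise, with
#' sparsity per [sim_config()]. All drawn effects, loadings, factors and the
#' causal variant per gene are recorded in the returned truth table.
#'
#' @param g A cohort from [simulate_genotypes()].
#' @param cfg The [sim_config()] used to draw `g`.
#' @param cohort Integer tag (use the one passed to [simulate_genotypes()]).
#' @param truth Optional pre-drawn truth (to share effects across cohorts,
#'   as in discovery/replication pairs).
#' @return List with `expression` (a residualized-stage
#'   [expression_matrix()]) and `truth` (class `sim_truth`): per-gene
#'   `sex_effect`, `causal_variant`, `beta_male`, `beta_female`, `beta_gxs`,
#'   `trait_effect_male`, `trait_effect_female`; plus `loadings`, `factors`
#'   and `sex`.
#' @export
simulate_expression <- function(g, cfg, cohort = 0L, truth = NULL) {
  n <- nrow(g$dosages)
  sex <- g$samples$sex
  ng <- cfg$n_genes; mpg <- cfg$snps_per_gene
  if (ncol(g$dosages) != ng * mpg) stop("genotype matrix does not match config dimensions")
  old <- get_seed_state(); on.exit(restore_seed_state(old))
  if (is.null(truth)) {
    set.seed(sub_seed(cfg$seed, 2))  # effect stream: shared across cohorts
    causal_idx <- sample.int(mpg, ng, replace = TRUE)
    has_cis <- stats::runif(ng) < cfg$cis_frac
    has_gxs <- stats::runif(ng) < cfg$gxs_frac
    has_cis <- has_cis | has_gxs
    base <- stats::rnorm(ng, 0, cfg$cis_beta_sd) * has_cis
    bgxs <- stats::rnorm(ng, 0, cfg$gxs_beta_sd) * has_gxs
    sexb <- stats::rnorm(ng, 0, cfg$sex_effect_sd) *
      (stats::runif(ng) < cfg$sex_effect_frac)
    loadings <- matrix(stats::rnorm(ng * cfg$n_hidden, 0, cfg$hidden_loading_sd) *
                         (stats::runif(ng * cfg$n_hidden) < cfg$hidden_frac),
                       ng, cfg$n_hidden)
    has_trait <- stats::runif(ng) < cfg$trait_frac
    ttype <- sample(c("shared", "female_only", "male_only"), ng, replace = TRUE)
    teff <- stats::rnorm(ng, 0, cfg$trait_effect_sd) +
      sign(stats::rnorm(ng)) * cfg$trait_effect_sd  # keep away from zero
    tf <- ifelse(has_trait & ttype != "male_only", teff, 0)
    tm <- ifelse(has_trait & ttype != "female_only", teff, 0)
    truth <- structure(list(
      gene_id = g$genes$gene_id,
      causal_variant = g$variants$id[(seq_len(ng) - 1) * mpg + causal_idx],
      sex_effect = sexb, beta_male = base, beta_female = base + bgxs,
      beta_gxs = bgxs, loadings = loadings,
      trait_effect_male = tm, trait_effect_female = tf),
      class = "sim_truth")
  }
  set.seed(sub_seed(cfg$seed, 200 + cohort))  # noise stream: per cohort
  factors <- matrix(stats::rnorm(n * cfg$n_hidden), n, cfg$n_hidden)
  Y <- matrix(0, ng, n)
  ci <- match(truth$causal_variant, g$variants$id)
  for (i in seq_len(ng)) {
    d <- g$dosages[, ci[i]]
    betas <- truth$beta_male[i] * (sex == 0) + truth$beta_female[i] * (sex == 1)
    Y[i, ] <- betas * d + truth$sex_effect[i] * sex +
      as.numeric(factors %*% truth$loadings[i, ]) +
      stats::rnorm(n, 0, cfg$noise_sd)
  }
  rownames(Y) <- truth$gene_id
  colnames(Y) <- g$sample_ids
  truth$factors <- factors
  truth$sex <- stats::setNames(sex, g$sample_ids)
  e <- expression_matrix(Y, "protein", "raw")
  e$stage <- "residualized"  # simulated on the clean scale, covariates already absent
  list(expression = e, truth = truth)
}

#' Simulate a discovery/replication cohort pair
#'
#' Draws two independent cohorts sharing the variant layout and the
#' discovery truth; a fraction `rho_rep` of the discovery's nonzero
#' interaction effects is retained in the replication truth, the rest are
#' zeroed. Sample ids are disjoint.
#'
#' @param cfg A [sim_config()].
#' @param rho_rep Replication fraction in \[0, 1\].
#' @return List with `discovery` and `replication` (each a list with
#'   `genotypes`, `expression`, `truth`) and `rho_rep`.
#' @export
simulate_replication_pair <- function(cfg, rho_rep) {
  if (rho_rep < 0 || rho_rep > 1) stop("rho_rep must lie in [0, 1]")
  g1 <- simulate_genotypes(cfg, n = cfg$n_samples, cohort = 0L, id_prefix = "D")
  d1 <- simulate_expression(g1, cfg, cohort = 0L)
  truth_rep <- d1$truth
  nz <- which(truth_rep$beta_gxs != 0)
  old <- get_seed_state(); on.exit(restore_seed_state(old))
  set.seed(sub_seed(cfg$seed, 3))
  keep <- nz[stats::runif(length(nz)) < rho_rep]
  zero <- setdiff(nz, keep)
  truth_rep$beta_gxs[zero] <- 0
  truth_rep$beta_female[zero] <- truth_rep$beta_male[zero]
  g2 <- simulate_genotypes(cfg, n = cfg$n_replication, cohort = 1L, id_prefix = "R")
  d2 <- simulate_expression(g2, cfg, cohort = 1L, truth = truth_rep)
  list(discovery = list(genotypes = g1, expression = d1$expression, truth = d1$truth),
       replication = list(genotypes = g2, expression = d2$expression, truth = d2$truth),
       rho_rep = rho_rep)
}

#' Simulate sex-stratified GWAS summary statistics
#'
#' Draws an independent GWAS cohort with the same variant layout, builds
#' each gene's protein from the truth's cis and interaction effects, forms
#' the phenotype as the sum of sex-specific protein-to-trait effects plus
#' noise, and computes per-variant marginal beta/se/z within each sex and
#' jointly. The LD matrix per gene is estimated from the GWAS cohort. The
#' cohort is regenerated gene by gene from per-gene seeds, so memory stays
#' flat in the number of genes.
#'
#' @param g The analysis cohort from [simulate_genotypes()] (provides the
#'   variant layout).
#' @param truth A `sim_truth` from [simulate_expression()].
#' @param cfg The [sim_config()].
#' @param genes Optional subset of gene ids to emit (default: all genes with
#'   a nonzero protein-to-trait effect in either sex, plus any gene listed
#'   in `genes`).
#' @return List with `sumstats` (list `male`/`female`/`joint` of data.frames
#'   `SNP`, `A1`, `A2`, `BETA`, `SE`, `Z`, `N`, `gene_id`), `ld` (list of
#'   per-gene correlation matrices) and `n` per stratum.
#' @export
simulate_gwas <- function(g, truth, cfg, genes = NULL) {
  ng <- cfg$n_genes; mpg <- cfg$snps_per_gene
  if (is.null(genes))
    genes <- truth$gene_id[truth$trait_effect_male != 0 | truth$trait_effect_female != 0]
  gidx <- match(genes, g$genes$gene_id)
  if (anyNA(gidx)) stop("unknown gene id(s)")
  n <- cfg$gwas_n
  old <- get_seed_state(); on.exit(restore_seed_state(old))
  set.seed(sub_seed(cfg$seed, 4))
  sex <- sample(rep(c(0L, 1L), length.out = n))
  ## replay the layout stream to recover per-variant MAFs deterministically
  layout_mafs <- {
    set.seed(sub_seed(cfg$seed, 1))
    stats::runif(cfg$n_genes * mpg, cfg$maf_range[1], cfg$maf_range[2])
  }
  gen_block <- function(i) {
    set.seed(sub_seed(cfg$seed, 5000 + i))
    cols <- ((i - 1) * mpg + 1):(i * mpg)
    h1 <- sim_haplotypes(n, layout_mafs[cols], cfg$ld_block_size, cfg$ld_rho)
    h2 <- sim_haplotypes(n, layout_mafs[cols], cfg$ld_block_size, cfg$ld_rho)
    d <- h1 + h2
    if (g$genes$chrom[i] == "X") d[sex == 0, ] <- 2L * h1[sex == 0, , drop = FALSE]
    d
  }
  ## pass 1: accumulate the phenotype over trait genes
  trait_genes <- which(truth$trait_effect_male != 0 | truth$trait_effect_female != 0)
  pheno <- stats::rnorm(n)  # unit residual noise
  for (i in trait_genes) {
    d <- gen_block(i)
    ci <- match(truth$causal_variant[i], g$variants$id) - (i - 1) * mpg
    betas <- truth$beta_male[i] * (sex == 0) + truth$beta_female[i] * (sex == 1)
    prot <- betas * d[, ci] + stats::rnorm(n, 0, cfg$noise_sd)
    te <- truth$trait_effect_male[i] * (sex == 0) +
      truth$trait_effect_female[i] * (sex == 1)
    pheno <- pheno + te * prot
  }
  ## pass 2: marginal summary statistics per emitted gene
  marg <- function(d, y) {
    x <- scale(d, scale = FALSE)
    yc <- y - mean(y)
    xx <- colSums(x^2)
    beta <- as.numeric(crossprod(x, yc)) / xx
    dofn <- length(y) - 2
    rss <- sum(yc^2) - beta^2 * xx
    se <- sqrt(pmax(rss, 0) / dofn / xx)
    z <- beta / se
    list(beta = beta, se = se, z = z)
  }
  res <- list(male = NULL, female = NULL, joint = NULL)
  ld <- list()
  for (i in gidx) {
    d <- gen_block(i)
    cols <- ((i - 1) * mpg + 1):(i * mpg)
    vinfo <- g$variants[cols, ]
    ld[[g$genes$gene_id[i]]] <- stats::cor(d)
    for (st in names(res)) {
      keep <- switch(st, male = sex == 0, female = sex == 1,
                     joint = rep(TRUE, n))
      mm <- marg(d[keep, , drop = FALSE], pheno[keep])
      df <- data.frame(SNP = vinfo$id, A1 = vinfo$alt, A2 = vinfo$ref,
                       BETA = mm$beta, SE = mm$se, Z = mm$z,
                       N = sum(keep), gene_id = g$genes$gene_id[i],
                       stringsAsFactors = FALSE)
      res[[st]] <- rbind(res[[st]], df)
    }
  }
  for (gid in names(ld)) {
    cols <- g$variants$id[g$variants$gene_id == gid]
    dimnames(ld[[gid]]) <- list(cols, cols)
  }
  list(sumstats = res, ld = ld,
       n = c(male = sum(sex == 0), female = sum(sex == 1), joint = n))
}

#' Write a simulated cohort to disk
#'
#' Emits the standard plain-text artifact set: PLINK bed/bim/fam, expression
#' TSV, sample TSV, gene BED (0-based half-open) and a truth JSON.
#'
#' @param g,expression,truth Simulated cohort pieces.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_cohort <- function(g, expression, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_plink(g, file.path(dir, "genotypes"))
  write_expression_tsv(expression, file.path(dir, "expression.tsv"))
  utils::write.table(g$samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bed <- data.frame(chrom = g$genes$chrom, start = g$genes$start - 1L,
                    end = g$genes$end, name = g$genes$gene_id)
  utils::write.table(bed, file.path(dir, "genes.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  tr <- truth
  tr$loadings <- NULL; tr$factors <- NULL
  tr$sex <- as.list(tr$sex)
  jsonlite::write_json(unclass(tr), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a gene BED file (0-based half-open) into 1-based coordinates
#' @param path BED path (4 columns: chrom, start, end, name).
#' @return data.frame with `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_gene_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  data.frame(gene_id = df$V4, chrom = norm_chrom(df$V1),
             start = df$V2 + 1L, end = df$V3, stringsAsFactors = FALSE)
}
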