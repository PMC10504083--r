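#' Default pipeline configuration
#'
#' Flat key-value configuration for [run_pipeline()]. Keys cover the
#' synthetic-cohort generator (see [sim_config()]) and the analysis
#' thresholds (see [analysis_config()]); unknown keys are rejected with the
#' list of valid keys.
#'
#' @param path Optional YAML file of overrides.
#' @param ... Named overrides applied after the file.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    ## simulation
    n_samples = 700, n_genes = 100, snps_per_gene = 50,
    maf_min = 0.05, maf_max = 0.5, ld_block_size = 10, ld_rho = 0.8,
    fraction_x_genes = 0.1, sex_effect_sd = 0.5, sex_effect_frac = 0.15,
    cis_beta_sd = 0.5, cis_frac = 0.4, gxs_beta_sd = 0.4, gxs_frac = 0.1,
    n_hidden = 3, hidden_loading_sd = 0.4, hidden_frac = 0.3, noise_sd = 1,
    trait_frac = 0.05, trait_effect_sd = 0.3, gwas_n = 20000,
    n_replication = 700, replication_rho = 1.0,
    ## analysis
    cis_window = 500000, fdr = 0.05, interaction_fdr = 0.05,
    clump_r2_index = 0.50, clump_r2_independent = 0.10, clump_window = 250000,
    n_pcs = 10, n_svs = NA,
    coloc_p1 = 1e-4, coloc_p2 = 1e-4, coloc_p12 = 1e-5,
    pp4_min = 0.75, heritability_p = 0.01)
  over <- list(...)
  if (!is.null(path)) over <- c(yaml::read_yaml(path), over)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("invalid config key(s): ", paste(bad, collapse = ", "),
                        "; valid keys: ", paste(names(cfg), collapse = ", "))
  cfg[names(over)] <- over
  for (k in c("fdr", "interaction_fdr")) if (cfg[[k]] <= 0 || cfg[[k]] > 1)
    stop(k, " must lie in (0, 1]")
  if (cfg$pp4_min < 0 || cfg$pp4_min > 1) stop("pp4_min must lie in [0, 1]")
  structure(cfg, class = "pipeline_config")
}

sim_cfg_from <- function(cfg, seed) {
  sim_config(n_samples = cfg$n_samples, n_genes = cfg$n_genes,
             snps_per_gene = cfg$snps_per_gene,
             maf_range = c(cfg$maf_min, cfg$maf_max),
             ld_block_size = cfg$ld_block_size, ld_rho = cfg$ld_rho,
             fraction_x_genes = cfg$fraction_x_genes,
             sex_effect_sd = cfg$sex_effect_sd, sex_effect_frac = cfg$sex_effect_frac,
             cis_beta_sd = cfg$cis_beta_sd, cis_frac = cfg$cis_frac,
             gxs_beta_sd = cfg$gxs_beta_sd, gxs_frac = cfg$gxs_frac,
             n_hidden = cfg$n_hidden, hidden_loading_sd = cfg$hidden_loading_sd,
             hidden_frac = cfg$hidden_frac, noise_sd = cfg$noise_sd,
             trait_frac = cfg$trait_frac, trait_effect_sd = cfg$trait_effect_sd,
             gwas_n = cfg$gwas_n, n_replication = cfg$n_replication, seed = seed)
}

write_tsv_sorted <- function(df, path, by = intersect(c("chrom", "pos", "gene_id", "variant_id"),
                                                      names(df))) {
  if (length(by) && nrow(df))
    df <- df[do.call(order, df[by]), , drop = FALSE]
  for (cl in names(df)) if (is.numeric(df[[cl]])) df[[cl]] <- signif(df[[cl]], 10)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the sb-QTL pipeline end to end on a synthetic cohort
#'
#' Stages, in dependency order: `simulate` (cohort + truth), `qc` (genotype
#' filters + report), `prep` (surrogate variables protecting sex), `sexde`
#' (sex-differential expression), `sbqtl` (joint/male/female cis scans,
#' stage-1 union, interaction scan, LD clumping, category classification),
#' `replicate` (discovery/replication pair + pi1), `causal` (GWAS
#' simulation, per-sex heritability, weights, PWAS, colocalization,
#' sex-specific calls). Every output TSV has a header and a deterministic
#' row order; a JSON run manifest is written last.
#'
#' @param config A [pipeline_config()], or a YAML path.
#' @param outdir Output directory (created; stages never mutate inputs).
#' @param stages Character vector of stage names or `"all"`.
#' @param seed Integer seed driving every source of randomness.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir, stages = "all",
                         seed = 1) {
  if (is.character(config)) config <- pipeline_config(path = config)
  all_stages <- c("simulate", "qc", "prep", "sexde", "sbqtl", "replicate", "causal")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  scfg <- sim_cfg_from(config, seed)
  state <- list(config = config, seed = seed)
  counts <- list()
  log_lines <- c(sprintf("seed=%d", seed),
                 sprintf("thresholds: fdr=%g interaction_fdr=%g cis_window=%d clump_r2=%g/%g clump_window=%d pp4=%g herit_p=%g",
                         config$fdr, config$interaction_fdr, config$cis_window,
                         config$clump_r2_index, config$clump_r2_independent,
                         config$clump_window, config$pp4_min, config$heritability_p))

  need <- function(what) if (is.null(state[[what]]))
    stop("stage requires prior output '", what, "'; run the earlier stages first")

  if ("simulate" %in% stages) {
    g <- simulate_genotypes(scfg)
    sim <- simulate_expression(g, scfg)
    state$genotypes <- g; state$expression <- sim$expression; state$truth <- sim$truth
    write_sim_cohort(g, sim$expression, sim$truth, file.path(outdir, "simulate"))
    counts$simulate <- c(samples = nrow(g$dosages), variants = ncol(g$dosages),
                         genes = nrow(g$genes))
  }
  if ("qc" %in% stages) {
    need("genotypes")
    qcres <- qc_filter(state$genotypes)
    state$genotypes_qc <- qcres$genotypes
    state$genotypes_qc$genes <- state$genotypes$genes
    sexcall <- infer_sex(qcres$genotypes)
    write_qc_report(qcres$report, file.path(outdir, "qc_report.json"))
    write_tsv_sorted(sexcall, file.path(outdir, "sex_calls.tsv"), by = "sample_id")
    counts$qc <- c(variants_retained = qcres$report$n_variants_retained)
  }
  if ("prep" %in% stages) {
    need("genotypes_qc"); need("expression")
    s <- state$genotypes_qc$samples
    nsv <- if (is.na(config$n_svs)) NULL else config$n_svs
    svs <- estimate_svs(state$expression, s, n_sv = nsv, seed = seed)
    pcs <- genetic_pcs(state$genotypes_qc, k = min(config$n_pcs,
                                                   nrow(state$genotypes_qc$dosages) - 1))
    state$svs <- svs
    state$covariates <- cbind(svs, pcs)
    state$zexpr <- zscore_expression(state$expression)
    counts$prep <- c(n_svs = ncol(svs), n_pcs = ncol(pcs))
  }
  if ("sexde" %in% stages) {
    need("zexpr")
    s <- state$genotypes_qc$samples
    de <- sexdiff_scan(state$zexpr, s, svs = state$svs, fdr = config$fdr,
                       gene_coords = state$genotypes_qc$genes)
    state$sexde <- de
    write_tsv_sorted(de, file.path(outdir, "sexde.tsv"), by = "gene_id")
    counts$sexde <- c(tested = nrow(de), significant = sum(de$significant))
  }
  if ("sbqtl" %in% stages) {
    need("zexpr"); need("covariates")
    g <- state$genotypes_qc
    sex <- stats::setNames(g$samples$sex, g$samples$sample_id)
    pairs <- map_cis_pairs(g$genes, g$variants, window = config$cis_window)
    scans <- lapply(c("joint", "male", "female"), function(md)
      cis_scan(pairs, g, state$zexpr, covariates = state$covariates,
               sex = sex, mode = md))
    names(scans) <- c("joint", "male", "female")
    s1 <- stage1_union(scans$joint, scans$male, scans$female, fdr = config$fdr)
    state$scans <- scans; state$stage1 <- s1
    counts$sbqtl <- c(pairs = nrow(pairs), stage1 = nrow(s1))
    for (md in names(scans))
      write_tsv_sorted(scans[[md]], file.path(outdir, paste0("assoc_", md, ".tsv")))
    if (nrow(s1) > 0) {
      inter <- interaction_scan(s1, g, state$zexpr, covariates = state$covariates,
                                sex = sex, fdr = config$interaction_fdr,
                                all_pairs = pairs)
      sb <- inter[inter$significant, , drop = FALSE]
      if (nrow(sb) > 0) {
        sb <- ld_clump(sb, g, r2 = config$clump_r2_index,
                       window = config$clump_window,
                       alt_r2 = config$clump_r2_independent)
        sb <- classify_sbqtl(sb, scans$male, scans$female, fdr = config$fdr)
      }
      state$interaction <- inter; state$sbqtl <- sb
      state$stage_p <- attr(inter, "stage_p")
      write_tsv_sorted(inter, file.path(outdir, "interaction.tsv"))
      write_tsv_sorted(sb, file.path(outdir, "sbqtl.tsv"))
      lam <- tryCatch(qq_lambda(inter$p[!is.na(inter$p)]), error = function(e) NULL)
      if (!is.null(lam)) {
        write_tsv_sorted(lam$qq, file.path(outdir, "interaction_qq.tsv"), by = NULL)
        counts$sbqtl <- c(counts$sbqtl, lambda = round(lam$lambda, 4))
      }
      counts$sbqtl <- c(counts$sbqtl, sbqtl = nrow(sb),
                        index = if (nrow(sb)) sum(sb$is_index) else 0L)
    }
  }
  if ("replicate" %in% stages) {
    pair <- simulate_replication_pair(scfg, rho_rep = config$replication_rho)
    rep_out <- tryCatch(replicate_pi1(pair, config), error = function(e)
      list(n_discovery_hits = 0L, n_matched = 0L, pi1 = NA_real_,
           note = conditionMessage(e)))
    if (!is.null(rep_out$note))
      warning("replication stage: ", rep_out$note)
    state$replication <- rep_out
    jsonlite::write_json(rep_out[intersect(c("n_discovery_hits", "n_matched",
                                             "pi1", "note"), names(rep_out))],
                         file.path(outdir, "replication.json"), auto_unbox = TRUE,
                         digits = NA)
    counts$replicate <- c(pi1 = rep_out$pi1)
  }
  if ("causal" %in% stages) {
    need("truth")
    ca <- causal_stage(state$genotypes, state$expression, state$truth, scfg, config)
    state$causal <- ca
    write_tsv_sorted(ca$calls, file.path(outdir, "causal_calls.tsv"), by = "gene_id")
    counts$causal <- c(genes_tested = nrow(ca$calls),
                       female_only = sum(ca$calls$classification == "female_only"),
                       male_only = sum(ca$calls$classification == "male_only"))
  }
  manifest <- list(config = unclass(config), seed = seed,
                   stages = stages, counts = counts,
                   package_version = as.character(utils::packageVersion("sbqtl")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   log = log_lines)
  out_files <- setdiff(list.files(outdir, recursive = TRUE), "manifest.json")
  manifest$checksums <- as.list(tools::md5sum(file.path(outdir, out_files)))
  names(manifest$checksums) <- out_files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(state, list(manifest = manifest)))
}

## run the two-stage procedure on a discovery/replication pair and return pi1
replicate_pi1 <- function(pair, config = pipeline_config()) {
  run_two_stage <- function(cohort) {
    g <- cohort$genotypes
    sex <- stats::setNames(g$samples$sex, g$samples$sample_id)
    e <- zscore_expression(cohort$expression)
    pairs <- map_cis_pairs(g$genes, g$variants, window = config$cis_window)
    scans <- lapply(c("joint", "male", "female"), function(md)
      cis_scan(pairs, g, e, covariates = NULL, sex = sex, mode = md))
    names(scans) <- c("joint", "male", "female")
    s1 <- stage1_union(scans$joint, scans$male, scans$female, fdr = config$fdr)
    if (nrow(s1) == 0) return(list(inter = NULL, scans = scans, pairs = pairs))
    inter <- interaction_scan(s1, g, e, covariates = NULL, sex = sex,
                              fdr = config$interaction_fdr, all_pairs = pairs)
    list(inter = inter, scans = scans, pairs = pairs)
  }
  disc <- run_two_stage(pair$discovery)
  if (is.null(disc$inter) || !any(disc$inter$significant))
    stop("no significant discovery sb-QTLs; cannot estimate pi1")
  sig <- disc$inter[disc$inter$significant, , drop = FALSE]
  sig <- ld_clump(sig, pair$discovery$genotypes, r2 = config$clump_r2_index,
                  window = config$clump_window,
                  alt_r2 = config$clump_r2_independent)
  idx <- sig[sig$is_index, , drop = FALSE]
  ## replication interaction statistics for the discovery index pairs
  g2 <- pair$replication$genotypes
  sex2 <- stats::setNames(g2$samples$sex, g2$samples$sample_id)
  e2 <- zscore_expression(pair$replication$expression)
  s1rep <- idx[, c("gene_id", "variant_id")]
  s1rep$source_modes <- "joint"
  rep_inter <- interaction_scan(s1rep, g2, e2, covariates = NULL, sex = sex2,
                                fdr = config$interaction_fdr, universe = "stage1")
  res <- pi1_replication(idx, rep_inter)
  c(res, list(discovery_inter = disc$inter, replication_inter = rep_inter,
              index = idx))
}

## sex-stratified causal integration on the trait genes of a simulated cohort
causal_stage <- function(g, expression, truth, scfg, config = pipeline_config(),
                         genes = NULL) {
  gw <- simulate_gwas(g, truth, scfg, genes = genes)
  genes <- names(gw$ld)
  e <- zscore_expression(expression)
  sex <- stats::setNames(g$samples$sex, g$samples$sample_id)
  pwas <- list(); coloc <- list(); herit <- list()
  for (gid in genes) {
    cols <- g$variants$id[g$variants$gene_id == gid]
    for (st in c("male", "female")) {
      keep <- if (st == "male") sex == 0 else sex == 1
      Gw <- g$dosages[keep, cols, drop = FALSE]
      y <- e$values[gid, names(sex)[keep]]
      h <- tryCatch(cis_heritability(Gw, y, stratum = st,
                                     p_min = config$heritability_p),
                    error = function(err) NULL)
      herit[[paste(gid, st)]] <- data.frame(
        gene_id = gid, stratum = st,
        h2 = if (is.null(h)) NA_real_ else h$h2,
        p = if (is.null(h)) NA_real_ else h$p,
        heritable = !is.null(h) && h$heritable)
      if (is.null(h) || !h$heritable) next
      w <- train_weights(Gw, y, seed = sub_seed(scfg$seed, 9) %% 100000 + 1,
                         stratum = st)
      attr(w, "alleles") <- data.frame(id = cols,
                                       a1 = g$variants$alt[match(cols, g$variants$id)],
                                       a2 = g$variants$ref[match(cols, g$variants$id)])
      ss <- gw$sumstats[[st]]
      ss <- ss[ss$gene_id == gid, ]
      pa <- tryCatch(pwas_assoc(w, ss, gw$ld[[gid]]), error = function(err) NULL)
      if (is.null(pa)) next
      pwas[[paste(gid, st)]] <- data.frame(gene_id = gid, stratum = st,
                                           z = pa$z, p = pa$p)
      ## colocalization of protein-association and trait-association signals
      xr <- cis_scan(data.frame(gene_id = gid, variant_id = cols),
                     g, e, covariates = NULL,
                     sex = sex[keep], mode = st)
      ok <- !is.na(xr$beta) & xr$variant_id %in% ss$SNP
      ssm <- ss[match(xr$variant_id[ok], ss$SNP), ]
      cl <- tryCatch(coloc_abf(xr$beta[ok], xr$se[ok], ssm$BETA, ssm$SE,
                               priors = coloc_priors(config$coloc_p1,
                                                     config$coloc_p2,
                                                     config$coloc_p12)),
                     error = function(err) NULL)
      if (!is.null(cl))
        coloc[[paste(gid, st)]] <- data.frame(gene_id = gid, stratum = st,
                                              pp4 = unname(cl$pp["PP4"]))
    }
  }
  herit <- do.call(rbind, herit)
  pwas <- if (length(pwas)) do.call(rbind, pwas) else
    data.frame(gene_id = character(), stratum = character(), z = numeric(), p = numeric())
  coloc <- if (length(coloc)) do.call(rbind, coloc) else
    data.frame(gene_id = character(), stratum = character(), pp4 = numeric())
  if (nrow(pwas)) {
    pwas$q <- NA_real_
    for (st in unique(pwas$stratum))
      pwas$q[pwas$stratum == st] <- bh_fdr(pwas$p[pwas$stratum == st])
  } else pwas$q <- numeric()
  calls <- if (nrow(pwas)) classify_sex_specific(pwas, coloc, fdr = config$fdr,
                                                 pp4_min = config$pp4_min)
  else data.frame(gene_id = character(), classification = character())
  rownames(herit) <- NULL
  list(heritability = herit, pwas = pwas, coloc = coloc, calls = calls,
       gwas = gw)
}
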