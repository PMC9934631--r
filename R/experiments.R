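#' Reproducible validation experiments
#'
#' Each `experiment_*` function runs one self-contained simulation study
#' against planted ground truth and returns the operating characteristics it
#' measures (calibration, FDR control, sensitivity, effect recovery,
#' classifier recall, colocalization discrimination). They are the package's
#' own evidence that the pipeline behaves as designed, and are exercised by
#' the test suite and the acceptance script.
#'
#' @name experiments
NULL

#' @describeIn experiments Null calibration of the genotype-by-condition
#'   interaction test: QTLs with equal effects in both conditions are
#'   simulated and the LRT rejection rate at p < 0.05 and KS uniformity
#'   p-value are reported.
#' @param n_donors donors in the simulated study.
#' @param n_qtl number of QTLs tested.
#' @param seed master seed.
#' @export
experiment_interaction_null <- function(n_donors = 70, n_qtl = 1000, seed = 1) {
  cfg <- sim_config(n_donors = n_donors, conditions = c("vehicle", "stim"),
                    n_variants = 6000, n_chrom = 4,
                    n_peaks = ceiling(n_qtl * 1.1),
                    n_genes = ceiling(n_qtl * 1.7),
                    missing_rate = 0, frac_caqtl = 1,
                    scenario_mix = c(shared = 1), target_r2 = 0.1,
                    frac_wre = 0, frac_deg = 0, frac_eqtl = 0,
                    n_gwas_loci = 0, seed = seed)
  sim <- suppressWarnings(simulate_dataset(cfg))
  norm <- normalize_counts(sim$atac, gc = sim$peaks$gc, n_pcs = 10)
  tf <- sim$truth$features
  tf <- tf[tf$assay == "atac" & !is.na(tf$causal_variant), ]
  pairs <- head(tibble(feature = tf$feature_id, variant = tf$causal_variant),
                n_qtl)
  ia <- fit_interaction_lmm(norm$residuals, sim$genotypes, sim$sheet, pairs,
                            condition_pair = c("vehicle", "stim"))
  p <- ia$p_interaction[!is.na(ia$p_interaction)]
  list(n = length(p), rejection_rate = mean(p < 0.05),
       ks_p = suppressWarnings(ks.test(p, "punif"))$p.value, p = p)
}

#' @describeIn experiments Hierarchical FDR control and sensitivity of the
#'   caQTL pipeline (eigenMT local + BH global) over replicate datasets with
#'   a planted fraction of true caQTLs.
#' @param n_reps replicate datasets.
#' @param n_peaks peaks per dataset.
#' @param frac_causal fraction of peaks with a true caQTL.
#' @param r2 variance fraction explained by each planted QTL.
#' @export
experiment_hierarchical_fdr <- function(n_reps = 20, n_peaks = 400,
                                        frac_causal = 0.1, r2 = 0.08,
                                        n_donors = 76, seed = 1) {
  tp <- fp <- fn <- 0
  sens <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(n_donors = n_donors, conditions = "vehicle",
                      n_variants = 3000, n_chrom = 3, n_peaks = n_peaks,
                      n_genes = ceiling(frac_causal * n_peaks * 2),
                      missing_rate = 0, frac_caqtl = frac_causal,
                      scenario_mix = c(shared = 1), target_r2 = r2,
                      frac_wre = 0, frac_deg = 0, frac_eqtl = 0,
                      n_gwas_loci = 0, seed = child_seed(seed, paste0("rep", r)))
    sim <- suppressWarnings(simulate_dataset(cfg))
    norm <- normalize_counts(sim$atac, gc = sim$peaks$gc, n_pcs = 10)
    q <- map_qtl(norm$residuals, sim$genotypes, sim$peaks, sim$sheet,
                 assay = "atac", seed = cfg$seed)
    truth <- sim$truth$pairs$peak_id
    called <- q$corrections$feature[q$corrections$significant]
    tp <- tp + sum(called %in% truth)
    fp <- fp + sum(!called %in% truth)
    fn <- fn + sum(!truth %in% called)
    sens[r] <- mean(truth %in% called)
  }
  list(fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
       sensitivity = mean(sens), n_reps = n_reps)
}

#' @describeIn experiments Concordance between the eigenMT local adjustment
#'   and a deep permutation-based adjustment on the same features.
#' @param n_features features compared.
#' @param n_cis cis variants per feature.
#' @param n_perm permutations for the reference adjustment.
#' @export
experiment_eigenmt_concordance <- function(n_features = 50, n_cis = 100,
                                           n_perm = 10000, seed = 1) {
  cfg <- sim_config(n_donors = 80, n_variants = max(2000, 4 * n_cis),
                    n_chrom = 1, seed = child_seed(seed, "emt"))
  g <- simulate_genotypes(cfg)
  n <- ncol(g$dosage)
  set.seed(child_seed(seed, "emt_pheno"))
  em <- pm <- numeric(n_features)
  for (f in seq_len(n_features)) {
    st <- sample.int(nrow(g$dosage) - n_cis, 1)
    idx <- st + seq_len(n_cis) - 1
    dos <- g$dosage[idx, , drop = FALSE]
    y <- rnorm(n)
    if (f %% 3 == 0) { # mix in some real signals so adjusted p spans (0,1)
      y <- y + dos[sample.int(n_cis, 1), ] * runif(1, 0.2, 0.6)
    }
    Xc <- dos - rowMeans(dos)
    yc <- y - mean(y)
    xx <- rowSums(Xc^2)
    beta <- drop(Xc %*% yc) / xx
    rss <- sum(yc^2) - beta^2 * xx
    se <- sqrt(pmax(rss / (n - 2), 1e-300) / xx)
    p <- 2 * pt(-abs(beta / se), n - 2)
    em[f] <- eigenmt_local(p, dos, seq_len(n_cis))$p_local
    pm[f] <- permutation_local(y, dos, n_perm = n_perm)$p_local
  }
  list(spearman = cor(em, pm, method = "spearman"),
       eigenmt = em, permutation = pm)
}

#' @describeIn experiments Recovery of planted per-allele effect sizes by the
#'   association scan: correlation and mean bias between planted and
#'   estimated betas (log2 scale).
#' @param n_qtl planted QTLs.
#' @export
experiment_beta_recovery <- function(n_qtl = 200, r2 = 0.1, n_donors = 80,
                                     seed = 1) {
  cfg <- sim_config(n_donors = n_donors, conditions = "vehicle",
                    n_variants = 4000, n_chrom = 4,
                    n_peaks = ceiling(n_qtl * 1.3),
                    n_genes = ceiling(n_qtl * 2),
                    missing_rate = 0, frac_caqtl = 0.885,
                    scenario_mix = c(shared = 1), target_r2 = r2,
                    frac_wre = 0, frac_deg = 0, frac_eqtl = 0,
                    n_gwas_loci = 0, seed = seed)
  sim <- suppressWarnings(simulate_dataset(cfg))
  norm <- normalize_counts(sim$atac, gc = sim$peaks$gc, n_pcs = 0)
  pr <- head(sim$truth$pairs, n_qtl)
  pairs <- tibble(feature = pr$peak_id, variant = pr$causal_variant)
  rec <- assoc_scan(norm$residuals, sim$genotypes, pairs, sim$sheet)
  tf <- sim$truth$features
  truth_b <- vapply(seq_len(nrow(pr)), function(i)
    tf$beta[[match(pr$peak_id[i], tf$feature_id)]][["vehicle"]] / log(2),
    numeric(1))
  est <- rec$beta[match(paste(pr$peak_id, pr$causal_variant),
                        paste(rec$feature, rec$variant))]
  ok <- !is.na(est)
  list(correlation = cor(truth_b[ok], est[ok]),
       mean_bias = mean(est[ok] - truth_b[ok]), n = sum(ok))
}

#' @describeIn experiments Recovery of enhancer-priming scenario labels:
#'   equal numbers of primed / stimulus-specific / shared caPeak-eGene pairs
#'   are planted, both assays are mapped per condition, and per-class recall
#'   plus the shared-to-primed mislabel rate are reported.
#' @param n_per_class planted pairs per scenario class.
#' @param n_perm_eqtl permutations for the expression local correction.
#' @export
experiment_priming_recovery <- function(n_per_class = 50, r2 = 0.15,
                                        n_donors = 80, n_perm_eqtl = 300,
                                        seed = 1) {
  n_pairs <- 3 * n_per_class
  cfg <- sim_config(n_donors = n_donors, conditions = c("vehicle", "stim"),
                    n_variants = 4000, n_chrom = 4,
                    n_peaks = ceiling(n_pairs * 1.2),
                    n_genes = ceiling(n_pairs * 2.1),
                    missing_rate = 0, frac_caqtl = n_pairs / ceiling(n_pairs * 1.2),
                    scenario_mix = c(shared = 1 / 3, primed = 1 / 3,
                                     stimulus_specific = 1 / 3),
                    target_r2 = r2, mediation_gamma = 1,
                    frac_wre = 0, frac_deg = 0, frac_eqtl = 0,
                    n_gwas_loci = 0, seed = seed)
  sim <- suppressWarnings(simulate_dataset(cfg))
  na <- normalize_counts(sim$atac, gc = sim$peaks$gc, n_pcs = 0)
  nr <- normalize_counts(sim$rna, gc = sim$genes$gc, n_pcs = 0)
  scaled <- sweep(sim$rna, 2, nr$size_factors, "/")
  qca <- list(); qe <- list()
  for (cn in c("vehicle", "stim")) {
    sh <- sim$sheet[sim$sheet$condition == cn, ]
    qca[[cn]] <- map_qtl(na$residuals, sim$genotypes, sim$peaks, sh,
                         assay = "atac", seed = seed)
    qe[[cn]] <- map_qtl(nr$residuals, sim$genotypes, sim$genes, sh,
                        assay = "rna", n_perm = n_perm_eqtl,
                        scaled_counts = scaled, seed = seed)
  }
  calls <- link_and_classify_priming(qca, qe, sim$genotypes, sim$peaks,
                                     sim$genes,
                                     condition_pair = c("vehicle", "stim"))
  tp <- sim$truth$pairs
  lab <- setNames(calls$label, paste(calls$peak, calls$gene))
  called <- lab[paste(tp$peak_id, tp$gene_id)]
  called[is.na(called)] <- "absent"
  recall <- function(sc) mean(called[tp$scenario == sc] == sc)
  list(recall_primed = recall("primed"),
       recall_stimulus_specific = recall("stimulus_specific"),
       recall_shared = recall("shared"),
       shared_mislabeled_primed =
         mean(called[tp$scenario == "shared"] == "primed"),
       confusion = table(truth = tp$scenario, called = called))
}

#' @describeIn experiments Motif-GLM effect recovery over replicates plus the
#'   null false-discovery behaviour of the BH gate across many null motifs.
#' @param n_reps replicates for the effect-recovery arm.
#' @param n_per_class peaks per class.
#' @param logor planted class log-odds.
#' @param n_null_motifs null motifs for the FDR arm.
#' @export
experiment_motif_recovery <- function(n_reps = 50, n_per_class = 2000,
                                      logor = 1, n_null_motifs = 200,
                                      seed = 1) {
  gen <- function(n_motifs, lo, sd) {
    cfg <- sim_config(n_donors = 10, n_variants = 200, n_chrom = 1,
                      n_peaks = 2 * n_per_class, n_genes = 20,
                      frac_caqtl = 0, frac_wre = 0.5, frac_deg = 0,
                      frac_eqtl = 0, motif_logOR = lo, n_motifs = n_motifs,
                      frac_motif_planted = 1, n_gwas_loci = 0, seed = sd)
    g <- simulate_genotypes(cfg)
    ft <- simulate_features(cfg, g)
    cls <- setNames(factor(ifelse(ft$peaks$name %in% ft$truth$wre_ids,
                                  "response", "background"),
                           levels = c("background", "response")),
                    ft$peaks$name)
    list(mt = ft$motif_table, cls = cls)
  }
  est <- vapply(seq_len(n_reps), function(r) {
    d <- gen(1, logor, child_seed(seed, paste0("motif", r)))
    motif_glm(d$mt, d$cls)$effect[1]
  }, numeric(1))
  null_counts <- vapply(1:3, function(r) {
    d <- gen(n_null_motifs, 0, child_seed(seed, paste0("motifnull", r)))
    sum(motif_glm(d$mt, d$cls)$fdr < 0.1, na.rm = TRUE)
  }, numeric(1))
  list(estimates = est,
       frac_within_0p3 = mean(abs(est - logor) < 0.3),
       null_bh_mean = mean(null_counts))
}

#' @describeIn experiments Discrimination of the colocalization verdict:
#'   loci whose GWAS shares the QTL causal variant versus loci with a
#'   distinct (r2 < 0.1) causal variant.
#' @param n_reps replicate locus pairs.
#' @export
experiment_clpp_discrimination <- function(n_reps = 100, seed = 1) {
  res <- list()
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(n_donors = 80, conditions = "vehicle",
                      n_variants = 1200, n_chrom = 1, n_peaks = 30,
                      n_genes = 60, missing_rate = 0, frac_caqtl = 0.5,
                      scenario_mix = c(shared = 1), target_r2 = 0.25,
                      gc_effect_amplitude = 0,
                      frac_wre = 0, frac_deg = 0, frac_eqtl = 0,
                      n_gwas_loci = 2, gwas_n = 20000,
                      gwas_var_explained = 0.005,
                      gwas_region_halfwidth = 100000,
                      seed = child_seed(seed, paste0("clpp", r)))
    sim <- suppressWarnings(simulate_dataset(cfg))
    loci <- sim$truth$gwas_loci
    norm <- normalize_counts(sim$atac, gc = NULL, n_pcs = 0)
    for (k in seq_len(nrow(loci))) {
      ft <- loci$qtl_feature[k]
      pk <- sim$peaks[sim$peaks$name == ft, ]
      pairs <- build_cis_pairs(pk, sim$genotypes, sim$sheet$donor_id,
                               assay = "atac")
      rec <- assoc_scan(norm$residuals, sim$genotypes, pairs, sim$sheet)
      idx <- rec[which.min(rec$p_nominal), ]
      cand <- find_candidates(sim$gwas,
                              tibble(feature = ft, variant = idx$variant),
                              sim$genotypes)
      verdict <- "not_colocalized"
      if (nrow(cand) && cand$candidate[1]) {
        verdict <- coloc_test(cand[1, ], sim$gwas, rec, sim$genotypes)$verdict
      }
      res[[length(res) + 1]] <- tibble(mode = loci$mode[k], verdict = verdict)
    }
  }
  res <- list_rbind(res)
  list(shared_coloc_rate = mean(res$verdict[res$mode == "shared"] == "colocalized"),
       distinct_coloc_rate = mean(res$verdict[res$mode == "distinct"] == "colocalized"),
       n_shared = sum(res$mode == "shared"),
       n_distinct = sum(res$mode == "distinct"))
}

#' @describeIn experiments Power and FDR of the paired differential test with
#'   planted responsive peaks at the standard WRE gate.
#' @param n_feat features; `frac_resp` responsive fraction; `lfc` planted
#'   |log2 fold change|.
#' @param frac_resp fraction of features that respond.
#' @param lfc planted |log2 fold change|.
#' @export
experiment_paired_power <- function(n_donors = 60, n_feat = 2000,
                                    frac_resp = 0.1, lfc = 0.8, seed = 1) {
  cfg <- sim_config(n_donors = n_donors, conditions = c("vehicle", "stim"),
                    n_variants = 400, n_chrom = 2, n_peaks = n_feat,
                    n_genes = 10, missing_rate = 0, frac_caqtl = 0,
                    frac_wre = frac_resp, frac_deg = 0, frac_eqtl = 0,
                    beta_lfc = lfc, n_gwas_loci = 0, seed = seed)
  sim <- simulate_dataset(cfg)
  norm <- normalize_counts(sim$atac, gc = sim$peaks$gc, n_pcs = 0)
  d <- paired_diff(norm$norm, sim$sheet, "stim", "vehicle")
  w <- call_responsive(d)
  truth <- sim$truth$wre_ids
  list(sensitivity = mean(truth %in% w$feature),
       fdr = if (nrow(w)) mean(!w$feature %in% truth) else 0,
       null_rejection = mean(d$p[!d$feature %in% truth] < 0.05))
}
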