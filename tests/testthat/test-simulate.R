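test_that("LD block generator spans the r2 range set by the copy probability", {
  cfg1 <- sim_config(n_donors = 30, n_variants = 100, n_chrom = 1,
                     within_block_copy_prob = 1, seed = 5)
  g1 <- simulate_genotypes(cfg1)
  blk1 <- which(g1$variants$block == 1)
  r2 <- suppressWarnings(cor(t(g1$dosage[blk1, ])))^2
  expect_true(all(abs(r2 - 1) < 1e-12))

  cfg0 <- sim_config(n_donors = 80, n_variants = 400, n_chrom = 1,
                     within_block_copy_prob = 0, seed = 4)
  g0 <- simulate_genotypes(cfg0)
  set.seed(1)
  rs <- replicate(100, {
    ij <- sample(400, 2)
    abs(cor(g0$dosage[ij[1], ], g0$dosage[ij[2], ]))
  })
  expect_lt(mean(rs), 0.15)
})

test_that("realized minor allele frequencies track their targets", {
  g <- simulate_genotypes(sim_config(n_donors = 80, n_variants = 400,
                                     n_chrom = 1, seed = 4))
  dev <- abs(g$variants$maf - pmin(g$variants$target_maf,
                                   1 - g$variants$target_maf))
  # per-variant binomial sd is ~0.04, so 0.1 is a ~2.5 sigma bound
  expect_gte(mean(dev <= 0.1), 0.98)
  expect_lt(median(dev), 0.05)
})

test_that("simulated genotypes are Hardy-Weinberg distributed", {
  g <- simulate_genotypes(sim_config(n_donors = 80, n_variants = 1000,
                                     n_chrom = 1, seed = 2))
  hard <- round(g$dosage)
  p_obs <- apply(hard, 1, function(r) {
    tb <- tabulate(r + 1L, nbins = 3)
    hwe_exact_test(tb[1], tb[2], tb[3])
  })
  # the exact test's p-values are discrete and conservative, so compare the
  # observed distribution with an oracle sample drawn from exact HWE at the
  # same frequencies rather than with a continuous uniform
  set.seed(9)
  p_ref <- apply(g$dosage, 1, function(r) {
    f <- mean(r) / 2
    sim <- rbinom(length(r), 1, f) + rbinom(length(r), 1, f)
    tb <- tabulate(sim + 1L, nbins = 3)
    hwe_exact_test(tb[1], tb[2], tb[3])
  })
  ks <- suppressWarnings(ks.test(p_obs, p_ref))
  expect_gt(ks$p.value, 0.001)
})

test_that("scenario wiring places causal variants inside the declared windows", {
  sim <- small_sim()
  vt <- sim$genotypes$variants
  pr <- sim$truth$pairs
  expect_gt(nrow(pr), 0)
  for (i in seq_len(nrow(pr))) {
    v <- vt[vt$id == pr$causal_variant[i], ]
    pk <- sim$peaks[sim$peaks$name == pr$peak_id[i], ]
    gn <- sim$genes[sim$genes$name == pr$gene_id[i], ]
    expect_equal(v$chrom, pk$chrom)
    expect_true(pos_in_interval(v$pos, pk$start - 25000, pk$end + 25000))
    expect_lte(abs(gn$tss - v$pos), 1e6)
  }
  # all-null mix: no wiring, no causal variants
  cfg0 <- sim_config(n_donors = 10, n_variants = 200, n_peaks = 20, n_genes = 20,
                     n_chrom = 1, scenario_mix = c(null = 1), frac_wre = 0,
                     n_gwas_loci = 0, seed = 7)
  s0 <- simulate_dataset(cfg0)
  expect_equal(nrow(s0$truth$pairs), 0)
  expect_true(all(is.na(s0$truth$features$causal_variant)))
})

test_that("motif planting is neutral when the planted log-odds is zero", {
  cfg <- sim_config(n_donors = 10, n_variants = 400, n_peaks = 400, n_genes = 20,
                    n_chrom = 1, frac_caqtl = 0, frac_wre = 0.5,
                    motif_logOR = 0, n_motifs = 20, n_gwas_loci = 0, seed = 8)
  g <- simulate_genotypes(cfg)
  ft <- simulate_features(cfg, g)
  wre <- ft$truth$wre_ids
  pres <- ft$motif_table$presence
  in_w <- rownames(pres) %in% wre
  # pooled rate difference within an exact binomial CI around equality
  k1 <- sum(pres[in_w, ]); n1 <- sum(in_w) * ncol(pres)
  k2 <- sum(pres[!in_w, ]); n2 <- sum(!in_w) * ncol(pres)
  pt <- prop.test(c(k1, k2), c(n1, n2))
  expect_gt(pt$p.value, 0.001)
})

test_that("count model reproduces planted means, fold changes and determinism", {
  # flat configuration: features exchangeable across samples
  cfg <- sim_config(n_donors = 80, conditions = "vehicle", n_variants = 200,
                    n_peaks = 100, n_genes = 20, n_chrom = 1,
                    missing_rate = 0, frac_caqtl = 0, frac_wre = 0, frac_deg = 0,
                    donor_sd = 0, gc_effect_amplitude = 0,
                    libsize_lognormal_sd = 0, n_gwas_loci = 0, seed = 11)
  sim <- simulate_dataset(cfg)
  mu_true <- exp(sim$truth$baselines$atac)
  se <- sqrt((mu_true + mu_true^2 / cfg$dispersion) / ncol(sim$atac))
  zdev <- abs(rowMeans(sim$atac) - mu_true) / se
  expect_gte(mean(zdev <= 3), 0.95)
  expect_true(all(zdev <= 6))
  # planted LFC recovered on average
  cfg2 <- sim_config(n_donors = 80, conditions = c("vehicle", "stim"),
                     n_variants = 200, n_peaks = 200, n_genes = 20, n_chrom = 1,
                     missing_rate = 0, frac_caqtl = 0, frac_wre = 0.5,
                     frac_deg = 0, beta_lfc = 0.5, n_gwas_loci = 0, seed = 12)
  sim2 <- simulate_dataset(cfg2)
  sheet <- sim2$sheet
  lv <- log2(sim2$atac + 0.5)
  stim_m <- rowMeans(lv[, sheet$sample_id[sheet$condition == "stim"]])
  veh_m <- rowMeans(lv[, sheet$sample_id[sheet$condition == "vehicle"]])
  wre <- sim2$truth$wre_ids
  planted <- vapply(wre, function(w)
    sim2$truth$lfc_peaks[w, "stim"], numeric(1))
  emp <- (stim_m - veh_m)[wre]
  expect_lt(mean(abs(emp - planted)), 0.15)
  # determinism
  sim2b <- simulate_dataset(cfg2)
  expect_identical(sim2$atac, sim2b$atac)
  expect_identical(sim2$rna, sim2b$rna)
})

test_that("count model guards against log-mean overflow", {
  cfg <- sim_config(n_donors = 5, n_variants = 100, n_peaks = 10, n_genes = 10,
                    n_chrom = 1, frac_caqtl = 0, frac_wre = 1, beta_lfc = 80,
                    n_gwas_loci = 0, seed = 1)
  g <- simulate_genotypes(cfg)
  ft <- simulate_features(cfg, g)
  expect_error(simulate_counts(g, ft, cfg), "overflow")
})

test_that("simulated GWAS matches panel frequencies and has calibrated nulls", {
  sim <- small_sim()
  ss <- sim$gwas
  expect_gt(nrow(ss), 0)
  panel_f <- rowMeans(sim$genotypes$dosage[ss$id, ]) / 2
  expect_lt(max(abs(ss$freq - panel_f)), 0.02)
  # null variants (low LD with the causal) have roughly uniform p
  loci <- sim$truth$gwas_loci
  null_p <- c()
  for (k in seq_len(nrow(loci))) {
    sub <- ss[ss$locus == loci$locus[k], ]
    r2 <- drop(ld_r2(sim$genotypes$dosage[sub$id, , drop = FALSE],
                     sim$genotypes$dosage[loci$gwas_causal[k], , drop = FALSE]))
    null_p <- c(null_p, sub$p[r2 < 0.02])
  }
  expect_gt(suppressWarnings(ks.test(null_p, "punif"))$p.value, 1e-4)
})

test_that("dataset writer produces a reproducible manifest and passes validation", {
  sim <- small_sim()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_dataset(sim, d1, force = TRUE)
  m2 <- write_dataset(sim, d2, force = TRUE)
  expect_identical(unname(unlist(m1$checksums)), unname(unlist(m2$checksums)))
  expect_error(write_dataset(sim, d1), "non-empty")
  # truth table row count covers every feature
  tf <- readr::read_tsv(file.path(d1, "truth_features.tsv"), show_col_types = FALSE)
  expect_equal(nrow(tf), nrow(sim$peaks) + nrow(sim$genes))
  # loaded dataset passes the validators and reproduces the matrices
  ds <- suppressMessages(load_dataset(d1))
  expect_identical(ds$atac, sim$atac)
  expect_equal(ds$genotypes$dosage, sim$genotypes$dosage, ignore_attr = FALSE)
  v <- suppressMessages(validate_dataset(ds$genotypes,
                                         list(atac = ds$atac, rna = ds$rna),
                                         ds$sheet))
  expect_gt(nrow(v$samples), 0)
})
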