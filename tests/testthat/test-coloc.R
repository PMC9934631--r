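coloc_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_donors = 80, conditions = "vehicle", n_variants = 1200,
                        n_chrom = 1, n_peaks = 30, n_genes = 60,
                        missing_rate = 0, frac_caqtl = 0.5,
                        scenario_mix = c(shared = 1), target_r2 = 0.25,
                        gc_effect_amplitude = 0, frac_wre = 0, frac_deg = 0,
                        frac_eqtl = 0, n_gwas_loci = 2, gwas_n = 20000,
                        gwas_var_explained = 0.005,
                        gwas_region_halfwidth = 100000, seed = 61)
      cache <<- suppressWarnings(simulate_dataset(cfg))
    }
    cache
  }
})

test_that("candidate extraction applies the genome-wide p and distance gates", {
  g <- coloc_fixture()$genotypes
  vt <- g$variants
  qv <- vt$id[100]
  ss <- tibble::tibble(id = vt$id[c(101, 120)], chrom = NA, pos = NA,
                       effect_allele = "G", other_allele = "A", freq = 0.3,
                       beta = 1, se = 0.1,
                       p = c(6e-8, 1e-10), n = 1e4, z = 10)
  # only the p < 5e-8 SNP counts
  cand <- find_candidates(ss, tibble::tibble(feature = "pk", variant = qv), g)
  expect_equal(cand$gwas_index, vt$id[120])
  # p = 6e-8 alone: no candidate locus
  cand2 <- find_candidates(ss[1, ], tibble::tibble(feature = "pk", variant = qv), g)
  expect_equal(nrow(cand2), 0)
  # identical index SNP: r2 = 1, candidate
  ss3 <- ss; ss3$id <- c(vt$id[5], qv)
  cand3 <- find_candidates(ss3, tibble::tibble(feature = "pk", variant = qv), g)
  expect_true(cand3$candidate)
  expect_equal(cand3$r2_index, 1)
  expect_error(find_candidates(dplyr::mutate(ss, id = paste0("x", id)),
                               tibble::tibble(feature = "pk", variant = qv), g),
               "no shared variants")
})

test_that("distance gate at 1 Mb is inclusive", {
  dos <- rbind(a = rbinom(100, 2, 0.4))
  dos <- rbind(dos, b = dos[1, ], c = dos[1, ])
  colnames(dos) <- paste0("D", 1:100)
  g <- geno_matrix(dos, tibble::tibble(
    chrom = "chr1", pos = c(1L, 1000001L, 1000002L),
    id = c("a", "b", "c"), ref = "A", alt = "G"))
  mk <- function(ids) tibble::tibble(id = ids, chrom = NA, pos = NA,
                                     effect_allele = "G", other_allele = "A",
                                     freq = 0.4, beta = 1, se = 0.1, p = 1e-10,
                                     n = 1e4, z = 10)
  expect_equal(nrow(find_candidates(mk("b"), tibble::tibble(feature = "f", variant = "a"), g)), 1)
  expect_equal(nrow(find_candidates(mk("c"), tibble::tibble(feature = "f", variant = "a"), g)), 0)
})

test_that("approximate conditional analysis follows its closed-form limits", {
  sim <- coloc_fixture()
  g <- sim$genotypes
  vt <- g$variants
  ids <- vt$id[1:60]
  gg <- geno_subset(g, variants = ids)
  ss <- tibble::tibble(id = ids, chrom = NA, pos = NA, effect_allele = "G",
                       other_allele = "A",
                       freq = rowMeans(gg$dosage) / 2,
                       beta = rnorm(60, 0, 0.02), se = 0.01,
                       p = runif(60, 0.001, 1), n = 2e4, z = 0)
  # empty conditioning set: marginals unchanged exactly
  c0 <- approx_conditional(ss, gg, conditioning = character(0))
  expect_identical(c0$beta_cond, ss$beta)
  expect_identical(c0$p_cond, ss$p)
  # conditioning on an uncorrelated variant leaves the target untouched
  r2 <- ld_r2(gg$dosage)
  lowpair <- which(r2 < 1e-4 & upper.tri(r2), arr.ind = TRUE)[1, ]
  cc <- approx_conditional(ss, gg, conditioning = ids[lowpair[2]])
  dev <- abs(cc$beta_cond[lowpair[1]] - ss$beta[lowpair[1]])
  expect_lt(dev, 1e-3)
  # collinear target is masked
  hi <- which(r2 > 0.95 & upper.tri(r2), arr.ind = TRUE)[1, ]
  ch <- approx_conditional(ss, gg, conditioning = ids[hi[2]])
  expect_equal(ch$status[hi[1]], "masked_collinear")
  # discordant frequency is excluded
  ss2 <- ss; ss2$freq[3] <- ss2$freq[3] + 0.5
  ce <- approx_conditional(ss2, gg, conditioning = ids[50])
  expect_equal(ce$status[3], "excluded_freq")
})

test_that("conditioning on the causal variant abolishes the locus signal", {
  sim <- coloc_fixture()
  loci <- sim$truth$gwas_loci
  k <- which(loci$mode == "shared")[1]
  ss <- sim$gwas[sim$gwas$locus == loci$locus[k], ]
  gg <- geno_subset(sim$genotypes, variants = ss$id)
  cond <- approx_conditional(ss, gg, conditioning = loci$gwas_causal[k])
  ok <- cond$status == "ok" & !is.na(cond$p_cond)
  expect_gt(mean(abs(cond$beta_cond[ok] / cond$se_cond[ok]) < 3), 0.9)
})

test_that("CLPP posteriors normalize and the single-SNP case is exact", {
  g <- coloc_fixture()$genotypes
  one <- tibble::tibble(id = g$variants$id[1], beta = 0.5, se = 0.1, p = 1e-6)
  qtl <- tibble::tibble(variant = g$variants$id[1], beta = 0.8, se = 0.15,
                        p_nominal = 1e-5)
  out <- clpp(one, qtl, g, gw_p = 1e-5)
  expect_equal(out$clpp_max, 1)
  expect_equal(out$verdict, "colocalized")
  # no jointly nominal SNPs
  none <- clpp(dplyr::mutate(one, p = 0.5), qtl, g)
  expect_equal(none$verdict, "not_colocalized")
  expect_match(none$reason, "no jointly nominal")
  # posterior sums to 1 over the included set; duplicating excluded SNPs is a no-op
  ids <- g$variants$id[1:20]
  gw <- tibble::tibble(id = ids, beta = rnorm(20, 0, 0.05), se = 0.01,
                       p = c(runif(10, 0, 0.04), runif(10, 0.2, 1)))
  qt <- tibble::tibble(variant = ids, beta = rnorm(20, 0, 0.3), se = 0.1,
                       p_nominal = c(runif(10, 0, 0.04), runif(10, 0.2, 1)))
  full <- clpp(gw, qt, g)
  expect_equal(sum(full$clpp$posterior_gwas), 1)
  expect_equal(sum(full$clpp$posterior_qtl), 1)
  dup <- clpp(dplyr::bind_rows(gw, gw[15:20, ]), qt, g)
  expect_equal(dup$clpp_max, full$clpp_max)
})

test_that("salvage re-tests only near-miss conditions below the raw threshold", {
  sim <- coloc_fixture()
  loci <- sim$truth$gwas_loci
  k <- which(loci$mode == "shared")[1]
  ft <- loci$qtl_feature[k]
  norm <- normalize_counts(sim$atac, gc = NULL, n_pcs = 0)
  pk <- sim$peaks[sim$peaks$name == ft, ]
  pairs <- build_cis_pairs(pk, sim$genotypes, sim$sheet$donor_id, assay = "atac")
  rec <- assoc_scan(norm$residuals, sim$genotypes, pairs, sim$sheet)
  base <- tibble::tibble(feature = ft, qtl_variant = rec$variant[which.min(rec$p_nominal)],
                         clpp_max = 0.5, clpp_snp = NA, r2_to_gw_snp = 1,
                         conditional_pass = TRUE, verdict = "colocalized",
                         salvage = FALSE, condition = "vehicle")
  mk_q <- function(p_min, significant) {
    structure(list(
      records = rec,
      corrections = tibble::tibble(feature = ft, p_min = p_min, m_eff = 10L,
                                   p_local = 1, p_global = 1,
                                   significant = significant,
                                   nominal_threshold = NA_real_),
      signals = NULL, params = list(assay = "atac")), class = "qtl_result")
  }
  # near miss at 5e-7: salvaged; 5e-6: not
  sal <- salvage_condition_specific(base, list(vehicle = mk_q(1e-9, TRUE),
                                               stim = mk_q(5e-7, FALSE)),
                                    sim$gwas, sim$genotypes)
  expect_equal(nrow(sal), 1)
  expect_true(all(sal$salvage))
  expect_equal(sal$condition, "stim")
  none <- salvage_condition_specific(base, list(vehicle = mk_q(1e-9, TRUE),
                                                stim = mk_q(5e-6, FALSE)),
                                     sim$gwas, sim$genotypes)
  expect_equal(nrow(none), 0)
  # nothing colocalized anywhere: no salvage attempted
  base2 <- dplyr::mutate(base, verdict = "not_colocalized")
  expect_equal(nrow(salvage_condition_specific(
    base2, list(vehicle = mk_q(1e-9, TRUE), stim = mk_q(5e-7, FALSE)),
    sim$gwas, sim$genotypes)), 0)
})
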