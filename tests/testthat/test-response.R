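make_lmm_data <- function(nd = 40, beta = 0.5, beta_int = 0, donor_sd = 0.7,
                          seed = 1) {
  set.seed(seed)
  donor <- rep(sprintf("d%02d", 1:nd), each = 2)
  cond <- rep(c("veh", "stim"), nd)
  x_d <- rbinom(nd, 2, 0.3)
  x <- rep(x_d, each = 2)
  u <- rep(rnorm(nd, 0, donor_sd), each = 2)
  y <- beta * x + 0.3 * (cond == "stim") +
    beta_int * x * (cond == "stim") + u + rnorm(2 * nd, 0, 0.5)
  sheet <- tibble::tibble(sample_id = paste(donor, cond, sep = "_"),
                          donor_id = donor, condition = cond)
  resid <- matrix(y, 1, dimnames = list("ft", sheet$sample_id))
  dos <- matrix(x_d, 1, dimnames = list("v1", sprintf("d%02d", 1:nd)))
  g <- geno_matrix(dos, tibble::tibble(chrom = "chr1", pos = 1L, id = "v1",
                                       ref = "A", alt = "G"))
  list(resid = resid, g = g, sheet = sheet)
}

test_that("interaction LMM matches the lme4 maximum-likelihood fit", {
  skip_if_not_installed("lme4")
  d <- make_lmm_data(beta_int = 0.4, seed = 2)
  ia <- fit_interaction_lmm(d$resid, d$g, d$sheet,
                            tibble::tibble(feature = "ft", variant = "v1"),
                            condition_pair = c("veh", "stim"))
  df <- data.frame(y = d$resid[1, d$sheet$sample_id],
                   x = d$g$dosage[1, d$sheet$donor_id],
                   cond = as.numeric(d$sheet$condition == "stim"),
                   donor = d$sheet$donor_id)
  m_full <- lme4::lmer(y ~ x * cond + (1 | donor), data = df, REML = FALSE)
  m_red <- lme4::lmer(y ~ x + cond + (1 | donor), data = df, REML = FALSE)
  lrt_ref <- as.numeric(2 * (stats::logLik(m_full) - stats::logLik(m_red)))
  expect_equal(ia$lrt_chi2, max(0, lrt_ref), tolerance = 1e-4)
  expect_equal(ia$beta_vehicle, unname(lme4::fixef(m_full)["x"]), tolerance = 1e-4)
  expect_equal(ia$beta_stim, unname(lme4::fixef(m_full)["x"] +
                                      lme4::fixef(m_full)["x:cond"]),
               tolerance = 1e-4)
})

test_that("per-condition betas decompose additively", {
  d <- make_lmm_data(beta_int = 0.6, seed = 3)
  ia <- fit_interaction_lmm(d$resid, d$g, d$sheet,
                            tibble::tibble(feature = "ft", variant = "v1"),
                            condition_pair = c("veh", "stim"))
  expect_equal(ia$beta_stim, ia$beta_vehicle + ia$beta_interaction,
               tolerance = 1e-10)
  expect_gte(ia$lrt_chi2, 0)
})

test_that("LMM reduces exactly to OLS for unpaired (singleton-donor) designs", {
  set.seed(4)
  n <- 60
  cond <- rep(0:1, each = n / 2)
  x <- rbinom(n, 2, 0.3)
  y <- 0.4 * x + 0.2 * cond + rnorm(n)
  X <- cbind(1, x, cond, x * cond)
  groups <- split(seq_len(n), seq_len(n))  # one observation per donor
  lmm_f <- stimqtl:::fit_lmm_ml(y, X, groups)
  lmm_r <- stimqtl:::fit_lmm_ml(y, X[, -4], groups)
  ols_f <- stimqtl:::fit_ols_ll(y, X)
  ols_r <- stimqtl:::fit_ols_ll(y, X[, -4])
  p_lmm <- pchisq(max(0, 2 * (lmm_f$ll - lmm_r$ll)), 1, lower.tail = FALSE)
  p_ols <- pchisq(max(0, 2 * (ols_f$ll - ols_r$ll)), 1, lower.tail = FALSE)
  # the profiled likelihood is flat in lambda for singleton groups, so the
  # mixed-model LRT collapses exactly to plain OLS
  expect_equal(p_lmm, p_ols, tolerance = 1e-6)
  expect_equal(lmm_f$beta, ols_f$beta, tolerance = 1e-6)
})

test_that("interaction p-values are calibrated under a null interaction", {
  set.seed(5)
  ps <- replicate(200, {
    d <- make_lmm_data(nd = 30, beta = 0.4, beta_int = 0,
                       seed = sample.int(1e6, 1))
    fit_interaction_lmm(d$resid, d$g, d$sheet,
                        tibble::tibble(feature = "ft", variant = "v1"),
                        condition_pair = c("veh", "stim"))$p_interaction
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("genotype constant within a condition is skipped with a reason", {
  d <- make_lmm_data(seed = 6)
  d$g$dosage[1, ] <- 1
  ia <- fit_interaction_lmm(d$resid, d$g, d$sheet,
                            tibble::tibble(feature = "ft", variant = "v1"),
                            condition_pair = c("veh", "stim"))
  expect_match(ia$fit, "skipped")
  expect_true(is.na(ia$p_interaction))
  cr <- call_response_qtls(ia)
  expect_false(any(cr$is_response))
})

test_that("response-QTL calling applies BH within the family", {
  ia <- tibble::tibble(feature = letters[1:4], variant = "v",
                       beta_vehicle = 0, beta_stim = 0, beta_interaction = 0,
                       lambda = 1, lrt_chi2 = 1,
                       p_interaction = c(0.04, 0.2, NA, 0.01), fit = "lmm")
  class(ia) <- c("interaction_result", class(ia))
  out <- call_response_qtls(ia, fdr = 0.1)
  expect_equal(out$fdr[!is.na(out$fdr)],
               p.adjust(c(0.04, 0.2, 0.01), "BH"))
  expect_equal(out$is_response, c(TRUE, FALSE, FALSE, TRUE))
  # single record at p = 0.04 is significant with m = 1
  one <- call_response_qtls(ia[1, ], fdr = 0.1)
  expect_true(one$is_response)
  empty <- call_response_qtls(ia[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("sharing classification counts combinations and the increment", {
  sets <- list(vehicle = c("A", "B"), stimA = c("A", "C"), stimB = c("A"))
  sh <- classify_sharing(sets, vehicle = "vehicle")
  memb <- sh$membership
  expect_true(all(unlist(memb[memb$feature == "A", c("vehicle", "stimA", "stimB")])))
  # stimulated-only = {C}; vehicle = {A, B} -> 50%
  expect_equal(sh$increment_pct, 50)
  expect_error(classify_sharing(sets, vehicle = "nope"), "absent")
})

test_that("sharing increment is recovered from a planted mixture", {
  # strong effects so detection differences do not distort the ratio
  cfg <- sim_config(n_donors = 80, conditions = c("vehicle", "stim"),
                    n_variants = 2000, n_chrom = 2, n_peaks = 120, n_genes = 150,
                    missing_rate = 0, frac_caqtl = 0.7,
                    scenario_mix = c(shared = 5 / 7, stimulus_specific = 2 / 7),
                    target_r2 = 0.3, frac_wre = 0, frac_deg = 0, frac_eqtl = 0,
                    n_gwas_loci = 0, seed = 55)
  sim <- suppressWarnings(simulate_dataset(cfg))
  truth_inc <- 100 * sum(sim$truth$pairs$scenario == "stimulus_specific") /
    sum(sim$truth$pairs$scenario == "shared")
  norm <- normalize_counts(sim$atac, gc = sim$peaks$gc, n_pcs = 0)
  qs <- lapply(c(vehicle = "vehicle", stim = "stim"), function(cn) {
    map_qtl(norm$residuals, sim$genotypes, sim$peaks,
            sim$sheet[sim$sheet$condition == cn, ], assay = "atac", seed = 55)
  })
  sh <- classify_sharing(qs, vehicle = "vehicle")
  expect_lt(abs(sh$increment_pct - truth_inc), 15)
})

test_that("priming labels follow the LD-link and condition-pattern rules", {
  # construct two qtl_result stubs over a 3-variant genotype panel
  set.seed(7)
  base <- rbinom(100, 2, 0.4)
  flip <- ifelse(runif(100) < 0.25, sample(0:2, 100, TRUE), base)
  dos <- rbind(ca = base, e_hi = base, e_lo = flip)
  colnames(dos) <- paste0("D", 1:100)
  g <- geno_matrix(dos, tibble::tibble(chrom = "chr1",
                                       pos = c(1000L, 2000L, 3000L),
                                       id = rownames(dos), ref = "A", alt = "G"))
  r2_lo <- ld_r2(dos["ca", , drop = FALSE], dos["e_lo", , drop = FALSE])[1, 1]
  expect_lt(r2_lo, 0.8)
  peaks <- tibble::tibble(chrom = "chr1", start = 500, end = 1500, name = "pk")
  genes <- tibble::tibble(chrom = "chr1", start = 1800, end = 2400, name = "gn",
                          strand = "+", tss = 1801)
  stub <- function(feature, sig, snp) {
    structure(list(
      records = tibble::tibble(feature = feature, variant = snp, beta = 1,
                               se = 0.1, t = 10, p_nominal = 1e-9, n = 100),
      corrections = tibble::tibble(feature = feature, p_min = 1e-9, m_eff = 1L,
                                   p_local = 1e-9, p_global = 1e-9,
                                   significant = sig,
                                   nominal_threshold = ifelse(sig, 1e-4, NA)),
      signals = tibble::tibble(feature = feature, variant = snp,
                               tier = "independent_index"),
      params = list(assay = "atac")), class = "qtl_result")
  }
  ca <- list(vehicle = stub("pk", TRUE, "ca"), stim = stub("pk", TRUE, "ca"))
  e_stim_only <- list(vehicle = stub("gn", FALSE, "e_hi"),
                      stim = stub("gn", TRUE, "e_hi"))
  out <- link_and_classify_priming(ca, e_stim_only, g, peaks, genes,
                                   condition_pair = c("vehicle", "stim"))
  expect_equal(out$label, "primed")
  # same pattern but low-LD eSNP: unlinked
  e_lo <- list(vehicle = stub("gn", FALSE, "e_lo"), stim = stub("gn", TRUE, "e_lo"))
  out2 <- link_and_classify_priming(ca, e_lo, g, peaks, genes,
                                    condition_pair = c("vehicle", "stim"))
  expect_equal(out2$label, "unlinked")
  # stimulus-specific and shared patterns
  ca_stim <- list(vehicle = stub("pk", FALSE, "ca"), stim = stub("pk", TRUE, "ca"))
  out3 <- link_and_classify_priming(ca_stim, e_stim_only, g, peaks, genes,
                                    condition_pair = c("vehicle", "stim"))
  expect_equal(out3$label, "stimulus_specific")
  e_both <- list(vehicle = stub("gn", TRUE, "e_hi"), stim = stub("gn", TRUE, "e_hi"))
  out4 <- link_and_classify_priming(ca, e_both, g, peaks, genes,
                                    condition_pair = c("vehicle", "stim"))
  expect_equal(out4$label, "shared")
  # labels partition candidates: one label per pair
  expect_equal(nrow(out4), 1)
})
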