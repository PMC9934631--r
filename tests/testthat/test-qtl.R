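sim_cond <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_donors = 60, conditions = "vehicle", n_variants = 1500,
                        n_chrom = 2, n_peaks = 80, n_genes = 80,
                        missing_rate = 0, frac_caqtl = 0.3,
                        scenario_mix = c(shared = 1), target_r2 = 0.2,
                        frac_wre = 0, frac_deg = 0, frac_eqtl = 0,
                        n_gwas_loci = 0, seed = 77)
      sim <- suppressWarnings(simulate_dataset(cfg))
      norm <- normalize_counts(sim$atac, gc = sim$peaks$gc, n_pcs = 0)
      cache <<- list(sim = sim, norm = norm,
                     sheet = sim$sheet)
    }
    cache
  }
})

test_that("cis-pair construction applies windows and variant filters", {
  set.seed(1)
  # hand-built genotypes: one common variant, one rare, one single-carrier
  dos <- rbind(
    common = rbinom(200, 2, 0.4),
    rare = c(1, rep(0, 199)),                 # MAF 0.25%: fails MAF and carriers
    onecarrier = c(2, rep(0, 199)),           # MAF 1%, one carrier
    hwe_bad = rep(1, 200)                     # all het: HWE p << 1e-6
  )
  colnames(dos) <- paste0("D", 1:200)
  g <- geno_matrix(dos, tibble::tibble(
    chrom = "chr1", pos = c(1000L, 1100L, 1200L, 1300L),
    id = rownames(dos), ref = "A", alt = "G"))
  peaks <- tibble::tibble(chrom = "chr1", start = 500, end = 1500, name = "pk")
  pairs <- build_cis_pairs(peaks, g, colnames(dos), assay = "atac")
  expect_equal(pairs$variant, "common")
  # window boundary: peak_end + 25000 inclusive, +25001 excluded
  g2 <- geno_matrix(rbind(a = rbinom(100, 2, 0.4), b = rbinom(100, 2, 0.4)),
                    tibble::tibble(chrom = "chr1", pos = c(26500L, 26501L),
                                   id = c("a", "b"), ref = "A", alt = "G"))
  colnames(g2$dosage) <- paste0("D", 1:100)
  g2$samples <- colnames(g2$dosage)
  pk2 <- tibble::tibble(chrom = "chr1", start = 1000, end = 1500, name = "pk2")
  p2 <- build_cis_pairs(pk2, g2, g2$samples, assay = "atac")
  expect_equal(p2$variant, "a")
})

test_that("gene expression filter removes weakly expressed genes", {
  sc <- rbind(hi = rep(50, 100), lo = rep(2, 100))
  colnames(sc) <- paste0("s", 1:100)
  g <- tiny_geno()
  genes <- tibble::tibble(chrom = "chr1", start = 1, end = 500,
                          name = c("hi", "lo"))
  pairs <- build_cis_pairs(genes, g, g$samples, assay = "rna",
                           scaled_counts = sc, maf_min = 0, min_carriers = 0)
  expect_true(all(pairs$feature == "hi"))
})

test_that("association scan recovers exact and planted relationships", {
  g <- tiny_geno()
  sheet <- tibble::tibble(sample_id = paste0("s", 1:6),
                          donor_id = paste0("D", 1:6), condition = "vehicle")
  y <- matrix(0.5 * g$dosage["v1", ], 1, 6,
              dimnames = list("ft", sheet$sample_id))
  rec <- assoc_scan(y, g, tibble::tibble(feature = "ft", variant = "v1"), sheet)
  expect_equal(rec$beta, 0.5, tolerance = 1e-10)
  expect_lt(rec$p_nominal, 1e-8)
  # constant genotype is skipped with a reason
  gc_ <- geno_matrix(rbind(v9 = rep(1, 6)),
                     tibble::tibble(chrom = "chr1", pos = 1L, id = "v9",
                                    ref = "A", alt = "G"))
  colnames(gc_$dosage) <- paste0("D", 1:6); gc_$samples <- colnames(gc_$dosage)
  rec2 <- assoc_scan(y, gc_, tibble::tibble(feature = "ft", variant = "v9"), sheet)
  expect_equal(nrow(rec2), 0)
  expect_match(attr(rec2, "skipped")$reason, "constant")
})

test_that("scan p-values are uniform under permuted phenotypes", {
  cc <- sim_cond()
  set.seed(8)
  resid <- cc$norm$residuals
  resid_perm <- resid[, sample(ncol(resid))]
  colnames(resid_perm) <- colnames(resid)
  pairs <- build_cis_pairs(cc$sim$peaks, cc$sim$genotypes,
                           unique(cc$sheet$donor_id), assay = "atac")
  rec <- assoc_scan(resid_perm, cc$sim$genotypes, pairs, cc$sheet)
  sub <- rec$p_nominal[sample(nrow(rec), min(5000, nrow(rec)))]
  expect_gt(suppressWarnings(ks.test(sub, "punif"))$p.value, 0.001)
})

test_that("eigenMT effective test counts respect the LD structure", {
  cc <- sim_cond()
  g <- cc$sim$genotypes
  # rank-1: 50 copies of one variant
  dup <- g$dosage[rep(1, 50), ]
  lc <- eigenmt_local(runif(50), dup, 1:50)
  expect_equal(lc$m_eff, 1L)
  expect_equal(lc$p_local, min(1, lc$p_min))
  # 50 independent variants at large n
  set.seed(9)
  ind <- matrix(rbinom(50 * 500, 2, 0.3), 50, 500)
  lci <- eigenmt_local(runif(50), ind, 1:50)
  expect_gte(lci$m_eff, 45L)
  expect_lte(lci$m_eff, 50L)
  # m_eff never exceeds the variant count; invariant to rescaling
  blk <- g$dosage[1:40, ]
  l1 <- eigenmt_local(runif(40), blk, 1:40)
  l2 <- eigenmt_local(runif(40), blk * 3.7, 1:40)
  expect_lte(l1$m_eff, 40L)
  expect_equal(l1$m_eff, l2$m_eff)
})

test_that("permutation correction follows its empirical formula and beta fit", {
  set.seed(10)
  n <- 60
  X <- matrix(rbinom(5 * n, 2, 0.3), 5, n)
  # strong signal: observed min-p below every permutation
  y <- X[1, ] * 2 + rnorm(n, 0, 0.5)
  pl <- permutation_local(y, X, n_perm = 1000, beta_approx = FALSE)
  expect_equal(pl$p_empirical, 1 / 1001)
  # single variant: gene-level p tracks nominal p
  X1 <- X[1, , drop = FALSE]
  y0 <- rnorm(n)
  pl1 <- permutation_local(y0, X1, n_perm = 2000)
  xc <- X1[1, ] - mean(X1[1, ]); yc <- y0 - mean(y0)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p_nom <- 2 * pt(-abs(tt), n - 2)
  expect_lt(abs(pl1$p_empirical - p_nom), 0.05)
  expect_warning(permutation_local(y0, X1, n_perm = 50), "unreliable")
})

test_that("beta approximation agrees with the empirical permutation p", {
  cc <- sim_cond()
  g <- cc$sim$genotypes
  set.seed(11)
  devs <- replicate(40, {
    idx <- sample(nrow(g$dosage) - 30, 1) + 0:29
    y <- rnorm(ncol(g$dosage))
    pl <- permutation_local(y, g$dosage[idx, ], n_perm = 500)
    abs(pl$p_local - pl$p_empirical)
  })
  expect_lt(max(devs), 0.06)
})

test_that("global correction reproduces BH and back-calculates thresholds", {
  cr <- tibble::tibble(feature = c("a", "b", "c"),
                       p_min = c(1e-5, 0.02, 0.5),
                       m_eff = c(10L, 5L, 20L),
                       p_local = pmin(1, p_min * m_eff))
  out <- global_correct(cr, fdr = 0.1)
  expect_equal(out$p_global, p.adjust(out$p_local, "BH"))
  p_star <- attr(out, "p_star")
  sig <- out[out$significant, ]
  expect_true(all(sig$nominal_threshold * sig$m_eff <= p_star + 1e-12))
  # single feature at p_local 0.05 is significant at FDR 0.1
  one <- global_correct(tibble::tibble(feature = "x", p_min = 0.005,
                                       m_eff = 10L, p_local = 0.05), fdr = 0.1)
  expect_true(one$significant)
  # all p_local = 1: nothing significant
  none <- global_correct(tibble::tibble(feature = letters[1:3], p_min = 1,
                                        m_eff = 1L, p_local = 1))
  expect_false(any(none$significant))
  expect_equal(nrow(global_correct(cr[0, ])), 0)
})

test_that("every flagged variant obeys the back-calculated nominal threshold", {
  cc <- sim_cond()
  q <- map_qtl(cc$norm$residuals, cc$sim$genotypes, cc$sim$peaks, cc$sheet,
               assay = "atac", seed = 3)
  p_star <- attr(q$corrections, "p_star")
  snps <- significant_snps(q)
  if (nrow(snps)) {
    meff <- setNames(q$corrections$m_eff, q$corrections$feature)
    expect_true(all(snps$p_nominal * meff[snps$feature] <= p_star + 1e-12))
  }
  expect_true(all(q$corrections$p_local >= q$corrections$p_min - 1e-12))
  expect_true(all(q$corrections$m_eff <=
                    table(q$records$feature)[q$corrections$feature]))
})

test_that("LD pruning keeps one index per linked cluster", {
  cc <- sim_cond()
  g <- cc$sim$genotypes
  vt <- g$variants
  # two variants in near-perfect LD: one index
  pair_ids <- vt$id[1:2]
  rec <- tibble::tibble(feature = "ft", variant = pair_ids,
                        beta = c(1, 0.9), se = 0.1, t = 10,
                        p_nominal = c(1e-8, 2e-8), n = 60)
  r2 <- ld_r2(g$dosage[pair_ids, ])[1, 2]
  out <- independent_signals(rec, g, nominal_threshold = 1e-6, mode = "prune")
  if (r2 >= 0.2) expect_equal(nrow(out), 1) else expect_equal(nrow(out), 2)
  # two distant variants (different blocks) with low LD: two signals
  far_ids <- vt$id[c(1, 600)]
  rec2 <- tibble::tibble(feature = "ft", variant = far_ids,
                         beta = c(1, 0.9), se = 0.1, t = 10,
                         p_nominal = c(1e-8, 2e-8), n = 60)
  expect_equal(nrow(independent_signals(rec2, g, 1e-6, mode = "prune")), 2)
})

test_that("conditional mode rarely invents secondary signals at single-causal loci", {
  cc <- sim_cond()
  sim <- cc$sim
  q <- map_qtl(cc$norm$residuals, sim$genotypes, sim$peaks, cc$sheet,
               assay = "atac", signal_mode = "conditional", seed = 4)
  sig <- q$signals
  if (!is.null(sig) && nrow(sig)) {
    n_secondary <- sum(sig$tier == "conditional_secondary")
    n_features <- length(unique(sig$feature))
    expect_lte(n_secondary / n_features, 0.15)
  } else {
    succeed()
  }
})
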