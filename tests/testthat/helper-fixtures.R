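# Small in-code fixtures shared across test files.

# A tiny deterministic genotype matrix: 4 variants x 6 samples.
tiny_geno <- function() {
  dos <- rbind(
    c(0, 1, 2, 0, 1, 2),
    c(0, 1, 2, 0, 1, 2),   # perfect LD with variant 1
    c(2, 1, 0, 2, 1, 0),   # mirrored (r = -1)
    c(0, 0, 1, 1, 0, 2)
  )
  colnames(dos) <- paste0("D", 1:6)
  geno_matrix(dos, tibble::tibble(
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
    id = paste0("v", 1:4), ref = "A", alt = "G"))
}

# Small simulated dataset reused by several files (built once per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_donors = 30, conditions = c("vehicle", "stimA"),
                        n_variants = 800, n_chrom = 2, n_peaks = 60,
                        n_genes = 60, missing_rate = 0.05,
                        frac_caqtl = 0.2, frac_wre = 0.2, frac_deg = 0.2,
                        n_gwas_loci = 2, gwas_n = 5000,
                        gwas_region_halfwidth = 80000, seed = 101)
      cache <<- suppressWarnings(simulate_dataset(cfg))
    }
    cache
  }
})

# Brute-force BH oracle: direct definition of the step-up procedure.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# Brute-force exact HWE oracle: enumerate all heterozygote counts.
hwe_oracle <- function(aa, ab, bb) {
  n <- aa + ab + bb
  na <- 2 * bb + ab
  nb <- 2 * n - na
  nm <- min(na, nb)
  hets <- seq(nm %% 2, nm, by = 2)
  pr <- vapply(hets, function(h) {
    hom_min <- (nm - h) / 2
    hom_maj <- n - h - hom_min
    exp(lfactorial(n) - lfactorial(hom_min) - lfactorial(h) - lfactorial(hom_maj) +
          h * log(2) + lfactorial(na) + lfactorial(nb) - lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(ab, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}
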