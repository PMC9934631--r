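#' Median-of-ratios size factors
#'
#' Per-sample factors computed over features with no zero count:
#' factor_s = median_j(count_js / geomean_j), rescaled to geometric mean 1.
#' When no all-positive feature exists the upper-quartile fallback is used
#' with a warning.
#'
#' @param counts integer matrix, features x samples.
#' @return named numeric vector of size factors (geometric mean 1).
#' @export
size_factors <- function(counts) {
  if (ncol(counts) < 2) abort("size_factors needs >= 2 samples")
  pos <- rowSums(counts == 0) == 0
  if (!any(pos)) {
    warn("no feature with all-positive counts; falling back to upper-quartile factors")
    f <- apply(counts, 2, quantile, probs = 0.75)
  } else {
    lg <- log(counts[pos, , drop = FALSE])
    gm <- rowMeans(lg)
    f <- exp(apply(lg - gm, 2, median))
  }
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Binned GC-content offsets
#'
#' Per sample, features are binned into GC quantile bins; the bin offset is
#' the median log2 ratio of the sample's (size-factor scaled) count to the
#' feature's cross-sample mean, and the per-feature offset is the linear
#' interpolation of the bin medians at the feature's GC value.
#'
#' @param counts integer matrix, features x samples.
#' @param gc numeric vector of per-feature GC fractions.
#' @param n_bins number of GC quantile bins.
#' @param sf optional size factors (defaults to [size_factors()]).
#' @return features x samples matrix of log2 offsets (subtract downstream).
#' @export
gc_normalize <- function(counts, gc, n_bins = 20, sf = NULL) {
  stopifnot(length(gc) == nrow(counts))
  if (diff(range(gc)) < 1e-12) {
    return(matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts)))
  }
  sf <- sf %||% size_factors(counts)
  # keep bins populated (>= ~20 features) so offsets track GC, not features
  n_bins <- max(2, min(n_bins, floor(nrow(counts) / 20)))
  if (nrow(counts) < 40) {
    warn("too few features for GC binning; returning zero offsets")
    return(matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts)))
  }
  lv <- log2(sweep(counts + 0.5, 2, sf, "/"))
  mu <- rowMeans(lv)
  ratio <- lv - mu
  qs <- unique(quantile(gc, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(gc, breaks = qs, include.lowest = TRUE)
  centers <- tapply(gc, bin, median)
  offsets <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (s in seq_len(ncol(counts))) {
    med <- tapply(ratio[, s], bin, median)
    ok <- !is.na(med)
    if (sum(ok) < 2) next
    offsets[, s] <- approx(centers[ok], med[ok], xout = gc, rule = 2)$y
  }
  offsets
}

#' Shifted-log variance-stabilizing transform
#'
#' value = log2(count / size_factor + pseudocount) - gc_offset. A simple,
#' closed-form transform putting counts on a scale where downstream models
#' are linear.
#'
#' @param counts integer matrix, features x samples.
#' @param sf size factors (default [size_factors()]).
#' @param gc_offsets optional log2 offset matrix from [gc_normalize()].
#' @param pseudocount added inside the log.
#' @return a `norm_matrix`: numeric matrix with a `provenance` attribute.
#' @export
vst_like <- function(counts, sf = NULL, gc_offsets = NULL, pseudocount = 0.5) {
  sf <- sf %||% size_factors(counts)
  if (any(sf <= 0)) abort("size factors must be positive")
  v <- log2(sweep(counts, 2, sf, "/") + pseudocount)
  if (!is.null(gc_offsets)) v <- v - gc_offsets
  structure(v, class = c("norm_matrix", "matrix", "array"),
            provenance = list(size_factors = sf,
                              gc_corrected = !is.null(gc_offsets),
                              n_pcs_removed = 0L, transform = "log2-shifted"))
}

#' Remove latent factors by principal-component residualization
#'
#' Features are centered, the top sample-space PCs are computed by SVD, and
#' each feature is regressed on them. Either the residual matrix (default)
#' or the PC scores for use as fixed covariates can be consumed downstream.
#'
#' @param norm a matrix from [vst_like()] (features x samples).
#' @param n_pcs number of PCs to remove; capped at n_samples/4 with a warning.
#' @return list with `residuals` (same shape, feature-centered) and `pcs`
#'   (samples x n_pcs score matrix, orthonormal columns).
#' @export
pca_residualize <- function(norm, n_pcs = 10) {
  n <- ncol(norm)
  if (n_pcs >= n) abort("n_pcs must be < n_samples")
  cap <- floor(n / 4)
  if (n_pcs > cap) {
    warn(sprintf("n_pcs reduced from %d to %d (n_samples/4 cap)", n_pcs, cap))
    n_pcs <- cap
  }
  x <- norm - rowMeans(norm)
  if (n_pcs == 0) {
    res <- structure(as.matrix(x), class = class(norm))
    attr(res, "provenance") <- c(attr(norm, "provenance")[setdiff(names(attr(norm, "provenance")), "n_pcs_removed")], list(n_pcs_removed = 0L))
    return(list(residuals = res, pcs = matrix(0, n, 0)))
  }
  sv <- svd(x, nu = 0, nv = n_pcs)
  V <- sv$v
  rownames(V) <- colnames(norm)
  resid <- x - (x %*% V) %*% t(V)
  prov <- attr(norm, "provenance")
  prov$n_pcs_removed <- n_pcs
  res <- structure(as.matrix(resid), class = c("norm_matrix", "matrix", "array"),
                   provenance = prov)
  list(residuals = res, pcs = V)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: heterozygote counts compatible with the observed
#' allele counts are enumerated, and the two-sided p-value is the total
#' probability of outcomes no more likely than the observed one.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) abort("negative genotype counts")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) return(1)
  na <- 2 * n_hom_alt + n_het        # alt allele count
  nb <- 2 * n - na
  n_minor <- min(na, nb)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  lp <- lgamma(n + 1) - lgamma((n_minor - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma(n - (n_minor + hets) / 2 + 1) + hets * log(2) +
    lgamma(na + 1) + lgamma(nb + 1) - lgamma(2 * n + 1)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  if (is.na(obs)) abort("observed het count incompatible with allele counts")
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Genotype principal components and genomic-relationship kinship
#'
#' Dosages are standardized per variant by sqrt(2 f (1-f)); the kinship is
#' K = Z'Z / M over donors, and ancestry PCs are the leading eigenvectors of
#' K. Monomorphic variants are excluded before standardization and missing
#' dosages are mean-imputed.
#'
#' @param genotypes a [geno_matrix()].
#' @param n_pcs number of ancestry components to return.
#' @return list with `kinship` (donors x donors) and `pcs` (donors x n_pcs).
#' @export
genotype_pcs_and_kinship <- function(genotypes, n_pcs = 10) {
  dos <- mean_impute_rows(genotypes$dosage)
  f <- rowMeans(dos) / 2
  poly <- f > 0 & f < 1
  dos <- dos[poly, , drop = FALSE]
  f <- f[poly]
  z <- (dos - 2 * f) / sqrt(2 * f * (1 - f))
  K <- crossprod(z) / nrow(z)
  dimnames(K) <- list(genotypes$samples, genotypes$samples)
  ev <- eigen(K, symmetric = TRUE)
  n_pcs <- min(n_pcs, ncol(K) - 1)
  pcs <- ev$vectors[, seq_len(n_pcs), drop = FALSE]
  rownames(pcs) <- genotypes$samples
  colnames(pcs) <- paste0("gPC", seq_len(n_pcs))
  list(kinship = K, pcs = pcs)
}

#' One-step normalization for an assay
#'
#' Convenience wrapper: size factors, GC offsets (when `gc` supplied),
#' shifted-log transform, then PC residualization.
#'
#' @param counts integer matrix, features x samples.
#' @param gc optional per-feature GC fraction.
#' @param n_pcs PCs to remove (see [pca_residualize()]).
#' @return list with `norm` (transformed matrix), `residuals`, `pcs`,
#'   `size_factors`.
#' @export
normalize_counts <- function(counts, gc = NULL, n_pcs = 10) {
  sf <- size_factors(counts)
  off <- if (!is.null(gc)) gc_normalize(counts, gc, sf = sf) else NULL
  v <- vst_like(counts, sf = sf, gc_offsets = off)
  pr <- pca_residualize(v, n_pcs = n_pcs)
  list(norm = v, residuals = pr$residuals, pcs = pr$pcs, size_factors = sf)
}
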