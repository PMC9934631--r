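#' Build cis feature-variant test pairs with the standard variant filters
#'
#' Windows are peak +/- 25 kb (caQTL) or gene body +/- 1 Mb (eQTL), boundary
#' inclusive, under 1-based variant / half-open interval arithmetic. Variant
#' filters, computed on the supplied donor subset: MAF >= 1%, exact
#' Hardy-Weinberg p >= 1e-6, at least two carriers of the minor allele, and
#' (when the variants table has an `r2` column) imputation quality >= 0.3.
#' For the RNA assay, genes with fewer than 1% of samples reaching 10
#' size-factor-scaled counts are excluded as untestable.
#'
#' @param features interval tibble (chrom, start, end, name; genes also
#'   strand/tss).
#' @param genotypes a [geno_matrix()].
#' @param donors donor ids of the analysis subset (filters are computed here).
#' @param assay `"atac"` (peak windows) or `"rna"` (gene windows).
#' @param window window half-width in bp; defaults 25000 (atac) / 1e6 (rna).
#' @param scaled_counts optional counts/size-factor matrix for the gene
#'   expression filter (rna only).
#' @param maf_min,hwe_p_min,min_carriers,impute_r2_min filter thresholds.
#' @return tibble: feature, variant, distance (bp, signed; 0 inside the
#'   feature). Features with zero passing variants are absent (untestable).
#' @export
build_cis_pairs <- function(features, genotypes, donors,
                            assay = c("atac", "rna"), window = NULL,
                            scaled_counts = NULL,
                            maf_min = 0.01, hwe_p_min = 1e-6,
                            min_carriers = 2, impute_r2_min = 0.3) {
  assay <- match.arg(assay)
  window <- window %||% if (assay == "atac") 25000 else 1e6
  dos <- genotypes$dosage[, donors, drop = FALSE]
  hard <- round(mean_impute_rows(dos))
  f <- rowMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  minor_is_alt <- f <= 0.5
  carriers <- ifelse(minor_is_alt, rowSums(hard >= 1), rowSums(hard <= 1))
  hwe_p <- vapply(seq_len(nrow(hard)), function(i) {
    tab <- tabulate(hard[i, ] + 1L, nbins = 3L)
    hwe_exact_test(tab[1], tab[2], tab[3])
  }, numeric(1))
  pass <- maf >= maf_min & hwe_p >= hwe_p_min & carriers >= min_carriers
  if ("r2" %in% names(genotypes$variants)) {
    pass <- pass & (is.na(genotypes$variants$r2) |
                      genotypes$variants$r2 >= impute_r2_min)
  }
  vt <- genotypes$variants[pass, ]

  feats <- features
  if (assay == "rna" && !is.null(scaled_counts)) {
    sc <- scaled_counts[, , drop = FALSE]
    ok <- rowMeans(sc >= 10) >= 0.01
    feats <- feats[feats$name %in% rownames(sc)[ok], ]
  }
  out <- vector("list", nrow(feats))
  for (i in seq_len(nrow(feats))) {
    fi <- feats[i, ]
    vv <- vt[vt$chrom == fi$chrom &
               pos_in_interval(vt$pos, fi$start - window, fi$end + window), ]
    if (!nrow(vv)) next
    dist <- ifelse(vv$pos <= fi$start, vv$pos - (fi$start + 1L),
                   ifelse(vv$pos > fi$end, vv$pos - fi$end, 0L))
    out[[i]] <- tibble(feature = fi$name, variant = vv$id, distance = dist)
  }
  list_rbind(out[!vapply(out, is.null, logical(1))])
}

# Residualize columns of m (samples x k) on covariates (with intercept).
residualize_on <- function(m, covariates) {
  z <- cbind(1, as.matrix(covariates))
  q <- qr.Q(qr(z))
  m - q %*% crossprod(q, m)
}

#' Per-pair ordinary least squares association scan
#'
#' Phenotypes are assumed PC-residualized (or covariates are passed as fixed
#' terms and projected out of both phenotype and genotype, Frisch-Waugh).
#' Missing dosages are mean-imputed. Optionally a kinship random effect is
#' included EMMAX-style: the variance ratio is fitted once per feature under
#' the null and the data are rotated before the per-variant OLS.
#'
#' @param resid normalized residual matrix (features x samples).
#' @param genotypes a [geno_matrix()].
#' @param pairs tibble from [build_cis_pairs()].
#' @param sheet sample sheet restricted to one condition (maps sample to
#'   donor).
#' @param covariates optional samples x q numeric matrix of fixed covariates.
#' @param kinship optional donor kinship matrix for a GLS scan.
#' @return tibble: feature, variant, beta, se, t, p_nominal, n. Pairs whose
#'   genotype is constant on the subset are skipped (attribute `skipped`).
#' @export
assoc_scan <- function(resid, genotypes, pairs, sheet,
                       covariates = NULL, kinship = NULL) {
  samples <- intersect(colnames(resid), sheet$sample_id)
  ord <- match(samples, sheet$sample_id)
  if (!is.null(covariates) && nrow(as.matrix(covariates)) == nrow(sheet)) {
    covariates <- as.matrix(covariates)[ord, , drop = FALSE]
  }
  sheet <- sheet[ord, ]
  donors <- sheet$donor_id
  y_all <- resid[, samples, drop = FALSE]
  dos <- mean_impute_rows(genotypes$dosage)[, donors, drop = FALSE]
  n <- length(samples)
  q <- 0L
  if (!is.null(kinship)) {
    K <- kinship[donors, donors]
    ek <- eigen(K, symmetric = TRUE)
    rot <- t(ek$vectors)
    lam <- pmax(ek$values, 1e-8)
    y_all <- y_all %*% t(rot) # features x samples, rotated
    dos <- dos %*% t(rot)
    if (!is.null(covariates)) covariates <- rot %*% as.matrix(covariates)
  }
  if (!is.null(covariates)) {
    q <- ncol(as.matrix(covariates))
    y_all <- t(residualize_on(t(y_all), covariates))
    dos <- t(residualize_on(t(dos), covariates))
  }
  skipped <- list()
  res <- vector("list", length(unique(pairs$feature)))
  k <- 0L
  for (ft in unique(pairs$feature)) {
    if (!ft %in% rownames(y_all)) next
    vids <- pairs$variant[pairs$feature == ft]
    X <- dos[vids, , drop = FALSE]
    y <- y_all[ft, ]
    w <- rep(1, n)
    if (!is.null(kinship)) {
      dl <- fit_delta_null(y, lam)
      w <- 1 / (lam + dl)
    }
    sw <- sum(w)
    ym <- sum(w * y) / sw
    yc <- y - ym
    xm <- (X %*% w) / sw
    Xc <- X - drop(xm)
    xx <- drop((Xc^2) %*% w)
    keep <- xx > 1e-10
    if (any(!keep)) {
      skipped[[length(skipped) + 1]] <- tibble(
        feature = ft, variant = vids[!keep], reason = "constant genotype on subset")
    }
    if (!any(keep)) next
    Xk <- Xc[keep, , drop = FALSE]
    xy <- drop(Xk %*% (w * yc))
    xxk <- xx[keep]
    beta <- xy / xxk
    yy <- sum(w * yc^2)
    df <- n - 2 - q
    rss <- pmax(yy - beta^2 * xxk, 0)
    se <- sqrt(pmax(rss / df, 1e-300) / xxk)
    tval <- beta / se
    k <- k + 1L
    res[[k]] <- tibble(feature = ft, variant = vids[keep], beta = unname(beta),
                       se = unname(se), t = unname(tval),
                       p_nominal = pmin(1, 2 * pt(-abs(tval), df = df)), n = n)
  }
  out <- list_rbind(res[seq_len(k)])
  structure(out, skipped = if (length(skipped)) list_rbind(skipped) else NULL,
            df_resid = n - 2 - q)
}

# Null-model ML fit of delta = sigma2_e/sigma2_g on rotated data (EMMAX-like).
fit_delta_null <- function(y_rot, lam) {
  nll <- function(logd) {
    d <- exp(logd)
    v <- lam + d
    sum(log(v)) + length(y_rot) * log(sum(y_rot^2 / v))
  }
  exp(optimize(nll, c(-10, 10))$minimum)
}

#' eigenMT local multiple-testing correction
#'
#' Estimates the effective number of independent tests from eigenvalues of
#' the cis genotype correlation matrix, computed in windows of at most
#' `window` position-ordered variants: per window, m_eff is the smallest k
#' whose top-k eigenvalues reach `var_explained` of the trace, and the
#' feature's m_eff is the sum over windows. The locally adjusted p-value is
#' min(1, p_min * m_eff).
#'
#' @param p_nominal named (by variant id) nominal p-values for one feature.
#' @param dosage cis dosage matrix (variants x samples), rows in any order.
#' @param positions variant positions (for ordering), aligned with rows.
#' @param window maximum variants per eigen window.
#' @param var_explained eigenvalue mass cutoff.
#' @return list: p_min, m_eff, p_local.
#' @export
eigenmt_local <- function(p_nominal, dosage, positions,
                          window = 200, var_explained = 0.99) {
  stopifnot(length(p_nominal) == nrow(dosage))
  ord <- order(positions)
  dos <- mean_impute_rows(dosage[ord, , drop = FALSE])
  sds <- apply(dos, 1, sd)
  dos <- dos[sds > 0, , drop = FALSE]
  m <- nrow(dos)
  m_eff <- 0L
  if (m > 0) {
    starts <- seq(1, m, by = window)
    for (s in starts) {
      idx <- s:min(s + window - 1, m)
      if (length(idx) == 1) {
        m_eff <- m_eff + 1L
        next
      }
      cc <- cor(t(dos[idx, , drop = FALSE]))
      ev <- sort(eigen(cc, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
      m_eff <- m_eff + which(cumsum(ev) >= var_explained * sum(ev))[1]
    }
  } else {
    m_eff <- 1L
  }
  p_min <- min(p_nominal)
  list(p_min = p_min, m_eff = as.integer(m_eff),
       p_local = min(1, p_min * m_eff))
}

#' Permutation-based local correction with Beta approximation
#'
#' The phenotype is permuted across samples; the empirical gene-level
#' p-value is (1 + #\{permutation min-p <= observed\})/(1 + n_perm). With
#' `beta_approx` a Beta(a, b) distribution is fitted to the permutation
#' minimum p-values by method of moments and its CDF at the observed
#' minimum is reported instead (smooth tail).
#'
#' @param y phenotype vector (residualized).
#' @param dosage cis dosage matrix (variants x samples).
#' @param n_perm number of permutations.
#' @param beta_approx report the Beta-CDF adjusted p (default TRUE).
#' @param df_resid residual df of the nominal scan (n - 2 by default).
#' @return list: p_min, p_empirical, p_local, beta_a, beta_b.
#' @export
permutation_local <- function(y, dosage, n_perm = 1000, beta_approx = TRUE,
                              df_resid = NULL) {
  if (n_perm < 100) warn("n_perm < 100: permutation tail unreliable")
  n <- length(y)
  df <- df_resid %||% (n - 2)
  X <- mean_impute_rows(dosage)
  Xc <- X - rowMeans(X)
  xs <- sqrt(rowSums(Xc^2))
  keep <- xs > 1e-8
  Xc <- Xc[keep, , drop = FALSE]; xs <- xs[keep]
  yc <- y - mean(y)
  ys <- sqrt(sum(yc^2))
  r_obs <- drop(Xc %*% yc) / (xs * ys)
  r2_obs <- max(r_obs^2)
  P <- vapply(seq_len(n_perm), function(b) sample.int(n), integer(n))
  Yp <- matrix(yc[P], n, n_perm)
  ysp <- sqrt(colSums(Yp^2))
  R <- (Xc %*% Yp) / outer(xs, ysp)
  r2_perm <- apply(R^2, 2, max)
  r2_to_p <- function(r2) {
    tt <- sqrt(pmax(r2, 0) * df / pmax(1 - r2, 1e-12))
    pmin(1, 2 * pt(-tt, df = df))
  }
  p_min <- r2_to_p(r2_obs)
  p_perm <- r2_to_p(r2_perm)
  p_emp <- (1 + sum(p_perm <= p_min)) / (1 + n_perm)
  a <- b <- NA_real_
  p_local <- p_emp
  if (beta_approx) {
    m <- mean(p_perm); v <- var(p_perm)
    if (is.finite(v) && v > 0 && m > 0 && m < 1) {
      common <- m * (1 - m) / v - 1
      a <- m * common; b <- (1 - m) * common
      if (a > 0 && b > 0) p_local <- pbeta(p_min, a, b)
    }
  }
  list(p_min = p_min, p_empirical = p_emp, p_local = min(1, max(p_local, 1e-300)),
       beta_a = a, beta_b = b)
}

#' Global BH correction across features with back-calculated thresholds
#'
#' BH is applied across features to the locally adjusted p-values; features
#' with globally adjusted p < `fdr` are significant. The global cutoff p*
#' is the largest locally adjusted p-value passing BH, and each significant
#' feature's nominal threshold is the nominal p whose local adjustment
#' equals p*: p*/m_eff in eigenMT mode, the inverse Beta CDF at p* in
#' permutation mode.
#'
#' @param corrections tibble with columns feature, p_min, p_local and either
#'   m_eff (eigenMT) or beta_a/beta_b (permutation).
#' @param fdr global FDR level.
#' @return the input tibble plus p_global, significant, nominal_threshold
#'   (NA for non-significant features); attribute `p_star`.
#' @export
global_correct <- function(corrections, fdr = 0.1) {
  if (!nrow(corrections)) {
    return(structure(mutate(corrections, p_global = numeric(0),
                            significant = logical(0),
                            nominal_threshold = numeric(0)), p_star = NA_real_))
  }
  cr <- corrections
  cr$p_global <- bh_adjust(cr$p_local)
  cr$significant <- cr$p_global < fdr
  p_star <- if (any(cr$significant)) max(cr$p_local[cr$significant]) else NA_real_
  cr$nominal_threshold <- NA_real_
  if (!is.na(p_star)) {
    sig <- which(cr$significant)
    if ("m_eff" %in% names(cr) && !all(is.na(cr$m_eff))) {
      cr$nominal_threshold[sig] <- p_star / cr$m_eff[sig]
    }
    if (all(c("beta_a", "beta_b") %in% names(cr))) {
      use_beta <- sig[!is.na(cr$beta_a[sig])]
      cr$nominal_threshold[use_beta] <-
        qbeta(p_star, cr$beta_a[use_beta], cr$beta_b[use_beta])
    }
  }
  structure(cr, p_star = p_star)
}

#' Identify independent signals per significant feature
#'
#' Prune mode (caQTL): significant variants are ranked by p ascending (ties:
#' larger |beta|, then smaller position); the head is taken as an index and
#' all variants with r2 >= `r2_max` to any chosen index are removed,
#' iteratively. Conditional mode (eQTL): the index dosage is added as a
#' covariate, the feature is re-scanned, and a secondary signal is called
#' while the minimum conditional p stays at or below the feature's nominal
#' threshold.
#'
#' @param records scan-tier records of one feature (from [assoc_scan()]).
#' @param genotypes a [geno_matrix()].
#' @param nominal_threshold the feature's back-calculated threshold.
#' @param mode `"prune"` or `"conditional"`.
#' @param resid,sheet,covariates needed in conditional mode (as in
#'   [assoc_scan()]).
#' @param r2_max LD pruning threshold.
#' @param max_signals iteration cap.
#' @return tibble of index/secondary records with a `tier` column.
#' @export
independent_signals <- function(records, genotypes, nominal_threshold,
                                mode = c("prune", "conditional"),
                                resid = NULL, sheet = NULL, covariates = NULL,
                                r2_max = 0.2, max_signals = 5) {
  mode <- match.arg(mode)
  sig <- records[records$p_nominal <= nominal_threshold, ]
  if (!nrow(sig)) return(sig)
  pos <- genotypes$variants$pos[match(sig$variant, genotypes$variants$id)]
  ord <- order(sig$p_nominal, -abs(sig$beta), pos)
  sig <- sig[ord, ]
  if (mode == "prune") {
    chosen <- sig[0, ]
    pool <- sig
    while (nrow(pool) && nrow(chosen) < max_signals) {
      top <- pool[1, ]
      chosen <- bind_rows(chosen, top)
      r2 <- drop(ld_r2(genotypes$dosage[pool$variant, , drop = FALSE],
                       genotypes$dosage[top$variant, , drop = FALSE]))
      r2[is.na(r2)] <- 1 # constant dosage: treat as fully linked, drop
      pool <- pool[r2 < r2_max, , drop = FALSE]
    }
    chosen$tier <- c("independent_index",
                     rep("independent_secondary", max(0, nrow(chosen) - 1)))
    return(chosen)
  }
  # conditional mode
  ft <- sig$feature[1]
  chosen <- sig[1, ]
  chosen$tier <- "independent_index"
  repeat {
    if (nrow(chosen) >= max_signals) break
    cond_dos <- t(genotypes$dosage[chosen$variant, sheet$donor_id, drop = FALSE])
    covs <- if (is.null(covariates)) cond_dos else cbind(covariates, cond_dos)
    pairs_ft <- tibble(feature = ft,
                       variant = setdiff(records$variant, chosen$variant))
    if (!nrow(pairs_ft)) break
    re <- assoc_scan(resid, genotypes, pairs_ft, sheet, covariates = covs)
    if (!nrow(re) || min(re$p_nominal) > nominal_threshold) break
    nxt <- re[which.min(re$p_nominal), ]
    nxt$tier <- "conditional_secondary"
    chosen <- bind_rows(chosen, nxt)
  }
  chosen
}

#' Map cis QTLs for one condition
#'
#' Runs the full per-condition pipeline: cis-pair construction with the
#' variant/feature filters, the OLS scan, local correction (eigenMT for the
#' accessibility assay, permutation for expression, by default), global BH
#' across features with back-calculated nominal thresholds, and
#' independent-signal discovery for significant features.
#'
#' @param resid residualized phenotype matrix (features x samples of one
#'   condition).
#' @param genotypes a [geno_matrix()].
#' @param features interval tibble (peaks or genes).
#' @param sheet sample sheet rows for this condition.
#' @param assay `"atac"` or `"rna"`.
#' @param local_method `"eigenmt"` or `"permutation"`; defaults to eigenmt
#'   for atac, permutation for rna.
#' @param fdr global FDR level.
#' @param n_perm permutations for permutation mode.
#' @param covariates,kinship passed to [assoc_scan()].
#' @param scaled_counts passed to [build_cis_pairs()] for the gene filter.
#' @param signal_mode `"prune"` or `"conditional"`; defaults prune for atac,
#'   conditional for rna.
#' @param seed seed for the permutation streams.
#' @return object of class `qtl_result`: list with `records` (scan tier),
#'   `corrections` (feature tier incl. thresholds), `signals` (index /
#'   secondary tier), `condition`-free metadata in `params`.
#' @export
map_qtl <- function(resid, genotypes, features, sheet,
                    assay = c("atac", "rna"), local_method = NULL,
                    fdr = 0.1, n_perm = 1000, covariates = NULL,
                    kinship = NULL, scaled_counts = NULL,
                    signal_mode = NULL, seed = 1) {
  assay <- match.arg(assay)
  local_method <- local_method %||% if (assay == "atac") "eigenmt" else "permutation"
  signal_mode <- signal_mode %||% if (assay == "atac") "prune" else "conditional"
  samples <- intersect(colnames(resid), sheet$sample_id)
  sheet <- sheet[match(samples, sheet$sample_id), ]
  pairs <- build_cis_pairs(features, genotypes, unique(sheet$donor_id),
                           assay = assay, scaled_counts = scaled_counts)
  pairs <- pairs[pairs$feature %in% rownames(resid), ]
  records <- assoc_scan(resid, genotypes, pairs, sheet,
                        covariates = covariates, kinship = kinship)
  vt <- genotypes$variants
  feats_tested <- unique(records$feature)
  corr <- with_stage_seed(seed, paste0("local_", assay), {
    map(feats_tested, function(ft) {
      rec <- records[records$feature == ft, ]
      idx <- match(rec$variant, vt$id)
      dos <- genotypes$dosage[idx, unique(sheet$donor_id), drop = FALSE]
      if (local_method == "eigenmt") {
        lc <- eigenmt_local(setNames(rec$p_nominal, rec$variant), dos, vt$pos[idx])
        tibble(feature = ft, p_min = lc$p_min, m_eff = lc$m_eff,
               p_local = lc$p_local, beta_a = NA_real_, beta_b = NA_real_)
      } else {
        y <- resid[ft, samples]
        lc <- permutation_local(y, dos, n_perm = n_perm,
                                df_resid = attr(records, "df_resid"))
        tibble(feature = ft, p_min = lc$p_min, m_eff = NA_integer_,
               p_local = lc$p_local, beta_a = lc$beta_a, beta_b = lc$beta_b)
      }
    }) |> list_rbind()
  })
  corr <- global_correct(corr, fdr = fdr)
  signals <- map(corr$feature[which(corr$significant)], function(ft) {
    thr <- corr$nominal_threshold[corr$feature == ft]
    independent_signals(records[records$feature == ft, ], genotypes, thr,
                        mode = signal_mode, resid = resid, sheet = sheet,
                        covariates = covariates)
  }) |> list_rbind()
  structure(
    list(records = records, corrections = corr, signals = signals,
         params = list(assay = assay, local_method = local_method,
                       signal_mode = signal_mode, fdr = fdr,
                       p_star = attr(corr, "p_star"),
                       donors = unique(sheet$donor_id))),
    class = "qtl_result")
}

#' @export
print.qtl_result <- function(x, ...) {
  cat(sprintf(
    "<qtl_result> %s: %d features tested, %d significant (FDR %.2g), %d signal(s)\n",
    x$params$assay, nrow(x$corrections), sum(x$corrections$significant),
    nrow(x$signals %||% tibble())))
  invisible(x)
}

#' @export
tidy.qtl_result <- function(x, ...) {
  left_join(x$corrections,
            summarise(group_by(x$records, .data$feature),
                      n_variants = n(), .groups = "drop"),
            by = "feature")
}

#' @export
glance.qtl_result <- function(x, ...) {
  tibble(assay = x$params$assay, n_features = nrow(x$corrections),
         n_significant = sum(x$corrections$significant),
         p_star = x$params$p_star %||% NA_real_,
         local_method = x$params$local_method)
}

#' Significant variants of a mapped feature at the scan tier
#'
#' All variants whose nominal p is at or below the feature's back-calculated
#' threshold.
#'
#' @param qtl a `qtl_result`.
#' @param feature feature id(s); default all significant features.
#' @return tibble of records with the threshold applied.
#' @export
significant_snps <- function(qtl, feature = NULL) {
  sig_feats <- qtl$corrections$feature[qtl$corrections$significant]
  feature <- feature %||% sig_feats
  feature <- intersect(feature, sig_feats)
  thr <- setNames(qtl$corrections$nominal_threshold, qtl$corrections$feature)
  rec <- qtl$records[qtl$records$feature %in% feature, ]
  rec[rec$p_nominal <= thr[rec$feature], ]
}

#' P-value histogram / QQ panel for a QTL scan
#' @param object a `qtl_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.qtl_result <- function(object, ...) {
  df <- object$records
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_nominal)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05),
                            fill = "grey40", colour = "white") +
    ggplot2::labs(x = "nominal p", y = "variant-feature pairs") +
    ggplot2::theme_minimal()
}
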