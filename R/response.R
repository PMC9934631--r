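#' Genotype-by-condition interaction test (response QTLs)
#'
#' For each feature-variant pair already showing a main effect, fits the
#' random-intercept-per-donor linear mixed model
#' y = SNP + condition + condition:SNP (+ covariates) + (1|Donor) by maximum
#' likelihood and compares it against the model without the interaction term
#' by a likelihood-ratio test on one degree of freedom. For a fixed variance
#' ratio lambda = sigma2_donor / sigma2_resid the GLS solution is closed
#' form after per-donor whitening; lambda is profiled by a bounded 1-D
#' search on log lambda in \[-10, 10\]. Negative LRT statistics are clipped
#' to zero. Unpaired donors are retained (the random intercept absorbs the
#' imbalance).
#'
#' @param resid residualized phenotype matrix (features x samples, both
#'   conditions present).
#' @param genotypes a [geno_matrix()].
#' @param sheet sample sheet rows covering exactly the two conditions.
#' @param qtl_pairs tibble (feature, variant) of index QTLs to test.
#' @param condition_pair c(reference, stimulated) labels; condition is coded
#'   0/1 in that order.
#' @param covariates optional samples x q matrix aligned with `sheet` rows.
#' @param random_intercept set FALSE for the no-random-effect variant of the
#'   model (plain OLS LRT).
#' @return `interaction_result` tibble: feature, variant, beta_vehicle,
#'   beta_stim, beta_interaction, lambda, lrt_chi2, p_interaction, fit
#'   (`"lmm"` or `"ols_fallback"`).
#' @export
fit_interaction_lmm <- function(resid, genotypes, sheet, qtl_pairs,
                                condition_pair, covariates = NULL,
                                random_intercept = TRUE) {
  stopifnot(length(condition_pair) == 2)
  sheet <- sheet[sheet$condition %in% condition_pair, ]
  samples <- intersect(colnames(resid), sheet$sample_id)
  ord <- match(samples, sheet$sample_id)
  if (!is.null(covariates) && nrow(as.matrix(covariates)) >= max(ord)) {
    covariates <- as.matrix(covariates)[ord, , drop = FALSE]
  }
  sheet <- sheet[ord, ]
  both <- intersect(sheet$donor_id[sheet$condition == condition_pair[1]],
                    sheet$donor_id[sheet$condition == condition_pair[2]])
  if (length(both) < 4) abort("fewer than 4 donors with both conditions")
  cond <- as.numeric(sheet$condition == condition_pair[2])
  groups <- split(seq_along(samples), sheet$donor_id)
  dos <- mean_impute_rows(genotypes$dosage)
  out <- vector("list", nrow(qtl_pairs))
  for (i in seq_len(nrow(qtl_pairs))) {
    ft <- qtl_pairs$feature[i]; vv <- qtl_pairs$variant[i]
    if (!ft %in% rownames(resid) || !vv %in% rownames(dos)) next
    y <- resid[ft, samples]
    x <- dos[vv, sheet$donor_id]
    if (sd(x[cond == 0]) < 1e-10 || sd(x[cond == 1]) < 1e-10) {
      out[[i]] <- tibble(feature = ft, variant = vv, beta_vehicle = NA_real_,
                         beta_stim = NA_real_, beta_interaction = NA_real_,
                         lambda = NA_real_, lrt_chi2 = NA_real_,
                         p_interaction = NA_real_,
                         fit = "skipped: genotype constant within a condition")
      next
    }
    Xf <- cbind(1, x, cond, x * cond)
    if (!is.null(covariates)) Xf <- cbind(Xf, covariates)
    Xr <- Xf[, -4, drop = FALSE]
    if (random_intercept) {
      full <- fit_lmm_ml(y, Xf, groups)
      red <- fit_lmm_ml(y, Xr, groups)
      fitlab <- "lmm"
      if (!is.finite(full$ll) || !is.finite(red$ll)) {
        full <- fit_ols_ll(y, cbind(Xf, donor_dummies(sheet$donor_id)))
        red <- fit_ols_ll(y, cbind(Xr, donor_dummies(sheet$donor_id)))
        fitlab <- "ols_fallback"
      }
    } else {
      full <- fit_ols_ll(y, Xf)
      red <- fit_ols_ll(y, Xr)
      fitlab <- "ols"
    }
    lrt <- max(0, 2 * (full$ll - red$ll))
    b <- full$beta
    out[[i]] <- tibble(
      feature = ft, variant = vv,
      beta_vehicle = b[2], beta_stim = b[2] + b[4], beta_interaction = b[4],
      lambda = full$lambda %||% NA_real_, lrt_chi2 = lrt,
      p_interaction = pchisq(lrt, df = 1, lower.tail = FALSE), fit = fitlab)
  }
  res <- list_rbind(out[!vapply(out, is.null, logical(1))])
  structure(res, class = c("interaction_result", class(res)),
            condition_pair = condition_pair)
}

donor_dummies <- function(donor) {
  d <- factor(donor)
  m <- stats::model.matrix(~ d)[, -1, drop = FALSE]
  m
}

# Profiled-ML fit of y = X b + u + e with a per-donor random intercept.
fit_lmm_ml <- function(y, X, groups) {
  n <- length(y)
  gidx <- rep(seq_along(groups), lengths(groups))[order(unlist(groups))]
  k_g <- lengths(groups)
  whiten <- function(loglam) {
    lam <- exp(loglam)
    c_g <- (1 - 1 / sqrt(1 + k_g * lam)) / k_g
    ysum <- rowsum(y, gidx)
    Xsum <- rowsum(X, gidx)
    yw <- y - (c_g * ysum)[gidx]
    Xw <- X - (c_g * Xsum)[gidx, , drop = FALSE]
    list(yw = yw, Xw = Xw, ldet = sum(log1p(k_g * lam)))
  }
  prof_nll <- function(loglam) {
    w <- whiten(loglam)
    fit <- .lm.fit(w$Xw, w$yw)
    rss <- sum(fit$residuals^2)
    n * log(rss / n) + w$ldet
  }
  opt <- optimize(prof_nll, c(-10, 10))
  w <- whiten(opt$minimum)
  fit <- .lm.fit(w$Xw, w$yw)
  rss <- sum(fit$residuals^2)
  ll <- -n / 2 * (log(2 * pi) + 1) - n / 2 * log(rss / n) - w$ldet / 2
  list(ll = ll, beta = unpivot_coef(fit, ncol(X)),
       lambda = exp(opt$minimum), sigma2 = rss / n)
}

# .lm.fit returns coefficients in pivoted order when rank-deficient.
unpivot_coef <- function(fit, p) {
  b <- rep(NA_real_, p)
  b[fit$pivot[seq_len(fit$rank)]] <- fit$coefficients[seq_len(fit$rank)]
  b
}

fit_ols_ll <- function(y, X) {
  n <- length(y)
  fit <- .lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  list(ll = -n / 2 * (log(2 * pi) + 1) - n / 2 * log(rss / n),
       beta = unpivot_coef(fit, ncol(X)), lambda = 0, sigma2 = rss / n)
}

#' Call response QTLs at an FDR threshold
#'
#' BH across the tested index QTLs of one condition pair and assay.
#'
#' @param interactions an `interaction_result`.
#' @param fdr BH threshold (default 0.1).
#' @return the input with `fdr` and `is_response` columns.
#' @export
call_response_qtls <- function(interactions, fdr = 0.1) {
  ok <- !is.na(interactions$p_interaction)
  interactions$fdr <- NA_real_
  interactions$fdr[ok] <- bh_adjust(interactions$p_interaction[ok])
  interactions$is_response <- !is.na(interactions$fdr) & interactions$fdr < fdr
  interactions
}

#' @export
tidy.interaction_result <- function(x, ...) as_tibble(x)

#' @export
glance.interaction_result <- function(x, ...) {
  tibble(n_tested = sum(!is.na(x$p_interaction)),
         n_response = if ("is_response" %in% names(x)) sum(x$is_response) else NA_integer_,
         median_lambda = median(x$lambda, na.rm = TRUE))
}

#' Per-condition effect comparison for interaction results
#' @param object an `interaction_result` (after [call_response_qtls()]).
#' @param ... unused.
#' @return a ggplot of vehicle vs stimulated per-condition betas.
#' @export
autoplot.interaction_result <- function(object, ...) {
  df <- as_tibble(object)
  df$response <- if ("is_response" %in% names(df)) df$is_response else FALSE
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta_vehicle, y = .data$beta_stim,
                                   colour = .data$response)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.7, size = 0.8) +
    ggplot2::labs(x = "beta (vehicle)", y = "beta (stimulated)",
                  colour = "response QTL") +
    ggplot2::theme_minimal()
}

#' Cross-condition sharing of genetically regulated features
#'
#' For each feature, records the subset of conditions in which it has at
#' least one significant QTL, tabulates upset-style combination counts, and
#' reports the stimulated-only increment: features significant only under
#' stimulation as a percentage of features significant in the vehicle
#' condition.
#'
#' @param qtl_by_condition named list (condition -> `qtl_result`, or
#'   condition -> character vector of significant feature ids).
#' @param vehicle label of the vehicle/reference condition.
#' @return list: `membership` (feature x condition logical tibble),
#'   `combo_counts`, `increment_pct`.
#' @export
classify_sharing <- function(qtl_by_condition, vehicle) {
  sets <- map(qtl_by_condition, function(q) {
    if (inherits(q, "qtl_result")) q$corrections$feature[q$corrections$significant]
    else as.character(q)
  })
  if (!vehicle %in% names(sets)) abort("vehicle condition absent from results")
  feats <- sort(unique(unlist(sets)))
  memb <- tibble(feature = feats)
  for (cn in names(sets)) memb[[cn]] <- feats %in% sets[[cn]]
  combo <- memb
  combo$combo <- apply(memb[, names(sets), drop = FALSE], 1, function(r) {
    paste(names(sets)[r], collapse = "+")
  })
  combo_counts <- summarise(group_by(combo, .data$combo), n = n(), .groups = "drop")
  stim <- setdiff(names(sets), vehicle)
  stim_only <- sum(!memb[[vehicle]] &
                     rowSums(as.matrix(memb[, stim, drop = FALSE])) > 0)
  n_veh <- sum(memb[[vehicle]])
  list(membership = memb, combo_counts = combo_counts,
       increment_pct = if (n_veh > 0) 100 * stim_only / n_veh else NA_real_)
}

peak_tss_distance <- function(peak, tss) {
  ifelse(tss <= peak$start, peak$start + 1L - tss,
         ifelse(tss > peak$end, tss - peak$end, 0L))
}

#' Link caPeaks to eGenes and classify enhancer priming
#'
#' Candidate pairs are caPeaks within `max_dist` of an eGene TSS; a pair is
#' linked when at least one significant caSNP and one significant eSNP are
#' in LD r2 >= `r2_link`. Linked pairs are labelled `primed` when the caPeak
#' is significant in both conditions and the eGene only under stimulation;
#' `stimulus_specific` when both assays are stimulation-only; `shared` when
#' both assays are significant in both conditions; otherwise `other`.
#' Non-linked candidates are `unlinked`.
#'
#' @param ca_by_condition,e_by_condition named lists (condition ->
#'   `qtl_result`) for the accessibility and expression assays; must contain
#'   both elements of `condition_pair`.
#' @param genotypes a [geno_matrix()].
#' @param peaks,genes interval tibbles (genes need `tss`).
#' @param condition_pair c(reference, stimulated).
#' @param r2_link LD threshold for linking.
#' @param max_dist peak-to-TSS distance cap (bp).
#' @param snp_tier `"scan"` links through any significant SNP at the
#'   back-calculated threshold; `"index"` restricts to index/secondary SNPs.
#' @return `priming_calls` tibble: peak, gene, label, ca_snp, e_snp, r2,
#'   distance, per-condition significance flags.
#' @export
link_and_classify_priming <- function(ca_by_condition, e_by_condition,
                                      genotypes, peaks, genes,
                                      condition_pair, r2_link = 0.8,
                                      max_dist = 1e6,
                                      snp_tier = c("scan", "index")) {
  snp_tier <- match.arg(snp_tier)
  veh <- condition_pair[1]; stim <- condition_pair[2]
  sig_feats <- function(q) q$corrections$feature[q$corrections$significant]
  snps_of <- function(q, ft) {
    if (snp_tier == "scan") unique(significant_snps(q, ft)$variant)
    else unique(q$signals$variant[q$signals$feature == ft])
  }
  ca_sig <- map(ca_by_condition[condition_pair], sig_feats)
  e_sig <- map(e_by_condition[condition_pair], sig_feats)
  cand_peaks <- union(ca_sig[[veh]], ca_sig[[stim]])
  cand_genes <- union(e_sig[[veh]], e_sig[[stim]])
  if (!length(cand_peaks) || !length(cand_genes)) {
    return(structure(tibble(peak = character(), gene = character(),
                            label = character()), class = c("priming_calls", "tbl_df", "tbl", "data.frame")))
  }
  pk <- peaks[match(cand_peaks, peaks$name), ]
  gn <- genes[match(cand_genes, genes$name), ]
  out <- list()
  for (i in seq_len(nrow(pk))) {
    same <- which(gn$chrom == pk$chrom[i])
    if (!length(same)) next
    dd <- peak_tss_distance(pk[i, ], gn$tss[same])
    same <- same[dd <= max_dist]
    dd <- dd[dd <= max_dist]
    if (!length(same)) next
    ca_snps <- unique(c(snps_of(ca_by_condition[[veh]], pk$name[i]),
                        snps_of(ca_by_condition[[stim]], pk$name[i])))
    for (jj in seq_along(same)) {
      g1 <- gn[same[jj], ]
      e_snps <- unique(c(snps_of(e_by_condition[[veh]], g1$name),
                         snps_of(e_by_condition[[stim]], g1$name)))
      best_r2 <- NA_real_; best_ca <- NA_character_; best_e <- NA_character_
      if (length(ca_snps) && length(e_snps)) {
        r2m <- ld_r2(genotypes$dosage[ca_snps, , drop = FALSE],
                     genotypes$dosage[e_snps, , drop = FALSE])
        bi <- which(r2m == max(r2m, na.rm = TRUE), arr.ind = TRUE)[1, ]
        best_r2 <- r2m[bi[1], bi[2]]
        best_ca <- ca_snps[bi[1]]; best_e <- e_snps[bi[2]]
      }
      linked <- !is.na(best_r2) && best_r2 >= r2_link
      ca_v <- pk$name[i] %in% ca_sig[[veh]]
      ca_s <- pk$name[i] %in% ca_sig[[stim]]
      e_v <- g1$name %in% e_sig[[veh]]
      e_s <- g1$name %in% e_sig[[stim]]
      label <- if (!linked) "unlinked"
      else if (ca_v && ca_s && e_s && !e_v) "primed"
      else if (!ca_v && ca_s && e_s && !e_v) "stimulus_specific"
      else if (ca_v && ca_s && e_v && e_s) "shared"
      else "other"
      out[[length(out) + 1]] <- tibble(
        peak = pk$name[i], gene = g1$name, label = label,
        ca_snp = best_ca, e_snp = best_e, r2 = best_r2,
        distance = dd[jj], ca_vehicle = ca_v, ca_stim = ca_s,
        e_vehicle = e_v, e_stim = e_s)
    }
  }
  res <- if (length(out)) list_rbind(out) else
    tibble(peak = character(), gene = character(), label = character())
  structure(res, class = c("priming_calls", class(res)),
            condition_pair = condition_pair)
}

#' @export
glance.priming_calls <- function(x, ...) {
  as_tibble(as.list(table(factor(x$label,
    levels = c("primed", "stimulus_specific", "shared", "other", "unlinked")))))
}
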