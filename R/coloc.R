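#' Find GWAS-QTL colocalization candidates
#'
#' Step 1-2 of the sharing procedure: genome-wide-significant GWAS SNPs
#' (p < `gw_p`) within `max_dist` of a QTL index variant define candidate
#' loci; a candidate is kept when the GWAS index (smallest-p GW SNP near the
#' QTL) is in LD r2 > `r2_min` with the QTL index, or any GW-significant SNP
#' in the window is.
#'
#' @param sumstats GWAS summary statistics (see [read_sumstats()]).
#' @param qtl_indexes tibble with `feature` and `variant` (QTL index SNPs).
#' @param genotypes LD reference [geno_matrix()].
#' @param gw_p genome-wide significance threshold.
#' @param max_dist distance cap in bp (inclusive).
#' @param r2_min LD threshold for candidacy.
#' @return tibble: feature, qtl_variant, gwas_index, distance, r2_index,
#'   r2_best_gw, candidate.
#' @export
find_candidates <- function(sumstats, qtl_indexes, genotypes,
                            gw_p = 5e-8, max_dist = 1e6, r2_min = 0.6) {
  vt <- genotypes$variants
  shared <- intersect(sumstats$id, vt$id)
  if (!length(shared)) abort("no shared variants between sumstats and LD reference")
  ss <- sumstats[sumstats$id %in% shared, ]
  ss$chrom <- vt$chrom[match(ss$id, vt$id)]
  ss$pos <- vt$pos[match(ss$id, vt$id)]
  gw <- ss[ss$p < gw_p, ]
  out <- list()
  for (i in seq_len(nrow(qtl_indexes))) {
    qv <- qtl_indexes$variant[i]
    qi <- match(qv, vt$id)
    if (is.na(qi)) next
    near <- gw[gw$chrom == vt$chrom[qi] & abs(gw$pos - vt$pos[qi]) <= max_dist, ]
    if (!nrow(near)) next
    gidx <- near$id[which.min(near$p)]
    r2s <- drop(ld_r2(genotypes$dosage[near$id, , drop = FALSE],
                      genotypes$dosage[qv, , drop = FALSE]))
    r2_index <- r2s[match(gidx, near$id)]
    r2_best <- max(r2s, na.rm = TRUE)
    out[[length(out) + 1]] <- tibble(
      feature = qtl_indexes$feature[i], qtl_variant = qv, gwas_index = gidx,
      distance = abs(near$pos[which.min(near$p)] - vt$pos[qi]),
      r2_index = r2_index, r2_best_gw = r2_best,
      candidate = (!is.na(r2_index) && r2_index > r2_min) || r2_best > r2_min)
  }
  if (!length(out)) {
    return(tibble(feature = character(), qtl_variant = character(),
                  gwas_index = character(), distance = numeric(),
                  r2_index = numeric(), r2_best_gw = numeric(),
                  candidate = logical()))
  }
  list_rbind(out)
}

#' Approximate conditional association analysis
#'
#' GCTA-style conditional estimator from summary statistics and a reference
#' LD panel. With D = diag(2 f_j (1 - f_j) n_j) and B the LD-scaled
#' cross-product (B_jk = r_jk sqrt(D_j D_k)), the conditional effect of
#' target t given conditioning set C is b_t - B_tC B_CC^-1 b_C, with
#' variance deflated by (1 - r_tC R_CC^-1 r_Ct). Variants whose summary
#' frequency differs from the reference by more than `freq_diff_max` are
#' excluded; variants with r2 above `collinearity` to any conditioning SNP
#' are masked (no conditional value).
#'
#' @param sumstats locus summary statistics.
#' @param genotypes LD reference [geno_matrix()] covering the locus.
#' @param conditioning character vector of conditioning variant ids (empty
#'   set returns the marginal statistics unchanged).
#' @param freq_diff_max allele-frequency concordance threshold.
#' @param collinearity r2 masking threshold.
#' @return tibble: id, beta_cond, se_cond, p_cond, status
#'   (`"ok"`, `"masked_collinear"`, `"excluded_freq"`).
#' @export
approx_conditional <- function(sumstats, genotypes, conditioning,
                               freq_diff_max = 0.2, collinearity = 0.9) {
  vt <- genotypes$variants
  ss <- sumstats[sumstats$id %in% vt$id, ]
  dos <- mean_impute_rows(genotypes$dosage[ss$id, , drop = FALSE])
  f_ref <- rowMeans(dos) / 2
  status <- rep("ok", nrow(ss))
  status[abs(ss$freq - f_ref) > freq_diff_max] <- "excluded_freq"
  if (!length(conditioning)) {
    return(tibble(id = ss$id, beta_cond = ss$beta, se_cond = ss$se,
                  p_cond = ss$p, status = status))
  }
  conditioning <- intersect(conditioning, ss$id)
  if (!length(conditioning)) abort("conditioning variant(s) absent from locus")
  keep <- status == "ok"
  R <- suppressWarnings(cor(t(dos)))
  R[is.na(R)] <- 0
  ci <- match(conditioning, ss$id)
  Rcc <- R[ci, ci, drop = FALSE]
  inv <- tryCatch(solve(Rcc), error = function(e)
    abort(paste("singular conditioning LD matrix for variants:",
                paste(conditioning, collapse = ", "))))
  D <- 2 * f_ref * (1 - f_ref) * ss$n
  beta_cond <- se_cond <- p_cond <- rep(NA_real_, nrow(ss))
  for (t in which(keep)) {
    if (ss$id[t] %in% conditioning) next
    r_tc <- R[t, ci, drop = FALSE]
    if (max(r_tc^2) > collinearity) {
      status[t] <- "masked_collinear"
      next
    }
    B_tc <- r_tc * sqrt(D[t] * D[ci])
    B_cc <- Rcc * sqrt(outer(D[ci], D[ci]))
    beta_cond[t] <- ss$beta[t] -
      drop(B_tc %*% solve(B_cc, ss$beta[ci]))
    defl <- max(1 - drop(r_tc %*% inv %*% t(r_tc)), 1e-8)
    se_cond[t] <- ss$se[t] * sqrt(defl)
    p_cond[t] <- min(1, 2 * pnorm(-abs(beta_cond[t] / se_cond[t])))
  }
  tibble(id = ss$id, beta_cond = beta_cond, se_cond = se_cond,
         p_cond = p_cond, status = status)
}

# Wakefield-style approximate Bayes factor under a N(0, W) effect prior.
abf_single <- function(beta, se, prior_sd = 0.15) {
  W <- prior_sd^2
  z2 <- (beta / se)^2
  sqrt(se^2 / (se^2 + W)) * exp(z2 * W / (2 * (se^2 + W)))
}

#' Single-causal-variant colocalization posterior (CLPP)
#'
#' Over SNPs nominally associated (p < `p_nominal_max`) in both studies,
#' each study's per-SNP causal posterior is its approximate Bayes factor
#' normalized over the set (single causal variant assumption); CLPP_j is the
#' product of the two posteriors. The verdict is `colocalized` when
#' clpp_max > `clpp_min` and the CLPP SNP has r2 > `r2_gw_min` with at least
#' one genome-wide-significant GWAS SNP at the locus.
#'
#' @param gwas locus GWAS summary statistics (id, beta, se, p).
#' @param qtl locus QTL statistics (variant, beta, se, p_nominal).
#' @param genotypes LD reference [geno_matrix()].
#' @param prior_sd effect-prior SD on the standardized scale.
#' @param p_nominal_max per-study inclusion threshold.
#' @param clpp_min,r2_gw_min,gw_p verdict thresholds.
#' @return list: clpp (per-SNP tibble), clpp_max, clpp_snp, r2_to_gw_snp,
#'   verdict, reason.
#' @export
clpp <- function(gwas, qtl, genotypes, prior_sd = 0.15,
                 p_nominal_max = 0.05, clpp_min = 0.01, r2_gw_min = 0.8,
                 gw_p = 5e-8) {
  g_ok <- gwas[gwas$p < p_nominal_max, ]
  q_ok <- qtl[qtl$p_nominal < p_nominal_max, ]
  common <- intersect(g_ok$id, q_ok$variant)
  if (!length(common)) {
    return(list(clpp = tibble(), clpp_max = 0, clpp_snp = NA_character_,
                r2_to_gw_snp = NA_real_, verdict = "not_colocalized",
                reason = "no jointly nominal SNPs"))
  }
  gb <- g_ok[match(common, g_ok$id), ]
  qb <- q_ok[match(common, q_ok$variant), ]
  p_g <- abf_single(gb$beta, gb$se, prior_sd)
  p_q <- abf_single(qb$beta, qb$se, prior_sd)
  p_g <- p_g / sum(p_g)
  p_q <- p_q / sum(p_q)
  cl <- p_g * p_q
  j <- which.max(cl)
  snp <- common[j]
  gw_snps <- gwas$id[gwas$p < gw_p]
  gw_snps <- intersect(gw_snps, genotypes$variants$id)
  r2gw <- if (length(gw_snps) && snp %in% genotypes$variants$id) {
    max(drop(ld_r2(genotypes$dosage[gw_snps, , drop = FALSE],
                   genotypes$dosage[snp, , drop = FALSE])), na.rm = TRUE)
  } else NA_real_
  verdict <- if (cl[j] > clpp_min && !is.na(r2gw) && r2gw > r2_gw_min) {
    "colocalized"
  } else "not_colocalized"
  list(clpp = tibble(id = common, posterior_gwas = p_g, posterior_qtl = p_q,
                     clpp = cl),
       clpp_max = cl[j], clpp_snp = snp, r2_to_gw_snp = r2gw,
       verdict = verdict, reason = NA_character_)
}

#' Full colocalization evidence for one candidate locus
#'
#' Combines the two approaches: (a) CLPP with the r2-to-GW-SNP gate, and
#' (b) approximate conditional analysis of the GWAS on the QTL index SNP,
#' where `conditional_pass` means the genome-wide signal is abolished (all
#' conditional p above `cond_p_floor`). The locus is `colocalized` when
#' either approach supports sharing.
#'
#' @param candidate one row of [find_candidates()] output.
#' @param sumstats GWAS summary statistics covering the locus.
#' @param qtl_records QTL scan records for the candidate feature.
#' @param genotypes LD reference [geno_matrix()].
#' @param locus_halfwidth bp window around the QTL index defining the locus.
#' @param cond_p_floor conditional-abolition threshold.
#' @param ... passed to [clpp()].
#' @return tibble row: feature, qtl_variant, clpp_max, clpp_snp,
#'   r2_to_gw_snp, conditional_pass, verdict.
#' @export
coloc_test <- function(candidate, sumstats, qtl_records, genotypes,
                       locus_halfwidth = 1e6, cond_p_floor = 1e-4, ...) {
  vt <- genotypes$variants
  qi <- match(candidate$qtl_variant, vt$id)
  loc_ids <- vt$id[vt$chrom == vt$chrom[qi] &
                     abs(vt$pos - vt$pos[qi]) <= locus_halfwidth]
  ss <- sumstats[sumstats$id %in% loc_ids, ]
  ss <- ss[order(ss$p), ]
  ss <- ss[!duplicated(ss$id), ]
  qr <- qtl_records[qtl_records$variant %in% loc_ids, ]
  cres <- clpp(ss, qr, genotypes, ...)
  cond <- approx_conditional(ss, geno_subset(genotypes, variants = ss$id),
                             conditioning = candidate$qtl_variant)
  gw_ids <- ss$id[ss$p < 5e-8]
  cp <- cond$p_cond[cond$id %in% gw_ids & cond$status == "ok"]
  conditional_pass <- length(cp) > 0 && all(cp > cond_p_floor)
  if (!length(cp)) {
    # all GW SNPs masked by collinearity with the QTL index: the signals are
    # statistically indistinguishable, which supports sharing
    conditional_pass <- any(cond$status[cond$id %in% gw_ids] == "masked_collinear")
  }
  tibble(feature = candidate$feature, qtl_variant = candidate$qtl_variant,
         clpp_max = cres$clpp_max, clpp_snp = cres$clpp_snp,
         r2_to_gw_snp = cres$r2_to_gw_snp,
         conditional_pass = conditional_pass,
         verdict = if (cres$verdict == "colocalized" || conditional_pass)
           "colocalized" else "not_colocalized",
         salvage = FALSE)
}

#' Salvage condition-specific near-miss loci
#'
#' For features colocalized in at least one condition, other conditions in
#' which the feature missed the FDR gate but reached a raw minimum p below
#' `threshold` are re-tested and appended with `salvage = TRUE`.
#'
#' @param coloc_results tibble of [coloc_test()] rows with a `condition`
#'   column.
#' @param qtl_by_condition named list (condition -> `qtl_result`).
#' @param sumstats,genotypes as in [coloc_test()].
#' @param threshold raw nominal-p gate (default 1e-6).
#' @param ... passed to [coloc_test()].
#' @return additional result rows (possibly empty) flagged `salvage`.
#' @export
salvage_condition_specific <- function(coloc_results, qtl_by_condition,
                                       sumstats, genotypes,
                                       threshold = 1e-6, ...) {
  shared <- unique(coloc_results$feature[coloc_results$verdict == "colocalized"])
  out <- list()
  for (ft in shared) {
    done <- coloc_results$condition[coloc_results$feature == ft]
    for (cn in setdiff(names(qtl_by_condition), done)) {
      q <- qtl_by_condition[[cn]]
      row <- q$corrections[q$corrections$feature == ft, ]
      if (!nrow(row) || isTRUE(row$significant) || row$p_min >= threshold) next
      rec <- q$records[q$records$feature == ft, ]
      idx <- rec[which.min(rec$p_nominal), ]
      cand <- tibble(feature = ft, qtl_variant = idx$variant)
      res <- coloc_test(cand, sumstats, rec, genotypes, ...)
      res$condition <- cn
      res$salvage <- TRUE
      out[[length(out) + 1]] <- res
    }
  }
  if (!length(out)) {
    return(tibble(feature = character(), qtl_variant = character(),
                  clpp_max = numeric(), verdict = character(),
                  condition = character(), salvage = logical()))
  }
  list_rbind(out)
}
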