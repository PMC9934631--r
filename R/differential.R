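#' Paired within-donor differential test
#'
#' For each feature, within-donor differences d_i = x(i, treatment) -
#' x(i, reference) are formed over donors present in both conditions;
#' lfc_raw = mean(d). Significance uses a moderated one-sample t:
#' per-feature variances are shrunk toward a common prior by empirical
#' Bayes, s2_post = (d0 s0^2 + df s^2) / (d0 + df), with (d0, s0^2) fitted
#' by method of moments across features, and p comes from a t distribution
#' with df + d0 degrees of freedom. Effect sizes are shrunk with a
#' normal prior whose variance is the across-feature variance of lfc_raw.
#' Numeric covariates named in `covariates` are regressed out per feature
#' (across the two conditions' samples) before pairing.
#'
#' @param norm normalized matrix (features x samples), e.g. from [vst_like()]
#'   on the log2 scale.
#' @param sheet sample sheet tibble (sample_id, donor_id, condition, ...).
#' @param treatment,reference condition labels; lfc is treatment - reference.
#' @param covariates character vector of numeric sheet columns to regress out.
#' @return a `diff_result` tibble: feature, lfc_raw, lfc_shrunk, se, t, p,
#'   padj, direction; attributes `n_pairs`, `d0`, `s0sq`, `contrast`.
#' @export
paired_diff <- function(norm, sheet, treatment, reference,
                        covariates = NULL) {
  sheet <- sheet[sheet$sample_id %in% colnames(norm) &
                   sheet$condition %in% c(treatment, reference), ]
  x <- norm[, sheet$sample_id, drop = FALSE]
  if (!is.null(covariates) && length(covariates)) {
    z <- as.matrix(sheet[, covariates, drop = FALSE])
    z <- scale(z, scale = FALSE)
    q <- qr.Q(qr(z))
    x <- x - (x %*% q) %*% t(q)
  }
  tr <- sheet[sheet$condition == treatment, ]
  rf <- sheet[sheet$condition == reference, ]
  donors <- intersect(tr$donor_id, rf$donor_id)
  dropped <- length(unique(sheet$donor_id)) - length(donors)
  if (dropped > 0) inform(sprintf("%d donor(s) present in only one condition dropped", dropped))
  if (length(donors) < 4) abort("fewer than 4 complete donor pairs")
  d <- x[, tr$sample_id[match(donors, tr$donor_id)], drop = FALSE] -
    x[, rf$sample_id[match(donors, rf$donor_id)], drop = FALSE]
  n <- length(donors)
  df <- n - 1
  lfc <- unname(rowMeans(d))
  s2 <- unname(rowSums((d - lfc)^2)) / df
  mom <- fit_f_moments(s2, df)
  s2_post <- (mom$d0 * mom$s0sq + df * s2) / (mom$d0 + df)
  se <- sqrt(s2_post / n)
  tval <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * pt(-abs(tval), df = df + mom$d0)
  p[s2 == 0 & lfc == 0] <- 1
  padj <- bh_adjust(p)
  s2_between <- var(lfc)
  shrink <- if (is.finite(s2_between) && s2_between > 0) {
    s2_between / (s2_between + se^2)
  } else 0
  lfc_shrunk <- lfc * shrink
  out <- tibble(
    feature = rownames(norm), lfc_raw = lfc, lfc_shrunk = lfc_shrunk,
    se = se, t = tval, p = p, padj = padj,
    direction = dplyr::case_when(
      padj < 0.1 & lfc_shrunk > 0.5 ~ "open_up",
      padj < 0.1 & lfc_shrunk < -0.5 ~ "closed_down",
      TRUE ~ "ns")
  )
  structure(out, class = c("diff_result", class(out)),
            n_pairs = n, d0 = mom$d0, s0sq = mom$s0sq,
            contrast = c(treatment = treatment, reference = reference))
}

# Method-of-moments fit of the scaled-F model for sample variances:
# s2 ~ s0^2 * chi2_df/df scaled by an inverse-chi2(d0) prior.
fit_f_moments <- function(s2, df) {
  m1 <- mean(s2)
  m2 <- var(s2)
  if (!is.finite(m2) || m2 <= 0 || m1 <= 0) {
    return(list(d0 = 1e6, s0sq = max(m1, 1e-12)))
  }
  r <- m2 / m1^2
  cc <- (r + 1) / (1 + 2 / df)
  if (cc <= 1) {
    d0 <- 1e6
  } else {
    d0 <- (4 * cc - 2) / (cc - 1)
  }
  s0sq <- if (is.finite(d0) && d0 < 1e6) m1 * (d0 - 2) / d0 else m1
  list(d0 = d0, s0sq = max(s0sq, 1e-12))
}

#' Call responsive elements/genes (WREs / DEGs)
#'
#' Applies the joint gate FDR-adjusted p < `fdr` and |shrunken LFC| >
#' `lfc_min` (both strict, matching the reported thresholds) and tabulates
#' counts per direction.
#'
#' @param diff a `diff_result` from [paired_diff()].
#' @param fdr BH-adjusted p threshold (default 0.1).
#' @param lfc_min absolute log2 fold-change threshold (default 0.5).
#' @param use_shrunk gate on shrunken (default) or raw LFC.
#' @return tibble of responsive features with `direction`; attribute
#'   `counts` gives per-direction totals.
#' @export
call_responsive <- function(diff, fdr = 0.1, lfc_min = 0.5, use_shrunk = TRUE) {
  lfc <- if (use_shrunk) diff$lfc_shrunk else diff$lfc_raw
  hit <- diff$padj < fdr & abs(lfc) > lfc_min
  out <- diff[hit, ]
  out$direction <- ifelse(lfc[hit] > 0, "open_up", "closed_down")
  counts <- c(open_up = sum(out$direction == "open_up"),
              closed_down = sum(out$direction == "closed_down"))
  structure(as_tibble(out), counts = counts)
}

#' @export
glance.diff_result <- function(x, ...) {
  tibble(n_features = nrow(x), n_pairs = attr(x, "n_pairs"),
         d0 = attr(x, "d0"), s0sq = attr(x, "s0sq"),
         n_responsive = sum(x$direction != "ns"))
}

#' @export
tidy.diff_result <- function(x, ...) as_tibble(x)

#' Volcano plot of a paired differential result
#'
#' @param object a `diff_result`.
#' @param fdr,lfc_min gate drawn on the plot.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.diff_result <- function(object, fdr = 0.1, lfc_min = 0.5, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lfc_shrunk,
                                   y = -log10(pmax(.data$padj, 1e-300)),
                                   colour = .data$direction)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(fdr), linetype = 2) +
    ggplot2::geom_vline(xintercept = c(-lfc_min, lfc_min), linetype = 2) +
    ggplot2::labs(x = "shrunken log2 fold change", y = "-log10 FDR-adjusted p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
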