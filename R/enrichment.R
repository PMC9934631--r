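#' Motif enrichment by logistic regression
#'
#' Per motif, fits presence ~ class + width + conserved_pct with a binomial
#' GLM and reports the Wald p-value of the class coefficient (log odds of
#' presence in the second class relative to the first), BH-adjusted across
#' motifs. When complete separation is detected the fit is redone with a
#' Firth-style penalty and flagged. Classes are e.g. opened vs closed
#' responsive peaks, or response vs non-response caPeaks; when `top_n` is
#' finite the peaks of each class are ranked by `rank_by` (absolute value,
#' descending) and capped at `top_n` per class first.
#'
#' @param motif_table list with `presence` (peaks x motifs 0/1 matrix) and
#'   `peaks` (tibble: name, width, conserved_pct).
#' @param peak_class named (by peak id) factor/character with two levels.
#' @param top_n per-class cap on peaks (default Inf = no cap).
#' @param rank_by optional named numeric (e.g. shrunken LFC) for the cap.
#' @return `enrichment_records` tibble: unit, effect (log-OR), se, p, fdr,
#'   k (presence count), n, flagged fits.
#' @export
motif_glm <- function(motif_table, peak_class, top_n = Inf, rank_by = NULL) {
  cls <- peak_class[!is.na(peak_class)]
  lev <- if (is.factor(cls)) levels(droplevels(cls)) else unique(cls)
  cls <- as.character(cls)
  names(cls) <- names(peak_class)[!is.na(peak_class)]
  if (length(lev) != 2) abort("peak_class must have exactly two classes")
  if (is.finite(top_n) && !is.null(rank_by)) {
    keep <- unlist(map(lev, function(l) {
      ids <- names(cls)[cls == l]
      ids[order(-abs(rank_by[ids]))][seq_len(min(top_n, length(ids)))]
    }))
    cls <- cls[keep]
  }
  ids <- intersect(names(cls), motif_table$peaks$name)
  cls <- cls[ids]
  pres <- motif_table$presence[ids, , drop = FALSE]
  pk <- motif_table$peaks[match(ids, motif_table$peaks$name), ]
  xcls <- as.numeric(cls == lev[2])
  w <- as.numeric(scale(pk$width))
  cp <- as.numeric(scale(pk$conserved_pct))
  out <- map(colnames(pres), function(m) {
    yy <- pres[, m]
    if (sum(yy) == 0) return(NULL)
    X <- cbind(1, xcls, w, cp)
    fit <- tryCatch(
      withCallingHandlers(
        glm.fit(X, yy, family = binomial()),
        warning = function(cw) {
          if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(cw)))
            invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    flagged <- FALSE
    est <- se <- NA_real_
    if (!is.null(fit) && fit$converged) {
      Xw <- X * sqrt(pmax(fit$weights, 0))
      vc <- tryCatch(chol2inv(chol(crossprod(Xw))), error = function(e) NULL)
      if (!is.null(vc)) {
        est <- fit$coefficients[2]
        se <- sqrt(vc[2, 2])
      }
    }
    separated <- is.null(fit) || !fit$converged || !is.finite(est) ||
      !is.finite(se) || abs(est) > 10 || se > 10
    if (separated) {
      ff <- firth_logistic(X, yy)
      if (is.null(ff)) return(tibble(unit = m, effect = NA_real_, se = NA_real_,
                                     p = NA_real_, flagged = TRUE,
                                     k = sum(yy), n = length(yy),
                                     note = "non-convergent"))
      est <- ff$beta[2]; se <- ff$se[2]; flagged <- TRUE
    }
    z <- est / se
    tibble(unit = m, effect = est, se = se,
           p = min(1, 2 * pnorm(-abs(z))), flagged = flagged,
           k = sum(yy), n = length(yy), note = NA_character_)
  })
  res <- list_rbind(out[!vapply(out, is.null, logical(1))])
  res$fdr <- bh_adjust(res$p)
  structure(res, class = c("enrichment_records", class(res)),
            classes = lev)
}

# Firth-penalized logistic regression by IRLS with hat-value correction.
firth_logistic <- function(X, y, max_iter = 50, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    wgt <- mu * (1 - mu)
    XW <- X * sqrt(wgt)
    XtWX <- crossprod(XW)
    inv <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    if (is.null(inv)) return(NULL)
    h <- rowSums((XW %*% inv) * XW)
    u <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    step <- inv %*% u
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  wgt <- plogis(eta) * (1 - plogis(eta))
  inv <- tryCatch(chol2inv(chol(crossprod(X * sqrt(wgt)))), error = function(e) NULL)
  if (is.null(inv)) return(NULL)
  list(beta = beta, se = sqrt(diag(inv)))
}

# Any-bp overlap of peaks (0-based half-open tibbles) with annotation
# intervals; returns logical per peak.
overlaps_any <- function(peaks, annotation) {
  hit <- rep(FALSE, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    ai <- which(annotation$chrom == ch)
    if (!length(ai)) next
    q <- IRanges::IRanges(start = peaks$start[pi] + 1L, end = peaks$end[pi])
    s <- IRanges::IRanges(start = annotation$start[ai] + 1L, end = annotation$end[ai])
    hit[pi] <- IRanges::overlapsAny(q, s)
  }
  hit
}

#' Interval-overlap enrichment by exact binomial test
#'
#' k is the number of query peaks overlapping (any bp) at least one
#' annotation interval; the null rate p0 is the proportion of background
#' peaks overlapping; the p-value is the one-sided (greater) exact binomial
#' tail and the fold is (k/n)/p0.
#'
#' @param query,background interval tibbles (query need not be a subset).
#' @param annotation interval tibble.
#' @return `enrichment_records` tibble (one row): unit, effect (fold), p,
#'   k, n, expected.
#' @export
overlap_binomial <- function(query, annotation, background) {
  k <- sum(overlaps_any(query, annotation))
  n <- nrow(query)
  p0 <- mean(overlaps_any(background, annotation))
  if (p0 == 0) {
    if (k > 0) {
      warn("background has zero overlap rate but query overlaps exist; background unrepresentative")
      p <- .Machine$double.xmin
    } else p <- 1
  } else {
    p <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  }
  structure(tibble(unit = "overlap", effect = if (p0 > 0) (k / n) / p0 else Inf,
                   p = p, k = k, n = n, expected = n * p0),
            class = c("enrichment_records", "tbl_df", "tbl", "data.frame"))
}

#' Difference between two overlap enrichments (Fisher's exact test)
#'
#' Builds the 2x2 table (overlap yes/no x class A/B) and returns the
#' two-sided Fisher exact p-value.
#'
#' @param record_a,record_b single-row tibbles from [overlap_binomial()]
#'   (need `k` and `n`).
#' @return p-value.
#' @export
enrichment_difference <- function(record_a, record_b) {
  tab <- matrix(c(record_a$k, record_a$n - record_a$k,
                  record_b$k, record_b$n - record_b$k), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  fisher.test(tab)$p.value
}

#' Compare eQTL-to-TSS distances between response and non-response QTLs
#'
#' Computes |variant position - strand-aware TSS| per eQTL and compares the
#' two groups with a two-sided Wilcoxon rank-sum test. With fewer than 3
#' observations in a group only the summary is returned.
#'
#' @param response,background tibbles with `feature` (gene id) and `variant`.
#' @param genes interval tibble with `tss`.
#' @param genotypes a [geno_matrix()] (for variant positions).
#' @return list: `summary` (per-group n and median distance), `p` (or NA).
#' @export
tss_distance_compare <- function(response, background, genes, genotypes) {
  dist_of <- function(df) {
    tss <- genes$tss[match(df$feature, genes$name)]
    pos <- genotypes$variants$pos[match(df$variant, genotypes$variants$id)]
    abs(pos - tss)
  }
  d1 <- dist_of(response); d2 <- dist_of(background)
  sm <- tibble(group = c("response", "non_response"),
               n = c(length(d1), length(d2)),
               median_distance = c(median(d1), median(d2)))
  p <- if (length(d1) >= 3 && length(d2) >= 3) {
    suppressWarnings(wilcox.test(d1, d2)$p.value)
  } else NA_real_
  list(summary = sm, p = p)
}

#' Forest-style plot of enrichment records
#' @param object an `enrichment_records` tibble with `effect` and `se`.
#' @param fdr significance level colouring.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.enrichment_records <- function(object, fdr = 0.1, ...) {
  df <- as_tibble(object)
  df <- df[is.finite(df$effect), ]
  df$sig <- if ("fdr" %in% names(df)) df$fdr < fdr else df$p < fdr
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect,
                                   y = stats::reorder(.data$unit, .data$effect),
                                   colour = .data$sig)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "effect (log-odds or fold)", y = NULL, colour = "significant") +
    ggplot2::theme_minimal()
}
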