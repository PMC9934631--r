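#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows bind_cols rename n across row_number
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_int map_lgl map2 pmap imap list_rbind
#' @importFrom stats p.adjust pt pf pchisq pnorm qnorm pbeta qbeta var sd cor
#'   median quantile rnorm rbinom runif rnbinom optimize setNames complete.cases
#'   binom.test fisher.test wilcox.test glm binomial coef vcov lm approx
#'   prcomp dbinom pbinom dhyper ks.test
#' @importFrom utils head tail
NULL

# Deterministic child seed for a named stage, below 2^31.
child_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((as.numeric(seed) %% 2147480009 + h * 7919) %% 2147480009)
}

with_stage_seed <- function(seed, stage, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(child_seed(seed, stage))
  force(code)
}

#' Variant-interval overlap under standard coordinate conventions
#'
#' A 1-based variant position p overlaps a 0-based half-open interval
#' \[start, end) iff start < p <= end.
#'
#' @param pos 1-based position(s).
#' @param start,end 0-based half-open interval bounds.
#' @return logical vector.
#' @export
pos_in_interval <- function(pos, start, end) pos > start & pos <= end

# Strand-aware TSS: start (converted to 1-based) for "+", end for "-".
tss_of <- function(start, end, strand) {
  ifelse(strand == "-", end, start + 1L)
}

#' Normalize contig names
#'
#' Applies a chrN/N alias map so that all loaded components share one contig
#' naming style. Mixed styles within a single vector are an error.
#'
#' @param x character vector of contig names.
#' @param style target style, `"chr"` (UCSC-like) or `"plain"`.
#' @return character vector in the requested style.
#' @export
normalize_contigs <- function(x, style = c("chr", "plain")) {
  style <- match.arg(style)
  has_chr <- grepl("^chr", x)
  if (any(has_chr) && !all(has_chr)) {
    abort("mixed contig naming (both 'chrN' and 'N') within one input")
  }
  if (style == "chr") ifelse(has_chr, x, paste0("chr", x)) else sub("^chr", "", x)
}

# Benjamini-Hochberg via stats::p.adjust; kept as a single chokepoint so every
# multiple-testing family in the package goes through the same code.
bh_adjust <- function(p) p.adjust(p, method = "BH")

mean_impute_rows <- function(m) {
  if (!anyNA(m)) return(m)
  for (i in seq_len(nrow(m))) {
    nas <- is.na(m[i, ])
    if (any(nas)) m[i, nas] <- mean(m[i, !nas])
  }
  m
}

#' Pairwise LD (r2) between dosage rows
#'
#' Squared Pearson correlation of dosages (variants x samples matrices),
#' after per-variant mean imputation of missing values; constant rows give
#' NA.
#'
#' @param dos_a,dos_b dosage matrices (variants x samples); `dos_b` defaults
#'   to `dos_a`.
#' @return matrix of r2 values (rows of `dos_a` x rows of `dos_b`).
#' @export
ld_r2 <- function(dos_a, dos_b = NULL) {
  a <- t(mean_impute_rows(as.matrix(dos_a)))
  b <- if (is.null(dos_b)) a else t(mean_impute_rows(as.matrix(dos_b)))
  suppressWarnings(cor(a, b))^2
}

check_prob <- function(p, what = "p") {
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    abort(sprintf("%s must lie in (0, 1]", what))
  }
  invisible(p)
}
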