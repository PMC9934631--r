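#' Construct a genotype dosage matrix
#'
#' Container for biallelic variants with per-sample dosages in \[0, 2\].
#' Dosages may be imputed (fractional) or hard calls; missing values are
#' allowed. Minor allele frequency is recomputed from the non-missing dosages.
#'
#' @param dosage numeric matrix, variants x samples, values in \[0, 2\] or NA.
#' @param variants tibble with columns `chrom`, `pos` (1-based), `id`, `ref`,
#'   `alt`; one row per row of `dosage`. Extra columns are kept.
#' @return an object of class `geno_matrix`: a list with elements `dosage`,
#'   `variants` (with an `maf` column) and `samples`.
#' @export
geno_matrix <- function(dosage, variants) {
  dosage <- as.matrix(dosage)
  stopifnot(is.numeric(dosage))
  variants <- as_tibble(variants)
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(variants))) {
    abort(paste("variants must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(variants) != nrow(dosage)) abort("variants/dosage row mismatch")
  if (anyDuplicated(variants$id)) abort("duplicate variant ids")
  if (any(variants$pos < 1)) abort("variant pos must be >= 1")
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 2 + 1e-9) abort("dosages must lie in [0, 2]")
  rownames(dosage) <- variants$id
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- paste0("S", seq_len(ncol(dosage)))
  }
  f <- rowMeans(dosage, na.rm = TRUE) / 2
  variants$maf <- pmin(f, 1 - f)
  structure(
    list(dosage = dosage, variants = variants, samples = colnames(dosage)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d variants x %d samples; median MAF %.3f\n",
    nrow(x$dosage), ncol(x$dosage), median(x$variants$maf)
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Tidy a genotype matrix into long format
#'
#' @param x a [geno_matrix()].
#' @param ... unused.
#' @return tibble with one row per variant-sample dosage.
#' @export
tidy.geno_matrix <- function(x, ...) {
  tibble(
    id = rep(x$variants$id, times = length(x$samples)),
    sample_id = rep(x$samples, each = nrow(x$dosage)),
    dosage = as.vector(x$dosage)
  )
}

#' Subset a genotype matrix by variant id and/or sample id
#'
#' @param x a [geno_matrix()].
#' @param variants,samples character vectors of ids to keep (NULL keeps all).
#' @return a [geno_matrix()].
#' @export
geno_subset <- function(x, variants = NULL, samples = NULL) {
  vi <- if (is.null(variants)) seq_len(nrow(x$dosage)) else match(variants, x$variants$id)
  si <- if (is.null(samples)) seq_len(ncol(x$dosage)) else match(samples, x$samples)
  if (anyNA(vi)) abort("unknown variant id in subset")
  if (anyNA(si)) abort("unknown sample id in subset")
  geno_matrix(x$dosage[vi, si, drop = FALSE], x$variants[vi, setdiff(names(x$variants), "maf")])
}
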