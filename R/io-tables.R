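#' Read a BED3-BED6 interval file
#'
#' Intervals are kept in BED convention: 0-based, half-open. Missing optional
#' columns are filled (`name = "."`, `score = 0`, `strand = "."`). Output is
#' sorted by (chrom, start).
#'
#' @param path path to an uncompressed BED file.
#' @return tibble with columns chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE, comment = "#")
  if (ncol(x) < 3) abort("BED file needs at least 3 columns")
  out <- tibble(
    chrom = as.character(x[[1]]),
    start = as.integer(x[[2]]),
    end = as.integer(x[[3]]),
    name = if (ncol(x) >= 4) as.character(x[[4]]) else ".",
    score = if (ncol(x) >= 5) as.numeric(x[[5]]) else 0,
    strand = if (ncol(x) >= 6) as.character(x[[6]]) else "."
  )
  bad <- which(out$start >= out$end | out$start < 0)
  if (length(bad)) {
    abort(sprintf("invalid interval (start >= end or start < 0) at line %d of %s",
                  bad[1], path))
  }
  arrange(out, .data$chrom, .data$start)
}

#' Write intervals as BED6
#'
#' @param intervals tibble as returned by [read_bed()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  out <- tibble(
    chrom = intervals$chrom,
    start = as.integer(intervals$start),
    end = as.integer(intervals$end),
    name = intervals$name %||% ".",
    score = intervals$score %||% 0,
    strand = intervals$strand %||% "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a feature-by-sample count matrix
#'
#' @param path TSV with a header; first column holds feature ids, remaining
#'   column names are sample ids.
#' @return integer matrix, features x samples.
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  feats <- as.character(x[[1]])
  m <- as.matrix(x[, -1, drop = FALSE])
  if (anyDuplicated(feats)) abort("duplicate feature ids in count matrix")
  if (anyDuplicated(colnames(m))) abort("duplicate sample ids in count matrix")
  if (!is.numeric(m)) abort("non-numeric counts")
  if (any(m < 0, na.rm = TRUE)) abort("negative counts")
  if (any(abs(m - round(m)) > 1e-8, na.rm = TRUE)) abort("non-integer counts")
  storage.mode(m) <- "integer"
  rownames(m) <- feats
  m
}

#' Write a count matrix as TSV
#' @param counts integer matrix with feature rownames and sample colnames.
#' @param path output path.
#' @param id_col name of the feature-id column.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, id_col = "feature_id") {
  df <- as.data.frame(counts)
  df <- cbind(setNames(data.frame(rownames(counts)), id_col), df)
  readr::write_tsv(as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Requires columns `sample_id`, `donor_id`, `condition`; any remaining
#' numeric columns are treated as covariates. Each (donor, condition) pair
#' must be unique (one sample per donor-condition).
#'
#' @param path TSV path.
#' @param conditions optional declared condition set; labels outside it error.
#' @return tibble.
#' @export
read_sample_sheet <- function(path, conditions = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_sheet(x, conditions)
}

validate_sample_sheet <- function(x, conditions = NULL) {
  need <- c("sample_id", "donor_id", "condition")
  if (!all(need %in% names(x))) {
    abort(paste("sample sheet must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(x$sample_id)) abort("duplicate sample_id in sheet")
  if (anyDuplicated(x[, c("donor_id", "condition")])) {
    abort("duplicated (donor_id, condition) pair in sheet")
  }
  if (!is.null(conditions) && !all(x$condition %in% conditions)) {
    abort("condition label outside the declared condition set")
  }
  as_tibble(x)
}

#' Read GWAS summary statistics
#'
#' Accepts either the COJO \code{.ma}-style header (`SNP A1 A2 freq b se p N`)
#' or long names (`id, chrom, pos, effect_allele, other_allele, freq, beta,
#' se, p, n`). A `z = beta/se` column is added.
#'
#' @param path TSV path.
#' @return tibble with columns id, chrom, pos, effect_allele, other_allele,
#'   freq, beta, se, p, n, z.
#' @export
read_sumstats <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ma_map <- c(SNP = "id", A1 = "effect_allele", A2 = "other_allele",
              freq = "freq", b = "beta", se = "se", p = "p", N = "n")
  hits <- intersect(names(ma_map), names(x))
  if (length(hits)) names(x)[match(hits, names(x))] <- ma_map[hits]
  need <- c("id", "effect_allele", "other_allele", "freq", "beta", "se", "p", "n")
  if (!all(need %in% names(x))) {
    abort(paste("sumstats missing column(s):",
                paste(setdiff(need, names(x)), collapse = ", ")))
  }
  if (!"chrom" %in% names(x)) x$chrom <- NA_character_
  if (!"pos" %in% names(x)) x$pos <- NA_integer_
  check_prob(x$p, "sumstats p")
  if (any(x$se <= 0)) abort("sumstats se must be > 0")
  x$z <- x$beta / x$se
  select(as_tibble(x), "id", "chrom", "pos", "effect_allele", "other_allele",
         "freq", "beta", "se", "p", "n", "z")
}

#' Write GWAS summary statistics in the COJO .ma dialect
#' @param ss tibble from [read_sumstats()] or [simulate_gwas()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  out <- tibble(SNP = ss$id, A1 = ss$effect_allele, A2 = ss$other_allele,
                freq = ss$freq, b = ss$beta, se = ss$se, p = ss$p, N = ss$n)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Cross-validate a loaded dataset
#'
#' Checks sample-id consistency between the sheet, the genotypes (donor
#' level) and each assay's count matrix; reports per-assay sample
#' intersections (assays may cover unequal donor subsets), orphan features
#' and contig-style mismatches between variant and interval coordinates.
#'
#' @param genotypes a [geno_matrix()].
#' @param counts named list of count matrices (e.g. `list(atac = ..., rna = ...)`).
#' @param sheet sample sheet tibble.
#' @param features optional named list of interval tibbles matching `counts`
#'   (rownames of each count matrix must appear in `name`).
#' @return list with `samples` (per-assay tibble of usable samples) and
#'   `messages` (character vector of warnings); hard error when an assay has
#'   no usable samples.
#' @export
validate_dataset <- function(genotypes, counts, sheet, features = NULL) {
  sheet <- validate_sample_sheet(sheet)
  msgs <- character()
  assays <- names(counts)
  usable <- map(assays, function(a) {
    samp <- colnames(counts[[a]])
    unknown <- setdiff(samp, sheet$sample_id)
    if (length(unknown)) {
      abort(sprintf("assay %s has sample(s) absent from sheet: %s",
                    a, paste(head(unknown, 5), collapse = ", ")))
    }
    sub <- sheet[sheet$sample_id %in% samp, ]
    keep <- sub$donor_id %in% genotypes$samples
    if (!all(keep)) {
      msgs <<- c(msgs, sprintf("assay %s: %d sample(s) without genotypes dropped",
                               a, sum(!keep)))
    }
    sub <- sub[keep, ]
    if (nrow(sub) == 0) abort(sprintf("assay %s: empty sample intersection", a))
    tibble(assay = a, sample_id = sub$sample_id, donor_id = sub$donor_id,
           condition = sub$condition)
  })
  usable <- list_rbind(usable)
  if (length(assays) == 2) {
    only <- setdiff(colnames(counts[[1]]), colnames(counts[[2]]))
    if (length(only)) {
      msgs <- c(msgs, sprintf("%d sample(s) present in %s only (retained for that assay)",
                              length(only), assays[1]))
    }
    only2 <- setdiff(colnames(counts[[2]]), colnames(counts[[1]]))
    if (length(only2)) {
      msgs <- c(msgs, sprintf("%d sample(s) present in %s only (retained for that assay)",
                              length(only2), assays[2]))
    }
  }
  if (!is.null(features)) {
    for (a in intersect(names(features), assays)) {
      orphan <- setdiff(rownames(counts[[a]]), features[[a]]$name)
      if (length(orphan)) {
        msgs <- c(msgs, sprintf("assay %s: %d orphan feature(s) without coordinates",
                                a, length(orphan)))
      }
      gchr <- unique(genotypes$variants$chrom)
      fchr <- unique(features[[a]]$chrom)
      if (length(gchr) && length(fchr) &&
          !any(fchr %in% gchr)) {
        if (any(sub("^chr", "", fchr) %in% sub("^chr", "", gchr))) {
          msgs <- c(msgs, sprintf(
            "assay %s: contig style differs from genotypes (chrN vs N); normalize with normalize_contigs()", a))
        } else {
          msgs <- c(msgs, sprintf("assay %s: no shared contigs with genotypes", a))
        }
      }
    }
  }
  for (m in msgs) inform(m)
  list(samples = usable, messages = msgs)
}
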