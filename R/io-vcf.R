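#' Read genotypes from a VCF file
#'
#' Reads a VCFv4.2-style text file into a [geno_matrix()]. Dosages come from
#' the `DS` FORMAT field when present, otherwise from the `GT` allele count.
#' Only biallelic SNV/indel records are kept; multiallelic records are skipped
#' with a warning giving the count. When an imputation-quality INFO key is
#' present (default `R2`), variants below `min_impute_quality` are dropped;
#' files without the key skip the filter with a message.
#'
#' @param path path to an uncompressed VCF.
#' @param min_impute_quality imputation-quality floor applied when the INFO
#'   key exists.
#' @param impute_key INFO key holding imputation quality.
#' @return a [geno_matrix()].
#' @export
read_vcf <- function(path, min_impute_quality = 0.3, impute_key = "R2") {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "##fileformat=VCF")) {
    abort(sprintf("malformed VCF header in %s: missing ##fileformat line", path))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT) | fix$ALT == "."
  if (any(multi)) {
    warn(sprintf("skipped %d non-biallelic record(s)", sum(multi)))
  }
  keep <- !multi
  info <- fix$INFO[keep]
  r2 <- suppressWarnings(as.numeric(sub(
    sprintf(".*(?:^|;)%s=([^;]+).*", impute_key), "\\1",
    ifelse(grepl(sprintf("(^|;)%s=", impute_key), info), info, NA)
  )))
  fmt <- if ("FORMAT" %in% colnames(v@gt)) v@gt[1, "FORMAT"] else ""
  fmt_has <- function(el) el %in% unlist(strsplit(fmt %||% "", ":"))
  if (fmt_has("DS")) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    dosage <- ds[keep, , drop = FALSE]
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
    cnt <- function(g) {
      if (is.na(g) || grepl("\\.", g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]))
    }
    dosage <- matrix(vapply(gt, cnt, numeric(1)), nrow = nrow(gt),
                     dimnames = dimnames(gt))
  }
  variants <- tibble(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    id = fix$ID[keep],
    ref = fix$REF[keep],
    alt = fix$ALT[keep]
  )
  if (anyDuplicated(variants$id)) abort("duplicate variant ids in VCF")
  if (all(is.na(r2))) {
    inform(sprintf("INFO key '%s' absent; imputation-quality filter skipped", impute_key))
  } else {
    drop <- !is.na(r2) & r2 < min_impute_quality
    if (any(drop)) {
      inform(sprintf("dropped %d variant(s) with %s < %g", sum(drop), impute_key, min_impute_quality))
      variants <- variants[!drop, ]
      dosage <- dosage[!drop, , drop = FALSE]
    }
  }
  geno_matrix(dosage, variants)
}

#' Write genotypes to a VCF file
#'
#' Emits the canonical dialect read back by [read_vcf()]: one biallelic record
#' per variant with `GT:DS` genotypes. `GT` is the rounded hard call when the
#' dosage is integral, otherwise `./.`; `DS` carries the dosage at full
#' precision so a write/read round trip reproduces the matrix exactly.
#'
#' @param geno a [geno_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            geno$samples), collapse = "\t")
  )
  fmt_cell <- function(d) {
    if (is.na(d)) return("./.:.")
    ds <- sprintf("%.15g", d)
    if (abs(d - round(d)) < 1e-9) {
      gt <- switch(as.character(round(d)), "0" = "0/0", "1" = "0/1", "2" = "1/1")
      paste0(gt, ":", ds)
    } else {
      paste0("./.:", ds)
    }
  }
  body <- vapply(seq_len(nrow(geno$dosage)), function(i) {
    v <- geno$variants[i, ]
    paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT:DS",
            vapply(geno$dosage[i, ], fmt_cell, character(1))), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
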