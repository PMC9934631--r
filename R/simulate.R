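#' Simulation configuration
#'
#' Declares the synthetic study design: a paired stimulation experiment in
#' which every donor is profiled (ATAC and RNA) under a vehicle condition and
#' one or more stimulated conditions, with genotypes shared across
#' conditions. Defaults mirror the statistical structure of an ~80-donor,
#' three-condition neural-progenitor stimulation study: LD-structured
#' biallelic variants in Hardy-Weinberg equilibrium, negative-binomial counts
#' with donor random intercepts, GC and library-size biases, planted
#' condition effects (responsive peaks/genes), planted shared /
#' condition-specific / interaction QTL effects with peak-mediated gene
#' effects, motif annotations enriched in responsive peaks, and a synthetic
#' GWAS cohort sharing causal variants with selected QTLs.
#'
#' @param n_donors number of donors (genotyped individuals).
#' @param conditions condition labels; the first is the vehicle/reference.
#' @param missing_rate per condition-assay probability that a sample is
#'   missing (emulates unequal n across assays/conditions).
#' @param n_variants,n_peaks,n_genes panel dimensions.
#' @param n_chrom number of chromosomes the features are laid out on.
#' @param variant_spacing mean spacing (bp) between adjacent variants.
#' @param ld_block_size variants per LD block.
#' @param within_block_copy_prob per-haplotype probability that a variant
#'   copies its predecessor's allele within a block (controls LD decay).
#' @param maf_range range of block base minor-allele frequencies.
#' @param causal_maf_min minimum MAF for planted causal variants.
#' @param dispersion negative-binomial size parameter.
#' @param donor_sd SD of the donor random intercept (natural-log scale).
#' @param gc_effect_amplitude SD of the per-sample GC-bias slope.
#' @param libsize_lognormal_sd SD of log library-size factors.
#' @param frac_wre,frac_deg fraction of peaks/genes given condition effects.
#' @param frac_caqtl fraction of peaks wired into QTL scenarios.
#' @param frac_eqtl fraction of genes given additional direct eQTLs.
#' @param scenario_mix proportions over scenarios
#'   `shared`, `primed`, `stimulus_specific`, `response_magnitude`, `null`.
#' @param beta_ca per-allele caQTL effect (natural-log scale).
#' @param beta_lfc planted condition log2 fold change magnitude.
#' @param beta_interaction added per-allele effect in stimulated conditions
#'   for `response_magnitude` scenarios (natural-log scale).
#' @param target_r2 optional target fraction of log-scale variance explained
#'   by each planted QTL; when set, per-variant betas are derived from it and
#'   `beta_ca` is ignored.
#' @param mediation_gamma scaling of the peak genetic effect passed to the
#'   wired gene.
#' @param rin_effect per-unit effect of the RIN-like covariate on gene means.
#' @param n_motifs,motif_base_rate,motif_logOR,frac_motif_planted motif-table
#'   parameters: planted motifs get `motif_logOR` extra log-odds of presence
#'   in responsive peaks.
#' @param annotation_sets named integer vector: interval count per annotation
#'   set (HAQER-like / HAR-like / enhancer-state stand-ins).
#' @param annotation_enrich fraction of each set's intervals placed onto
#'   QTL-bearing peaks (planted enrichment).
#' @param gwas_n GWAS cohort size.
#' @param gwas_var_explained per-locus trait variance explained.
#' @param n_gwas_loci number of GWAS loci (alternating shared / distinct).
#' @param gwas_region_halfwidth half-width (bp) of each simulated GWAS region.
#' @param n_subpops number of donor subpopulations (1 = panmictic, default).
#' @param fst allele-frequency divergence between subpopulations
#'   (Balding-Nichols Beta model), used when `n_subpops > 1`.
#' @param seed master seed; each stage derives an independent child stream.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_donors = 80,
                       conditions = c("vehicle", "stimA", "stimB"),
                       missing_rate = 0.05,
                       n_variants = 3000, n_peaks = 300, n_genes = 150,
                       n_chrom = 2, variant_spacing = 1000,
                       ld_block_size = 20, within_block_copy_prob = 0.9,
                       maf_range = c(0.05, 0.5), causal_maf_min = 0.2,
                       dispersion = 10, donor_sd = 0.3,
                       gc_effect_amplitude = 0.15, libsize_lognormal_sd = 0.3,
                       frac_wre = 0.1, frac_deg = 0.1,
                       frac_caqtl = 0.2, frac_eqtl = 0.1,
                       scenario_mix = c(shared = 0.3, primed = 0.2,
                                        stimulus_specific = 0.2,
                                        response_magnitude = 0.1, null = 0.2),
                       beta_ca = 0.3, beta_lfc = 0.8, beta_interaction = 0.3,
                       target_r2 = NULL,
                       mediation_gamma = 1, rin_effect = 0.05,
                       n_motifs = 50, motif_base_rate = 0.2,
                       motif_logOR = 1, frac_motif_planted = 0.3,
                       annotation_sets = c(enhancer_like = 300,
                                           haqer_like = 150, har_like = 250),
                       annotation_enrich = 0.3,
                       gwas_n = 20000, gwas_var_explained = 0.005,
                       n_gwas_loci = 6, gwas_region_halfwidth = 150000,
                       n_subpops = 1, fst = 0.05,
                       seed = 1) {
  cfg <- as.list(environment())
  if (n_donors < 4) abort("n_donors must be >= 4 (paired models unfittable below)")
  if (abs(sum(scenario_mix)) > 1 + 1e-8) abort("scenario_mix proportions must sum to <= 1")
  rates <- c(missing_rate, frac_wre, frac_deg, frac_caqtl, frac_eqtl)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' Simulate an LD-structured genotype panel
#'
#' Variants are laid out in blocks of `ld_block_size`; within a block each
#' haplotype copies the previous variant's allele with probability
#' `within_block_copy_prob` (otherwise a fresh Hardy-Weinberg draw at the
#' block base frequency), giving r2 that decays geometrically with distance.
#' Haplotypes are retained (attribute `"haplotypes"`) so a GWAS cohort can be
#' resampled from the same panel.
#'
#' @param config a [sim_config()].
#' @return a [geno_matrix()] whose `variants` carry `block` and `target_maf`
#'   columns, with a `haplotypes` attribute (2 n_donors x n_variants, 0/1).
#' @export
simulate_genotypes <- function(config) {
  with_stage_seed(config$seed, "genotypes", {
    n <- config$n_donors
    n_sub <- max(1L, as.integer(config$n_subpops %||% 1L))
    # donor -> subpopulation, repeated per haplotype
    subpop <- rep(rep(seq_len(n_sub), length.out = n), each = 2)
    v_per_chr <- diff(round(seq(0, config$n_variants, length.out = config$n_chrom + 1)))
    hap <- matrix(0L, nrow = 2 * n, ncol = config$n_variants)
    chrom <- integer(config$n_variants)
    pos <- integer(config$n_variants)
    block <- integer(config$n_variants)
    tmaf <- numeric(config$n_variants)
    j <- 0L; b <- 0L
    # Balding-Nichols: subpopulation frequencies around the ancestral block
    # frequency with divergence controlled by fst
    sub_freqs <- function(f) {
      if (n_sub == 1 || config$fst <= 0) return(rep(f, n_sub))
      a <- f * (1 - config$fst) / config$fst
      bb <- (1 - f) * (1 - config$fst) / config$fst
      pmin(pmax(stats::rbeta(n_sub, a, bb), 0.01), 0.99)
    }
    for (ch in seq_len(config$n_chrom)) {
      nv <- v_per_chr[ch]
      p <- sort(sample.int(nv * config$variant_spacing, nv))
      in_block <- 0L
      fk <- NULL
      for (k in seq_len(nv)) {
        j <- j + 1L
        if (in_block == 0L) {
          b <- b + 1L
          f <- runif(1, config$maf_range[1], config$maf_range[2])
          fk <- sub_freqs(f)
          hap[, j] <- rbinom(2 * n, 1, fk[subpop])
          in_block <- config$ld_block_size - 1L
        } else {
          copy <- runif(2 * n) < config$within_block_copy_prob
          fresh <- rbinom(2 * n, 1, fk[subpop])
          hap[, j] <- ifelse(copy, hap[, j - 1L], fresh)
          in_block <- in_block - 1L
        }
        chrom[j] <- ch; pos[j] <- p[k]; block[j] <- b
        tmaf[j] <- mean(fk[subpop])  # expected overall allele frequency
      }
    }
    dosage <- hap[seq(1, 2 * n, by = 2), , drop = FALSE] +
      hap[seq(2, 2 * n, by = 2), , drop = FALSE]
    dosage <- t(dosage)
    colnames(dosage) <- sprintf("D%03d", seq_len(n))
    variants <- tibble(
      chrom = paste0("chr", chrom), pos = pos,
      id = sprintf("var%05d", seq_len(config$n_variants)),
      ref = "A", alt = "G", block = block, target_maf = tmaf
    )
    g <- geno_matrix(dosage, variants)
    attr(g, "haplotypes") <- hap
    attr(g, "subpop") <- subpop[seq(1, 2 * n, by = 2)]
    g
  })
}

sample_intervals <- function(n, chrom_lens, width_lo, width_hi, prefix) {
  ch <- sample(names(chrom_lens), n, replace = TRUE,
               prob = chrom_lens / sum(chrom_lens))
  w <- round(runif(n, width_lo, width_hi))
  s <- vapply(seq_len(n), function(i) {
    sample.int(max(1, chrom_lens[[ch[i]]] - w[i]), 1)
  }, numeric(1))
  arrange(tibble(chrom = ch, start = as.integer(s), end = as.integer(s + w),
                 name = sprintf("%s%05d", prefix, seq_len(n)),
                 score = 0, strand = "."),
          .data$chrom, .data$start)
}

#' Simulate features, QTL wiring, motif table and annotation tracks
#'
#' Places peaks and genes on the simulated genome, wires QTL scenarios
#' (`shared`, `primed`, `stimulus_specific`, `response_magnitude`) by pairing
#' a peak with a gene whose TSS lies within 1 Mb and assigning a common-variant
#' causal SNP inside the peak +/- 25 kb, plants condition fold changes on
#' responsive peaks/genes, emits a peak-by-motif presence table with extra
#' log-odds for planted motifs in responsive peaks, and lays annotation
#' interval sets with planted enrichment over QTL peaks.
#'
#' @param config a [sim_config()].
#' @param genotypes panel from [simulate_genotypes()].
#' @return list with `peaks`, `genes`, `motif_table`, `annotations` (named
#'   list of interval tibbles) and `truth` (features / pairs / motifs tibbles).
#' @export
simulate_features <- function(config, genotypes) {
  with_stage_seed(config$seed, "features", {
    vt <- genotypes$variants
    chrom_lens <- vapply(split(vt$pos, vt$chrom), max, numeric(1)) + 50000
    peaks <- sample_intervals(config$n_peaks, chrom_lens, 200, 2000, "peak")
    peaks$gc <- runif(config$n_peaks, 0.3, 0.7)
    genes <- sample_intervals(config$n_genes, chrom_lens, 2000, 50000, "gene")
    genes$strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    genes$gc <- runif(config$n_genes, 0.35, 0.65)
    genes$tss <- tss_of(genes$start, genes$end, genes$strand)

    stim <- setdiff(config$conditions, config$conditions[1])
    veh <- config$conditions[1]

    n_pairs <- round(config$frac_caqtl * config$n_peaks)
    mix <- config$scenario_mix / sum(config$scenario_mix)
    scen <- sample(names(mix), n_pairs, replace = TRUE, prob = mix)
    scen <- scen[scen != "null"]

    common <- vt[vt$maf >= config$causal_maf_min, ]
    used_peaks <- character(); used_genes <- character()
    pairs <- list()
    for (sc in scen) {
      pk <- peaks[!peaks$name %in% used_peaks, ]
      if (nrow(pk) == 0) abort("genome too small: no free peaks left; increase n_peaks")
      ok <- FALSE
      for (pi in sample.int(nrow(pk))) {
        p1 <- pk[pi, ]
        cand_v <- common[common$chrom == p1$chrom &
                           pos_in_interval(common$pos, p1$start - 25000, p1$end + 25000), ]
        gn <- genes[!genes$name %in% used_genes & genes$chrom == p1$chrom, ]
        if (nrow(gn)) {
          d <- abs(gn$tss - (p1$start + p1$end) / 2)
          gn <- gn[d <= 1e6, ]
        }
        if (nrow(cand_v) && nrow(gn)) {
          cv <- cand_v[sample.int(nrow(cand_v), 1), ]
          gn <- gn[abs(gn$tss - cv$pos) <= 1e6, ]
          if (nrow(gn)) {
            g1 <- gn[sample.int(nrow(gn), 1), ]
            pairs[[length(pairs) + 1]] <- tibble(
              peak_id = p1$name, gene_id = g1$name, scenario = sc,
              causal_variant = cv$id)
            used_peaks <- c(used_peaks, p1$name)
            used_genes <- c(used_genes, g1$name)
            ok <- TRUE
            break
          }
        }
      }
      if (!ok) {
        n_short <- sum(scen == sc) # at least this scenario unmet
        if (!length(pairs)) {
          abort("genome too small to satisfy wiring constraints; increase n_variants/n_genes or chromosome length")
        }
        warn(sprintf(
          "wiring stopped at %d of %d requested scenario pairs (no wireable free peak left); increase n_peaks/n_genes for more",
          length(pairs), length(scen)))
        break
      }
    }
    pairs <- if (length(pairs)) list_rbind(pairs) else
      tibble(peak_id = character(), gene_id = character(),
             scenario = character(), causal_variant = character())

    # extra direct eQTLs on unwired genes
    n_eg <- round(config$frac_eqtl * config$n_genes)
    egenes <- list()
    free_g <- genes[!genes$name %in% used_genes, ]
    if (n_eg > 0 && nrow(free_g)) {
      idx <- sample.int(nrow(free_g), min(n_eg, nrow(free_g)))
      esc <- sample(names(mix), length(idx), replace = TRUE, prob = mix)
      for (i in seq_along(idx)) {
        if (esc[i] == "null") next
        g1 <- free_g[idx[i], ]
        cand_v <- common[common$chrom == g1$chrom &
                           common$pos >= g1$start - 1e6 & common$pos <= g1$end + 1e6, ]
        if (!nrow(cand_v)) next
        cv <- cand_v[sample.int(nrow(cand_v), 1), ]
        egenes[[length(egenes) + 1]] <- tibble(
          gene_id = g1$name, scenario = esc[i], causal_variant = cv$id)
      }
    }
    egenes <- if (length(egenes)) list_rbind(egenes) else
      tibble(gene_id = character(), scenario = character(), causal_variant = character())

    # condition fold changes (log2): responsive peaks / genes
    wre_ids <- sample(peaks$name, round(config$frac_wre * config$n_peaks))
    deg_ids <- sample(genes$name, round(config$frac_deg * config$n_genes))
    lfc_tbl <- function(ids, all_ids) {
      sgn <- sample(c(-1, 1), length(ids), replace = TRUE)
      out <- matrix(0, nrow = length(all_ids), ncol = length(config$conditions),
                    dimnames = list(all_ids, config$conditions))
      for (s in stim) out[ids, s] <- sgn * config$beta_lfc
      out
    }
    lfc_peaks <- lfc_tbl(wre_ids, peaks$name)
    lfc_genes <- lfc_tbl(deg_ids, genes$name)

    # per-condition genetic effects (natural log per allele)
    beta_for <- function(vid) {
      if (is.null(config$target_r2)) return(config$beta_ca)
      f <- vt$maf[match(vid, vt$id)]
      noise <- 1 / config$dispersion + 1 / 150 + config$donor_sd^2
      sqrt(config$target_r2 / (1 - config$target_r2) * noise / (2 * f * (1 - f)))
    }
    beta_peaks <- matrix(0, nrow = config$n_peaks, ncol = length(config$conditions),
                         dimnames = list(peaks$name, config$conditions))
    gamma_pairs <- matrix(0, nrow = nrow(pairs), ncol = length(config$conditions),
                          dimnames = list(pairs$peak_id, config$conditions))
    if (nrow(pairs)) for (i in seq_len(nrow(pairs))) {
      b <- beta_for(pairs$causal_variant[i]) * sample(c(-1, 1), 1)
      sc <- pairs$scenario[i]
      if (sc %in% c("shared", "primed")) {
        beta_peaks[pairs$peak_id[i], ] <- b
      } else if (sc == "stimulus_specific") {
        beta_peaks[pairs$peak_id[i], stim] <- b
      } else if (sc == "response_magnitude") {
        beta_peaks[pairs$peak_id[i], veh] <- b
        beta_peaks[pairs$peak_id[i], stim] <- b + sign(b) * config$beta_interaction
      }
      gamma_pairs[i, ] <- config$mediation_gamma
      if (sc == "primed") gamma_pairs[i, veh] <- 0
    }
    beta_genes <- matrix(0, nrow = config$n_genes, ncol = length(config$conditions),
                         dimnames = list(genes$name, config$conditions))
    if (nrow(egenes)) for (i in seq_len(nrow(egenes))) {
      b <- beta_for(egenes$causal_variant[i]) * sample(c(-1, 1), 1)
      sc <- egenes$scenario[i]
      if (sc %in% c("shared", "primed")) {
        beta_genes[egenes$gene_id[i], ] <- b
        if (sc == "primed") beta_genes[egenes$gene_id[i], veh] <- 0
      } else if (sc == "stimulus_specific") {
        beta_genes[egenes$gene_id[i], stim] <- b
      } else if (sc == "response_magnitude") {
        beta_genes[egenes$gene_id[i], veh] <- b
        beta_genes[egenes$gene_id[i], stim] <- b + sign(b) * config$beta_interaction
      }
    }

    # motif table: planted motifs over-represented in responsive (WRE) peaks
    motif_ids <- sprintf("motif%03d", seq_len(config$n_motifs))
    planted <- rep(0, config$n_motifs)
    planted[seq_len(round(config$frac_motif_planted * config$n_motifs))] <- config$motif_logOR
    is_wre <- as.numeric(peaks$name %in% wre_ids)
    eta <- qlogis(config$motif_base_rate)
    motif_mat <- vapply(seq_len(config$n_motifs), function(m) {
      rbinom(config$n_peaks, 1, plogis(eta + planted[m] * is_wre))
    }, numeric(config$n_peaks))
    dimnames(motif_mat) <- list(peaks$name, motif_ids)
    motif_table <- list(
      presence = motif_mat,
      peaks = tibble(name = peaks$name, width = peaks$end - peaks$start,
                     conserved_pct = runif(config$n_peaks, 0, 0.5))
    )

    # annotation tracks with planted enrichment over QTL peaks
    qtl_peaks <- peaks[peaks$name %in% pairs$peak_id, ]
    annotations <- imap(as.list(config$annotation_sets), function(nn, set) {
      base <- sample_intervals(nn, chrom_lens, 100, 1000, paste0(set, "_"))
      n_enr <- if (nrow(qtl_peaks)) round(config$annotation_enrich * nn) else 0
      if (n_enr > 0) {
        tgt <- qtl_peaks[sample.int(nrow(qtl_peaks), n_enr, replace = TRUE), ]
        mid <- floor((tgt$start + tgt$end) / 2)
        w <- round(runif(n_enr, 100, 1000))
        base[seq_len(n_enr), c("chrom", "start", "end")] <-
          tibble(chrom = tgt$chrom, start = as.integer(pmax(0, mid - w %/% 2)),
                 end = as.integer(mid + w %/% 2 + 1))
      }
      arrange(base, .data$chrom, .data$start)
    })

    feat_truth <- bind_rows(
      tibble(feature_id = peaks$name, assay = "atac",
             scenario = ifelse(peaks$name %in% pairs$peak_id,
                               pairs$scenario[match(peaks$name, pairs$peak_id)], "null"),
             causal_variant = pairs$causal_variant[match(peaks$name, pairs$peak_id)],
             lfc2 = map(peaks$name, ~ setNames(lfc_peaks[.x, ], config$conditions)),
             beta = map(peaks$name, ~ setNames(beta_peaks[.x, ], config$conditions))),
      tibble(feature_id = genes$name, assay = "rna",
             scenario = dplyr::case_when(
               genes$name %in% pairs$gene_id ~ pairs$scenario[match(genes$name, pairs$gene_id)],
               genes$name %in% egenes$gene_id ~ egenes$scenario[match(genes$name, egenes$gene_id)],
               TRUE ~ "null"),
             causal_variant = dplyr::coalesce(
               pairs$causal_variant[match(genes$name, pairs$gene_id)],
               egenes$causal_variant[match(genes$name, egenes$gene_id)]),
             lfc2 = map(genes$name, ~ setNames(lfc_genes[.x, ], config$conditions)),
             beta = map(genes$name, ~ setNames(beta_genes[.x, ], config$conditions)))
    )

    list(
      peaks = peaks, genes = genes, motif_table = motif_table,
      annotations = annotations,
      truth = list(
        features = feat_truth,
        pairs = pairs, egenes = egenes,
        beta_peaks = beta_peaks, beta_genes = beta_genes,
        gamma_pairs = gamma_pairs,
        lfc_peaks = lfc_peaks, lfc_genes = lfc_genes,
        motifs = tibble(motif_id = motif_ids, planted_logor = planted),
        wre_ids = wre_ids, deg_ids = deg_ids
      )
    )
  })
}

#' Simulate paired negative-binomial count matrices
#'
#' For sample s (donor d, condition c) and feature j the count is
#' NB(mean = exp(logL_s + slope_s (GC_j - 0.5) + a_j + u_d + ln2 LFC2_jc +
#' beta_jc x_dj), size = dispersion) with u_d ~ N(0, donor_sd^2). Wired genes
#' additionally receive `mediation_gamma` times the peak's realized genetic
#' log-effect, so their eQTLs are peak-mediated. Samples are dropped per
#' condition-assay at `missing_rate`.
#'
#' @param genotypes panel from [simulate_genotypes()].
#' @param features output of [simulate_features()].
#' @param config a [sim_config()].
#' @return list with `atac`, `rna` (integer count matrices), `sheet`
#'   (sample sheet tibble with a `rin` covariate) and `truth` additions
#'   (`donor_effects`, `log_libsize`).
#' @export
simulate_counts <- function(genotypes, features, config) {
  with_stage_seed(config$seed, "counts", {
    donors <- genotypes$samples
    conds <- config$conditions
    sheet <- tidyr::expand_grid(donor_id = donors, condition = conds)
    sheet$sample_id <- paste(sheet$donor_id, sheet$condition, sep = "_")
    sheet$rin <- round(rnorm(nrow(sheet), 8, 0.5), 2)
    sheet <- select(sheet, "sample_id", "donor_id", "condition", "rin")

    # feature-specific donor intercepts (cell-line intrinsic effects vary by
    # feature, so latent-factor removal cannot absorb them)
    u_peaks <- matrix(rnorm(config$n_peaks * length(donors), 0, config$donor_sd),
                      config$n_peaks, length(donors), dimnames = list(NULL, donors))
    u_genes <- matrix(rnorm(config$n_genes * length(donors), 0, config$donor_sd),
                      config$n_genes, length(donors), dimnames = list(NULL, donors))
    logL <- rnorm(nrow(sheet), 0, config$libsize_lognormal_sd)
    gcslope <- rnorm(nrow(sheet), 0, config$gc_effect_amplitude)
    names(logL) <- names(gcslope) <- sheet$sample_id

    truth <- features$truth
    vt <- genotypes$variants
    dos <- genotypes$dosage

    base_mean <- function(n_feat, mu0, sdlog) rnorm(n_feat, log(mu0), sdlog)
    a_peaks <- base_mean(config$n_peaks, 150, 0.5)
    a_genes <- base_mean(config$n_genes, 300, 0.7)
    names(a_peaks) <- features$peaks$name
    names(a_genes) <- features$genes$name

    genetic_part <- function(feat_ids, beta_mat, causal_ids) {
      # features x samples matrix of beta_jc * dosage
      out <- matrix(0, length(feat_ids), nrow(sheet))
      has <- which(!is.na(causal_ids))
      for (i in has) {
        x <- dos[causal_ids[i], sheet$donor_id]
        out[i, ] <- beta_mat[feat_ids[i], sheet$condition] * x
      }
      out
    }
    ca_caus <- truth$pairs$causal_variant[match(features$peaks$name, truth$pairs$peak_id)]
    peak_gen <- genetic_part(features$peaks$name, truth$beta_peaks, ca_caus)

    log_mu_peaks <- outer(a_peaks, rep(0, nrow(sheet)), "+") +
      matrix(logL, config$n_peaks, nrow(sheet), byrow = TRUE) +
      outer(features$peaks$gc - 0.5, gcslope) +
      u_peaks[, sheet$donor_id, drop = FALSE] +
      log(2) * t(vapply(seq_len(config$n_peaks), function(j)
        truth$lfc_peaks[j, sheet$condition], numeric(nrow(sheet)))) +
      peak_gen

    g_caus <- dplyr::coalesce(
      truth$pairs$causal_variant[match(features$genes$name, truth$pairs$gene_id)],
      truth$egenes$causal_variant[match(features$genes$name, truth$egenes$gene_id)])
    gene_gen <- genetic_part(features$genes$name, truth$beta_genes, g_caus)
    # mediated component: gamma_c * beta_peak_c * x for wired pairs
    if (nrow(truth$pairs)) for (i in seq_len(nrow(truth$pairs))) {
      gi <- match(truth$pairs$gene_id[i], features$genes$name)
      x <- dos[truth$pairs$causal_variant[i], sheet$donor_id]
      med <- truth$gamma_pairs[i, sheet$condition] *
        truth$beta_peaks[truth$pairs$peak_id[i], sheet$condition] * x
      gene_gen[gi, ] <- gene_gen[gi, ] + med
    }
    log_mu_genes <- outer(a_genes, rep(0, nrow(sheet)), "+") +
      matrix(logL, config$n_genes, nrow(sheet), byrow = TRUE) +
      outer(features$genes$gc - 0.5, gcslope) +
      u_genes[, sheet$donor_id, drop = FALSE] +
      log(2) * t(vapply(seq_len(config$n_genes), function(j)
        truth$lfc_genes[j, sheet$condition], numeric(nrow(sheet)))) +
      matrix(config$rin_effect * (sheet$rin - 8), config$n_genes, nrow(sheet), byrow = TRUE) +
      gene_gen

    if (max(log_mu_peaks, log_mu_genes) > 30) {
      abort("log-mean overflow (> 30); check sim_config effect sizes / baselines")
    }
    draw <- function(log_mu, feat_names) {
      m <- matrix(rnbinom(length(log_mu), mu = exp(log_mu), size = config$dispersion),
                  nrow = nrow(log_mu),
                  dimnames = list(feat_names, sheet$sample_id))
      storage.mode(m) <- "integer"
      m
    }
    atac <- draw(log_mu_peaks, features$peaks$name)
    rna <- draw(log_mu_genes, features$genes$name)
    keep_cols <- function() runif(nrow(sheet)) >= config$missing_rate
    atac <- atac[, keep_cols(), drop = FALSE]
    rna <- rna[, keep_cols(), drop = FALSE]
    list(atac = atac, rna = rna, sheet = sheet,
         donor_effects = list(atac = u_peaks, rna = u_genes),
         baselines = list(atac = a_peaks, rna = a_genes),
         log_libsize = logL)
  })
}

#' Simulate GWAS summary statistics sharing causal variants with planted QTLs
#'
#' Loci are taken from wired QTL scenarios; `shared` loci reuse the QTL
#' causal variant as the trait's causal variant, `distinct` loci use a
#' low-LD (r2 < 0.1) variant in the same region. An independent cohort of
#' `gwas_n` individuals is resampled from the panel haplotypes (mosaic
#' copying with a small switch rate, preserving allele frequencies and LD)
#' and per-variant marginal regressions give beta/se/p/freq/n.
#'
#' @param genotypes panel from [simulate_genotypes()] (needs the
#'   `haplotypes` attribute).
#' @param features output of [simulate_features()].
#' @param config a [sim_config()].
#' @return list with `sumstats` (tibble, one row per region variant, extra
#'   `locus` column) and `loci` (tibble: locus, qtl_feature, qtl_variant,
#'   gwas_causal, mode).
#' @export
simulate_gwas <- function(genotypes, features, config) {
  hap <- attr(genotypes, "haplotypes")
  if (is.null(hap)) abort("genotypes lack the 'haplotypes' attribute; use simulate_genotypes()")
  if (config$gwas_n < 100) warn("gwas_n < 100: no genome-wide-significant loci expected")
  with_stage_seed(config$seed, "gwas", {
    vt <- genotypes$variants
    pairs <- features$truth$pairs
    if (!nrow(pairs)) {
      return(list(sumstats = tibble(), loci = tibble()))
    }
    # pick loci whose regions do not overlap (one sumstats row per variant)
    cand <- seq_len(nrow(pairs))
    idx <- integer(); taken <- tibble(chrom = character(), pos = integer())
    min_gap <- 2 * config$gwas_region_halfwidth + 1
    for (i in cand) {
      if (length(idx) >= config$n_gwas_loci) break
      vi <- match(pairs$causal_variant[i], vt$id)
      if (any(taken$chrom == vt$chrom[vi] & abs(taken$pos - vt$pos[vi]) < min_gap)) next
      idx <- c(idx, i)
      taken <- bind_rows(taken, tibble(chrom = vt$chrom[vi], pos = vt$pos[vi]))
    }
    if (!length(idx)) {
      return(list(sumstats = tibble(), loci = tibble()))
    }
    modes <- rep(c("shared", "distinct"), length.out = length(idx))
    loci <- list(); stats <- list()
    for (k in seq_along(idx)) {
      qv <- pairs$causal_variant[idx[k]]
      qi <- match(qv, vt$id)
      region <- which(vt$chrom == vt$chrom[qi] &
                        abs(vt$pos - vt$pos[qi]) <= config$gwas_region_halfwidth)
      causal <- qv
      if (modes[k] == "distinct") {
        r2 <- drop(ld_r2(genotypes$dosage[region, , drop = FALSE],
                         genotypes$dosage[qi, , drop = FALSE]))
        cand <- region[which(r2 < 0.1 & vt$maf[region] >= config$causal_maf_min)]
        if (!length(cand)) cand <- region[which.min(r2)]
        causal <- vt$id[sample(rep(cand, 2), 1)]
      }
      X <- resample_cohort(hap[, region, drop = FALSE], config$gwas_n, switch_rate = 0.05)
      colnames(X) <- vt$id[region]
      xc <- X[, causal]
      ve <- config$gwas_var_explained
      vx <- var(xc)
      b_true <- if (vx > 0) sqrt(ve / vx) else 0
      y <- b_true * xc + rnorm(config$gwas_n, 0, sqrt(max(1 - ve, 0.01)))
      st <- marginal_scan(X, y)
      st$id <- vt$id[region]
      st$chrom <- vt$chrom[region]
      st$pos <- vt$pos[region]
      st$effect_allele <- "G"; st$other_allele <- "A"
      st$n <- config$gwas_n
      st$locus <- sprintf("locus%02d", k)
      stats[[k]] <- st
      loci[[k]] <- tibble(locus = st$locus[1], qtl_feature = pairs$peak_id[idx[k]],
                          qtl_gene = pairs$gene_id[idx[k]],
                          qtl_variant = qv, gwas_causal = causal, mode = modes[k])
    }
    ss <- list_rbind(stats)
    ss$z <- ss$beta / ss$se
    ss <- select(ss, "id", "chrom", "pos", "effect_allele", "other_allele",
                 "freq", "beta", "se", "p", "n", "z", "locus")
    list(sumstats = ss, loci = list_rbind(loci))
  })
}

# Mosaic-resample a cohort of n diploid individuals from panel haplotypes.
resample_cohort <- function(hap_region, n, switch_rate = 0.05) {
  nh <- nrow(hap_region); nv <- ncol(hap_region)
  m <- 2L * n
  idx <- sample.int(nh, m, replace = TRUE)
  out <- matrix(0L, m, nv)
  for (j in seq_len(nv)) {
    if (j > 1) {
      sw <- which(runif(m) < switch_rate)
      if (length(sw)) idx[sw] <- sample.int(nh, length(sw), replace = TRUE)
    }
    out[, j] <- hap_region[idx, j]
  }
  out[seq(1, m, 2), , drop = FALSE] + out[seq(2, m, 2), , drop = FALSE]
}

# Vectorized per-variant simple regression y ~ x.
marginal_scan <- function(X, y) {
  n <- length(y)
  xm <- colMeans(X)
  yc <- y - mean(y)
  xx <- colSums(X^2) - n * xm^2
  xy <- drop(crossprod(X, yc))
  beta <- ifelse(xx > 0, xy / xx, 0)
  rss <- sum(yc^2) - beta^2 * xx
  se <- sqrt(pmax(rss / (n - 2), 1e-300) / pmax(xx, 1e-12))
  tval <- beta / se
  tibble(freq = xm / 2, beta = beta, se = se,
         p = pmin(1, 2 * pt(-abs(tval), df = n - 2)))
}

#' Simulate a complete dataset
#'
#' Runs all simulator stages under one master seed and returns the dataset
#' plus its planted ground truth.
#'
#' @param config a [sim_config()].
#' @return list: `genotypes`, `peaks`, `genes`, `atac`, `rna`, `sheet`,
#'   `motif_table`, `annotations`, `gwas`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  geno <- simulate_genotypes(config)
  feats <- simulate_features(config, geno)
  cnt <- simulate_counts(geno, feats, config)
  gwas <- simulate_gwas(geno, feats, config)
  truth <- feats$truth
  truth$donor_effects <- cnt$donor_effects
  truth$baselines <- cnt$baselines
  truth$gwas_loci <- gwas$loci
  list(genotypes = geno, peaks = feats$peaks, genes = feats$genes,
       atac = cnt$atac, rna = cnt$rna, sheet = cnt$sheet,
       motif_table = feats$motif_table, annotations = feats$annotations,
       gwas = gwas$sumstats, truth = truth, config = config)
}

#' Write a simulated dataset to disk
#'
#' Emits the external-format files (VCF, BEDs, count TSVs, sheet, sumstats,
#' motif table, ground-truth TSVs) plus a manifest recording the
#' configuration, seed and per-file MD5 checksums. Re-running with the same
#' configuration reproduces the files byte-identically.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory.
#' @param force overwrite a non-empty directory.
#' @return manifest list, invisibly.
#' @export
write_dataset <- function(sim, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force) {
    abort(sprintf("directory %s is non-empty; use force = TRUE", dir))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_vcf(sim$genotypes, p("genotypes.vcf"))
  write_bed(sim$peaks, p("peaks.bed"))
  readr::write_tsv(sim$genes, p("genes.tsv"), progress = FALSE)
  write_counts(sim$atac, p("atac_counts.tsv"), id_col = "peak_id")
  write_counts(sim$rna, p("rna_counts.tsv"), id_col = "gene_id")
  readr::write_tsv(sim$sheet, p("sample_sheet.tsv"), progress = FALSE)
  if (nrow(sim$gwas)) write_sumstats(sim$gwas, p("gwas.ma"))
  mt <- cbind(sim$motif_table$peaks,
              as.data.frame(sim$motif_table$presence))
  readr::write_tsv(as_tibble(mt), p("motif_table.tsv"), progress = FALSE)
  for (set in names(sim$annotations)) {
    write_bed(sim$annotations[[set]], p(paste0("annotation_", set, ".bed")))
  }
  ft <- sim$truth$features
  ft_flat <- bind_cols(
    select(ft, "feature_id", "assay", "scenario", "causal_variant"),
    as_tibble(do.call(rbind, ft$lfc2), .name_repair = ~ paste0("lfc2_", .x)),
    as_tibble(do.call(rbind, ft$beta), .name_repair = ~ paste0("beta_", .x))
  )
  readr::write_tsv(ft_flat, p("truth_features.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$pairs, p("truth_pairs.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$motifs, p("truth_motifs.tsv"), progress = FALSE)
  if (!is.null(sim$truth$gwas_loci) && nrow(sim$truth$gwas_loci)) {
    readr::write_tsv(sim$truth$gwas_loci, p("truth_gwas_loci.tsv"), progress = FALSE)
  }
  files <- sort(list.files(dir))
  manifest <- list(
    config = sim$config[setdiff(names(sim$config), character())],
    seed = sim$config$seed,
    checksums = as.list(tools::md5sum(file.path(dir, files)))
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
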