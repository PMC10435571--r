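# End-to-end drivers: peaks -> ranked blood-group candidates with motif hits
# and variant impacts; genotype table -> haplotype/LD report; cohort table ->
# ANOVA/OLS association report.

#' Mine blood-group regulatory candidates from ChIP-seq peak sets
#'
#' Runs the full mining pipeline: replicate merging per dataset, reference
#' selection (most peaks), cross-dataset overlap counting at each reference
#' peak, gene annotation (body / promoter / nearest TSS), filtering to
#' blood-group genes with excluded-TF removal, motif scanning of the genome,
#' per-site best-hit attachment, optional variant-impact scoring, and
#' ranking by overlap count, peak score and motif score.
#'
#' @param peaks A peak tibble covering >= 2 `dataset_id`s (bind several
#'   [read_narrowpeak()] results).
#' @param genome Genome tibble from [read_fasta()].
#' @param genes Gene tibble from [read_gene_bed()].
#' @param pfm A [pfm()] count matrix.
#' @param variants Optional variant tibble from [read_vcf_lite()].
#' @param config A [run_config()]; its `pseudocount`, `background`,
#'   `rel_threshold`, `min_overlap` and `upstream_window` drive the run.
#' @return An object of class `"mining_result"`: `candidates` (ranked
#'   tibble), `hits` (all motif hits), `site_hits` (hits inside candidate
#'   sites), `impacts` (variant impact records, possibly empty), `reference`
#'   dataset id, `removed` (filtered sites with reasons) and the `config`.
#' @export
mine_candidates <- function(peaks, genome, genes, pfm, variants = NULL,
                            config = run_config()) {
  merged <- merge_replicates(peaks)
  reference <- select_reference(merged)
  sites <- consensus_sites(merged, reference)
  sites <- annotate_to_genes(sites, genes, config$upstream_window)
  sites <- filter(sites, .data$k >= config$min_overlap)
  sites <- filter_candidates(sites, genes)
  removed <- attr(sites, "removed")

  pwm <- build_pwm(pfm, background = config$background, pseudocount = config$pseudocount)
  hits <- scan_sequence(pwm, genome, threshold = config$rel_threshold)

  site_hits <- hits[0, ]
  sites$n_motif_hits <- 0L
  sites$best_relative_score <- NA_real_
  if (nrow(sites) > 0 && nrow(hits) > 0) {
    ov <- GenomicRanges::findOverlaps(intervals_to_gr(hits), intervals_to_gr(sites))
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    site_hits <- hits[qh, ]
    site_hits$site_index <- sh
    agg <- site_hits |>
      group_by(.data$site_index) |>
      summarise(n_motif_hits = n(), best_relative_score = max(.data$relative_score))
    sites$n_motif_hits[agg$site_index] <- agg$n_motif_hits
    sites$best_relative_score[agg$site_index] <- agg$best_relative_score
  }

  impacts <- NULL
  if (!is.null(variants) && nrow(site_hits) > 0) {
    pairs <- variants_in_motif(site_hits, variants)
    impacts <- delta_relative_score(pwm, pairs) |> frequency_triage()
  }

  structure(list(
    candidates = rank_candidates(sites),
    hits = hits, site_hits = site_hits,
    impacts = impacts, reference = reference,
    removed = removed, config = config, pwm = pwm
  ), class = "mining_result")
}

#' @export
print.mining_result <- function(x, ...) {
  cat(sprintf(
    "<mining_result> reference %s | %d candidate site(s) | %d motif hit(s) in sites\n",
    x$reference, nrow(x$candidates), nrow(x$site_hits)
  ))
  if (!is.null(x$impacts) && nrow(x$impacts)) {
    cat(sprintf("  %d variant impact record(s); top delta %.3f (%s)\n",
                nrow(x$impacts), x$impacts$delta[1], x$impacts$id[1]))
  }
  print(head(x$candidates, 10))
  invisible(x)
}

#' @method tidy mining_result
#' @export
tidy.mining_result <- function(x, ...) x$candidates

#' Two-locus haplotype and linkage-disequilibrium report
#'
#' @param genotypes A genotype tibble (`dose_locus1`, `dose_locus2`).
#' @param mode Estimation mode passed to [estimate_haplotypes()].
#' @return An object of class `"ld_report"` bundling the haplotype
#'   frequencies, the LD statistics and the genotype-concordance report.
#' @export
run_ld <- function(genotypes, mode = "paper-rule") {
  hf <- estimate_haplotypes(genotypes, mode = mode)
  structure(list(
    haplotypes = hf,
    ld = compute_ld(hf),
    concordance = genotype_concordance(genotypes)
  ), class = "ld_report")
}

#' @export
print.ld_report <- function(x, ...) {
  print(x$haplotypes)
  cat(sprintf("  D = %.4f, D' = %.4f, r^2 = %s\n", x$ld$D, x$ld$D_prime,
              format(x$ld$r_squared, digits = 4)))
  cat(sprintf("  separable samples: %d/%d\n", x$concordance$n_separable, x$concordance$n))
  invisible(x)
}

#' @method tidy ld_report
#' @export
tidy.ld_report <- function(x, ...) tidy(x$haplotypes)

#' @method glance ld_report
#' @export
glance.ld_report <- function(x, ...) {
  dplyr::bind_cols(
    x$ld,
    tibble(mode = x$haplotypes$mode, n = x$haplotypes$n,
           n_separable = x$concordance$n_separable)
  )
}

#' Cohort genotype-dose association analysis
#'
#' Computes per-sample ddCt, compares geometric MFI across locus-1 genotype
#' groups by one-way ANOVA with Bonferroni post-hoc tests, and fits OLS
#' dose regressions for log geometric MFI and for ddCt against both loci
#' (0/1/2 coding). When the two dose columns are collinear (loci in complete
#' LD) the two-locus regressions are skipped with a note and single-locus
#' fits are reported instead.
#'
#' @param cohort A cohort tibble (see [simulate_cohort()] for columns).
#' @param calibrator Calibrator dCt for the ddCt normalization.
#' @return An object of class `"assoc_report"`.
#' @export
run_assoc <- function(cohort, calibrator = 0) {
  cohort <- cohort_ddct(cohort, calibrator)
  cohort$log_mfi <- log(cohort$mfi_geometric)
  keep <- cohort |>
    group_by(.data$dose_locus1) |>
    filter(n() >= 2) |>
    ungroup()
  anova_mfi <- anova_bonferroni(keep, .data$mfi_geometric, .data$dose_locus1)
  collinear <- all(cohort$dose_locus1 == cohort$dose_locus2)
  if (collinear) {
    inform("dose_locus1 and dose_locus2 are identical (complete LD): reporting single-locus regressions")
    doses <- "dose_locus1"
  } else {
    doses <- c("dose_locus1", "dose_locus2")
  }
  structure(list(
    anova_mfi = anova_mfi,
    ols_mfi = ols_dose_regression(cohort, .data$log_mfi, doses = doses),
    ols_ddct = ols_dose_regression(cohort, .data$ddct, doses = doses),
    collinear = collinear, cohort = cohort
  ), class = "assoc_report")
}

#' @export
print.assoc_report <- function(x, ...) {
  print(x$anova_mfi)
  cat("log geometric MFI ~ doses:\n")
  print(x$ols_mfi)
  cat("ddCt ~ doses:\n")
  print(x$ols_ddct)
  invisible(x)
}

#' @method tidy assoc_report
#' @export
tidy.assoc_report <- function(x, ...) {
  bind_rows(
    mutate(tidy(x$ols_mfi), outcome = "log_mfi"),
    mutate(tidy(x$ols_ddct), outcome = "ddct")
  ) |> relocate("outcome")
}
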