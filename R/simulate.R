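# Synthetic ground-truth input bundles: genome with planted GATA-type motifs,
# multi-dataset peak sets with jitter and false peaks, a motif-disrupting SNV
# at a stated MAF, and a cohort with a dose-dependent expression effect.

#' The package's synthetic GATA1-type position frequency matrix
#'
#' An 11-column GATA-type count matrix with a WGATAR core (highest-information
#' columns 4-7 spelling GATA). It is a synthetic stand-in constructed for
#' simulation and testing, not a database matrix.
#'
#' @return A [pfm()] object.
#' @export
gata1_synthetic_pfm <- function() {
  read_jaspar_pfm(system.file("extdata", "gata1_synthetic.jaspar", package = "regulomine"))
}

default_sim_genes <- function() {
  tibble(
    gene = c("BG1", "BG2", "TF1", "HK1"),
    contig = "chrS",
    start = c(2000L, 12000L, 18000L, 24000L),
    end = c(9000L, 15000L, 21000L, 26500L),
    strand = c("+", "-", "+", "+"),
    is_blood_group = c(TRUE, TRUE, TRUE, FALSE),
    is_excluded_tf = c(FALSE, FALSE, TRUE, FALSE)
  )
}

default_sim_sites <- function() {
  # two motifs 710 bp apart in the CR1-like gene BG1 (motif 2 on the minus
  # strand), one site in a second blood-group gene, one decoy in the
  # excluded-TF gene and one in a non-blood-group gene to exercise filters
  tibble(
    site_id = c("motif1", "motif2", "bg2_site", "tf_decoy", "hk_decoy"),
    gene = c("BG1", "BG1", "BG2", "TF1", "HK1"),
    contig = "chrS",
    start = c(4000L, 4710L, 13500L, 19500L, 25200L),
    strand = c("+", "-", "+", "+", "+"),
    is_decoy = c(FALSE, FALSE, FALSE, TRUE, TRUE)
  )
}

#' Build a simulation manifest
#'
#' The manifest is the ground-truth ledger for a synthetic input bundle. Its
#' defaults mirror the shape of the study the pipeline targets: K = 4
#' ChIP-seq datasets, two planted motifs 710 bp apart in a CR1-like
#' blood-group gene, a motif-disrupting SNV at minor allele frequency 0.157,
#' and a cohort of n = 396 with a negative log-scale expression effect per
#' copy of the minor allele at locus 1 and no direct effect at locus 2.
#'
#' @param seed Integer seed; every derived dataset is a deterministic
#'   function of the manifest.
#' @param genome_length Genome length, bp.
#' @param gc GC content of the background sequence.
#' @param genes Gene annotation tibble (see [read_gene_bed()] for columns).
#' @param sites Planted-site tibble (`site_id`, `gene`, `contig`, `start`,
#'   `strand`, `is_decoy`).
#' @param pfm The motif count matrix planted and scanned.
#' @param n_datasets Number of ChIP-seq datasets K.
#' @param peak_width Nominal peak width, bp.
#' @param jitter_sd Normal jitter SD applied to each peak end, bp.
#' @param miss_rate Probability a dataset misses a true site.
#' @param false_per_dataset Number of false peaks per dataset.
#' @param snv_maf Minor allele frequency of the motif-disrupting SNV.
#' @param cohort_n Cohort size.
#' @param hap_freq Four haplotype frequencies (AB, Ab, aB, ab); locus-1 minor
#'   allele frequency is `aB + ab`.
#' @param mfi_mu_log Baseline log geometric MFI.
#' @param beta_mfi Log-scale MFI decrease per dose-1 minor allele.
#' @param mfi_sigma Log-scale MFI noise SD.
#' @param beta_ct ddCt increase (cycles) per dose-1 minor allele.
#' @param ct_sigma SD of the realized ddCt noise (cycles).
#' @param calibrator_dct Calibrator sample dCt (cycles).
#' @return A list of class `"sim_manifest"`.
#' @export
simulation_manifest <- function(seed = 1L,
                                genome_length = 30000L, gc = 0.41,
                                genes = default_sim_genes(),
                                sites = default_sim_sites(),
                                pfm = gata1_synthetic_pfm(),
                                n_datasets = 4L, peak_width = 300L,
                                jitter_sd = 25, miss_rate = 0,
                                false_per_dataset = 6L,
                                snv_maf = 0.157,
                                cohort_n = 396L,
                                hap_freq = c(AB = 0.828, Ab = 0.015, aB = 0.010, ab = 0.147),
                                mfi_mu_log = log(1000), beta_mfi = 0.5, mfi_sigma = 0.35,
                                beta_ct = 0.8, ct_sigma = 0.5, calibrator_dct = 4) {
  stopifnot(
    genome_length > 0, gc > 0, gc < 1, n_datasets >= 2,
    miss_rate >= 0, miss_rate < 1, snv_maf > 0, snv_maf < 1,
    cohort_n >= 10, length(hap_freq) == 4, all(hap_freq >= 0),
    abs(sum(hap_freq) - 1) < 1e-9
  )
  L <- ncol(pfm$counts)
  if (any(sites$start < 0 | sites$start + L > genome_length)) {
    abort("planted sites must lie within genome bounds")
  }
  structure(list(
    seed = as.integer(seed), genome_length = as.integer(genome_length), gc = gc,
    genes = genes, sites = sites, pfm = pfm, motif_length = L,
    n_datasets = as.integer(n_datasets), peak_width = as.integer(peak_width),
    jitter_sd = jitter_sd, miss_rate = miss_rate,
    false_per_dataset = as.integer(false_per_dataset),
    snv_maf = snv_maf, cohort_n = as.integer(cohort_n),
    hap_freq = setNames(as.numeric(hap_freq), HAPLOTYPES),
    mfi_mu_log = mfi_mu_log, beta_mfi = beta_mfi, mfi_sigma = mfi_sigma,
    beta_ct = beta_ct, ct_sigma = ct_sigma, calibrator_dct = calibrator_dct
  ), class = "sim_manifest")
}

#' @export
print.sim_manifest <- function(x, ...) {
  cat(sprintf(
    "<sim_manifest> seed %d | genome %d bp | %d planted sites | K = %d datasets | cohort n = %d\n",
    x$seed, x$genome_length, nrow(x$sites), x$n_datasets, x$cohort_n
  ))
  invisible(x)
}

#' Simulate a genome with planted motifs
#'
#' Generates an i.i.d. background sequence at the manifest's GC content and
#' writes consensus motif instances (relative score 1) at the recorded
#' positions and strands, including one decoy inside an excluded-TF gene and
#' one inside a non-blood-group gene. Background windows that would score at
#' relative score >= 0.9 by chance are re-randomized so the planted truth is
#' unambiguous; overlapping planted motifs are an error.
#'
#' @param manifest A [simulation_manifest()].
#' @return A list: `genome` (tibble, see [read_fasta()]), `genes`, `truth`
#'   (planted-site table with `start`, `end`, `strand`, `is_decoy`).
#' @export
simulate_genome <- function(manifest) {
  L <- manifest$motif_length
  sites <- manifest$sites
  o <- order(sites$start)
  if (any(diff(sites$start[o]) < L)) abort("planted motifs overlap; truth would be ambiguous")
  pw <- build_pwm(manifest$pfm)
  with_pipeline_seed(manifest$seed, {
    p <- c(A = (1 - manifest$gc) / 2, C = manifest$gc / 2, G = manifest$gc / 2, T = (1 - manifest$gc) / 2)
    bases <- sample(DNA_BASES, manifest$genome_length, replace = TRUE, prob = p)
    for (i in seq_len(nrow(sites))) {
      w <- if (sites$strand[i] == "+") pw$consensus else revcomp(pw$consensus)
      bases[(sites$start[i] + 1):(sites$start[i] + L)] <- strsplit(w, "")[[1]]
    }
    planted_mask <- logical(manifest$genome_length)
    for (i in seq_len(nrow(sites))) {
      planted_mask[(sites$start[i] + 1):(sites$start[i] + L)] <- TRUE
    }
    for (iter in 1:50) {
      seq_str <- paste(bases, collapse = "")
      hits <- scan_sequence(pw, tibble(contig = "chrS", sequence = seq_str),
                            threshold = 0.9, p_values = FALSE)
      spurious <- hits[!(hits$start %in% sites$start), ]
      if (nrow(spurious) == 0) break
      for (s in spurious$start) {
        idx <- (s + 1):(s + L)
        idx <- idx[!planted_mask[idx]]
        if (length(idx)) bases[idx] <- sample(DNA_BASES, length(idx), replace = TRUE, prob = p)
      }
    }
    if (nrow(spurious) > 0) abort("could not de-noise background after 50 passes")
    genome <- tibble(contig = "chrS", sequence = paste(bases, collapse = ""))
    truth <- mutate(sites, end = .data$start + L)
    list(genome = genome, genes = manifest$genes, truth = truth)
  })
}

#' Simulate multi-dataset ChIP-seq peak sets
#'
#' For each of the K datasets, every true site yields a peak centered on the
#' motif with Normal end jitter (kept valid), dropped with the miss rate;
#' false peaks are added at the stated per-dataset rate in motif-free regions
#' (constructively never overlapping planted motifs). Peak scores are drawn
#' so true sites score stochastically higher than false peaks.
#'
#' @param manifest A [simulation_manifest()].
#' @param truth The planted-site truth table from [simulate_genome()].
#' @return A peak tibble across all datasets (columns as [read_narrowpeak()]).
#' @export
simulate_peaksets <- function(manifest, truth) {
  stopifnot(manifest$n_datasets >= 2)
  w <- manifest$peak_width
  half <- w %/% 2
  glen <- manifest$genome_length
  with_pipeline_seed(manifest$seed + 1L, {
    out <- purrr::map(seq_len(manifest$n_datasets), function(d) {
      id <- sprintf("d%d", d)
      center <- truth$start + manifest$motif_length %/% 2
      keep <- runif(nrow(truth)) >= manifest$miss_rate
      s <- pmax(0L, as.integer(round(center - half + rnorm(nrow(truth), 0, manifest$jitter_sd))))
      e <- pmin(glen, as.integer(round(center + half + rnorm(nrow(truth), 0, manifest$jitter_sd))))
      e <- pmax(e, s + manifest$motif_length) # keep valid and motif-covering
      true_peaks <- tibble(
        dataset_id = id, contig = truth$contig, start = s, end = e,
        score = pmax(100, round(rnorm(nrow(truth), 650, 80))),
        summit = center
      )[keep, ]
      # false peaks: uniform placement rejected near any planted motif
      n_false <- manifest$false_per_dataset
      fs <- integer(0)
      while (length(fs) < n_false) {
        cand <- sample.int(glen - w, n_false * 2, replace = TRUE)
        ok <- vapply(cand, function(x) {
          all(x + w < truth$start - 100 | x > truth$end + 100)
        }, logical(1))
        fs <- c(fs, cand[ok])
      }
      fs <- fs[seq_len(n_false)]
      false_peaks <- tibble(
        dataset_id = id, contig = truth$contig[1], start = as.integer(fs),
        end = as.integer(fs + w),
        score = pmax(10, round(rnorm(n_false, 250, 60))),
        summit = as.integer(fs + half)
      )
      bind_rows(true_peaks, false_peaks)
    })
    peaks <- bind_rows(out)
    peaks |>
      mutate(
        name = sprintf("%s_peak%d", .data$dataset_id, row_number()),
        strand = ".",
        signal_value = .data$score / 100,
        p_value = 5, q_value = 3
      ) |>
      select("dataset_id", "contig", "start", "end", "name", "score",
             "strand", "signal_value", "p_value", "q_value", "summit") |>
      arrange(.data$dataset_id, .data$contig, .data$start)
  })
}

#' Simulate the variant set
#'
#' Emits the motif-disrupting SNV of the default study design — a T>C change
#' on the forward strand that turns the minus-strand motif-2 core from GATA
#' to GGTA, at the manifest's MAF — plus an exceedingly rare G>A SNV
#' disrupting motif 1 (GATA to AATA) and one common SNV outside any motif.
#'
#' @param manifest A [simulation_manifest()].
#' @param sim_genome The [simulate_genome()] result (for reference bases).
#' @return A variant tibble (columns as [read_vcf_lite()]); attribute
#'   `"causal_id"` names the planted motif-2 SNV.
#' @export
simulate_variants <- function(manifest, sim_genome) {
  L <- manifest$motif_length
  truth <- sim_genome$truth
  seq_str <- sim_genome$genome$sequence[1]
  base_at <- function(pos) substr(seq_str, pos + 1, pos + 1)
  core2 <- 4L # second core column (0-based offset 4 in motif orientation)
  m1 <- truth[truth$site_id == "motif1", ]
  m2 <- truth[truth$site_id == "motif2", ]
  pos1 <- m1$start + 3L # first core column, "+" strand
  pos2 <- m2$start + (L - 1L - core2) # "-" strand: mirrored offset
  neutral_pos <- 6000L
  while (any(neutral_pos >= truth$start - 1 & neutral_pos < truth$end + 1)) {
    neutral_pos <- neutral_pos + 50L
  }
  nref <- base_at(neutral_pos)
  nalt <- setdiff(DNA_BASES, nref)[1]
  out <- tibble(
    contig = truth$contig[1],
    position = c(pos1, pos2, neutral_pos),
    id = c("snv_motif1", "snv_motif2", "snv_neutral"),
    ref = c(base_at(pos1), base_at(pos2), nref),
    alt = c("A", "C", nalt),
    allele_frequency = c(1.31e-5, manifest$snv_maf, 0.30)
  ) |> arrange(.data$position)
  attr(out, "causal_id") <- "snv_motif2"
  out
}

#' Simulate a genotyped cohort with a dose-dependent expression effect
#'
#' Per sample, two haplotypes are drawn i.i.d. from the manifest frequencies
#' (Hardy-Weinberg random mating) giving minor-allele doses at the two loci.
#' Geometric MFI is lognormal, `exp(mu - beta_mfi * dose1 + N(0, sigma))`;
#' Ct triplicates for target and reference genes are constructed so that the
#' normalized ddCt equals `beta_ct * dose1` plus Normal noise of SD
#' `ct_sigma`. Locus 2 has no direct effect — any association it shows arises
#' only through linkage with locus 1.
#'
#' @param manifest A [simulation_manifest()].
#' @return A cohort tibble: `sample_id`, `dose_locus1`, `dose_locus2`,
#'   `mfi_geometric`, `ct_target_1..3`, `ct_ref_1..3`. True parameters are
#'   attached as attribute `"truth"`.
#' @export
simulate_cohort <- function(manifest) {
  n <- manifest$cohort_n
  with_pipeline_seed(manifest$seed + 2L, {
    hap <- matrix(sample.int(4, 2 * n, replace = TRUE, prob = manifest$hap_freq), ncol = 2)
    d1 <- rowSums(hap == 3) + rowSums(hap == 4) # aB or ab carry minor at locus 1
    d2 <- rowSums(hap == 2) + rowSums(hap == 4) # Ab or ab carry minor at locus 2
    mfi <- exp(manifest$mfi_mu_log - manifest$beta_mfi * d1 + rnorm(n, 0, manifest$mfi_sigma))
    rep_sd <- manifest$ct_sigma * sqrt(3 / 2) / sqrt(2)
    ref_ct <- matrix(rnorm(3 * n, 20, rep_sd), ncol = 3)
    target_center <- 20 + manifest$calibrator_dct + manifest$beta_ct * d1
    tgt_ct <- matrix(rnorm(3 * n, rep(target_center, 3), rep_sd), ncol = 3)
    out <- tibble(
      sample_id = sprintf("S%04d", seq_len(n)),
      dose_locus1 = as.integer(d1), dose_locus2 = as.integer(d2),
      mfi_geometric = mfi,
      ct_target_1 = tgt_ct[, 1], ct_target_2 = tgt_ct[, 2], ct_target_3 = tgt_ct[, 3],
      ct_ref_1 = ref_ct[, 1], ct_ref_2 = ref_ct[, 2], ct_ref_3 = ref_ct[, 3]
    )
    attr(out, "truth") <- list(
      hap_freq = manifest$hap_freq,
      beta_mfi_log = -manifest$beta_mfi, beta_ct = manifest$beta_ct,
      calibrator_dct = manifest$calibrator_dct
    )
    out
  })
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits the exact formats the pipeline reads — FASTA genome, per-dataset
#' narrowPeak files, gene BED, VCF, JASPAR PFM, cohort TSV — plus the
#' ground-truth site table and a machine-readable manifest. Identical
#' manifests produce byte-identical bundles.
#'
#' @param manifest A [simulation_manifest()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
simulate_bundle <- function(manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- simulate_genome(manifest)
  peaks <- simulate_peaksets(manifest, g$truth)
  variants <- simulate_variants(manifest, g)
  cohort <- simulate_cohort(manifest)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.bed"),
    pwm = file.path(dir, "pwm.jaspar"),
    vcf = file.path(dir, "variants.vcf"),
    cohort = file.path(dir, "cohort.tsv"),
    truth = file.path(dir, "truth_sites.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_fasta(g$genome, paths$genome)
  write_gene_bed(g$genes, paths$genes)
  write_jaspar_pfm(manifest$pfm, paths$pwm)
  write_vcf_lite(variants, paths$vcf)
  readr::write_tsv(cohort, paths$cohort)
  readr::write_tsv(g$truth, paths$truth)
  peak_paths <- character(0)
  for (id in unique(peaks$dataset_id)) {
    p <- file.path(dir, sprintf("peaks_%s.narrowPeak", id))
    write_narrowpeak(filter(peaks, .data$dataset_id == id), p)
    peak_paths[id] <- p
  }
  paths$peaks <- peak_paths
  man_json <- manifest[setdiff(names(manifest), c("genes", "sites", "pfm"))]
  man_json$genes <- manifest$genes
  man_json$sites <- as.data.frame(g$truth)
  man_json$pfm_id <- manifest$pfm$id
  jsonlite::write_json(man_json, paths$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
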