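# Variant-in-motif intersection and motif-disruption scoring: the change in
# relative PWM score between the reference and alternate alleles.

#' Pair variants with the motif hits they fall in
#'
#' A (hit, variant) pair is reported iff the variant position lies within the
#' hit's half-open interval `[start, end)` on the same contig.
#'
#' @param hits A motif-hit tibble (see [scan_sequence()]).
#' @param variants A variant tibble (see [read_vcf_lite()]).
#' @return A tibble with one row per pair: all hit columns (hit interval as
#'   `start`/`end`) plus `position`, `id`, `ref`, `alt`, `allele_frequency`.
#' @export
variants_in_motif <- function(hits, variants) {
  if (nrow(hits) == 0 || nrow(variants) == 0) {
    return(dplyr::bind_cols(hits[0, ], variants[0, c("position", "id", "ref", "alt", "allele_frequency")]))
  }
  inner_join(hits, variants, by = "contig", relationship = "many-to-many") |>
    filter(.data$start <= .data$position, .data$position < .data$end)
}

# genomic variant offset -> motif-orientation offset within a window
motif_offset <- function(hit_start, strand, position, L) {
  fwd <- position - hit_start
  ifelse(strand == "+", fwd, L - 1L - fwd)
}

#' Apply a single-nucleotide variant to a motif window
#'
#' The window is in motif (scanned-strand) orientation, so for hits on the
#' `"-"` strand the variant's REF/ALT bases are complemented and the offset
#' mirrored. The window's base at the variant offset must equal the expected
#' reference base — a mismatch indicates an assembly or coordinate slip and
#' raises an error naming both bases.
#'
#' @param window Motif-orientation window (length L DNA string).
#' @param hit_start 0-based start of the hit interval.
#' @param strand Hit strand, `"+"` or `"-"`.
#' @param position 0-based genomic position of the variant.
#' @param ref,alt Reference and alternate bases (forward genomic strand).
#' @return The mutated window (motif orientation).
#' @export
apply_variant <- function(window, hit_start, strand, position, ref, alt) {
  L <- nchar(window)
  off <- motif_offset(hit_start, strand, position, L)
  if (off < 0 || off >= L) abort("variant lies outside the motif window")
  expect_ref <- if (strand == "+") ref else complement_base(ref)
  sub_base <- if (strand == "+") alt else complement_base(alt)
  have <- substr(window, off + 1L, off + 1L)
  if (have != expect_ref) {
    abort(sprintf(
      "reference mismatch at motif offset %d: window has '%s' but variant REF implies '%s'",
      off, have, expect_ref
    ))
  }
  substr(window, off + 1L, off + 1L) <- sub_base
  window
}

# per-column information content (bits) of a pseudocounted PFM
column_information <- function(pwm) {
  p <- sweep(pwm$counts + pwm$pseudocount * pwm$background,
             2, colSums(pwm$counts) + pwm$pseudocount, "/")
  2 + colSums(p * log2(p))
}

#' Quantify motif disruption by paired variants
#'
#' For each (hit, variant) pair, the wild-type relative score is the hit's
#' stored `relative_score`; the mutant relative score comes from rescoring
#' the window after [apply_variant()]; `delta = rel_wt - rel_mut`. A variant
#' is flagged `core_disrupted` when its motif-orientation offset falls on one
#' of the matrix's `n_core` highest-information columns (the WGATAR core for
#' a GATA-type matrix).
#'
#' @param pwm A [build_pwm()] object.
#' @param pairs A paired tibble from [variants_in_motif()].
#' @param n_core Number of highest-information columns treated as the core
#'   (default 4).
#' @return `pairs` with `rel_wt`, `rel_mut`, `delta`, `core_disrupted`
#'   columns, sorted by `delta` descending.
#' @export
delta_relative_score <- function(pwm, pairs, n_core = 4L) {
  if (nrow(pairs) == 0) {
    return(mutate(pairs, rel_wt = double(), rel_mut = double(),
                  delta = double(), core_disrupted = logical()))
  }
  L <- motif_length(pwm)
  core_cols <- order(column_information(pwm), decreasing = TRUE)[seq_len(n_core)]
  mut_window <- purrr::pmap_chr(
    list(pairs$window, pairs$start, pairs$strand, pairs$position, pairs$ref, pairs$alt),
    apply_variant
  )
  off <- motif_offset(pairs$start, pairs$strand, pairs$position, L)
  out <- mutate(pairs,
    rel_wt = .data$relative_score,
    rel_mut = relative_score(pwm, score_window(pwm, mut_window)),
    delta = .data$rel_wt - .data$rel_mut,
    core_disrupted = (off + 1L) %in% core_cols
  )
  arrange(out, desc(.data$delta))
}

#' Triage variant impacts by allele frequency
#'
#' Annotates each impact with the Hardy-Weinberg expected homozygote
#' frequency `AF^2` and flags how well it fits a phenotype prevalence:
#' `"candidate_fit"` when `|AF^2 - prevalence|` is within `tolerance`,
#' `"too_rare"` when the allele frequency is below `af_floor` (too rare to
#' explain the phenotype), `"no_fit"` otherwise, `"unknown_af"` when the
#' allele frequency is missing.
#'
#' @param impacts An impact tibble (see [delta_relative_score()]) carrying
#'   `allele_frequency`.
#' @param prevalence Phenotype prevalence to match (default 0.01, i.e. 1%).
#' @param tolerance Absolute tolerance on `|AF^2 - prevalence|` (default 0.02).
#' @param af_floor Allele frequencies below this are flagged too rare
#'   (default 1e-3).
#' @return `impacts` with `hom_freq` and `fit` columns.
#' @export
frequency_triage <- function(impacts, prevalence = 0.01, tolerance = 0.02, af_floor = 1e-3) {
  mutate(impacts,
    hom_freq = .data$allele_frequency^2,
    fit = dplyr::case_when(
      is.na(.data$allele_frequency) ~ "unknown_af",
      .data$allele_frequency < af_floor ~ "too_rare",
      abs(.data$hom_freq - prevalence) <= tolerance ~ "candidate_fit",
      TRUE ~ "no_fit"
    )
  )
}
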