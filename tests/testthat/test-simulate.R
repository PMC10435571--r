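test_that("genome simulation is deterministic and its truth table is recoverable", {
  m <- simulation_manifest(seed = 5)
  g1 <- simulate_genome(m)
  g2 <- simulate_genome(m)
  expect_identical(g1$genome$sequence, g2$genome$sequence)

  pw <- build_pwm(m$pfm)
  hits <- scan_sequence(pw, g1$genome, threshold = 0.95, p_values = FALSE)
  expect_setequal(hits$start, g1$truth$start)
  expect_equal(nrow(hits), nrow(g1$truth))
  # planted strands are honoured
  expect_equal(
    hits$strand[match(g1$truth$start, hits$start)],
    g1$truth$strand
  )
})

test_that("overlapping planted motifs are rejected", {
  sites <- regulomine:::default_sim_sites()
  sites$start[2] <- sites$start[1] + 5L
  expect_error(
    simulate_genome(simulation_manifest(seed = 1, sites = sites)),
    "overlap"
  )
})

test_that("noiseless peak simulation gives k = K everywhere; false peaks avoid motifs", {
  m0 <- simulation_manifest(seed = 3, jitter_sd = 0, miss_rate = 0, false_per_dataset = 0)
  g <- simulate_genome(m0)
  pk <- simulate_peaksets(m0, g$truth)
  per <- split(pk, pk$dataset_id)
  expect_equal(length(per), 4)
  for (d in per) expect_equal(d$start, per[[1]]$start)
  sites <- consensus_sites(merge_replicates(pk))
  expect_true(all(sites$k == 4L))

  m <- simulation_manifest(seed = 3)
  pk2 <- simulate_peaksets(m, g$truth)
  false_pk <- pk2[!pk2$summit %in% (g$truth$start + m$motif_length %/% 2), ]
  for (i in seq_len(nrow(false_pk))) {
    expect_true(all(false_pk$end[i] <= g$truth$start | false_pk$start[i] >= g$truth$end))
  }
})

test_that("missed detections thin k as a binomial of the miss rate", {
  m <- simulation_manifest(seed = 13, miss_rate = 0.25, false_per_dataset = 0)
  g <- simulate_genome(m)
  # non-reference datasets each retain a true site w.p. 0.75; with the
  # reference present, P(k = 4) = 0.75^3 for sites the reference kept
  reps <- 60
  fracs <- c()
  for (r in seq_len(reps)) {
    mr <- simulation_manifest(seed = 1000 + r, miss_rate = 0.25, false_per_dataset = 0)
    pk <- simulate_peaksets(mr, g$truth)
    if (!"d1" %in% pk$dataset_id) next
    sites <- consensus_sites(merge_replicates(pk), reference = "d1")
    if (nrow(sites) == 0) next
    fracs <- c(fracs, mean(sites$k == 4))
  }
  expected <- 0.75^3
  se <- sqrt(expected * (1 - expected) / (length(fracs) * nrow(g$truth)))
  expect_lt(abs(mean(fracs) - expected), 4 * se)
})

test_that("simulated variants disrupt the planted motifs as designed", {
  m <- simulation_manifest(seed = 9)
  g <- simulate_genome(m)
  v <- simulate_variants(m, g)
  expect_equal(attr(v, "causal_id"), "snv_motif2")
  causal <- v[v$id == "snv_motif2", ]
  expect_equal(causal$ref, "T")
  expect_equal(causal$alt, "C")
  expect_equal(causal$allele_frequency, 0.157)
  rare <- v[v$id == "snv_motif1", ]
  expect_equal(rare$ref, "G")
  expect_equal(rare$alt, "A")
  expect_equal(rare$allele_frequency, 1.31e-5)
  # REF bases agree with the emitted genome (apply_variant guard holds)
  for (i in seq_len(nrow(v))) {
    expect_equal(substr(g$genome$sequence, v$position[i] + 1, v$position[i] + 1), v$ref[i])
  }
})

test_that("cohort simulation reproduces manifest allele frequency and LD structure", {
  # degenerate frequencies: single haplotype, all doses zero, baseline MFI
  m1 <- simulation_manifest(seed = 2, hap_freq = c(AB = 1, Ab = 0, aB = 0, ab = 0))
  c1 <- simulate_cohort(m1)
  expect_true(all(c1$dose_locus1 == 0))
  expect_true(all(c1$dose_locus2 == 0))
  expect_lt(abs(mean(log(c1$mfi_geometric)) - m1$mfi_mu_log), 4 * m1$mfi_sigma / sqrt(m1$cohort_n))

  # Swedish-style: no recombinant haplotypes -> doses identical, collinear path
  m2 <- simulation_manifest(seed = 4, hap_freq = c(AB = 0.9, Ab = 0, aB = 0, ab = 0.1),
                            cohort_n = 100)
  c2 <- simulate_cohort(m2)
  expect_true(all(c2$dose_locus1 == c2$dose_locus2))
  expect_error(ols_dose_regression(c2, mfi_geometric), "single-locus")

  # empirical MAF across replicates centres on the manifest value
  set.seed(1)
  mafs <- vapply(1:80, function(r) {
    cc <- simulate_cohort(simulation_manifest(seed = 5000 + r))
    mean(cc$dose_locus1) / 2
  }, numeric(1))
  maf_se <- sqrt(0.157 * (1 - 0.157) / (2 * 396)) / sqrt(80)
  expect_lt(abs(mean(mafs) - 0.157), 5 * maf_se)

  # separable-sample count matches the analytic expectation under HWE
  p <- simulation_manifest(seed = 1)$hap_freq
  hap_d1 <- c(0, 0, 1, 1) # minor-allele indicator at locus 1 per haplotype
  hap_d2 <- c(0, 1, 0, 1)
  probs <- outer(p, p)
  diff_mat <- outer(seq_len(4), seq_len(4), function(i, j) {
    (hap_d1[i] + hap_d1[j]) != (hap_d2[i] + hap_d2[j])
  })
  p_diff <- sum(probs[diff_mat])
  seps <- vapply(1:80, function(r) {
    genotype_concordance(simulate_cohort(simulation_manifest(seed = 7000 + r)))$fraction
  }, numeric(1))
  se <- sqrt(p_diff * (1 - p_diff) / 396) / sqrt(80)
  expect_lt(abs(mean(seps) - p_diff), 5 * se)
})

test_that("bundles are byte-identical for identical manifests", {
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  simulate_bundle(simulation_manifest(seed = 77), d1)
  simulate_bundle(simulation_manifest(seed = 77), d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    a <- readBin(file.path(d1, f), "raw", file.size(file.path(d1, f)))
    b <- readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    expect_identical(a, b)
  }
  d3 <- file.path(tempdir(), "det3")
  simulate_bundle(simulation_manifest(seed = 78), d3)
  expect_false(identical(
    readBin(file.path(d1, "genome.fa"), "raw", file.size(file.path(d1, "genome.fa"))),
    readBin(file.path(d3, "genome.fa"), "raw", file.size(file.path(d3, "genome.fa")))
  ))
})
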