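test_that("haplotype estimation reduces to direct counting without double heterozygotes", {
  gt <- tibble::tibble(
    dose_locus1 = c(0, 0, 1, 2, 2, 0),
    dose_locus2 = c(0, 1, 0, 2, 1, 0)
  )
  h_rule <- estimate_haplotypes(gt, mode = "paper-rule")
  h_em <- estimate_haplotypes(gt, mode = "em")
  expect_equal(h_rule$mode, "direct")
  expect_equal(h_em$mode, "direct")
  expect_equal(h_rule$frequencies, h_em$frequencies)
  # direct gamete counting by hand: 12 gametes
  # (0,0)->2 AB; (0,1)->AB,Ab; (1,0)->AB,aB; (2,2)->2 ab; (2,1)->aB,ab; (0,0)->2 AB
  expect_equal(unname(h_rule$counts), c(6, 1, 2, 3))
})

test_that("complete-LD genotypes yield only the two parental haplotypes", {
  gt <- tibble::tibble(dose_locus1 = c(0, 0, 1, 1, 2), dose_locus2 = c(0, 0, 1, 1, 2))
  h <- estimate_haplotypes(gt)
  expect_equal(h$frequencies[["Ab"]], 0)
  expect_equal(h$frequencies[["aB"]], 0)
  expect_true(all(h$frequencies[c("AB", "ab")] > 0))
  ld <- compute_ld(h)
  expect_equal(ld$D_prime, 1)
  expect_equal(ld$r_squared, 1)
})

test_that("EM recovers simulated haplotype frequencies within +/- 0.02", {
  set.seed(71)
  truth <- c(0.80, 0.04, 0.01, 0.15)
  reps <- 200
  est <- matrix(NA_real_, nrow = reps, ncol = 4)
  for (r in seq_len(reps)) {
    gt <- random_genotypes(400, truth)
    est[r, ] <- estimate_haplotypes(gt, mode = "em")$frequencies
  }
  expect_true(all(abs(colMeans(est) - truth) < 0.02))
})

test_that("LD statistics match closed-form hand evaluation", {
  ld <- compute_ld(c(0.7, 0.1, 0.1, 0.1))
  expect_equal(ld$D, 0.06)
  expect_equal(ld$D_max, 0.16)
  expect_equal(ld$D_prime, 0.375)
  expect_equal(ld$r_squared, 0.140625)
  # independence: D = 0, r^2 = 0
  ind <- compute_ld(c(0.64, 0.16, 0.16, 0.04))
  expect_equal(ind$D, 0, tolerance = 1e-12)
  expect_equal(ind$r_squared, 0, tolerance = 1e-12)
  # monomorphic locus: r^2 undefined
  expect_warning(mono <- compute_ld(c(0.8, 0.2, 0, 0)), "monomorphic")
  expect_true(is.na(mono$r_squared))
  # relabeling A<->a and B<->b preserves |D|, D', r^2
  set.seed(14)
  for (i in 1:25) {
    p <- random_simplex()
    a <- compute_ld(p)
    b <- compute_ld(p[c(4, 3, 2, 1)]) # ab, aB, Ab, AB relabeled
    expect_equal(abs(b$D), abs(a$D), tolerance = 1e-12)
    expect_equal(b$D_prime, a$D_prime, tolerance = 1e-12)
    expect_equal(b$r_squared, a$r_squared, tolerance = 1e-12)
  }
})

test_that("concordance report counts samples separating the two loci", {
  gt <- tibble::tibble(
    sample_id = sprintf("s%d", 1:11),
    dose_locus1 = c(rep(0, 10), 0),
    dose_locus2 = c(rep(0, 10), 1)
  )
  rep_ <- genotype_concordance(gt)
  expect_equal(rep_$n_separable, 1)
  expect_equal(rep_$fraction, 1 / 11)
  expect_equal(rep_$samples, "s11")
  all_same <- tibble::tibble(dose_locus1 = c(0, 1, 2), dose_locus2 = c(0, 1, 2))
  expect_equal(genotype_concordance(all_same)$n_separable, 0)
})

test_that("geometric MFI equals the log-domain mean and rejects non-positive values", {
  expect_equal(geometric_mfi(rep(42, 10)), 42)
  expect_equal(geometric_mfi(c(1, 100)), 10)
  set.seed(8)
  x <- rlnorm(500, 3, 1)
  expect_equal(geometric_mfi(x), exp(mean(log(x))), tolerance = 1e-12)
  expect_error(geometric_mfi(c(1, 0)), "positive")
})

test_that("two-group ANOVA equals the squared pooled t test", {
  set.seed(19)
  d <- tibble::tibble(
    value = c(rnorm(15, 10), rnorm(12, 11)),
    group = rep(c("a", "b"), c(15, 12))
  )
  res <- anova_bonferroni(d, value, group)
  tt <- t.test(value ~ group, data = d, var.equal = TRUE)
  expect_equal(res$overall$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$overall$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(res$pairwise$p_raw, tt$p.value, tolerance = 1e-10)
  expect_equal(res$pairwise$p_adj, min(1, tt$p.value)) # m = 1 pair
})

test_that("ANOVA handles constant data and dose groups with strong effects", {
  flat <- tibble::tibble(value = rep(5, 9), group = rep(c("a", "b", "c"), 3))
  res <- anova_bonferroni(flat, value, group)
  expect_equal(res$overall$statistic, 0)
  expect_equal(res$overall$p_value, 1)
  expect_true(all(res$pairwise$p_adj == 1))

  set.seed(23)
  d <- tibble::tibble(
    value = c(rnorm(30, 1000, 100), rnorm(30, 600, 100), rnorm(30, 300, 100)),
    group = rep(c("0", "1", "2"), each = 30)
  )
  res <- anova_bonferroni(d, value, group)
  expect_lt(res$overall$p_value, 0.001)
  expect_true(all(res$pairwise$p_adj < 0.05))
  expect_equal(res$m, 3)
})

test_that("dose regression reproduces exact fits and the normal-equations oracle", {
  d <- tibble::tibble(
    dose_locus1 = rep(0:2, each = 4),
    dose_locus2 = rep(c(0, 1, 0, 1), 3)
  )
  d$y <- 5 - 2 * d$dose_locus1
  # zero-residual fit: stats warns that the summary may be unreliable
  fit <- suppressWarnings(ols_dose_regression(d, y))
  co <- tidy(fit)
  expect_equal(co$estimate[co$term == "dose_locus1"], -2)
  expect_equal(co$estimate[co$term == "(Intercept)"], 5)
  expect_lt(sum(residuals(fit$fit)^2), 1e-20)

  set.seed(31)
  n <- 60
  r <- tibble::tibble(
    dose_locus1 = sample(0:2, n, TRUE), dose_locus2 = sample(0:2, n, TRUE),
    y = rnorm(n)
  )
  fit2 <- ols_dose_regression(r, y)
  X <- cbind(1, r$dose_locus1, r$dose_locus2)
  beta <- solve(t(X) %*% X, t(X) %*% r$y)
  expect_equal(tidy(fit2)$estimate, as.numeric(beta), tolerance = 1e-8)
  s2 <- sum((r$y - X %*% beta)^2) / (n - 3)
  se <- sqrt(diag(solve(t(X) %*% X)) * s2)
  tcrit <- qt(0.975, n - 3)
  expect_equal(tidy(fit2)$conf_low, as.numeric(beta - tcrit * se), tolerance = 1e-8)
  expect_equal(tidy(fit2)$conf_high, as.numeric(beta + tcrit * se), tolerance = 1e-8)
})

test_that("collinear doses raise an error pointing to single-locus analysis", {
  d <- tibble::tibble(dose_locus1 = rep(0:2, each = 5))
  d$dose_locus2 <- d$dose_locus1 # Swedish-cohort situation: complete LD
  d$y <- rnorm(15)
  expect_error(ols_dose_regression(d, y), "single-locus")
})

test_that("delta-delta-Ct follows the stated arithmetic and is linear in Ct", {
  expect_equal(delta_delta_ct(c(25.0, 25.2, 25.1), c(20.0, 20.1, 19.9), 4.0), 1.1)
  expect_equal(delta_delta_ct(c(24.0, 24.2, 24.1), c(20.0, 20.1, 19.9), 4.0), 0.1)
  # sample dCt equal to the calibrator gives 0
  expect_equal(delta_delta_ct(c(24, 24, 24), c(20, 20, 20), 4), 0)
  expect_error(delta_delta_ct(c(25, NA, 25), c(20, 20, 20), 4), "triplicate")
  tbl <- tibble::tibble(
    ct_target_1 = 25.0, ct_target_2 = 25.2, ct_target_3 = 25.1,
    ct_ref_1 = 20.0, ct_ref_2 = 20.1, ct_ref_3 = 19.9
  )
  expect_equal(cohort_ddct(tbl, 4)$ddct, 1.1)
})

test_that("luciferase analysis normalizes to baseline and runs paired t tests", {
  d <- tidyr::expand_grid(
    construct = c("empty", "enh"), experiment = 1:3, well = 1:3
  )
  ratios <- c(empty = 1, enh = 2)
  d$renilla <- 10
  d$firefly <- 10 * ratios[d$construct] + rep(c(0, 0.5, -0.5), length.out = nrow(d))
  # paired t oracle on per-experiment means (well jitter averages out exactly)
  res <- luciferase_ratio_test(d, baseline = "empty")
  expect_equal(res$relative_activity, 2, tolerance = 1e-9)
  means_e <- tapply(d$firefly[d$construct == "enh"] / 10, d$experiment[d$construct == "enh"], mean)
  means_b <- tapply(d$firefly[d$construct == "empty"] / 10, d$experiment[d$construct == "empty"], mean)
  diffs <- means_e - means_b
  if (sd(diffs) > 0) {
    tt <- t.test(means_e, means_b, paired = TRUE)
    expect_equal(res$p_value, tt$p.value)
  } else {
    expect_equal(res$p_value, 0) # constant nonzero difference
  }
  # construct identical to baseline: degenerate, p = 1
  same <- dplyr::bind_rows(d, dplyr::mutate(d[d$construct == "empty", ], construct = "copy"))
  res2 <- luciferase_ratio_test(same, baseline = "empty")
  row <- res2[res2$construct == "copy", ]
  expect_equal(row$relative_activity, 1)
  expect_true(row$degenerate)
  expect_equal(row$p_value, 1)
  # hand-computed paired t on three experiment means
  h <- tibble::tibble(
    construct = rep(c("b", "x"), each = 3), experiment = rep(1:3, 2),
    firefly = c(1.0, 1.1, 0.9, 2.0, 2.2, 1.9), renilla = 1
  )
  res3 <- luciferase_ratio_test(h, baseline = "b")
  dd <- c(2.0 - 1.0, 2.2 - 1.1, 1.9 - 0.9)
  t_hand <- mean(dd) / (sd(dd) / sqrt(3))
  expect_equal(res3$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res3$p_value, 2 * pt(-abs(t_hand), df = 2), tolerance = 1e-12)
  expect_error(luciferase_ratio_test(dplyr::mutate(h, renilla = 0), "b"), "positive")
})

test_that("EM never has lower likelihood than the counting rule", {
  set.seed(91)
  for (i in 1:30) {
    gt <- random_genotypes(80, random_simplex())
    h_rule <- suppressMessages(estimate_haplotypes(gt, mode = "paper-rule"))
    h_em <- estimate_haplotypes(gt, mode = "em")
    expect_gte(h_em$log_likelihood, h_rule$log_likelihood - 1e-8)
  }
})
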