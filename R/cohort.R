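# Cohort genetics: two-locus haplotype frequency estimation (double-het
# counting rule and EM), linkage disequilibrium D'/r^2, genotype-dose
# association with expression readouts, delta-delta-Ct, luciferase ratios.

HAPLOTYPES <- c("AB", "Ab", "aB", "ab") # A/a = major/minor locus 1, B/b = locus 2

# haplotype counts contributed by unambiguous (not doubly heterozygous)
# genotypes; (1,1) samples contribute nothing here
unambiguous_hap_counts <- function(d1, d2) {
  counts <- setNames(numeric(4), HAPLOTYPES)
  for (i in seq_along(d1)) {
    if (d1[i] == 1 && d2[i] == 1) next
    a1 <- c(rep("A", 2 - d1[i]), rep("a", d1[i]))
    a2 <- c(rep("B", 2 - d2[i]), rep("b", d2[i]))
    # at most one locus is het, so pairing alleles in order is the unique phase
    h <- paste0(a1, a2)
    for (hh in h) counts[hh] <- counts[hh] + 1
  }
  counts
}

# log-likelihood of haplotype frequencies given unphased two-locus genotypes
# under random union of gametes
hap_loglik <- function(freq, d1, d2) {
  p <- setNames(pmax(freq, 0), HAPLOTYPES)
  g <- paste(d1, d2)
  gp <- function(h1, h2) unname(if (h1 == h2) p[h1]^2 else 2 * p[h1] * p[h2])
  probs <- c(
    "0 0" = gp("AB", "AB"), "0 1" = gp("AB", "Ab"), "0 2" = gp("Ab", "Ab"),
    "1 0" = gp("AB", "aB"), "2 0" = gp("aB", "aB"),
    "1 2" = gp("Ab", "ab"), "2 1" = gp("aB", "ab"), "2 2" = gp("ab", "ab"),
    "1 1" = gp("AB", "ab") + gp("Ab", "aB")
  )
  sum(log(pmax(probs[g], .Machine$double.xmin)))
}

#' Estimate two-locus haplotype frequencies from unphased genotypes
#'
#' Two estimators are provided. `"paper-rule"` resolves phase by counting:
#' every genotype other than the double heterozygote (1,1) has a unique
#' phase; double heterozygotes are assigned en bloc to whichever
#' configuration (AB/ab "cis" vs Ab/aB "trans") has the higher likelihood
#' under the frequencies of the unambiguous samples — i.e. double
#' heterozygotes are assumed to carry the common haplotypes, ties going to
#' AB/ab. `"em"` runs the standard two-locus EM to the maximum-likelihood
#' frequencies. When the table contains no double heterozygotes both
#' estimators reduce to direct gamete counting and the mode is reported as
#' `"direct"`.
#'
#' @param genotypes A tibble with columns `dose_locus1`, `dose_locus2`
#'   (minor-allele counts in 0/1/2; homozygous major = 0, heterozygous = 1,
#'   homozygous minor = 2).
#' @param mode `"paper-rule"` (default) or `"em"`.
#' @param tol,max_iter EM convergence tolerance and iteration cap.
#' @return An object of class `"haplotype_freq"`: frequencies and counts of
#'   the four haplotypes AB/Ab/aB/ab, the estimation mode, sample size and
#'   the log-likelihood of the estimate.
#' @export
estimate_haplotypes <- function(genotypes, mode = c("paper-rule", "em"),
                                tol = 1e-8, max_iter = 1000L) {
  mode <- match.arg(mode)
  if (nrow(genotypes) == 0) abort("genotype table is empty")
  d1 <- genotypes$dose_locus1
  d2 <- genotypes$dose_locus2
  assert_doses(d1, "dose_locus1")
  assert_doses(d2, "dose_locus2")
  n <- length(d1)
  n11 <- sum(d1 == 1 & d2 == 1)
  base <- unambiguous_hap_counts(d1, d2)
  if (n11 == 0) {
    counts <- base
    mode_out <- "direct"
  } else if (mode == "paper-rule") {
    f <- if (sum(base) > 0) base / sum(base) else rep(0.25, 4)
    cis <- f[["AB"]] * f[["ab"]]
    trans <- f[["Ab"]] * f[["aB"]]
    counts <- base
    if (cis >= trans) {
      if (cis == trans) inform("double-heterozygote likelihood tie; assigning cis (AB/ab)")
      counts[c("AB", "ab")] <- counts[c("AB", "ab")] + n11
    } else {
      counts[c("Ab", "aB")] <- counts[c("Ab", "aB")] + n11
    }
    mode_out <- "paper-rule"
  } else {
    # start the ascent from the counting-rule estimate: every EM step is
    # non-decreasing in likelihood, so EM can never fall below that estimate
    rule <- estimate_haplotypes(
      tibble(dose_locus1 = d1, dose_locus2 = d2),
      mode = "paper-rule"
    )
    p <- rule$frequencies
    if (all(p[c("Ab", "aB")] == 0) && n11 > 0) {
      # keep the trans configuration reachable from a boundary start
      p <- (p * 2 * n + 0.25) / (2 * n + 1)
    }
    for (it in seq_len(max_iter)) {
      cis <- p[["AB"]] * p[["ab"]]
      trans <- p[["Ab"]] * p[["aB"]]
      w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
      counts <- base
      counts[c("AB", "ab")] <- counts[c("AB", "ab")] + w * n11
      counts[c("Ab", "aB")] <- counts[c("Ab", "aB")] + (1 - w) * n11
      p_new <- counts / sum(counts)
      if (max(abs(p_new - p)) < tol) {
        p <- p_new
        break
      }
      p <- p_new
    }
    # finite iteration must not leave EM an epsilon below its starting point
    if (hap_loglik(p, d1, d2) < rule$log_likelihood) p <- rule$frequencies
    counts <- p * 2 * n
    mode_out <- "em"
  }
  freq <- counts / sum(counts)
  structure(list(
    frequencies = freq, counts = counts, n = n, n_double_het = n11,
    mode = mode_out, log_likelihood = hap_loglik(freq, d1, d2)
  ), class = "haplotype_freq")
}

#' @export
print.haplotype_freq <- function(x, ...) {
  cat(sprintf("<haplotype_freq> n = %d samples, mode = %s (double hets: %d)\n",
              x$n, x$mode, x$n_double_het))
  print(round(x$frequencies, 4))
  invisible(x)
}

#' @method tidy haplotype_freq
#' @export
tidy.haplotype_freq <- function(x, ...) {
  tibble(
    haplotype = HAPLOTYPES,
    count = unname(x$counts[HAPLOTYPES]),
    frequency = unname(x$frequencies[HAPLOTYPES])
  )
}

#' Linkage disequilibrium statistics from haplotype frequencies
#'
#' Computes `D = p_AB - p_A * p_B`, the normalization bound `D_max`
#' (`min(p_A p_b, p_a p_B)` for positive D, `min(p_A p_B, p_a p_b)` for
#' negative D), `D' = |D| / D_max` and `r^2 = D^2 / (p_A p_a p_B p_b)`.
#' D' is reported non-negative (the LDpair convention); the sign of the
#' association is retrievable from `D`. When `D = 0`, `D'` is 1 if any
#' haplotype frequency is zero and 0 otherwise, matching the convention that
#' an absent haplotype marks complete LD. For a monomorphic locus `r^2` is
#' undefined and returned as `NA` with a warning.
#'
#' @param hf A [estimate_haplotypes()] result, or a numeric vector of the
#'   four haplotype frequencies in AB, Ab, aB, ab order.
#' @return A one-row tibble: `p_AB`..`p_ab`, `p_A`, `p_B`, `D`, `D_max`,
#'   `D_prime`, `r_squared`, `monomorphic`.
#' @export
compute_ld <- function(hf) {
  p <- if (inherits(hf, "haplotype_freq")) hf$frequencies else setNames(as.numeric(hf), HAPLOTYPES)
  if (length(p) != 4 || anyNA(p) || any(p < 0)) abort("need 4 non-negative haplotype frequencies")
  if (abs(sum(p) - 1) > 1e-9) abort("haplotype frequencies must sum to 1")
  pA <- p[["AB"]] + p[["Ab"]]
  pB <- p[["AB"]] + p[["aB"]]
  pa <- 1 - pA
  pb <- 1 - pB
  D <- p[["AB"]] - pA * pB
  D_max <- if (D > 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  # a zero haplotype frequency means |D| attains D_max, so D' = 1 exactly
  # (and by convention also when D = 0 with an absent haplotype)
  D_prime <- if (any(p == 0)) {
    1
  } else if (D != 0) {
    abs(D) / D_max
  } else {
    0
  }
  monomorphic <- pA %in% c(0, 1) || pB %in% c(0, 1)
  r_squared <- if (monomorphic) {
    warn("monomorphic locus: r^2 is undefined")
    NA_real_
  } else {
    D^2 / (pA * pa * pB * pb)
  }
  tibble(
    p_AB = p[["AB"]], p_Ab = p[["Ab"]], p_aB = p[["aB"]], p_ab = p[["ab"]],
    p_A = pA, p_B = pB, D = D, D_max = D_max,
    D_prime = D_prime, r_squared = r_squared, monomorphic = monomorphic
  )
}

#' Report samples separable under imperfect linkage
#'
#' Counts samples whose two-locus genotype doses differ — genotypes
#' incompatible with perfect LD between the loci, hence the samples that
#' allow the two markers' effects to be separated.
#'
#' @param genotypes A tibble with `dose_locus1`, `dose_locus2` and optionally
#'   `sample_id`.
#' @return A list: `n`, `n_separable`, `fraction`, `samples` (ids or row
#'   indices of the separable samples).
#' @export
genotype_concordance <- function(genotypes) {
  if (nrow(genotypes) == 0) abort("genotype table is empty")
  sep <- genotypes$dose_locus1 != genotypes$dose_locus2
  ids <- if ("sample_id" %in% names(genotypes)) genotypes$sample_id else seq_len(nrow(genotypes))
  list(
    n = nrow(genotypes),
    n_separable = sum(sep),
    fraction = mean(sep),
    samples = ids[sep]
  )
}

#' Geometric mean fluorescence intensity
#'
#' `exp(mean(log(values)))`. Values must be strictly positive; filtering
#' non-positive events is the caller's explicit step.
#'
#' @param values Positive fluorescence values.
#' @return The geometric mean.
#' @export
geometric_mfi <- function(values) {
  if (length(values) == 0 || anyNA(values) || any(values <= 0)) {
    abort("geometric MFI requires strictly positive, non-missing values")
  }
  exp(mean(log(values)))
}

# pooled-variance two-sample t for one pair; handles zero-variance pairs
pair_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0))
  }
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), df = nx + ny - 2))
}

#' One-way ANOVA with Bonferroni post-hoc pairwise tests
#'
#' Classic equal-variance one-way ANOVA across genotype (or other) groups,
#' followed by all pairwise two-sided pooled-variance t tests with Bonferroni
#' adjustment (`m` = number of pairs, adjusted p capped at 1). When every
#' value is identical the ANOVA is degenerate and reported as `F = 0, p = 1`.
#'
#' @param data A data frame.
#' @param value Column with the outcome values (tidy-eval).
#' @param group Column with the group labels (tidy-eval).
#' @return An object of class `"assoc_anova"`; see [tidy()] / [glance()].
#' @export
anova_bonferroni <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  if (anyNA(v) || anyNA(g)) abort("missing values in outcome or group")
  sizes <- table(g)
  if (length(sizes) < 2) abort("need at least 2 groups")
  if (any(sizes < 2)) abort("every group needs at least 2 values")
  if (stats::var(v) == 0) {
    overall <- tibble(statistic = 0, df_between = length(sizes) - 1L,
                      df_within = length(v) - length(sizes), p_value = 1)
  } else {
    fit <- aov(v ~ factor(g))
    an <- summary(fit)[[1]]
    overall <- tibble(
      statistic = an[["F value"]][1],
      df_between = an[["Df"]][1], df_within = an[["Df"]][2],
      p_value = an[["Pr(>F)"]][1]
    )
  }
  levs <- sort(unique(g))
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  m <- length(pairs)
  pw <- purrr::map(pairs, function(pr) {
    r <- pair_t(v[g == pr[1]], v[g == pr[2]])
    tibble(group1 = pr[1], group2 = pr[2], statistic = r$t,
           p_raw = r$p, p_adj = min(1, m * r$p))
  }) |> bind_rows()
  structure(list(
    overall = overall, pairwise = pw, m = m,
    data = tibble(value = v, group = g)
  ), class = "assoc_anova")
}

#' @export
print.assoc_anova <- function(x, ...) {
  cat(sprintf("<assoc_anova> one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$overall$df_between, x$overall$df_within,
              x$overall$statistic, x$overall$p_value))
  cat(sprintf("  %d pairwise t tests, Bonferroni m = %d\n", nrow(x$pairwise), x$m))
  invisible(x)
}

#' @method tidy assoc_anova
#' @export
tidy.assoc_anova <- function(x, ...) x$pairwise

#' @method glance assoc_anova
#' @export
glance.assoc_anova <- function(x, ...) x$overall

#' Genotype-dose ordinary least squares regression
#'
#' Fits `y = b0 + b1 * dose1 + b2 * dose2 + e` by OLS with 0/1/2 genotype
#' dose coding, reporting per-term coefficients, t-distribution 95%
#' confidence intervals and two-sided p-values without multiplicity
#' adjustment. Collinear doses (e.g. the two loci in perfect LD, so
#' `dose1 == dose2` for every sample) make the design rank-deficient and
#' raise an error instructing a single-locus analysis.
#'
#' @param data A data frame.
#' @param outcome Outcome column (tidy-eval).
#' @param doses Character vector of dose column names (default
#'   `c("dose_locus1", "dose_locus2")`).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `"assoc_ols"` wrapping the `lm` fit; see
#'   [tidy()] / [glance()].
#' @export
ols_dose_regression <- function(data, outcome, doses = c("dose_locus1", "dose_locus2"),
                                conf_level = 0.95) {
  y <- dplyr::pull(data, {{ outcome }})
  X <- as.data.frame(data[, doses, drop = FALSE])
  if (length(y) <= length(doses) + 1) abort("need n > number of coefficients")
  Xm <- cbind(`(Intercept)` = 1, as.matrix(X))
  if (qr(Xm)$rank < ncol(Xm)) {
    abort(paste(
      "design matrix is rank-deficient (collinear genotype doses, e.g. loci in",
      "complete LD); the loci cannot be separated — run a single-locus analysis"
    ))
  }
  df_fit <- cbind(.y = y, X)
  fit <- lm(stats::reformulate(doses, response = ".y"), data = df_fit)
  ci <- confint(fit, level = conf_level)
  sm <- summary(fit)
  coefs <- tibble(
    term = rownames(sm$coefficients),
    estimate = unname(sm$coefficients[, "Estimate"]),
    std_error = unname(sm$coefficients[, "Std. Error"]),
    statistic = unname(sm$coefficients[, "t value"]),
    p_value = unname(sm$coefficients[, "Pr(>|t|)"]),
    conf_low = unname(ci[, 1]), conf_high = unname(ci[, 2])
  )
  structure(list(fit = fit, coefficients = coefs, conf_level = conf_level,
                 n = length(y)), class = "assoc_ols")
}

#' @export
print.assoc_ols <- function(x, ...) {
  cat(sprintf("<assoc_ols> OLS genotype-dose regression, n = %d\n", x$n))
  print(as.data.frame(x$coefficients), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @method tidy assoc_ols
#' @export
tidy.assoc_ols <- function(x, ...) x$coefficients

#' @method glance assoc_ols
#' @export
glance.assoc_ols <- function(x, ...) {
  sm <- summary(x$fit)
  f <- sm$fstatistic
  tibble(
    r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
    sigma = sm$sigma, statistic = unname(f[1]),
    p_value = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
    df = unname(f[2]), df_residual = unname(f[3]), n = x$n
  )
}

#' Delta-delta-Ct relative expression statistic
#'
#' `dCt = mean(target Ct) - mean(reference Ct)`; `ddCt = dCt - calibrator
#' dCt`, the calibrator being an inter-plate normalizing sample. Lower ddCt
#' means higher relative expression of the target.
#'
#' @param target Ct triplicate for the target gene.
#' @param reference Ct triplicate for the reference (housekeeping) gene.
#' @param calibrator The calibrator sample's dCt (cycles).
#' @return The ddCt value (cycles).
#' @export
delta_delta_ct <- function(target, reference, calibrator) {
  if (length(target) != 3 || length(reference) != 3 || anyNA(target) || anyNA(reference)) {
    abort("delta_delta_ct requires complete Ct triplicates")
  }
  (mean(target) - mean(reference)) - calibrator
}

#' Compute per-sample delta-delta-Ct for a cohort table
#'
#' @param cohort A tibble with columns `ct_target_1..3` and `ct_ref_1..3`.
#' @param calibrator The calibrator dCt (cycles).
#' @return `cohort` with a `ddct` column.
#' @export
cohort_ddct <- function(cohort, calibrator) {
  tcols <- paste0("ct_target_", 1:3)
  rcols <- paste0("ct_ref_", 1:3)
  if (!all(c(tcols, rcols) %in% names(cohort))) abort("cohort table lacks Ct triplicate columns")
  mutate(cohort,
    ddct = rowMeans(across(all_of(tcols))) - rowMeans(across(all_of(rcols))) - calibrator
  )
}

#' Luciferase firefly/Renilla ratio analysis with paired t tests
#'
#' Per-well firefly/Renilla ratios are averaged within each independent
#' experiment, scaled relative to the baseline construct's per-experiment
#' mean, and each construct is compared with the baseline by a two-sided
#' paired t test on the experiment means of the raw ratios. A comparison
#' whose paired differences are all zero is degenerate and reported with
#' `p = 1` and `degenerate = TRUE`.
#'
#' @param data A tibble with columns `construct`, `experiment`, `firefly`,
#'   `renilla` (one row per technical replicate well).
#' @param baseline Name of the baseline construct.
#' @return A tibble per non-baseline construct: `relative_activity` (mean of
#'   per-experiment ratios scaled to baseline), `n_experiments`, `statistic`,
#'   `p_value`, `degenerate`.
#' @export
luciferase_ratio_test <- function(data, baseline) {
  if (any(data$renilla <= 0)) abort("Renilla values must be positive")
  if (!baseline %in% data$construct) abort(sprintf("baseline construct '%s' not found", baseline))
  means <- data |>
    mutate(ratio = .data$firefly / .data$renilla) |>
    group_by(.data$construct, .data$experiment) |>
    summarise(ratio = mean(.data$ratio), .groups = "drop")
  base <- filter(means, .data$construct == baseline) |>
    select("experiment", base_ratio = "ratio")
  scaled <- means |>
    inner_join(base, by = "experiment") |>
    mutate(relative = .data$ratio / .data$base_ratio)
  others <- setdiff(unique(means$construct), baseline)
  purrr::map(others, function(cn) {
    sub <- filter(scaled, .data$construct == cn)
    if (nrow(sub) < 2) abort(sprintf("construct '%s': need >= 2 paired experiments", cn))
    d <- sub$ratio - sub$base_ratio
    degenerate <- all(d == 0)
    if (degenerate) {
      stat <- 0; p <- 1
    } else if (sd(d) == 0) {
      stat <- sign(mean(d)) * Inf; p <- 0
    } else {
      tt <- t.test(sub$ratio, sub$base_ratio, paired = TRUE)
      stat <- unname(tt$statistic); p <- tt$p.value
    }
    tibble(
      construct = cn, relative_activity = mean(sub$relative),
      n_experiments = nrow(sub), statistic = stat, p_value = p,
      degenerate = degenerate
    )
  }) |> bind_rows()
}
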