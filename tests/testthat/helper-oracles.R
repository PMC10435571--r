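# Independent oracles and small fixture builders used across the suite.

# random count matrix for a motif of length L (positive column sums)
random_pfm <- function(L, max_count = 20L, id = "RND") {
  counts <- matrix(sample.int(max_count + 1L, 4L * L, replace = TRUE) - 1L, nrow = 4)
  zero <- colSums(counts) == 0
  counts[1, zero] <- 1L
  pfm(counts, id = id)
}

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob), collapse = "")
}

# independent per-cell summation score of one window
oracle_score <- function(pwm, window) {
  chars <- strsplit(window, "")[[1]]
  tot <- 0
  for (j in seq_along(chars)) {
    tot <- tot + unname(pwm$weights[chars[j], j])
  }
  tot
}

# exhaustive enumeration of all 4^L window scores (uniform background)
enumerate_scores <- function(pwm) {
  L <- ncol(pwm$weights)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- numeric(nrow(grid))
  for (j in seq_len(L)) scores <- scores + pwm$weights[, j][grid[, j]]
  scores
}

# sort-sweep interval coalescing oracle (>=1 bp overlap), independent of
# the GenomicRanges path under test
oracle_merge <- function(start, end, score) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]; score <- score[o]
  run_end <- cummax(c(-Inf, head(end, -1)))
  grp <- cumsum(start >= run_end) # new group unless start < max end so far
  data.frame(
    start = tapply(start, grp, min),
    end = tapply(end, grp, max),
    score = tapply(score, grp, max),
    row.names = NULL
  )
}

# all-pairs overlap counting oracle: for each reference interval, the number
# of datasets with at least one >=1 bp intersecting interval
oracle_overlap_k <- function(ref_start, ref_end, others) {
  k <- rep(1L, length(ref_start))
  for (d in others) {
    hit <- vapply(seq_along(ref_start), function(i) {
      any(d$start < ref_end[i] & ref_start[i] < d$end)
    }, logical(1))
    k <- k + as.integer(hit)
  }
  k
}

random_intervals <- function(n, span = 10000L, max_len = 200L) {
  s <- sample.int(span, n, replace = TRUE)
  data.frame(start = s, end = s + sample.int(max_len, n, replace = TRUE),
             score = round(runif(n, 1, 1000)))
}

# random point on the 3-simplex (4 haplotype frequencies)
random_simplex <- function() {
  x <- stats::rexp(4)
  x / sum(x)
}

# genotype table drawn from haplotype frequencies under random mating
random_genotypes <- function(n, freq) {
  hap <- matrix(sample.int(4, 2 * n, replace = TRUE, prob = freq), ncol = 2)
  tibble::tibble(
    dose_locus1 = rowSums(hap == 3) + rowSums(hap == 4),
    dose_locus2 = rowSums(hap == 2) + rowSums(hap == 4)
  )
}

default_bundle_cached <- local({
  cache <- new.env()
  function(seed = 101) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(), sprintf("regulomine_bundle_%d", seed))
      manifest <- simulation_manifest(seed = seed)
      paths <- simulate_bundle(manifest, dir)
      cache[[key]] <- list(manifest = manifest, dir = dir, paths = paths)
    }
    cache[[key]]
  }
})
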