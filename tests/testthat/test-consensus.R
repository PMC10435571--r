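peaks_tbl <- function(df, id = "d1") {
  tibble::tibble(dataset_id = id, contig = "chr1", start = as.integer(df$start),
                 end = as.integer(df$end), score = df$score)
}

test_that("replicate merging coalesces overlapping peaks with the max score", {
  single <- peaks_tbl(data.frame(start = c(10, 400), end = c(60, 500), score = c(5, 7)))
  expect_equal(merge_replicates(single)[, names(single)], single)

  two <- peaks_tbl(data.frame(start = c(100, 150), end = c(200, 250), score = c(5, 9)))
  m <- merge_replicates(two)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 100L)
  expect_equal(m$end, 250L)
  expect_equal(m$score, 9)

  # book-ended intervals ([100,200) and [200,300)) share no base: not merged
  adj <- peaks_tbl(data.frame(start = c(100, 200), end = c(200, 300), score = c(1, 2)))
  expect_equal(nrow(merge_replicates(adj)), 2)
})

test_that("replicate merging matches the sweep oracle on random intervals", {
  set.seed(21)
  for (rep in 1:20) {
    iv <- random_intervals(100)
    m <- merge_replicates(peaks_tbl(iv))
    o <- oracle_merge(iv$start, iv$end, iv$score)
    expect_equal(m$start, as.integer(o$start))
    expect_equal(m$end, as.integer(o$end))
    expect_equal(m$score, as.numeric(o$score))
  }
})

test_that("reference selection picks the largest dataset with lexicographic ties", {
  mk <- function(id, n) peaks_tbl(random_intervals(n), id)
  set.seed(5)
  expect_equal(select_reference(dplyr::bind_rows(mk("d1", 50), mk("d2", 30))), "d1")
  expect_equal(select_reference(dplyr::bind_rows(mk("b", 10), mk("a", 10))), "a")
  # winner independent of row order
  x <- dplyr::bind_rows(mk("d2", 40), mk("d1", 25), mk("d3", 40))
  for (i in 1:5) {
    expect_equal(select_reference(x[sample(nrow(x)), ]), "d2")
  }
  expect_error(select_reference(mk("only", 5)), "at least 2")
})

test_that("overlap counting gives k = K for identical sets and matches the definition", {
  set.seed(9)
  base <- random_intervals(30)
  four <- dplyr::bind_rows(lapply(sprintf("d%d", 1:4), function(id) peaks_tbl(base, id)))
  sites <- consensus_sites(four, reference = "d1")
  expect_true(all(sites$k == 4L))
  expect_true(all(grepl("^d1", sites$datasets)))

  # a site overlapped by {ref, d2} only
  p <- dplyr::bind_rows(
    peaks_tbl(data.frame(start = c(100, 1000), end = c(200, 1100), score = 1), "ref"),
    peaks_tbl(data.frame(start = 150, end = 260, score = 1), "d2"),
    peaks_tbl(data.frame(start = 5000, end = 5100, score = 1), "d3")
  )
  s <- consensus_sites(p, reference = "ref")
  expect_equal(s$k[s$start == 100], 2L)
  expect_equal(s$k[s$start == 1000], 1L)
})

test_that("overlap counts equal the all-pairs oracle on random collections", {
  set.seed(33)
  for (rep in 1:20) {
    ref <- random_intervals(80)
    others <- lapply(1:3, function(i) random_intervals(60))
    peaks <- dplyr::bind_rows(
      peaks_tbl(ref, "ref"),
      dplyr::bind_rows(lapply(seq_along(others), function(i) peaks_tbl(others[[i]], sprintf("d%d", i))))
    )
    sites <- consensus_sites(peaks, reference = "ref")
    ref_sorted <- ref[order(ref$start, ref$end), ]
    expect_equal(sites$k, oracle_overlap_k(ref_sorted$start, ref_sorted$end, others))
  }
})

test_that("adding a dataset never decreases k and thresholds nest", {
  set.seed(55)
  ref <- random_intervals(60)
  d2 <- random_intervals(50)
  d3 <- random_intervals(50)
  p2 <- dplyr::bind_rows(peaks_tbl(ref, "ref"), peaks_tbl(d2, "d2"))
  p3 <- dplyr::bind_rows(p2, peaks_tbl(d3, "d3"))
  k2 <- consensus_sites(p2, "ref")$k
  k3 <- consensus_sites(p3, "ref")$k
  expect_true(all(k3 >= k2))
  s3 <- consensus_sites(p3, "ref")
  at <- function(th) which(s3$k >= th)
  expect_true(all(at(3) %in% at(2)))
  expect_true(all(which(s3$k == 3) %in% at(2)))
})

test_that("gene assignment uses body, then promoter, then nearest TSS", {
  genes <- tibble::tibble(
    gene = c("G1", "G2"), contig = "chr1",
    start = c(10000L, 30000L), end = c(12000L, 32000L),
    strand = c("+", "-"),
    is_blood_group = TRUE, is_excluded_tf = FALSE
  )
  site <- function(s, e) tibble::tibble(contig = "chr1", start = s, end = e,
                                        reference_score = 1, k = 2L, datasets = "r")
  a <- annotate_to_genes(site(10500L, 10600L), genes)
  expect_equal(a$assigned_gene, "G1")
  expect_equal(a$category, "body")
  # 1 kb upstream of a +-strand TSS with 2 kb window
  b <- annotate_to_genes(site(9000L, 9100L), genes, upstream_window = 2000L)
  expect_equal(b$assigned_gene, "G1")
  expect_equal(b$category, "promoter")
  # minus-strand promoter sits right of the gene end
  c_ <- annotate_to_genes(site(32500L, 32600L), genes, upstream_window = 2000L)
  expect_equal(c_$assigned_gene, "G2")
  expect_equal(c_$category, "promoter")
  # equidistant between the two TSSs (10000 and 31999): earlier gene wins
  mid <- (10000L + 31999L) / 2
  d <- annotate_to_genes(site(as.integer(mid), as.integer(mid) + 1L), genes,
                         upstream_window = 100L)
  expect_equal(d$category, "nearest")
  expect_equal(d$assigned_gene, "G1")
})

test_that("candidate filtering removes excluded TFs and non-blood-group genes", {
  genes <- tibble::tibble(
    gene = c("CR1", "KLF1", "HK"), contig = "chr1",
    start = c(1L, 100L, 200L), end = c(50L, 150L, 250L), strand = "+",
    is_blood_group = c(TRUE, TRUE, FALSE), is_excluded_tf = c(FALSE, TRUE, FALSE)
  )
  sites <- tibble::tibble(
    contig = "chr1", start = c(1L, 100L, 200L), end = c(10L, 110L, 210L),
    reference_score = 1, k = 2L, datasets = "r",
    assigned_gene = c("CR1", "KLF1", "HK"), category = "body"
  )
  kept <- suppressMessages(filter_candidates(sites, genes))
  expect_equal(kept$assigned_gene, "CR1")
  removed <- attr(kept, "removed")
  expect_equal(removed$reason[removed$assigned_gene == "KLF1"], "excluded_tf")
  expect_equal(removed$reason[removed$assigned_gene == "HK"], "not_blood_group")
})

test_that("candidate ranking is a stable total order on (k, score, motif)", {
  sites <- tibble::tibble(
    contig = "chr1", start = c(1L, 2L, 3L, 4L), end = c(11L, 12L, 13L, 14L),
    reference_score = c(5, 9, 9, 9), k = c(4L, 2L, 2L, 2L),
    datasets = "r", assigned_gene = "G", category = "body",
    best_relative_score = c(0.5, 0.93, 0.88, NA)
  )
  r <- rank_candidates(sites)
  expect_equal(r$k[1], 4L) # k dominates score
  expect_equal(r$best_relative_score[2], 0.93) # tertiary key
  expect_equal(r$best_relative_score[3], 0.88)
  expect_true(is.na(r$best_relative_score[4])) # missing motif scores last
  set.seed(2)
  for (i in 1:5) {
    shuffled <- rank_candidates(sites[sample(nrow(sites)), ])
    expect_equal(shuffled$start, r$start)
  }
})
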