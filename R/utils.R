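DNA_BASES <- c("A", "C", "G", "T")

# reverse complement of character DNA strings (vectorised)
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(b) {
  chartr("ACGTN", "TGCAN", b)
}

# peak/site tibble (0-based half-open) -> GRanges (1-based closed)
intervals_to_gr <- function(tbl) {
  GenomicRanges::GRanges(
    seqnames = tbl$contig,
    ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end)
  )
}

assert_doses <- function(d, name) {
  if (length(d) == 0 || anyNA(d) || !all(d %in% 0:2)) {
    abort(sprintf("`%s` must be genotype doses in {0, 1, 2} with no missing values", name))
  }
}

# deterministic RNG contract: fixed generator kinds regardless of session options
with_pipeline_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

#' Write a report table with a commented key=value header
#'
#' Reports produced by the pipeline (candidate tables, LD and association
#' reports) are plain TSV preceded by `# key=value` comment lines that record
#' the provenance of the run: seed, package version and the hash of the
#' resolved configuration.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param meta Named list of scalar metadata written as `# key=value` lines.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(x, path, meta = list()) {
  meta <- c(list(package = paste0("regulomine ", as.character(packageVersion("regulomine")))), meta)
  header <- sprintf("# %s=%s", names(meta), vapply(meta, function(v) paste(format(v, trim = TRUE), collapse = ","), character(1)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(readr::format_tsv(x), con, sep = "")
  invisible(path)
}

#' Read a report table written by [write_report_tsv()]
#'
#' @param path Path to a report TSV.
#' @return A tibble; the parsed `# key=value` header is attached as
#'   attribute `"meta"`.
#' @export
read_report_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  if (length(hdr)) {
    kv <- sub("^#\\s*", "", lines[hdr])
    kv <- strsplit(kv, "=", fixed = TRUE)
    meta <- setNames(
      lapply(kv, function(p) paste(p[-1], collapse = "=")),
      vapply(kv, `[[`, character(1), 1)
    )
  }
  out <- readr::read_tsv(I(paste0(paste(lines[setdiff(seq_along(lines), hdr)], collapse = "\n"), "\n")),
    show_col_types = FALSE, progress = FALSE
  )
  attr(out, "meta") <- meta
  out
}

#' Assemble a mining run configuration
#'
#' Collects the tunable parameters of the peak-to-candidate mining run into a
#' single validated list. The configuration hash (stable across sessions) is
#' embedded in every output header so a run can be reproduced exactly.
#'
#' @param peaks,genome,genes,pwm,vcf Input file paths (may be `NULL` when the
#'   corresponding objects are passed in memory).
#' @param pseudocount Non-negative pseudocount added to the count matrix,
#'   distributed proportionally to the background (default 0.8).
#' @param background Length-4 background base probabilities (A, C, G, T).
#' @param rel_threshold Minimum relative motif score for a reported hit, in
#'   `[0, 1]` (default 0.8).
#' @param min_overlap Minimum number of datasets (including the reference)
#'   that must overlap a consensus site (default 2).
#' @param upstream_window Promoter window upstream of the TSS, bp (default 2000).
#' @param seed Integer random seed recorded in every output header.
#' @return A list of class `"run_config"` with a `hash` field.
#' @export
run_config <- function(peaks = NULL, genome = NULL, genes = NULL, pwm = NULL, vcf = NULL,
                       pseudocount = 0.8, background = c(0.25, 0.25, 0.25, 0.25),
                       rel_threshold = 0.8, min_overlap = 2L,
                       upstream_window = 2000L, seed = 1L) {
  stopifnot(
    pseudocount >= 0,
    length(background) == 4, all(background > 0), abs(sum(background) - 1) < 1e-9,
    rel_threshold >= 0, rel_threshold <= 1,
    min_overlap >= 1, upstream_window >= 0
  )
  cfg <- list(
    peaks = peaks, genome = genome, genes = genes, pwm = pwm, vcf = vcf,
    pseudocount = pseudocount, background = background,
    rel_threshold = rel_threshold, min_overlap = as.integer(min_overlap),
    upstream_window = as.integer(upstream_window), seed = as.integer(seed)
  )
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "hash")])
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> hash", x$hash, "seed", x$seed, "\n")
  cat("  pseudocount", x$pseudocount, "| rel_threshold", x$rel_threshold,
      "| min_overlap", x$min_overlap, "| upstream_window", x$upstream_window, "\n")
  invisible(x)
}
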