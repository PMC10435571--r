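# Position frequency/weight matrices, motif scanning, relative scores and
# exact score p-values by dynamic-programming convolution.

#' Construct a position frequency matrix
#'
#' @param counts A 4 x L numeric matrix of non-negative base counts with rows
#'   in A, C, G, T order (row names are set accordingly).
#' @param id Matrix identifier (e.g. a JASPAR accession).
#' @param name Optional matrix name (e.g. the factor name).
#' @return An object of class `"pfm"`.
#' @export
pfm <- function(counts, id = "PFM", name = id) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) abort("`counts` must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 4) abort("motif length must be at least 4")
  if (any(counts < 0) || anyNA(counts)) abort("counts must be non-negative and complete")
  if (any(colSums(counts) <= 0)) abort("every motif position needs at least one positive count")
  rownames(counts) <- DNA_BASES
  structure(list(id = id, name = name, counts = counts), class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> %s (%s), %d positions\n", x$id, x$name, ncol(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Read a JASPAR-format position frequency matrix
#'
#' Parses the JASPAR PFM text format: a `>ID name` header followed by four
#' rows of counts, either bracketed (`A [ 3 5 ... ]`) or bare numbers in
#' A, C, G, T order.
#'
#' @param path Path to a JASPAR PFM file.
#' @return A [pfm()] object (the first matrix in the file).
#' @export
read_jaspar_pfm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) abort(sprintf("%s: no JASPAR '>' header found", path))
  first <- hdr[1]
  body_end <- if (length(hdr) > 1) hdr[2] - 1 else length(lines)
  body <- lines[(first + 1):body_end]
  if (length(body) < 4) abort(sprintf("%s: expected 4 count rows", path))
  parse_row <- function(line) {
    line <- sub("^[ACGTacgt]\\s*", "", line)
    line <- gsub("\\[|\\]", " ", line)
    as.numeric(strsplit(trimws(line), "\\s+")[[1]])
  }
  counts <- do.call(rbind, lapply(body[1:4], parse_row))
  if (anyNA(counts)) abort(sprintf("%s: could not parse count rows", path))
  header <- sub("^>\\s*", "", lines[first])
  parts <- strsplit(header, "\\s+")[[1]]
  pfm(counts, id = parts[1], name = if (length(parts) > 1) paste(parts[-1], collapse = " ") else parts[1])
}

#' Write a position frequency matrix in JASPAR format
#'
#' @param x A [pfm()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(x, path) {
  rows <- vapply(seq_len(4), function(i) {
    sprintf("%s  [ %s ]", DNA_BASES[i], paste(format(x$counts[i, ], trim = TRUE), collapse = "  "))
  }, character(1))
  writeLines(c(sprintf(">%s %s", x$id, x$name), rows), path)
  invisible(path)
}

#' Build a log-odds position weight matrix
#'
#' Weights are log2 odds of the pseudocounted base frequency against the
#' background:
#' `w[b, j] = log2( (count[b, j] + pseudocount * background[b]) /
#'                  ((N_j + pseudocount) * background[b]) )`
#' where `N_j` is the column total. The pseudocount is distributed across
#' bases proportionally to the background (the common JASPAR/TFBS
#' convention). `s_min`/`s_max` are the column-wise minimal/maximal total
#' scores used by [relative_score()].
#'
#' @param x A [pfm()] object.
#' @param background Length-4 background probabilities (A, C, G, T), strictly
#'   positive, summing to 1. Default uniform.
#' @param pseudocount Non-negative pseudocount (default 0.8).
#' @return An object of class `"pwm"` with fields `weights` (4 x L), `s_min`,
#'   `s_max`, `consensus` and `anti_consensus` windows, and the inputs.
#' @export
build_pwm <- function(x, background = c(0.25, 0.25, 0.25, 0.25), pseudocount = 0.8) {
  stopifnot(inherits(x, "pfm"))
  if (length(background) != 4 || any(background <= 0) || abs(sum(background) - 1) > 1e-9) {
    abort("`background` must be 4 strictly positive probabilities summing to 1")
  }
  if (pseudocount < 0) abort("`pseudocount` must be non-negative")
  counts <- x$counts
  N <- colSums(counts)
  if (pseudocount == 0 && any(counts == 0)) {
    abort("zero counts with zero pseudocount give log(0) weights; use a positive pseudocount")
  }
  background <- setNames(as.numeric(background), DNA_BASES)
  num <- counts + pseudocount * background # recycles background down columns
  den <- matrix((N + pseudocount), nrow = 4, ncol = ncol(counts), byrow = TRUE) * background
  w <- log2(num / den)
  rownames(w) <- DNA_BASES
  cons <- apply(w, 2, which.max)
  anti <- apply(w, 2, which.min)
  structure(list(
    id = x$id, name = x$name, counts = counts,
    weights = w, background = background, pseudocount = pseudocount,
    s_min = sum(apply(w, 2, min)), s_max = sum(apply(w, 2, max)),
    consensus = paste(DNA_BASES[cons], collapse = ""),
    anti_consensus = paste(DNA_BASES[anti], collapse = "")
  ), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf(
    "<pwm> %s (%s), %d positions, pseudocount %g\n  score range [%.3f, %.3f] bits, consensus %s\n",
    x$id, x$name, ncol(x$weights), x$pseudocount, x$s_min, x$s_max, x$consensus
  ))
  invisible(x)
}

motif_length <- function(pwm) ncol(pwm$weights)

#' Score DNA windows against a PWM
#'
#' The score of a window is the sum of the per-position log2-odds weights.
#' Windows containing `N` (or any base outside A/C/G/T) are unscorable and
#' return `NA`.
#'
#' @param pwm A [build_pwm()] object.
#' @param window Character vector of windows, each of the motif length.
#' @return Numeric vector of log2-odds scores (`NA` for unscorable windows).
#' @export
score_window <- function(pwm, window) {
  L <- motif_length(pwm)
  vapply(toupper(window), function(wd) {
    if (nchar(wd) != L) abort(sprintf("window length %d != motif length %d", nchar(wd), L))
    b <- match(strsplit(wd, "", fixed = TRUE)[[1]], DNA_BASES)
    if (anyNA(b)) return(NA_real_)
    sum(pwm$weights[cbind(b, seq_len(L))])
  }, numeric(1), USE.NAMES = FALSE)
}

#' JASPAR-style relative score
#'
#' Linearly rescales a PWM score to `[0, 1]`:
#' `(s - s_min) / (s_max - s_min)`, so the consensus window scores 1 and the
#' anti-consensus window scores 0.
#'
#' @param pwm A [build_pwm()] object.
#' @param s Numeric vector of log2-odds scores.
#' @return Numeric vector of relative scores.
#' @export
relative_score <- function(pwm, s) {
  rng <- pwm$s_max - pwm$s_min
  if (!is.finite(rng) || rng <= 0) abort("degenerate matrix: s_max must exceed s_min")
  (s - pwm$s_min) / rng
}

# Discretized null distribution of the total PWM score under the background
# model: column scores are shifted to non-negative integers at resolution
# `eps` and convolved column by column. Returns the integer support offset
# and the right-tail probabilities.
pwm_score_distribution <- function(pwm, granularity = 1e-3) {
  if (granularity <= 0) abort("`granularity` must be positive")
  w <- pwm$weights
  L <- ncol(w)
  eps <- (pwm$s_max - pwm$s_min) * granularity
  colmin <- apply(w, 2, min)
  iw <- round(sweep(w, 2, colmin) / eps) # 4 x L non-negative integers
  probs <- c(1) # distribution over integer sums, starting at sum 0
  for (j in seq_len(L)) {
    mx <- max(iw[, j])
    nxt <- numeric(length(probs) + mx)
    for (b in 1:4) {
      k <- iw[b, j]
      idx <- seq_along(probs) + k
      nxt[idx] <- nxt[idx] + probs * pwm$background[b]
    }
    probs <- nxt
  }
  list(
    eps = eps,
    offset = sum(colmin), # score corresponding to integer sum 0
    tail = rev(cumsum(rev(probs))) # tail[k+1] = P(int sum >= k)
  )
}

#' Exact PWM score p-value
#'
#' `P(S >= s)` for a random window under the background model, computed by
#' dynamic-programming convolution of the per-column score distributions
#' discretized to `granularity` (expressed as a fraction of the score range;
#' the FIMO approach to exact motif p-values).
#'
#' @param pwm A [build_pwm()] object.
#' @param s Numeric vector of scores.
#' @param granularity Discretization step as a fraction of `s_max - s_min`
#'   (default `1e-3`).
#' @param dist Optional precomputed distribution from an earlier call
#'   (internal use).
#' @return Numeric vector of p-values in `(0, 1]`, monotone non-increasing
#'   in `s`.
#' @export
score_pvalue <- function(pwm, s, granularity = 1e-3, dist = NULL) {
  d <- dist %||% pwm_score_distribution(pwm, granularity)
  k <- as.integer(round((s - d$offset) / d$eps))
  k <- pmax(k, 0L)
  n <- length(d$tail)
  p <- ifelse(k >= n, d$tail[n], d$tail[pmin(k, n - 1L) + 1L])
  pmin(pmax(p, .Machine$double.xmin), 1)
}

# reverse-complement PWM: scanning it forward scores the minus strand
revcomp_pwm <- function(pwm) {
  w <- pwm$weights[4:1, rev(seq_len(ncol(pwm$weights))), drop = FALSE]
  rownames(w) <- DNA_BASES
  out <- pwm
  out$weights <- w
  out
}

scan_strand <- function(weights, code) {
  L <- ncol(weights)
  n <- length(code)
  if (n < L) return(numeric(0))
  S <- numeric(n - L + 1)
  for (j in seq_len(L)) {
    S <- S + unname(weights[, j][code[j:(n - L + j)]])
  }
  S
}

#' Scan sequences for motif occurrences
#'
#' Scores every length-L window on the requested strands and reports those
#' with relative score at or above `threshold`. Reverse-strand hits are
#' reported at their forward-strand interval with strand `"-"`; the `window`
#' column always holds the scanned-strand (motif-orientation) sequence.
#' Windows containing `N` are skipped and counted (attribute `"n_skipped"`).
#'
#' @param pwm A [build_pwm()] object.
#' @param genome A tibble with columns `contig` and `sequence` (as from
#'   [read_fasta()]), or a single DNA string.
#' @param threshold Minimum relative score in `[0, 1]` (default 0.8).
#' @param strands Strands to scan (default both).
#' @param granularity p-value discretization, see [score_pvalue()].
#' @param p_values Compute exact p-values for the hits (default TRUE).
#' @return A tibble of motif hits sorted by (`contig`, `start`): columns
#'   `contig`, `start`, `end` (0-based half-open), `strand`, `window`,
#'   `score`, `relative_score` and (optionally) `p_value`.
#' @export
scan_sequence <- function(pwm, genome, threshold = 0.8, strands = c("+", "-"),
                          granularity = 1e-3, p_values = TRUE) {
  if (is.character(genome)) genome <- tibble(contig = "seq", sequence = genome)
  strands <- match.arg(strands, c("+", "-"), several.ok = TRUE)
  L <- motif_length(pwm)
  rng <- pwm$s_max - pwm$s_min
  n_skipped <- 0L
  weights <- list(`+` = pwm$weights, `-` = revcomp_pwm(pwm)$weights)
  hits <- purrr::pmap(list(genome$contig, toupper(genome$sequence)), function(contig, seq) {
    code <- match(strsplit(seq, "", fixed = TRUE)[[1]], DNA_BASES)
    purrr::map(strands, function(st) {
      S <- scan_strand(weights[[st]], code)
      if (length(S) == 0) return(NULL)
      n_skipped <<- n_skipped + sum(is.na(S))
      rel <- (S - pwm$s_min) / rng
      keep <- which(!is.na(rel) & rel >= threshold)
      if (length(keep) == 0) return(NULL)
      win <- substring(seq, keep, keep + L - 1L)
      if (st == "-") win <- revcomp(win)
      tibble(
        contig = contig, start = keep - 1L, end = keep + L - 1L,
        strand = st, window = win, score = S[keep], relative_score = rel[keep]
      )
    })
  })
  out <- bind_rows(purrr::flatten(hits))
  if (nrow(out) == 0) {
    out <- tibble(
      contig = character(), start = integer(), end = integer(),
      strand = character(), window = character(), score = double(),
      relative_score = double()
    )
  }
  if (p_values) {
    dist <- pwm_score_distribution(pwm, granularity)
    out$p_value <- if (nrow(out)) score_pvalue(pwm, out$score, dist = dist) else double()
  }
  out <- arrange(out, .data$contig, .data$start, .data$strand)
  attr(out, "n_skipped") <- n_skipped
  out
}
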