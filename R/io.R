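# Readers and writers for the plain-text formats the pipeline touches.
# All internal coordinates are 0-based half-open; conversion to and from
# 1-based conventions happens only here (VCF positions, FASTA substring calls).

#' Read genome sequences from FASTA
#'
#' Sequences are uppercased on read; lowercase (soft-masked) input is accepted.
#' Only the alphabet A/C/G/T/N is permitted.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `contig` (first word of the header) and
#'   `sequence` (uppercase DNA string). An empty file yields an empty tibble.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  if (file.size(path) == 0) {
    return(tibble(contig = character(), sequence = character()))
  }
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("malformed FASTA in %s: %s", path, conditionMessage(e)))
  )
  tbl <- tibble(
    contig = sub("\\s.*$", "", names(seqs)),
    sequence = unname(toupper(as.character(seqs)))
  )
  bad <- stringr::str_detect(tbl$sequence, "[^ACGTN]")
  if (any(bad)) {
    ch <- stringr::str_extract(tbl$sequence[bad][1], "[^ACGTN]")
    abort(sprintf("illegal character '%s' in FASTA record '%s'", ch, tbl$contig[bad][1]))
  }
  if (any(nchar(tbl$sequence) == 0)) {
    abort(sprintf("empty sequence for FASTA record '%s'", tbl$contig[nchar(tbl$sequence) == 0][1]))
  }
  tbl
}

#' Write genome sequences to FASTA
#'
#' @param x A tibble with columns `contig` and `sequence`.
#' @param path Output path.
#' @param width Line width for wrapped sequence.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  set <- Biostrings::DNAStringSet(x$sequence)
  names(set) <- x$contig
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

narrowpeak_cols <- c(
  "contig", "start", "end", "name", "score", "strand",
  "signal_value", "p_value", "q_value", "summit"
)

empty_peaks <- function(dataset_id = character()) {
  tibble(
    dataset_id = dataset_id[0], contig = character(),
    start = integer(), end = integer(), name = character(),
    score = double(), strand = character(), signal_value = double(),
    p_value = double(), q_value = double(), summit = integer()
  )
}

#' Read a narrowPeak / BED6 peak file
#'
#' Accepts 6-column BED or 10-column ENCODE narrowPeak (BED6+4). Coordinates
#' are 0-based half-open as in BED. Records with `start >= end` are rejected
#' with a warning and counted (attribute `"n_rejected"`); a non-numeric score
#' column is a parse error.
#'
#' @param path Path to the peak file.
#' @param dataset_id Identifier attached to every peak; defaults to the file
#'   name without extension.
#' @return A tibble of peaks sorted by (`contig`, `start`) with columns
#'   `dataset_id`, `contig`, `start`, `end`, `name`, `score`, `strand`, and —
#'   for narrowPeak input — `signal_value`, `p_value`, `q_value` and `summit`
#'   (absolute summit position, `start` + offset; `NA` when the offset is -1).
#' @export
read_narrowpeak <- function(path, dataset_id = NULL) {
  if (!file.exists(path)) abort(sprintf("peak file not found: %s", path))
  dataset_id <- dataset_id %||% sub("\\.[^.]*$", "", basename(path))
  if (file.size(path) == 0) {
    out <- empty_peaks()
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  raw <- readr::read_tsv(path,
    col_names = FALSE, col_types = readr::cols(.default = "c"),
    comment = "#", progress = FALSE
  )
  if (!ncol(raw) %in% c(6L, 10L)) {
    abort(sprintf("%s: expected 6 (BED6) or 10 (narrowPeak) columns, found %d", path, ncol(raw)))
  }
  names(raw) <- narrowpeak_cols[seq_len(ncol(raw))]
  to_num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v[!is.na(x)])) {
      abort(sprintf("%s: non-numeric %s ('%s')", path, what, x[which(is.na(v) & !is.na(x))[1]]))
    }
    v
  }
  tbl <- tibble(
    dataset_id = dataset_id,
    contig = raw$contig,
    start = as.integer(to_num(raw$start, "start")),
    end = as.integer(to_num(raw$end, "end")),
    name = raw$name,
    score = to_num(raw$score, "score"),
    strand = raw$strand
  )
  if (ncol(raw) == 10L) {
    tbl$signal_value <- to_num(raw$signal_value, "signalValue")
    tbl$p_value <- to_num(raw$p_value, "pValue")
    tbl$q_value <- to_num(raw$q_value, "qValue")
    off <- as.integer(to_num(raw$summit, "summit offset"))
    tbl$summit <- ifelse(off < 0L, NA_integer_, tbl$start + off)
  } else {
    tbl$signal_value <- NA_real_
    tbl$p_value <- NA_real_
    tbl$q_value <- NA_real_
    tbl$summit <- NA_integer_
  }
  bad <- tbl$start >= tbl$end
  if (any(bad)) {
    warn(sprintf("%s: rejected %d record(s) with start >= end", path, sum(bad)))
    tbl <- tbl[!bad, ]
  }
  out <- arrange(tbl, .data$contig, .data$start)
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Write peaks as ENCODE narrowPeak
#'
#' @param x A peak tibble as returned by [read_narrowpeak()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(x, path) {
  off <- ifelse(is.na(x$summit), -1L, as.integer(x$summit - x$start))
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%g\t%s\t%g\t%g\t%g\t%d",
    x$contig, x$start, x$end,
    x$name %||% ".", x$score,
    ifelse(is.na(x$strand), ".", x$strand),
    ifelse(is.na(x$signal_value), 0, x$signal_value),
    ifelse(is.na(x$p_value), -1, x$p_value),
    ifelse(is.na(x$q_value), -1, x$q_value),
    off
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation BED with blood-group flags
#'
#' Expects BED6 plus two 0/1 flag columns: `is_blood_group` and
#' `is_excluded_tf` (transcription-factor genes such as KLF1/GATA1 that are
#' removed from the candidate list in a later filtering step).
#'
#' @param path Path to the annotation file.
#' @return A tibble with columns `gene`, `contig`, `start`, `end`, `strand`,
#'   `is_blood_group`, `is_excluded_tf`.
#' @export
read_gene_bed <- function(path) {
  raw <- readr::read_tsv(path,
    col_names = c("contig", "start", "end", "gene", "score", "strand",
                  "is_blood_group", "is_excluded_tf"),
    col_types = "ciicdcii", comment = "#", progress = FALSE
  )
  if (any(raw$start >= raw$end)) abort(sprintf("%s: gene with start >= end", path))
  if (anyDuplicated(raw$gene)) abort(sprintf("%s: duplicated gene symbol '%s'", path, raw$gene[duplicated(raw$gene)][1]))
  tibble(
    gene = raw$gene, contig = raw$contig,
    start = raw$start, end = raw$end, strand = raw$strand,
    is_blood_group = raw$is_blood_group == 1L,
    is_excluded_tf = raw$is_excluded_tf == 1L
  )
}

#' Write a gene annotation BED with blood-group flags
#'
#' @param x A gene tibble as returned by [read_gene_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(x, path) {
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t0\t%s\t%d\t%d",
    x$contig, x$start, x$end, x$gene, x$strand,
    as.integer(x$is_blood_group), as.integer(x$is_excluded_tf)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read single-nucleotide variants from a VCF
#'
#' A deliberately narrow VCF 4.x reader: only single-nucleotide REF/ALT
#' records are retained, multi-allelic records are split into one row per
#' alternate allele, indels are skipped with a counted warning, and records
#' with REF equal to ALT are rejected. Positions are converted from 1-based
#' VCF to the package's 0-based convention. An `AF` INFO field, when present,
#' is carried as `allele_frequency`.
#'
#' @param path Path to a VCF file.
#' @return A tibble with columns `contig`, `position` (0-based), `id`,
#'   `ref`, `alt`, `allele_frequency`; the number of skipped non-SNV alleles
#'   is attached as attribute `"n_skipped"`.
#' @export
read_vcf_lite <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    out <- tibble(
      contig = character(), position = integer(), id = character(),
      ref = character(), alt = character(), allele_frequency = double()
    )
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  af_field <- function(info) {
    m <- stringr::str_match(info, "(?:^|;)AF=([^;]+)")[, 2]
    m
  }
  rows <- purrr::pmap(
    list(fix$CHROM, fix$POS, fix$ID, fix$REF, fix$ALT, af_field(fix$INFO)),
    function(chrom, pos, id, ref, alt, af) {
      alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
      afs <- if (is.na(af)) rep(NA_real_, length(alts)) else suppressWarnings(as.numeric(strsplit(af, ",", fixed = TRUE)[[1]]))
      afs <- rep_len(afs, length(alts))
      tibble(
        contig = chrom, position = as.integer(pos) - 1L,
        id = ifelse(is.na(id) | id == ".", NA_character_, id),
        ref = toupper(ref), alt = toupper(alts), allele_frequency = afs
      )
    }
  )
  tbl <- bind_rows(rows)
  is_snv <- nchar(tbl$ref) == 1L & nchar(tbl$alt) == 1L &
    tbl$ref %in% DNA_BASES & tbl$alt %in% DNA_BASES
  n_skipped <- sum(!is_snv)
  if (n_skipped > 0) {
    warn(sprintf("%s: skipped %d non-SNV allele(s) (indels or symbolic)", path, n_skipped))
  }
  tbl <- tbl[is_snv, ]
  same <- tbl$ref == tbl$alt
  if (any(same)) {
    warn(sprintf("%s: rejected %d record(s) with REF == ALT", path, sum(same)))
    tbl <- tbl[!same, ]
  }
  out <- arrange(tbl, .data$contig, .data$position)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write single-nucleotide variants as minimal VCF 4.2
#'
#' @param x A variant tibble as returned by [read_vcf_lite()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_lite <- function(x, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"), collapse = "\t")
  )
  info <- ifelse(is.na(x$allele_frequency), ".", sprintf("AF=%g", x$allele_frequency))
  lines <- sprintf(
    "%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
    x$contig, x$position + 1L,
    ifelse(is.na(x$id), ".", x$id),
    x$ref, x$alt, info
  )
  writeLines(c(header, lines), path)
  invisible(path)
}
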