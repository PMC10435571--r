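# Consensus peak intersection: replicate merging, reference selection,
# cross-dataset overlap counting, gene annotation, filtering and ranking.
# Overlap means >= 1 bp intersection (BEDtools intersect default).

#' Merge replicate peaks within each dataset
#'
#' Peaks sharing a `dataset_id` are coalesced: any peaks intersecting by at
#' least 1 bp are replaced by a single interval spanning them, carrying the
#' maximum member score. Replicate merging happens at peak level; the
#' coalesced set is the dataset's peak set for all downstream steps.
#'
#' @param peaks A peak tibble with columns `dataset_id`, `contig`, `start`,
#'   `end`, `score` (e.g. several [read_narrowpeak()] results bound together).
#' @return A peak tibble with one row per coalesced interval, sorted by
#'   (`dataset_id`, `contig`, `start`).
#' @export
merge_replicates <- function(peaks) {
  if (nrow(peaks) == 0) return(peaks[, c("dataset_id", "contig", "start", "end", "score")])
  peaks |>
    group_by(.data$dataset_id) |>
    dplyr::group_modify(function(g, key) {
      gr <- intervals_to_gr(g)
      red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
      ov <- GenomicRanges::findOverlaps(red, gr)
      score <- vapply(
        split(g$score[S4Vectors::subjectHits(ov)], S4Vectors::queryHits(ov)),
        max, numeric(1)
      )
      tibble(
        contig = as.character(GenomicRanges::seqnames(red)),
        start = GenomicRanges::start(red) - 1L,
        end = GenomicRanges::end(red),
        score = unname(score)
      )
    }) |>
    ungroup() |>
    arrange(.data$dataset_id, .data$contig, .data$start)
}

#' Select the reference dataset
#'
#' The reference is the dataset with the most peaks; ties are broken by the
#' lexicographically smallest `dataset_id`.
#'
#' @param peaks A peak tibble with a `dataset_id` column covering at least
#'   two datasets.
#' @return The reference `dataset_id` (length-1 character).
#' @export
select_reference <- function(peaks) {
  counts <- peaks |>
    dplyr::count(.data$dataset_id) |>
    arrange(desc(.data$n), .data$dataset_id)
  if (nrow(counts) < 2) abort("reference selection needs at least 2 datasets")
  counts$dataset_id[1]
}

#' Count cross-dataset overlaps at each reference peak
#'
#' Produces one consensus site per reference peak; its interval is the
#' reference peak's interval and its overlap count `k` is 1 (for the
#' reference itself) plus the number of other datasets having at least one
#' peak intersecting it by >= 1 bp.
#'
#' @param peaks A merged peak tibble (see [merge_replicates()]).
#' @param reference Reference `dataset_id`; defaults to [select_reference()].
#' @return A tibble of consensus sites: `contig`, `start`, `end`,
#'   `reference_score`, `k`, `datasets` (comma-separated contributing ids,
#'   reference first).
#' @export
consensus_sites <- function(peaks, reference = NULL) {
  reference <- reference %||% select_reference(peaks)
  if (!reference %in% peaks$dataset_id) abort(sprintf("reference dataset '%s' not present", reference))
  ref <- filter(peaks, .data$dataset_id == reference) |>
    arrange(.data$contig, .data$start, .data$end)
  others <- setdiff(sort(unique(peaks$dataset_id)), reference)
  ref_gr <- intervals_to_gr(ref)
  contrib <- matrix(FALSE, nrow = nrow(ref), ncol = length(others),
                    dimnames = list(NULL, others))
  for (d in others) {
    d_gr <- intervals_to_gr(filter(peaks, .data$dataset_id == d))
    hit <- GenomicRanges::countOverlaps(ref_gr, d_gr, minoverlap = 1L) > 0
    contrib[, d] <- hit
  }
  tibble(
    contig = ref$contig, start = ref$start, end = ref$end,
    reference_score = ref$score,
    k = 1L + as.integer(rowSums(contrib)),
    datasets = vapply(seq_len(nrow(ref)), function(i) {
      paste(c(reference, others[contrib[i, ]]), collapse = ",")
    }, character(1))
  )
}

# distance from 0-based half-open interval [s, e) to point t (0 if inside)
interval_point_distance <- function(s, e, t) {
  ifelse(t < s, s - t, ifelse(t >= e, t - (e - 1L), 0L))
}

#' Annotate consensus sites to genes
#'
#' A site is assigned to a gene if it overlaps the gene body ("body"); else
#' if it lies within `upstream_window` bp upstream of the TSS, strand-aware
#' ("promoter"); otherwise to the gene with the nearest TSS ("nearest").
#' When several genes qualify in the same category, or two TSSs are
#' equidistant, the gene earlier in coordinate order (start, then symbol)
#' wins.
#'
#' @param sites A consensus-site tibble (see [consensus_sites()]).
#' @param genes A gene tibble (see [read_gene_bed()]).
#' @param upstream_window Promoter window upstream of the TSS, bp.
#' @return `sites` with `assigned_gene` and `category` columns.
#' @export
annotate_to_genes <- function(sites, genes, upstream_window = 2000L) {
  if (nrow(genes) == 0) abort("gene annotation is empty")
  genes <- arrange(genes, .data$contig, .data$start, .data$gene)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$prom_start <- ifelse(genes$strand == "+", genes$start - upstream_window, genes$end)
  genes$prom_end <- ifelse(genes$strand == "+", genes$start, genes$end + upstream_window)
  assign_one <- function(contig, s, e) {
    g <- genes[genes$contig == contig, ]
    if (nrow(g) == 0) return(list(NA_character_, NA_character_))
    body <- which(g$start < e & s < g$end)
    if (length(body)) return(list(g$gene[body[1]], "body"))
    prom <- which(g$prom_start < e & s < g$prom_end)
    if (length(prom)) return(list(g$gene[prom[1]], "promoter"))
    d <- interval_point_distance(s, e, g$tss)
    list(g$gene[which.min(d)], "nearest") # which.min: first index on ties
  }
  res <- purrr::pmap(list(sites$contig, sites$start, sites$end), assign_one)
  sites$assigned_gene <- vapply(res, `[[`, character(1), 1)
  sites$category <- vapply(res, `[[`, character(1), 2)
  sites
}

#' Filter candidate sites to blood-group genes
#'
#' Retains sites assigned to blood-group genes and removes sites assigned to
#' excluded transcription-factor genes (KLF1/GATA1-type entries flagged
#' `is_excluded_tf`). Removals are logged with a reason and returned as the
#' `"removed"` attribute.
#'
#' @param sites An annotated site tibble (see [annotate_to_genes()]).
#' @param genes A gene tibble carrying `is_blood_group` / `is_excluded_tf`.
#' @return The retained sites; removed rows (with a `reason` column) are in
#'   `attr(, "removed")`.
#' @export
filter_candidates <- function(sites, genes) {
  flags <- select(genes, gene = "gene", "is_blood_group", "is_excluded_tf")
  x <- left_join(sites, flags, by = c(assigned_gene = "gene"))
  reason <- dplyr::case_when(
    is.na(x$assigned_gene) ~ "unassigned",
    x$is_excluded_tf ~ "excluded_tf",
    !x$is_blood_group ~ "not_blood_group",
    TRUE ~ NA_character_
  )
  removed <- x[!is.na(reason), ]
  removed$reason <- reason[!is.na(reason)]
  if (nrow(removed) > 0) {
    inform(sprintf(
      "filter_candidates: removed %d site(s) (%s)", nrow(removed),
      paste(sprintf("%s: %d", names(table(removed$reason)), table(removed$reason)), collapse = ", ")
    ))
  }
  out <- select(x[is.na(reason), ], -"is_blood_group", -"is_excluded_tf")
  attr(out, "removed") <- select(removed, -"is_blood_group", -"is_excluded_tf")
  out
}

#' Rank candidate sites
#'
#' Orders candidates by overlap count `k` (descending), then reference peak
#' score (descending), then best motif relative score (descending, absent
#' scores last), then (`contig`, `start`) — a stable total order.
#'
#' @param sites A candidate tibble; a `best_relative_score` column is used as
#'   the tertiary key when present.
#' @return The ranked tibble with a `rank` column.
#' @export
rank_candidates <- function(sites) {
  if (!"best_relative_score" %in% names(sites)) sites$best_relative_score <- NA_real_
  out <- arrange(
    sites,
    desc(.data$k), desc(.data$reference_score),
    desc(dplyr::coalesce(.data$best_relative_score, -Inf)),
    .data$contig, .data$start
  )
  out$rank <- seq_len(nrow(out))
  relocate(out, "rank")
}
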