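#' Parameters for coverage-dropout deletion calling
#'
#' @param dropout_ratio_max maximum ratio of the sample's normalized exon
#'   coverage to the cohort median for the exon to count as dropped out.
#' @param cohort_median_min minimum cohort-median normalized coverage for an
#'   exon to serve as a trustworthy reference; exons below it can neither be
#'   called nor be spanned by a call.
#' @param min_exons minimum run length reported; 1 permits single-exon
#'   dropout alleles (setting 3 reproduces the multi-exon-only behavior of
#'   conventional exome CNV callers).
#' @return a `deletion_params` list.
#' @export
deletion_params <- function(dropout_ratio_max = 0.10, cohort_median_min = 0.30,
                            min_exons = 1) {
  if (!(dropout_ratio_max < cohort_median_min))
    stop("dropout_ratio_max must be smaller than cohort_median_min")
  stopifnot(dropout_ratio_max > 0, min_exons >= 1)
  structure(list(dropout_ratio_max = dropout_ratio_max,
                 cohort_median_min = cohort_median_min,
                 min_exons = as.integer(min_exons)),
            class = "deletion_params")
}

#' Normalize per-exon read counts
#'
#' Converts raw exon read counts to a dimensionless coverage: the length
#' rate `read_count / exon_length` divided by the median of that rate over
#' the sample's exons. The result is invariant to uniform scaling of a
#' sample's read counts, removing library-size differences.
#'
#' @param records data.frame with columns `sample_id`, `gene`, `exon_index`,
#'   `exon_length`, `read_count` (a `chrom` column, if present, is carried
#'   through).
#' @return `records` with an added `normalized_coverage` column.
#' @export
normalize_exon_coverage <- function(records) {
  need <- c("sample_id", "gene", "exon_index", "exon_length", "read_count")
  if (!all(need %in% names(records)))
    stop("coverage table missing columns: ",
         paste(setdiff(need, names(records)), collapse = ", "))
  stopifnot(all(records$exon_length > 0), all(records$read_count >= 0))
  rate <- records$read_count / records$exon_length
  med <- tapply(rate, records$sample_id, stats::median)
  if (any(med == 0))
    stop("sample(s) with zero median coverage: ",
         paste(names(med)[med == 0], collapse = ", "))
  records$normalized_coverage <- rate / as.numeric(med[records$sample_id])
  records
}

#' Call homozygous/hemizygous dropout deletions from exon coverage
#'
#' Per sample and gene, finds maximal runs of contiguous exons whose
#' normalized coverage falls to at most `dropout_ratio_max` times the cohort
#' median for that exon, restricted to exons whose cohort median is itself
#' reliable (`>= cohort_median_min`); runs of at least `min_exons` exons are
#' reported. Near-zero residual coverage implies loss of both alleles, so
#' calls are homozygous, or hemizygous for chrX genes in males.
#'
#' @param records coverage table; [normalize_exon_coverage()] is applied if
#'   the `normalized_coverage` column is absent. Needs at least 2 samples.
#' @param ped optional [pedigree()] used to mark male samples for chrX
#'   zygosity.
#' @param params a [deletion_params()].
#' @param chrx_genes gene symbols on chrX; taken from a `chrom` column when
#'   present.
#' @return data.frame of deletion calls: `sample_id`, `gene`, `start_index`,
#'   `end_index`, `n_exons`, `mean_ratio`, `zygosity`.
#' @export
call_dropout_deletions <- function(records, ped = NULL,
                                   params = deletion_params(),
                                   chrx_genes = NULL) {
  if (!"normalized_coverage" %in% names(records))
    records <- normalize_exon_coverage(records)
  if (length(unique(records$sample_id)) < 2)
    stop("cohort must contain at least 2 samples")
  if (is.null(chrx_genes) && "chrom" %in% names(records))
    chrx_genes <- unique(records$gene[normalize_chrom(records$chrom) == "X"])
  chrx_genes <- chrx_genes %||% character()
  key <- paste(records$gene, records$exon_index, sep = "\r")
  cohort_med <- tapply(records$normalized_coverage, key, stats::median)
  records$cohort_median <- as.numeric(cohort_med[key])
  records$ratio <- ifelse(records$cohort_median > 0,
                          records$normalized_coverage / records$cohort_median,
                          NA_real_)
  reliable <- !is.na(records$ratio) &
    records$cohort_median >= params$cohort_median_min
  dropout <- reliable & records$ratio <= params$dropout_ratio_max

  out <- list()
  grp <- split(seq_len(nrow(records)),
               list(records$sample_id, records$gene), drop = TRUE)
  for (idx in grp) {
    idx <- idx[order(records$exon_index[idx])]
    d <- dropout[idx]
    if (!any(d)) next
    r <- rle(d)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= params$min_exons)) {
      rows <- idx[starts[k]:ends[k]]
      samp <- records$sample_id[rows[1]]
      gene <- records$gene[rows[1]]
      male <- !is.null(ped) &&
        identical(ped$sex[match(samp, ped$sample_id)], "male")
      out[[length(out) + 1L]] <- data.frame(
        sample_id = samp, gene = gene,
        start_index = records$exon_index[rows[1]],
        end_index = records$exon_index[rows[length(rows)]],
        n_exons = length(rows),
        mean_ratio = mean(records$ratio[rows]),
        zygosity = if (gene %in% chrx_genes && male) "hemizygous"
                   else "homozygous",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(), gene = character(),
                      start_index = integer(), end_index = integer(),
                      n_exons = integer(), mean_ratio = numeric(),
                      zygosity = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$sample_id, res$gene, res$start_index), , drop = FALSE]
  rownames(res) <- NULL
  res
}
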