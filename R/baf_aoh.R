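#' Parameters for AOH segmentation and UPD flagging
#'
#' @param min_total_reads minimum site depth for a marker to be informative.
#' @param het_band numeric length-2: B-allele-frequency band regarded as
#'   heterozygous; markers with BAF inside the band break AOH runs.
#' @param min_markers_per_segment minimum run length reported as a segment.
#' @param upd_chromosome_fraction minimum fraction of a chromosome's
#'   informative markers inside AOH segments for a whole-chromosome flag
#'   ("encompassing almost the entire chromosome").
#' @param max_background_aoh_fraction maximum AOH marker fraction tolerated
#'   across the remaining autosomes (the "single region in the genome"
#'   condition; widespread AOH suggests consanguinity, not UPD).
#' @return an `aoh_params` list.
#' @export
aoh_params <- function(min_total_reads = 15, het_band = c(0.15, 0.85),
                       min_markers_per_segment = 50,
                       upd_chromosome_fraction = 0.80,
                       max_background_aoh_fraction = 0.10) {
  stopifnot(length(het_band) == 2, het_band[1] < het_band[2],
            het_band[1] >= 0, het_band[2] <= 1,
            min_markers_per_segment >= 1,
            upd_chromosome_fraction > 0, upd_chromosome_fraction <= 1,
            max_background_aoh_fraction >= 0)
  structure(list(min_total_reads = min_total_reads, het_band = het_band,
                 min_markers_per_segment = min_markers_per_segment,
                 upd_chromosome_fraction = upd_chromosome_fraction,
                 max_background_aoh_fraction = max_background_aoh_fraction),
            class = "aoh_params")
}

#' Compute per-site B-allele frequencies for one sample
#'
#' BAF is the exact fraction of reads supporting the alternate allele.
#' Sites with total depth below `min_total_reads` are kept but marked
#' non-informative.
#'
#' @param calls a [site_calls()].
#' @param sample sample id.
#' @param params an [aoh_params()].
#' @return data.frame (`chrom`, `pos`, `baf`, `total_reads`, `informative`)
#'   sorted by chromosome and position.
#' @export
compute_baf <- function(calls, sample, params = aoh_params()) {
  g <- calls$geno[calls$geno$sample_id == sample, , drop = FALSE]
  if (!nrow(g)) stop("sample not in call set: ", sample)
  i <- match(g$site_id, calls$sites$site_id)
  total <- g$ref_reads + g$alt_reads
  out <- data.frame(chrom = calls$sites$chrom[i], pos = calls$sites$pos[i],
                    baf = ifelse(total > 0, g$alt_reads / total, NA_real_),
                    total_reads = total,
                    informative = !is.na(total) & total >= params$min_total_reads &
                      g$gt != "missing",
                    stringsAsFactors = FALSE)
  out <- out[order(chrom_rank(out$chrom), out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect runs of absence of heterozygosity
#'
#' Scans the informative markers of each chromosome for maximal runs of
#' consecutive markers whose BAF lies outside the heterozygous band, and
#' reports runs of at least `min_markers_per_segment` markers. Segment
#' coordinates are the first and last marker of the run;
#' `fraction_of_chromosome_span` is the segment span divided by the
#' chromosome's informative-marker span.
#'
#' @param baf_points output of [compute_baf()], sorted by chromosome and
#'   position (unsorted input raises an error).
#' @param params an [aoh_params()].
#' @return data.frame of segments (`chrom`, `start`, `end`, `n_markers`,
#'   `fraction_of_chromosome_span`), non-overlapping and sorted.
#' @export
detect_aoh <- function(baf_points, params = aoh_params()) {
  ord <- order(chrom_rank(baf_points$chrom), baf_points$pos)
  if (!identical(ord, seq_len(nrow(baf_points))))
    stop("baf_points must be sorted by chromosome and position")
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_markers = integer(),
                      fraction_of_chromosome_span = numeric(),
                      stringsAsFactors = FALSE)
  inf_pts <- baf_points[baf_points$informative & !is.na(baf_points$baf), ,
                        drop = FALSE]
  if (!nrow(inf_pts)) return(empty)
  segs <- list()
  for (chr in unique(inf_pts$chrom)) {
    p <- inf_pts[inf_pts$chrom == chr, , drop = FALSE]
    span <- max(p$pos) - min(p$pos)
    non_het <- p$baf < params$het_band[1] | p$baf > params$het_band[2]
    r <- rle(non_het)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & r$lengths >= params$min_markers_per_segment)
    for (k in keep) {
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chr, start = p$pos[starts[k]], end = p$pos[ends[k]],
        n_markers = r$lengths[k],
        fraction_of_chromosome_span =
          if (span > 0) (p$pos[ends[k]] - p$pos[starts[k]]) / span else 1,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(segs)) return(empty)
  out <- do.call(rbind, segs)
  out <- out[order(chrom_rank(out$chrom), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag whole-chromosome UPD from AOH segments
#'
#' An autosome is flagged as suggestive of (isodisomic) uniparental disomy
#' when its AOH segments cover at least `upd_chromosome_fraction` of its
#' informative markers while the AOH marker fraction across all other
#' autosomes stays at or below `max_background_aoh_fraction`. When two or
#' more autosomes exceed the chromosome threshold, none is flagged and the
#' pattern is reported as `consanguinity_pattern`. chrX is excluded (male
#' hemizygosity mimics chromosome-wide AOH).
#'
#' @param segments output of [detect_aoh()].
#' @param baf_points the [compute_baf()] table the segments came from
#'   (supplies per-chromosome informative marker counts).
#' @param params an [aoh_params()].
#' @return data.frame with one row per autosome present in `baf_points`:
#'   `chrom`, `n_informative`, `n_aoh_markers`, `aoh_fraction`,
#'   `background_fraction`, `flagged`, `pattern`.
#' @export
flag_upd <- function(segments, baf_points, params = aoh_params()) {
  pts <- baf_points[baf_points$informative & is_autosome(baf_points$chrom), ,
                    drop = FALSE]
  chroms <- unique(pts$chrom)
  n_inf <- vapply(chroms, function(ch) sum(pts$chrom == ch), 0L)
  n_aoh <- vapply(chroms, function(ch) {
    segs <- segments[segments$chrom == ch, , drop = FALSE]
    if (!nrow(segs)) return(0L)
    sum(segs$n_markers)
  }, 0L)
  frac <- ifelse(n_inf > 0, n_aoh / n_inf, 0)
  over <- frac >= params$upd_chromosome_fraction
  bg_frac <- vapply(seq_along(chroms), function(i) {
    tot <- sum(n_inf[-i]); if (tot == 0) 0 else sum(n_aoh[-i]) / tot
  }, 0)
  single <- sum(over) == 1
  flagged <- over & single & bg_frac <= params$max_background_aoh_fraction
  pattern <- ifelse(flagged, "upd_suggestive",
                    ifelse(over & !single, "consanguinity_pattern", "none"))
  out <- data.frame(chrom = chroms, n_informative = n_inf,
                    n_aoh_markers = n_aoh, aoh_fraction = frac,
                    background_fraction = bg_frac, flagged = flagged,
                    pattern = pattern, stringsAsFactors = FALSE)
  out <- out[order(chrom_rank(out$chrom)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Infer the parental origin of a flagged UPD chromosome
#'
#' Counts Mendelian-inconsistent sites on the chromosome at which the proband
#' is homozygous for an allele that one parent cannot have transmitted
#' (e.g. proband homozygous-alternate with the mother homozygous-reference
#' while the father carries the allele: paternal evidence). The parent
#' supported by at least 90% of informative inconsistent sites is returned;
#' otherwise `undetermined`.
#'
#' @param calls a [site_calls()].
#' @param ped a [pedigree()].
#' @param family_id family of the proband.
#' @param chromosome flagged chromosome.
#' @param proband proband sample id; defaults to the family's first affected
#'   trio child.
#' @return list with `origin` (`paternal`, `maternal`, `undetermined`),
#'   `n_paternal`, `n_maternal`.
#' @export
infer_upd_parent <- function(calls, ped, family_id, chromosome,
                             proband = NULL) {
  proband <- proband %||% trio_children(ped, family_id)[1]
  if (is.na(proband)) stop("no trio proband in family ", family_id)
  par <- parents_of(ped, proband)
  keep <- normalize_chrom(calls$sites$chrom) == normalize_chrom(chromosome)
  sub <- subset_sites(calls, calls$sites$site_id[keep])
  gt <- geno_matrix(sub, c(proband, par$father, par$mother), "gt")
  pr <- gt[, 1]; fa <- gt[, 2]; mo <- gt[, 3]
  # sites impossible under biparental transmission, attributable to one parent
  paternal <- (pr == "hom_alt" & mo == "hom_ref" & gt_has_alt(fa)) |
    (pr == "hom_ref" & mo == "hom_alt" & fa %in% c("hom_ref", "het"))
  maternal <- (pr == "hom_alt" & fa == "hom_ref" & gt_has_alt(mo)) |
    (pr == "hom_ref" & fa == "hom_alt" & mo %in% c("hom_ref", "het"))
  n_p <- sum(paternal, na.rm = TRUE)
  n_m <- sum(maternal, na.rm = TRUE)
  origin <- if (n_p + n_m == 0) "undetermined"
  else if (n_p / (n_p + n_m) >= 0.9) "paternal"
  else if (n_m / (n_p + n_m) >= 0.9) "maternal"
  else "undetermined"
  list(origin = origin, n_paternal = n_p, n_maternal = n_m)
}
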