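#' Run the full reanalysis pipeline over a cohort
#'
#' For every family: the stepwise inheritance-model workflow (including de
#' novo detection and the parental-mosaicism screen; singletons run in
#' proband-only mode), B-allele-frequency AOH segmentation with UPD flagging
#' and parental-origin inference for every trio proband, and coverage-dropout
#' deletion calling over the cohort coverage table. Heterozygous candidates
#' are annotated with trans deletion evidence.
#'
#' @param calls a [site_calls()] for the whole cohort.
#' @param ped a [pedigree()].
#' @param coverage per-exon coverage table (see
#'   [call_dropout_deletions()]); optional.
#' @param config a [workflow_config()].
#' @param dnm a [dnm_config()].
#' @param mosaic a [mosaic_config()].
#' @param aoh an [aoh_params()].
#' @param del a [deletion_params()].
#' @return list with `candidates`, `deletions`, `upd` (per-proband flag table
#'   with inferred origin), `aoh_segments`.
#' @export
run_pipeline <- function(calls, ped, coverage = NULL,
                         config = workflow_config(), dnm = dnm_config(),
                         mosaic = mosaic_config(), aoh = aoh_params(),
                         del = deletion_params()) {
  fams <- unique(ped$family_id)
  cands <- list()
  upd_rows <- list()
  aoh_rows <- list()
  for (fam in fams) {
    fam_ped <- ped[ped$family_id == fam, , drop = FALSE]
    singleton <- all(is.na(fam_ped$father_id) & is.na(fam_ped$mother_id))
    cfg <- config
    cfg$proband_only_mode <- singleton || config$proband_only_mode
    cands[[fam]] <- run_stepwise(calls, ped, fam, cfg, dnm, mosaic)
    for (pr in trio_children(ped, fam)) {
      baf <- compute_baf(calls, pr, aoh)
      segs <- detect_aoh(baf, aoh)
      aoh_rows[[paste(fam, pr)]] <-
        if (nrow(segs)) cbind(family_id = fam, sample_id = pr, segs) else NULL
      flags <- flag_upd(segs, baf, aoh)
      flagged <- flags[flags$flagged, , drop = FALSE]
      for (ch in flagged$chrom) {
        ori <- infer_upd_parent(calls, ped, fam, ch, proband = pr)
        upd_rows[[paste(fam, pr, ch)]] <- data.frame(
          family_id = fam, sample_id = pr, chrom = ch,
          aoh_fraction = flagged$aoh_fraction[flagged$chrom == ch],
          origin = ori$origin, n_paternal = ori$n_paternal,
          n_maternal = ori$n_maternal, stringsAsFactors = FALSE)
      }
    }
  }
  candidates <- candidate_frame(cands)
  deletions <- if (!is.null(coverage))
    call_dropout_deletions(coverage, ped, del) else NULL
  if (!is.null(deletions))
    candidates <- join_snv_deletion_trans(candidates, deletions)
  list(candidates = candidates,
       deletions = deletions,
       upd = if (length(upd_rows)) do.call(rbind, c(upd_rows,
                                                    make.row.names = FALSE))
             else data.frame(family_id = character(), sample_id = character(),
                             chrom = character(), aoh_fraction = numeric(),
                             origin = character(), n_paternal = integer(),
                             n_maternal = integer(), stringsAsFactors = FALSE),
       aoh_segments = if (length(aoh_rows))
         do.call(rbind, c(aoh_rows, make.row.names = FALSE)) else NULL)
}

#' Score pipeline results against a synthetic truth table
#'
#' For each planted event, checks whether the pipeline recovered it: a
#' candidate of the matching inheritance class at the planted site (both
#' sites for compound heterozygotes), a flagged mosaic parent, a UPD flag on
#' the planted chromosome with the correct parental origin, or a deletion
#' call with exactly the planted exon span.
#'
#' @param results output of [run_pipeline()].
#' @param truth truth table of a [simulate_cohort()] cohort.
#' @return data.frame with one row per planted event (`event_type`,
#'   `family_id`, `recovered`) plus a `sensitivity` attribute per event type.
#' @export
compare_to_truth <- function(results, truth) {
  cand <- results$candidates
  recovered <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    carriers <- strsplit(tr$carriers, ",")[[1]]
    hit_class <- function(class, pos, sample) {
      any(cand$inheritance_class == class & cand$family_id == tr$family_id &
            cand$chrom == tr$chrom & cand$pos == pos &
            cand$sample_id == sample)
    }
    recovered[i] <- switch(
      tr$event_type,
      de_novo = hit_class("de_novo", tr$pos, carriers[1]),
      ar_homozygous = hit_class("ar_homozygous", tr$pos, carriers[1]),
      xl_hemizygous = hit_class("xl_hemizygous", tr$pos, carriers[1]),
      compound_het = hit_class("compound_het", tr$pos, carriers[1]) &&
        hit_class("compound_het", tr$pos2, carriers[1]),
      mosaic_parent = hit_class("mosaic_parent", tr$pos,
                                carriers[length(carriers)]),
      upd = any(results$upd$family_id == tr$family_id &
                  results$upd$chrom == tr$chrom &
                  results$upd$origin ==
                    c(father = "paternal", mother = "maternal")[tr$upd_parent]),
      exon_dropout = !is.null(results$deletions) &&
        any(results$deletions$sample_id == carriers[1] &
              results$deletions$gene == tr$gene &
              results$deletions$start_index == tr$exon_start &
              results$deletions$end_index == tr$exon_end),
      FALSE)
  }
  out <- data.frame(event_type = truth$event_type,
                    family_id = truth$family_id, recovered = recovered,
                    stringsAsFactors = FALSE)
  sens <- tapply(out$recovered, out$event_type, mean)
  attr(out, "sensitivity") <- sens
  out
}
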