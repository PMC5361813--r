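#' Configuration for the stepwise inheritance-model workflow
#'
#' @param maf_max retain variants with population MAF strictly below this
#'   value; variants with no MAF annotation are treated as novel and retained.
#' @param lof_classes consequence classes counted as loss-of-function.
#' @param missense_allowed_steps steps in which missense variants
#'   participate (the heterozygous-LOF step is LOF-only by definition).
#' @param proband_only_mode when `TRUE`, parental genotypes are not required:
#'   compound-heterozygote pairs are reported with unknown phase and the
#'   de novo / mosaic step is skipped.
#' @return a `workflow_config` list.
#' @export
workflow_config <- function(maf_max = 0.005,
                            lof_classes = c("stop_gain", "frameshift_indel",
                                            "splice_site"),
                            missense_allowed_steps = c("ar_homozygous",
                                                       "compound_het"),
                            proband_only_mode = FALSE) {
  stopifnot(maf_max > 0, maf_max <= 1, length(lof_classes) > 0)
  structure(list(maf_max = maf_max, lof_classes = lof_classes,
                 missense_allowed_steps = missense_allowed_steps,
                 proband_only_mode = proband_only_mode),
            class = "workflow_config")
}

#' Filter calls by population allele frequency
#'
#' Retains sites with `maf < maf_max` (strict) or with no MAF annotation
#' (novel variants).
#'
#' @param calls a [site_calls()].
#' @param maf_max frequency cutoff, strict `<`.
#' @return the filtered [site_calls()].
#' @export
filter_by_frequency <- function(calls, maf_max = 0.005) {
  keep <- is.na(calls$sites$maf) | calls$sites$maf < maf_max
  subset_sites(calls, calls$sites$site_id[keep])
}

#' @noRd
allowed_classes <- function(config, step) {
  cls <- config$lof_classes
  if (step %in% config$missense_allowed_steps) cls <- c(cls, "missense")
  cls
}

#' Step 1: autosomal-recessive homozygous candidates
#'
#' Proband homozygous-alternate rare LOF/missense variants with both parents
#' heterozygous. A proband homozygote with a parent lacking the alternate
#' allele violates Mendelian transmission and is reported as class
#' `mendelian_inconsistent` (to be explained by uniparental disomy or an
#' overlapping deletion) rather than silently dropped.
#'
#' @param calls a [site_calls()] (the MAF filter is applied internally).
#' @param ped a [pedigree()].
#' @param family_id family to analyze.
#' @param config a [workflow_config()].
#' @return candidate data.frame.
#' @export
find_ar_homozygous <- function(calls, ped, family_id,
                               config = workflow_config()) {
  calls <- filter_by_frequency(calls, config$maf_max)
  cls <- allowed_classes(config, "ar_homozygous")
  keep <- calls$sites$consequence %in% cls & is_autosome(calls$sites$chrom)
  calls <- subset_sites(calls, calls$sites$site_id[keep])
  out <- list()
  for (pr in trio_children(ped, family_id)) {
    par <- parents_of(ped, pr)
    gt <- geno_matrix(calls, c(pr, par$father, par$mother), "gt")
    ar <- geno_matrix(calls, c(pr, par$father, par$mother), "alt_reads")
    rr <- geno_matrix(calls, c(pr, par$father, par$mother), "ref_reads")
    hom <- gt[, 1] == "hom_alt"
    both_het <- gt[, 2] == "het" & gt[, 3] == "het"
    inconsistent <- hom & (gt_lacks_alt(gt[, 2]) | gt_lacks_alt(gt[, 3]))
    usable <- gt[, 2] != "missing" & gt[, 3] != "missing"
    pick <- function(rows, class) {
      if (!any(rows)) return(NULL)
      s <- calls$sites[rows, , drop = FALSE]
      data.frame(family_id = family_id, sample_id = pr, chrom = s$chrom,
                 pos = s$pos, ref = s$ref, alt = s$alt, site_id = s$site_id,
                 gene = s$gene, consequence = s$consequence, maf = s$maf,
                 inheritance_class = class, workflow_step = 1L,
                 gt = "hom_alt",
                 proband_af = ar[rows, 1] / pmax(ar[rows, 1] + rr[rows, 1], 1),
                 evidence = sprintf("father_gt=%s;mother_gt=%s",
                                    gt[rows, 2], gt[rows, 3]),
                 stringsAsFactors = FALSE)
    }
    out[[paste0(pr, "_ar")]] <- pick(hom & both_het & usable, "ar_homozygous")
    out[[paste0(pr, "_mi")]] <- pick(inconsistent & usable,
                                     "mendelian_inconsistent")
  }
  candidate_frame(out)
}

# transmission origin of a proband het variant: which parent carries the alt
#' @noRd
het_origin <- function(father_gt, mother_gt) {
  f <- gt_has_alt(father_gt); m <- gt_has_alt(mother_gt)
  ifelse(f & m, "both",
         ifelse(f, "father_only", ifelse(m, "mother_only", "neither")))
}

#' Step 2: compound-heterozygote candidate pairs
#'
#' Pairs of rare LOF/missense variants in one gene for which the proband is
#' heterozygous at both sites. In trio mode a pair is reported in trans when
#' one variant is transmitted only by the father and the other only by the
#' mother; pairs with a doubly-transmitted variant are phase-undecidable and
#' reported `phase_unknown`; pairs transmitted by a single parent (cis) are
#' excluded. In proband-only mode every het pair in a gene is reported
#' `phase_unknown`. Each reported pair yields two candidate rows linked by
#' `partner_site_id`.
#'
#' @inheritParams find_ar_homozygous
#' @return candidate data.frame.
#' @export
find_compound_het <- function(calls, ped, family_id,
                              config = workflow_config()) {
  calls <- filter_by_frequency(calls, config$maf_max)
  cls <- allowed_classes(config, "compound_het")
  keep <- calls$sites$consequence %in% cls
  calls <- subset_sites(calls, calls$sites$site_id[keep])
  probands <- if (config$proband_only_mode) {
    ped$sample_id[ped$family_id == family_id & ped$affected == "affected"]
  } else trio_children(ped, family_id)
  out <- list()
  for (pr in probands) {
    if (config$proband_only_mode) {
      gt <- geno_matrix(calls, pr, "gt")
      origin <- rep(NA_character_, nrow(calls$sites))
    } else {
      par <- parents_of(ped, pr)
      gt <- geno_matrix(calls, c(pr, par$father, par$mother), "gt")
      origin <- het_origin(gt[, 2], gt[, 3])
    }
    het_idx <- which(gt[, 1] == "het")
    if (length(het_idx) < 2) next
    s <- calls$sites[het_idx, , drop = FALSE]
    org <- origin[het_idx]
    genes <- unique(s$gene[duplicated(s$gene)])
    for (g in genes[!is.na(genes)]) {
      gi <- which(s$gene == g)
      for (i in gi) for (j in gi) {
        if (i >= j) next
        if (config$proband_only_mode) {
          phase <- "phase_unknown"
        } else {
          oi <- org[i]; oj <- org[j]
          if (oi == "neither" || oj == "neither") next # de novo screen's job
          trans <- (oi == "father_only" && oj == "mother_only") ||
            (oi == "mother_only" && oj == "father_only")
          cis <- oi == oj && oi %in% c("father_only", "mother_only")
          if (cis) next
          phase <- if (trans) "trans" else "phase_unknown"
        }
        pair <- data.frame(
          family_id = family_id, sample_id = pr,
          chrom = s$chrom[c(i, j)], pos = s$pos[c(i, j)],
          ref = s$ref[c(i, j)], alt = s$alt[c(i, j)],
          site_id = s$site_id[c(i, j)], gene = g,
          consequence = s$consequence[c(i, j)], maf = s$maf[c(i, j)],
          inheritance_class = "compound_het", workflow_step = 2L,
          gt = "het",
          partner_site_id = s$site_id[c(j, i)], phase = phase,
          parental_origin = if (config$proband_only_mode) NA_character_
                            else c(oi, oj),
          stringsAsFactors = FALSE)
        out[[length(out) + 1L]] <- pair
      }
    }
  }
  candidate_frame(out)
}

#' Step 3: heterozygous loss-of-function candidates
#'
#' Rare heterozygous LOF variants in the proband. This step is what makes
#' truncating de novo events discoverable in proband-only analyses, where
#' parental subtraction is impossible.
#'
#' @inheritParams find_ar_homozygous
#' @return candidate data.frame.
#' @export
find_het_lof <- function(calls, ped, family_id, config = workflow_config()) {
  calls <- filter_by_frequency(calls, config$maf_max)
  keep <- calls$sites$consequence %in% config$lof_classes
  calls <- subset_sites(calls, calls$sites$site_id[keep])
  probands <- ped$sample_id[ped$family_id == family_id &
                              ped$affected == "affected"]
  out <- list()
  for (pr in probands) {
    gt <- geno_matrix(calls, pr, "gt")
    hit <- which(gt[, 1] == "het")
    if (!length(hit)) next
    s <- calls$sites[hit, , drop = FALSE]
    out[[pr]] <- data.frame(
      family_id = family_id, sample_id = pr, chrom = s$chrom, pos = s$pos,
      ref = s$ref, alt = s$alt, site_id = s$site_id, gene = s$gene,
      consequence = s$consequence, maf = s$maf,
      inheritance_class = "het_lof", workflow_step = 3L, gt = "het",
      stringsAsFactors = FALSE)
  }
  candidate_frame(out)
}

#' X-linked hemizygous candidates
#'
#' Rare chrX LOF/missense variants hemizygous in a male proband with the
#' mother carrying the allele (het or hom-alt). A maternal absence of the
#' allele is instead routed through the de novo read-count criteria and, if
#' they pass, reported as a de novo on chrX. Female probands follow the
#' autosomal rules elsewhere; probands of unknown sex skip chrX with a
#' warning.
#'
#' @inheritParams find_ar_homozygous
#' @param dnm a [dnm_config()] for the de-novo-on-X routing.
#' @return candidate data.frame.
#' @export
find_hemizygous <- function(calls, ped, family_id,
                            config = workflow_config(), dnm = dnm_config()) {
  calls <- filter_by_frequency(calls, config$maf_max)
  cls <- allowed_classes(config, "compound_het") # LOF and/or missense
  keep <- calls$sites$consequence %in% cls &
    normalize_chrom(calls$sites$chrom) == "X"
  calls <- subset_sites(calls, calls$sites$site_id[keep])
  out <- list()
  for (pr in trio_children(ped, family_id)) {
    sex <- ped$sex[match(pr, ped$sample_id)]
    if (sex == "unknown") {
      warning("proband ", pr, " has unknown sex; chrX skipped")
      next
    }
    if (sex != "male") next
    par <- parents_of(ped, pr)
    trio <- c(pr, par$father, par$mother)
    gt <- geno_matrix(calls, trio, "gt")
    ar <- geno_matrix(calls, trio, "alt_reads")
    rr <- geno_matrix(calls, trio, "ref_reads")
    hemi <- gt[, 1] %in% c("hemi_alt", "hom_alt")
    mother_carries <- gt[, 3] %in% c("het", "hom_alt")
    mother_clear <- gt_lacks_alt(gt[, 3])
    mk <- function(rows, class, step, phase = NA_character_) {
      if (!any(rows)) return(NULL)
      s <- calls$sites[rows, , drop = FALSE]
      data.frame(family_id = family_id, sample_id = pr, chrom = s$chrom,
                 pos = s$pos, ref = s$ref, alt = s$alt, site_id = s$site_id,
                 gene = s$gene, consequence = s$consequence, maf = s$maf,
                 inheritance_class = class, workflow_step = step,
                 gt = gt[rows, 1],
                 proband_af = ar[rows, 1] / pmax(ar[rows, 1] + rr[rows, 1], 1),
                 evidence = sprintf("mother_gt=%s", gt[rows, 3]),
                 parental_origin = phase, stringsAsFactors = FALSE)
    }
    out[[paste0(pr, "_xl")]] <- mk(hemi & mother_carries, "xl_hemizygous", 1L,
                                   "mother")
    # de-novo-on-X routing: apply the read-count criteria
    route <- hemi & mother_clear
    if (any(route)) {
      dec <- dnm_criteria(ar[route, 1], rr[route, 1], ar[route, 2],
                          rr[route, 2], ar[route, 3], rr[route, 3], dnm)
      rows <- which(route)[dec$pass]
      sel <- rep(FALSE, nrow(gt)); sel[rows] <- TRUE
      out[[paste0(pr, "_dnx")]] <- mk(sel, "de_novo", 4L)
    }
  }
  candidate_frame(out)
}

#' Run the stepwise inheritance-model workflow for one family
#'
#' Executes all four analysis steps in order — (1) autosomal-recessive
#' homozygous plus X-linked hemizygous, (2) compound heterozygous, (3)
#' heterozygous LOF, (4) de novo plus parental-mosaicism screen — and
#' concatenates their candidates. Later steps always run even when earlier
#' steps produced hits, so dual molecular diagnoses are never missed. Output
#' ordering is deterministic (step, chromosome, position, sample) and
#' invariant to input row order.
#'
#' @param calls a [site_calls()].
#' @param ped a [pedigree()].
#' @param family_id family to analyze.
#' @param config a [workflow_config()].
#' @param dnm a [dnm_config()].
#' @param mosaic a [mosaic_config()].
#' @return candidate data.frame with `workflow_step` and evidence columns.
#' @export
run_stepwise <- function(calls, ped, family_id, config = workflow_config(),
                         dnm = dnm_config(), mosaic = mosaic_config()) {
  flt <- filter_by_frequency(calls, config$maf_max)
  pieces <- list()
  if (!config$proband_only_mode) {
    pieces$ar <- find_ar_homozygous(flt, ped, family_id, config)
    pieces$xl <- find_hemizygous(flt, ped, family_id, config, dnm)
  }
  pieces$ch <- find_compound_het(flt, ped, family_id, config)
  pieces$hl <- find_het_lof(flt, ped, family_id, config)
  if (!config$proband_only_mode) {
    pieces$dn <- find_de_novo(flt, ped, family_id, dnm)
    pieces$mo <- screen_parental_mosaicism(flt, ped, family_id, mosaic)
  }
  out <- candidate_frame(pieces)
  # a chrX de novo can be reached both via the hemizygous routing and via
  # plain subtraction; keep one row per (site, sample, class)
  out <- out[!duplicated(out[c("site_id", "sample_id", "inheritance_class")]),
             , drop = FALSE]
  if (nrow(out))
    out <- out[order(out$workflow_step, chrom_rank(out$chrom), out$pos,
                     out$sample_id, out$inheritance_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}
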