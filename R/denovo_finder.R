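#' Configuration for the de novo read-count criteria
#'
#' Four criteria applied after in-silico parental subtraction, all strict
#' inequalities: (1) proband alternate read count > 5; (2) proband
#' alternate/reference read ratio > 30%; (3) reference read count > 10 in
#' each parent; (4) alternate/reference read ratio < 5% in each parent.
#'
#' @param proband_min_alt_reads criterion 1 threshold (strict >).
#' @param proband_min_alt_ref_ratio criterion 2 threshold (strict >).
#' @param parent_min_ref_reads criterion 3 threshold (strict >).
#' @param parent_max_alt_ref_ratio criterion 4 threshold (strict <).
#' @return a `dnm_config` list.
#' @export
dnm_config <- function(proband_min_alt_reads = 5,
                       proband_min_alt_ref_ratio = 0.30,
                       parent_min_ref_reads = 10,
                       parent_max_alt_ref_ratio = 0.05) {
  stopifnot(proband_min_alt_reads >= 0, parent_min_ref_reads >= 0,
            proband_min_alt_ref_ratio >= 0, proband_min_alt_ref_ratio <= 1,
            parent_max_alt_ref_ratio >= 0, parent_max_alt_ref_ratio <= 1)
  structure(list(proband_min_alt_reads = proband_min_alt_reads,
                 proband_min_alt_ref_ratio = proband_min_alt_ref_ratio,
                 parent_min_ref_reads = parent_min_ref_reads,
                 parent_max_alt_ref_ratio = parent_max_alt_ref_ratio),
            class = "dnm_config")
}

#' Subtract parental variants in silico
#'
#' Returns the proband's variant sites (alternate allele called) at which
#' neither parent carries the alternate allele. Sites where either parent's
#' genotype is missing are excluded (subtraction requires evidence of
#' absence); their count is attached as attribute `n_skipped_missing`.
#'
#' @param calls a [site_calls()] covering the trio.
#' @param proband,father,mother sample ids; each must be genotyped in `calls`.
#' @return a [site_calls()] subset of the proband's variant sites.
#' @export
subtract_parental <- function(calls, proband, father, mother) {
  trio <- c(proband, father, mother)
  absent <- setdiff(trio, unique(calls$geno$sample_id))
  if (length(absent))
    stop("samples missing from call set: ", paste(absent, collapse = ", "))
  gt <- geno_matrix(calls, trio, "gt")
  proband_variant <- gt_has_alt(gt[, 1])
  parent_clear <- gt_lacks_alt(gt[, 2]) & gt_lacks_alt(gt[, 3])
  parent_missing <- gt[, 2] == "missing" | gt[, 3] == "missing"
  keep <- proband_variant & parent_clear & !parent_missing
  out <- subset_sites(calls, calls$sites$site_id[keep])
  attr(out, "n_skipped_missing") <- sum(proband_variant & parent_missing)
  out
}

#' Apply the four de novo read-count criteria
#'
#' Vectorized decision over proband and parental allelic depths. Conventions
#' for zero denominators: a proband with zero reference reads has an infinite
#' alt/ref ratio and passes criterion 2; a parent with zero reference reads
#' fails criterion 3 and its criterion 4 is indeterminate (`NA`, never
#' counted as a pass).
#'
#' @param proband_alt,proband_ref,father_alt,father_ref,mother_alt,mother_ref
#'   integer vectors of allelic depths (recycled to a common length).
#' @param config a [dnm_config()].
#' @param detail when `FALSE`, skip assembling the `failed_criteria` strings
#'   (cheaper for bulk decision tables).
#' @return data.frame with logical columns `c1`..`c4`, `pass`, and a
#'   `failed_criteria` string listing violated criterion numbers.
#' @export
dnm_criteria <- function(proband_alt, proband_ref, father_alt, father_ref,
                         mother_alt, mother_ref, config = dnm_config(),
                         detail = TRUE) {
  n <- max(lengths(list(proband_alt, proband_ref, father_alt, father_ref,
                        mother_alt, mother_ref)))
  pa <- rep_len(proband_alt, n); pr <- rep_len(proband_ref, n)
  fa <- rep_len(father_alt, n); fr <- rep_len(father_ref, n)
  ma <- rep_len(mother_alt, n); mr <- rep_len(mother_ref, n)
  ratio <- function(alt, ref) ifelse(ref == 0, Inf, alt / ref)
  c1 <- pa > config$proband_min_alt_reads
  c2 <- ratio(pa, pr) > config$proband_min_alt_ref_ratio
  c3 <- fr > config$parent_min_ref_reads & mr > config$parent_min_ref_reads
  c4f <- ifelse(fr == 0, NA, fa / fr < config$parent_max_alt_ref_ratio)
  c4m <- ifelse(mr == 0, NA, ma / mr < config$parent_max_alt_ref_ratio)
  c4 <- c4f & c4m # NA & FALSE = FALSE; NA & TRUE = NA
  pass <- c1 & c2 & c3 & !is.na(c4) & c4
  out <- data.frame(c1 = c1, c2 = c2, c3 = c3, c4 = c4, pass = pass)
  if (detail) {
    part <- function(bad, label) {
      ch <- character(n); ch[bad] <- label; ch
    }
    failed <- paste0(part(!c1, "1,"), part(!c2, "2,"), part(!c3, "3,"),
                     part(is.na(c4) | !c4, "4,"))
    out$failed_criteria <- sub(",$", "", failed)
  }
  out
}

#' Find de novo variant candidates in a trio
#'
#' Composition of [subtract_parental()] and [dnm_criteria()]: sites called in
#' the proband and in neither parent, whose allelic depths satisfy all four
#' read-count criteria.
#'
#' @param calls a [site_calls()].
#' @param ped a [pedigree()].
#' @param family_id family to analyze; every affected child with both parents
#'   sampled is screened.
#' @param config a [dnm_config()].
#' @return candidate data.frame (class `de_novo`, workflow step 4) with the
#'   proband allele fraction and per-criterion evidence.
#' @export
find_de_novo <- function(calls, ped, family_id, config = dnm_config()) {
  probands <- trio_children(ped, family_id)
  out <- list()
  for (pr in probands) {
    par <- parents_of(ped, pr)
    sub <- subtract_parental(calls, pr, par$father, par$mother)
    if (!nrow(sub$sites)) next
    trio <- c(pr, par$father, par$mother)
    ar <- geno_matrix(sub, trio, "alt_reads")
    rr <- geno_matrix(sub, trio, "ref_reads")
    dec <- dnm_criteria(ar[, 1], rr[, 1], ar[, 2], rr[, 2], ar[, 3], rr[, 3],
                        config)
    hit <- which(dec$pass)
    if (!length(hit)) next
    s <- sub$sites[hit, , drop = FALSE]
    out[[pr]] <- data.frame(
      family_id = family_id, sample_id = pr,
      chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
      site_id = s$site_id, gene = s$gene, consequence = s$consequence,
      maf = s$maf, inheritance_class = "de_novo", workflow_step = 4L,
      gt = "het",
      proband_af = ar[hit, 1] / pmax(ar[hit, 1] + rr[hit, 1], 1),
      evidence = sprintf("proband=%d/%d;father=%d/%d;mother=%d/%d",
                         ar[hit, 1], rr[hit, 1], ar[hit, 2], rr[hit, 2],
                         ar[hit, 3], rr[hit, 3]),
      stringsAsFactors = FALSE)
  }
  candidate_frame(out)
}

# bind candidate frames, guaranteeing the standard columns exist
#' @noRd
candidate_frame <- function(pieces) {
  base <- data.frame(family_id = character(), sample_id = character(),
                     chrom = character(), pos = integer(), ref = character(),
                     alt = character(), site_id = character(),
                     gene = character(), consequence = character(),
                     maf = numeric(), inheritance_class = character(),
                     workflow_step = integer(), gt = character(),
                     proband_af = numeric(), evidence = character(),
                     partner_site_id = character(), phase = character(),
                     parental_origin = character(), p_value = numeric(),
                     stringsAsFactors = FALSE)
  pieces <- Filter(function(p) !is.null(p) && nrow(p) > 0, pieces)
  if (!length(pieces)) return(base)
  pieces <- lapply(pieces, function(p) {
    for (col in setdiff(names(base), names(p)))
      p[[col]] <- base[[col]][NA_integer_][rep(1, nrow(p))]
    p[, names(base), drop = FALSE]
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
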