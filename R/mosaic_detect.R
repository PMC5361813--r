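#' Configuration for the parental-mosaicism screen
#'
#' A constitutional heterozygote carries the variant on one of two alleles, so
#' its variant-read fraction is expected to be 50%. A parent whose fraction
#' deviates significantly below/above that expectation while every carrier
#' child looks constitutional is flagged as potentially mosaic.
#'
#' @param alpha two-sided significance level for the exact binomial test.
#'   The default 0.01 separates clearly deviating parental fractions from
#'   ordinary binomial sampling noise at exome depths.
#' @param min_total_reads minimum parental depth for a decision; below it the
#'   evidence is returned unflagged with reason `insufficient_depth`.
#' @param require_affected_carriers minimum number of affected children
#'   carrying the variant for the site to be screened.
#' @return a `mosaic_config` list.
#' @export
mosaic_config <- function(alpha = 0.01, min_total_reads = 20,
                          require_affected_carriers = 1) {
  stopifnot(alpha > 0, alpha < 1, min_total_reads >= 0,
            require_affected_carriers >= 1)
  structure(list(alpha = alpha, min_total_reads = min_total_reads,
                 require_affected_carriers = require_affected_carriers),
            class = "mosaic_config")
}

#' Variant allele fraction
#'
#' Exact ratio of variant (alternate) reads to total reads at a site.
#'
#' @param alt_reads,total_reads non-negative integers, `alt_reads <=
#'   total_reads`, `total_reads > 0` (vectorized).
#' @return numeric fraction(s) in \[0, 1\].
#' @export
variant_allele_fraction <- function(alt_reads, total_reads) {
  if (any(total_reads == 0)) stop("total_reads must be positive")
  if (any(alt_reads > total_reads) || any(alt_reads < 0))
    stop("alt_reads must lie in [0, total_reads]")
  alt_reads / total_reads
}

#' Exact two-sided binomial test against a 50% variant-read fraction
#'
#' Minimum-likelihood two-sided p-value: the sum of the probabilities of all
#' outcomes no more probable than the observed count under
#' Binomial(n, 0.5). Computed by direct enumeration of the probability mass
#' function (with the customary relative tolerance guard for floating-point
#' ties between symmetric outcomes).
#'
#' @param alt_reads observed variant read count(s).
#' @param total_reads total read count(s) (> 0).
#' @return p-value(s) in \[0, 1\].
#' @export
binomial_deviation_test <- function(alt_reads, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  mapply(function(k, n) {
    d <- stats::dbinom(0:n, n, 0.5)
    min(1, sum(d[d <= d[k + 1] * (1 + 1e-07)]))
  }, alt_reads, total_reads)
}

#' Screen one site for parental mosaicism
#'
#' For a site carried by affected children and by a parent, computes the
#' variant-read fraction and the exact binomial deviation p-value for the
#' parent and every carrier child. The parent is flagged as potentially
#' mosaic iff its p-value falls below `alpha` while every carrier child's
#' p-value stays at or above `alpha` (children consistent with constitutional
#' heterozygosity).
#'
#' @param calls a [site_calls()].
#' @param ped a [pedigree()].
#' @param family_id family to screen.
#' @param site_id site to screen.
#' @param config a [mosaic_config()].
#' @return data.frame of mosaic evidence, one row per carrier parent, with
#'   columns `sample_id`, `site_id`, `alt_reads`, `total_reads`, `fraction`,
#'   `p_value`, `flagged`, `reason` and the carrier children's evidence
#'   serialized in `children`.
#' @export
flag_parental_mosaic <- function(calls, ped, family_id, site_id,
                                 config = mosaic_config()) {
  fam <- ped[ped$family_id == family_id, , drop = FALSE]
  g <- calls$geno[calls$geno$site_id == site_id &
                    calls$geno$sample_id %in% fam$sample_id, , drop = FALSE]
  if (!nrow(g)) stop("site ", site_id, " not genotyped in family ", family_id)
  parents <- unique(stats::na.omit(c(fam$father_id, fam$mother_id)))
  children <- fam$sample_id[fam$affected == "affected" &
                              !fam$sample_id %in% parents]
  gt_of <- setNames(g$gt, g$sample_id)
  carrier_children <- children[gt_has_alt(gt_of[children])]
  out <- list()
  for (p in parents) {
    if (!gt_has_alt(gt_of[p])) next
    if (length(carrier_children) < config$require_affected_carriers) next
    row <- g[g$sample_id == p, ]
    total <- row$ref_reads + row$alt_reads
    child_rows <- g[g$sample_id %in% carrier_children, , drop = FALSE]
    child_tot <- child_rows$ref_reads + child_rows$alt_reads
    child_p <- ifelse(child_tot > 0,
                      binomial_deviation_test(child_rows$alt_reads,
                                              pmax(child_tot, 1)), NA)
    if (total < config$min_total_reads) {
      flagged <- FALSE; reason <- "insufficient_depth"
      p_val <- if (total > 0) binomial_deviation_test(row$alt_reads, total)
               else NA_real_
    } else {
      p_val <- binomial_deviation_test(row$alt_reads, total)
      children_ok <- all(!is.na(child_p) & child_p >= config$alpha)
      flagged <- p_val < config$alpha && children_ok
      reason <- if (flagged) "parent_deviates_children_constitutional"
                else if (p_val >= config$alpha) "parent_consistent_with_het"
                else "carrier_child_also_deviates"
    }
    out[[p]] <- data.frame(
      sample_id = p, family_id = family_id, site_id = site_id,
      alt_reads = row$alt_reads, total_reads = total,
      fraction = if (total > 0) row$alt_reads / total else NA_real_,
      p_value = p_val, flagged = flagged, reason = reason,
      children = paste(sprintf("%s=%d/%d(p=%.3g)", carrier_children,
                               child_rows$alt_reads, child_tot, child_p),
                       collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(mosaic_evidence_frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @noRd
mosaic_evidence_frame <- function() {
  data.frame(sample_id = character(), family_id = character(),
             site_id = character(), alt_reads = integer(),
             total_reads = integer(), fraction = numeric(),
             p_value = numeric(), flagged = logical(), reason = character(),
             children = character(), stringsAsFactors = FALSE)
}

#' Screen all qualifying sites of a family for parental mosaicism
#'
#' Applies [flag_parental_mosaic()] to every site carried by at least
#' `require_affected_carriers` affected children and by a parent, and returns
#' flagged parents as workflow candidates (class `mosaic_parent`, step 4).
#'
#' @inheritParams flag_parental_mosaic
#' @return candidate data.frame of flagged parents (possibly empty).
#' @export
screen_parental_mosaicism <- function(calls, ped, family_id,
                                      config = mosaic_config()) {
  fam <- ped[ped$family_id == family_id, , drop = FALSE]
  parents <- unique(stats::na.omit(c(fam$father_id, fam$mother_id)))
  if (!length(parents)) return(candidate_frame(list()))
  children <- fam$sample_id[fam$affected == "affected" &
                              !fam$sample_id %in% parents]
  g <- calls$geno[calls$geno$sample_id %in% fam$sample_id, , drop = FALSE]
  carrier <- g[gt_has_alt(g$gt), , drop = FALSE]
  n_child <- tapply(carrier$sample_id %in% children, carrier$site_id, sum)
  has_parent <- tapply(carrier$sample_id %in% parents, carrier$site_id, any)
  cand_sites <- names(n_child)[n_child >= config$require_affected_carriers &
                                 has_parent[names(n_child)]]
  out <- list()
  for (sid in cand_sites) {
    ev <- flag_parental_mosaic(calls, ped, family_id, sid, config)
    ev <- ev[ev$flagged, , drop = FALSE]
    if (!nrow(ev)) next
    s <- calls$sites[match(sid, calls$sites$site_id), , drop = FALSE]
    out[[sid]] <- data.frame(
      family_id = family_id, sample_id = ev$sample_id, chrom = s$chrom,
      pos = s$pos, ref = s$ref, alt = s$alt, site_id = sid, gene = s$gene,
      consequence = s$consequence, maf = s$maf,
      inheritance_class = "mosaic_parent", workflow_step = 4L,
      gt = "het", proband_af = ev$fraction, p_value = ev$p_value,
      evidence = sprintf("fraction=%d/%d;p=%.3g;%s", ev$alt_reads,
                         ev$total_reads, ev$p_value, ev$children),
      stringsAsFactors = FALSE)
  }
  candidate_frame(out)
}
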