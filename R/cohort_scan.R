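#' Tally rare homozygous stop-gain variants per gene across a cohort
#'
#' The "bulk data" scan: genes are ranked by the number of distinct
#' individuals carrying at least one rare (`maf < maf_max`, or unannotated)
#' homozygous stop-gain variant in the gene. Hemizygous chrX stop-gains in
#' males count as homozygous-equivalent (single-allele loss of function).
#' Each individual counts once per gene regardless of how many qualifying
#' variants it carries; the qualifying variant count is reported alongside.
#'
#' @param calls a [site_calls()] over the whole cohort.
#' @param maf_max rare-variant frequency cutoff, strict `<`.
#' @return data.frame (`gene`, `n_individuals`, `n_variants`, `sample_ids`,
#'   `site_ids`) sorted by `n_individuals` descending, ties broken
#'   lexicographically by gene symbol.
#' @export
tally_rare_homozygous_stopgain <- function(calls, maf_max = 0.005) {
  s <- calls$sites
  qual_site <- s$consequence %in% "stop_gain" &
    (is.na(s$maf) | s$maf < maf_max) & !is.na(s$gene)
  sids <- s$site_id[qual_site]
  g <- calls$geno[calls$geno$site_id %in% sids &
                    calls$geno$gt %in% c("hom_alt", "hemi_alt"), , drop = FALSE]
  if (!nrow(g))
    return(data.frame(gene = character(), n_individuals = integer(),
                      n_variants = integer(), sample_ids = character(),
                      site_ids = character(), stringsAsFactors = FALSE))
  g$gene <- s$gene[match(g$site_id, s$site_id)]
  per_gene <- split(g, g$gene)
  out <- do.call(rbind, lapply(per_gene, function(d) {
    data.frame(gene = d$gene[1],
               n_individuals = length(unique(d$sample_id)),
               n_variants = length(unique(d$site_id)),
               sample_ids = paste(sort(unique(d$sample_id)), collapse = ","),
               site_ids = paste(sort(unique(d$site_id)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n_individuals, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
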