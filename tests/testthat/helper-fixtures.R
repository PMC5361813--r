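# compact builders for hand-written call tables used across the tests

# trio pedigree: father FA, mother MO, proband P1 (male unless stated)
trio_ped <- function(fam = "F1", proband_sex = "male") {
  pedigree(sample_id = paste0(fam, c("_FA", "_MO", "_P1")),
           family_id = fam,
           father_id = c(NA, NA, paste0(fam, "_FA")),
           mother_id = c(NA, NA, paste0(fam, "_MO")),
           sex = c("male", "female", proband_sex),
           affected = c("unaffected", "unaffected", "affected"))
}

# build site_calls from a compact per-site spec:
#   list(chrom, pos, gene, csq, maf, gt = c(sample = "het", ...),
#        ad = list(sample = c(ref, alt), ...))
# depths default to clean values for the genotype at depth 40
make_calls <- function(site_list, samples) {
  default_ad <- c(hom_ref = "40,0", het = "20,20", hom_alt = "0,40",
                  hemi_ref = "40,0", hemi_alt = "0,40", missing = "NA,NA")
  sites <- list(); geno <- list()
  for (i in seq_along(site_list)) {
    s <- site_list[[i]]
    sid <- paste(s$chrom, s$pos, s$ref %||% "C", s$alt %||% "T", sep = ":")
    sites[[i]] <- data.frame(
      site_id = sid, chrom = as.character(s$chrom), pos = as.integer(s$pos),
      ref = s$ref %||% "C", alt = s$alt %||% "T",
      gene = s$gene %||% "GENE1", consequence = s$csq %||% "missense",
      maf = if (is.null(s$maf)) NA_real_ else s$maf, stringsAsFactors = FALSE)
    gt <- rep("hom_ref", length(samples)); names(gt) <- samples
    gt[names(s$gt)] <- s$gt
    ad <- default_ad[gt]
    names(ad) <- samples
    if (!is.null(s$ad)) ad[names(s$ad)] <-
        vapply(s$ad, function(x) paste(x, collapse = ","), "")
    parts <- strsplit(unname(ad), ",")
    geno[[i]] <- data.frame(
      site_id = sid, sample_id = samples, gt = unname(gt),
      ref_reads = suppressWarnings(as.integer(vapply(parts, `[`, "", 1))),
      alt_reads = suppressWarnings(as.integer(vapply(parts, `[`, "", 2))),
      stringsAsFactors = FALSE)
  }
  site_calls(do.call(rbind, sites), do.call(rbind, geno))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# default small planted-event set exercising every detector
all_event_specs <- function() {
  list(event_spec("de_novo", 1),
       event_spec("ar_homozygous", 2),
       event_spec("compound_het", 1),
       event_spec("xl_hemizygous", 2),
       event_spec("mosaic_parent", 3, mosaic_fraction = 0.15),
       event_spec("exon_dropout", 1, n_exons = 2))
}

# affected children with both parents sampled
trio_children_for_test <- function(ped) {
  ped$sample_id[!is.na(ped$father_id) & !is.na(ped$mother_id)]
}
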