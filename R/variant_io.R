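#' Site-call container
#'
#' Variant calls are kept in two aligned tables: `sites`, one row per
#' biallelic site (`site_id`, `chrom`, `pos`, `ref`, `alt`, `gene`,
#' `consequence`, `maf`; `maf = NA` means the annotation is absent, i.e. the
#' variant is novel to the reference population), and `geno`, one row per
#' (site, sample) with the genotype class (`hom_ref`, `het`, `hom_alt`,
#' `hemi_ref`, `hemi_alt`, `missing`) and the allelic depths `ref_reads`,
#' `alt_reads`.
#'
#' @param sites,geno data frames as described above.
#' @return an object of class `site_calls`.
#' @export
site_calls <- function(sites, geno) {
  need_s <- c("site_id", "chrom", "pos", "ref", "alt", "gene", "consequence", "maf")
  need_g <- c("site_id", "sample_id", "gt", "ref_reads", "alt_reads")
  if (!all(need_s %in% names(sites)))
    stop("sites table missing columns: ",
         paste(setdiff(need_s, names(sites)), collapse = ", "))
  if (!all(need_g %in% names(geno)))
    stop("geno table missing columns: ",
         paste(setdiff(need_g, names(geno)), collapse = ", "))
  if (anyDuplicated(sites$site_id))
    stop("duplicate site_id in sites table")
  stopifnot(all(sites$pos >= 1), all(nchar(sites$ref) > 0),
            all(nchar(sites$alt) > 0), all(geno$gt %in% GT_LEVELS),
            all(geno$ref_reads >= 0 | geno$gt == "missing"),
            all(geno$alt_reads >= 0 | geno$gt == "missing"))
  sites <- sites[order_sites(sites), , drop = FALSE]
  rownames(sites) <- NULL
  geno <- geno[order(match(geno$site_id, sites$site_id), geno$sample_id), ,
               drop = FALSE]
  rownames(geno) <- NULL
  structure(list(sites = sites, geno = geno), class = "site_calls")
}

#' @export
print.site_calls <- function(x, ...) {
  cat("<site_calls> ", nrow(x$sites), " sites x ",
      length(unique(x$geno$sample_id)), " samples\n", sep = "")
  invisible(x)
}

#' @noRd
make_site_id <- function(chrom, pos, ref, alt) {
  paste(normalize_chrom(chrom), pos, ref, alt, sep = ":")
}

# genotype / depth matrices (sites x samples), aligned to calls$sites order
#' @noRd
geno_matrix <- function(calls, samples, field = "gt") {
  out <- matrix(if (field == "gt") "missing" else NA_integer_,
                nrow = nrow(calls$sites), ncol = length(samples),
                dimnames = list(calls$sites$site_id, samples))
  g <- calls$geno[calls$geno$sample_id %in% samples, , drop = FALSE]
  i <- match(g$site_id, calls$sites$site_id)
  j <- match(g$sample_id, samples)
  out[cbind(i, j)] <- g[[field]]
  out
}

#' @noRd
subset_sites <- function(calls, keep_site_ids) {
  sites <- calls$sites[calls$sites$site_id %in% keep_site_ids, , drop = FALSE]
  geno <- calls$geno[calls$geno$site_id %in% keep_site_ids, , drop = FALSE]
  site_calls(sites, geno)
}

#' Read a multi-sample VCF into site calls
#'
#' Reads a VCF v4.2 with per-sample `GT` and `AD`, pulls gene symbol,
#' consequence class and population minor allele frequency from INFO, and
#' decomposes multi-allelic records into one biallelic call per alternate
#' allele (per-allele depths: `ref_reads` = AD of the reference allele,
#' `alt_reads` = AD of that alternate). Chromosome names are normalized by
#' stripping a leading `"chr"`.
#'
#' @param path path to the VCF (plain text or bgzipped).
#' @param ped a [pedigree()]; every pedigree sample must be genotyped in the
#'   VCF, otherwise an error is raised.
#' @param info_keys named character vector mapping the fields `gene`,
#'   `consequence`, `maf` to INFO keys.
#' @return a [site_calls()] object restricted to the pedigree samples.
#' @export
read_calls <- function(path, ped,
                       info_keys = c(gene = "GENE", consequence = "CSQ",
                                     maf = "MAF")) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix # CHROM..INFO; getFIX() would drop the INFO column
  vcf_samples <- colnames(v@gt)[-1]
  missing_samples <- setdiff(ped$sample_id, vcf_samples)
  if (length(missing_samples))
    stop("pedigree samples absent from VCF: ",
         paste(missing_samples, collapse = ", "))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  ad_raw <- vcfR::extract.gt(v, element = "AD")
  if (is.null(dim(gt_raw))) {
    gt_raw <- matrix(gt_raw, nrow = nrow(fix), dimnames = list(NULL, vcf_samples))
    ad_raw <- matrix(ad_raw, nrow = nrow(fix), dimnames = list(NULL, vcf_samples))
  }
  keep <- ped$sample_id
  gt_raw <- gt_raw[, keep, drop = FALSE]
  ad_raw <- ad_raw[, keep, drop = FALSE]
  info <- fix[, "INFO"]
  get_info <- function(key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    hit <- grepl(paste0("(^|;)", key, "="), info)
    out[hit] <- sub(paste0("^;?", key, "="), "",
                    regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info)))
    out
  }
  gene <- get_info(info_keys[["gene"]])
  csq <- get_info(info_keys[["consequence"]])
  maf <- suppressWarnings(as.numeric(get_info(info_keys[["maf"]])))

  chrom <- normalize_chrom(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt_field <- fix[, "ALT"]
  alt_list <- strsplit(alt_field, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)

  # fast vectorized path for biallelic records with simple GT encodings
  simple_gt <- c("0/0" = "hom_ref", "0|0" = "hom_ref", "0/1" = "het",
                 "1/0" = "het", "0|1" = "het", "1|0" = "het",
                 "1/1" = "hom_alt", "1|1" = "hom_alt",
                 "0" = "hemi_ref", "1" = "hemi_alt")
  biallelic <- which(n_alt == 1L &
                       apply(gt_raw, 1, function(g)
                         all(is.na(g) | g %in% c(names(simple_gt),
                                                 ".", "./.", ".|."))))
  sites_fast <- NULL
  geno_fast <- NULL
  if (length(biallelic)) {
    rb <- biallelic
    gt_b <- gt_raw[rb, , drop = FALSE]
    ad_b <- ad_raw[rb, , drop = FALSE]
    cls <- matrix(unname(simple_gt[gt_b]), nrow = length(rb))
    cls[is.na(cls)] <- "missing"
    genotyped <- cls != "missing"
    no_ad <- genotyped & (is.na(ad_b) | ad_b == ".")
    if (any(no_ad)) {
      w <- which(no_ad, arr.ind = TRUE)[1, ]
      stop("missing AD for genotyped sample ", keep[w[2]],
           " at ", chrom[rb[w[1]]], ":", pos[rb[w[1]]])
    }
    ref_b <- suppressWarnings(as.integer(sub(",.*", "", ad_b)))
    alt_b <- suppressWarnings(as.integer(sub("^[^,]*,", "", ad_b)))
    ref_b[!genotyped] <- NA_integer_
    alt_b[!genotyped] <- NA_integer_
    sid_b <- make_site_id(chrom[rb], pos[rb], ref[rb],
                          unlist(alt_list[rb], use.names = FALSE))
    sites_fast <- data.frame(
      site_id = sid_b, chrom = chrom[rb], pos = pos[rb], ref = ref[rb],
      alt = unlist(alt_list[rb], use.names = FALSE), gene = gene[rb],
      consequence = csq[rb], maf = maf[rb], stringsAsFactors = FALSE)
    geno_fast <- data.frame(
      site_id = rep(sid_b, times = length(keep)),
      sample_id = rep(keep, each = length(rb)),
      gt = as.vector(cls), ref_reads = as.vector(ref_b),
      alt_reads = as.vector(alt_b), stringsAsFactors = FALSE)
  }
  slow <- setdiff(seq_along(pos), biallelic)
  sites_out <- vector("list", sum(n_alt[slow]))
  geno_out <- vector("list", sum(n_alt[slow]))
  k <- 0L
  for (r in slow) {
    ad_parts <- strsplit(ad_raw[r, ], ",", fixed = TRUE)
    gt_r <- gt_raw[r, ]
    genotyped <- !is.na(gt_r) & gt_r != "." & gt_r != "./." & gt_r != ".|."
    no_ad <- genotyped & (is.na(ad_raw[r, ]) | ad_raw[r, ] == ".")
    if (any(no_ad))
      stop("missing AD for genotyped sample ", keep[which(no_ad)[1]],
           " at ", chrom[r], ":", pos[r])
    allele_mat <- t(vapply(gt_r, function(g) {
      if (is.na(g) || g %in% c(".", "./.", ".|.")) return(c(NA, NA))
      a <- strsplit(g, "[/|]")[[1]]
      a[a == "."] <- NA
      if (length(a) == 1) c(as.integer(a), NA_integer_)
      else as.integer(a[1:2])
    }, integer(2)))
    ploidy <- ifelse(grepl("[/|]", gt_r), 2L, 1L)
    for (a in seq_len(n_alt[r])) {
      k <- k + 1L
      this_alt <- alt_list[[r]][a]
      n_copies <- rowSums(allele_mat == a, na.rm = TRUE)
      gt_class <- rep("missing", length(gt_r))
      dip <- genotyped & ploidy == 2L
      hap <- genotyped & ploidy == 1L
      gt_class[dip & n_copies == 0] <- "hom_ref"
      gt_class[dip & n_copies == 1] <- "het"
      gt_class[dip & n_copies == 2] <- "hom_alt"
      gt_class[hap & n_copies == 0] <- "hemi_ref"
      gt_class[hap & n_copies == 1] <- "hemi_alt"
      ref_reads <- vapply(ad_parts, function(p) {
        if (length(p) == 0 || is.na(p[1])) NA_integer_ else as.integer(p[1])
      }, integer(1))
      alt_reads <- vapply(ad_parts, function(p) {
        if (length(p) < a + 1 || is.na(p[a + 1])) NA_integer_
        else as.integer(p[a + 1])
      }, integer(1))
      sid <- make_site_id(chrom[r], pos[r], ref[r], this_alt)
      sites_out[[k]] <- data.frame(
        site_id = sid, chrom = chrom[r], pos = pos[r], ref = ref[r],
        alt = this_alt, gene = gene[r], consequence = csq[r], maf = maf[r],
        stringsAsFactors = FALSE)
      geno_out[[k]] <- data.frame(
        site_id = sid, sample_id = keep, gt = gt_class,
        ref_reads = ifelse(gt_class == "missing", NA_integer_, ref_reads),
        alt_reads = ifelse(gt_class == "missing", NA_integer_, alt_reads),
        stringsAsFactors = FALSE)
    }
  }
  site_calls(rbind(sites_fast, do.call(rbind, sites_out)),
             rbind(geno_fast, do.call(rbind, geno_out)))
}

#' Write site calls to a VCF v4.2 file
#'
#' Emits a minimal valid VCF with INFO keys `GENE`, `CSQ`, `MAF` and FORMAT
#' `GT:AD`. Haploid genotypes (`hemi_*`) are written with single-allele GT.
#' Output is deterministically sorted by chromosome and position.
#'
#' @param calls a [site_calls()].
#' @param path output path.
#' @param samples sample column order; defaults to sorted unique samples.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, samples = NULL) {
  samples <- samples %||% sort(unique(calls$geno$sample_id))
  sites <- calls$sites
  gt <- geno_matrix(calls, samples, "gt")
  rr <- geno_matrix(calls, samples, "ref_reads")
  ar <- geno_matrix(calls, samples, "alt_reads")
  gt_str <- matrix("./.:.", nrow = nrow(gt), ncol = ncol(gt))
  code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
            hemi_ref = "0", hemi_alt = "1")
  for (g in names(code)) {
    i <- which(gt == g)
    gt_str[i] <- paste0(code[g], ":", rr[i], ",", ar[i])
  }
  info <- paste0("GENE=", ifelse(is.na(sites$gene), ".", sites$gene),
                 ";CSQ=", ifelse(is.na(sites$consequence), ".", sites$consequence),
                 ifelse(is.na(sites$maf), "",
                        paste0(";MAF=", sprintf("%.6g", sites$maf))))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Population minor allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                "PASS", info, "GT:AD", sep = "\t")
  body <- paste(body, apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Merge adjacent SNVs into dinucleotide variants
#'
#' Two single-nucleotide substitutions at consecutive positions with identical
#' per-sample genotype classes are emitted by some variant callers as two
#' records although they represent one dinucleotide (MNV) event. This merges
#' such pairs into a single call with concatenated ref/alt alleles; merged
#' per-sample depths are the elementwise minimum of the pair (conservative
#' support). Non-qualifying calls pass through unchanged. Runs of more than
#' two adjacent SNVs are merged greedily left to right into non-overlapping
#' pairs. The operation is idempotent (a merged call is no longer an SNV).
#'
#' @param calls a [site_calls()] sorted by chromosome and position (the
#'   constructor guarantees this; unsorted tables raise an error).
#' @return a [site_calls()] with qualifying pairs merged.
#' @export
merge_adjacent_snvs <- function(calls) {
  sites <- calls$sites
  if (is.unsorted(order(order_sites(sites))) ||
      !identical(order_sites(sites), seq_len(nrow(sites))))
    stop("calls must be sorted by chromosome and position")
  if (nrow(sites) < 2) return(calls)
  samples <- sort(unique(calls$geno$sample_id))
  gt <- geno_matrix(calls, samples, "gt")
  rr <- geno_matrix(calls, samples, "ref_reads")
  ar <- geno_matrix(calls, samples, "alt_reads")
  is_snv <- nchar(sites$ref) == 1 & nchar(sites$alt) == 1
  drop <- rep(FALSE, nrow(sites))
  merged_sites <- list()
  merged_geno <- list()
  i <- 1L
  while (i < nrow(sites)) {
    j <- i + 1L
    qualifies <- !drop[i] && is_snv[i] && is_snv[j] &&
      sites$chrom[i] == sites$chrom[j] && sites$pos[j] == sites$pos[i] + 1L &&
      identical(unname(gt[i, ]), unname(gt[j, ]))
    if (qualifies) {
      sid <- make_site_id(sites$chrom[i], sites$pos[i],
                          paste0(sites$ref[i], sites$ref[j]),
                          paste0(sites$alt[i], sites$alt[j]))
      merged_sites[[length(merged_sites) + 1L]] <- data.frame(
        site_id = sid, chrom = sites$chrom[i], pos = sites$pos[i],
        ref = paste0(sites$ref[i], sites$ref[j]),
        alt = paste0(sites$alt[i], sites$alt[j]),
        gene = sites$gene[i], consequence = sites$consequence[i],
        maf = min(sites$maf[i], sites$maf[j]), stringsAsFactors = FALSE)
      merged_geno[[length(merged_geno) + 1L]] <- data.frame(
        site_id = sid, sample_id = samples, gt = unname(gt[i, ]),
        ref_reads = pmin(rr[i, ], rr[j, ]),
        alt_reads = pmin(ar[i, ], ar[j, ]), stringsAsFactors = FALSE)
      drop[c(i, j)] <- TRUE
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(merged_sites)) return(calls)
  keep_ids <- sites$site_id[!drop]
  sites_keep <- sites[!drop, , drop = FALSE]
  geno_keep <- calls$geno[calls$geno$site_id %in% keep_ids, , drop = FALSE]
  site_calls(rbind(sites_keep, do.call(rbind, merged_sites)),
             rbind(geno_keep, do.call(rbind, merged_geno)))
}

#' Write candidate variants to a TSV
#'
#' Tab-separated, one row per candidate, stable column order and a
#' deterministic (chromosome, position, sample) sort, so identical inputs
#' produce identical bytes. An empty candidate table yields a header-only
#' file.
#'
#' @param candidates a candidate data frame as produced by [run_stepwise()]
#'   or [find_de_novo()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  cols <- c("family_id", "sample_id", "chrom", "pos", "ref", "alt", "gene",
            "consequence", "maf", "inheritance_class", "workflow_step",
            "evidence", "partner_site_id", "phase", "parental_origin",
            "proband_af")
  for (col in setdiff(cols, names(candidates)))
    candidates[[col]] <- rep(NA, nrow(candidates))
  candidates <- candidates[, cols, drop = FALSE]
  if (nrow(candidates))
    candidates <- candidates[order(chrom_rank(candidates$chrom),
                                   candidates$pos, candidates$sample_id), ,
                             drop = FALSE]
  con <- file(path, open = "wb") # fixed EOL across platforms
  on.exit(close(con))
  utils::write.table(candidates, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".", eol = "\n")
  invisible(path)
}
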