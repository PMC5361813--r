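#' Simulation configuration for a synthetic trio cohort
#'
#' Defines the cohort structure and noise model of the synthetic data
#' generator. Defaults mirror a research-reanalysis exome setting: mean
#' on-target depth of 40 reads, a per-base error fraction of 0.005, and a
#' population MAF annotation mixture dominated by common polymorphic sites
#' (point masses at 0.10 / 0.25 / 0.40) plus a uniform rare tail on
#' \[0, 0.05\].
#'
#' @param n_families number of families.
#' @param family_structures character vector (recycled to `n_families`) in
#'   `trio`, `quartet`, `multiplex3`, `singleton`.
#' @param n_background_sites number of background variant sites in the shared
#'   cohort site grid.
#' @param mean_depth mean total read depth per site and sample.
#' @param base_error_fraction probability in \[0, 0.05\] that a read reports
#'   the wrong allele.
#' @param planted_events list of [event_spec()] objects.
#' @param maf_distribution list with `points` (data.frame `value`, `weight`),
#'   `tail_weight` and `tail_max`; MAF annotations are drawn from this
#'   mixture and genotypes are sampled at the annotated frequency.
#' @param upd_chromosome optional chromosome name; if set and no `upd` event
#'   is listed, a paternal isodisomy of that chromosome is planted in the
#'   first family.
#' @param seed mandatory integer seed; identical configs reproduce
#'   byte-identical outputs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_families = 10,
                       family_structures = "trio",
                       n_background_sites = 20000,
                       mean_depth = 40,
                       base_error_fraction = 0.005,
                       planted_events = list(),
                       maf_distribution = default_maf_distribution(),
                       upd_chromosome = NULL,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_families >= 1, n_background_sites >= 0, mean_depth > 0,
            base_error_fraction >= 0, base_error_fraction <= 0.05)
  family_structures <- rep_len(family_structures, n_families)
  stopifnot(all(family_structures %in%
                  c("trio", "quartet", "multiplex3", "singleton")))
  cfg <- list(n_families = as.integer(n_families),
              family_structures = family_structures,
              n_background_sites = as.integer(n_background_sites),
              mean_depth = mean_depth,
              base_error_fraction = base_error_fraction,
              planted_events = planted_events,
              maf_distribution = maf_distribution,
              upd_chromosome = if (is.null(upd_chromosome)) NULL
                               else normalize_chrom(upd_chromosome),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_maf_distribution <- function() {
  list(points = data.frame(value = c(0.10, 0.25, 0.40),
                           weight = c(0.30, 0.30, 0.25)),
       tail_weight = 0.15, tail_max = 0.05)
}

#' Specify a planted event for the simulator
#'
#' @param event_type one of `de_novo`, `compound_het`, `ar_homozygous`,
#'   `xl_hemizygous`, `mosaic_parent`, `upd`, `exon_dropout`.
#' @param target_family 1-based family index or family id.
#' @param gene gene symbol; default chosen automatically.
#' @param consequence consequence class for the planted variant.
#' @param mosaic_fraction parental alternate-allele fraction
#'   (`mosaic_parent` only; required there, forbidden elsewhere).
#' @param upd_parent `father` or `mother` (`upd` only).
#' @param n_exons number of contiguous exons deleted (`exon_dropout` only).
#' @param proband_fraction optional proband alternate-allele fraction for
#'   `de_novo` events (default 0.5); values well below 0.5 emulate
#'   low-fraction, artifact-like calls that survive parental subtraction but
#'   fail the read-count criteria.
#' @return an `event_spec` list.
#' @export
event_spec <- function(event_type, target_family = 1, gene = NULL,
                       consequence = NULL, mosaic_fraction = NULL,
                       upd_parent = NULL, n_exons = 1,
                       proband_fraction = NULL) {
  types <- c("de_novo", "compound_het", "ar_homozygous", "xl_hemizygous",
             "mosaic_parent", "upd", "exon_dropout")
  if (!event_type %in% types)
    stop("unknown event_type: ", event_type)
  if (event_type == "mosaic_parent") {
    if (is.null(mosaic_fraction) || mosaic_fraction < 0 || mosaic_fraction > 1)
      stop("mosaic_parent events require mosaic_fraction in [0,1]")
  } else if (!is.null(mosaic_fraction)) {
    stop("mosaic_fraction is only valid for mosaic_parent events")
  }
  if (event_type == "upd") {
    upd_parent <- upd_parent %||% "father"
    stopifnot(upd_parent %in% c("father", "mother"))
  }
  stopifnot(n_exons >= 1)
  structure(list(event_type = event_type, target_family = target_family,
                 gene = gene, consequence = consequence,
                 mosaic_fraction = mosaic_fraction, upd_parent = upd_parent,
                 n_exons = as.integer(n_exons),
                 proband_fraction = proband_fraction),
            class = "event_spec")
}

#' Sample allelic read depths for one genotype
#'
#' Total depth is Poisson with mean `mean_depth`; alternate reads are binomial
#' on the total at the genotype's allele fraction, perturbed by the base error
#' fraction (`f_eff = f (1 - e) + (1 - f) e`). This is the simplest generative
#' model matching the read-ratio statistics the downstream criteria consume.
#'
#' @param genotype one of `hom_ref`, `het`, `hom_alt`, `hemi_alt`, `mosaic`
#'   (recycled against the longest argument).
#' @param allele_fraction expected alternate fraction; defaults per genotype
#'   (0, 0.5, 1, 1); mandatory for `mosaic`.
#' @param mean_depth mean total reads (> 0).
#' @param base_error_fraction per-read error probability.
#' @param n number of draws; defaults to the longest argument length.
#' @return data.frame with integer columns `ref_reads`, `alt_reads`.
#' @export
sample_read_depths <- function(genotype, allele_fraction = NULL,
                               mean_depth, base_error_fraction = 0, n = NULL) {
  stopifnot(mean_depth > 0)
  defaults <- c(hom_ref = 0, het = 0.5, hom_alt = 1, hemi_ref = 0,
                hemi_alt = 1, mosaic = NA_real_)
  if (!all(genotype %in% names(defaults)))
    stop("unknown genotype: ", paste(setdiff(genotype, names(defaults)), collapse = ","))
  n <- n %||% max(length(genotype), length(allele_fraction))
  genotype <- rep_len(genotype, n)
  af <- if (is.null(allele_fraction)) defaults[genotype]
        else rep_len(allele_fraction, n)
  af[is.na(af) & genotype != "mosaic"] <- defaults[genotype[is.na(af) & genotype != "mosaic"]]
  if (any(is.na(af))) stop("mosaic genotype requires an explicit allele_fraction")
  if (any(af < 0 | af > 1)) stop("allele_fraction must lie in [0, 1]")
  total <- stats::rpois(n, mean_depth)
  f_eff <- af * (1 - base_error_fraction) + (1 - af) * base_error_fraction
  alt <- stats::rbinom(n, total, f_eff)
  data.frame(ref_reads = as.integer(total - alt), alt_reads = as.integer(alt))
}

#' @noRd
draw_maf <- function(n, dist) {
  w <- c(dist$points$weight, dist$tail_weight)
  w <- w / sum(w)
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  maf <- dist$points$value[comp]
  tail_idx <- comp == length(w)
  maf[tail_idx] <- stats::runif(sum(tail_idx), 0, dist$tail_max)
  maf
}

# deterministic family / sample naming
#' @noRd
family_samples <- function(structure, fam_id) {
  children <- switch(structure,
                     trio = "P1", quartet = c("P1", "S1"),
                     multiplex3 = c("P1", "P2", "P3"), singleton = "P1")
  parents <- if (structure == "singleton") character() else c("FA", "MO")
  paste(fam_id, c(parents, children), sep = "_")
}

#' Simulate a synthetic trio/quartet exome cohort
#'
#' Generates a multi-family cohort on a shared site grid: per-site population
#' MAF annotations drawn from the configured mixture, Hardy-Weinberg parental
#' genotypes at the annotated frequency, Mendelian transmission to children
#' (hemizygous chrX in males), Poisson/binomial allelic depths with base
#' error, a per-exon read-count table, and all requested planted events
#' (recorded in a truth table). Planted variant sites are given clean read
#' support (no base-error perturbation, zero alternate reads in non-carriers)
#' so that a planted event is a validated true positive; background sites
#' carry the full error model.
#'
#' @param config a [sim_config()].
#' @return an object of class `synthetic_cohort`: list with `pedigree`,
#'   `calls` ([site_calls()]), `exon_coverage` (data.frame `sample_id`,
#'   `gene`, `chrom`, `exon_index`, `exon_length`, `read_count`), `truth`
#'   (data.frame of planted events) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

#' @noRd
simulate_cohort_impl <- function(config) {
  chroms <- c(as.character(1:22), "X")
  n_bg <- config$n_background_sites
  # ~4% of sites on chrX, remainder split evenly over the autosomes
  n_x <- ceiling(0.04 * n_bg)
  n_auto <- n_bg - n_x
  per_auto <- rep(n_auto %/% 22, 22)
  extra <- n_auto %% 22
  if (extra > 0) per_auto[seq_len(extra)] <- per_auto[seq_len(extra)] + 1L
  site_chrom <- rep(chroms, times = c(per_auto, n_x))
  site_pos <- unlist(lapply(c(per_auto, n_x), function(k) seq_len(k) * 1000L),
                     use.names = FALSE)
  # gene blocks of 10 consecutive sites per chromosome
  gene_of <- unlist(lapply(seq_along(chroms), function(ci) {
    k <- c(per_auto, n_x)[ci]
    if (k == 0) return(character())
    sprintf("G%s_%04d", chroms[ci], (seq_len(k) - 1L) %/% 10L + 1L)
  }), use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_bg, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  maf <- draw_maf(n_bg, config$maf_distribution)
  csq <- sample(CONSEQUENCE_LEVELS, n_bg, replace = TRUE,
                prob = c(0.04, 0.03, 0.03, 0.38, 0.40, 0.12))
  sites <- data.frame(
    site_id = make_site_id(site_chrom, site_pos, ref, alt),
    chrom = site_chrom, pos = site_pos, ref = ref, alt = alt,
    gene = gene_of, consequence = csq, maf = maf, stringsAsFactors = FALSE)

  # pedigree -----------------------------------------------------------------
  fam_ids <- sprintf("FAM%02d", seq_len(config$n_families))
  # a family targeted by an xl_hemizygous event needs a male proband
  xl_fams <- vapply(config$planted_events, function(e)
    if (e$event_type == "xl_hemizygous") resolve_family(e$target_family, fam_ids)
    else NA_character_, "")
  ped_rows <- list()
  for (fi in seq_along(fam_ids)) {
    fam <- fam_ids[fi]
    struct <- config$family_structures[fi]
    samp <- family_samples(struct, fam)
    has_parents <- struct != "singleton"
    children <- samp[grepl("_(P|S)", samp)]
    child_sex <- ifelse(stats::rbinom(length(children), 1, 0.5) == 1,
                        "male", "female")
    if (fam %in% xl_fams) child_sex[1] <- "male"
    rows <- data.frame(
      sample_id = samp,
      family_id = fam,
      father_id = c(rep(NA_character_, sum(!samp %in% children)),
                    rep(if (has_parents) samp[1] else NA_character_,
                        length(children))),
      mother_id = c(rep(NA_character_, sum(!samp %in% children)),
                    rep(if (has_parents) samp[2] else NA_character_,
                        length(children))),
      sex = c(if (has_parents) c("male", "female") else character(), child_sex),
      affected = c(if (has_parents) rep("unaffected", 2) else character(),
                   ifelse(grepl("_S", children), "unaffected", "affected")),
      stringsAsFactors = FALSE)
    ped_rows[[fi]] <- rows
  }
  ped <- validate_pedigree(do.call(rbind, ped_rows))

  # background genotypes ------------------------------------------------------
  geno_list <- list()
  on_x <- sites$chrom == "X"
  p <- sites$maf
  for (fi in seq_along(fam_ids)) {
    fam <- fam_ids[fi]
    fam_ped <- ped[ped$family_id == fam, , drop = FALSE]
    has_parents <- config$family_structures[fi] != "singleton"
    if (has_parents) {
      fa <- fam_ped$sample_id[1]; mo <- fam_ped$sample_id[2]
      # maternal allele dosage (0/1 per homolog)
      mo_a1 <- stats::rbinom(n_bg, 1, p); mo_a2 <- stats::rbinom(n_bg, 1, p)
      fa_a1 <- stats::rbinom(n_bg, 1, p); fa_a2 <- stats::rbinom(n_bg, 1, p)
      fa_gt <- dosage_to_gt(fa_a1 + fa_a2)
      fa_gt[on_x] <- c("hemi_ref", "hemi_alt")[fa_a1[on_x] + 1L]
      mo_gt <- dosage_to_gt(mo_a1 + mo_a2)
      geno_list[[length(geno_list) + 1L]] <-
        background_geno(sites$site_id, fa, fa_gt, config)
      geno_list[[length(geno_list) + 1L]] <-
        background_geno(sites$site_id, mo, mo_gt, config)
      children <- fam_ped$sample_id[-(1:2)]
      for (ch in children) {
        male <- fam_ped$sex[match(ch, fam_ped$sample_id)] == "male"
        pick_m <- stats::rbinom(n_bg, 1, 0.5)
        m_allele <- ifelse(pick_m == 1, mo_a1, mo_a2)
        pick_f <- stats::rbinom(n_bg, 1, 0.5)
        f_allele <- ifelse(pick_f == 1, fa_a1, fa_a2)
        ch_gt <- dosage_to_gt(m_allele + f_allele)
        if (male) {
          ch_gt[on_x] <- c("hemi_ref", "hemi_alt")[m_allele[on_x] + 1L]
        } else {
          ch_gt[on_x] <- dosage_to_gt(m_allele[on_x] + fa_a1[on_x])
        }
        geno_list[[length(geno_list) + 1L]] <-
          background_geno(sites$site_id, ch, ch_gt, config)
      }
    } else {
      pr <- fam_ped$sample_id[1]
      male <- fam_ped$sex[1] == "male"
      a1 <- stats::rbinom(n_bg, 1, p); a2 <- stats::rbinom(n_bg, 1, p)
      gt <- dosage_to_gt(a1 + a2)
      if (male) gt[on_x] <- c("hemi_ref", "hemi_alt")[a1[on_x] + 1L]
      geno_list[[length(geno_list) + 1L]] <-
        background_geno(sites$site_id, pr, gt, config)
    }
  }
  geno <- do.call(rbind, geno_list)

  # exon coverage table --------------------------------------------------------
  n_cov_genes <- 40L
  cov_genes <- sprintf("CGENE%03d", seq_len(n_cov_genes))
  cov_chrom <- c(rep(as.character(rep(1:18, length.out = 36)), 1), rep("X", 4))
  n_exons_per_gene <- 10L
  exon_length <- matrix(sample(60:300, n_cov_genes * n_exons_per_gene,
                               replace = TRUE),
                        nrow = n_cov_genes)
  cov_rows <- list()
  for (s in ped$sample_id) {
    lam <- config$mean_depth * as.vector(t(exon_length)) / 150
    cov_rows[[s]] <- data.frame(
      sample_id = s,
      gene = rep(cov_genes, each = n_exons_per_gene),
      chrom = rep(cov_chrom, each = n_exons_per_gene),
      exon_index = rep(seq_len(n_exons_per_gene), n_cov_genes),
      exon_length = as.vector(t(exon_length)),
      read_count = stats::rpois(n_cov_genes * n_exons_per_gene, lam),
      stringsAsFactors = FALSE)
  }
  coverage <- do.call(rbind, cov_rows)
  rownames(coverage) <- NULL

  # planted events -------------------------------------------------------------
  events <- config$planted_events
  if (!is.null(config$upd_chromosome) &&
      !any(vapply(events, function(e) e$event_type == "upd", TRUE))) {
    events <- c(events, list(event_spec("upd", target_family = 1,
                                        upd_parent = "father")))
  }
  state <- list(sites = sites, geno = geno, coverage = coverage,
                truth = list(), extra_pos = integer())
  for (ei in seq_along(events)) {
    state <- plant_event(state, events[[ei]], ei, ped, config, fam_ids)
  }

  calls <- site_calls(state$sites, state$geno)
  truth <- if (length(state$truth)) {
    do.call(rbind, state$truth)
  } else {
    data.frame(event_type = character(), family_id = character(),
               chrom = character(), pos = integer(), pos2 = integer(),
               gene = character(), carriers = character(),
               mosaic_fraction = numeric(), upd_parent = character(),
               exon_start = integer(), exon_end = integer(),
               stringsAsFactors = FALSE)
  }
  rownames(truth) <- NULL
  structure(list(pedigree = ped, calls = calls,
                 exon_coverage = state$coverage, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", x$config$n_families, " families, ",
      nrow(x$calls$sites), " sites, ", nrow(x$truth), " planted events\n",
      sep = "")
  invisible(x)
}

#' @noRd
dosage_to_gt <- function(d) c("hom_ref", "het", "hom_alt")[d + 1L]

#' @noRd
background_geno <- function(site_ids, sample_id, gt, config) {
  d <- sample_read_depths(gt, mean_depth = config$mean_depth,
                          base_error_fraction = config$base_error_fraction)
  data.frame(site_id = site_ids, sample_id = rep(sample_id, length(site_ids)),
             gt = gt, ref_reads = d$ref_reads, alt_reads = d$alt_reads,
             stringsAsFactors = FALSE)
}

#' @noRd
resolve_family <- function(target, fam_ids) {
  if (is.numeric(target)) {
    if (target < 1 || target > length(fam_ids))
      stop("target_family index out of range: ", target)
    return(fam_ids[target])
  }
  if (!target %in% fam_ids) stop("unknown target_family: ", target)
  target
}

# clean depths for a planted site: no error, exact genotype fractions
#' @noRd
clean_depths <- function(gt, mean_depth, allele_fraction = NULL) {
  sample_read_depths(ifelse(gt %in% c("het", "hom_ref", "hom_alt",
                                      "hemi_ref", "hemi_alt"), gt, "mosaic"),
                     allele_fraction = allele_fraction,
                     mean_depth = mean_depth, base_error_fraction = 0)
}

# add one fresh biallelic site with specified per-sample genotypes (all other
# samples hom_ref / hemi_ref with clean depths)
#' @noRd
add_planted_site <- function(state, ped, config, chrom, gene, consequence,
                             maf, carrier_gt, carrier_af = NULL) {
  chrom_sites <- state$sites$pos[state$sites$chrom == chrom]
  base <- if (length(chrom_sites)) max(chrom_sites) else 0L
  n_extra <- sum(state$extra_pos == chrom_rank(chrom))
  pos <- as.integer(base + 137L * (n_extra + 1L))
  state$extra_pos <- c(state$extra_pos, chrom_rank(chrom))
  ref <- "C"; alt <- "T"
  sid <- make_site_id(chrom, pos, ref, alt)
  state$sites <- rbind(state$sites, data.frame(
    site_id = sid, chrom = chrom, pos = pos, ref = ref, alt = alt,
    gene = gene, consequence = consequence, maf = maf,
    stringsAsFactors = FALSE))
  on_x <- chrom == "X"
  gt <- rep("hom_ref", nrow(ped))
  names(gt) <- ped$sample_id
  if (on_x) gt[ped$sex == "male"] <- "hemi_ref"
  gt[names(carrier_gt)] <- carrier_gt
  af <- rep(NA_real_, nrow(ped)); names(af) <- ped$sample_id
  if (!is.null(carrier_af)) af[names(carrier_af)] <- carrier_af
  d <- clean_depths(unname(gt), config$mean_depth,
                    allele_fraction = ifelse(is.na(af), c(
                      hom_ref = 0, het = 0.5, hom_alt = 1,
                      hemi_ref = 0, hemi_alt = 1)[unname(gt)], unname(af)))
  state$geno <- rbind(state$geno, data.frame(
    site_id = sid, sample_id = ped$sample_id, gt = unname(gt),
    ref_reads = d$ref_reads, alt_reads = d$alt_reads,
    stringsAsFactors = FALSE))
  state$last_site <- list(site_id = sid, chrom = chrom, pos = pos)
  state
}

#' @noRd
plant_event <- function(state, ev, ev_index, ped, config, fam_ids) {
  fam <- resolve_family(ev$target_family, fam_ids)
  fam_ped <- ped[ped$family_id == fam, , drop = FALSE]
  children <- fam_ped$sample_id[fam_ped$affected == "affected" &
                                  !is.na(fam_ped$father_id)]
  singleton <- all(is.na(fam_ped$father_id))
  proband <- if (singleton) fam_ped$sample_id[1] else children[1]
  fa <- fam_ped$father_id[match(proband, fam_ped$sample_id)]
  mo <- fam_ped$mother_id[match(proband, fam_ped$sample_id)]
  truth_row <- function(chrom, pos, gene, carriers, pos2 = NA_integer_,
                        mosaic_fraction = NA_real_,
                        upd_parent = NA_character_,
                        exon_start = NA_integer_, exon_end = NA_integer_) {
    data.frame(event_type = ev$event_type, family_id = fam, chrom = chrom,
               pos = pos, pos2 = pos2, gene = gene,
               carriers = paste(carriers, collapse = ","),
               mosaic_fraction = mosaic_fraction, upd_parent = upd_parent,
               exon_start = exon_start, exon_end = exon_end,
               stringsAsFactors = FALSE)
  }

  if (ev$event_type == "de_novo") {
    if (singleton) stop("de_novo events need a trio family")
    gene <- ev$gene %||% sprintf("DNGENE%02d", ev_index)
    pf <- ev$proband_fraction %||% 0.5
    state <- add_planted_site(state, ped, config, chrom = "7", gene = gene,
                              consequence = ev$consequence %||% "missense",
                              maf = NA_real_,
                              carrier_gt = setNames("het", proband),
                              carrier_af = setNames(pf, proband))
    s <- state$last_site
    state$truth[[length(state$truth) + 1L]] <-
      truth_row(s$chrom, s$pos, gene, proband)
  } else if (ev$event_type == "ar_homozygous") {
    if (singleton) stop("ar_homozygous events need a trio family")
    gene <- ev$gene %||% sprintf("ARGENE%02d", ev_index)
    state <- add_planted_site(state, ped, config, chrom = "5", gene = gene,
                              consequence = ev$consequence %||% "stop_gain",
                              maf = 0.001,
                              carrier_gt = setNames(c("hom_alt", "het", "het"),
                                                    c(proband, fa, mo)))
    s <- state$last_site
    state$truth[[length(state$truth) + 1L]] <-
      truth_row(s$chrom, s$pos, gene, c(proband, fa, mo))
  } else if (ev$event_type == "compound_het") {
    if (singleton) stop("compound_het events need a trio family")
    gene <- ev$gene %||% sprintf("CHGENE%02d", ev_index)
    state <- add_planted_site(state, ped, config, chrom = "3", gene = gene,
                              consequence = "stop_gain", maf = 0.001,
                              carrier_gt = setNames(c("het", "het"),
                                                    c(proband, fa)))
    s1 <- state$last_site
    state <- add_planted_site(state, ped, config, chrom = "3", gene = gene,
                              consequence = ev$consequence %||% "missense",
                              maf = 0.002,
                              carrier_gt = setNames(c("het", "het"),
                                                    c(proband, mo)))
    s2 <- state$last_site
    state$truth[[length(state$truth) + 1L]] <-
      truth_row(s1$chrom, s1$pos, gene, c(proband, fa, mo), pos2 = s2$pos)
  } else if (ev$event_type == "xl_hemizygous") {
    if (singleton) stop("xl_hemizygous events need a trio family")
    gene <- ev$gene %||% sprintf("XLGENE%02d", ev_index)
    state <- add_planted_site(state, ped, config, chrom = "X", gene = gene,
                              consequence = ev$consequence %||% "missense",
                              maf = 0.001,
                              carrier_gt = setNames(c("hemi_alt", "het"),
                                                    c(proband, mo)))
    s <- state$last_site
    state$truth[[length(state$truth) + 1L]] <-
      truth_row(s$chrom, s$pos, gene, c(proband, mo))
  } else if (ev$event_type == "mosaic_parent") {
    if (singleton) stop("mosaic_parent events need parental samples")
    gene <- ev$gene %||% sprintf("MOGENE%02d", ev_index)
    carriers <- c(children, fa)
    gt <- setNames(c(rep("het", length(children)), "het"), carriers)
    af <- setNames(c(rep(0.5, length(children)), ev$mosaic_fraction), carriers)
    state <- add_planted_site(state, ped, config, chrom = "1", gene = gene,
                              consequence = ev$consequence %||% "missense",
                              maf = NA_real_, carrier_gt = gt, carrier_af = af)
    s <- state$last_site
    state$truth[[length(state$truth) + 1L]] <-
      truth_row(s$chrom, s$pos, gene, carriers,
                mosaic_fraction = ev$mosaic_fraction)
  } else if (ev$event_type == "upd") {
    if (singleton) stop("upd events need a trio family")
    chrom <- config$upd_chromosome %||%
      stop("upd event requires upd_chromosome in sim_config")
    idx <- which(state$sites$chrom == chrom)
    if (!length(idx)) stop("upd_chromosome absent from site grid: ", chrom)
    donor <- if (ev$upd_parent == "father") fa else mo
    sid <- state$sites$site_id[idx]
    donor_gt <- state$geno$gt[state$geno$sample_id == donor &
                                state$geno$site_id %in% sid]
    names(donor_gt) <- state$geno$site_id[state$geno$sample_id == donor &
                                            state$geno$site_id %in% sid]
    donor_gt <- donor_gt[sid]
    transmitted <- ifelse(donor_gt == "hom_alt", 1L,
                          ifelse(donor_gt == "hom_ref", 0L,
                                 stats::rbinom(length(donor_gt), 1, 0.5)))
    new_gt <- c("hom_ref", "hom_alt")[transmitted + 1L]
    pr_rows <- which(state$geno$sample_id == proband &
                       state$geno$site_id %in% sid)
    pr_rows <- pr_rows[match(sid, state$geno$site_id[pr_rows])]
    state$geno$gt[pr_rows] <- new_gt
    d <- sample_read_depths(new_gt, mean_depth = config$mean_depth,
                            base_error_fraction = config$base_error_fraction)
    state$geno$ref_reads[pr_rows] <- d$ref_reads
    state$geno$alt_reads[pr_rows] <- d$alt_reads
    # guarantee >=1 site homozygous-alt in the child with the other parent
    # homozygous reference (the Mendelian-inconsistency signature)
    other <- if (ev$upd_parent == "father") mo else fa
    other_gt <- state$geno$gt[state$geno$sample_id == other &
                                state$geno$site_id %in% sid]
    names(other_gt) <- state$geno$site_id[state$geno$sample_id == other &
                                            state$geno$site_id %in% sid]
    other_gt <- other_gt[sid]
    ok <- any(new_gt == "hom_alt" & other_gt == "hom_ref")
    if (!ok) {
      force_i <- which(gt_has_alt(donor_gt))[1]
      if (is.na(force_i)) force_i <- 1L
      # make the donor het, the other parent hom_ref, the child hom_alt
      fix_gt <- function(smp, g) {
        row <- which(state$geno$sample_id == smp &
                       state$geno$site_id == sid[force_i])
        state$geno$gt[row] <<- g
        dd <- clean_depths(g, config$mean_depth)
        state$geno$ref_reads[row] <<- dd$ref_reads
        state$geno$alt_reads[row] <<- dd$alt_reads
      }
      fix_gt(donor, "het"); fix_gt(other, "hom_ref"); fix_gt(proband, "hom_alt")
    }
    state$truth[[length(state$truth) + 1L]] <-
      truth_row(chrom, min(state$sites$pos[idx]), NA_character_, proband,
                pos2 = max(state$sites$pos[idx]), upd_parent = ev$upd_parent)
  } else if (ev$event_type == "exon_dropout") {
    gene <- ev$gene %||% "CGENE005"
    cov <- state$coverage
    gene_exons <- sort(unique(cov$exon_index[cov$gene == gene]))
    if (!length(gene_exons)) stop("exon_dropout gene absent from coverage: ", gene)
    if (ev$n_exons > length(gene_exons) - 2L)
      stop("exon_dropout span too long for gene ", gene)
    start <- 3L
    span <- start:(start + ev$n_exons - 1L)
    rows <- cov$sample_id == proband & cov$gene == gene &
      cov$exon_index %in% span
    state$coverage$read_count[rows] <- 0L
    chrom <- cov$chrom[match(gene, cov$gene)]
    state$truth[[length(state$truth) + 1L]] <-
      truth_row(chrom, NA_integer_, gene, proband,
                exon_start = start, exon_end = start + ev$n_exons - 1L)
  }
  state
}

#' Write a synthetic cohort to disk
#'
#' Emits `cohort.vcf` (VCF v4.2, GT:AD), `cohort.ped`, `exon_coverage.tsv`
#' and `truth.tsv` under `dir`. Deterministic: identical cohorts produce
#' byte-identical files.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(cohort$calls, file.path(dir, "cohort.vcf"),
            samples = cohort$pedigree$sample_id)
  write_pedigree(cohort$pedigree, file.path(dir, "cohort.ped"))
  write_tsv_lf(cohort$exon_coverage, file.path(dir, "exon_coverage.tsv"))
  write_tsv_lf(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' @noRd
write_tsv_lf <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".", eol = "\n")
}

#' Read a simulator configuration from a YAML file
#'
#' Keys mirror the [sim_config()] arguments; `planted_events` is a list of
#' maps with an `event_type` key and the remaining [event_spec()] fields.
#'
#' @param path YAML file.
#' @param seed overrides any seed in the file when non-NULL.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  events <- lapply(y$planted_events %||% list(), function(e)
    do.call(event_spec, e))
  sim_config(n_families = y$n_families %||% 10,
             family_structures = y$family_structures %||% "trio",
             n_background_sites = y$n_background_sites %||% 20000,
             mean_depth = y$mean_depth %||% 40,
             base_error_fraction = y$base_error_fraction %||% 0.005,
             planted_events = events,
             upd_chromosome = y$upd_chromosome,
             seed = seed %||% y$seed %||% stop("seed required"))
}
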