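ped <- trio_ped() # F1_FA, F1_MO, F1_P1 (male proband)

test_that("frequency filter is strict and keeps unannotated variants", {
  calls <- make_calls(list(
    list(chrom = 1, pos = 100, maf = 0.004, gt = c(F1_P1 = "het")),
    list(chrom = 1, pos = 200, maf = 0.005, gt = c(F1_P1 = "het")),
    list(chrom = 1, pos = 300, gt = c(F1_P1 = "het"))),
    ped$sample_id)
  kept <- filter_by_frequency(calls, 0.005)$sites$pos
  expect_setequal(kept, c(100, 300))
  # monotone in maf_max
  expect_true(all(filter_by_frequency(calls, 0.001)$sites$site_id %in%
                    filter_by_frequency(calls, 0.01)$sites$site_id))
})

test_that("AR-homozygous step classifies biparental and inconsistent homozygotes", {
  calls <- make_calls(list(
    list(chrom = 5, pos = 100, csq = "stop_gain", maf = 0.001,
         gt = c(F1_P1 = "hom_alt", F1_FA = "het", F1_MO = "het")),
    list(chrom = 5, pos = 200, csq = "missense", maf = 0.001,
         gt = c(F1_P1 = "hom_alt", F1_FA = "het", F1_MO = "hom_ref")),
    list(chrom = 5, pos = 300, csq = "synonymous", maf = 0.001,
         gt = c(F1_P1 = "hom_alt", F1_FA = "het", F1_MO = "het"))),
    ped$sample_id)
  cand <- find_ar_homozygous(calls, ped, "F1")
  expect_equal(cand$inheritance_class[cand$pos == 100], "ar_homozygous")
  # only one carrier parent: Mendelian-inconsistent, never silently dropped
  expect_equal(cand$inheritance_class[cand$pos == 200],
               "mendelian_inconsistent")
  expect_false(300 %in% cand$pos) # synonymous excluded by type
  expect_true(all(cand$workflow_step == 1))
})

test_that("compound-het pairs require trans transmission in trio mode", {
  calls <- make_calls(list(
    list(chrom = 3, pos = 100, gene = "GENE_A", csq = "stop_gain", maf = 0.001,
         gt = c(F1_P1 = "het", F1_FA = "het")),
    list(chrom = 3, pos = 200, gene = "GENE_A", csq = "missense", maf = 0.002,
         gt = c(F1_P1 = "het", F1_MO = "het")),
    list(chrom = 3, pos = 300, gene = "GENE_B", csq = "missense", maf = 0.001,
         gt = c(F1_P1 = "het", F1_FA = "het")),
    list(chrom = 3, pos = 400, gene = "GENE_B", csq = "missense", maf = 0.001,
         gt = c(F1_P1 = "het", F1_FA = "het"))),
    ped$sample_id)
  cand <- find_compound_het(calls, ped, "F1")
  # GENE_A: paternal stop-gain + maternal missense -> trans pair (2 rows)
  a <- cand[cand$gene == "GENE_A", ]
  expect_equal(nrow(a), 2)
  expect_equal(unique(a$phase), "trans")
  expect_setequal(a$parental_origin, c("father_only", "mother_only"))
  expect_equal(a$partner_site_id, rev(a$site_id))
  # GENE_B: both variants from the father -> cis, excluded
  expect_equal(nrow(cand[cand$gene == "GENE_B", ]), 0)
})

test_that("undecidable and proband-only pairs are flagged phase_unknown", {
  calls <- make_calls(list(
    list(chrom = 3, pos = 100, gene = "GENE_C", csq = "stop_gain", maf = 0.001,
         gt = c(F1_P1 = "het", F1_FA = "het", F1_MO = "het")),
    list(chrom = 3, pos = 200, gene = "GENE_C", csq = "missense", maf = 0.002,
         gt = c(F1_P1 = "het", F1_MO = "het"))),
    ped$sample_id)
  cand <- find_compound_het(calls, ped, "F1")
  expect_equal(unique(cand$phase), "phase_unknown")
  solo_ped <- pedigree("S1", "F9", sex = "male", affected = "affected")
  solo <- make_calls(list(
    list(chrom = 3, pos = 100, gene = "GENE_D", csq = "stop_gain", maf = 0.001,
         gt = c(S1 = "het")),
    list(chrom = 3, pos = 200, gene = "GENE_D", csq = "frameshift_indel",
         gt = c(S1 = "het"))), "S1")
  cand2 <- find_compound_het(solo, solo_ped, "F9",
                             workflow_config(proband_only_mode = TRUE))
  expect_equal(nrow(cand2), 2)
  expect_equal(unique(cand2$phase), "phase_unknown")
})

test_that("het-LOF step is LOF-only and frequency-filtered", {
  calls <- make_calls(list(
    list(chrom = 2, pos = 100, csq = "frameshift_indel",
         gt = c(F1_P1 = "het")),
    list(chrom = 2, pos = 200, csq = "missense", maf = 0.001,
         gt = c(F1_P1 = "het")),
    list(chrom = 2, pos = 300, csq = "splice_site", maf = 0.01,
         gt = c(F1_P1 = "het"))),
    ped$sample_id)
  cand <- find_het_lof(calls, ped, "F1")
  expect_equal(cand$pos, 100)
  expect_equal(cand$inheritance_class, "het_lof")
  expect_equal(cand$workflow_step, 3)
})

test_that("X-linked hemizygous logic distinguishes maternal carriers from de novo", {
  calls <- make_calls(list(
    list(chrom = "X", pos = 100, csq = "missense", maf = 0.001,
         gt = c(F1_P1 = "hemi_alt", F1_MO = "het", F1_FA = "hemi_ref")),
    list(chrom = "X", pos = 200, csq = "missense", maf = 0.001,
         gt = c(F1_P1 = "hemi_alt", F1_FA = "hemi_ref"),
         ad = list(F1_P1 = c(0, 30), F1_FA = c(25, 0), F1_MO = c(28, 0)))),
    ped$sample_id)
  cand <- find_hemizygous(calls, ped, "F1")
  expect_equal(cand$inheritance_class[cand$pos == 100], "xl_hemizygous")
  # mother without the allele: routed through the de novo read criteria
  expect_equal(cand$inheritance_class[cand$pos == 200], "de_novo")
  # female proband: chrX het handled by autosomal rules, not here
  ped_f <- trio_ped("F2", proband_sex = "female")
  calls_f <- make_calls(list(
    list(chrom = "X", pos = 100, csq = "missense", maf = 0.001,
         gt = c(F2_P1 = "het", F2_MO = "het"))), ped_f$sample_id)
  expect_equal(nrow(find_hemizygous(calls_f, ped_f, "F2")), 0)
  # unknown sex: chrX skipped with a warning
  ped_u <- trio_ped("F3", proband_sex = "unknown")
  calls_u <- make_calls(list(
    list(chrom = "X", pos = 100, csq = "missense", maf = 0.001,
         gt = c(F3_P1 = "hemi_alt", F3_MO = "het"))), ped_u$sample_id)
  expect_warning(out <- find_hemizygous(calls_u, ped_u, "F3"), "unknown sex")
  expect_equal(nrow(out), 0)
})

test_that("all workflow steps run even after earlier hits (dual diagnosis)", {
  calls <- make_calls(list(
    # trans compound het in GENE_A
    list(chrom = 3, pos = 100, gene = "GENE_A", csq = "stop_gain", maf = 0.001,
         gt = c(F1_P1 = "het", F1_FA = "het")),
    list(chrom = 3, pos = 200, gene = "GENE_A", csq = "missense", maf = 0.001,
         gt = c(F1_P1 = "het", F1_MO = "het")),
    # clean de novo in GENE_B
    list(chrom = 7, pos = 500, gene = "GENE_B", csq = "missense",
         gt = c(F1_P1 = "het"),
         ad = list(F1_P1 = c(14, 16), F1_FA = c(40, 0), F1_MO = c(38, 1)))),
    ped$sample_id)
  cand <- run_stepwise(calls, ped, "F1")
  expect_setequal(unique(cand$inheritance_class),
                  c("compound_het", "het_lof", "de_novo"))
  expect_equal(sum(cand$inheritance_class == "de_novo"), 1)
  expect_equal(sum(cand$inheritance_class == "compound_het"), 2)
  # steps are recorded and ordered
  expect_true(!is.unsorted(cand$workflow_step))
  # no candidate at or above the frequency cutoff
  expect_true(all(is.na(cand$maf) | cand$maf < 0.005))
})

test_that("stepwise output is invariant to input row order", {
  cfg <- sim_config(n_families = 1, n_background_sites = 1000, seed = 5,
                    planted_events = list(event_spec("de_novo", 1),
                                          event_spec("compound_het", 1)))
  co <- simulate_cohort(cfg)
  out1 <- run_stepwise(co$calls, co$pedigree, "FAM01")
  set.seed(1)
  perm <- sample(nrow(co$calls$sites))
  shuffled <- site_calls(co$calls$sites[perm, ],
                         co$calls$geno[sample(nrow(co$calls$geno)), ])
  out2 <- run_stepwise(shuffled, co$pedigree, "FAM01")
  rownames(out1) <- rownames(out2) <- NULL
  expect_identical(out1, out2)
})

test_that("step classes are disjoint per (site, sample, class)", {
  cfg <- sim_config(n_families = 2, n_background_sites = 3000, seed = 23,
                    planted_events = all_event_specs()[1:4])
  co <- simulate_cohort(cfg)
  for (fam in unique(co$pedigree$family_id)) {
    cand <- run_stepwise(co$calls, co$pedigree, fam)
    key <- paste(cand$site_id, cand$sample_id, cand$inheritance_class)
    expect_false(any(duplicated(key)))
  }
})
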