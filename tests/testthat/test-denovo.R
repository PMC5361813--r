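test_that("read-count criteria honor their strict thresholds", {
  # all four criteria met
  d <- dnm_criteria(6, 12, 0, 25, 1, 30)
  expect_true(d$pass)
  expect_equal(d$failed_criteria, "")
  # alt = 5 fails criterion 1 ("greater than 5" is strict)
  d <- dnm_criteria(5, 12, 0, 25, 1, 30)
  expect_false(d$pass)
  expect_equal(d$failed_criteria, "1")
  # parent ref = 10 fails criterion 3 ("greater than 10" is strict)
  d <- dnm_criteria(6, 12, 0, 10, 1, 30)
  expect_false(d$pass)
  expect_equal(d$failed_criteria, "3")
  # parent at exactly 5% alt/ref fails criterion 4 (strict <)
  d <- dnm_criteria(6, 12, 1, 20, 0, 30)
  expect_false(d$pass)
  expect_equal(d$failed_criteria, "4")
  # proband with zero ref reads: ratio +Inf, criterion 2 passes
  d <- dnm_criteria(10, 0, 0, 25, 0, 30)
  expect_true(d$pass)
  # parent with zero ref reads: criterion 3 fails, criterion 4 indeterminate
  d <- dnm_criteria(10, 10, 0, 0, 0, 30)
  expect_false(d$pass)
  expect_true(is.na(d$c4))
  expect_match(d$failed_criteria, "3")
})

test_that("criteria decision matches a direct rule evaluation on random depths", {
  set.seed(21)
  n <- 20000
  pa <- sample(0:60, n, TRUE); pr <- sample(0:60, n, TRUE)
  fa <- sample(0:8, n, TRUE); fr <- sample(0:60, n, TRUE)
  ma <- sample(0:8, n, TRUE); mr <- sample(0:60, n, TRUE)
  got <- dnm_criteria(pa, pr, fa, fr, ma, mr, detail = FALSE)$pass
  # integer-arithmetic oracle, written independently of the implementation:
  # alt/ref > 0.30 <=> 10*alt > 3*ref; alt/ref < 0.05 <=> 20*alt < ref
  want <- (pa > 5L) & (pr == 0L | 10L * pa > 3L * pr) &
    (fr > 10L) & (mr > 10L) & (20L * fa < fr) & (20L * ma < mr)
  expect_identical(unname(got), unname(want))
})

test_that("parental subtraction equals a per-site set-difference oracle", {
  set.seed(3)
  samples <- c("F1_P1", "F1_FA", "F1_MO")
  gts <- c("hom_ref", "het", "hom_alt")
  site_list <- lapply(1:300, function(i) {
    list(chrom = 1, pos = i * 10,
         gt = setNames(sample(gts, 3, TRUE), samples))
  })
  calls <- make_calls(site_list, samples)
  sub <- subtract_parental(calls, "F1_P1", "F1_FA", "F1_MO")
  # brute-force oracle: walk every site and compare genotype strings
  want <- vapply(seq_len(nrow(calls$sites)), function(i) {
    sid <- calls$sites$site_id[i]
    g <- calls$geno[calls$geno$site_id == sid, ]
    gt <- setNames(g$gt, g$sample_id)
    gt["F1_P1"] %in% c("het", "hom_alt", "hemi_alt") &&
      gt["F1_FA"] %in% c("hom_ref", "hemi_ref") &&
      gt["F1_MO"] %in% c("hom_ref", "hemi_ref")
  }, TRUE)
  expect_setequal(sub$sites$site_id, calls$sites$site_id[want])
  # output is a subset of the proband's variant sites
  pr_var <- calls$geno$site_id[calls$geno$sample_id == "F1_P1" &
                                 calls$geno$gt != "hom_ref"]
  expect_true(all(sub$sites$site_id %in% pr_var))
})

test_that("inherited variants are removed, true de novos retained", {
  ped <- trio_ped()
  calls <- make_calls(list(
    list(chrom = 1, pos = 100, gt = c(F1_P1 = "het", F1_FA = "het")),
    list(chrom = 1, pos = 200, gt = c(F1_P1 = "het"),
         ad = list(F1_P1 = c(12, 6), F1_FA = c(25, 0), F1_MO = c(30, 1)))),
    ped$sample_id)
  cand <- find_de_novo(calls, ped, "F1")
  expect_equal(nrow(cand), 1)
  expect_equal(cand$pos, 200)
  expect_equal(cand$inheritance_class, "de_novo")
  expect_equal(cand$proband_af, 6 / 18)
})

test_that("sites with a missing parental genotype are excluded from calling", {
  ped <- trio_ped()
  calls <- make_calls(list(
    list(chrom = 1, pos = 100, gt = c(F1_P1 = "het", F1_FA = "missing"))),
    ped$sample_id)
  sub <- subtract_parental(calls, "F1_P1", "F1_FA", "F1_MO")
  expect_equal(nrow(sub$sites), 0)
  expect_equal(attr(sub, "n_skipped_missing"), 1)
  expect_error(subtract_parental(calls, "F1_P1", "F1_FA", "NOBODY"),
               "missing from call set")
})

test_that("raising any threshold never adds candidates", {
  cfg <- sim_config(n_families = 2, n_background_sites = 2000, seed = 13,
                    planted_events = list(
                      event_spec("de_novo", 1),
                      event_spec("de_novo", 2, proband_fraction = 0.2)))
  co <- simulate_cohort(cfg)
  base_cfg <- dnm_config()
  base <- do.call(rbind, lapply(c("FAM01", "FAM02"), function(f)
    find_de_novo(co$calls, co$pedigree, f, base_cfg)))
  for (tweak in list(dnm_config(proband_min_alt_reads = 8),
                     dnm_config(proband_min_alt_ref_ratio = 0.45),
                     dnm_config(parent_min_ref_reads = 20),
                     dnm_config(parent_max_alt_ref_ratio = 0.01))) {
    stricter <- do.call(rbind, lapply(c("FAM01", "FAM02"), function(f)
      find_de_novo(co$calls, co$pedigree, f, tweak)))
    expect_true(all(stricter$site_id %in% base$site_id))
  }
})

test_that("subtraction survivors exceed criteria survivors when a
           low-fraction artifact is planted", {
  cfg <- sim_config(n_families = 1, n_background_sites = 2000,
                    base_error_fraction = 0.005, seed = 17,
                    planted_events = list(
                      event_spec("de_novo", 1),
                      event_spec("de_novo", 1, proband_fraction = 0.1)))
  co <- simulate_cohort(cfg)
  pr <- trio_children_for_test(co$pedigree)[1]
  i <- match(pr, co$pedigree$sample_id)
  sub <- subtract_parental(co$calls, pr, co$pedigree$father_id[i],
                           co$pedigree$mother_id[i])
  cand <- find_de_novo(co$calls, co$pedigree, "FAM01")
  expect_gt(nrow(sub$sites), nrow(cand))
  # the clean planted de novo survives, the 10%-fraction artifact does not
  expect_equal(nrow(cand), 1)
  expect_true(all(!is.na(cand$proband_af) & cand$proband_af > 0.3 / 1.3))
})
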