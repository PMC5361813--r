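vcf_header <- c(
  "##fileformat=VCFv4.2",
  "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
  "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"c\">",
  "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"m\">",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
  "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">")

write_mini_vcf <- function(records, samples) {
  f <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  writeLines(c(vcf_header,
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               records), f)
  f
}

test_that("PED parsing resolves parents and rejects malformed files", {
  f <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("F1 FA 0 0 1 1", "F1 MO 0 0 2 1", "F1 P1 FA MO 1 2"), f)
  ped <- read_pedigree(f)
  expect_equal(nrow(ped), 3)
  expect_equal(ped$father_id, c(NA, NA, "FA"))
  expect_equal(ped$sex, c("male", "female", "male"))
  expect_equal(ped$affected, c("unaffected", "unaffected", "affected"))

  writeLines("F1 S1 0 0 0 0", f)
  solo <- read_pedigree(f)
  expect_true(is.na(solo$father_id) && is.na(solo$mother_id))
  expect_equal(solo$sex, "unknown")

  writeLines(c("F1 A 0 0 1 1", "F1 A 0 0 1 1"), f)
  expect_error(read_pedigree(f), "duplicate sample_id.*A")
  writeLines("F1 P1 FA 0 1 2", f)
  expect_error(read_pedigree(f), "unresolvable")
})

test_that("VCF records map to genotype classes and allelic depths", {
  ped <- pedigree(c("S1", "S2"), "F1")
  f <- write_mini_vcf(
    c("1\t100\t.\tA\tG\t.\tPASS\tGENE=GX;CSQ=missense;MAF=0.001\tGT:AD\t0/1:12,6\t0/0:30,0",
      "X\t500\t.\tC\tT\t.\tPASS\tGENE=GY;CSQ=stop_gain\tGT:AD\t1:0,22\t./.:.",
      "2\t300\t.\tA\tG,T\t.\tPASS\tGENE=GZ;CSQ=other;MAF=0.2\tGT:AD\t1/2:3,7,9\t0/1:10,5,0"),
    c("S1", "S2"))
  calls <- read_calls(f, ped)
  expect_equal(nrow(calls$sites), 4) # multi-allelic decomposed
  het <- calls$geno[calls$geno$site_id == "1:100:A:G" &
                      calls$geno$sample_id == "S1", ]
  expect_equal(het$gt, "het")
  expect_equal(c(het$ref_reads, het$alt_reads), c(12L, 6L))
  hemi <- calls$geno[calls$geno$site_id == "X:500:C:T", ]
  expect_equal(hemi$gt[hemi$sample_id == "S1"], "hemi_alt")
  expect_equal(hemi$gt[hemi$sample_id == "S2"], "missing")
  # per-allele depths after decomposition
  g1 <- calls$geno[calls$geno$site_id == "2:300:A:G" &
                     calls$geno$sample_id == "S1", ]
  g2 <- calls$geno[calls$geno$site_id == "2:300:A:T" &
                     calls$geno$sample_id == "S1", ]
  expect_equal(c(g1$gt, g1$ref_reads, g1$alt_reads), c("het", 3, 7))
  expect_equal(c(g2$gt, g2$ref_reads, g2$alt_reads), c("het", 3, 9))
  expect_true(g1$alt_reads + g2$alt_reads <= 3 + 7 + 9)
  # missing MAF annotation is kept as NA (novel), not zero
  expect_true(is.na(calls$sites$maf[calls$sites$site_id == "X:500:C:T"]))
})

test_that("reader errors on missing AD and on absent pedigree samples", {
  ped <- pedigree("S1", "F1")
  f <- write_mini_vcf("1\t100\t.\tA\tG\t.\tPASS\tGENE=GX;CSQ=missense\tGT\t0/1",
                      "S1")
  expect_error(read_calls(f, ped), "AD")
  f2 <- write_mini_vcf("1\t100\t.\tA\tG\t.\tPASS\tG=1\tGT:AD\t0/1:1,1", "S9")
  expect_error(read_calls(f2, ped), "absent from VCF")
})

test_that("simulator output round-trips exactly through VCF and PED", {
  cfg <- sim_config(n_families = 2, n_background_sites = 400, seed = 7,
                    planted_events = list(event_spec("de_novo", 1),
                                          event_spec("xl_hemizygous", 2)))
  co <- simulate_cohort(cfg)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  ped <- read_pedigree(file.path(d, "cohort.ped"))
  expect_identical(as.data.frame(ped), as.data.frame(co$pedigree))
  back <- read_calls(file.path(d, "cohort.vcf"), ped)
  a <- co$calls$geno[order(co$calls$geno$site_id, co$calls$geno$sample_id), ]
  b <- back$geno[order(back$geno$site_id, back$geno$sample_id), ]
  expect_identical(a$gt, b$gt)
  expect_identical(as.integer(a$ref_reads), as.integer(b$ref_reads))
  expect_identical(as.integer(a$alt_reads), as.integer(b$alt_reads))
  expect_identical(co$calls$sites$site_id, back$sites$site_id)
  expect_identical(co$calls$sites$consequence, back$sites$consequence)
})

test_that("adjacent SNVs with matching genotype classes merge into an MNV", {
  samples <- c("P1", "FA", "MO")
  calls <- make_calls(list(
    list(chrom = 22, pos = 1444, gt = c(P1 = "het"), ad = list(P1 = c(18, 15))),
    list(chrom = 22, pos = 1445, gt = c(P1 = "het"), ad = list(P1 = c(20, 13)))),
    samples)
  m <- merge_adjacent_snvs(calls)
  expect_equal(nrow(m$sites), 1)
  expect_equal(m$sites$ref, "CC")
  expect_equal(m$sites$alt, "TT")
  g <- m$geno[m$geno$sample_id == "P1", ]
  expect_equal(c(g$ref_reads, g$alt_reads), c(18, 13)) # elementwise minimum
  # idempotent
  expect_identical(merge_adjacent_snvs(m)$sites, m$sites)
})

test_that("non-adjacent or genotype-discordant SNVs are not merged", {
  samples <- c("P1", "FA", "MO")
  two_apart <- make_calls(list(
    list(chrom = 1, pos = 100, gt = c(P1 = "het")),
    list(chrom = 1, pos = 102, gt = c(P1 = "het"))), samples)
  expect_equal(nrow(merge_adjacent_snvs(two_apart)$sites), 2)
  discordant <- make_calls(list(
    list(chrom = 1, pos = 100, gt = c(P1 = "het", FA = "het")),
    list(chrom = 1, pos = 101, gt = c(P1 = "het"))), samples)
  expect_equal(nrow(merge_adjacent_snvs(discordant)$sites), 2)
  # indels never merge
  indel <- make_calls(list(
    list(chrom = 1, pos = 100, ref = "CA", alt = "C", gt = c(P1 = "het")),
    list(chrom = 1, pos = 101, gt = c(P1 = "het"))), samples)
  expect_equal(nrow(merge_adjacent_snvs(indel)$sites), 2)
})

test_that("candidate TSV output is deterministic and handles empty input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  empty <- data.frame(family_id = character(), sample_id = character(),
                      chrom = character(), pos = integer())
  write_candidates(empty, f)
  expect_equal(length(readLines(f)), 1) # header only
  cand <- data.frame(family_id = "F1", sample_id = c("P1", "P1"),
                     chrom = c("2", "1"), pos = c(5L, 9L), ref = "C",
                     alt = "T", inheritance_class = "de_novo")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(cand, f)
  write_candidates(cand[2:1, ], f2) # shuffled input, identical bytes
  expect_identical(readBin(f, "raw", 10^6), readBin(f2, "raw", 10^6))
  lines <- readLines(f)
  expect_equal(length(lines), 3)
  expect_match(lines[2], "^F1\tP1\t1\t9") # chromosome-ordered
})
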