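chrom_rank_for_test <- function(chrom) match(chrom, as.character(1:22))

# build a BAF point table directly
baf_tab <- function(chrom, pos, baf, total = 40) {
  data.frame(chrom = as.character(chrom), pos = as.integer(pos), baf = baf,
             total_reads = rep_len(total, length(pos)),
             informative = rep_len(total, length(pos)) >= 15,
             stringsAsFactors = FALSE)
}

test_that("BAF is the exact alternate read fraction with a depth gate", {
  calls <- make_calls(list(
    list(chrom = 1, pos = 100, gt = c(S1 = "het"), ad = list(S1 = c(20, 20))),
    list(chrom = 1, pos = 200, gt = c(S1 = "het"), ad = list(S1 = c(5, 3))),
    list(chrom = 1, pos = 300, gt = c(S1 = "hom_alt"), ad = list(S1 = c(0, 30)))),
    "S1")
  b <- compute_baf(calls, "S1")
  expect_equal(b$baf, c(0.5, 3 / 8, 1))
  expect_equal(b$informative, c(TRUE, FALSE, TRUE))
  expect_error(compute_baf(calls, "S9"), "not in call set")
})

test_that("AOH detection finds maximal homozygous runs and their boundaries", {
  # all-heterozygous chromosome: nothing
  expect_equal(nrow(detect_aoh(baf_tab(1, (1:300) * 10, 0.5))), 0)
  # fully homozygous chromosome: one segment spanning first..last marker
  segs <- detect_aoh(baf_tab(2, (1:300) * 10, rep(c(0, 1), 150)))
  expect_equal(nrow(segs), 1)
  expect_equal(c(segs$start, segs$end, segs$n_markers), c(10, 3000, 300))
  expect_equal(segs$fraction_of_chromosome_span, 1)
  # planted 120-marker run inside het background: exact boundaries
  baf <- rep(0.5, 1000)
  baf[301:420] <- 0
  segs2 <- detect_aoh(baf_tab(3, (1:1000) * 10, baf))
  expect_equal(nrow(segs2), 1)
  expect_equal(c(segs2$start, segs2$end, segs2$n_markers),
               c(3010, 4200, 120))
  # runs shorter than min_markers_per_segment are dropped
  baf3 <- rep(0.5, 200); baf3[50:80] <- 1
  expect_equal(nrow(detect_aoh(baf_tab(4, (1:200) * 10, baf3))), 0)
  # unsorted input is rejected
  expect_error(detect_aoh(baf_tab(1, c(30, 10, 20), c(0, 0, 0))), "sorted")
})

test_that("AOH segmentation equals a brute-force maximal-run scan", {
  brute_force_aoh <- function(pts, params) {
    segs <- list()
    for (chr in unique(pts$chrom)) {
      p <- pts[pts$chrom == chr & pts$informative & !is.na(pts$baf), ]
      run <- integer()
      flush <- function(run) {
        if (length(run) >= params$min_markers_per_segment)
          segs[[length(segs) + 1]] <<- data.frame(
            chrom = chr, start = p$pos[run[1]],
            end = p$pos[run[length(run)]], n_markers = length(run))
      }
      for (i in seq_len(nrow(p))) {
        out_band <- p$baf[i] < params$het_band[1] | p$baf[i] > params$het_band[2]
        if (out_band) run <- c(run, i) else { flush(run); run <- integer() }
      }
      flush(run)
    }
    if (!length(segs)) return(NULL)
    do.call(rbind, segs)
  }
  params <- aoh_params(min_markers_per_segment = 10)
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(2000:10000, 1)
    pts <- baf_tab(sample(1:5, n, TRUE), seq_len(n) * 7,
                   sample(c(0, 0.1, 0.5, 0.9, 1), n, TRUE),
                   total = sample(c(8, 40), n, TRUE))
    pts <- pts[order(chrom_rank_for_test(pts$chrom), pts$pos), ]
    rownames(pts) <- NULL
    got <- detect_aoh(pts, params)
    want <- brute_force_aoh(pts, params)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got[, c("chrom", "start", "end", "n_markers")], want,
                   ignore_attr = TRUE)
    }
  }
})

test_that("whole-chromosome UPD flagging honors the single-region condition", {
  mk_pts <- function(frac2, frac5 = 0) {
    n <- 400
    mk <- function(chr, frac) {
      baf <- rep(0.5, n)
      if (frac > 0) baf[seq_len(round(frac * n))] <- 0
      baf_tab(chr, seq_len(n) * 10, baf)
    }
    rbind(mk(1, 0), mk(2, frac2), mk(5, frac5))
  }
  params <- aoh_params()
  # chr2 AOH over ~95% of markers, rest heterozygous: flagged
  pts <- mk_pts(0.95)
  flags <- flag_upd(detect_aoh(pts, params), pts, params)
  expect_true(flags$flagged[flags$chrom == "2"])
  expect_equal(flags$pattern[flags$chrom == "2"], "upd_suggestive")
  expect_false(any(flags$flagged[flags$chrom != "2"]))
  # two chromosomes ~90% AOH: consanguinity pattern, neither flagged
  pts2 <- mk_pts(0.9, 0.9)
  flags2 <- flag_upd(detect_aoh(pts2, params), pts2, params)
  expect_false(any(flags2$flagged))
  expect_setequal(flags2$pattern[flags2$chrom %in% c("2", "5")],
                  "consanguinity_pattern")
  # 40% AOH: below the chromosome threshold
  pts3 <- mk_pts(0.4)
  flags3 <- flag_upd(detect_aoh(pts3, params), pts3, params)
  expect_false(any(flags3$flagged))
})

test_that("parental origin is inferred from Mendelian-inconsistent homozygotes", {
  ped <- trio_ped()
  mk <- function(pr, fa, mo, n, offset = 0) {
    lapply(seq_len(n), function(i)
      list(chrom = 2, pos = offset + i * 10, maf = 0.2,
           gt = c(F1_P1 = pr, F1_FA = fa, F1_MO = mo)))
  }
  # 40 sites proband hom_alt, father het, mother hom_ref -> paternal
  calls <- make_calls(mk("hom_alt", "het", "hom_ref", 40), ped$sample_id)
  ori <- infer_upd_parent(calls, ped, "F1", "2")
  expect_equal(ori$origin, "paternal")
  expect_equal(ori$n_paternal, 40)
  # evenly split evidence -> undetermined
  calls2 <- make_calls(c(mk("hom_alt", "het", "hom_ref", 20),
                         mk("hom_alt", "hom_ref", "het", 20, offset = 1000)),
                       ped$sample_id)
  expect_equal(infer_upd_parent(calls2, ped, "F1", "2")$origin, "undetermined")
  # no informative sites -> undetermined with zero counts
  calls3 <- make_calls(mk("het", "het", "het", 5), ped$sample_id)
  ori3 <- infer_upd_parent(calls3, ped, "F1", "2")
  expect_equal(ori3$origin, "undetermined")
  expect_equal(ori3$n_paternal + ori3$n_maternal, 0)
})

test_that("a planted isodisomic chromosome is flagged with the right parent", {
  for (parent in c("father", "mother")) {
    cfg <- sim_config(n_families = 2, n_background_sites = 8000, seed = 41,
                      planted_events = list(
                        event_spec("upd", 2, upd_parent = parent)),
                      upd_chromosome = "2")
    co <- simulate_cohort(cfg)
    res <- run_pipeline(co$calls, co$pedigree)
    upd <- res$upd
    expect_equal(nrow(upd), 1)
    expect_equal(upd$family_id, "FAM02")
    expect_equal(upd$chrom, "2")
    expect_equal(upd$origin,
                 c(father = "paternal", mother = "maternal")[[parent]])
  }
})
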