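test_that("CNV burden is the altered fraction of covered genome", {
  expect_equal(compute_cnv_burden(make_profile(cn = 2, major = 1)), 0)
  # gains on 1p, 1q, 2p and a loss on 3p: 50+50+40+30 = 170 Mb of 240
  prof <- make_profile(overrides = list(`1p` = c(5, 3), `1q` = c(5, 3),
                                        `2p` = c(5, 3), `3p` = c(1, 1)),
                       ploidy = 2)
  expect_equal(compute_cnv_burden(prof), 100 * 170 / 240)
  # exactly half the covered genome gained: 1p + 1q + one 20 Mb sub-segment
  segs <- data.frame(chrom = c("1", "2", "2", "3"),
                     start = c(1, 1, 20000001, 1),
                     end = c(100000000, 20000000, 80000000, 60000000),
                     total_cn = c(5, 5, 2, 2))
  expect_equal(compute_cnv_burden(segment_profile("S", segs, ploidy = 2)),
               50)
  zero <- make_profile()
  zero$segments <- zero$segments[0, ]
  expect_error(compute_cnv_burden(zero), "zero covered")
})

test_that("burden and wGII are invariant to splitting a segment", {
  prof <- make_profile(overrides = list(`1p` = c(5, 3)), ploidy = 2)
  segs <- prof$segments
  i <- 1 # 1p
  left <- segs[i, ]; left$end <- 25000000
  right <- segs[i, ]; right$start <- 25000001
  split_prof <- segment_profile("S1", rbind(left, right, segs[-i, ]),
                                ploidy = 2)
  expect_equal(compute_cnv_burden(split_prof), compute_cnv_burden(prof))
  expect_equal(compute_wgii(split_prof, toy_arms),
               compute_wgii(prof, toy_arms))
})

test_that("wGII is ploidy-relative and averages per-chromosome fractions", {
  expect_equal(compute_wgii(make_profile(cn = 2, ploidy = 2), toy_arms), 0)
  # whole-genome doubled, cleanly tetraploid: no instability
  expect_equal(compute_wgii(make_profile(cn = 4, major = 2, ploidy = 4),
                            toy_arms), 0)
  # chromosome 1 fully gained out of 3 toy autosomes
  prof <- make_profile(overrides = list(`1p` = c(3, 2), `1q` = c(3, 2)),
                       ploidy = 2)
  expect_equal(compute_wgii(prof, toy_arms), 1 / 3)
  # with the hg19 arm table, one autosome of 22 fully gained
  arms19 <- load_arm_definitions("hg19")
  len19 <- chromosome_lengths(arms19)
  segs <- data.frame(chrom = names(len19), start = 1, end = len19,
                     total_cn = 2)
  segs$total_cn[segs$chrom == "1"] <- 3
  expect_equal(compute_wgii(segment_profile("S", segs, ploidy = 2), arms19),
               1 / 22)
  # a chromosome with no segments is excluded with a warning
  part <- make_profile(ploidy = 2)
  part$segments <- part$segments[part$segments$chrom != "3", ]
  expect_warning(w <- compute_wgii(part, toy_arms), "excluded")
  expect_equal(w, 0)
})

test_that("segment gain/loss cutoffs match the printed log2 thresholds", {
  # cn=5 at ploidy 2: r = log2(2.5) >= log2(1.25) -> gain
  prof <- make_profile(overrides = list(`1p` = c(5, 3)), ploidy = 2)
  calls <- call_arm_events(prof, toy_arms)
  expect_equal(calls$state[calls$arm == "1p"], "gain")
  expect_equal(calls$state[calls$arm == "1q"], "neutral")
  # at ploidy 2 the cutoffs are exactly cn >= 2.5 and cn <= 1.5
  for (cn in 0:6) {
    p <- make_profile(overrides = list(`1p` = c(cn, cn)), ploidy = 2)
    st <- call_arm_events(p, toy_arms)$state[1]
    expect_equal(st, if (cn >= 2.5) "gain" else if (cn <= 1.5) "loss"
                     else "neutral")
  }
})

test_that("arm calls need >98% of arm length and ignore segment order", {
  # 97% of 1p gained -> neutral
  segs <- data.frame(chrom = c("1", "1", "1", "2", "3"),
                     start = c(1, 48500001, 50000001, 1, 1),
                     end = c(48500000, 50000000, 100000000, 80000000,
                             60000000),
                     total_cn = c(5, 2, 2, 2, 2))
  prof <- segment_profile("S", segs, ploidy = 2)
  calls <- call_arm_events(prof, toy_arms)
  expect_equal(calls$state[calls$arm == "1p"], "neutral")
  expect_gt(calls$gain_fraction[calls$arm == "1p"], 0.96)
  # 99% gained -> gain
  segs$end[1] <- 49500000
  segs$start[2] <- 49500001
  prof99 <- segment_profile("S", segs, ploidy = 2)
  expect_equal(call_arm_events(prof99, toy_arms)$state[1], "gain")
  # order invariance
  shuf <- segment_profile("S", segs[c(4, 2, 5, 1, 3), ], ploidy = 2)
  expect_equal(call_arm_events(shuf, toy_arms)$state,
               call_arm_events(prof99, toy_arms)$state)
})

test_that("segments straddling an arm boundary are split before accounting", {
  # one segment covering all of chr1 (both arms), gained
  segs <- data.frame(chrom = c("1", "2", "3"), start = 1,
                     end = c(100000000, 80000000, 60000000),
                     total_cn = c(5, 2, 2))
  calls <- call_arm_events(segment_profile("S", segs, ploidy = 2), toy_arms)
  expect_equal(calls$state[calls$arm %in% c("1p", "1q")], c("gain", "gain"))
})

test_that("arm clonality follows the remaining-regions rule", {
  call_row <- function(sample, arm, state)
    data.frame(sample_id = sample, arm = arm, state = state,
               gain_fraction = 1, loss_fraction = 0, covered_fraction = 1)
  # gain in 4/4 regions -> clonal
  calls <- do.call(rbind, lapply(paste0("L", 1:4), call_row, arm = "1p",
                                 state = "gain"))
  out <- classify_arm_clonality(calls)
  expect_equal(out$clonality[out$arm == "1p"], "clonal")
  # gain in 1/4 regions (0% of remaining) -> subclonal
  calls2 <- rbind(call_row("L1", "1p", "gain"),
                  do.call(rbind, lapply(paste0("L", 2:4), call_row,
                                        arm = "1p", state = "neutral")))
  expect_equal(classify_arm_clonality(calls2)$clonality, "subclonal")
  # 3/4 = 2/3 of remaining <= 0.75 -> subclonal; 4/5 = 3/4 not > 0.75
  calls3 <- rbind(do.call(rbind, lapply(paste0("L", 1:3), call_row,
                                        arm = "1p", state = "gain")),
                  call_row("L4", "1p", "neutral"))
  expect_equal(classify_arm_clonality(calls3)$clonality, "subclonal")
  # single-region patient: clonal by convention, with a warning
  expect_warning(out1 <- classify_arm_clonality(call_row("L1", "1p", "gain")),
                 "single-region")
  expect_equal(out1$clonality, "clonal")
  # conflicting gain and loss -> subclonal with warning
  mixed <- rbind(call_row("L1", "1p", "gain"), call_row("L2", "1p", "loss"),
                 call_row("L3", "1p", "gain"))
  expect_warning(outm <- classify_arm_clonality(mixed), "conflicting")
  expect_equal(outm$clonality, "subclonal")
})

test_that("genome doubling is a majority of major copies >= 2", {
  expect_true(detect_genome_doubling(make_profile(cn = 4, major = 2)))
  expect_false(detect_genome_doubling(make_profile(cn = 2, major = 1)))
  noma <- make_profile(cn = 2, major = 1)
  noma$segments$major_cn <- NULL
  expect_error(detect_genome_doubling(noma), "major_cn")
})

test_that("SEG round-trip and profile validation", {
  prof <- make_profile()
  path <- tempfile(fileext = ".seg")
  segs <- cbind(sample_id = "S1", prof$segments)
  write_seg(segs, path)
  back <- read_seg(path)
  expect_equal(back$total_cn, prof$segments$total_cn)
  bad <- prof$segments
  bad$minor_cn[1] <- bad$minor_cn[1] + 1
  expect_error(segment_profile("S", bad), "major_cn \\+ minor_cn")
  rev <- prof$segments
  rev$end[1] <- rev$start[1] - 10
  expect_error(segment_profile("S", rev), "exceed")
})
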