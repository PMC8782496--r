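# Shared fixture builders for the test suite. Everything is constructed in
# code; the only on-disk fixtures are the packaged clinical table and arm
# definitions.

toy_arms <- load_arm_definitions("toy")

# A minimal variant-call row; override fields as needed.
make_call <- function(gene = "KRAS", consequence = "missense",
                      depth_tumor = 100, depth_normal = 80, alt_tumor = 30,
                      alt_normal = 0, popfreq_max = 0, fathmm_mkl = NA,
                      sift = NA, polyphen2_class = NA,
                      mutationassessor_class = NA, patient_id = "P1",
                      lesion_id = "P1-L1") {
  data.frame(patient_id = patient_id, lesion_id = lesion_id, gene = gene,
             chrom = "1", pos = 1e6, ref = "A", alt = "T",
             consequence = consequence, depth_tumor = depth_tumor,
             depth_normal = depth_normal, alt_tumor = alt_tumor,
             alt_normal = alt_normal, popfreq_max = popfreq_max,
             fathmm_mkl = fathmm_mkl, sift = sift,
             polyphen2_class = polyphen2_class,
             mutationassessor_class = mutationassessor_class,
             stringsAsFactors = FALSE)
}

make_calls <- function(n, ...) {
  args <- list(...)
  do.call(rbind, lapply(seq_len(n), function(i) do.call(make_call, args)))
}

# A segment profile tiling the toy genome at a uniform copy number, with
# optional per-arm overrides: list(arm_id = c(total, major)).
make_profile <- function(sample_id = "S1", cn = 2, major = 1, ploidy = NULL,
                         overrides = list(), purity = 0.6) {
  segs <- data.frame(chrom = toy_arms$chrom, start = toy_arms$start,
                     end = toy_arms$end, total_cn = cn, major_cn = major,
                     stringsAsFactors = FALSE)
  arm_id <- paste0(toy_arms$chrom, toy_arms$arm)
  for (a in names(overrides)) {
    i <- match(a, arm_id)
    segs$total_cn[i] <- overrides[[a]][1]
    segs$major_cn[i] <- overrides[[a]][2]
  }
  segs$minor_cn <- segs$total_cn - segs$major_cn
  segment_profile(sample_id, segs, purity = purity, ploidy = ploidy)
}

# Peak-set row builder (0-based half-open intervals).
make_peaks <- function(sample_id, starts, ends = starts + 1000,
                       chrom = "1", fold = 3, q = 0.001) {
  data.frame(sample_id = sample_id, chrom = chrom, start = starts,
             end = ends, enrichment_fold = fold, q_value = q,
             stringsAsFactors = FALSE)
}

# Exhaustive two-sided Fisher p-value by hypergeometric enumeration over
# all tables with the observed margins (probability-mass rule); the
# independent oracle for fisher_association.
fisher_enumeration_p <- function(tab) {
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(xs, function(x) {
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[match(tab[1, 1], xs)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
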