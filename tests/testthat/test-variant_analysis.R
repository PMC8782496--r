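test_that("somatic filters apply the depth, alt-read and frequency rules", {
  cases <- list(
    list(args = list(), pass = TRUE),                       # clean pass
    list(args = list(depth_tumor = 19, alt_tumor = 8), pass = FALSE),
    list(args = list(depth_normal = 19), pass = FALSE),     # normal depth
    list(args = list(depth_tumor = 20, depth_normal = 20, alt_tumor = 10),
         pass = TRUE),
    list(args = list(alt_normal = 6), pass = FALSE),
    list(args = list(alt_normal = 5), pass = TRUE),
    list(args = list(alt_tumor = 4), pass = FALSE),
    list(args = list(alt_tumor = 5), pass = TRUE),
    list(args = list(popfreq_max = 0.01), pass = FALSE),
    list(args = list(popfreq_max = 0.009), pass = TRUE),
    list(args = list(popfreq_max = NA), pass = TRUE)        # missing = novel
  )
  calls <- do.call(rbind, lapply(cases, function(cs) do.call(make_call,
                                                             cs$args)))
  out <- filter_somatic_variants(calls)
  expect_equal(out$passed_filter, vapply(cases, `[[`, logical(1), "pass"))
})

test_that("the spec'd example call passes all four criteria", {
  out <- filter_somatic_variants(make_call(depth_tumor = 25,
                                           depth_normal = 30,
                                           alt_normal = 0, alt_tumor = 8,
                                           popfreq_max = 0))
  expect_true(out$passed_filter)
})

test_that("filtering handles empty input, rejects bad reads, is idempotent", {
  empty <- filter_somatic_variants(make_call()[0, ])
  expect_equal(nrow(empty), 0)
  expect_error(filter_somatic_variants(make_call(alt_tumor = -1)),
               "negative")
  expect_error(filter_somatic_variants(make_call(alt_tumor = 200)),
               "exceed")
  calls <- make_calls(5, depth_tumor = 25, alt_tumor = 8)
  once <- filter_somatic_variants(calls)
  twice <- filter_somatic_variants(once)
  expect_identical(once, twice)
})

test_that("TMB is nonsynonymous count over exome size and linear", {
  empty <- filter_somatic_variants(make_call()[0, ])
  expect_equal(compute_tmb(empty), 0)
  t38 <- filter_somatic_variants(make_calls(38))
  expect_equal(compute_tmb(t38), 1.0)
  t239 <- filter_somatic_variants(make_calls(239))
  expect_equal(compute_tmb(t239), 239 / 38)
  # synonymous mutations do not count
  syn <- filter_somatic_variants(rbind(make_calls(38),
                                       make_calls(10,
                                                  consequence = "synonymous")))
  expect_equal(compute_tmb(syn), 1.0)
  expect_error(compute_tmb(t38, exome_mb = 0), "positive")
  # linearity in mutation count
  expect_equal(compute_tmb(filter_somatic_variants(make_calls(76))),
               2 * compute_tmb(t38))
})

test_that("mutation-type proportions form a probability vector and flag multi-hits", {
  tab <- filter_somatic_variants(make_calls(10))
  p <- classify_mutation_types(tab)$proportions
  expect_equal(unname(p["missense"]), 1.0)
  mixed <- filter_somatic_variants(rbind(make_calls(9),
                                         make_call(consequence = "nonsense")))
  p <- classify_mutation_types(mixed)$proportions
  expect_equal(unname(p["missense"]), 0.9)
  expect_equal(unname(p["nonsense"]), 0.1)
  expect_equal(sum(p), 1)
  expect_error(classify_mutation_types(
    filter_somatic_variants(make_call(consequence = "weird"))), "unknown")
  # two CDKN2A mutations in one lesion -> multi-hit
  mh <- classify_mutation_types(filter_somatic_variants(
    make_calls(2, gene = "CDKN2A")))$multi_hit
  expect_equal(mh$gene, "CDKN2A")
  expect_equal(mh$n_mutations, 2L)
  # same gene in different lesions is not multi-hit
  two_lesions <- rbind(make_call(gene = "CDKN2A", lesion_id = "P1-L1"),
                       make_call(gene = "CDKN2A", lesion_id = "P1-L2"))
  mh2 <- classify_mutation_types(
    filter_somatic_variants(two_lesions))$multi_hit
  expect_equal(nrow(mh2), 0)
})

test_that("driver candidacy follows the catalog and damage rules", {
  catalog <- driver_catalog(pdac = c("KRAS", "TP53"))
  cases <- list(
    list(args = list(gene = "KRAS", consequence = "nonsense"), hit = TRUE),
    list(args = list(gene = "KRAS", consequence = "frameshift"), hit = TRUE),
    list(args = list(gene = "KRAS", consequence = "splice"), hit = TRUE),
    list(args = list(gene = "KRAS", fathmm_mkl = 0.6), hit = TRUE),
    list(args = list(gene = "KRAS", fathmm_mkl = 0.4), hit = FALSE),
    # two damaging algorithms without FATHMM
    list(args = list(gene = "KRAS", sift = 0.01,
                     polyphen2_class = "probably damaging"), hit = TRUE),
    # one algorithm only
    list(args = list(gene = "KRAS", sift = 0.01), hit = FALSE),
    # missing scores are non-damaging
    list(args = list(gene = "KRAS"), hit = FALSE),
    # non-catalog gene never a candidate
    list(args = list(gene = "NOTDRIVER", consequence = "nonsense"),
         hit = FALSE),
    # synonymous never a candidate
    list(args = list(gene = "KRAS", consequence = "synonymous",
                     fathmm_mkl = 0.9), hit = FALSE)
  )
  calls <- filter_somatic_variants(
    do.call(rbind, lapply(cases, function(cs) do.call(make_call, cs$args))))
  out <- annotate_driver_mutations(calls, catalog)
  expect_equal(out$is_candidate_driver,
               vapply(cases, `[[`, logical(1), "hit"))
})

test_that("driver mutation frequency counts patients, not lesions", {
  catalog <- driver_catalog(pdac = c("KRAS", "TP53"))
  calls <- rbind(
    make_call(gene = "KRAS", consequence = "nonsense", patient_id = "P1",
              lesion_id = "P1-L1"),
    make_call(gene = "KRAS", consequence = "nonsense", patient_id = "P1",
              lesion_id = "P1-L2"),
    make_call(gene = "KRAS", consequence = "nonsense", patient_id = "P2"),
    make_call(gene = "TP53", consequence = "missense", patient_id = "P2"))
  tab <- annotate_driver_mutations(filter_somatic_variants(calls), catalog)
  freq <- driver_mutation_frequency(tab)
  expect_equal(freq$frequency[freq$gene == "KRAS"], 1.0)
  # TP53 missense without damaging scores is not a candidate
  expect_false("TP53" %in% freq$gene)
  expect_equal(driver_mutation_frequency(tab, genes = "ABSENT")$frequency, 0)
  expect_error(driver_mutation_frequency(tab[0, ]), "no patients")
})

test_that("MAF round-trip preserves the mutation table", {
  calls <- filter_somatic_variants(rbind(
    make_call(gene = "KRAS"), make_call(gene = "TP53",
                                        consequence = "nonsense")))
  path <- tempfile(fileext = ".tsv")
  write_maf(calls, path)
  back <- read_maf(path)
  expect_equal(back$gene, calls$gene)
  expect_equal(back$consequence, calls$consequence)
  expect_equal(back$depth_tumor, calls$depth_tumor)
})
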