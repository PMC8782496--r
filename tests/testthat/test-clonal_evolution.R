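test_that("CCF estimation inverts the purity/copy-number model", {
  # diploid clonal heterozygous: VAF 0.5 -> m = 1, CCF = 1
  e <- estimate_ccf(0.5, 1, 2)
  expect_equal(e$multiplicity, 1)
  expect_equal(e$ccf, 1)
  # half purity halves the VAF of a clonal diploid mutation
  e <- estimate_ccf(0.25, 0.5, 2)
  expect_equal(e$ccf, 1)
  # tetraploid locus, one mutated copy: VAF 0.25 at purity 1
  e <- estimate_ccf(0.25, 1, 4)
  expect_equal(e$multiplicity, 1)
  expect_equal(e$ccf, 1)
  # doubled locus carrying the mutation on both copies
  e <- estimate_ccf(0.5, 1, 4)
  expect_equal(e$multiplicity, 2)
  expect_equal(e$ccf, 1)
  expect_error(estimate_ccf(0.5, 0, 2), "purity")
  # CCF above 1 is flagged and capped
  e <- estimate_ccf(0.6, 1, 2)
  expect_true(e$ccf_exceeds_one)
  expect_lte(e$ccf, 1.2)
})

test_that("clonality requires presence and near-1 CCF in every region", {
  expect_equal(classify_mutation_clonality(c(1.0, 0.98, 0.95)), "clonal")
  expect_equal(classify_mutation_clonality(c(1.0, 0.3)), "subclonal")
  expect_equal(classify_mutation_clonality(c(1.0, NA)), "subclonal")
  expect_equal(classify_mutation_clonality(c(0.89)), "subclonal")
  expect_error(classify_mutation_clonality(c(NA, NA)), "no region")
})

test_that("mutation timing follows the multiplicity/doubling rules", {
  # doubled genome, two mutated copies everywhere -> early
  expect_equal(time_clonal_mutation(c(2, 2, 2), c(TRUE, TRUE, TRUE),
                                    c(2, 2, 2)), "clonal early")
  # doubled genome, single mutated copy on a duplicated locus -> late
  expect_equal(time_clonal_mutation(c(1, 1), c(TRUE, TRUE), c(2, 2)),
               "clonal late")
  # tie between timeable regions -> untimed
  expect_equal(time_clonal_mutation(c(2, 1), c(TRUE, TRUE), c(2, 2)),
               "clonal untimed")
  # major copy number 1 carries no timing information
  expect_equal(time_clonal_mutation(c(1, 1), c(FALSE, FALSE), c(1, 1)),
               "clonal untimed")
  # untimeable regions are excluded from the majority denominator
  expect_equal(time_clonal_mutation(c(2, 2, 1), c(TRUE, TRUE, FALSE),
                                    c(2, 2, 1)), "clonal early")
  expect_error(time_clonal_mutation(1, TRUE, 2, clonality = "subclonal"),
               "clonal")
})

test_that("arm-event timing uses multiplicity for gains and LOH for losses", {
  expect_equal(time_arm_event("gain", multiplicities = c(2, 2, 1)), "early")
  expect_equal(time_arm_event("gain", multiplicities = c(1, 1, 2)), "late")
  expect_equal(time_arm_event("gain", multiplicities = numeric(0)),
               "untimed")
  expect_equal(time_arm_event("loss", minor_cn = c(0, 0, 0)), "early")
  expect_equal(time_arm_event("loss", minor_cn = c(0, 1)), "late")
})

test_that("presence-pattern clustering groups and splits correctly", {
  m <- rbind(a = c(1, 1), b = c(1, 1), c = c(0.5, 0), d = c(0.48, 0),
             e = c(0, 0.4))
  cl <- cluster_mutations(m)
  memberships <- lapply(cl, `[[`, "mutations")
  expect_true(any(vapply(memberships, function(x)
    setequal(x, c("a", "b")), logical(1))))
  expect_true(any(vapply(memberships, function(x)
    setequal(x, c("c", "d")), logical(1))))
  expect_true(any(vapply(memberships, function(x) setequal(x, "e"),
                         logical(1))))
  # same pattern, well-separated CCFs are split
  m2 <- rbind(a = c(1, 1), b = c(0.4, 0.4), c = c(0.41, 0.39))
  cl2 <- cluster_mutations(m2)
  expect_equal(length(cl2), 2)
  # single mutation -> single cluster
  expect_equal(length(cluster_mutations(matrix(0.7, 1, 2))), 1)
  expect_error(cluster_mutations(matrix(0, 2, 2)), "all-zero")
  # clusters partition the mutations
  expect_setequal(unlist(memberships), rownames(m))
})

test_that("clone trees are built by CCF containment from the trunk", {
  clusters <- list(list(id = 1, mutations = "a", ccf = c(1, 1)),
                   list(id = 2, mutations = "b", ccf = c(0.5, 0)),
                   list(id = 3, mutations = "c", ccf = c(0, 0.4)))
  tree <- build_clone_tree(clusters)
  expect_equal(tree$truncal, 1)
  expect_equal(sort(tree$edges$child[tree$edges$parent == 1]), c(2, 3))
  expect_equal(tree$edges$child[tree$edges$parent == 0], 1)
  # nested chain attaches to the smallest containing parent
  chain <- list(list(id = 1, mutations = "a", ccf = c(1, 1)),
                list(id = 2, mutations = "b", ccf = c(0.6, 0.5)),
                list(id = 3, mutations = "c", ccf = c(0.3, 0.2)))
  tr2 <- build_clone_tree(chain)
  expect_equal(tr2$edges$parent[tr2$edges$child == 3], 2)
  # single cluster -> trunk-only tree
  solo <- build_clone_tree(list(list(id = 1, mutations = "a",
                                     ccf = c(1, 1))))
  expect_equal(nrow(solo$edges), 1)
  expect_error(build_clone_tree(list(list(id = 1, mutations = "a",
                                          ccf = c(0.5, 0.5)))),
               "truncal")
  # Newick export is parseable and carries all clusters
  nwk <- clone_tree_newick(tree)
  phy <- ape::read.tree(text = nwk)
  expect_true(all(c("2", "3") %in% phy$tip.label))
})

test_that("trunk/branch labels partition mutations with correct proportions", {
  clusters <- list(list(id = 1, mutations = sprintf("t%d", 1:5),
                        ccf = c(1, 1)),
                   list(id = 2, mutations = sprintf("b%d", 1:95),
                        ccf = c(0.5, 0)))
  tb <- assign_trunk_branch(build_clone_tree(clusters))
  expect_equal(unname(tb$proportions["trunk"]), 0.05)
  expect_equal(sum(tb$proportions), 1)
  expect_equal(length(tb$labels), 100)
  solo <- assign_trunk_branch(build_clone_tree(clusters[1]))
  expect_equal(unname(solo$proportions["trunk"]), 1)
})

test_that("downsampled driver enrichment separates trunk from branch", {
  # drivers exclusively truncal, non-drivers exclusively branch
  labels <- do.call(rbind, lapply(paste0("P", 1:15), function(p) {
    data.frame(patient_id = p,
               gene = c(rep("KRAS", 5), sprintf("G%d", 1:45)),
               label = c(rep("trunk", 5), rep("branch", 45)),
               is_driver = c(rep(TRUE, 5), rep(FALSE, 45)))
  }))
  enr <- driver_fold_enrichment(labels, n_sample = 12, n_reps = 20, seed = 1)
  expect_true(all(enr$replicates$or > 1))
  expect_lt(enr$p_value, 0.001)
  # identical driver fraction on trunk and branch -> fold ratios near 1
  null_labels <- do.call(rbind, lapply(paste0("P", 1:15), function(p) {
    data.frame(patient_id = p,
               gene = sprintf("G%d", 1:40),
               label = rep(c("trunk", "branch"), each = 20),
               is_driver = rep(c(TRUE, FALSE, TRUE, FALSE), each = 10))
  }))
  enr0 <- driver_fold_enrichment(null_labels, n_sample = 12, n_reps = 20,
                                 seed = 2)
  expect_equal(median(enr0$replicates$fold_trunk), 1, tolerance = 0.05)
  expect_equal(median(enr0$replicates$or), 1, tolerance = 0.1)
  # determinism under a fixed seed
  enr_a <- driver_fold_enrichment(labels, n_reps = 10, seed = 7)
  enr_b <- driver_fold_enrichment(labels, n_reps = 10, seed = 7)
  expect_identical(enr_a$replicates, enr_b$replicates)
  expect_error(driver_fold_enrichment(labels, n_sample = 99), "exceeds")
})

test_that("trunk/branch labels are stable under region reordering", {
  m <- rbind(a = c(1, 1, 1), b = c(0.98, 1, 0.97), c = c(0.5, 0, 0.2),
             d = c(0, 0.4, 0.1))
  tb1 <- assign_trunk_branch(build_clone_tree(cluster_mutations(m)))
  m2 <- m[, c(3, 1, 2)]
  tb2 <- assign_trunk_branch(build_clone_tree(cluster_mutations(m2)))
  expect_equal(tb1$labels[sort(names(tb1$labels))],
               tb2$labels[sort(names(tb2$labels))])
})
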