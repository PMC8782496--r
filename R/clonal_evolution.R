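# Cancer cell fraction estimation, clonality and genome-doubling-relative
# timing, clone-tree reconstruction and trunk/branch statistics.
#
# The CCF model: a mutation present in a fraction CCF of tumour cells at
# multiplicity m (mutated copies per carrying cell), in a sample of purity
# rho with local total copy number CNt, has expected variant allele fraction
#   VAF = CCF * rho * m / (rho * CNt + 2 * (1 - rho)).
# Multiplicity is estimated by rounding VAF/rho * (rho*CNt + 2(1-rho)) and
# CCF by inverting the expression at the estimated multiplicity.

#' Estimate cancer cell fraction and multiplicity
#'
#' @param vaf Variant allele fraction(s), alt/total reads.
#' @param purity Tumour purity rho in (0, 1].
#' @param cn_total Local total copy number (>= 1).
#' @param major_cn Optional major allele copy number; when given, the
#'   estimated multiplicity is capped at it (a mutation cannot sit on more
#'   copies than the major allele provides).
#' @param ccf_cap CCF values are clipped to \[0, `ccf_cap`\] (default 1.2);
#'   values above 1 before clipping are flagged.
#' @return Data.frame with `vaf`, `multiplicity`, `ccf`, `ccf_exceeds_one`.
#' @export
estimate_ccf <- function(vaf, purity, cn_total, major_cn = NULL,
                         ccf_cap = 1.2) {
  if (any(purity <= 0)) stop("purity must be positive")
  if (any(purity > 1)) stop("purity cannot exceed 1")
  if (any(cn_total < 1)) stop("cn_total must be >= 1")
  denom <- purity * cn_total + 2 * (1 - purity)
  m <- pmax(1, round(vaf / purity * denom))
  if (!is.null(major_cn)) m <- pmin(m, pmax(major_cn, 1))
  ccf <- vaf * denom / (purity * m)
  exceeds <- ccf > 1
  data.frame(vaf = vaf, multiplicity = m,
             ccf = pmin(pmax(ccf, 0), ccf_cap),
             ccf_exceeds_one = exceeds)
}

#' Classify a mutation as clonal or subclonal across regions
#'
#' Clonal means present in every region of the patient with CCF at least
#' `ccf_threshold` ("close to 1") in each; anything else is subclonal.
#'
#' @param ccfs Numeric vector of per-region CCFs; `NA` marks a region where
#'   the mutation was not observed.
#' @param ccf_threshold Per-region clonality threshold (default 0.9).
#' @return `"clonal"` or `"subclonal"`.
#' @export
classify_mutation_clonality <- function(ccfs, ccf_threshold = 0.9) {
  if (all(is.na(ccfs))) stop("mutation observed in no region")
  if (!any(is.na(ccfs)) && all(ccfs >= ccf_threshold)) "clonal" else "subclonal"
}

# Region-level timing relative to genome doubling: a mutation on >= 2 copies
# in a doubled region must predate the doubling; a single-copy mutation on a
# locus whose major allele was duplicated postdates it; a locus that never
# gained a second major copy carries no timing information.
time_region <- function(m, gd, major_cn) {
  if (major_cn < 2) return("untimed")
  if (m >= 2 && (gd || m >= major_cn)) return("early")
  if (m == 1) return("late")
  "untimed"
}

#' Time a clonal mutation relative to genome doubling
#'
#' Per region, the mutation is early when its multiplicity is >= 2 in a
#' genome-doubled region (or >= the major copy number >= 2 without genome
#' doubling), late when multiplicity is 1 while the major copy number is
#' >= 2, and untimed when the major copy number is 1. The aggregate label
#' is early/late when that state holds in a strict majority of timeable
#' regions; otherwise "clonal untimed". Untimeable regions are excluded
#' from the denominator.
#'
#' @param multiplicity Per-region multiplicities.
#' @param gd Per-region logical genome-doubling flags.
#' @param major_cn Per-region major allele copy numbers.
#' @param clonality Label from [classify_mutation_clonality()]; must be
#'   "clonal".
#' @return One of `"clonal early"`, `"clonal late"`, `"clonal untimed"`.
#' @export
time_clonal_mutation <- function(multiplicity, gd, major_cn,
                                 clonality = "clonal") {
  if (!identical(clonality, "clonal"))
    stop("timing applies to clonal mutations only")
  labels <- mapply(time_region, multiplicity, gd, major_cn)
  timeable <- labels[labels != "untimed"]
  if (!length(timeable)) return("clonal untimed")
  n_early <- sum(timeable == "early")
  n_late <- sum(timeable == "late")
  if (n_early > length(timeable) / 2) return("clonal early")
  if (n_late > length(timeable) / 2) return("clonal late")
  "clonal untimed"
}

#' Time a clonal arm-level event
#'
#' Clonal arm gain is timed by the mutation copy number on the arm: early
#' when the median multiplicity of clonal mutations on the arm is >= 2,
#' late otherwise, untimed with no informative mutations. Clonal arm loss
#' is timed by loss-of-heterozygosity: early when the minor copy number is
#' 0 in every region, late otherwise.
#'
#' @param state `"gain"` or `"loss"`.
#' @param multiplicities Multiplicities of clonal mutations on the arm
#'   (gains; may be empty).
#' @param minor_cn Per-region minor copy numbers on the arm (losses).
#' @return `"early"`, `"late"` or `"untimed"`.
#' @export
time_arm_event <- function(state, multiplicities = numeric(0),
                           minor_cn = numeric(0)) {
  state <- match.arg(state, c("gain", "loss"))
  if (state == "gain") {
    if (!length(multiplicities)) return("untimed")
    if (median(multiplicities) >= 2) "early" else "late"
  } else {
    if (!length(minor_cn)) return("untimed")
    if (all(minor_cn == 0)) "early" else "late"
  }
}

# Split mean CCFs at gaps larger than `tol`, capped at max_k groups by
# keeping the largest gaps. Used for groups too small to support a mixture
# fit, and as the fallback when the mixture fit fails.
gap_partition <- function(x, max_k, tol) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  gaps <- diff(xs)
  cand <- which(gaps > tol)
  if (length(cand) > max_k - 1)
    cand <- sort(cand[order(-gaps[cand])[seq_len(max_k - 1)]])
  assign <- integer(n)
  assign[ord] <- cumsum(c(1L, as.integer(seq_len(n - 1) %in% cand)))
  assign
}

# Deterministic 1-D clustering of mean CCFs within a presence pattern: a
# one-dimensional Gaussian mixture (shared variance) with the component
# count chosen by BIC. The mixture likelihood keeps a single noisy clone
# whole (splitting one Gaussian gains almost no likelihood) while a small
# clonal subpopulation beside a large subclonal cloud is still detected.
# Tiny groups fall back to gap partitioning at `tol`.
kmeans_1d <- function(x, max_k, tol = 0.15) {
  n <- length(x)
  if (n == 1) return(1L)
  if (length(unique(x)) == 1) return(rep(1L, n))
  if (n < 8) return(gap_partition(x, max_k, tol))
  fit <- try(suppressWarnings(
    Mclust(x, G = seq_len(min(max_k, n - 1)), modelNames = "E",
           verbose = FALSE)), silent = TRUE)
  if (inherits(fit, "try-error") || is.null(fit))
    return(gap_partition(x, max_k, tol))
  as.integer(fit$classification)
}

#' Cluster mutations into clones
#'
#' Mutations are grouped first by their region presence pattern (CCF above
#' `presence_threshold`), then by deterministic one-dimensional
#' Gaussian-mixture clustering (shared variance, BIC-selected component
#' count) on the mean CCF across present regions within each pattern;
#' patterns with fewer than eight mutations are split at CCF gaps larger
#' than `tol` instead. This is a desk-scale, deterministic replacement for
#' Dirichlet-process clustering: only cluster mean CCFs are consumed
#' downstream.
#'
#' @param ccf_matrix Mutations-by-regions matrix of CCFs (0 or `NA` =
#'   absent).
#' @param max_clusters Maximum clusters per presence pattern (default 4).
#' @param presence_threshold CCF above which a mutation counts as present
#'   in a region (default 0.01).
#' @param tol Minimum CCF gap used when a pattern is too small for the
#'   mixture fit (default 0.15).
#' @return List of clusters; each has `id`, `mutations` (rownames or
#'   indices), and `ccf` (per-region mean CCF vector).
#' @export
cluster_mutations <- function(ccf_matrix, max_clusters = 4,
                              presence_threshold = 0.01, tol = 0.15) {
  ccf_matrix <- as.matrix(ccf_matrix)
  ccf_matrix[is.na(ccf_matrix)] <- 0
  if (all(ccf_matrix == 0)) stop("all-zero CCF matrix")
  ids <- rownames(ccf_matrix)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(ccf_matrix)))
  present <- ccf_matrix > presence_threshold
  pattern <- apply(present, 1, function(p) paste(as.integer(p), collapse = ""))
  clusters <- list()
  for (pat in sort(unique(pattern))) {
    idx <- which(pattern == pat)
    mean_ccf <- rowMeans(ccf_matrix[idx, , drop = FALSE][,
      strsplit(pat, "")[[1]] == "1", drop = FALSE])
    if (!length(mean_ccf) || all(is.nan(mean_ccf))) next
    assign <- if (length(idx) == 1) 1L else kmeans_1d(mean_ccf, max_clusters, tol)
    for (cl in sort(unique(assign))) {
      members <- idx[assign == cl]
      clusters[[length(clusters) + 1L]] <- list(
        id = NA_integer_,
        mutations = ids[members],
        ccf = colMeans(ccf_matrix[members, , drop = FALSE]))
    }
  }
  # order clusters by decreasing mean CCF so the truncal cluster comes first
  ord <- order(-vapply(clusters, function(cl) mean(cl$ccf), numeric(1)))
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) clusters[[i]]$id <- i
  clusters
}

#' Build a clone tree from clusters by CCF containment
#'
#' The truncal cluster must have CCF close to 1 in every region. Every
#' other cluster is attached to the smallest (lowest mean CCF) cluster that
#' contains it, where cluster A contains B when A's CCF is at least B's in
#' every region within `tolerance`. The tree is rooted at a germline node
#' `"GL"` above the truncal cluster.
#'
#' @param clusters List from [cluster_mutations()].
#' @param truncal_threshold Minimum per-region mean CCF for the truncal
#'   cluster (default 0.85; cluster means sit slightly below 1 under read
#'   sampling noise). Several clusters passing the threshold are merged
#'   into a single truncal cluster, since clones indistinguishable from
#'   full clonality in every region cannot be ordered.
#' @param tolerance Per-region slack allowed in the containment comparison
#'   (default 0.1).
#' @param patient_id Optional patient identifier stored on the tree.
#' @return A `clone_tree` object: list with `clusters`, `edges`
#'   (data.frame parent/child of cluster ids, `0` = germline root),
#'   `truncal` (truncal cluster id), `patient_id`.
#' @export
build_clone_tree <- function(clusters, truncal_threshold = 0.85,
                             tolerance = 0.1, patient_id = NA_character_) {
  if (!length(clusters)) stop("no clusters")
  ccfs <- do.call(rbind, lapply(clusters, `[[`, "ccf"))
  truncal_set <- which(apply(ccfs, 1, function(x)
    all(x >= truncal_threshold)))
  if (!length(truncal_set) && length(clusters) > 1) {
    # fallback for noisy low-purity profiles: the root clone is the
    # full-presence cluster that contains every other cluster per region
    contains_all <- vapply(seq_along(clusters), function(j) {
      all(ccfs[j, ] >= 0.7) &&
        all(vapply(seq_along(clusters)[-j], function(i) {
          all(ccfs[j, ] >= ccfs[i, ] - tolerance)
        }, logical(1)))
    }, logical(1))
    if (any(contains_all)) {
      cand <- which(contains_all)
      truncal_set <- cand[which.max(apply(ccfs[cand, , drop = FALSE], 1,
                                          min))]
    }
  }
  if (!length(truncal_set))
    stop("no truncal cluster (CCF close to 1 in all regions); tree not buildable")
  if (length(truncal_set) > 1) {
    sizes <- vapply(clusters[truncal_set], function(cl)
      length(cl$mutations), numeric(1))
    merged <- list(
      id = clusters[[truncal_set[1]]]$id,
      mutations = unlist(lapply(clusters[truncal_set], `[[`, "mutations"),
                         use.names = FALSE),
      ccf = colSums(ccfs[truncal_set, , drop = FALSE] * sizes) / sum(sizes))
    clusters <- c(list(merged), clusters[-truncal_set])
    for (i in seq_along(clusters)) clusters[[i]]$id <- i
    ccfs <- do.call(rbind, lapply(clusters, `[[`, "ccf"))
    truncal_set <- 1L
  }
  truncal <- truncal_set[which.max(rowMeans(ccfs[truncal_set, ,
                                                 drop = FALSE]))]
  mean_ccf <- rowMeans(ccfs)
  edges <- data.frame(parent = 0L, child = clusters[[truncal]]$id)
  for (i in seq_along(clusters)) {
    if (i == truncal) next
    contains <- vapply(seq_along(clusters), function(j) {
      j != i && all(ccfs[j, ] >= ccfs[i, ] - tolerance) &&
        mean_ccf[j] >= mean_ccf[i]
    }, logical(1))
    contains[truncal] <- contains[truncal] ||
      all(ccfs[truncal, ] >= ccfs[i, ] - tolerance)
    candidates <- which(contains)
    if (!length(candidates)) candidates <- truncal
    parent <- candidates[which.min(mean_ccf[candidates])]
    edges <- rbind(edges, data.frame(parent = clusters[[parent]]$id,
                                     child = clusters[[i]]$id))
  }
  structure(list(clusters = clusters, edges = edges,
                 truncal = clusters[[truncal]]$id, patient_id = patient_id),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("clone_tree: %d clusters, truncal = %d\n",
              length(x$clusters), x$truncal))
  invisible(x)
}

#' Export a clone tree as Newick
#'
#' Cluster ids are used as labels; the germline root is labelled `GL`.
#'
#' @param tree A `clone_tree`.
#' @return Newick string.
#' @export
clone_tree_newick <- function(tree) {
  children <- function(id) tree$edges$child[tree$edges$parent == id]
  rec <- function(id) {
    kids <- children(id)
    label <- if (id == 0) "GL" else as.character(id)
    if (!length(kids)) return(label)
    paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")",
           label)
  }
  paste0(rec(0L), ";")
}

#' Assign trunk/branch labels from a clone tree
#'
#' Trunk mutations are the members of the first ancestor clone (the truncal
#' cluster); all remaining mutations are branch.
#'
#' @param tree A `clone_tree`.
#' @return List with `labels` (named character vector, mutation ->
#'   "trunk"/"branch") and `proportions` (named numeric, sums to 1).
#' @export
assign_trunk_branch <- function(tree) {
  labels <- unlist(lapply(tree$clusters, function(cl) {
    setNames(rep(if (cl$id == tree$truncal) "trunk" else "branch",
                 length(cl$mutations)), cl$mutations)
  }))
  prop <- c(trunk = mean(labels == "trunk"), branch = mean(labels == "branch"))
  list(labels = labels, proportions = prop)
}

# 2x2 driver-by-category table statistics with Haldane-Anscombe correction.
enrichment_stats <- function(is_driver, is_trunk, cap = 100) {
  a <- sum(is_driver & is_trunk) + 0.5
  b <- sum(!is_driver & is_trunk) + 0.5
  cc <- sum(is_driver & !is_trunk) + 0.5
  d <- sum(!is_driver & !is_trunk) + 0.5
  or <- min((a * d) / (b * cc), cap)
  overall <- (a + cc) / (a + b + cc + d)
  c(or = or,
    fold_trunk = (a / (a + b)) / overall,
    fold_branch = (cc / (cc + d)) / overall)
}

#' Downsampled driver fold enrichment between trunk and branch
#'
#' Repeatedly downsamples `n_sample` of the patients without replacement;
#' per replicate builds the 2x2 table of driver vs non-driver mutations by
#' trunk vs branch (with Haldane-Anscombe 0.5 correction), recording the
#' trunk-enrichment odds ratio and the per-category fold enrichment
#' (driver-mutation proportion in the category divided by the overall
#' driver-mutation proportion). The trunk and branch fold-enrichment
#' distributions are then compared with a two-sided Wilcoxon test
#' (unpaired rank-sum by default; paired signed-rank available).
#'
#' @param labels Data.frame with columns `patient_id`, `gene`, `label`
#'   ("trunk"/"branch") and `is_driver` (logical), one row per mutation.
#' @param n_sample Patients drawn per replicate (default 12).
#' @param n_reps Number of replicates (default 100).
#' @param seed Integer seed driving the replicate draws.
#' @param paired Use the paired signed-rank test instead of the rank-sum
#'   test (default FALSE).
#' @param or_cap Cap for degenerate odds ratios (default 100).
#' @return List with `replicates` (data.frame `or`, `fold_trunk`,
#'   `fold_branch`), `statistic`, `p_value`, `n_reps`, `test`.
#' @export
driver_fold_enrichment <- function(labels, n_sample = 12, n_reps = 100,
                                   seed = 1, paired = FALSE, or_cap = 100) {
  patients <- unique(labels$patient_id)
  if (n_sample > length(patients))
    stop("n_sample exceeds number of patients")
  set.seed(seed)
  reps <- lapply(seq_len(n_reps), function(i) {
    drawn <- sample(patients, n_sample, replace = FALSE)
    sub <- labels[labels$patient_id %in% drawn, , drop = FALSE]
    enrichment_stats(sub$is_driver, sub$label == "trunk", cap = or_cap)
  })
  reps <- as.data.frame(do.call(rbind, reps))
  wt <- suppressWarnings(
    wilcox.test(reps$fold_trunk, reps$fold_branch, paired = paired,
                exact = FALSE))
  list(replicates = reps, statistic = unname(wt$statistic),
       p_value = wt$p.value, n_reps = n_reps,
       test = if (paired) "wilcoxon signed-rank" else "wilcoxon rank-sum")
}
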