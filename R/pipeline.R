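# Convenience wrappers running the clonal-evolution stages end to end on a
# cohort mutation table: per-mutation CCF estimation across regions, clone
# clustering, tree reconstruction and trunk/branch labelling.

#' Per-mutation CCF matrix for one patient
#'
#' Runs [estimate_ccf()] on every observed (mutation, region) pair and
#' spreads the results into a mutations-by-regions matrix (0 = absent).
#'
#' @param reads Data.frame with `mutation_id`, `lesion_id`, `alt_tumor`,
#'   `depth_tumor`, `cn_total` for one patient.
#' @param purity Named per-region purity vector.
#' @return List with `ccf` (matrix), `multiplicity` (matrix, NA = absent).
#' @export
ccf_matrix_from_reads <- function(reads, purity) {
  regions <- names(purity)
  muts <- unique(reads$mutation_id)
  ccf <- matrix(0, length(muts), length(regions),
                dimnames = list(muts, regions))
  mult <- matrix(NA_real_, length(muts), length(regions),
                 dimnames = list(muts, regions))
  se <- matrix(NA_real_, length(muts), length(regions),
               dimnames = list(muts, regions))
  for (r in regions) {
    sub <- reads[reads$lesion_id == r, , drop = FALSE]
    if (!nrow(sub)) next
    vaf <- if ("vaf" %in% names(sub)) sub$vaf
           else sub$alt_tumor / sub$depth_tumor
    major <- if ("major_cn" %in% names(sub)) sub$major_cn else NULL
    est <- estimate_ccf(vaf, purity[[r]], sub$cn_total, major_cn = major)
    ccf[sub$mutation_id, r] <- est$ccf
    mult[sub$mutation_id, r] <- est$multiplicity
    if ("depth_tumor" %in% names(sub)) {
      se_vaf <- sqrt(pmax(vaf * (1 - vaf), 0.01) / sub$depth_tumor)
      se[sub$mutation_id, r] <- est$ccf * se_vaf / pmax(vaf, 0.02)
    }
  }
  list(ccf = ccf, multiplicity = mult, se = se)
}

#' Clonality and timing calls for one patient's mutation table
#'
#' Estimates per-region CCF and multiplicity, classifies each mutation as
#' clonal or subclonal across the patient's regions, and times clonal
#' mutations relative to genome doubling.
#'
#' @param reads Patient mutation table with `mutation_id`, `lesion_id`,
#'   `cn_total`, `major_cn` and either a `vaf` column or
#'   `alt_tumor`/`depth_tumor`.
#' @param purity Named per-region purity vector.
#' @param gd Named per-region logical genome-doubling flags.
#' @param ccf_threshold Per-region clonality threshold (default 0.9).
#' @return Data.frame `mutation_id`, `clonality`, `timing`.
#' @export
classify_and_time_mutations <- function(reads, purity, gd,
                                        ccf_threshold = 0.9) {
  cm <- ccf_matrix_from_reads(reads, purity)
  regions <- names(purity)
  out <- lapply(rownames(cm$ccf), function(id) {
    rows <- reads[reads$mutation_id == id, , drop = FALSE]
    observed <- regions %in% rows$lesion_id
    ccfs <- ifelse(observed, cm$ccf[id, ], NA)
    cl <- classify_mutation_clonality(ccfs, ccf_threshold)
    timing <- if (cl == "clonal") {
      time_clonal_mutation(cm$multiplicity[id, rows$lesion_id],
                           gd[rows$lesion_id], rows$major_cn)
    } else "subclonal"
    data.frame(mutation_id = id, clonality = cl, timing = timing,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Reconstruct a patient's clone tree from a mutation table
#'
#' @param reads Patient mutation table (see [ccf_matrix_from_reads()]).
#' @param purity Named per-region purity vector.
#' @param max_clusters Per-pattern cluster cap for [cluster_mutations()].
#' @param patient_id Stored on the returned tree.
#' @return List with `tree` (clone_tree), `ccf` (matrix), `trunk_branch`
#'   (output of [assign_trunk_branch()]).
#' @export
reconstruct_patient_tree <- function(reads, purity, max_clusters = 4,
                                     patient_id = NA_character_) {
  cm <- ccf_matrix_from_reads(reads, purity)
  # split threshold scaled to the sampling noise of the mean CCF estimates
  se_mean <- apply(cm$se, 1, function(s) {
    s <- s[!is.na(s)]
    if (!length(s)) NA_real_ else sqrt(mean(s^2) / length(s))
  })
  tol <- max(0.15, 2 * median(se_mean, na.rm = TRUE))
  clusters <- cluster_mutations(cm$ccf, max_clusters = max_clusters,
                                tol = tol)
  tree <- build_clone_tree(clusters, patient_id = patient_id)
  list(tree = tree, ccf = cm$ccf, multiplicity = cm$multiplicity,
       trunk_branch = assign_trunk_branch(tree))
}

#' Trunk/branch labels for a whole synthetic cohort
#'
#' Reconstructs every patient's clone tree and returns one row per
#' mutation with its trunk/branch label and driver status, the input
#' expected by [driver_fold_enrichment()].
#'
#' @param bundle Output of [generate_cohort()].
#' @param use_truth Use the generator's ground-truth labels instead of
#'   reconstructing trees (default FALSE).
#' @return Data.frame `patient_id`, `mutation_id`, `gene`, `label`,
#'   `is_driver`.
#' @export
cohort_trunk_branch_labels <- function(bundle, use_truth = FALSE) {
  maf <- bundle$cohort$mutations
  catalog <- bundle$cohort$catalog
  out <- lapply(names(bundle$truth$patients), function(p) {
    sub <- maf[maf$patient_id == p, , drop = FALSE]
    pt <- bundle$truth$patients[[p]]
    if (use_truth) {
      labels <- pt$trunk_label
    } else {
      rec <- reconstruct_patient_tree(sub, pt$purity, patient_id = p)
      labels <- rec$trunk_branch$labels
    }
    ids <- unique(sub$mutation_id)
    genes <- sub$gene[match(ids, sub$mutation_id)]
    data.frame(patient_id = p, mutation_id = ids, gene = genes,
               label = unname(labels[ids]),
               is_driver = genes %in% catalog$genes,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
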