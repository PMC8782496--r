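# Private/shared DMR classification over merged methylation peak sets,
# enrichment-fold matrices, phyloepigenetic trees and top-k
# hypermethylation similarity.

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1, end = peaks$end))
}

#' Classify DMRs as private or shared across samples
#'
#' The region universe is the merged union of significant peaks (q-value
#' below `q_cut`) over all samples. A region is private when it is
#' overlapped by significant peaks of exactly one sample, shared when by
#' two or more.
#'
#' @param peaksets Data.frame of peaks across samples (`sample_id`,
#'   `chrom`, `start`, `end` 0-based half-open, `enrichment_fold`,
#'   `q_value`), e.g. rbind of [read_peaks_bed()] outputs.
#' @param q_cut Significance cutoff on the q-value (default 0.01,
#'   exclusive).
#' @return A `dmr_partition`: list with `universe` (data.frame `chrom`,
#'   `start`, `end`, `region_id`, `n_samples`, `status`, `private_sample`),
#'   `private`, `shared` (row subsets) and `samples`.
#' @export
classify_dmrs <- function(peaksets, q_cut = 0.01) {
  samples <- unique(peaksets$sample_id)
  if (length(samples) < 2) stop("at least two samples required")
  sig <- peaksets[peaksets$q_value < q_cut, , drop = FALSE]
  if (!nrow(sig)) {
    universe <- data.frame(chrom = character(0), start = integer(0),
                           end = integer(0), region_id = character(0),
                           n_samples = integer(0), status = character(0),
                           private_sample = character(0))
    return(structure(list(universe = universe, private = universe,
                          shared = universe, samples = samples),
                     class = "dmr_partition"))
  }
  gr <- peaks_to_granges(sig)
  universe_gr <- GenomicRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(universe_gr, gr)
  by_region <- split(sig$sample_id[S4Vectors::subjectHits(hits)],
                     S4Vectors::queryHits(hits))
  n_samples <- integer(length(universe_gr))
  private_sample <- rep(NA_character_, length(universe_gr))
  for (i in seq_along(by_region)) {
    idx <- as.integer(names(by_region)[i])
    u <- unique(by_region[[i]])
    n_samples[idx] <- length(u)
    if (length(u) == 1) private_sample[idx] <- u
  }
  universe <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(universe_gr)),
    start = GenomicRanges::start(universe_gr) - 1L,
    end = GenomicRanges::end(universe_gr),
    n_samples = n_samples,
    status = ifelse(n_samples >= 2, "shared", "private"),
    private_sample = private_sample,
    stringsAsFactors = FALSE)
  universe$region_id <- sprintf("%s:%d-%d", universe$chrom, universe$start,
                                universe$end)
  structure(list(universe = universe,
                 private = universe[universe$status == "private", ,
                                    drop = FALSE],
                 shared = universe[universe$status == "shared", ,
                                   drop = FALSE],
                 samples = samples),
            class = "dmr_partition")
}

#' @export
print.dmr_partition <- function(x, ...) {
  cat(sprintf("dmr_partition: %d regions (%d private, %d shared) over %d samples\n",
              nrow(x$universe), nrow(x$private), nrow(x$shared),
              length(x$samples)))
  invisible(x)
}

#' Enrichment-fold matrix over the private-DMR regions
#'
#' For each private region and each sample, the maximum enrichment fold of
#' any of that sample's peaks (significant or not) overlapping the region;
#' 0 when the sample has no overlapping peak. Using all peaks, not only
#' significant ones, lets samples related to the private carrier show
#' sub-threshold enrichment at the same regions, which is what the
#' phyloepigenetic distances are built from.
#'
#' @param peaksets Full peak table across samples (all q-values).
#' @param partition A `dmr_partition` from [classify_dmrs()].
#' @return Regions-by-samples numeric matrix (rownames = region ids).
#' @export
private_fold_matrix <- function(peaksets, partition) {
  regions <- partition$private
  samples <- unique(peaksets$sample_id)
  mat <- matrix(0, nrow = nrow(regions), ncol = length(samples),
                dimnames = list(regions$region_id, samples))
  if (!nrow(regions)) return(mat)
  region_gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end))
  peak_gr <- peaks_to_granges(peaksets)
  hits <- GenomicRanges::findOverlaps(region_gr, peak_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  for (k in seq_along(qh)) {
    j <- match(peaksets$sample_id[sh[k]], samples)
    mat[qh[k], j] <- max(mat[qh[k], j], peaksets$enrichment_fold[sh[k]])
  }
  mat
}

#' Build a phyloepigenetic tree from enrichment-fold vectors
#'
#' Pairwise Euclidean distances between per-sample enrichment-fold vectors
#' (absent region = 0), then neighbour-joining (default) or UPGMA. When a
#' matched-normal sample is named, the tree is rooted on it as outgroup.
#'
#' @param fold_matrix Regions-by-samples matrix, e.g. from
#'   [private_fold_matrix()], or a precomputed [stats::dist] object.
#' @param root Sample to root the tree at (typically the matched normal),
#'   or `NULL` for an unrooted tree.
#' @param method `"nj"` (default) or `"upgma"`.
#' @return List with `distances` (dist), and, when >= 3 samples, `tree`
#'   (phylo) and `newick`; with fewer samples only the distance matrix.
#' @export
build_phyloepigenetic_tree <- function(fold_matrix, root = NULL,
                                       method = c("nj", "upgma")) {
  method <- match.arg(method)
  d <- if (inherits(fold_matrix, "dist")) fold_matrix
       else dist(t(fold_matrix))
  if (attr(d, "Size") < 3) {
    return(list(distances = d, tree = NULL, newick = NULL))
  }
  tree <- if (method == "nj") ape::nj(d)
          else ape::as.phylo(hclust(d, method = "average"))
  if (!is.null(root)) {
    stopifnot(root %in% tree$tip.label)
    tree <- ape::root(tree, outgroup = root, resolve.root = TRUE)
  }
  list(distances = d, tree = tree, newick = ape::write.tree(tree))
}

#' Top-k hypermethylation similarity between samples
#'
#' Each sample's top `k` regions by enrichment fold are taken over the
#' merged universe of all peaks; similarity between two samples is the
#' Jaccard index of their top-k region sets.
#'
#' @param peaksets Full peak table across samples.
#' @param k Number of top regions per sample (default 2000). When `k`
#'   exceeds the number of regions a sample covers, all its regions are
#'   used with a warning.
#' @return Samples-by-samples symmetric similarity matrix with unit
#'   diagonal.
#' @export
hypermethylation_similarity <- function(peaksets, k = 2000) {
  samples <- unique(peaksets$sample_id)
  universe_gr <- GenomicRanges::reduce(peaks_to_granges(peaksets))
  peak_gr <- peaks_to_granges(peaksets)
  hits <- GenomicRanges::findOverlaps(universe_gr, peak_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  fold <- matrix(0, nrow = length(universe_gr), ncol = length(samples),
                 dimnames = list(NULL, samples))
  for (idx in seq_along(qh)) {
    j <- match(peaksets$sample_id[sh[idx]], samples)
    fold[qh[idx], j] <- max(fold[qh[idx], j], peaksets$enrichment_fold[sh[idx]])
  }
  top_sets <- lapply(samples, function(s) {
    v <- fold[, s]
    covered <- which(v > 0)
    kk <- k
    if (kk > length(covered)) {
      warning("k exceeds covered region count for sample ", s,
              "; using all ", length(covered), " regions")
      kk <- length(covered)
    }
    covered[order(-v[covered])][seq_len(kk)]
  })
  names(top_sets) <- samples
  sim <- matrix(1, length(samples), length(samples),
                dimnames = list(samples, samples))
  for (i in seq_along(samples)) {
    for (j in seq_along(samples)) {
      if (j <= i) next
      a <- top_sets[[i]]
      b <- top_sets[[j]]
      jac <- if (!length(a) && !length(b)) 0
             else length(intersect(a, b)) / length(union(a, b))
      sim[i, j] <- jac
      sim[j, i] <- jac
    }
  }
  sim
}
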