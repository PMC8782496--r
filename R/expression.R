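# Replicate-free differential expression via a conservative posterior
# fold-change statistic, shared/private DEG partitioning, and intra- vs
# inter-tumoural transcriptional heterogeneity by hierarchical clustering.
#
# The statistic: with a Poisson read-count likelihood and flat prior, the
# posterior of the normalised expression of a gene with count k and size
# factor s is Gamma(k + 1, rate = s). For a tumour/normal pair the signed
# conservative log2 fold change is the c-quantile of the posterior log2
# ratio when that quantile is positive, the (1-c)-quantile when that is
# negative, and 0 otherwise (the posterior straddles no change). Because
# the ratio of independent Gamma variables is a scaled beta-prime variable,
# the quantile has the closed form
#   q_c(log2 (X/Y)) = log2( (s_n/s_t) * B / (1 - B) ),
# with B the c-quantile of Beta(k_t + 1, k_n + 1). The analytic path is
# exact and deterministic and is the default; a Monte-Carlo path is kept as
# an independent cross-check.

gfold_quantile <- function(kt, kn, st, sn, p) {
  b <- qbeta(p, kt + 1, kn + 1)
  log2((sn / st) * b / (1 - b))
}

#' Conservative posterior fold-change statistic (GFOLD-style)
#'
#' @param tumor Integer vector of tumour read counts (one per gene).
#' @param normal Integer vector of matched-normal read counts.
#' @param sf_tumor,sf_normal Size factors (> 0); by default the library-size
#'   ratio normalisation, each library total divided by the geometric mean
#'   of the two totals.
#' @param c Conservative quantile (default 0.01).
#' @param method `"analytic"` (exact beta-prime quantile, default) or
#'   `"mc"` (Monte-Carlo over posterior draws).
#' @param n_draws Posterior draws for the Monte-Carlo path (default 10000).
#' @param seed Seed for the Monte-Carlo path.
#' @param genes Optional gene names.
#' @return Data.frame with `gene`, `gfold` (signed conservative log2 fold
#'   change) and `log2fc` (posterior-mean log2 fold change).
#' @export
compute_gfold_statistic <- function(tumor, normal, sf_tumor = NULL,
                                    sf_normal = NULL, c = 0.01,
                                    method = c("analytic", "mc"),
                                    n_draws = 10000, seed = 1,
                                    genes = NULL) {
  method <- match.arg(method)
  if (any(tumor != round(tumor)) || any(normal != round(normal)))
    stop("counts must be integers")
  if (any(tumor < 0) || any(normal < 0)) stop("counts must be non-negative")
  if (length(tumor) != length(normal)) stop("count vectors differ in length")
  if (is.null(sf_tumor) || is.null(sf_normal)) {
    tot_t <- sum(as.numeric(tumor))
    tot_n <- sum(as.numeric(normal))
    gm <- sqrt(tot_t * tot_n)
    sf_tumor <- if (gm > 0) tot_t / gm else 1
    sf_normal <- if (gm > 0) tot_n / gm else 1
  }
  if (sf_tumor <= 0 || sf_normal <= 0) stop("size factors must be positive")
  if (method == "analytic") {
    lo <- gfold_quantile(tumor, normal, sf_tumor, sf_normal, c)
    hi <- gfold_quantile(tumor, normal, sf_tumor, sf_normal, 1 - c)
  } else {
    set.seed(seed)
    qs <- vapply(seq_along(tumor), function(i) {
      lt <- rgamma(n_draws, tumor[i] + 1, rate = sf_tumor)
      ln <- rgamma(n_draws, normal[i] + 1, rate = sf_normal)
      quantile(log2(lt / ln), c(c, 1 - c), names = FALSE, type = 7)
    }, numeric(2))
    lo <- qs[1, ]
    hi <- qs[2, ]
  }
  gfold <- ifelse(lo > 0, lo, ifelse(hi < 0, hi, 0))
  log2fc <- log2(((tumor + 1) / sf_tumor) / ((normal + 1) / sf_normal))
  if (is.null(genes)) {
    genes <- names(tumor)
    if (is.null(genes)) genes <- as.character(seq_along(tumor))
  }
  data.frame(gene = genes, gfold = gfold, log2fc = log2fc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call differentially expressed genes from fold-change results
#'
#' DEGs are genes with absolute conservative fold change above `threshold`
#' (default 2 on the log2 scale).
#'
#' @param results Data.frame from [compute_gfold_statistic()].
#' @param threshold Absolute gfold cutoff (default 2, exclusive).
#' @return Data.frame `gene`, `gfold`, `direction` ("up"/"down") for DEGs
#'   only.
#' @export
call_degs <- function(results, threshold = 2) {
  up <- results$gfold > threshold
  down <- results$gfold < -threshold
  out <- results[up | down, c("gene", "gfold"), drop = FALSE]
  out$direction <- ifelse(out$gfold > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Shared and private DEGs across a patient's lesions
#'
#' A gene is a shared DEG when it is differentially expressed with the same
#' direction in every lesion of the patient; each lesion's private DEGs are
#' its DEGs minus the shared set.
#'
#' @param deg_sets Named list (one element per lesion) of data.frames from
#'   [call_degs()].
#' @return List with `shared` (data.frame `gene`, `direction`) and
#'   `private` (named list of per-lesion data.frames).
#' @export
shared_private_degs <- function(deg_sets) {
  if (!length(deg_sets)) stop("at least one lesion required")
  keyed <- lapply(deg_sets, function(d) paste(d$gene, d$direction))
  shared_keys <- Reduce(intersect, keyed)
  first <- deg_sets[[1]]
  shared <- first[paste(first$gene, first$direction) %in% shared_keys,
                  c("gene", "direction"), drop = FALSE]
  rownames(shared) <- NULL
  private <- lapply(deg_sets, function(d) {
    out <- d[!(paste(d$gene, d$direction) %in% shared_keys), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  list(shared = shared, private = private)
}

#' Cluster lesions by fold-change profiles
#'
#' Hierarchical clustering (average linkage on Euclidean distances between
#' per-lesion log2 fold-change vectors), with a summary of mean
#' intra-patient vs inter-patient pairwise distances and the fraction of
#' patients whose lesions form a contiguous cluster (a monophyletic clade
#' of the dendrogram).
#'
#' @param fc_matrix Genes-by-lesions numeric matrix of log2 fold changes.
#' @param patients Character vector assigning each column to a patient.
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   "average").
#' @return List with `hclust`, `newick`, `intra_patient_distance`,
#'   `inter_patient_distance`, `fraction_patients_clustered`, `degenerate`
#'   (TRUE when all distances are zero).
#' @export
cluster_samples <- function(fc_matrix, patients, linkage = "average") {
  fc_matrix <- as.matrix(fc_matrix)
  if (ncol(fc_matrix) < 2) stop("at least two lesions required")
  stopifnot(length(patients) == ncol(fc_matrix))
  d <- dist(t(fc_matrix))
  degenerate <- all(d == 0)
  hc <- hclust(d, method = linkage)
  phy <- ape::as.phylo(hc)
  dm <- as.matrix(d)
  same <- outer(patients, patients, "==")
  diag(same) <- NA
  intra <- mean(dm[same & upper.tri(dm)], na.rm = TRUE)
  inter <- mean(dm[!same & upper.tri(dm)])
  mono <- vapply(unique(patients), function(p) {
    tips <- colnames(fc_matrix)[patients == p]
    if (length(tips) < 2) return(TRUE)
    ape::is.monophyletic(phy, tips)
  }, logical(1))
  list(hclust = hc, newick = ape::write.tree(phy),
       intra_patient_distance = intra, inter_patient_distance = inter,
       fraction_patients_clustered = mean(mono), degenerate = degenerate)
}
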