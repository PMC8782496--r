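# Synthetic multi-region cohort generator with full ground truth.
#
# Each patient gets a random rooted clone tree with a single truncal clone
# present in every region at CCF 1; branch clones receive region-specific
# cancer cell fractions from a recursive stick-breaking draw that respects
# CCF containment (a child's CCF never exceeds its parent's in any region).
# Mutations are assigned to clones, drivers with elevated odds on the
# truncal clone, and read counts are drawn binomially around the expected
# VAF = CCF * purity * m / (purity * CNt + 2(1 - purity)). Copy-number
# profiles plant clonal and subclonal arm events on a three-chromosome toy
# genome; genome-doubled patients carry a baseline of four copies and
# truncal mutations split into pre-doubling (multiplicity 2) and
# post-doubling (multiplicity 1) sets. Expression counts plant
# patient-level (shared) and lesion-level (private) differentially
# expressed genes; methylation peak sets plant patient-shared
# hypermethylated regions and per-lesion private DMRs; clinical records
# link simulated survival to copy-number burden through a log-hazard
# coefficient.

#' Simulation configuration
#'
#' Parameters of the synthetic multi-region cohort. Defaults emulate a
#' 19-patient pancreatic cohort sampled at 2-4 lesions per tumour with
#' mostly low tumour mutational burden, a dominant branch mutation load,
#' driver mutations concentrated on the trunk, and survival linked to
#' copy-number burden.
#'
#' @param n_patients Number of patients (default 19).
#' @param regions_per_patient Integer range of lesions per patient
#'   (default c(2, 4)).
#' @param n_clones Integer range of clones per patient including the trunk
#'   (default c(3, 6)).
#' @param purity Range of per-lesion tumour purity (default c(0.3, 0.8)).
#' @param mean_depth Mean sequencing depth at variant sites (default 120).
#' @param n_mutations Integer range of somatic mutations per patient
#'   (default c(200, 320)).
#' @param trunk_fraction Expected fraction of mutations on the truncal
#'   clone (default 0.08, matching a branch-dominant architecture).
#' @param driver_gene_fraction Fraction of the gene pool that is in the
#'   driver catalog (default 0.05).
#' @param truncal_driver_boost Odds multiplier for planting a driver
#'   mutation on the trunk rather than a branch (default 4).
#' @param gd_probability Probability that a patient is genome-doubled
#'   (default 0.4).
#' @param n_genes_expression Genes in the expression matrix (default 2000).
#' @param deg_fraction Fraction of genes planted as patient-level shared
#'   DEGs (default 0.05); an equal fraction is planted lesion-private.
#' @param n_peak_regions Methylation region universe size (default 800).
#' @param private_dmr_fraction Fraction of the universe reserved for
#'   per-lesion private DMRs (default 0.4).
#' @param burden_hazard_coef Per-percent log-hazard of CNV burden on
#'   simulated disease-free survival (default 0.06).
#' @param seed Global integer seed; all subsidiary draws derive from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 19,
                              regions_per_patient = c(2, 4),
                              n_clones = c(3, 6),
                              purity = c(0.3, 0.8),
                              mean_depth = 120,
                              n_mutations = c(200, 320),
                              trunk_fraction = 0.08,
                              driver_gene_fraction = 0.05,
                              truncal_driver_boost = 4,
                              gd_probability = 0.4,
                              n_genes_expression = 2000,
                              deg_fraction = 0.05,
                              n_peak_regions = 800,
                              private_dmr_fraction = 0.4,
                              burden_hazard_coef = 0.06,
                              seed = 1) {
  cfg <- list(n_patients = n_patients,
              regions_per_patient = regions_per_patient,
              n_clones = n_clones, purity = purity, mean_depth = mean_depth,
              n_mutations = n_mutations, trunk_fraction = trunk_fraction,
              driver_gene_fraction = driver_gene_fraction,
              truncal_driver_boost = truncal_driver_boost,
              gd_probability = gd_probability,
              n_genes_expression = n_genes_expression,
              deg_fraction = deg_fraction,
              n_peak_regions = n_peak_regions,
              private_dmr_fraction = private_dmr_fraction,
              burden_hazard_coef = burden_hazard_coef, seed = seed)
  fracs <- c(cfg$purity, cfg$trunk_fraction, cfg$driver_gene_fraction,
             cfg$gd_probability, cfg$deg_fraction, cfg$private_dmr_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  counts <- c(cfg$n_patients, cfg$regions_per_patient, cfg$n_clones,
              cfg$n_mutations, cfg$n_genes_expression, cfg$n_peak_regions)
  if (any(counts < 1)) stop("counts must be >= 1")
  if (cfg$purity[1] <= 0) stop("purity must be positive")
  if (cfg$truncal_driver_boost <= 0) stop("boost must be positive")
  structure(cfg, class = "simulation_config")
}

# sample() treats a length-1 numeric x as 1:x; this keeps set semantics
safe_sample <- function(x, size) x[sample.int(length(x), size)]

range_draw <- function(rng, n = 1) {
  if (length(rng) == 1) rep(rng, n) else sample(seq(rng[1], rng[2]), n,
                                                replace = TRUE)
}

# Random rooted clone tree: clone 1 is truncal; each later clone attaches
# to a uniformly chosen earlier clone.
sample_clone_tree <- function(n_clones) {
  parent <- c(0L, vapply(seq_len(n_clones - 1) + 1L, function(i) {
    sample.int(i - 1L, 1L)
  }, integer(1)))
  parent
}

# Region-specific clone CCFs honouring containment. The trunk is 1 in every
# region; each branch clone is present in a random non-empty subset of
# regions, and within a region the children of a node share at most
# max_branch_ccf of the parent's CCF via a stick-breaking draw.
sample_clone_ccfs <- function(parent, n_regions, max_branch_ccf = 0.7,
                              min_ccf = 0.1) {
  n_clones <- length(parent)
  ccf <- matrix(0, n_clones, n_regions)
  ccf[1, ] <- 1
  present <- matrix(FALSE, n_clones, n_regions)
  present[1, ] <- TRUE
  for (k in seq_len(n_clones)[-1]) {
    sub <- sample(c(TRUE, FALSE), n_regions, replace = TRUE,
                  prob = c(0.6, 0.4))
    if (!any(sub)) sub[sample.int(n_regions, 1)] <- TRUE
    present[k, ] <- sub & present[parent[k], ]
    if (!any(present[k, ])) {
      r <- which(present[parent[k], ])[1]
      present[k, r] <- TRUE
    }
  }
  for (r in seq_len(n_regions)) {
    for (k in seq_len(n_clones)[-1]) {
      if (!present[k, r]) next
      p <- parent[k]
      sibs_done <- which(parent == p & seq_len(n_clones) < k)
      budget <- ccf[p, r] * max_branch_ccf - sum(ccf[sibs_done, r])
      if (budget <= min_ccf) {
        present[k, r] <- FALSE
        next
      }
      ccf[k, r] <- runif(1, min_ccf, budget)
    }
  }
  # a clone squeezed out of every region is dropped from presence but kept
  # in the tree with zero CCF; mutations are only assigned to live clones
  list(ccf = ccf, present = present)
}

toy_genome_segments <- function(arms) {
  data.frame(chrom = arms$chrom, start = arms$start, end = arms$end,
             arm = paste0(arms$chrom, arms$arm), stringsAsFactors = FALSE)
}

# Plant per-region segment profiles on the toy genome. Clonal arm events
# appear in all regions, subclonal ones in a strict subset; a partial-arm
# altered segment (never crossing the arm-call threshold) adds continuous
# burden variation. GD patients use a baseline of 4 copies (major 2 /
# minor 2).
simulate_segments <- function(patient_id, regions, gd, arms,
                              n_clonal_events = NULL,
                              n_subclonal_events = NULL) {
  base <- toy_genome_segments(arms)
  n_arms <- nrow(base)
  baseline_cn <- if (gd) 4 else 2
  baseline_major <- if (gd) 2 else 1
  if (is.null(n_clonal_events))
    n_clonal_events <- sample(0:2, 1, prob = c(0.45, 0.35, 0.2))
  if (is.null(n_subclonal_events)) n_subclonal_events <- sample(0:1, 1)
  event_arms <- if (n_clonal_events + n_subclonal_events > 0)
    sample.int(n_arms, min(n_clonal_events + n_subclonal_events, n_arms))
  else integer(0)
  clonal_arms <- head(event_arms, n_clonal_events)
  subclonal_arms <- setdiff(event_arms, clonal_arms)
  arm_state <- setNames(rep("neutral", n_arms), base$arm)
  arm_state[clonal_arms] <- sample(c("gain", "loss"), length(clonal_arms),
                                   replace = TRUE)
  arm_state[subclonal_arms] <- sample(c("gain", "loss"),
                                      length(subclonal_arms), replace = TRUE)
  sub_regions <- lapply(subclonal_arms, function(a) {
    if (length(regions) == 1) return(regions)
    sample(regions, sample.int(max(length(regions) - 1, 1), 1))
  })
  names(sub_regions) <- base$arm[subclonal_arms]
  # partial-arm alteration on one neutral arm, shared by all regions
  partial <- NULL
  neutral_arms <- setdiff(seq_len(n_arms), event_arms)
  if (length(neutral_arms) && runif(1) < 0.6) {
    pa <- if (length(neutral_arms) == 1) neutral_arms
          else sample(neutral_arms, 1)
    frac <- runif(1, 0.05, 0.6)
    partial <- list(arm = pa,
                    split_at = round(base$start[pa] +
                                       frac * (base$end[pa] - base$start[pa])),
                    state = sample(c("gain", "loss"), 1))
  }
  profiles <- lapply(regions, function(r) {
    segs <- base[c("chrom", "start", "end")]
    segs$total_cn <- baseline_cn
    segs$major_cn <- baseline_major
    for (i in seq_len(n_arms)) {
      st <- arm_state[i]
      if (st == "neutral") next
      active <- if (base$arm[i] %in% names(sub_regions))
        r %in% sub_regions[[base$arm[i]]] else TRUE
      if (!active) next
      if (st == "gain") {
        # gain clears the 1.25x ploidy cutoff: 3 on diploid, 6 on doubled
        segs$total_cn[i] <- if (gd) 6 else 3
        segs$major_cn[i] <- if (gd) 4 else 2
      } else {
        # loss clears the 0.75x cutoff: 1 on diploid, 3 on doubled;
        # diploid losses are LOH by construction
        segs$total_cn[i] <- if (gd) 3 else 1
        segs$major_cn[i] <- if (gd) 2 else 1
      }
    }
    if (!is.null(partial)) {
      i <- partial$arm
      left <- segs[i, , drop = FALSE]
      left$end <- partial$split_at
      right <- segs[i, , drop = FALSE]
      right$start <- partial$split_at + 1
      if (partial$state == "gain") {
        left$total_cn <- if (gd) 6 else 3
        left$major_cn <- if (gd) 4 else 2
      } else {
        left$total_cn <- if (gd) 3 else 1
        left$major_cn <- if (gd) 2 else 1
      }
      segs <- rbind(segs[-i, , drop = FALSE], left, right)
      segs <- segs[order(segs$chrom, segs$start), , drop = FALSE]
    }
    segs$minor_cn <- segs$total_cn - segs$major_cn
    rownames(segs) <- NULL
    segs
  })
  names(profiles) <- regions
  true_clonality <- ifelse(arm_state == "neutral", "absent",
                           ifelse(base$arm %in% names(sub_regions),
                                  "subclonal", "clonal"))
  list(profiles = profiles,
       truth = data.frame(arm = base$arm, state = unname(arm_state),
                          clonality = unname(true_clonality),
                          stringsAsFactors = FALSE))
}

expected_vaf <- function(ccf, purity, m, cn_total) {
  ccf * purity * m / (purity * cn_total + 2 * (1 - purity))
}

#' Simulate per-region mutation read counts for one patient
#'
#' Draws alt read counts binomially around the expected VAF implied by the
#' clone CCFs, purities, local copy number and multiplicity; germline alt
#' reads are near zero. With `noise = "none"` the alt count is the rounded
#' expectation, which downstream CCF estimation inverts exactly.
#'
#' @param mutations Data.frame with `mutation_id`, `clone`, `chrom`, `pos`,
#'   `multiplicity_intended`.
#' @param clone_ccf Clones-by-regions CCF matrix.
#' @param purity Named per-region purity vector.
#' @param profiles Named list of per-region segment data.frames.
#' @param depth Mean sequencing depth.
#' @param noise `"binomial"` (default) or `"none"`.
#' @return Data.frame of per-mutation, per-region read counts and the true
#'   CCF/multiplicity.
#' @export
simulate_mutations <- function(mutations, clone_ccf, purity, profiles,
                               depth = 120, noise = c("binomial", "none")) {
  noise <- match.arg(noise)
  regions <- names(profiles)
  rows <- lapply(regions, function(r) {
    segs <- profiles[[r]]
    seg_idx <- vapply(seq_len(nrow(mutations)), function(i) {
      which(segs$chrom == mutations$chrom[i] &
              segs$start <= mutations$pos[i] & segs$end >= mutations$pos[i])[1]
    }, integer(1))
    cn <- segs$total_cn[seg_idx]
    major <- segs$major_cn[seg_idx]
    if (any(cn == 0)) stop("mutation on a zero-copy segment")
    ccf <- clone_ccf[mutations$clone, r]
    m <- pmin(mutations$multiplicity_intended, major)
    m <- pmax(m, 1)
    vaf <- expected_vaf(ccf, purity[[r]], m, cn)
    dp <- if (noise == "binomial") pmax(rpois(nrow(mutations), depth), 20)
          else rep(depth, nrow(mutations))
    alt <- if (noise == "binomial") rbinom(nrow(mutations), dp, vaf)
           else round(dp * vaf)
    data.frame(mutation_id = mutations$mutation_id, lesion_id = r,
               clone = mutations$clone, chrom = mutations$chrom,
               pos = mutations$pos, depth_tumor = dp, alt_tumor = alt,
               cn_total = cn, major_cn = major, vaf_expected = vaf,
               true_multiplicity = ifelse(ccf > 0, m, NA_real_),
               true_ccf = ccf, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # a site with no supporting reads is not called in that region
  out[out$alt_tumor > 0, , drop = FALSE]
}

#' Simulate clinical records from per-patient burdens
#'
#' Disease-free survival times are exponential with hazard proportional to
#' `exp(coef * (burden - mean(burden)))`; administrative censoring is drawn
#' uniformly on 18-36 months. Overall survival adds an exponential
#' post-relapse time. Liver-metastasis probability is logistic and
#' monotone increasing in burden.
#'
#' @param burdens Named per-patient average CNV burden values (percent).
#' @param coef Per-percent log-hazard coefficient (default 0.06).
#' @param base_median_dfs Median DFS in months at the mean burden
#'   (default 14).
#' @return Data.frame of clinical records (one row per patient) with the
#'   same derived columns as [read_clinical_table()].
#' @export
simulate_clinical <- function(burdens, coef = 0.06, base_median_dfs = 14) {
  n <- length(burdens)
  ids <- names(burdens)
  if (is.null(ids)) ids <- paste0("P", seq_len(n))
  centred <- burdens - mean(burdens)
  rate <- log(2) / base_median_dfs * exp(coef * centred)
  t_dfs <- rexp(n, rate)
  censor <- runif(n, 18, 36)
  dfs <- pmin(t_dfs, censor)
  relapse <- t_dfs <= censor
  t_os <- t_dfs + rexp(n, log(2) / 6)
  os <- pmin(t_os, censor)
  dead <- t_os <= censor
  dead[!relapse] <- FALSE
  os[!relapse] <- censor[!relapse]
  p_liver <- plogis(-3.5 + 0.12 * burdens)
  liver <- relapse & (runif(n) < p_liver)
  metastasis <- ifelse(liver, "Yes (liver metastasis)",
                       ifelse(relapse, "Yes (other metastasis)", "No"))
  out <- data.frame(patient_id = ids,
                    status = ifelse(dead, "Dead", "Live"),
                    metastasis_after_surgery = metastasis,
                    os_months = round(os, 1), dfs_months = round(dfs, 1),
                    average_cnv_burden = unname(burdens),
                    stringsAsFactors = FALSE)
  out$liver_metastasis <- liver
  out$relapse_or_metastasis <- relapse
  out$dead <- dead
  out$survival_excluded <- FALSE
  out$disease_specific_death <- dead
  out
}

simulate_expression <- function(patients, lesions_by_patient, n_genes,
                                deg_fraction) {
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  base_mean <- exp(rnorm(n_genes, log(80), 1))
  n_deg <- max(1, round(n_genes * deg_fraction))
  shared_deg <- list()
  private_deg <- list()
  counts <- list()
  normals <- list()
  pool <- seq_len(n_genes)
  for (p in patients) {
    idx <- sample(pool, n_deg)
    sign_p <- sample(c(1, -1), n_deg, replace = TRUE)
    shared_deg[[p]] <- data.frame(gene = genes[idx],
                                  direction = ifelse(sign_p > 0, "up", "down"),
                                  stringsAsFactors = FALSE)
    normals[[p]] <- rpois(n_genes, base_mean)
    for (l in lesions_by_patient[[p]]) {
      mean_l <- base_mean
      shift <- rep(0, n_genes)
      shift[idx] <- sign_p * runif(n_deg, 3.5, 5)
      pidx <- sample(setdiff(pool, idx), max(1, round(n_deg / 2)))
      psign <- sample(c(1, -1), length(pidx), replace = TRUE)
      shift[pidx] <- psign * runif(length(pidx), 3.5, 5)
      private_deg[[l]] <- data.frame(gene = genes[pidx],
                                     direction = ifelse(psign > 0, "up",
                                                        "down"),
                                     stringsAsFactors = FALSE)
      counts[[l]] <- rpois(n_genes, mean_l * 2^shift)
    }
  }
  lesion_ids <- unlist(lesions_by_patient, use.names = FALSE)
  count_mat <- do.call(cbind, counts[lesion_ids])
  colnames(count_mat) <- lesion_ids
  normal_mat <- do.call(cbind, normals[patients])
  colnames(normal_mat) <- paste0(patients, "-N")
  rownames(count_mat) <- rownames(normal_mat) <- genes
  list(tumor = count_mat, normal = normal_mat, shared_deg = shared_deg,
       private_deg = private_deg)
}

simulate_methylation <- function(patients, lesions_by_patient,
                                 n_peak_regions, private_dmr_fraction,
                                 arms) {
  # fixed universe of candidate regions tiled over the toy genome
  genome_len <- sum(arms$length)
  width <- 2000
  gap <- floor(genome_len / n_peak_regions)
  offs <- (seq_len(n_peak_regions) - 1) * gap
  bounds <- cumsum(chromosome_lengths(arms))
  chrom_of <- function(x) names(bounds)[findInterval(x, c(0, bounds),
                                                     rightmost.closed = TRUE)]
  chrom_start <- c(0, head(bounds, -1))
  names(chrom_start) <- names(bounds)
  universe <- data.frame(
    chrom = chrom_of(offs + 1),
    start = offs - chrom_start[chrom_of(offs + 1)],
    stringsAsFactors = FALSE)
  universe$start <- pmax(universe$start, 0)
  universe$end <- universe$start + width
  n_private_pool <- round(n_peak_regions * private_dmr_fraction)
  private_pool <- sample.int(n_peak_regions, n_private_pool)
  background_pool <- setdiff(seq_len(n_peak_regions), private_pool)
  peaksets <- list()
  truth_private <- list()
  free_private <- private_pool
  for (p in patients) {
    lesions <- lesions_by_patient[[p]]
    # allocate each lesion's private regions up front so sister lesions can
    # carry sub-threshold enrichment at the same regions
    priv_idx <- list()
    for (l in lesions) {
      n_priv <- min(max(2, rpois(1, 2) + 1), length(free_private))
      priv_idx[[l]] <- if (n_priv > 0) safe_sample(free_private, n_priv)
                       else integer(0)
      free_private <- setdiff(free_private, priv_idx[[l]])
      truth_private[[l]] <- universe[priv_idx[[l]], , drop = FALSE]
    }
    patient_priv <- unlist(priv_idx, use.names = FALSE)
    # patient-level hypermethylated block shared by all lesions
    n_shared <- max(5, round(length(background_pool) * 0.25))
    shared_idx <- sample(background_pool, n_shared)
    shared_fold <- runif(n_shared, 4, 8)
    for (l in lesions) {
      own <- priv_idx[[l]]
      sig <- data.frame(
        universe[c(shared_idx, own), , drop = FALSE],
        enrichment_fold = c(shared_fold + rnorm(n_shared, 0, 0.3),
                            runif(length(own), 3, 6)),
        q_value = runif(n_shared + length(own), 1e-6, 0.009))
      # sub-threshold enrichment at sister lesions' private regions binds
      # a patient's lesions together in the phyloepigenetic distances
      sister_idx <- setdiff(patient_priv, own)
      nonsig <- data.frame(
        universe[sister_idx, , drop = FALSE],
        enrichment_fold = runif(length(sister_idx), 0.5, 1.5),
        q_value = runif(length(sister_idx), 0.02, 0.5))
      ps <- rbind(sig, nonsig)
      ps$sample_id <- l
      peaksets[[l]] <- ps[c("sample_id", "chrom", "start", "end",
                            "enrichment_fold", "q_value")]
    }
    # matched normal: background methylation only
    nb <- sample(background_pool, max(5, round(n_shared / 2)))
    pn <- data.frame(universe[nb, , drop = FALSE],
                     enrichment_fold = runif(length(nb), 1, 2.5),
                     q_value = runif(length(nb), 1e-6, 0.009))
    pn$sample_id <- paste0(p, "-N")
    peaksets[[paste0(p, "-N")]] <- pn[c("sample_id", "chrom", "start",
                                        "end", "enrichment_fold", "q_value")]
  }
  list(peaks = do.call(rbind, c(peaksets, list(make.row.names = FALSE))),
       truth_private = truth_private)
}

#' Generate a synthetic multi-region cohort with ground truth
#'
#' @param config A [simulation_config()].
#' @param layers Which data layers to generate (all by default); dropping
#'   layers speeds up simulation studies that only need mutations and
#'   copy number.
#' @return List with `cohort` (data layers: `mutations` MAF-like table,
#'   `segment_profiles`, `expression`, `methylation`, `clinical`, `arms`,
#'   `catalog`) and `truth` (per-patient clone trees, assignments,
#'   per-region clone CCFs, timing labels, arm events, GD flags, DEG and
#'   private-DMR sets, burdens).
#' @export
generate_cohort <- function(config = simulation_config(),
                            layers = c("mutations", "cnv", "expression",
                                       "methylation", "clinical")) {
  stopifnot(inherits(config, "simulation_config"))
  layers <- match.arg(layers, several.ok = TRUE)
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 8)
  arms <- load_arm_definitions("toy")
  patients <- paste0("P", seq_len(config$n_patients))

  set.seed(sub_seeds[1])
  n_regions <- range_draw(config$regions_per_patient, config$n_patients)
  n_clones <- range_draw(config$n_clones, config$n_patients)
  gd_flags <- runif(config$n_patients) < config$gd_probability
  names(gd_flags) <- patients
  lesions_by_patient <- setNames(lapply(seq_len(config$n_patients),
    function(i) paste0(patients[i], "-L", seq_len(n_regions[i]))), patients)

  catalog <- default_driver_catalog()
  n_genes_pool <- max(500, round(length(catalog$genes) /
                                   config$driver_gene_fraction))
  gene_pool <- c(catalog$genes,
                 sprintf("SYN%04d", seq_len(n_genes_pool -
                                              length(catalog$genes))))

  truth <- list()
  mut_tables <- list()
  seg_profiles <- list()
  burdens <- setNames(numeric(config$n_patients), patients)

  set.seed(sub_seeds[2])
  for (i in seq_len(config$n_patients)) {
    p <- patients[i]
    regions <- lesions_by_patient[[p]]
    parent <- sample_clone_tree(n_clones[i])
    ccfs <- sample_clone_ccfs(parent, length(regions))
    clone_ccf <- ccfs$ccf
    colnames(clone_ccf) <- regions
    live <- which(rowSums(clone_ccf) > 0)

    seg <- simulate_segments(p, regions, gd_flags[[p]], arms)
    purity <- setNames(runif(length(regions), config$purity[1],
                             config$purity[2]), regions)

    n_mut <- range_draw(config$n_mutations)
    w <- rep((1 - config$trunk_fraction) / max(length(live) - 1, 1),
             length(live))
    w[live == 1] <- config$trunk_fraction
    clone_of <- sample(live, n_mut, replace = TRUE, prob = w)
    is_trunk <- clone_of == 1
    # drivers land on the trunk with boosted odds
    p_driver_branch <- 0.05
    p_driver_trunk <- min(p_driver_branch * config$truncal_driver_boost, 0.9)
    is_driver <- runif(n_mut) < ifelse(is_trunk, p_driver_trunk,
                                       p_driver_branch)
    driver_genes <- catalog$genes
    passenger_genes <- setdiff(gene_pool, driver_genes)
    gene <- ifelse(is_driver, sample(driver_genes, n_mut, replace = TRUE),
                   sample(passenger_genes, n_mut, replace = TRUE))
    # positions uniform over the toy genome
    seg_pick <- sample.int(nrow(arms), n_mut, replace = TRUE,
                           prob = arms$length)
    pos <- round(runif(n_mut, arms$start[seg_pick], arms$end[seg_pick]))
    # genome-doubled patients: truncal mutations split into pre-doubling
    # (multiplicity 2) and post-doubling (multiplicity 1)
    pre_gd <- is_trunk & gd_flags[[p]] & runif(n_mut) < 0.6
    m_intended <- ifelse(pre_gd, 2, 1)
    consequence <- sample(c("missense", "nonsense", "splice", "frameshift",
                            "synonymous"),
                          n_mut, replace = TRUE,
                          prob = c(0.62, 0.04, 0.02, 0.02, 0.30))
    mut <- data.frame(
      mutation_id = sprintf("%s_M%04d", p, seq_len(n_mut)),
      clone = clone_of, gene = gene, chrom = arms$chrom[seg_pick],
      pos = pos, consequence = consequence,
      multiplicity_intended = m_intended, is_driver_gene = is_driver,
      stringsAsFactors = FALSE)

    reads <- simulate_mutations(mut, clone_ccf, purity, seg$profiles,
                                depth = config$mean_depth)
    maf <- merge(reads, mut[c("mutation_id", "gene", "consequence",
                              "is_driver_gene")], by = "mutation_id")
    maf$patient_id <- p
    maf$ref <- "A"
    maf$alt <- "T"
    maf$depth_normal <- pmax(rpois(nrow(maf), config$mean_depth), 20)
    maf$alt_normal <- rbinom(nrow(maf), maf$depth_normal, 0.001)
    maf$popfreq_max <- 0
    maf$fathmm_mkl <- ifelse(maf$is_driver_gene,
                             runif(nrow(maf), 0.6, 1),
                             runif(nrow(maf), 0, 0.5))
    maf$sift <- ifelse(maf$is_driver_gene, runif(nrow(maf), 0, 0.05),
                       runif(nrow(maf), 0.1, 1))
    mut_tables[[p]] <- maf

    profs <- lapply(regions, function(r) {
      # baseline ploidy (2, or 4 after doubling) is the reference state,
      # as a copy-number caller would report it
      segment_profile(r, seg$profiles[[r]], purity = purity[[r]],
                      ploidy = if (gd_flags[[p]]) 4 else 2, patient_id = p)
    })
    names(profs) <- regions
    seg_profiles[[p]] <- profs
    burdens[p] <- mean(vapply(profs, compute_cnv_burden, numeric(1)))

    timing <- ifelse(!is_trunk, "subclonal",
                     if (gd_flags[[p]])
                       ifelse(pre_gd, "clonal early", "clonal late")
                     else "clonal untimed")
    truth[[p]] <- list(
      parent = parent, clone_ccf = clone_ccf,
      clone_assignment = setNames(mut$clone, mut$mutation_id),
      trunk_label = setNames(ifelse(is_trunk, "trunk", "branch"),
                             mut$mutation_id),
      timing = setNames(timing, mut$mutation_id),
      is_driver = setNames(is_driver, mut$mutation_id),
      gd = gd_flags[[p]], purity = purity, arm_events = seg$truth)
  }

  mutations <- do.call(rbind, c(mut_tables, list(make.row.names = FALSE)))

  expression <- NULL
  if ("expression" %in% layers) {
    set.seed(sub_seeds[3])
    expression <- simulate_expression(patients, lesions_by_patient,
                                      config$n_genes_expression,
                                      config$deg_fraction)
  }
  methylation <- NULL
  if ("methylation" %in% layers) {
    set.seed(sub_seeds[4])
    methylation <- simulate_methylation(patients, lesions_by_patient,
                                        config$n_peak_regions,
                                        config$private_dmr_fraction, arms)
  }
  clinical <- NULL
  if ("clinical" %in% layers) {
    set.seed(sub_seeds[5])
    clinical <- simulate_clinical(burdens, coef = config$burden_hazard_coef)
  }

  list(cohort = list(mutations = mutations, segment_profiles = seg_profiles,
                     expression = expression, methylation = methylation,
                     clinical = clinical, arms = arms, catalog = catalog),
       truth = list(patients = truth, burdens = burdens,
                    gd = gd_flags,
                    lesions_by_patient = lesions_by_patient,
                    expression = if (is.null(expression)) NULL else
                      expression[c("shared_deg", "private_deg")],
                    methylation = if (is.null(methylation)) NULL else
                      methylation["truth_private"]))
}

#' Write a synthetic cohort to disk in the analysis formats
#'
#' MAF-like mutation TSV, per-lesion SEG tables, expression TSVs, peak BED
#' and clinical TSV, plus a JSON ground-truth sidecar when jsonlite is
#' available.
#'
#' @param bundle Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  co <- bundle$cohort
  write_maf(co$mutations, file.path(dir, "mutations.maf.tsv"))
  segs <- do.call(rbind, lapply(unlist(co$segment_profiles,
                                       recursive = FALSE), function(pr) {
    cbind(sample_id = pr$sample_id, pr$segments,
          purity = pr$purity, ploidy = pr$ploidy)
  }))
  write_seg(segs, file.path(dir, "segments.seg.tsv"))
  if (!is.null(co$expression)) {
    write_count_matrix(co$expression$tumor, file.path(dir, "counts_tumor.tsv"))
    write_count_matrix(co$expression$normal,
                       file.path(dir, "counts_normal.tsv"))
  }
  if (!is.null(co$methylation))
    write_peaks_bed(co$methylation$peaks, file.path(dir, "peaks.bed"))
  if (!is.null(co$clinical))
    write.table(co$clinical, file.path(dir, "clinical.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- bundle$truth
    jsonlite::write_json(
      list(burdens = as.list(truth$burdens), gd = as.list(truth$gd)),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}
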