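# Somatic variant filtering, tumour mutational burden and candidate driver
# annotation for multi-region whole-exome cohorts.

NONSYNONYMOUS_CLASSES <- c("missense", "nonsense", "splice", "frameshift",
                           "inframe")
CONSEQUENCE_CLASSES <- c(NONSYNONYMOUS_CLASSES, "synonymous")

#' Filter somatic variant calls
#'
#' Applies the standard multi-region WES somatic filters: sequencing depth
#' of at least 20 reads at the variant site in both tumour and matched
#' normal, at most 5 alternative reads in the normal, at least 5
#' alternative reads in the tumour, and a maximum population allele
#' frequency below 1% across ExAC / ESP6500 / gnomAD. Missing population
#' frequency is treated as 0 (a variant absent from all databases).
#'
#' @param calls Data.frame of variant calls with columns `depth_tumor`,
#'   `depth_normal`, `alt_tumor`, `alt_normal` and optionally `popfreq_max`.
#' @param min_depth Depth threshold applied to both samples (default 20,
#'   inclusive).
#' @param max_alt_normal Maximum alternative reads in the normal (default 5).
#' @param min_alt_tumor Minimum alternative reads in the tumour (default 5).
#' @param max_popfreq Population-frequency ceiling (default 0.01, exclusive).
#' @return The input with logical columns `passed_filter` and
#'   `is_nonsynonymous` added.
#' @export
filter_somatic_variants <- function(calls, min_depth = 20,
                                    max_alt_normal = 5, min_alt_tumor = 5,
                                    max_popfreq = 0.01) {
  if (nrow(calls) == 0) {
    calls$passed_filter <- logical(0)
    calls$is_nonsynonymous <- logical(0)
    return(calls)
  }
  req <- c("depth_tumor", "depth_normal", "alt_tumor", "alt_normal")
  missing_cols <- setdiff(req, names(calls))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  reads <- as.matrix(calls[req])
  if (any(reads < 0, na.rm = TRUE)) stop("negative read counts")
  if (any(calls$alt_tumor > calls$depth_tumor, na.rm = TRUE) ||
      any(calls$alt_normal > calls$depth_normal, na.rm = TRUE))
    stop("alt reads exceed depth")
  popfreq <- if ("popfreq_max" %in% names(calls)) calls$popfreq_max else 0
  popfreq[is.na(popfreq)] <- 0
  calls$passed_filter <- calls$depth_tumor >= min_depth &
    calls$depth_normal >= min_depth &
    calls$alt_normal <= max_alt_normal &
    calls$alt_tumor >= min_alt_tumor &
    popfreq < max_popfreq
  calls$is_nonsynonymous <- calls$consequence %in% NONSYNONYMOUS_CLASSES
  calls
}

#' Tumour mutational burden
#'
#' Number of filtered nonsynonymous somatic mutations per megabase of exome.
#' The default exome size of 38 Mb corresponds to a standard whole-exome
#' capture design.
#'
#' @param table Filtered mutation table (see [filter_somatic_variants()]).
#' @param exome_mb Exome size in megabases (default 38).
#' @return Mutations per Mb (single non-negative number).
#' @export
compute_tmb <- function(table, exome_mb = 38) {
  if (exome_mb <= 0) stop("exome_mb must be positive")
  if (!"passed_filter" %in% names(table))
    stop("table must be filtered first (passed_filter column missing)")
  sum(table$passed_filter & table$is_nonsynonymous) / exome_mb
}

#' Per-lesion and per-patient TMB for a cohort table
#'
#' @param table Filtered multi-lesion mutation table with `patient_id` and
#'   `lesion_id` columns.
#' @param exome_mb Exome size in megabases.
#' @return Data.frame with one row per lesion (`patient_id`, `lesion_id`,
#'   `tmb`).
#' @export
tmb_by_lesion <- function(table, exome_mb = 38) {
  keep <- table$passed_filter & table$is_nonsynonymous
  key <- paste(table$patient_id, table$lesion_id, sep = "\r")
  counts <- tapply(keep, key, sum)
  ids <- do.call(rbind, strsplit(names(counts), "\r", fixed = TRUE))
  data.frame(patient_id = ids[, 1], lesion_id = ids[, 2],
             tmb = as.numeric(counts) / exome_mb,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mutation-type proportions and multi-hit genes
#'
#' Computes the proportion of each nonsynonymous consequence class among
#' filtered nonsynonymous mutations, and flags genes carrying two or more
#' distinct nonsynonymous mutations within a single lesion ("multi-hit").
#'
#' @param table Filtered mutation table.
#' @return List with `proportions` (named numeric vector summing to 1 over
#'   observed nonsynonymous classes) and `multi_hit` (data.frame of
#'   `patient_id`, `lesion_id`, `gene`, `n_mutations`).
#' @export
classify_mutation_types <- function(table) {
  unknown <- setdiff(unique(table$consequence), CONSEQUENCE_CLASSES)
  if (length(unknown))
    stop("unknown consequence labels: ", paste(unknown, collapse = ", "))
  keep <- table[table$passed_filter & table$is_nonsynonymous, , drop = FALSE]
  if (nrow(keep) == 0) {
    return(list(proportions = setNames(numeric(0), character(0)),
                multi_hit = data.frame(patient_id = character(0),
                                       lesion_id = character(0),
                                       gene = character(0),
                                       n_mutations = integer(0))))
  }
  tab <- table(keep$consequence)
  proportions <- as.numeric(tab) / sum(tab)
  names(proportions) <- names(tab)
  key <- paste(keep$patient_id, keep$lesion_id, keep$gene, sep = "\r")
  counts <- table(key)
  multi <- names(counts)[counts >= 2]
  parts <- do.call(rbind, strsplit(multi, "\r", fixed = TRUE))
  multi_hit <- if (length(multi)) {
    data.frame(patient_id = parts[, 1], lesion_id = parts[, 2],
               gene = parts[, 3], n_mutations = as.integer(counts[multi]),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(patient_id = character(0), lesion_id = character(0),
               gene = character(0), n_mutations = integer(0))
  }
  list(proportions = proportions, multi_hit = multi_hit)
}

#' Construct a driver-gene catalog
#'
#' @param pan_cancer Character vector of pan-cancer driver gene symbols.
#' @param pdac Character vector of PDAC-specific driver gene symbols.
#' @return A `driver_catalog` object (list with unique `pan_cancer`, `pdac`
#'   and combined `genes`).
#' @export
driver_catalog <- function(pan_cancer = character(0), pdac = character(0)) {
  pan_cancer <- unique(pan_cancer)
  pdac <- unique(pdac)
  genes <- union(pan_cancer, pdac)
  if (!length(genes)) stop("driver catalog must be non-empty")
  structure(list(pan_cancer = pan_cancer, pdac = pdac, genes = genes),
            class = "driver_catalog")
}

#' Default driver-gene catalog
#'
#' A compact catalog combining frequently reported pan-cancer driver genes
#' with PDAC driver genes. Intended as a sensible default for synthetic and
#' exploratory analyses; studies with a curated list should pass their own
#' via [driver_catalog()].
#'
#' @return A `driver_catalog`.
#' @export
default_driver_catalog <- function() {
  driver_catalog(
    pan_cancer = c("TP53", "KRAS", "PIK3CA", "PTEN", "APC", "ARID1A",
                   "EGFR", "BRAF", "ATM", "RB1", "NF1", "CTNNB1", "IDH1",
                   "FBXW7", "SMARCA4", "CREBBP", "MYC", "CDKN2A", "STK11",
                   "BRCA2", "CHEK2", "MDM4"),
    pdac = c("KRAS", "TP53", "CDKN2A", "SMAD4", "ARID1A", "KDM6A", "RNF43",
             "TGFBR2", "GNAS", "RREB1", "U2AF1", "ZNF521", "PLCB4",
             "BCL11A", "KIF5B", "NIPBL", "CEBPA", "CACNA1A", "CBFA2T3")
  )
}

#' Flag candidate driver mutations
#'
#' A filtered mutation is a candidate driver when its gene is in the
#' catalog and it is either (i) a nonsense, frameshift or splice-site
#' mutation, or (ii) a missense mutation with FATHMM-MKL score > 0.5 or
#' called damaging by at least two of: SIFT score in \[0, 0.05\],
#' PolyPhen2 "possibly"/"probably damaging", MutationAssessor
#' "medium"/"high", FATHMM-MKL > 0.5. Missing scores count as
#' non-damaging.
#'
#' @param table Filtered mutation table with score columns `fathmm_mkl`,
#'   `sift`, `polyphen2_class`, `mutationassessor_class` (any may be
#'   missing).
#' @param catalog A [driver_catalog()].
#' @return The table with a logical `is_candidate_driver` column.
#' @export
annotate_driver_mutations <- function(table, catalog) {
  stopifnot(inherits(catalog, "driver_catalog"))
  n <- nrow(table)
  get_num <- function(col) {
    if (col %in% names(table)) table[[col]] else rep(NA_real_, n)
  }
  get_chr <- function(col) {
    if (col %in% names(table)) table[[col]] else rep(NA_character_, n)
  }
  fathmm <- get_num("fathmm_mkl")
  sift <- get_num("sift")
  pp2 <- get_chr("polyphen2_class")
  ma <- get_chr("mutationassessor_class")
  fathmm_dam <- !is.na(fathmm) & fathmm > 0.5
  sift_dam <- !is.na(sift) & sift >= 0 & sift <= 0.05
  pp2_dam <- !is.na(pp2) & pp2 %in% c("possibly damaging", "probably damaging")
  ma_dam <- !is.na(ma) & ma %in% c("medium", "high")
  n_damaging <- fathmm_dam + sift_dam + pp2_dam + ma_dam
  truncating <- table$consequence %in% c("nonsense", "frameshift", "splice")
  missense_dam <- table$consequence == "missense" &
    (fathmm_dam | n_damaging >= 2)
  table$is_candidate_driver <- table$passed_filter &
    table$gene %in% catalog$genes & (truncating | missense_dam)
  table
}

#' Per-gene driver mutation frequency across patients
#'
#' @param table Mutation table annotated by [annotate_driver_mutations()],
#'   with `patient_id`.
#' @param genes Optional gene subset; defaults to all genes with at least
#'   one candidate driver mutation.
#' @return Data.frame `gene`, `n_patients`, `frequency` sorted by decreasing
#'   frequency.
#' @export
driver_mutation_frequency <- function(table, genes = NULL) {
  total <- length(unique(table$patient_id))
  if (total == 0) stop("no patients in table")
  hits <- table[table$is_candidate_driver, c("patient_id", "gene")]
  if (is.null(genes)) genes <- sort(unique(hits$gene))
  n_pat <- vapply(genes, function(g) {
    length(unique(hits$patient_id[hits$gene == g]))
  }, integer(1))
  out <- data.frame(gene = genes, n_patients = n_pat,
                    frequency = n_pat / total, stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(-out$frequency, out$gene), , drop = FALSE]
}
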