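# Copy-number burden, weighted genome instability index (wGII), arm-level
# gain/loss calling and arm-event clonality across a patient's regions.
#
# A segment profile is the per-sample unit: integer (allele-specific) copy
# number segments plus purity and ploidy. Gain/loss states are defined on
# the ploidy-normalised log2 ratio r = log2(total_cn / ploidy) with the
# cutoffs log2(2.5/2) for gain and log2(1.5/2) for loss, so that for a
# diploid sample gain means total_cn >= 2.5 and loss total_cn <= 1.5.

GAIN_CUTOFF <- log2(2.5 / 2)
LOSS_CUTOFF <- log2(1.5 / 2)

#' Construct a segment profile
#'
#' @param sample_id Sample (lesion) identifier.
#' @param segments Data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive), `total_cn`, and optionally `major_cn`, `minor_cn`.
#' @param purity Tumour purity in (0, 1].
#' @param ploidy Average copy number; if `NULL`, the length-weighted mean of
#'   `total_cn` is used.
#' @param patient_id Optional patient identifier.
#' @return A `segment_profile` object.
#' @export
segment_profile <- function(sample_id, segments, purity = NA_real_,
                            ploidy = NULL, patient_id = NA_character_) {
  stopifnot(all(c("chrom", "start", "end", "total_cn") %in% names(segments)))
  if (any(segments$end <= segments$start)) stop("segment end must exceed start")
  if (any(segments$total_cn < 0)) stop("negative total_cn")
  if (all(c("major_cn", "minor_cn") %in% names(segments))) {
    if (any(segments$minor_cn < 0)) stop("negative minor_cn")
    if (any(segments$total_cn != segments$major_cn + segments$minor_cn))
      stop("total_cn must equal major_cn + minor_cn")
  }
  segments$chrom <- as.character(segments$chrom)
  len <- segments$end - segments$start + 1
  if (is.null(ploidy)) ploidy <- sum(len * segments$total_cn) / sum(len)
  if (ploidy <= 0) stop("ploidy must be positive")
  structure(list(sample_id = sample_id, patient_id = patient_id,
                 purity = purity, ploidy = ploidy, segments = segments),
            class = "segment_profile")
}

#' @export
print.segment_profile <- function(x, ...) {
  cat(sprintf("segment_profile: %s (%d segments, ploidy %.2f, purity %s)\n",
              x$sample_id, nrow(x$segments), x$ploidy,
              ifelse(is.na(x$purity), "NA", sprintf("%.2f", x$purity))))
  invisible(x)
}

# Per-segment gain/loss/neutral state on the ploidy-normalised log2 scale.
segment_states <- function(profile) {
  r <- log2(pmax(profile$segments$total_cn, 0.01) / profile$ploidy)
  ifelse(r >= GAIN_CUTOFF, "gain", ifelse(r <= LOSS_CUTOFF, "loss", "neutral"))
}

#' Copy-number burden
#'
#' Percentage of the covered autosomal genome lying in segments called gain
#' or loss (ploidy-normalised log2 cutoffs log2(2.5/2) and log2(1.5/2)).
#'
#' @param profile A [segment_profile()].
#' @return Burden in percent, in \[0, 100\].
#' @export
compute_cnv_burden <- function(profile) {
  stopifnot(inherits(profile, "segment_profile"))
  segs <- profile$segments
  len <- segs$end - segs$start + 1
  total <- sum(len)
  if (total == 0) stop("zero covered genome length")
  state <- segment_states(profile)
  100 * sum(len[state != "neutral"]) / total
}

#' Weighted genome instability index
#'
#' Mean over autosomes of the fraction of chromosome length whose rounded
#' total copy number differs from the rounded sample ploidy. The
#' ploidy-relative definition makes a cleanly whole-genome-doubled sample
#' score 0.
#'
#' @param profile A [segment_profile()].
#' @param arms Arm table from [load_arm_definitions()], used for chromosome
#'   lengths and the autosome set.
#' @return Index in \[0, 1\].
#' @export
compute_wgii <- function(profile, arms = load_arm_definitions("hg19")) {
  stopifnot(inherits(profile, "segment_profile"))
  chrom_len <- chromosome_lengths(arms)
  segs <- profile$segments
  segs <- segs[segs$chrom %in% names(chrom_len), , drop = FALSE]
  missing_chroms <- setdiff(names(chrom_len), unique(segs$chrom))
  if (length(missing_chroms)) {
    warning("no segments on chromosome(s) ",
            paste(missing_chroms, collapse = ", "), "; excluded from wGII")
    chrom_len <- chrom_len[setdiff(names(chrom_len), missing_chroms)]
  }
  ploidy_state <- round(profile$ploidy)
  altered <- round(segs$total_cn) != ploidy_state
  len <- segs$end - segs$start + 1
  frac <- vapply(names(chrom_len), function(ch) {
    on <- segs$chrom == ch
    sum(len[on & altered]) / chrom_len[[ch]]
  }, numeric(1))
  mean(frac)
}

# Split segments at arm boundaries and attach arm labels; lengths are then
# attributable to exactly one arm.
split_segments_by_arm <- function(segments, arms) {
  out <- lapply(seq_len(nrow(arms)), function(i) {
    a <- arms[i, ]
    on <- segments$chrom == a$chrom &
      segments$start <= a$end & segments$end >= a$start
    if (!any(on)) return(NULL)
    s <- segments[on, , drop = FALSE]
    s$start <- pmax(s$start, a$start)
    s$end <- pmin(s$end, a$end)
    s$arm <- paste0(a$chrom, a$arm)
    s$arm_length <- a$length
    s
  })
  do.call(rbind, out)
}

#' Call arm-level copy-number events
#'
#' A chromosome arm is called gained (resp. lost) when more than
#' `min_fraction` of the arm length is covered by segments in the gain
#' (resp. loss) state; otherwise the arm is neutral. Segments straddling an
#' arm boundary are split at the boundary first.
#'
#' @param profile A [segment_profile()].
#' @param arms Arm table from [load_arm_definitions()].
#' @param min_fraction Minimum fraction of arm length (default 0.98,
#'   exclusive).
#' @return Data.frame with `sample_id`, `arm`, `state`
#'   (gain/loss/neutral), `gain_fraction`, `loss_fraction`,
#'   `covered_fraction`.
#' @export
call_arm_events <- function(profile, arms = load_arm_definitions("hg19"),
                            min_fraction = 0.98) {
  stopifnot(inherits(profile, "segment_profile"))
  if (any(profile$segments$total_cn < 0)) stop("negative total_cn")
  segs <- profile$segments
  segs$state <- segment_states(profile)
  split <- split_segments_by_arm(segs, arms)
  arm_ids <- paste0(arms$chrom, arms$arm)
  res <- lapply(seq_along(arm_ids), function(i) {
    id <- arm_ids[i]
    s <- if (is.null(split)) segs[0, , drop = FALSE]
         else split[split$arm == id, , drop = FALSE]
    arm_len <- arms$length[i]
    len <- if (nrow(s)) s$end - s$start + 1 else numeric(0)
    gain_frac <- sum(len[s$state == "gain"]) / arm_len
    loss_frac <- sum(len[s$state == "loss"]) / arm_len
    state <- if (gain_frac > min_fraction) "gain"
             else if (loss_frac > min_fraction) "loss" else "neutral"
    data.frame(sample_id = profile$sample_id, arm = id, state = state,
               gain_fraction = gain_frac, loss_fraction = loss_frac,
               covered_fraction = sum(len) / arm_len,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Classify arm-event clonality across a patient's regions
#'
#' An arm event exists for the patient when it is called in at least one
#' region. It is clonal when the same state is called in more than
#' `clonal_fraction` of the remaining regions, otherwise subclonal.
#' Single-region patients are clonal by convention (the remaining-regions
#' rule is vacuous) and a warning is emitted. Conflicting gain and loss
#' calls on one arm yield subclonal with a warning.
#'
#' @param patient_calls Data.frame of per-region arm calls
#'   (rbind of [call_arm_events()] outputs for one patient).
#' @param clonal_fraction Fraction of remaining regions required
#'   (default 0.75, exclusive).
#' @return Data.frame with `arm`, `state`, `clonality`
#'   (clonal/subclonal/absent), `n_regions`, `n_called`.
#' @export
classify_arm_clonality <- function(patient_calls, clonal_fraction = 0.75) {
  regions <- unique(patient_calls$sample_id)
  n_regions <- length(regions)
  if (n_regions < 1) stop("at least one region required")
  if (n_regions == 1)
    warning("single-region patient: arm events clonal by convention")
  arms_seen <- unique(patient_calls$arm)
  res <- lapply(arms_seen, function(a) {
    calls <- patient_calls[patient_calls$arm == a, , drop = FALSE]
    states <- calls$state[match(regions, calls$sample_id)]
    states[is.na(states)] <- "neutral"
    event_states <- setdiff(unique(states), "neutral")
    if (!length(event_states)) {
      return(data.frame(arm = a, state = "neutral", clonality = "absent",
                        n_regions = n_regions, n_called = 0L,
                        stringsAsFactors = FALSE))
    }
    if (length(event_states) > 1) {
      warning("conflicting gain and loss calls on arm ", a,
              "; classified subclonal")
      state <- event_states[which.max(tabulate(match(states, event_states)))]
      return(data.frame(arm = a, state = state, clonality = "subclonal",
                        n_regions = n_regions,
                        n_called = sum(states != "neutral"),
                        stringsAsFactors = FALSE))
    }
    state <- event_states
    n_called <- sum(states == state)
    clonality <- if (n_regions == 1) {
      "clonal"
    } else {
      # fraction of the remaining regions (beyond the first carrying it)
      if ((n_called - 1) / (n_regions - 1) > clonal_fraction) "clonal"
      else "subclonal"
    }
    data.frame(arm = a, state = state, clonality = clonality,
               n_regions = n_regions, n_called = n_called,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Detect whole-genome doubling
#'
#' A sample is called genome-doubled when the length-weighted fraction of
#' the covered autosomal genome with major allele copy number >= 2 exceeds
#' 0.5.
#'
#' @param profile A [segment_profile()] with `major_cn` populated.
#' @param threshold Fraction cutoff (default 0.5, exclusive).
#' @return Logical.
#' @export
detect_genome_doubling <- function(profile, threshold = 0.5) {
  stopifnot(inherits(profile, "segment_profile"))
  segs <- profile$segments
  if (!"major_cn" %in% names(segs) || any(is.na(segs$major_cn)))
    stop("major_cn required for genome-doubling detection")
  len <- segs$end - segs$start + 1
  sum(len[segs$major_cn >= 2]) / sum(len) > threshold
}
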