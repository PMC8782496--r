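# Readers and writers for the plain-text formats the pipeline exchanges:
# MAF-like mutation TSV, SEG copy-number segments, BED-like methylation
# peaks, count matrices and the clinical table. File coordinates are 1-based
# inclusive for MAF/SEG and 0-based half-open for BED, per the conventions
# of those formats.

.maf_column_map <- c(
  Hugo_Symbol = "gene", Chromosome = "chrom", Start_Position = "pos",
  Reference_Allele = "ref", Tumor_Seq_Allele2 = "alt",
  Variant_Classification = "consequence",
  t_depth = "depth_tumor", t_alt_count = "alt_tumor",
  n_depth = "depth_normal", n_alt_count = "alt_normal",
  Tumor_Sample_Barcode = "lesion_id", Patient_ID = "patient_id",
  popfreq_max = "popfreq_max", fathmm_mkl = "fathmm_mkl", sift = "sift",
  polyphen2_class = "polyphen2_class",
  mutationassessor_class = "mutationassessor_class"
)

.maf_class_map <- c(
  Missense_Mutation = "missense", Nonsense_Mutation = "nonsense",
  Splice_Site = "splice", Frame_Shift_Del = "frameshift",
  Frame_Shift_Ins = "frameshift", Silent = "synonymous",
  In_Frame_Del = "inframe", In_Frame_Ins = "inframe"
)

#' Read a MAF-style somatic mutation table
#'
#' Accepts either standard MAF column headers (`Hugo_Symbol`, `t_depth`, ...)
#' or the package's internal names (`gene`, `depth_tumor`, ...). MAF
#' `Variant_Classification` labels are normalised to the internal consequence
#' vocabulary (`missense`, `nonsense`, `splice`, `frameshift`, `synonymous`,
#' `inframe`).
#'
#' @param path Tab-separated file, coordinates 1-based inclusive.
#' @return A data.frame of variant calls.
#' @export
read_maf <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  hit <- names(x) %in% names(.maf_column_map)
  names(x)[hit] <- .maf_column_map[names(x)[hit]]
  num_cols <- intersect(
    c("pos", "depth_tumor", "alt_tumor", "depth_normal", "alt_normal",
      "popfreq_max", "fathmm_mkl", "sift"), names(x))
  for (cc in num_cols) x[[cc]] <- as.numeric(x[[cc]])
  if ("consequence" %in% names(x)) {
    maf_style <- x$consequence %in% names(.maf_class_map)
    x$consequence[maf_style] <- .maf_class_map[x$consequence[maf_style]]
  }
  x
}

#' Write a mutation table with MAF column headers
#'
#' @param maf Data.frame in internal representation.
#' @param path Output path.
#' @export
write_maf <- function(maf, path) {
  out <- maf
  rev_map <- setNames(names(.maf_column_map), .maf_column_map)
  hit <- names(out) %in% names(rev_map)
  names(out)[hit] <- rev_map[names(out)[hit]]
  if ("Variant_Classification" %in% names(out)) {
    rev_class <- setNames(names(.maf_class_map), .maf_class_map)
    # frameshift/inframe each map back to the Del spelling
    rev_class <- rev_class[!duplicated(names(rev_class))]
    hit <- out$Variant_Classification %in% names(rev_class)
    out$Variant_Classification[hit] <- rev_class[out$Variant_Classification[hit]]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read copy-number segments (SEG or extended TSV)
#'
#' Standard SEG columns (`ID`, `chrom`, `loc.start`, `loc.end`, `num.mark`,
#' `seg.mean`) or an extended table with integer allele-specific copy numbers
#' (`total_cn`, `major_cn`, `minor_cn`). File coordinates are 1-based
#' inclusive and kept as such in the returned data.frame.
#'
#' @param path Tab-separated segment file.
#' @return Data.frame with at least `sample_id`, `chrom`, `start`, `end`.
#' @export
read_seg <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  map <- c(ID = "sample_id", Sample = "sample_id", chrom = "chrom",
           chromosome = "chrom", loc.start = "start", loc.end = "end",
           num.mark = "num_mark", seg.mean = "log2_ratio")
  hit <- names(x) %in% names(map)
  names(x)[hit] <- map[names(x)[hit]]
  x$chrom <- as.character(x$chrom)
  x
}

#' Write segments as SEG-style TSV
#' @param segs Data.frame with `sample_id`, `chrom`, `start`, `end` and copy
#'   number columns.
#' @param path Output path.
#' @export
write_seg <- function(segs, path) {
  write.table(segs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a methylation peak set (BED + enrichment fold + q-value)
#'
#' BED-style file: `chrom`, `start` (0-based), `end` (half-open), `name`,
#' `enrichment_fold`, `q_value`. Returned coordinates stay 0-based half-open.
#'
#' @param path BED-like file; a `sample_id` is taken from the `name` column
#'   unless `sample_id` is given.
#' @param sample_id Optional sample identifier overriding the name column.
#' @return Data.frame with `sample_id`, `chrom`, `start`, `end`,
#'   `enrichment_fold`, `q_value`.
#' @export
read_peaks_bed <- function(path, sample_id = NULL) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(x)[seq_len(min(6, ncol(x)))] <-
    c("chrom", "start", "end", "name", "enrichment_fold", "q_value")[seq_len(min(6, ncol(x)))]
  x$chrom <- as.character(x$chrom)
  x$sample_id <- if (is.null(sample_id)) x$name else sample_id
  x[c("sample_id", "chrom", "start", "end", "enrichment_fold", "q_value")]
}

#' Write a methylation peak set as BED
#' @param peaks Data.frame as returned by [read_peaks_bed()].
#' @param path Output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$sample_id,
                    peaks$enrichment_fold, peaks$q_value)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a gene-by-sample count (or value) matrix
#' @param path TSV with genes in rows (first column = gene id).
#' @return Numeric matrix with gene rownames.
#' @export
read_count_matrix <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  row.names = 1)
  as.matrix(x)
}

#' Write a gene-by-sample matrix as TSV
#' @param mat Matrix with gene rownames.
#' @param path Output path.
#' @export
write_count_matrix <- function(mat, path) {
  out <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
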