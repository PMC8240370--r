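#' @importFrom stats pt prcomp rnorm runif sd setNames
#' @importFrom utils packageVersion
#' @keywords internal
"_PACKAGE"

# Core containers.
#
# Matrices are plain numeric matrices, probes in rows (rownames = probe IDs),
# samples in columns (colnames = sample IDs). Missing values are NA_real_ --
# never a numeric sentinel -- so readers must map "NA"/"null"/blank cells to
# NA explicitly and 0 always means a genuine measurement.

#' Validate an intensity matrix pair
#'
#' Checks that methylated (M) and unmethylated (U) signal-intensity matrices
#' share shape, probe and sample ordering, carry unique identifiers, and
#' contain no negative finite values.
#'
#' @param methylated,unmethylated Numeric probes x samples matrices with
#'   rownames (probe IDs) and colnames (sample IDs). `NA` marks missing cells.
#' @return Invisibly, a list with elements `methylated` and `unmethylated`.
#' @export
intensity_matrix <- function(methylated, unmethylated) {
  if (!is.matrix(methylated) || !is.matrix(unmethylated))
    stop("methylated and unmethylated must be matrices")
  if (!identical(dim(methylated), dim(unmethylated)))
    stop("methylated and unmethylated matrices differ in shape")
  if (!identical(rownames(methylated), rownames(unmethylated)) ||
      !identical(colnames(methylated), colnames(unmethylated)))
    stop("methylated and unmethylated matrices differ in probe/sample ordering")
  .check_ids(rownames(methylated), "probe")
  .check_ids(colnames(methylated), "sample")
  for (nm in c("methylated", "unmethylated")) {
    m <- if (nm == "methylated") methylated else unmethylated
    bad <- which(is.finite(m) & m < 0, arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop(sprintf("negative %s intensity at probe '%s', sample '%s'",
                   nm, rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  invisible(list(methylated = methylated, unmethylated = unmethylated))
}

.check_ids <- function(ids, what) {
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    stop(sprintf("%s identifiers are required and must be non-empty", what))
  if (anyDuplicated(ids))
    stop(sprintf("duplicated %s identifiers: %s", what,
                 paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))],
                       collapse = ", ")))
  invisible(TRUE)
}

#' Validate a beta-value matrix
#'
#' A beta matrix holds methylation ratios in `[0, 1]`; `NA` marks missing
#' cells. Betas computed from intensities via [compute_beta()] are strictly
#' below 1 because of the +100 offset; externally supplied matrices may touch
#' the closed bounds after rounding, so the validator accepts the closed
#' interval.
#'
#' @param values Numeric probes x samples matrix with rownames/colnames.
#' @return The validated matrix, invisibly.
#' @export
validate_beta <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("beta values must be a numeric matrix")
  .check_ids(rownames(values), "probe")
  .check_ids(colnames(values), "sample")
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "beta value %g out of [0, 1] at probe '%s', sample '%s'",
      values[bad[1L, 1L], bad[1L, 2L]],
      rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]]))
  invisible(values)
}

#' Construct a probe annotation table
#'
#' Maps probe IDs to a chromosome class used for all probe partitioning.
#' Labels are normalized on construction: `"chrX"`, `"X"`, `"x"` all map to
#' `"X"` (same for Y); every other label is an autosome. The three classes
#' are disjoint and exhaustive over annotated probes.
#'
#' @param probe_id Character vector of unique probe IDs.
#' @param chromosome Character vector of chromosome labels, recycled is not
#'   allowed; must match `probe_id` in length.
#' @return A `data.frame` with columns `probe_id`, `chromosome` (normalized
#'   label) and `class` (factor: `autosome`, `X`, `Y`).
#' @export
probe_annotation <- function(probe_id, chromosome) {
  probe_id <- as.character(probe_id)
  chromosome <- as.character(chromosome)
  if (length(probe_id) != length(chromosome))
    stop("probe_id and chromosome must have the same length")
  .check_ids(probe_id, "probe")
  chrom <- normalize_chromosome(chromosome)
  cls <- ifelse(chrom == "X", "X", ifelse(chrom == "Y", "Y", "autosome"))
  data.frame(probe_id = probe_id, chromosome = chrom,
             class = factor(cls, levels = c("autosome", "X", "Y")),
             stringsAsFactors = FALSE)
}

#' Normalize chromosome labels
#'
#' Strips a leading `"chr"` (any case) and upper-cases `x`/`y` so that
#' `"chrX"`, `"X"` and `"x"` agree. Other labels are returned with the
#' `"chr"` prefix stripped.
#'
#' @param x Character vector of chromosome labels.
#' @return Character vector of normalized labels.
#' @export
normalize_chromosome <- function(x) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  x <- ifelse(toupper(x) %in% c("X", "Y"), toupper(x), x)
  x
}

#' Construct a sample sheet
#'
#' @param sample_id Character vector of unique sample IDs.
#' @param sex Optional labelled sex; values are normalized so `"F"`,
#'   `"f"`, `"female"`, `"Female"` map to `"female"` (same scheme for male);
#'   anything else, `NA` included, becomes `NA` (unknown). Unannotated
#'   samples are a first-class use case.
#' @return A `data.frame` with columns `sample_id` and `sex`.
#' @export
sample_sheet <- function(sample_id, sex = NULL) {
  sample_id <- as.character(sample_id)
  .check_ids(sample_id, "sample")
  if (is.null(sex)) sex <- rep(NA_character_, length(sample_id))
  if (length(sex) != length(sample_id))
    stop("sex must match sample_id in length")
  data.frame(sample_id = sample_id, sex = normalize_sex(sex),
             stringsAsFactors = FALSE)
}

#' @rdname sample_sheet
#' @param x Character vector of sex labels.
#' @export
normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("f", "female", "woman", "w")] <- "female"
  out[x %in% c("m", "male", "man")] <- "male"
  out
}

#' Restrict a beta matrix to annotated probes
#'
#' Drops probes absent from the annotation, preserving the matrix's probe
#' order, and reports how many were dropped. All cross-structure alignment is
#' by probe ID, never by row position.
#'
#' @param beta Numeric probes x samples beta matrix.
#' @param annotation A [probe_annotation()] table.
#' @param require_sex_chromosomes If `TRUE`, warn when the restricted matrix
#'   has no ChrX or no ChrY probes (training and prediction need both;
#'   preprocessing alone does not).
#' @return A list: `beta` (restricted matrix), `annotation` (rows matching
#'   the retained probes, in matrix order), `n_dropped`.
#' @export
validate_aligned <- function(beta, annotation, require_sex_chromosomes = FALSE) {
  validate_beta(beta)
  if (!all(c("probe_id", "class") %in% names(annotation)))
    stop("annotation must be a probe_annotation() table")
  keep <- rownames(beta) %in% annotation$probe_id
  if (!any(keep))
    stop("no overlap between beta matrix probes and annotation")
  beta2 <- beta[keep, , drop = FALSE]
  ann2 <- annotation[match(rownames(beta2), annotation$probe_id), , drop = FALSE]
  rownames(ann2) <- NULL
  if (sum(ann2$class == "autosome") == 0L)
    stop("no autosomal probes after annotation restriction; Z-scoring impossible")
  if (require_sex_chromosomes &&
      (sum(ann2$class == "X") == 0L || sum(ann2$class == "Y") == 0L))
    warning("annotation restriction leaves no ChrX or no ChrY probes; ",
            "training/prediction will fail")
  list(beta = beta2, annotation = ann2, n_dropped = sum(!keep))
}
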