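# Preprocessing: beta computation, sample QC, imputation, per-sample
# autosomal Z-score normalization.

#' Compute beta values from signal intensities
#'
#' beta = M / (M + U + 100), elementwise. The +100 offset stabilizes
#' low-intensity probes and keeps every beta strictly below 1 for finite
#' intensities. A missing M or U cell yields a missing beta.
#'
#' @param methylated,unmethylated Numeric probes x samples matrices of
#'   nonnegative signal intensities (`NA` = missing).
#' @param offset Additive offset in the denominator; 100 is the array
#'   convention and the default.
#' @return Numeric beta matrix with the same dimnames; values in `[0, 1)`.
#' @export
compute_beta <- function(methylated, unmethylated, offset = 100) {
  intensity_matrix(methylated, unmethylated)
  beta <- methylated / (methylated + unmethylated + offset)
  beta[is.na(methylated) | is.na(unmethylated)] <- NA_real_
  beta
}

#' Exclude samples with excessive missing data
#'
#' Removes samples whose fraction of missing probe values is strictly
#' greater than `max_frac` ("more than 10%" is a strict inequality: a sample
#' at exactly 10% is retained). The fraction is computed over the probes
#' present in the matrix at this stage.
#'
#' @param beta Numeric beta matrix (`NA` = missing).
#' @param max_frac Maximum tolerated missing fraction per sample, in
#'   `[0, 1)`; default 0.10.
#' @return A list: `beta` (filtered matrix) and `removed` (character vector
#'   of excluded sample IDs).
#' @export
filter_samples_by_missingness <- function(beta, max_frac = 0.10) {
  validate_beta(beta)
  if (!is.numeric(max_frac) || max_frac < 0 || max_frac >= 1)
    stop("max_frac must be in [0, 1)")
  frac <- colMeans(is.na(beta))
  drop <- frac > max_frac
  if (all(drop))
    stop("all samples exceed the missingness threshold of ", max_frac)
  list(beta = beta[, !drop, drop = FALSE], removed = colnames(beta)[drop])
}

#' Impute missing betas with probe means
#'
#' Each missing cell is replaced by the mean of that probe's non-missing
#' values across samples. Probes missing in every sample have no defined
#' mean and are dropped with a warning.
#'
#' @param beta Numeric beta matrix (`NA` = missing).
#' @return Beta matrix with no missing values; possibly fewer probes.
#' @export
impute_missing <- function(beta) {
  validate_beta(beta)
  if (!anyNA(beta)) return(beta)
  all_missing <- rowSums(!is.na(beta)) == 0L
  if (any(all_missing)) {
    warning(sum(all_missing), " probe(s) missing in every sample were dropped")
    beta <- beta[!all_missing, , drop = FALSE]
  }
  idx <- which(is.na(beta), arr.ind = TRUE)
  if (nrow(idx) > 0L) {
    means <- rowMeans(beta, na.rm = TRUE)
    beta[idx] <- means[idx[, 1L]]
  }
  beta
}

#' Per-sample autosomal Z-score normalization
#'
#' For each sample, every probe value (autosomal and sex-chromosomal alike)
#' is centered by the mean and scaled by the standard deviation of that
#' sample's autosomal betas. This removes per-sample technical shifts using
#' a statistic that is sex-independent by construction, and puts ChrX/ChrY
#' probes of all samples on a common scale.
#'
#' @param beta Numeric beta matrix with no missing values (run
#'   [impute_missing()] first).
#' @param annotation A [probe_annotation()] table covering the matrix probes.
#' @param sd_method `"population"` (divide by n, the default, matching the
#'   numeric-stack convention the model format records) or `"sample"`
#'   (divide by n-1). The choice is stored in trained models.
#' @return Numeric matrix of Z-scores with the same dimnames. Autosomal
#'   entries of each sample have mean 0 and sd 1 (in the chosen convention)
#'   to within 1e-8.
#' @export
zscore_normalize <- function(beta, annotation,
                             sd_method = c("population", "sample")) {
  sd_method <- match.arg(sd_method)
  if (anyNA(beta))
    stop("beta matrix contains missing values; run impute_missing() first")
  al <- validate_aligned(beta, annotation)
  beta <- al$beta
  auto <- al$annotation$class == "autosome"
  n_auto <- sum(auto)
  if (n_auto < 2L)
    stop("need at least 2 autosomal probes for Z-score normalization")
  a <- beta[auto, , drop = FALSE]
  mu <- colMeans(a)
  if (sd_method == "population") {
    sigma <- sqrt(pmax(colMeans(sweep(a, 2L, mu, "-")^2), 0))
  } else {
    sigma <- apply(a, 2L, stats::sd)
  }
  zero <- sigma <= .Machine$double.eps * 100
  if (any(zero))
    stop("constant autosomal profile (sd = 0) for sample(s): ",
         paste(colnames(beta)[zero], collapse = ", "))
  z <- sweep(sweep(beta, 2L, mu, "-"), 2L, sigma, "/")
  z
}

#' Flag samples with atypical beta density shape
#'
#' Whole-blood beta densities are strongly bimodal (peaks near 0 and 1). A
#' sample whose mid-range mass (betas in `[low, high]`) exceeds
#' `max_mid_fraction` is flagged as having an abnormal density. The flag is
#' advisory: nothing is dropped automatically, because silent removal hides
#' data problems.
#'
#' @param beta Numeric beta matrix.
#' @param low,high Mid-range interval bounds; defaults 0.3 and 0.7.
#' @param max_mid_fraction Threshold on the mid-range mass; default 0.5.
#' @return A data.frame with `sample_id`, `mid_fraction` and logical
#'   `flagged`. Emits a warning naming flagged samples.
#' @export
flag_abnormal_density <- function(beta, low = 0.3, high = 0.7,
                                  max_mid_fraction = 0.5) {
  validate_beta(beta)
  mid <- colMeans(!is.na(beta) & beta >= low & beta <= high) /
    pmax(colMeans(!is.na(beta)), .Machine$double.eps)
  flagged <- mid > max_mid_fraction
  if (any(flagged))
    warning("abnormal beta density distribution for sample(s): ",
            paste(colnames(beta)[flagged], collapse = ", "))
  data.frame(sample_id = colnames(beta), mid_fraction = as.numeric(mid),
             flagged = as.logical(flagged), stringsAsFactors = FALSE)
}
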