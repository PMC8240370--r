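# Prediction: project Z-scored samples onto the stored ChrX/ChrY axes and
# call sex / karyotype by quadrant. Only matrix arithmetic is needed at this
# stage, so prediction works on a single sample as well as on a batch.

#' Project samples onto the trained axes
#'
#' For each sample s, the ChrX score is
#' `x_sign * sum_p x_loadings[p] * (z[p, s] - x_center[p])`
#' over the model's ChrX probes (analogously for ChrY). Model probes absent
#' from `z` (or NA for a sample) are tolerated up to `max_missing` of each
#' axis's probes; the partial sum is rescaled by
#' (total probes / available probes) to keep scores on the training scale.
#' A sample's scores depend only on that sample's values.
#'
#' @param z Numeric probes x samples matrix of Z-scores (see
#'   [zscore_normalize()]).
#' @param model A `sex_model`.
#' @param max_missing Maximum tolerated fraction of an axis's probes missing
#'   per sample; default 0.2. Exceeding it is an error naming the axis.
#' @return A data.frame with `sample_id`, `x_score`, `y_score`.
#' @export
project_samples <- function(z, model, max_missing = 0.2) {
  validate_model(model)
  score_axis <- function(probes, center, loadings, sign, axis) {
    present <- probes %in% rownames(z)
    zz <- matrix(NA_real_, length(probes), ncol(z),
                 dimnames = list(probes, colnames(z)))
    zz[probes[present], ] <- z[probes[present], , drop = FALSE]
    avail <- colSums(!is.na(zz))
    if (any(avail < length(probes) * (1 - max_missing)))
      stop(sprintf(
        "more than %.0f%% of the model's Chr%s probes are missing for sample(s): %s",
        100 * max_missing, axis,
        paste(colnames(z)[avail < length(probes) * (1 - max_missing)],
              collapse = ", ")))
    centered <- (zz - center) * loadings
    partial <- colSums(centered, na.rm = TRUE)
    sign * partial * (length(probes) / avail)
  }
  x <- score_axis(model$x_probes, model$x_center, model$x_loadings,
                  model$x_sign, "X")
  y <- score_axis(model$y_probes, model$y_center, model$y_loadings,
                  model$y_sign, "Y")
  data.frame(sample_id = colnames(z), x_score = unname(x),
             y_score = unname(y), stringsAsFactors = FALSE)
}

#' Call karyotype and sex from axis scores
#'
#' Quadrant map on the oriented, training-centered axes (x = ChrX axis,
#' higher means two X copies; y = ChrY axis, higher means Y present):
#' \itemize{
#'   \item x > 0, y <= 0: 46,XX (female)
#'   \item x <= 0, y > 0: 46,XY (male)
#'   \item x <= 0, y <= 0: 45,XO (aneuploid; Turner syndrome)
#'   \item x > 0, y > 0: 47,XXY (aneuploid; Klinefelter syndrome)
#' }
#' Boundaries are at 0 because both axes are centered on the training data,
#' which puts the between-sex midline near the origin. Scores within
#' `boundary_frac` of the training-group separation of either axis are
#' flagged `near_boundary` — such samples can be low-level sex chromosome
#' mosaics and deserve inspection rather than a confident call.
#'
#' @param x_score,y_score Numeric vectors of finite axis scores.
#' @param model Optional `sex_model` providing the training separations used
#'   for the near-boundary flag; without it the flag is `NA`.
#' @param boundary_frac Near-boundary band as a fraction of the training
#'   separation; default 0.05.
#' @return A data.frame with `karyotype`, `predicted_sex` (`female`, `male`
#'   or `aneuploid`) and logical `near_boundary`.
#' @export
classify_karyotype <- function(x_score, y_score, model = NULL,
                               boundary_frac = 0.05) {
  if (any(!is.finite(x_score)) || any(!is.finite(y_score)))
    stop("axis scores must be finite")
  if (length(x_score) != length(y_score))
    stop("x_score and y_score must have the same length")
  xx <- x_score > 0
  yy <- y_score > 0
  karyotype <- ifelse(xx & !yy, "46,XX",
               ifelse(!xx & yy, "46,XY",
               ifelse(!xx & !yy, "45,XO", "47,XXY")))
  predicted_sex <- ifelse(karyotype == "46,XX", "female",
                   ifelse(karyotype == "46,XY", "male", "aneuploid"))
  near <- rep(NA, length(x_score))
  if (!is.null(model)) {
    xs <- model$metadata$x_separation
    ys <- model$metadata$y_separation
    if (!is.null(xs) && !is.null(ys))
      near <- abs(x_score) < boundary_frac * xs |
              abs(y_score) < boundary_frac * ys
  }
  data.frame(karyotype = karyotype, predicted_sex = predicted_sex,
             near_boundary = near, stringsAsFactors = FALSE)
}

#' Predict sex and karyotype for a beta matrix
#'
#' The full prediction pipeline: restrict to annotated probes, impute
#' missing betas (probe means within the supplied dataset), Z-score
#' normalize per sample on autosomal probes, project onto the model axes and
#' call the quadrant. When a sample sheet with labelled sex is supplied,
#' `label_mismatch` is TRUE for samples whose binary prediction contradicts
#' the label; aneuploid calls are never counted as plain mismatches — they
#' are flagged through `karyotype` instead.
#'
#' @param beta Numeric beta matrix (probes x samples); missing values are
#'   imputed with within-dataset probe means.
#' @param annotation A [probe_annotation()] table.
#' @param model A `sex_model` from [train_sex_model()] or [read_model()].
#' @param sheet Optional [sample_sheet()] with labelled sex.
#' @param max_missing Passed to [project_samples()].
#' @return A data.frame with one row per sample: `sample_id`, `x_score`,
#'   `y_score`, `karyotype`, `predicted_sex`, `labelled_sex`,
#'   `label_mismatch`, `near_boundary`.
#' @export
estimate_sex <- function(beta, annotation, model, sheet = NULL,
                         max_missing = 0.2) {
  al <- validate_aligned(beta, annotation)
  b <- impute_missing(al$beta)
  z <- zscore_normalize(b, al$annotation,
                        sd_method = model$metadata$sd_method %||% "population")
  sc <- project_samples(z, model, max_missing = max_missing)
  cl <- classify_karyotype(sc$x_score, sc$y_score, model = model)
  labelled <- rep(NA_character_, nrow(sc))
  if (!is.null(sheet))
    labelled <- sheet$sex[match(sc$sample_id, sheet$sample_id)]
  mismatch <- ifelse(
    is.na(labelled) | cl$predicted_sex == "aneuploid", NA,
    labelled != cl$predicted_sex)
  data.frame(sample_id = sc$sample_id,
             x_score = sc$x_score, y_score = sc$y_score,
             karyotype = cl$karyotype, predicted_sex = cl$predicted_sex,
             labelled_sex = labelled, label_mismatch = mismatch,
             near_boundary = cl$near_boundary, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
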