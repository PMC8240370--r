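# Training: sex-associated probe selection (pooled-variance t-test on raw
# betas, Bonferroni), balanced subsampling, and the two PCA axes (ChrX, ChrY)
# that form the classifier.

#' Select sex-associated probes by differential methylation
#'
#' Runs a two-sample pooled-variance (Student's) t-test on the *raw* beta
#' values of every probe, comparing labelled females against labelled males.
#' P-values are Bonferroni-corrected with m = the number of probes actually
#' tested. A probe is selected when its corrected p-value is below
#' `p_threshold` AND the absolute between-sex mean beta difference exceeds
#' `delta_threshold`; both conditions must hold.
#'
#' Selection intentionally uses raw betas while the downstream PCA uses
#' Z-scores: the effect-size threshold is interpretable on the beta scale
#' only.
#'
#' @param beta Numeric beta matrix with no missing values.
#' @param sheet A [sample_sheet()] with labelled sex for the training
#'   samples; at least 2 females and 2 males are required.
#' @param annotation A [probe_annotation()] table.
#' @param p_threshold Bonferroni-corrected p-value cutoff; default 0.01.
#' @param delta_threshold Minimum |mean(female) - mean(male)| beta
#'   difference; default 0.2.
#' @return A data.frame with one row per tested probe: `probe_id`,
#'   `chromosome`, `class`, `t_statistic`, `raw_p`, `bonferroni_p`,
#'   `mean_female`, `mean_male`, `delta` (female minus male) and logical
#'   `selected`.
#' @export
select_sex_associated_probes <- function(beta, sheet, annotation,
                                         p_threshold = 0.01,
                                         delta_threshold = 0.2) {
  al <- validate_aligned(beta, annotation)
  beta <- al$beta
  ann <- al$annotation
  sex <- sheet$sex[match(colnames(beta), sheet$sample_id)]
  f <- which(!is.na(sex) & sex == "female")
  m <- which(!is.na(sex) & sex == "male")
  if (length(f) < 2L || length(m) < 2L)
    stop(sprintf("need >= 2 labelled samples per sex (found %d female, %d male)",
                 length(f), length(m)))
  tt <- pooled_t_test(beta[, f, drop = FALSE], beta[, m, drop = FALSE])
  m_tests <- nrow(beta)
  bonf <- pmin(1, tt$p * m_tests)
  delta <- tt$mean1 - tt$mean2
  res <- data.frame(
    probe_id = rownames(beta),
    chromosome = ann$chromosome,
    class = ann$class,
    t_statistic = tt$t,
    raw_p = tt$p,
    bonferroni_p = bonf,
    mean_female = tt$mean1,
    mean_male = tt$mean2,
    delta = delta,
    selected = bonf < p_threshold & abs(delta) > delta_threshold,
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

#' Vectorized pooled-variance two-sample t-test
#'
#' Student's t-test with pooled variance, applied row-wise to two matrices
#' sharing rows (probes). Degenerate rows with zero pooled variance get
#' t = 0, p = 1 when the group means agree (no evidence), and t = +/-Inf,
#' p = 0 when they differ with zero within-group spread.
#'
#' @param x1,x2 Numeric matrices, rows = probes, columns = samples of group 1
#'   (female) and group 2 (male).
#' @return A list of per-row vectors: `t`, `p` (two-sided), `df`, `mean1`,
#'   `mean2`.
#' @export
pooled_t_test <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 samples")
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[se == 0 & m1 == m2] <- 0
  p <- 2 * stats::pt(-abs(t), df)
  p[se == 0 & m1 == m2] <- 1
  list(t = t, p = p, df = rep(df, length(t)), mean1 = m1, mean2 = m2)
}

#' Draw a sex-balanced training subset
#'
#' Samples exactly `n_per_sex` labelled females and `n_per_sex` labelled
#' males without replacement, reproducibly under `seed`.
#'
#' @param sheet A [sample_sheet()].
#' @param n_per_sex Number of samples to draw from each sex.
#' @param seed Integer RNG seed.
#' @return Character vector of selected sample IDs (females first).
#' @export
balance_by_sex <- function(sheet, n_per_sex, seed = 1L) {
  f <- sheet$sample_id[!is.na(sheet$sex) & sheet$sex == "female"]
  m <- sheet$sample_id[!is.na(sheet$sex) & sheet$sex == "male"]
  if (length(f) < n_per_sex || length(m) < n_per_sex)
    stop(sprintf(
      "need %d samples per sex but only %d female and %d male are labelled",
      n_per_sex, length(f), length(m)))
  set.seed(as.integer(seed))
  c(sample(f, n_per_sex), sample(m, n_per_sex))
}

#' Fit one principal-component axis
#'
#' Computes the first principal component of the centered training Z-scores
#' restricted to one chromosome's selected probes (covariance PCA: probes
#' are mean-centered but not variance-scaled, because per-sample scaling
#' already happened in the Z-score step). The axis is oriented so the stated
#' convention holds on the training data: on the ChrX axis females score
#' higher (`higher = "female"`), on the ChrY axis males score higher.
#'
#' @param z Numeric probes x samples matrix of Z-scores restricted to one
#'   axis's probes; >= 2 probes and >= 3 samples.
#' @param sexes Character vector of `"female"`/`"male"` aligned with the
#'   columns of `z`; both sexes must be present.
#' @param higher Which sex must have the larger mean score on the oriented
#'   axis.
#' @return A list: `center` (per-probe training means), `loadings` (unit
#'   vector), `orientation_sign` (+1 or -1), `variance_explained`
#'   (lambda_1 / sum(lambda)), `scores` (oriented training scores) and
#'   `separation` (|mean female - mean male| of the oriented scores).
#' @export
fit_axis <- function(z, sexes, higher = c("female", "male")) {
  higher <- match.arg(higher)
  if (nrow(z) < 2L) stop("need >= 2 probes to fit an axis")
  if (ncol(z) < 3L) stop("need >= 3 samples to fit an axis")
  sexes <- as.character(sexes)
  if (length(sexes) != ncol(z))
    stop("sexes must align with the columns of z")
  if (!all(c("female", "male") %in% sexes))
    stop("both sexes must be present to orient the axis")
  p <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  loadings <- p$rotation[, 1L]
  center <- p$center
  scores <- p$x[, 1L]
  ve <- p$sdev[1L]^2 / sum(p$sdev^2)
  mf <- mean(scores[sexes == "female"])
  mm <- mean(scores[sexes == "male"])
  sign <- if (higher == "female") { if (mf >= mm) 1 else -1 } else {
    if (mm >= mf) 1 else -1 }
  scores <- sign * scores
  list(center = center, loadings = loadings, orientation_sign = sign,
       variance_explained = ve, scores = scores,
       separation = abs(mean(scores[sexes == "female"]) -
                        mean(scores[sexes == "male"])))
}

#' Train the two-axis sex classifier
#'
#' End-to-end training: align to annotation, QC samples by missingness,
#' impute, draw a balanced subset, select sex-associated probes on raw
#' betas, Z-score normalize, then fit one PCA axis on the selected ChrX
#' probes and another on the selected ChrY probes. Autosomal probes passing
#' selection are reported in metadata but excluded from the model: the
#' classifier is built from sex-chromosome probes only.
#'
#' @param beta Numeric beta matrix (missing values allowed; QC and
#'   imputation run first).
#' @param sheet A [sample_sheet()] with labelled sex.
#' @param annotation A [probe_annotation()] table.
#' @param p_threshold,delta_threshold Selection thresholds; see
#'   [select_sex_associated_probes()].
#' @param n_per_sex Balanced subset size per sex; `NULL` (default) uses the
#'   size of the smaller labelled sex group.
#' @param seed Integer seed for the balanced subsampling.
#' @param max_missing_frac Sample missingness cutoff; see
#'   [filter_samples_by_missingness()].
#' @return A `sex_model` object; see [write_model()] for its on-disk form.
#' @export
train_sex_model <- function(beta, sheet, annotation,
                            p_threshold = 0.01, delta_threshold = 0.2,
                            n_per_sex = NULL, seed = 1L,
                            max_missing_frac = 0.10) {
  al <- validate_aligned(beta, annotation, require_sex_chromosomes = TRUE)
  qc <- filter_samples_by_missingness(al$beta, max_missing_frac)
  beta <- impute_missing(qc$beta)
  sheet <- sheet[match(colnames(beta), sheet$sample_id), , drop = FALSE]
  n_f <- sum(sheet$sex == "female", na.rm = TRUE)
  n_m <- sum(sheet$sex == "male", na.rm = TRUE)
  if (n_f < 2L || n_m < 2L)
    stop(sprintf("need >= 2 labelled samples per sex (found %d female, %d male)",
                 n_f, n_m))
  if (is.null(n_per_sex))
    n_per_sex <- min(sum(sheet$sex == "female", na.rm = TRUE),
                     sum(sheet$sex == "male", na.rm = TRUE))
  ids <- balance_by_sex(sheet, n_per_sex, seed)
  beta_tr <- beta[, ids, drop = FALSE]
  sheet_tr <- sheet[match(ids, sheet$sample_id), , drop = FALSE]

  sel <- select_sex_associated_probes(beta_tr, sheet_tr, al$annotation,
                                      p_threshold, delta_threshold)
  x_probes <- sel$probe_id[sel$selected & sel$class == "X"]
  y_probes <- sel$probe_id[sel$selected & sel$class == "Y"]
  n_auto_sel <- sum(sel$selected & sel$class == "autosome")
  if (length(x_probes) < 2L || length(y_probes) < 2L)
    stop(sprintf(
      "too few selected sex-chromosome probes (ChrX: %d, ChrY: %d); training data lacks sex signal",
      length(x_probes), length(y_probes)))

  z <- zscore_normalize(beta_tr, al$annotation)
  sexes <- sheet_tr$sex
  xa <- fit_axis(z[x_probes, , drop = FALSE], sexes, higher = "female")
  ya <- fit_axis(z[y_probes, , drop = FALSE], sexes, higher = "male")

  model <- structure(list(
    x_probes = x_probes, y_probes = y_probes,
    x_center = unname(xa$center), y_center = unname(ya$center),
    x_loadings = unname(xa$loadings), y_loadings = unname(ya$loadings),
    x_sign = xa$orientation_sign, y_sign = ya$orientation_sign,
    metadata = list(
      schema_version = 1L,
      package_version = as.character(utils::packageVersion("methylSex")),
      n_female = n_per_sex, n_male = n_per_sex,
      p_threshold = p_threshold, delta_threshold = delta_threshold,
      seed = as.integer(seed), sd_method = "population",
      n_selected_total = sum(sel$selected),
      n_selected_x = length(x_probes), n_selected_y = length(y_probes),
      n_selected_autosomal = n_auto_sel,
      x_variance_explained = xa$variance_explained,
      y_variance_explained = ya$variance_explained,
      x_separation = xa$separation, y_separation = ya$separation
    ),
    selection = sel
  ), class = "sex_model")
  validate_model(model)
  model
}

#' Validate a sex_model object
#'
#' Checks unit-norm loadings (tolerance 1e-10), disjoint probe sets, matched
#' center/loading lengths and legal orientation signs.
#'
#' @param model A `sex_model`.
#' @return The model, invisibly; errors otherwise.
#' @export
validate_model <- function(model) {
  if (!inherits(model, "sex_model")) stop("not a sex_model object")
  for (ax in c("x", "y")) {
    l <- model[[paste0(ax, "_loadings")]]
    if (abs(sqrt(sum(l^2)) - 1) > 1e-10)
      stop(sprintf("%s-axis loadings are not unit norm", toupper(ax)))
    if (length(l) != length(model[[paste0(ax, "_center")]]) ||
        length(l) != length(model[[paste0(ax, "_probes")]]))
      stop(sprintf("%s-axis probe/center/loading lengths disagree", toupper(ax)))
    if (!model[[paste0(ax, "_sign")]] %in% c(-1, 1))
      stop("orientation signs must be +1 or -1")
  }
  if (length(intersect(model$x_probes, model$y_probes)) > 0L)
    stop("ChrX and ChrY probe sets overlap")
  invisible(model)
}

#' @export
print.sex_model <- function(x, ...) {
  md <- x$metadata
  cat("methylSex two-axis PCA sex classifier\n")
  cat(sprintf("  ChrX axis: %d probes, PC1 variance explained %.3f\n",
              length(x$x_probes), md$x_variance_explained))
  cat(sprintf("  ChrY axis: %d probes, PC1 variance explained %.3f\n",
              length(x$y_probes), md$y_variance_explained))
  cat(sprintf("  trained on %d female + %d male samples (seed %d)\n",
              md$n_female, md$n_male, md$seed))
  cat(sprintf("  selection: Bonferroni p < %g, |delta beta| > %g\n",
              md$p_threshold, md$delta_threshold))
  invisible(x)
}
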