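# Synthetic methylation cohorts with ground-truth karyotypes.
#
# The generator reproduces the distributional geometry that drives the
# classifier, not probe-level biology: female ChrX probes mid-methylated
# (X-inactivation averages an active and a silenced allele), male ChrX
# probes hypomethylated, a minority of X-inactivation escape probes with the
# opposite pattern, male ChrY probes hypermethylated, Y-absent samples
# showing low background-level ChrY signal, and bimodal autosomal betas
# identical across sexes.

#' Generator configuration
#'
#' Defaults encode the observed regimes of blood methylation arrays: female
#' ChrX betas mostly in \[0.2, 0.8\], male ChrX betas below 0.2, male ChrY
#' betas above 0.6, Y-absent ChrY signal around 0.35 (sd 0.07) from
#' background and cross-hybridisation, and ~7% of ChrX probes escaping
#' X-inactivation with male-higher methylation. Probe counts (2000
#' autosomal, 400 X, 60 Y) scale down a 450K/EPIC shared-probe panel while
#' preserving the ~14:1 X:Y ratio of sex-associated sites.
#'
#' @param n_samples Number of samples.
#' @param karyotype_proportions Named numeric over `46XX`, `46XY`, `45XO`,
#'   `47XXY`, summing to 1.
#' @param n_autosomal,n_x,n_y Probe counts per chromosome class.
#' @param x_female_range Beta interval for two-X ChrX probe means.
#' @param x_male_upper Upper bound for one-X ChrX probe means.
#' @param y_male_lower Lower bound for Y-present ChrY probe means.
#' @param y_absent_mean,y_absent_sd Normal parameters for Y-absent ChrY
#'   betas (truncated to `[0, 1]`).
#' @param escape_fraction Fraction of ChrX probes with the
#'   X-inactivation-escape (male-higher) pattern.
#' @param noise_sd Per-cell Gaussian noise sd on the beta scale.
#' @param missing_rate Fraction of cells set missing, uniformly at random.
#' @param seed Integer RNG seed; the cohort is a fixed function of
#'   (config, seed).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_samples = 200,
                             karyotype_proportions = c(`46XX` = 0.45,
                                                       `46XY` = 0.45,
                                                       `45XO` = 0.05,
                                                       `47XXY` = 0.05),
                             n_autosomal = 2000, n_x = 400, n_y = 60,
                             x_female_range = c(0.2, 0.8),
                             x_male_upper = 0.2,
                             y_male_lower = 0.6,
                             y_absent_mean = 0.35, y_absent_sd = 0.07,
                             escape_fraction = 0.07,
                             noise_sd = 0.03, missing_rate = 0,
                             seed = 1L) {
  kp <- karyotype_proportions
  if (!all(c("46XX", "46XY", "45XO", "47XXY") %in% names(kp)))
    stop("karyotype_proportions must name 46XX, 46XY, 45XO and 47XXY")
  kp <- kp[c("46XX", "46XY", "45XO", "47XXY")]
  if (abs(sum(kp) - 1) > 1e-9) stop("karyotype proportions must sum to 1")
  if (any(kp < 0)) stop("karyotype proportions must be nonnegative")
  if (n_samples < 1 || n_autosomal < 1 || n_x < 1 || n_y < 1)
    stop("all counts must be >= 1")
  for (r in c(escape_fraction, missing_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  structure(list(
    n_samples = as.integer(n_samples), karyotype_proportions = kp,
    n_autosomal = as.integer(n_autosomal), n_x = as.integer(n_x),
    n_y = as.integer(n_y), x_female_range = x_female_range,
    x_male_upper = x_male_upper, y_male_lower = y_male_lower,
    y_absent_mean = y_absent_mean, y_absent_sd = y_absent_sd,
    escape_fraction = escape_fraction, noise_sd = noise_sd,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "generator_config")
}

.rtrunc_norm <- function(n, mean, sd, lower = 0, upper = 1) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lower | x > upper
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lower | x > upper
  }
  x
}

#' Generate a synthetic methylation cohort
#'
#' Draws per-probe baseline means once per cohort, then per-sample betas by
#' karyotype: two-X states (46,XX and 47,XXY) use the female ChrX regime
#' except at escape probes; one-X states (46,XY and 45,XO) use the
#' hypomethylated ChrX regime except at escape probes (male-higher);
#' Y-present states (46,XY and 47,XXY) use the hypermethylated ChrY regime;
#' Y-absent states draw ChrY betas from the background distribution.
#' Autosomal betas come from a bimodal mixture (peaks near 0.1 and 0.9)
#' identical across karyotypes. Per-cell Gaussian noise is added and values
#' are clipped to `[0, 1)`.
#'
#' Labelled sex in the sample sheet follows phenotype: 45,XO samples are
#' labelled female and 47,XXY samples male.
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_cohort`: `beta` (matrix, `NA` where
#'   masked), `annotation`, `sheet`, `truth` (data.frame `sample_id`,
#'   `karyotype`), `config`.
#' @export
generate_cohort <- function(config = generator_config()) {
  if (!inherits(config, "generator_config"))
    stop("config must come from generator_config()")
  set.seed(config$seed)
  n <- config$n_samples
  ks <- c("46XX", "46XY", "45XO", "47XXY")
  counts <- floor(config$karyotype_proportions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- config$karyotype_proportions * n - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  karyotype <- rep(ks, counts)
  if (any(counts > 0 & config$n_x == 0))
    stop("n_x must be positive to generate karyotype-bearing cohorts")

  probe_ids <- c(sprintf("auto%05d", seq_len(config$n_autosomal)),
                 sprintf("cgX%04d", seq_len(config$n_x)),
                 sprintf("cgY%04d", seq_len(config$n_y)))
  chrom <- c(sample(as.character(1:22), config$n_autosomal, replace = TRUE),
             rep("X", config$n_x), rep("Y", config$n_y))
  annotation <- probe_annotation(probe_ids, chrom)

  # Per-probe baselines, fixed across samples.
  auto_high <- stats::runif(config$n_autosomal) < 0.5
  auto_mean <- ifelse(auto_high,
                      stats::runif(config$n_autosomal, 0.82, 0.95),
                      stats::runif(config$n_autosomal, 0.05, 0.18))
  n_escape <- round(config$escape_fraction * config$n_x)
  escape <- rep(FALSE, config$n_x)
  if (n_escape > 0) escape[sample(config$n_x, n_escape)] <- TRUE
  # draw two-X means from the noise-adjusted interior of the female range
  # so that realized (noisy) betas land inside the stated interval
  pad <- 2 * config$noise_sd
  x_two_mean <- stats::runif(config$n_x, config$x_female_range[1L] + pad,
                             config$x_female_range[2L] - pad)
  x_one_mean <- stats::runif(config$n_x, 0.01, config$x_male_upper)
  # escape probes: more methylated in one-X (male-like) state
  x_two_mean[escape] <- stats::runif(n_escape, 0.02, 0.18)
  x_one_mean[escape] <- stats::runif(n_escape, 0.6, 0.9)
  y_present_mean <- stats::runif(config$n_y, config$y_male_lower, 0.95)

  n_probes <- length(probe_ids)
  beta <- matrix(NA_real_, n_probes, n,
                 dimnames = list(probe_ids,
                                 sprintf("sample%04d", seq_len(n))))
  ia <- seq_len(config$n_autosomal)
  ix <- config$n_autosomal + seq_len(config$n_x)
  iy <- config$n_autosomal + config$n_x + seq_len(config$n_y)
  for (s in seq_len(n)) {
    k <- karyotype[s]
    two_x <- k %in% c("46XX", "47XXY")
    has_y <- k %in% c("46XY", "47XXY")
    v <- numeric(n_probes)
    v[ia] <- auto_mean
    v[ix] <- if (two_x) x_two_mean else x_one_mean
    v[iy] <- if (has_y) y_present_mean else
      .rtrunc_norm(config$n_y, config$y_absent_mean, config$y_absent_sd)
    v <- v + stats::rnorm(n_probes, 0, config$noise_sd)
    # 0.99 is the beta ceiling at array-scale total intensities
    # (T / (T + 100) with T ~ 10^4), so clipped values stay invertible
    beta[, s] <- pmin(pmax(v, 0), 0.99)
  }
  if (config$missing_rate > 0) {
    mask <- stats::runif(length(beta)) < config$missing_rate
    beta[mask] <- NA_real_
  }
  sex <- ifelse(karyotype %in% c("46XX", "45XO"), "female", "male")
  cohort <- list(
    beta = beta,
    annotation = annotation,
    sheet = sample_sheet(colnames(beta), sex),
    truth = data.frame(sample_id = colnames(beta), karyotype = karyotype,
                       stringsAsFactors = FALSE),
    config = config
  )
  class(cohort) <- "synthetic_cohort"
  cohort
}

#' Invert betas into synthetic signal-intensity tables
#'
#' Chooses a per-cell total intensity T near `total_intensity_scale` and
#' solves M = beta * (T + 100), U = T - M, so that [compute_beta()] exactly
#' recovers the betas (to <= 1e-9). ChrY totals of Y-absent samples are
#' scaled to ~11% of Y-present totals, mimicking the background-level raw
#' signal that Y-less genomes produce on ChrY probes.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param total_intensity_scale Target total intensity per cell.
#' @return A list with matrices `methylated` and `unmethylated`.
#' @export
generate_intensity_tables <- function(cohort, total_intensity_scale = 10000) {
  beta <- cohort$beta
  set.seed(cohort$config$seed + 1L)
  totals <- matrix(
    stats::runif(length(beta), 0.8, 1.2) * total_intensity_scale,
    nrow(beta), ncol(beta), dimnames = dimnames(beta))
  y_rows <- cohort$annotation$class == "Y"
  y_absent <- cohort$truth$karyotype %in% c("46XX", "45XO")
  totals[y_rows, y_absent] <- totals[y_rows, y_absent] * 0.11
  m <- beta * (totals + 100)
  u <- totals - m
  # betas above T/(T+100) would need negative U; raise the total instead
  neg <- !is.na(u) & u < 0
  if (any(neg)) {
    totals[neg] <- (100 * beta[neg] + 1) / pmax(1 - beta[neg], 1e-12)
    m[neg] <- beta[neg] * (totals[neg] + 100)
    u[neg] <- totals[neg] - m[neg]
  }
  m[is.na(beta)] <- NA_real_
  u[is.na(beta)] <- NA_real_
  list(methylated = m, unmethylated = u)
}

#' Flip labelled sex for a random subset of samples
#'
#' Used to emulate sample mislabelling: exactly `n_swaps` labelled samples
#' get their recorded sex flipped, and the affected IDs are returned so
#' detection can be scored against ground truth.
#'
#' @param sheet A [sample_sheet()] with labelled sex.
#' @param n_swaps Number of labels to flip.
#' @param seed Integer RNG seed.
#' @return A list: `sheet` (with flipped labels) and `swapped` (character
#'   vector of affected sample IDs).
#' @export
scramble_labels <- function(sheet, n_swaps, seed = 1L) {
  labelled <- which(!is.na(sheet$sex))
  if (n_swaps > length(labelled))
    stop("n_swaps exceeds the number of labelled samples")
  set.seed(as.integer(seed))
  pick <- if (n_swaps > 0) sample(labelled, n_swaps) else integer(0)
  sheet$sex[pick] <- ifelse(sheet$sex[pick] == "female", "male", "female")
  list(sheet = sheet, swapped = sheet$sample_id[sort(pick)])
}
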