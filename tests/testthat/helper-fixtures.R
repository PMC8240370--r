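# Fixture builders shared across test files. Everything is generated in
# code; no fixture files on disk.

# Tiny beta matrix with explicit dimnames.
tiny_beta <- function(values, probes = NULL, samples = NULL) {
  if (is.null(probes)) probes <- sprintf("p%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(probes, samples)
  values
}

# Annotation where the first n_auto probes are autosomal, then n_x ChrX,
# then n_y ChrY, matching tiny_beta's default probe names.
tiny_annotation <- function(n_auto, n_x = 0, n_y = 0) {
  n <- n_auto + n_x + n_y
  probe_annotation(sprintf("p%d", seq_len(n)),
                   c(rep("1", n_auto), rep("X", n_x), rep("Y", n_y)))
}

# A hand-built valid sex_model for projection/classification tests.
toy_model <- function(x_probes = c("x1", "x2"), y_probes = c("y1", "y2"),
                      x_center = rep(0, length(x_probes)),
                      y_center = rep(0, length(y_probes)),
                      x_loadings = rep(1 / sqrt(length(x_probes)),
                                       length(x_probes)),
                      y_loadings = rep(1 / sqrt(length(y_probes)),
                                       length(y_probes)),
                      x_sign = 1, y_sign = 1,
                      x_separation = 10, y_separation = 10) {
  structure(list(
    x_probes = x_probes, y_probes = y_probes,
    x_center = x_center, y_center = y_center,
    x_loadings = x_loadings, y_loadings = y_loadings,
    x_sign = x_sign, y_sign = y_sign,
    metadata = list(schema_version = 1L, n_female = 2L, n_male = 2L,
                    p_threshold = 0.01, delta_threshold = 0.2, seed = 1L,
                    sd_method = "population",
                    x_variance_explained = 1, y_variance_explained = 1,
                    x_separation = x_separation,
                    y_separation = y_separation)
  ), class = "sex_model")
}

# Cohort with planted between-sex effects for selection-recovery tests:
# n_auto null autosomal probes (identical means in both sexes) plus planted
# sex-chromosome probes with |delta beta| = effect and within-group sd `sd`.
planted_cohort <- function(seed, n_auto = 1000, n_x = 150, n_y = 40,
                           n_per_sex = 100, effect = 0.5, sd = 0.05) {
  set.seed(seed)
  n <- 2 * n_per_sex
  sex <- rep(c("female", "male"), each = n_per_sex)
  n_probes <- n_auto + n_x + n_y
  probes <- sprintf("p%d", seq_len(n_probes))
  auto_mean <- runif(n_auto, 0.2, 0.8)
  f_x <- runif(n_x, 0.05 + effect, 0.95)   # female high by `effect`
  f_y <- runif(n_y, 0.05, 0.95 - effect)   # male high by `effect`
  means_f <- c(auto_mean, f_x, f_y)
  means_m <- c(auto_mean, f_x - effect, f_y + effect)
  beta <- matrix(NA_real_, n_probes, n,
                 dimnames = list(probes, sprintf("s%d", seq_len(n))))
  for (i in seq_len(n)) {
    mu <- if (sex[i] == "female") means_f else means_m
    beta[, i] <- pmin(pmax(mu + rnorm(n_probes, 0, sd), 0), 1)
  }
  list(beta = beta,
       annotation = probe_annotation(
         probes, c(rep("5", n_auto), rep("X", n_x), rep("Y", n_y))),
       sheet = sample_sheet(colnames(beta), sex),
       planted_sex = probes[(n_auto + 1):n_probes])
}

# Small trained model on a clean two-sex cohort, reused where training
# itself is not under test.
trained_fixture <- function(seed = 11, n = 160) {
  co <- generate_cohort(generator_config(
    n_samples = n,
    karyotype_proportions = c(`46XX` = 0.5, `46XY` = 0.5,
                              `45XO` = 0, `47XXY` = 0),
    seed = seed))
  model <- train_sex_model(co$beta, co$sheet, co$annotation, seed = seed)
  list(cohort = co, model = model)
}
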