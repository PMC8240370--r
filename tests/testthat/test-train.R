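test_that("pooled t-test matches stats::t.test(var.equal = TRUE) per probe", {
  set.seed(101)
  for (rep in 1:30) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    x1 <- matrix(runif(20 * n1), 20, n1)
    x2 <- matrix(runif(20 * n2), 20, n2)
    got <- pooled_t_test(x1, x2)
    for (i in sample(20, 5)) {
      ref <- t.test(x1[i, ], x2[i, ], var.equal = TRUE)
      expect_equal(got$t[i], unname(ref$statistic), tolerance = 1e-10)
      expect_equal(got$p[i], ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("degenerate probes: identical groups give t = 0, p = 1", {
  x1 <- matrix(0.4, 3, 5); x2 <- matrix(0.4, 3, 6)
  got <- pooled_t_test(x1, x2)
  expect_equal(got$t, rep(0, 3))
  expect_equal(got$p, rep(1, 3))
  # zero variance but different means: infinitely strong evidence
  got2 <- pooled_t_test(matrix(0.8, 1, 4), matrix(0.2, 1, 4))
  expect_true(is.infinite(got2$t[1]) && got2$p[1] == 0)
})

test_that("selection requires both Bonferroni p and delta thresholds", {
  set.seed(7)
  n <- 50
  probes <- c("null1", "bigboth", "smalldelta")
  beta <- rbind(
    null1 = runif(2 * n, 0.3, 0.7),
    bigboth = c(rnorm(n, 0.8, 0.02), rnorm(n, 0.2, 0.02)),
    smalldelta = c(rnorm(n, 0.50, 0.001), rnorm(n, 0.35, 0.001)))
  beta <- pmin(pmax(beta, 0), 1)
  colnames(beta) <- sprintf("s%d", 1:(2 * n))
  sheet <- sample_sheet(colnames(beta), rep(c("female", "male"), each = n))
  ann <- probe_annotation(probes, c("1", "X", "X"))
  res <- select_sex_associated_probes(beta, sheet, ann)
  expect_equal(res$selected, c(FALSE, TRUE, FALSE))
  # smalldelta fails only the delta rule despite a tiny p-value
  expect_lt(res$bonferroni_p[3], 0.01)
  expect_lt(abs(res$delta[3]), 0.2)
  # delta is female minus male
  expect_equal(res$delta[2], res$mean_female[2] - res$mean_male[2])
  # the oracle t-statistic for the well-separated probe is enormous
  expect_gt(abs(res$t_statistic[2]), 100)
  # Bonferroni never lowers a p-value and uses m = probes tested
  expect_true(all(res$bonferroni_p >= res$raw_p))
  expect_equal(res$bonferroni_p, pmin(1, res$raw_p * 3))
})

test_that("selected counts are monotone in both thresholds", {
  pc <- planted_cohort(3, n_auto = 200, n_x = 40, n_y = 10, n_per_sex = 20)
  counts <- sapply(c(1e-6, 1e-3, 0.01, 0.1), function(p)
    sum(select_sex_associated_probes(pc$beta, pc$sheet, pc$annotation,
                                     p_threshold = p)$selected))
  expect_true(all(diff(counts) >= 0))
  counts_d <- sapply(c(0.05, 0.2, 0.4, 0.6), function(d)
    sum(select_sex_associated_probes(pc$beta, pc$sheet, pc$annotation,
                                     delta_threshold = d)$selected))
  expect_true(all(diff(counts_d) <= 0))
})

test_that("selection errors without two labelled samples per sex", {
  b <- tiny_beta(matrix(runif(12), 3, 4))
  ann <- tiny_annotation(3)
  sheet <- sample_sheet(colnames(b), c("female", "female", "female", "male"))
  expect_error(select_sex_associated_probes(b, sheet, ann), "1 male")
})

test_that("balanced subsampling is reproducible and checks availability", {
  sheet <- sample_sheet(sprintf("s%d", 1:60),
                        rep(c("female", "male"), c(26, 34)))
  ids1 <- balance_by_sex(sheet, 20, seed = 9)
  ids2 <- balance_by_sex(sheet, 20, seed = 9)
  expect_identical(ids1, ids2)
  expect_equal(length(ids1), 40L)
  sx <- sheet$sex[match(ids1, sheet$sample_id)]
  expect_equal(sum(sx == "female"), 20L)
  expect_equal(sum(sx == "male"), 20L)
  # boundary: minority sex used in full
  ids3 <- balance_by_sex(sheet, 26, seed = 1)
  expect_setequal(intersect(ids3, sheet$sample_id[1:26]),
                  sheet$sample_id[1:26])
  expect_error(balance_by_sex(sheet, 30, seed = 1), "26 female")
})

test_that("fit_axis recovers closed-form PCA on rank-1 two-cluster data", {
  a <- 1.7; p <- 6; n <- 10
  z <- matrix(rep(c(a, -a), each = p * (n / 2)), p, n)
  dimnames(z) <- list(sprintf("p%d", 1:p), sprintf("s%d", 1:n))
  sexes <- rep(c("female", "male"), each = n / 2)
  ax <- fit_axis(z, sexes, higher = "female")
  expect_equal(ax$variance_explained, 1)
  expect_equal(sort(unique(round(ax$scores, 10))),
               round(c(-a * sqrt(p), a * sqrt(p)), 10))
  # orientation convention: females score higher
  expect_gt(mean(ax$scores[sexes == "female"]),
            mean(ax$scores[sexes == "male"]))
  # flipped request flips the sign, never the convention
  ax2 <- fit_axis(z, sexes, higher = "male")
  expect_equal(ax2$orientation_sign, -ax$orientation_sign)
  expect_gt(mean(ax2$scores[sexes == "male"]),
            mean(ax2$scores[sexes == "female"]))
})

test_that("fit_axis loadings are the top eigenvector of the covariance", {
  set.seed(13)
  z <- matrix(rnorm(8 * 30), 8, 30,
              dimnames = list(sprintf("p%d", 1:8), sprintf("s%d", 1:30)))
  z[, 1:15] <- z[, 1:15] + 2  # make the sexes separable for orientation
  ax <- fit_axis(z, rep(c("female", "male"), each = 15))
  eig <- eigen(cov(t(z)))
  v <- eig$vectors[, 1]
  # equal up to sign
  expect_equal(abs(sum(ax$loadings * v)), 1, tolerance = 1e-8)
  expect_equal(sqrt(sum(ax$loadings^2)), 1, tolerance = 1e-12)
  expect_equal(ax$variance_explained,
               eig$values[1] / sum(eig$values), tolerance = 1e-8)
})

test_that("planted sex effects are recovered with no autosomal selections", {
  for (seed in 1:3) {
    pc <- planted_cohort(seed, n_auto = 400, n_x = 60, n_y = 15,
                         n_per_sex = 50)
    res <- select_sex_associated_probes(pc$beta, pc$sheet, pc$annotation)
    sel <- res$probe_id[res$selected]
    expect_gte(mean(pc$planted_sex %in% sel), 0.99)
    expect_equal(sum(res$selected & res$class == "autosome"), 0L)
  }
})

test_that("end-to-end training separates sexes and is deterministic", {
  fx <- trained_fixture(seed = 31, n = 120)
  model <- fx$model
  expect_s3_class(model, "sex_model")
  expect_gt(model$metadata$x_variance_explained, 0.9)
  expect_gt(model$metadata$y_variance_explained, 0.9)
  # self-prediction separates the sexes with zero overlap on both axes
  preds <- estimate_sex(fx$cohort$beta, fx$cohort$annotation, model,
                        fx$cohort$sheet)
  truth_sex <- fx$cohort$sheet$sex
  expect_gt(min(preds$x_score[truth_sex == "female"]),
            max(preds$x_score[truth_sex == "male"]))
  expect_gt(min(preds$y_score[truth_sex == "male"]),
            max(preds$y_score[truth_sex == "female"]))
  # retraining with the same data and seed gives a bit-identical model file
  model2 <- train_sex_model(fx$cohort$beta, fx$cohort$sheet,
                            fx$cohort$annotation, seed = 31)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_model(model, f1); write_model(model2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # all-female input cannot be trained on
  sheet_f <- fx$cohort$sheet; sheet_f$sex <- "female"
  expect_error(train_sex_model(fx$cohort$beta, sheet_f,
                               fx$cohort$annotation), "male")
})
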