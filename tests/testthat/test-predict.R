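test_that("projection is centered, scaled and sign-oriented as stored", {
  model <- toy_model()
  # z exactly at the centers scores (0, 0)
  z <- matrix(0, 4, 1, dimnames = list(c("x1", "x2", "y1", "y2"), "s1"))
  sc <- project_samples(z, model)
  expect_equal(c(sc$x_score, sc$y_score), c(0, 0))
  # one-probe axis reduces to the oriented centered z-value
  m1 <- toy_model(x_probes = "x1", y_probes = "y1",
                  x_center = 0, y_center = 0,
                  x_loadings = 1, y_loadings = 1)
  z1 <- matrix(c(2.5, -1), 2, 1, dimnames = list(c("x1", "y1"), "s1"))
  sc1 <- project_samples(z1, m1)
  expect_equal(sc1$x_score, 2.5)
  expect_equal(sc1$y_score, -1)
  # orientation sign flips the score
  m2 <- toy_model(x_probes = "x1", y_probes = "y1", x_loadings = 1,
                  y_loadings = 1, x_sign = -1)
  expect_equal(project_samples(z1, m2)$x_score, -2.5)
})

test_that("missing model probes rescale the projection up to a 20% cap", {
  probes <- sprintf("x%d", 1:10)
  model <- toy_model(x_probes = probes, y_probes = c("y1", "y2"),
                     x_center = rep(0, 10),
                     x_loadings = rep(1 / sqrt(10), 10))
  z_full <- matrix(1, 12, 1, dimnames = list(c(probes, "y1", "y2"), "s1"))
  full <- project_samples(z_full, model)$x_score
  # drop 2 of 10 X probes (20% missing, at the cap): rescaled, same score
  z_part <- z_full[-(1:2), , drop = FALSE]
  part <- project_samples(z_part, model)$x_score
  expect_equal(part, full, tolerance = 1e-12)
  # drop 3 of 10 (30%): beyond tolerance, error names the axis
  expect_error(project_samples(z_full[-(1:3), , drop = FALSE], model),
               "ChrX")
})

test_that("quadrant map is exhaustive, exclusive and breaks ties to 45,XO", {
  cl <- classify_karyotype(c(5, -5, -5, 5, 0), c(-5, 5, -5, 5, 0))
  expect_equal(cl$karyotype, c("46,XX", "46,XY", "45,XO", "47,XXY", "45,XO"))
  expect_equal(cl$predicted_sex,
               c("female", "male", "aneuploid", "aneuploid", "aneuploid"))
  # every finite score pair gets exactly one call
  set.seed(2)
  grid <- classify_karyotype(rnorm(500), rnorm(500))
  expect_true(all(grid$karyotype %in% c("46,XX", "46,XY", "45,XO", "47,XXY")))
  expect_error(classify_karyotype(NaN, 1), "finite")
  # near-boundary annotation uses the training separation
  m <- toy_model(x_separation = 100, y_separation = 100)
  cl2 <- classify_karyotype(c(2, 80), c(80, 80), model = m)
  expect_equal(cl2$near_boundary, c(TRUE, FALSE))
})

test_that("batch membership never changes a sample's prediction", {
  fx <- trained_fixture(seed = 41, n = 100)
  co <- generate_cohort(generator_config(n_samples = 40, seed = 42))
  batch <- estimate_sex(co$beta, co$annotation, fx$model, co$sheet)
  for (i in c(1, 17, 40)) {
    single <- estimate_sex(co$beta[, i, drop = FALSE], co$annotation,
                           fx$model, co$sheet)
    expect_identical(single$x_score, batch$x_score[i])
    expect_identical(single$y_score, batch$y_score[i])
    expect_identical(single$karyotype, batch$karyotype[i])
  }
})

test_that("raising a sample's model ChrY betas never lowers its y_score", {
  fx <- trained_fixture(seed = 43, n = 100)
  co <- generate_cohort(generator_config(
    n_samples = 4,
    karyotype_proportions = c(`46XX` = 0.5, `46XY` = 0.5, `45XO` = 0,
                              `47XXY` = 0),
    seed = 44))
  y_probes <- intersect(fx$model$y_probes, rownames(co$beta))
  base <- estimate_sex(co$beta, co$annotation, fx$model)
  prev <- base$y_score
  b <- co$beta
  for (step in c(0.05, 0.1, 0.2)) {
    b[y_probes, ] <- pmin(co$beta[y_probes, ] + step, 1 - 1e-9)
    cur <- estimate_sex(b, co$annotation, fx$model)$y_score
    expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})

test_that("label mismatches flag binary contradictions only", {
  fx <- trained_fixture(seed = 45, n = 100)
  co <- generate_cohort(generator_config(n_samples = 40, seed = 46))
  sheet <- co$sheet
  # flip two clean labels; give one aneuploid sample a (correct-phenotype) label
  xx <- which(co$truth$karyotype == "46XX")[1]
  xy <- which(co$truth$karyotype == "46XY")[1]
  xo <- which(co$truth$karyotype == "45XO")[1]
  sheet$sex[xx] <- "male"
  sheet$sex[xy] <- "female"
  preds <- estimate_sex(co$beta, co$annotation, fx$model, sheet)
  expect_true(preds$label_mismatch[xx])
  expect_true(preds$label_mismatch[xy])
  # aneuploid calls are flagged through karyotype, never as plain mismatches
  expect_equal(preds$karyotype[xo], "45,XO")
  expect_true(is.na(preds$label_mismatch[xo]))
  # unlabelled samples get NA mismatch
  sheet$sex[3] <- NA
  preds2 <- estimate_sex(co$beta, co$annotation, fx$model, sheet)
  expect_true(is.na(preds2$label_mismatch[3]))
  # without a sheet, all label fields are NA
  preds3 <- estimate_sex(co$beta, co$annotation, fx$model)
  expect_true(all(is.na(preds3$labelled_sex)))
})
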