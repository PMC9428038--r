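test_that("alternating split sends even 0-based positions to training, per patient", {
  X <- matrix(rnorm(12 * 2), 12)
  tbl <- toy_table(X, rep(c("SQ", "LUAD"), each = 6),
                   patient_id = rep(c("a", "b"), each = 6))
  sp <- split_alternating(tbl)
  expect_equal(sp$role[sp$patient_id == "a"],
               c("train", "test", "train", "test", "train", "test"))
  expect_equal(sp$role[sp$patient_id == "b"],
               c("train", "test", "train", "test", "train", "test"))
  # empty in, empty out
  expect_equal(nrow(split_alternating(tbl[0, ])), 0L)
})

test_that("a full-size patient splits 1,920 / 1,920 and odd counts differ by one", {
  cfg <- phantom_config(patients_per_class = 1, patient_amplitude_sd = 0,
                        pixel_noise_sd = 0, baseline_sd = 0, seed = 2)
  cube <- generate_patient_cube(cfg, "SQ", "SQ_01", 1)
  tbl <- split_alternating(flatten_cohort(list(cube)))
  expect_equal(sum(tbl$role == "train"), 1920L)
  expect_equal(sum(tbl$role == "test"), 1920L)
  odd <- split_alternating(toy_table(matrix(rnorm(10), 5), rep("SQ", 5),
                                     patient_id = rep("a", 5)))
  expect_equal(abs(sum(odd$role == "train") - sum(odd$role == "test")), 1L)
})

test_that("pooled covariance matches the hand-worked two-class example", {
  # channel 1 carries the classes {0,0,2,2} and {8,8,10,10}; channel 2 is
  # an alternating 0/1 pattern, uncorrelated with channel 1 within class
  X <- cbind(c(0, 0, 2, 2, 8, 8, 10, 10), rep(c(0, 1), 4))
  tbl <- toy_table(X, rep(c("SQ", "LUAD"), each = 4))
  m <- fit_discriminant(tbl, "linear", ridge_eps = 0)
  expect_equal(unname(m$means[, 1]), c(1, 9))
  expect_equal(unname(m$cov[1, 1]), 4 / 3) # unbiased, pooled over 6 df
  expect_equal(unname(m$cov[1, 2]), 0)
  expect_equal(unname(m$priors), c(0.5, 0.5))
})

test_that("identical data passed as two classes scores them equally", {
  X <- matrix(rnorm(8 * 3), 8)
  tbl <- toy_table(rbind(X, X), rep(c("SQ", "LUAD"), each = 8))
  m <- fit_discriminant(tbl, "linear")
  sc <- discriminant_scores(m, matrix(rnorm(6 * 3), 6))
  expect_equal(sc[, "SQ"], sc[, "LUAD"], tolerance = 1e-9)
})

test_that("singular covariances error without ridge and succeed with it", {
  # duplicated channel makes every covariance rank-deficient
  base <- matrix(rnorm(10), 10)
  X <- cbind(base, base, rnorm(10))
  tbl <- toy_table(X, rep(c("SQ", "LUAD"), each = 5))
  expect_error(fit_discriminant(tbl, "quadratic", ridge_eps = 0), "singular")
  expect_s3_class(fit_discriminant(tbl, "quadratic", ridge_eps = 1e-6), "mir_lda")
})

test_that("a class absent from training is rejected by name", {
  X <- matrix(rnorm(12 * 2), 12)
  tbl <- toy_table(X, rep(c("SQ", "LUAD", "SCLC"), each = 4),
                   role = rep(c("train", "train", "test"), each = 4))
  expect_error(fit_discriminant(tbl, "linear"), "SCLC")
  expect_error(fit_margin(tbl, "c_svc"), "SCLC")
})

test_that("a query at a class mean is assigned that class by every variant", {
  set.seed(4)
  sep <- separable_3class(per_class = 5, p = 3)
  tbl <- toy_table(sep$X, sep$y)
  for (variant in c("linear", "quadratic", "mahalanobis")) {
    m <- fit_discriminant(tbl, variant)
    preds <- predict(m, m$means)
    expect_equal(as.character(preds), m$labels)
  }
})

test_that("an exact midpoint tie resolves to the lexicographically smaller label", {
  # two classes, identical covariance by construction, means (0,0) and (2,0)
  X <- rbind(c(-1, -1), c(1, 1), c(-1, 1), c(1, -1),
             c(1, -1), c(3, 1), c(1, 1), c(3, -1))
  tbl <- toy_table(X, rep(c("SQ", "LUAD"), each = 4))
  m <- fit_discriminant(tbl, "linear")
  pred <- predict(m, matrix(c(1, 0), 1))
  expect_equal(as.character(pred), "LUAD") # "LUAD" < "SQ"
})

test_that("all three variants agree with the direct-formula oracle on random data", {
  set.seed(21)
  Xtr <- matrix(rnorm(40 * 5), 40)
  ytr <- sample(rep(subtype_levels(), length.out = 40))
  Xq <- matrix(rnorm(10 * 5), 10)
  tbl <- toy_table(Xtr, ytr)
  for (variant in c("linear", "quadratic", "mahalanobis")) {
    m <- fit_discriminant(tbl, variant)
    expect_equal(as.character(predict(m, Xq)),
                 unname(oracle_discriminant(Xtr, ytr, Xq, variant)),
                 info = variant)
  }
})

test_that("linear and quadratic variants agree with MASS on well-separated data", {
  skip_if_not_installed("MASS")
  set.seed(31)
  sep <- separable_3class(per_class = 12, p = 2, spread = 1)
  tbl <- toy_table(sep$X, sep$y)
  Xq <- sep$X + matrix(rnorm(length(sep$X), 0, 0.3), nrow(sep$X))
  ours_lin <- predict(fit_discriminant(tbl, "linear", ridge_eps = 0), Xq)
  mass_lin <- predict(MASS::lda(sep$X, grouping = sep$y,
                                prior = rep(1 / 3, 3)), Xq)$class
  expect_equal(as.character(ours_lin), as.character(mass_lin))
  ours_q <- predict(fit_discriminant(tbl, "quadratic", ridge_eps = 0), Xq)
  mass_q <- predict(MASS::qda(sep$X, grouping = sep$y,
                              prior = rep(1 / 3, 3)), Xq)$class
  expect_equal(as.character(ours_q), as.character(mass_q))
})

test_that("with pooled covariance substituted, mahalanobis equals the linear rule", {
  set.seed(13)
  for (rep_i in 1:5) {
    Xtr <- matrix(rnorm(30 * 4), 30)
    ytr <- sample(rep(subtype_levels(), each = 10))
    Xq <- matrix(rnorm(8 * 4), 8)
    tbl <- toy_table(Xtr, ytr)
    lin <- fit_discriminant(tbl, "linear")
    mah <- fit_discriminant(tbl, "mahalanobis")
    mah$covs <- stats::setNames(rep(list(lin$cov), 3), mah$labels)
    expect_equal(as.character(predict(lin, Xq)), as.character(predict(mah, Xq)))
  }
})

test_that("discriminant predictions are translation invariant and deterministic", {
  set.seed(17)
  Xtr <- matrix(rnorm(30 * 4), 30)
  ytr <- rep(subtype_levels(), each = 10)
  Xq <- matrix(rnorm(9 * 4), 9)
  shift <- rnorm(4)
  tbl <- toy_table(Xtr, ytr)
  tbl_s <- toy_table(sweep(Xtr, 2, shift, `+`), ytr)
  Xq_s <- sweep(Xq, 2, shift, `+`)
  for (variant in c("linear", "quadratic", "mahalanobis")) {
    m <- fit_discriminant(tbl, variant)
    m2 <- fit_discriminant(tbl, variant)
    ms <- fit_discriminant(tbl_s, variant)
    expect_identical(predict(m, Xq), predict(m2, Xq))
    expect_equal(as.character(predict(m, Xq)), as.character(predict(ms, Xq_s)))
  }
})

test_that("channel mismatches are rejected at prediction", {
  tbl <- random_table(12, 5, seed = 2)
  tbl$role <- "train"
  m <- fit_discriminant(tbl, "linear")
  expect_error(predict(m, matrix(0, 2, 4)), "channel")
})
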