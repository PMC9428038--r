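test_that("flatten emits pixels row-major per patient, patients in order", {
  cfg <- noise_free_phantom(width = 2, height = 2)
  tbl <- flatten_cohort(generate_cohort(cfg))
  first <- dplyr::filter(tbl, .data$patient_id == tbl$patient_id[1])
  expect_equal(nrow(first), 4L)
  expect_equal(first$row, c(0L, 0L, 1L, 1L))
  expect_equal(first$col, c(0L, 1L, 0L, 1L))
  expect_true(all(tbl$role == "unassigned"))
  # flattened rows reproduce the cube pixels exactly
  cube <- generate_cohort(cfg)$cubes[[1]]
  expect_equal(as.vector(spc_matrix(first)[2, ]), as.vector(cube$absorbance[1, 2, ]))
})

test_that("cohorts on mixed grids cannot be flattened", {
  c1 <- generate_cohort(noise_free_phantom())$cubes[[1]]
  cfg2 <- phantom_config(grid = wn_grid(1800, 648, 8), image_width_px = 4,
                         image_height_px = 3, patients_per_class = 1,
                         patient_amplitude_sd = 0, pixel_noise_sd = 0,
                         baseline_sd = 0)
  c2 <- generate_cohort(cfg2)$cubes[[1]]
  expect_error(flatten_cohort(list(c1, c2)), "different wavenumber grids")
})

test_that("atmospheric suppression annihilates pure contamination and recovers its scale", {
  g <- wn_grid(4000, 648, 8)
  refs <- atmospheric_references(g)
  s <- 0.5 * refs$references["co2", ]
  tbl <- spectra_table(
    tibble::tibble(patient_id = c("a", "b"), subtype = c("SQ", "LUAD"),
                   row = 0, col = 0:1, role = "unassigned"),
    rbind(s, 0 * s), g
  )
  out <- atmospheric_correct(tbl, refs)
  expect_lt(max(abs(spc_matrix(out)[1, ])), 1e-10)
  expect_equal(unname(out$atmospheric_coef[1, "co2"]), 0.5, tolerance = 1e-8)
})

test_that("spectra orthogonal to the references pass through unchanged", {
  g <- wn_grid(4000, 648, 8)
  refs <- atmospheric_references(g)
  # build a spectrum orthogonal to both references and to the constant
  set.seed(1)
  raw <- rnorm(g$n_channels)
  basis <- cbind(1, t(refs$references))
  q <- qr.Q(qr(basis))
  s <- raw - q %*% crossprod(q, raw)
  tbl <- spectra_table(
    tibble::tibble(patient_id = "p", subtype = "SQ", row = 0, col = 0,
                   role = "unassigned"),
    matrix(s, 1), g
  )
  out <- atmospheric_correct(tbl, refs)
  expect_equal(as.vector(spc_matrix(out)), as.vector(s), tolerance = 1e-10)
  expect_lt(max(abs(out$atmospheric_coef)), 1e-10)
})

test_that("fitted coefficients match the explicit normal-equations oracle", {
  g <- wn_grid(4000, 648, 8)
  refs <- atmospheric_references(g)
  set.seed(7)
  S <- matrix(rnorm(5 * g$n_channels), 5)
  tbl <- spectra_table(
    tibble::tibble(patient_id = paste0("p", 1:5), subtype = "SQ",
                   row = 0, col = 0:4, role = "unassigned"),
    S, g
  )
  out <- atmospheric_correct(tbl, refs)
  X <- cbind(1, t(refs$references))
  for (i in 1:5) {
    beta <- oracle_normal_eq(X, S[i, ])
    expect_equal(as.vector(out$atmospheric_coef[i, ]), beta[-1], tolerance = 1e-8)
  }
})

test_that("a rank-deficient reference set is rejected naming the culprit", {
  g <- wn_grid(4000, 648, 8)
  refs <- atmospheric_references(g)
  refs$references <- rbind(refs$references, h2o_copy = refs$references["h2o", ])
  refs$species <- c(refs$species, "h2o_copy")
  tbl <- spectra_table(
    tibble::tibble(patient_id = "p", subtype = "SQ", row = 0, col = 0,
                   role = "unassigned"),
    matrix(0.1, 1, g$n_channels), g
  )
  expect_error(atmospheric_correct(tbl, refs), "rank-deficient.*h2o")
})

test_that("atmospheric correction is linear in its input", {
  g <- wn_grid(1800, 648, 8)
  refs <- atmospheric_references(g)
  set.seed(3)
  A <- matrix(rnorm(2 * g$n_channels), 2)
  mk <- function(M, n) spectra_table(
    tibble::tibble(patient_id = paste0("p", seq_len(n)), subtype = "SQ",
                   row = 0, col = seq_len(n) - 1, role = "unassigned"),
    M, g
  )
  f <- function(M, n = nrow(M)) spc_matrix(atmospheric_correct(mk(M, n), refs))
  lhs <- f(matrix(2 * A[1, ] + 3 * A[2, ], 1), 1)
  rhs <- 2 * f(A)[1, , drop = FALSE] + 3 * f(A)[2, , drop = FALSE]
  expect_equal(as.vector(lhs), as.vector(rhs), tolerance = 1e-9)
})

test_that("full-rank PCA reconstruction is the identity and the map idempotent", {
  set.seed(11)
  # rank-3 matrix: 3 archetypes mixed across 12 rows
  arch <- matrix(rnorm(3 * 20), 3)
  W <- matrix(runif(12 * 3), 12)
  tbl <- toy_table(W %*% arch, rep_len(subtype_levels(), 12))
  out3 <- pca_denoise(tbl, 3)
  expect_equal(spc_matrix(out3), spc_matrix(tbl), tolerance = 1e-9)
  noisy <- toy_table(W %*% arch + matrix(rnorm(12 * 20, 0, 0.1), 12),
                     rep_len(subtype_levels(), 12))
  once <- pca_denoise(noisy, 2)
  twice <- pca_denoise(once, 2)
  expect_equal(spc_matrix(twice), spc_matrix(once), tolerance = 1e-9)
})

test_that("truncated reconstruction matches the eigendecomposition oracle", {
  set.seed(5)
  X <- matrix(rnorm(50 * 145), 50)
  tbl <- toy_table(X, rep_len(subtype_levels(), 50))
  out <- pca_denoise(tbl, 20)
  expect_equal(spc_matrix(out), oracle_rank_k(X, 20), tolerance = 1e-8,
               ignore_attr = TRUE)
  rep20 <- denoise_report(out)
  expect_equal(rep20$n_factors, 20L)
  expect_true(all(diff(rep20$variance_captured) <= 1e-12))
  expect_lte(sum(rep20$variance_captured), 1 + 1e-12)
  expect_equal(rep20$grand_mean, colMeans(X), ignore_attr = TRUE)
  expect_error(pca_denoise(tbl, 0), "n_factors")
})

test_that("denoising never broadens a peak: FWHM preserved within one channel step", {
  g <- wn_grid(1800, 1000, 8)
  sig <- ir_signature("SQ", ir_band(1400, 48, 1, "gaussian"))
  s <- eval_signature(sig, g)
  # rows scaled copies of one gaussian so rank is 1
  scales <- seq(0.5, 1.5, length.out = 10)
  tbl <- spectra_table(
    tibble::tibble(patient_id = paste0("p", 1:10), subtype = "SQ",
                   row = 0, col = 0:9, role = "unassigned"),
    outer(scales, s), g
  )
  wn <- wn_values(g)
  before <- measure_fwhm(wn, spc_matrix(tbl)[1, ])
  after <- measure_fwhm(wn, spc_matrix(pca_denoise(tbl, 1))[1, ])
  expect_lt(abs(before - after), 8)
})

test_that("fingerprint slicing keeps exactly the 145 channels of the analysis window", {
  cfg <- noise_free_phantom()
  tbl <- flatten_cohort(generate_cohort(cfg))
  fp <- slice_fingerprint(tbl)
  wn <- spc_wavenumbers(fp)
  expect_length(wn, 145L)
  expect_equal(wn[1], 1800)
  expect_equal(wn[145], 648)
  # idempotent, identity at full span, error on empty windows
  expect_identical(slice_fingerprint(fp), fp)
  expect_identical(spc_matrix(slice_fingerprint(tbl, 4000, 648)), spc_matrix(tbl))
  expect_error(slice_fingerprint(tbl, 1799, 1795), "No channel")
})
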