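test_that("luminance is the band sum and is linear", {
  arr <- array(2, c(4, 5, 3))
  cube <- hyperspectral_cube(arr, c(400, 500, 600))
  expect_true(all(luminance_map(cube) == 6))
  cube2 <- hyperspectral_cube(arr * 2, c(400, 500, 600))
  expect_equal(luminance_map(cube2), 2 * luminance_map(cube))
})

test_that("percent luminance change recovers programmed contrasts", {
  sc <- generate_scene(scene_spec(texture_amplitude = 0))
  r <- percent_luminance_change(sc$cube, sc$mask)
  expect_equal(r$mean, 0); expect_equal(r$sd, 0)

  # butterfly luminance exactly twice the background
  sc2 <- generate_scene(scene_spec(texture_amplitude = 0,
                                   butterfly_spectrum = 2 * gaussian_spectrum(
                                     seq(360, 660, length.out = 16), 550, 60)))
  r2 <- percent_luminance_change(sc2$cube, sc2$mask)
  expect_equal(r2$mean, 100, tolerance = 1e-9)

  # arbitrary programmed contrast (+37%) on a noiseless scene
  wl <- seq(360, 660, length.out = 16)
  bg <- gaussian_spectrum(wl, 550, 60)
  sc3 <- generate_scene(scene_spec(texture_amplitude = 0,
                                   background_spectrum = bg,
                                   butterfly_spectrum = bg * 1.37))
  r3 <- percent_luminance_change(sc3$cube, sc3$mask)
  expect_equal(r3$mean, 37, tolerance = 1e-9)
  expect_equal(sc3$truth$luminance_contrast_pct, 37, tolerance = 1e-9)
})

test_that("granularity spectra normalize, detect structure, and flag degeneracy", {
  # identical content in two disjoint regions gives identical spectra
  tile <- matrix(sin(2 * pi * (1:16) / 8), 16, 32) +
    matrix(rep(cos(2 * pi * (1:32) / 4), each = 16), 16, 32)
  left <- matrix(FALSE, 16, 32); left[, 1:16] <- TRUE
  g_l <- granularity_spectrum(tile, left)
  g_r <- granularity_spectrum(tile, !left)
  expect_equal(g_l$energy, g_r$energy, tolerance = 1e-9)
  expect_equal(sum(g_l$energy), 1, tolerance = 1e-9)

  # constant region: uniform spectrum with the degeneracy flag
  g0 <- granularity_spectrum(matrix(3, 20, 20), matrix(TRUE, 20, 20))
  expect_true(g0$degenerate)
  expect_equal(g0$energy, rep(1 / 7, 7))

  # a pure sinusoid lands nearly all of its power in its analytic band
  n <- 64; k <- 10
  img <- matrix(rep(sin(2 * pi * k * (0:(n - 1)) / n), each = n), n, n)
  gs <- granularity_spectrum(img, matrix(TRUE, n, n))
  f <- k / n
  band <- as.integer(min(7, max(1, findInterval(f, gs$edges))))
  expect_identical(band, 3L)
  expect_gte(gs$energy[band], 0.95)
})

test_that("KL divergence is zero at equality, asymmetric, and matches hand math", {
  sc <- generate_scene(scene_spec(seed = 41))
  L <- luminance_map(sc$cube)
  g1 <- granularity_spectrum(L, sc$mask)
  expect_equal(kl_divergence(g1, g1), 0, tolerance = 1e-9)

  spec2 <- function(e) list(energy = e, edges = c(0, 1, 2))
  p <- spec2(c(0.9, 0.1)); q <- spec2(c(0.5, 0.5))
  expect_equal(kl_divergence(p, q), 0.9 * log(1.8) + 0.1 * log(0.2),
               tolerance = 1e-6)
  expect_false(isTRUE(all.equal(kl_divergence(p, q), kl_divergence(q, p))))
  expect_error(kl_divergence(p, list(energy = c(1, 0), edges = c(0, 2, 4))),
               "band")
})

test_that("quantum catches integrate sensitivity against radiance", {
  wl <- seq(400, 700, length.out = 4)          # dlambda = 100 everywhere
  rec <- receptor_model(wl, peaks = c(450, 650), sigma = 5, eta = c(1, 1))
  # sensitivities are effectively concentrated in one band each
  spec <- c(3, 0, 0, 7)
  q <- quantum_catches(spec, rec)
  expect_equal(unname(q[1] / q[2]),
               unname(3 / 7 * rec$sensitivity[1, 1] / rec$sensitivity[4, 2]),
               tolerance = 1e-6)
  expect_equal(unname(quantum_catches(2 * spec, rec)), unname(2 * q))

  # flat spectrum: catches equal the sensitivity integrals
  flat <- rep(1, 4)
  expect_equal(unname(quantum_catches(flat, rec)),
               unname(colSums(rec$sensitivity * 100)), tolerance = 1e-12)
})

test_that("JND is zero at the reference, scale-invariant, and matches the dichromat form", {
  sc <- generate_scene(scene_spec(texture_amplitude = 0))
  rec4 <- receptor_model_tetra(sc$cube$wavelengths)
  j <- jnd_map(sc$cube, sc$mask, rec4)
  expect_lt(max(j$jnd), 1e-12)

  # chromatic contrast: global radiance scaling leaves JND unchanged
  wl <- seq(360, 660, length.out = 16)
  sc2 <- generate_scene(scene_spec(
    butterfly_spectrum = gaussian_spectrum(wl, 480, 50),
    texture_amplitude = 0.15, seed = 42))
  j1 <- jnd_map(sc2$cube, sc2$mask, rec4)
  cube3 <- hyperspectral_cube(sc2$cube$data * 3.7, wl)
  j2 <- jnd_map(cube3, sc2$mask, rec4)
  expect_equal(j1$jnd, j2$jnd, tolerance = 1e-12)
  expect_gt(j1$mean, 0)

  # dichromatic reduction: |df1 - df2| / sqrt(e1^2 + e2^2)
  rec2 <- receptor_model(wl, peaks = c(430, 560), sigma = 45, eta = c(1, 3),
                         weber = 0.08)
  j3 <- jnd_map(sc2$cube, sc2$mask, rec2)
  flat <- matrix(sc2$cube$data, ncol = 16)
  ref_spec <- colMeans(flat[!sc2$mask, ])
  qr <- quantum_catches(ref_spec, rec2)
  closed <- apply(flat[sc2$mask, ], 1, function(px) {
    q <- quantum_catches(px, rec2)
    df <- log(q / qr)
    abs(df[1] - df[2]) / sqrt(sum(rec2$e^2))
  })
  expect_lt(max(abs(j3$jnd - closed)), 1e-10)
})

test_that("JND summaries normalize their histograms and expose bimodality", {
  wl <- seq(360, 660, length.out = 16)
  bg <- gaussian_spectrum(wl, 550, 60)
  # butterfly with two spectrally distinct halves: a bimodal JND field
  sp <- scene_spec(texture_amplitude = 0, butterfly_spectrum = bg)
  sc <- generate_scene(sp)
  cube <- sc$cube
  half <- col(sc$mask) <= ncol(sc$mask) / 2
  spec_a <- gaussian_spectrum(wl, 470, 45)
  spec_b <- gaussian_spectrum(wl, 620, 45)
  for (b in seq_along(wl)) {
    plane <- cube$data[, , b]
    plane[sc$mask & half] <- spec_a[b]
    plane[sc$mask & !half] <- spec_b[b]
    cube$data[, , b] <- plane
  }
  j <- jnd_map(cube, sc$mask, receptor_model_tetra(wl))
  s <- jnd_summary(j, breaks = 12)
  expect_equal(sum(s$density$mass), 1, tolerance = 1e-12)
  expect_identical(length(unique(round(j$jnd, 9))), 2L)
  expect_identical(sum(s$density$mass > 0), 2L)

  # constant field: SD exactly 0
  sc0 <- generate_scene(scene_spec(texture_amplitude = 0,
                                   butterfly_spectrum = bg * 1.4))
  j0 <- jnd_map(sc0$cube, sc0$mask, receptor_model_tetra(wl))
  expect_equal(j0$sd, 0, tolerance = 1e-12)
})

test_that("a spectrally matched butterfly is indistinguishable from background", {
  # matched reflectance + achromatic texture: chromatic JND is exactly 0
  # and the pattern spectra of butterfly and background agree closely
  sc <- generate_scene(scene_spec(texture_amplitude = 0.25, seed = 44))
  j <- jnd_map(sc$cube, sc$mask, receptor_model_tetra(sc$cube$wavelengths))
  expect_lt(max(j$jnd), 1e-10)
  L <- luminance_map(sc$cube)
  kl_matched <- kl_divergence(granularity_spectrum(L, sc$mask),
                              granularity_spectrum(L, !sc$mask))
  # contrast case: butterfly carrying a strong artificial grating
  n <- nrow(L)
  L2 <- L
  L2[sc$mask] <- L2[sc$mask] *
    (1 + 0.8 * sin(2 * pi * 12 * col(L)[sc$mask] / n))
  kl_pattern <- kl_divergence(granularity_spectrum(L2, sc$mask),
                              granularity_spectrum(L2, !sc$mask))
  expect_lt(kl_matched, kl_pattern)
})

test_that("cube text serialization round-trips", {
  sc <- generate_scene(scene_spec(H = 10, W = 12, B = 5,
                                  wavelengths = seq(400, 600, 50), seed = 45))
  f <- tempfile(fileext = ".txt")
  write_cube_txt(sc$cube, f)
  c2 <- read_cube_txt(f)
  expect_equal(c2$data, sc$cube$data, tolerance = 1e-12)
  expect_equal(c2$wavelengths, sc$cube$wavelengths)
})
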