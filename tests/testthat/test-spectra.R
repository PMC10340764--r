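test_that("spectrum construction validates and normalises orientation", {
  s <- spectrum(c(1700, 1650, 1600), c(1, 2, 3), "ftir")
  expect_equal(s$wavenumbers, c(1600, 1650, 1700))
  expect_equal(s$intensities, c(3, 2, 1))
  expect_error(spectrum(c(1, 2, 2), c(0, 0, 0)), "monotonic")
  expect_error(spectrum(c(1, 2), c(NA, 0)), "NA")
  # two-column files with and without header, comma or whitespace
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber,intensity", "1600,0.1", "1600.5,0.2"), f)
  expect_equal(read_spectrum(f)$intensities, c(0.1, 0.2))
  writeLines(c("1600 0.1", "1600.5 0.2"), f)
  expect_equal(read_spectrum(f)$wavenumbers, c(1600, 1600.5))
})

test_that("a single band yields a 100% fraction in its window", {
  g <- gen_spectrum(3, bands = data.frame(center = 1655, sigma = 5, area = 30),
                    snr_db = Inf)
  f <- fit_amide1(g$spectrum)
  expect_equal(unname(f$fractions["alpha_helix"]), 100, tolerance = 1e-6)
  expect_equal(sum(f$fractions), 100, tolerance = 1e-6)
  expect_lt(f$residual_rms, 1e-6 * max(g$spectrum$intensities))
})

test_that("known four-band mixtures are recovered within 3 points", {
  bands <- data.frame(
    center = c(1628, 1655, 1672, 1641),
    sigma = c(5, 4.5, 4, 3.5),
    area = c(48, 21, 20, 11)  # beta, alpha, turn, coil
  )
  for (s in c(2, 17, 31)) {
    g <- gen_spectrum(s, bands = bands, snr_db = 40)
    f <- fit_amide1(g$spectrum, seed = s)
    expect_equal(sum(f$fractions), 100, tolerance = 1e-6)
    expect_lt(abs(f$fractions[["beta_sheet"]] - 48), 3)
    expect_lt(abs(f$fractions[["alpha_helix"]] - 21), 3)
    expect_lt(abs(f$fractions[["beta_turn"]] - 20), 3)
    expect_lt(abs(f$fractions[["random_coil"]] - 11), 3)
  }
})

test_that("fractions are invariant to intensity scaling and sum to 100", {
  for (s in c(4, 9)) {
    g <- gen_spectrum(s)
    f1 <- fit_amide1(g$spectrum, seed = s)
    sp <- g$spectrum
    sp$intensities <- sp$intensities * 12.5
    f2 <- fit_amide1(sp, seed = s)
    expect_equal(f1$fractions, f2$fractions, tolerance = 1e-6)
    expect_equal(sum(f1$fractions), 100, tolerance = 1e-6)
    expect_true(all(f1$fractions >= 0))
  }
})

test_that("fit errors are informative on unusable input", {
  sp <- spectrum(seq(1640, 1660, 0.5), rep(1, 41))
  expect_error(fit_amide1(sp), "cover the analysis window")
})

test_that("tyrosine doublet ratio classifies exposure with a >= 1 boundary", {
  d <- tyrosine_doublet(make_doublet_spectrum(0.77))
  expect_equal(d$i850_i830, 0.77, tolerance = 0.01)
  expect_equal(d$state, "buried")
  expect_equal(tyrosine_doublet(make_doublet_spectrum(0.88))$state, "buried")
  d2 <- tyrosine_doublet(make_doublet_spectrum(1.07))
  expect_equal(d2$i850_i830, 1.07, tolerance = 0.01)
  expect_equal(d2$state, "exposed")
  # boundary: equal intensities are exposed
  expect_equal(tyrosine_doublet(make_doublet_spectrum(1.0))$state, "exposed")
  # invariant to a linear baseline removed by correction
  d3 <- tyrosine_doublet(make_doublet_spectrum(0.77, baseline = c(5, 0.01)))
  expect_equal(d3$i850_i830, d$i850_i830, tolerance = 0.02)
  expect_error(tyrosine_doublet(spectrum(seq(500, 700, 0.5),
                                         rep(1, 401), "raman")),
               "820-860")
})

test_that("disulfide conformer banding matches the published windows", {
  expect_equal(disulfide_conformer(510), "g-g-g")
  expect_equal(disulfide_conformer(528), "g-g-t")
  expect_equal(disulfide_conformer(560), "none")
  expect_equal(disulfide_conformer(c(500, 515.9, 516, 530.9, 531, 545, 545.1, 499)),
               c("g-g-g", "g-g-g", "g-g-t", "g-g-t", "t-g-t", "t-g-t",
                 "none", "none"))
})
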