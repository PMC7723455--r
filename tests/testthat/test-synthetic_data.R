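test_that("cp_weight realizes the rigid-site polarization bias", {
  m <- cp_model()
  expect_equal(cp_weight(20e-6, 0, m), 0)
  expect_equal(cp_weight(0, 0.8, m), 0)
  # short contact: rigid helical sites vastly out-polarize the mobile tag
  ratio <- cp_weight(20e-6, 0.85, m) / cp_weight(20e-6, 0.17, m)
  expect_gt(ratio, 10)
  # increasing in S at fixed short contact time
  w <- cp_weight(20e-6, seq(0.05, 1, by = 0.05), m)
  expect_true(all(diff(w) > 0))
  expect_true(all(w >= 0 & w <= 1))
  # long contact times lose intensity to rotating-frame relaxation
  expect_lt(cp_weight(20e-3, 0.85, m), cp_weight(2e-3, 0.85, m))
  expect_error(cp_weight(-1e-6, 0.5, m), "non-negative")
})

test_that("single-population noise-free generation reduces to the simulator", {
  cv <- gen_dephasing(site_population(0.5, 1), "direct", mas = fix_mas9,
                      pair = fix_pair, scale = fix_scale,
                      powder = fix_powder, noise_sd = 0)[[1]]
  ref <- dephasing_curve(effective_coupling(0.5, fix_pair, fix_scale),
                         fix_mas9, fix_powder)
  expect_equal(cv$intensity, ref$intensity, tolerance = 1e-12)
})

test_that("generation is bit-identical under a fixed seed", {
  pops <- list(site_population(0.85, 0.5), site_population(0.34, 0.5))
  a <- gen_dephasing(pops, "cp", t_cp = 20e-6, mas = fix_mas9,
                     pair = fix_pair, scale = fix_scale, powder = fix_powder,
                     noise_sd = 0.02, n_rep = 3, seed = 99)
  b <- gen_dephasing(pops, "cp", t_cp = 20e-6, mas = fix_mas9,
                     pair = fix_pair, scale = fix_scale, powder = fix_powder,
                     noise_sd = 0.02, n_rep = 3, seed = 99)
  expect_identical(a, b)
})

test_that("degenerate ensembles and bad weights are rejected", {
  expect_error(
    gen_dephasing(site_population(0, 1), "cp", t_cp = 20e-6,
                  mas = fix_mas9, pair = fix_pair, scale = fix_scale,
                  powder = fix_powder),
    "nothing polarized")
  expect_error(
    gen_dephasing(list(site_population(0.5, 0.4)), "direct",
                  mas = fix_mas9, pair = fix_pair, scale = fix_scale,
                  powder = fix_powder),
    "sum to 1")
  expect_error(site_population(1.2), "\\[0, 1\\]")
  expect_error(site_population(0.5, weight = -1), "non-negative")
})

test_that("contact-time bias orders the fitted ensemble order parameter", {
  pops <- list(site_population(0.85, 0.5, "rigid-helix"),
               site_population(0.34, 0.5, "mobile-terminus"))
  fit_at <- function(excitation, t_cp = NULL) {
    cv <- gen_dephasing(pops, excitation, t_cp = t_cp, mas = fix_mas9,
                        pair = fix_pair, scale = fix_scale,
                        powder = fix_powder, noise_sd = 0)[[1]]
    fit_dephasing(cv, fix_pair, fix_scale, sim = fix_sim9,
                  uncertainty = "none")$S_fit
  }
  s20 <- fit_at("cp", 20e-6)
  s700 <- fit_at("cp", 700e-6)
  sdir <- fit_at("direct")
  expect_gt(s20, s700)
  expect_gt(s700, sdir)
  # the bias ordering holds for other two-population ensembles too
  pops2 <- list(site_population(0.9, 0.3), site_population(0.2, 0.7))
  fit_at2 <- function(excitation, t_cp = NULL) {
    cv <- gen_dephasing(pops2, excitation, t_cp = t_cp, mas = fix_mas9,
                        pair = fix_pair, scale = fix_scale,
                        powder = fix_powder, noise_sd = 0)[[1]]
    fit_dephasing(cv, fix_pair, fix_scale, sim = fix_sim9,
                  uncertainty = "none")$S_fit
  }
  expect_gte(fit_at2("cp", 20e-6), fit_at2("cp", 700e-6))
  expect_gte(fit_at2("cp", 700e-6), fit_at2("direct"))
})

test_that("synthetic spectra have analytic peak areas and respect seeds", {
  ax <- seq(70, 40, length.out = 1501)
  sp <- gen_spectrum_1d(data.frame(ppm = 55, width = 0.5, area = 2), ax)
  expect_equal(integrate_region_1d(sp, c(50, 60)), 2, tolerance = 0.01)
  expect_error(gen_spectrum_1d(data.frame(ppm = 30, width = 0.5, area = 1),
                               ax), "outside")
  a <- gen_spectrum_1d(data.frame(ppm = 55, width = 0.5, area = 2), ax,
                       noise_sd = 0.05, seed = 4)
  b <- gen_spectrum_1d(data.frame(ppm = 55, width = 0.5, area = 2), ax,
                       noise_sd = 0.05, seed = 4)
  expect_identical(a, b)
  # zero peaks: flat noise, integrals near zero
  z <- gen_spectrum_1d(data.frame(ppm = numeric(0), width = numeric(0),
                                  area = numeric(0)), ax,
                       noise_sd = 0.01, seed = 5)
  expect_lt(abs(integrate_region_1d(z, c(45, 65))),
            0.05 * diff(c(45, 65)))
})

test_that("Met-like 2D spectrum recovers the generated sheet fraction", {
  rt <- region_table()
  w <- rt$windows$Met
  peaks <- data.frame(
    ppm_f1 = c(57.1, 53.75, 50.7),
    ppm_f2 = c(34, 30, 36),
    width_f1 = 0.35, width_f2 = 0.5,
    volume = c(0.67, 0.10, 0.23)
  )
  sp <- gen_spectrum_2d(peaks, seq(65, 45, length.out = 241),
                        seq(42, 24, length.out = 217))
  boxes <- list(helix = list(f1 = w$helix, f2 = c(31.5, 38)),
                coil = list(f1 = w$coil, f2 = c(24.5, 31.5)),
                sheet = list(f1 = c(45, w$sheet[2]), f2 = c(31.5, 40)))
  fr <- class_fractions(integrate_crosspeaks_2d(sp, boxes))
  expect_equal(unname(fr["sheet"]), 0.23, tolerance = 0.05)
  expect_lt(abs(fr[["sheet"]] - 0.23), 0.01)
  expect_equal(sum(fr), 1)
})
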