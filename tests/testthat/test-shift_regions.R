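test_that("Calpha shifts classify into the published analysis windows", {
  expect_equal(classify_shift("Met", 57.0), "helix")
  expect_equal(classify_shift("Met", 52.0), "sheet")
  expect_equal(classify_shift("Met", 53.5), "coil")
  expect_equal(classify_shift("Arg", 58.0), "helix")
  expect_equal(classify_shift("Arg", 55.0), "coil")
  expect_equal(classify_shift("Arg", 52.0), "sheet")
  expect_equal(classify_shift("His", 57.0), "helix")
  expect_equal(classify_shift("His", 54.0), "coil")
  expect_equal(classify_shift("His", 51.0), "sheet")
  expect_error(classify_shift("Trp", 57.0), "unknown residue")
})

test_that("window gaps are unassigned, boundaries go to the higher window", {
  # the 53.3-54.0 ppm strip between the Arg sheet cutoff and coil window has
  # no defined class and must not be silently merged
  expect_equal(classify_shift("Arg", 53.7), "unassigned")
  expect_equal(classify_shift("Met", 54.9), "unassigned")  # 54.8-55.0 gap
  expect_equal(classify_shift("Met", 60.0), "unassigned")  # above all windows
  # shared boundary belongs to the higher-ppm window
  expect_equal(classify_shift("Met", 52.7), "coil")
  expect_equal(classify_shift("His", 56.0), "helix")
  expect_equal(classify_shift("His", 52.5), "coil")
})

test_that("secondary-shift-difference classification matches the windows", {
  rc <- random_coil_table()
  expect_equal(classify_dca_dcb("Met", rc$Met[["ca"]], rc$Met[["cb"]]), "coil")
  # +4 ppm secondary shift difference: helical; -4 ppm: sheet
  expect_equal(classify_dca_dcb("Met", rc$Met[["ca"]] + 2,
                                rc$Met[["cb"]] - 2), "helix")
  expect_equal(classify_dca_dcb("Met", rc$Met[["ca"]] - 2,
                                rc$Met[["cb"]] + 2), "sheet")
  expect_error(classify_dca_dcb("Gly", 45, 0), "no random-coil")

  # consistency with the window classification for helix/sheet placements,
  # with Cbeta mirroring the same secondary-structure offset (coil windows
  # are not centered on the random-coil reference, so only the signed
  # classes admit this check)
  for (res in c("Met", "Arg", "His")) {
    rt <- region_table()
    for (cl in c("helix", "sheet")) {
      w <- rt$windows[[res]][[cl]]
      ca <- if (cl == "sheet") w[2] - 1.5 else mean(w)
      offset <- ca - rc[[res]][["ca"]]
      cb <- rc[[res]][["cb"]] - offset  # opposite-signed Cbeta offset
      expect_equal(classify_dca_dcb(res, ca, cb, rc), cl,
                   label = paste(res, cl))
      expect_equal(classify_shift(res, ca, rt), cl, label = paste(res, cl))
    }
  }
})

test_that("1D integration recovers rectangles and analytic Gaussian areas", {
  ax <- seq(70, 40, length.out = 3001)
  rect <- ifelse(ax >= 54 & ax <= 56, 1, 0)
  sp <- spectrum_1d(ax, rect)
  expect_equal(integrate_region_1d(sp, c(50, 60)), 2, tolerance = 0.01)
  g <- gen_spectrum_1d(data.frame(ppm = 55, width = 0.5, area = 3.2), ax)
  expect_equal(integrate_region_1d(g, c(50, 60)), 3.2, tolerance = 0.01)
  flat <- spectrum_1d(ax, rep(0, length(ax)))
  expect_equal(integrate_region_1d(flat, c(50, 60)), 0)
  expect_error(integrate_region_1d(g, c(10, 20)), "overlap")
  # ascending input axis gives the same area
  g2 <- spectrum_1d(rev(ax), rev(g$intensity))
  expect_equal(integrate_region_1d(g2, c(50, 60)),
               integrate_region_1d(g, c(50, 60)))
})

test_that("2D crosspeak volumes are analytic and order-invariant", {
  a1 <- seq(65, 45, length.out = 301)
  a2 <- seq(42, 24, length.out = 271)
  peaks <- data.frame(ppm_f1 = c(57, 50.5), ppm_f2 = c(33, 36),
                      width_f1 = 0.4, width_f2 = 0.5,
                      volume = c(1.0, 0.3))
  sp <- gen_spectrum_2d(peaks, a1, a2)
  b_helix <- list(f1 = c(55, 59.2), f2 = c(30, 36))
  b_sheet <- list(f1 = c(46, 52.7), f2 = c(33.5, 39))
  v <- integrate_crosspeaks_2d(sp, list(helix = b_helix, sheet = b_sheet))
  expect_equal(unname(v["helix"]), 1.0, tolerance = 0.01)
  expect_equal(unname(v["sheet"]), 0.3, tolerance = 0.01)
  v_swapped <- integrate_crosspeaks_2d(sp, list(sheet = b_sheet,
                                                helix = b_helix))
  expect_equal(unname(v_swapped["helix"]), unname(v["helix"]))
  # empty region integrates to ~0
  v0 <- integrate_crosspeaks_2d(sp, list(list(f1 = c(60, 64),
                                              f2 = c(25, 29))))
  expect_lt(abs(v0), 1e-6)
  expect_error(
    integrate_crosspeaks_2d(sp, list(b_helix, list(f1 = c(54, 56),
                                                   f2 = c(29, 31)))),
    "overlap")
})

test_that("integration is linear in the spectrum", {
  ax <- seq(70, 40, length.out = 1501)
  g1 <- gen_spectrum_1d(data.frame(ppm = 55, width = 0.5, area = 1), ax)
  g2 <- gen_spectrum_1d(data.frame(ppm = 58, width = 0.7, area = 2), ax)
  both <- spectrum_1d(g1$ppm, g1$intensity + g2$intensity)
  w <- c(50, 62)
  expect_equal(integrate_region_1d(both, w),
               integrate_region_1d(g1, w) + integrate_region_1d(g2, w),
               tolerance = 1e-10)
})

test_that("class fractions normalize and reject degenerate input", {
  f <- class_fractions(c(helix = 77, sheet = 23))
  expect_equal(sum(f), 1)
  expect_equal(unname(f["sheet"]), 0.23)
  expect_equal(unname(class_fractions(c(helix = 5))), 1)
  expect_error(class_fractions(c(a = 0, b = 0)), "all-zero")
  expect_error(class_fractions(c(a = -1, b = 2)), "non-negative")
})

test_that("spectrum constructors normalize axis direction", {
  expect_error(spectrum_1d(c(1, 2, 1.5), c(0, 0, 0)), "monotone")
  s <- spectrum_1d(c(1, 2, 3), c(10, 20, 30))
  expect_equal(s$ppm, c(3, 2, 1))
  expect_equal(s$intensity, c(30, 20, 10))
  M <- matrix(1:6, 2, 3)
  s2 <- spectrum_2d(c(1, 2), c(3, 2, 1), M)
  expect_equal(s2$ppm_f1, c(2, 1))
  expect_equal(s2$intensity[1, ], M[2, ])
})
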