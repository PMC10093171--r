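test_that("disc closed forms: perimeter, moments, eccentricity", {
  g <- make_section(size = 512, outer_radius = 100, inner_radius = 0,
                    resolution = 10)
  geo <- measure_geometry(g$section)
  r <- 100 * 10 / 1000                       # mm
  expect_lt(abs(geo$Ecc - 1), 0.01)
  expect_lt(abs(geo$Pe_min - 2 * pi * r) / (2 * pi * r), 0.01)
  expect_lt(abs(geo$I_max - pi * r^4 / 4) / (pi * r^4 / 4), 0.01)
  expect_lt(abs(geo$I_min - pi * r^4 / 4) / (pi * r^4 / 4), 0.01)
  expect_lt(abs(geo$TCSA - pi * r^2) / (pi * r^2), 0.01)
})

test_that("ellipse with a = 2b has eccentricity 4", {
  g <- make_section(size = 512, outer_radius = 230, inner_radius = 0,
                    axis_ratio = 2)
  geo <- measure_geometry(g$section)
  expect_lt(abs(geo$Ecc - 4) / 4, 0.02)
})

test_that("annulus moments and polar modulus match closed forms", {
  g <- make_section(size = 512, outer_radius = 200, inner_radius = 0.5,
                    resolution = 20)
  geo <- measure_geometry(g$section)
  ro <- 200 * 20 / 1000
  ri <- 0.5 * ro
  I <- pi * (ro^4 - ri^4) / 4
  expect_lt(abs(geo$I_max - I) / I, 0.01)
  expect_lt(abs(geo$I_min - I) / I, 0.01)
  expect_lt(abs(geo$TCSA - pi * ro^2) / (pi * ro^2), 0.01)
  expect_lt(abs(geo$BCSA - 0.75 * pi * ro^2) / (0.75 * pi * ro^2), 0.01)
  expect_lt(abs(geo$Z_pol - 2 * I / ro) / (2 * I / ro), 0.02)
})

test_that("slenderness ratio follows its defining arithmetic", {
  expect_equal(slenderness_ratio(100, I_min = 100, TCSA = 4), 20)
  # solid circular rod of radius r, length 10r: I/A = r^2/4 -> SR = 20
  r <- 3
  expect_equal(slenderness_ratio(10 * r, pi * r^4 / 4, pi * r^2), 20)
  expect_true(is.na(slenderness_ratio(NA, 1, 1)))
})

test_that("dimensional quantities scale with the right powers of resolution", {
  g <- make_section(size = 256, outer_radius = 100, inner_radius = 0.4,
                    axis_ratio = 1.4, resolution = 10)
  s2 <- g$section
  s2$resolution <- 20
  g1 <- measure_geometry(g$section)
  g2 <- measure_geometry(s2)
  expect_equal(g2$TCSA / g1$TCSA, 4, tolerance = 1e-9)
  expect_equal(g2$BCSA / g1$BCSA, 4, tolerance = 1e-9)
  expect_equal(g2$Pe_min / g1$Pe_min, 2, tolerance = 1e-9)
  expect_equal(g2$I_max / g1$I_max, 16, tolerance = 1e-9)
  expect_equal(g2$Ecc, g1$Ecc, tolerance = 1e-12)
  # SR is scale-free: double length and all linear dimensions
  sr1 <- slenderness_ratio(50, g1$I_min, g1$TCSA)
  sr2 <- slenderness_ratio(100, g2$I_min, g2$TCSA)
  expect_equal(sr1, sr2, tolerance = 1e-9)
})

test_that("I_max + I_min equals the direct polar second moment", {
  g <- make_section(size = 256, outer_radius = 100, inner_radius = 0.5,
                    axis_ratio = 1.6, thickness_amp = 0.1, seed = 4)
  geo <- measure_geometry(g$section)
  res_mm <- g$section$resolution / 1000
  idx <- which(g$section$mask == 1L, arr.ind = TRUE)
  x <- idx[, 2] * res_mm; y <- idx[, 1] * res_mm
  dx <- x - mean(x); dy <- y - mean(y)
  Jdirect <- sum(dx^2 + dy^2) * res_mm^2 + 2 * nrow(idx) * res_mm^4 / 12
  expect_equal(geo$I_max + geo$I_min, Jdirect, tolerance = 1e-9)
})

test_that("principal axis matches a brute-force rotation search", {
  g <- make_section(size = 256, outer_radius = 110, inner_radius = 0,
                    axis_ratio = 1.8)
  s <- g$section
  sr <- section_image(rotate90(s$mask), s$resolution)
  for (sec in list(s, sr)) {
    geo <- measure_geometry(sec)
    res_mm <- sec$resolution / 1000
    idx <- which(sec$mask == 1L, arr.ind = TRUE)
    x <- idx[, 2] * res_mm; y <- idx[, 1] * res_mm
    dx <- x - mean(x); dy <- y - mean(y)
    phis <- seq(0, pi, length.out = 361)
    # moment about an axis at angle phi: distances perpendicular to the axis
    Is <- vapply(phis, function(phi) {
      sum((-sin(phi) * dx + cos(phi) * dy)^2)
    }, numeric(1))
    best <- phis[which.max(Is)]
    dif <- abs(((geo$major_axis_angle - best) + pi / 2) %% pi - pi / 2)
    expect_lt(dif, pi / 180)
  }
})

test_that("degenerate pixel sets are rejected", {
  m <- matrix(0L, 16, 16)
  m[8, 8] <- 1L
  expect_error(measure_geometry(section_image(m, 10)), "degenerate")
  m[8, 9] <- 1L; m[8, 10] <- 1L
  expect_error(measure_geometry(section_image(m, 10)), "collinear")
})

test_that("the filled-section moment convention behaves like a solid shape", {
  g <- make_section(size = 384, outer_radius = 160, inner_radius = 0.5,
                    resolution = 10)
  solid <- measure_geometry(g$section, moments_on = "filled")
  ro <- 1.6
  I_solid <- pi * ro^4 / 4
  expect_lt(abs(solid$I_max - I_solid) / I_solid, 0.01)
  # BCSA still reports bone area under either convention
  hollow <- measure_geometry(g$section)
  expect_equal(solid$BCSA, hollow$BCSA)
})
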