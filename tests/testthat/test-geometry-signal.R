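test_that("prism dimensions follow the closed forms", {
  dims <- prism_dimensions(geometry_params())
  expect_equal(dims$strut_nm, 3.40)
  expect_equal(dims$side_nm, 7.14)
  expect_equal(dims$volume_nm3, sqrt(3) / 4 * 7.14^2 * 3.40)
  expect_equal(dims$volume_nm3, 75, tolerance = 0.01)
  expect_error(geometry_params(rise_per_bp = 0), "non-positive")
  expect_error(geometry_params(strut_bp = -1), "non-positive")
})

test_that("the coordinate model realizes the declared geometry", {
  p <- geometry_params()
  geom <- build_geometry(p)
  expect_setequal(geom$point,
                  c(paste0("A", 1:3), paste0("B", 1:3), "nickA", "nickB"))
  va <- geom[geom$point %in% paste0("A", 1:3), ]
  vb <- geom[geom$point %in% paste0("B", 1:3), ]
  # equilateral faces with the B-form side length, separated by the strut
  d12 <- sqrt(sum((va[1, c("x", "y", "z")] - va[2, c("x", "y", "z")])^2))
  expect_equal(d12, 7.14, tolerance = 1e-9)
  expect_equal(unique(vb$z), 3.40)
  # nicks sit at side midpoints, radially offset by the helix radius
  nick <- geom[geom$point == "nickA", ]
  mid <- c(mean(va$x[2:3]), mean(va$y[2:3]))
  expect_equal(sqrt(nick$x^2 + nick$y^2),
               sqrt(sum(mid^2)) + p$helix_radius, tolerance = 1e-9)
  # eclipsed faces by default: nickB directly above nickA
  nickB <- geom[geom$point == "nickB", ]
  expect_equal(nick$x, nickB$x, tolerance = 1e-9)
  expect_equal(nickB$z - nick$z, 3.40)
})

test_that("Foerster efficiency behaves as the point-dipole form", {
  expect_equal(fret_efficiency(5.99, 5.99), 0.5)
  expect_equal(fret_efficiency(Inf, 5.99), 0)
  expect_equal(fret_efficiency(5.5, 5.99), 0.625, tolerance = 1e-3)
  r <- seq(0.5, 15, by = 0.25)
  expect_true(all(diff(fret_efficiency(r, 6)) < 0))
  expect_error(fret_efficiency(-1, 6), "non-negative")
  expect_error(fret_efficiency(5, 0), "positive")
})

test_that("invert_fret is the exact inverse of fret_efficiency", {
  expect_equal(invert_fret(0.5, 5.99), 5.99)
  expect_equal(invert_fret(0.625, 5.99), 5.5, tolerance = 1e-3)
  for (r in 2:10) {
    expect_equal(invert_fret(fret_efficiency(r, 5.99), 5.99), r,
                 tolerance = 1e-9)
  }
  expect_error(invert_fret(0, 5.99), "within")
  expect_error(invert_fret(1, 5.99), "within")
})

test_that("the calibrated signal model reproduces the closed-state photophysics", {
  m <- signal_model()
  expect_equal(m$R0, 5.5 / 0.6^(1 / 6))
  expect_equal(m$R0, 5.99, tolerance = 0.01)
  expect_equal(nfi("closed", m), 0.375)
  expect_equal(invert_fret(1 - nfi("closed", m), m$R0), m$r_closed)
})

test_that("NFI respects the structural partial order", {
  m <- signal_model()
  v_closed <- nfi("closed", m)
  v_c3 <- nfi("mono-SD(C3)", m)
  v_lid <- nfi("mono-SD(C1)", m)
  v_tri <- nfi("tri-SD(C1/C2/C3)", m)
  expect_true(v_closed < v_c3)
  expect_true(v_c3 > 0.375 && v_c3 < 0.6)   # a tiny increase, below threshold
  expect_true(v_c3 < v_lid)
  expect_equal(nfi("mono-SD(C2)", m), v_lid)
  expect_equal(nfi("di-SD(C1/C3)", m), v_lid)
  expect_true(v_lid <= v_tri)
  expect_equal(v_tri, 1.0)
  expect_gt(v_lid, 0.6)
  expect_error(nfi("pentagon", m), "unknown state")
})

test_that("signal-model invariants reject inconsistent parameters", {
  expect_error(signal_model(r_closed = 6, r_monoC3 = 5.8))
  expect_error(signal_model(threshold = 1.2))
})

test_that("xyz export writes one record per point", {
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(build_geometry(geometry_params()), path)
  lines <- readLines(path)
  expect_equal(as.integer(lines[1]), 8)
  expect_length(lines, 10)
})
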