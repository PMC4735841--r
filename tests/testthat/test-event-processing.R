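geo <- default_prototype()

test_that("list-mode events reshape into triples with summed energy", {
  ev <- tibble::tibble(event_id = rep(1:2, each = 3), layer = rep(1:3, 2),
                       x_mm = 0, y_mm = 0, z_mm = rep(c(2.5, 67.5, 140), 2),
                       e_kev = c(300, 500, 475, 100, 200, 211))
  tr <- triples_from_events(ev)
  expect_equal(nrow(tr), 2)
  expect_equal(tr$total_kev, c(1275, 511))
  expect_error(triples_from_events(ev[ev$layer != 3, ]), "missing layer")
})

test_that("sum-energy selection keeps the 1275 peak and drops 511", {
  ev <- tibble::tibble(event_id = rep(1:2, each = 3), layer = rep(1:3, 2),
                       x_mm = 0, y_mm = 0, z_mm = rep(c(2.5, 67.5, 140), 2),
                       e_kev = c(300, 500, 475, 100, 200, 211))
  tr <- triples_from_events(ev)
  suppressMessages({
    sel <- select_events(tr, c(800, 1400))
    expect_equal(sel$event_id, 1)    # sum 1275 kept, sum 511 rejected
    expect_equal(attr(sel, "pass_fraction"), 0.5)
    # idempotent
    sel2 <- select_events(sel, c(800, 1400))
    expect_equal(strip_attrs(sel2), strip_attrs(sel))
    # empty input passes through
    expect_equal(nrow(select_events(tr[0, ], c(800, 1400))), 0)
  })
})

test_that("geometric second-scatter angle covers the canonical cases", {
  expect_equal(geometric_cos_angle(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2)), 1)
  expect_equal(geometric_cos_angle(c(0, 0, 0), c(0, 0, 1), c(1, 0, 1)), 0,
               tolerance = 1e-12)
  expect_equal(geometric_cos_angle(c(0, 0, 0), c(0, 0, 1), c(0, 0, 0)), -1)
  expect_error(geometric_cos_angle(c(0, 0, 0), c(0, 0, 0), c(0, 0, 1)),
               "degenerate")
})

test_that("three-interaction energy estimator matches the forward
          construction", {
  # a 611 keV photon deposits 100 keV, leaving 511 keV, which at 90 deg
  # deposits exactly 255.5 keV
  expect_equal(incident_energy_from_triple(100, 255.5, 0), 611,
               tolerance = 1e-9)
  expect_error(incident_energy_from_triple(100, 255.5, 1), "degenerate")
  expect_true(is.na(incident_energy_from_triple(100, 255.5, 1,
                                                on_invalid = "na")))
  expect_error(incident_energy_from_triple(-1, 255.5, 0))
  # E0 always exceeds e1 + e2
  set.seed(77)
  e1 <- runif(200, 50, 500); e2 <- runif(200, 50, 500)
  ct <- runif(200, -1, 0.99)
  expect_true(all(incident_energy_from_triple(e1, e2, ct) > e1 + e2))
})

test_that("noise-free simulated triples recover the incident energy and
          contain the source on the cone", {
  tr <- make_fixture("noise_free_triples", list(n_decays = 3e7), seed = 5)
  expect_gt(nrow(tr), 2)
  ct2 <- geometric_cos_angle(cbind(tr$x1, tr$y1, tr$z1),
                             cbind(tr$x2, tr$y2, tr$z2),
                             cbind(tr$x3, tr$y3, tr$z3))
  e0 <- incident_energy_from_triple(tr$e1, tr$e2, ct2, on_invalid = "na")
  expect_equal(unname(e0), rep(1275, nrow(tr)), tolerance = 1e-9)
  cones <- cone_from_triples(tr, ideal_geometry())
  expect_equal(nrow(cones), nrow(tr))
  # axis normalization
  nrm <- sqrt(cones$axis_x^2 + cones$axis_y^2 + cones$axis_z^2)
  expect_equal(unname(nrm), rep(1, nrow(cones)), tolerance = 1e-12)
  # source-on-cone: the source direction lies on the cone surface
  v <- cbind(-cones$apex_x_mm, -cones$apex_y_mm, -35 - cones$apex_z_mm)
  v <- v / sqrt(rowSums(v^2))
  ang <- acos(pmin(pmax(v[, 1] * cones$axis_x + v[, 2] * cones$axis_y +
                          v[, 3] * cones$axis_z, -1), 1))
  expect_lt(max(abs(ang - cones$half_angle_rad)), 1e-6)
})

test_that("kinematically inconsistent triples are rejected with reason
          counts", {
  # deposits beyond the backscatter limit make |cos theta1| > 1
  tr <- tibble::tibble(event_id = 1:2,
                       e1 = c(500, 100), e2 = c(700, 200), e3 = c(50, 211),
                       x1 = 0, y1 = 0, z1 = 2.5,
                       x2 = 5, y2 = 0, z2 = 67.5,
                       x3 = 5, y3 = 5, z3 = 140,
                       total_kev = c(1250, 511))
  cones <- cone_from_triples(tr, geo)
  rej <- attr(cones, "rejections")
  expect_equal(nrow(cones) + sum(rej), 2)
  expect_true(all(cones$sigma_rad > 0))
})

test_that("blurred 1275-photopeak events yield cones for most events", {
  sim <- sim_midrun()
  tr <- triples_from_events(sim$events)
  suppressMessages(sel <- select_events(tr, c(800, 1400)))
  cones <- cone_from_triples(sel, geo)
  expect_gt(nrow(cones) / nrow(sel), 0.5) # rejection rate < 50%
  # E0 distribution of selected events peaks near 1275 (mode within 2%)
  dens <- density(cones$e0_kev[cones$e0_kev < 2000])
  expect_lt(abs(dens$x[which.max(dens$y)] - 1275) / 1275, 0.02)
})

test_that("cone files round-trip", {
  cones <- make_fixture("analytic_cones", list(n = 20), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cones(cones, path)
  back <- read_cones(path)
  expect_equal(strip_attrs(back), strip_attrs(cones), tolerance = 1e-12)
})
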