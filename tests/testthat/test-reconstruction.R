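geo <- default_prototype()

test_that("voxel grids expose centres and validate", {
  g <- voxel_grid(c(-2, -2, -35), 1, c(5, 5, 1))
  cen <- voxel_centers(g)
  expect_equal(nrow(cen), 25)
  expect_equal(cen[1, ], c(x = -2, y = -2, z = -35))
  expect_equal(cen[25, ], c(x = 2, y = 2, z = -35))
  expect_error(voxel_grid(c(0, 0, 0), -1, c(2, 2, 1)))
  dg <- default_grid(geo)
  # the default grid covers the source position
  expect_true(any(abs(voxel_centers(dg)[, 1]) < 1) &&
                dg$origin_mm[3] == -35)
})

test_that("system rows weight the cone surface with an inverse-square law",
          {
  cone <- list(apex_x_mm = 0, apex_y_mm = 0, apex_z_mm = 0,
               axis_x = 0, axis_y = 0, axis_z = -1,
               half_angle_rad = 0.4, sigma_rad = 0.05)
  # two voxels along the half-angle direction at distances d and 2d
  d <- 30
  dir <- c(sin(0.4), 0, -cos(0.4))
  g1 <- voxel_grid(dir * d, 1, c(1, 1, 1))
  g2 <- voxel_grid(dir * 2 * d, 1, c(1, 1, 1))
  w1 <- system_row(cone, g1)
  w2 <- system_row(cone, g2)
  # on the surface the angular term is exactly 1 -> w = 1/d^2
  expect_equal(as.numeric(w1) * d^2, 1, tolerance = 1e-9)
  expect_equal(as.numeric(w1) / as.numeric(w2), 4, tolerance = 1e-9)
  # weights finite and non-negative on a full grid
  w <- system_row(tibble::as_tibble(cone), default_grid(geo))
  expect_true(all(is.finite(w)) && all(w >= 0))
})

test_that("single noise-free cone backprojects onto its surface", {
  cones <- make_fixture("analytic_cones", list(n = 1, point_mm = c(0, 0, -35),
                                               sigma_rad = 0.01), seed = 9)
  grid <- default_grid(geo)
  img <- mlem_reconstruct(cones, grid, 1)
  sl <- extract_plane(img, -35)
  m <- attr(sl, "matrix")
  w <- system_row(cones[1, ], grid)
  expect_true(all(m[matrix(w == 0, nrow(m))] == 0))
  expect_gt(max(m), 0)
})

test_that("ML-EM raises the list-mode log-likelihood monotonically and
          stays non-negative", {
  set.seed(19)
  cones <- make_fixture("analytic_cones", list(n = 120, sigma_rad = 0.03),
                        seed = 19)
  # jitter the half-angles so the data are not perfectly consistent
  cones$half_angle_rad <- pmax(cones$half_angle_rad +
                                 rnorm(120, 0, 0.03), 0.05)
  img <- mlem_reconstruct(cones, default_grid(geo), 30)
  expect_true(all(img$values >= 0))
  ll <- img$loglik
  expect_true(all(diff(ll) >= -1e-9 * abs(ll[-length(ll)])))
  expect_equal(img$iteration_count, 30)
})

test_that("scaling all system weights leaves the normalized image unchanged",
          {
  cones <- make_fixture("analytic_cones", list(n = 50, sigma_rad = 0.03),
                        seed = 23)
  grid <- default_grid(geo)
  sm <- system_matrix(cones, grid)
  img1 <- mlem_reconstruct(sm, grid, 10)
  sm2 <- sm; sm2$W <- sm$W * 7.3
  img2 <- mlem_reconstruct(sm2, grid, 10)
  n1 <- img1$values / sum(img1$values)
  n2 <- img2$values / sum(img2$values)
  expect_equal(n1, n2, tolerance = 1e-9)
})

test_that("point-source image peaks at the source and tightens with
          iterations", {
  set.seed(29)
  cones <- make_fixture("analytic_cones",
                        list(n = 500, point_mm = c(3, -2, -35),
                             sigma_rad = 0.05), seed = 29)
  cones$half_angle_rad <- pmax(cones$half_angle_rad +
                                 rnorm(500, 0, 0.05), 0.05)
  grid <- default_grid(geo)
  img30 <- mlem_reconstruct(cones, grid, 30)
  g <- glance(img30)
  expect_lt(abs(g$max_x_mm - 3), 1.01)
  expect_lt(abs(g$max_y_mm + 2), 1.01)
  img5 <- mlem_reconstruct(cones, grid, 5)
  f5 <- profile_fwhm(extract_plane(img5, -35), "x")$fwhm_mm
  f30 <- profile_fwhm(extract_plane(img30, -35), "x")$fwhm_mm
  expect_lte(f30, f5 * 1.05)
})

test_that("plane extraction is exact and bounded", {
  img <- make_fixture("gaussian_image", list(sigma_mm = 4))
  sl <- extract_plane(img, -35)
  expect_equal(attr(sl, "z_mm"), -35)
  expect_equal(as.numeric(attr(sl, "matrix")),
               as.numeric(img$values[, , 1]))
  expect_equal(nrow(sl), 80 * 80)
  expect_error(extract_plane(img, 0), "extent")
})

test_that("images round-trip through text + JSON sidecar", {
  cones <- make_fixture("analytic_cones", list(n = 30, sigma_rad = 0.04),
                        seed = 31)
  img <- mlem_reconstruct(cones, default_grid(geo), 3)
  dir <- withr::local_tempdir()
  write_image(img, file.path(dir, "img"))
  back <- read_image(file.path(dir, "img"))
  expect_equal(back$values, img$values, tolerance = 1e-12)
  expect_equal(back$grid$dims, img$grid$dims)
  expect_equal(back$iteration_count, 30 * 0 + img$iteration_count)
})
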