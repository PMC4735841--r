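geo <- default_prototype()

test_that("22Na emission has the right intensities and geometry", {
  src <- na22_source()
  set.seed(41)
  ph <- emit_decays(src, 1e4)
  # annihilation pairs are antiparallel
  pairs <- ph[ph$e_kev == 511, ]
  split_pairs <- split(pairs, pairs$decay_id)
  two <- split_pairs[vapply(split_pairs, nrow, integer(1)) == 2]
  dots <- vapply(two, function(p) {
    sum(p$ux[1] * p$ux[2] + p$uy[1] * p$uy[2] + p$uz[1] * p$uz[2])
  }, numeric(1))
  expect_equal(unname(dots), rep(-1, length(dots)), tolerance = 1e-12)
  # line intensity 0.999 within 3 binomial sigma
  n1275 <- attr(ph, "n_emitted_1275")
  se <- sqrt(0.999 * 0.001 * 1e4)
  expect_lt(abs(n1275 - 0.999 * 1e4), 3 * se + 1)
  # origins confined to the 0.25 mm disc at the source plane
  r <- sqrt((ph$x_mm - 0)^2 + (ph$y_mm - 0)^2)
  expect_true(all(r <= 0.125 + 1e-12))
  expect_true(all(ph$z_mm == -35))
})

test_that("inter-decay times are exponential at the source activity", {
  src <- na22_source()
  set.seed(43)
  ph <- emit_decays(src, 1e4)
  t_decay <- sort(unique(ph$t_ns[!duplicated(ph$decay_id)])) * 1e-9
  gaps <- diff(t_decay)
  ks <- suppressWarnings(ks.test(gaps, "pexp", rate = 7e5))
  expect_gt(ks$p.value, 0.001)
})

test_that("aimed emission preserves the 4-pi bookkeeping", {
  src <- na22_source(annihilation = FALSE)
  set.seed(47)
  ph <- emit_decays_aimed(src, 1e5, geometry = geo)
  expect_equal(attr(ph, "n_emitted_1275_equivalent"), 0.999 * 1e5)
  # all primaries point into the 30-degree cone
  expect_true(all(ph$uz >= cos(30 * pi / 180) - 1e-12))
  # incident count is a subset of the aimed photons
  expect_lte(attr(ph, "n_incident_1275"), 0.999 * 1e5 * 0.067)
  expect_gt(attr(ph, "n_incident_1275"), 0)
})

test_that("first-interaction probability follows Beer-Lambert", {
  att <- labr3_attenuation()
  n <- 1e5
  ph <- tibble::tibble(decay_id = seq_len(n), e_kev = 511,
                       x_mm = 0, y_mm = 0, z_mm = -35,
                       ux = 0, uy = 0, uz = 1, t_ns = 0)
  set.seed(53)
  ints <- transport_photons(ph, geo, att)
  first_in_l1 <- sum(ints$layer == 1 & ints$seq == 1)
  p_exp <- 1 - exp(-mu(att, 511, "total") * 5)
  se <- sqrt(p_exp * (1 - p_exp) * n)
  expect_lt(abs(first_in_l1 - p_exp * n), 3 * se)
})

test_that("every photon history conserves energy exactly", {
  src <- na22_source()
  set.seed(59)
  ph <- emit_decays_aimed(src, 3e5, geometry = geo)
  set.seed(60)
  ints <- transport_photons(ph, geo, keep_escapes = TRUE)
  esc <- attr(ints, "escapes")
  tot <- rep(0, nrow(ph))
  dep <- tapply(ints$e_kev, ints$photon_id, sum)
  tot[as.integer(names(dep))] <- dep
  tot[esc$photon_id] <- tot[esc$photon_id] + esc$e_kev
  expect_lt(max(abs(tot - ph$e_kev)), 1e-9)
  # all deposits inside a crystal volume
  for (l in 1:3) {
    li <- ints[ints$layer == l, ]
    lay <- geo$layers[[l]]
    expect_true(all(abs(li$x_mm) <= lay$size_x_mm / 2 + 1e-6))
    expect_true(all(li$z_mm >= lay$z_entry_mm - 1e-6 &
                      li$z_mm <= lay$z_entry_mm + lay$thickness_mm + 1e-6))
  }
})

test_that("compiled transport agrees with the R reference stepper", {
  src <- na22_source(annihilation = FALSE)
  set.seed(61)
  ph <- emit_decays_aimed(src, 4e5, geometry = geo)
  set.seed(62)
  a <- transport_photons(ph, geo)
  set.seed(62)
  b <- comptwin:::transport_photons_r(ph, geo)
  # different RNG consumption patterns: compare layer-interaction statistics
  ta <- tabulate(a$layer, 3); tb <- tabulate(b$layer, 3)
  for (l in 1:3) {
    expect_lt(abs(ta[l] - tb[l]), 4 * sqrt(max(ta[l], tb[l], 1)))
  }
  expect_lt(abs(mean(a$e_kev) - mean(b$e_kev)),
            4 * sd(a$e_kev) * sqrt(1 / nrow(a) + 1 / nrow(b)))
})

test_that("digitize merges same-layer deposits of one decay before blurring",
          {
  ideal <- ideal_geometry()
  ints <- tibble::tibble(
    decay_id = c(1L, 1L, 1L), photon_id = c(1L, 1L, 1L), seq = 1:3,
    layer = c(2L, 2L, 3L),
    x_mm = c(1, 3, 0), y_mm = c(0, 0, 0), z_mm = c(66, 68, 140),
    e_kev = c(100, 200, 50), t_ns = 0, process = "compton")
  set.seed(63)
  m <- digitize(ints, ideal)
  expect_equal(nrow(m), 2)
  l2 <- m[m$layer == 2, ]
  expect_equal(l2$true_e_kev, 300)
  # energy-weighted centroid: (1*100 + 3*200) / 300
  expect_equal(l2$true_x_mm, 7 / 3, tolerance = 1e-12)
  expect_equal(l2$n_merged, 2L)
  expect_equal(l2$n_photons, 1L)
  # ideal geometry reads out exactly
  expect_equal(l2$e_kev, 300, tolerance = 1e-5)
  expect_equal(l2$x_mm, 7 / 3, tolerance = 1e-6)
})

fake_measured <- function(t_ns, layer, e_kev, decay_id = seq_along(t_ns),
                          photon_id = decay_id) {
  z <- c(2.5, 67.5, 140)[layer]
  tibble::tibble(decay_id = as.integer(decay_id), layer = as.integer(layer),
                 x_mm = 0, y_mm = 0, z_mm = z, e_kev = e_kev, t_ns = t_ns,
                 true_x_mm = 0, true_y_mm = 0, true_z_mm = z,
                 true_e_kev = e_kev, photon_id = as.integer(photon_id),
                 seq_min = 1L, n_merged = 1L, n_photons = 1L)
}

test_that("coincidence builder triggers on three above-threshold layers in
          one window", {
  m <- fake_measured(c(0, 5, 10), c(1, 2, 3), c(300, 200, 100),
                     decay_id = c(1, 1, 1))
  ev <- build_coincidences(m, geo)
  expect_equal(length(unique(ev$event_id)), 1)
  expect_equal(ev$layer, 1:3)
  expect_false(any(ev$accidental))
  # two layers only: no trigger
  ev2 <- build_coincidences(fake_measured(c(0, 5), c(1, 2), c(300, 200),
                                          c(1, 1)), geo)
  expect_equal(nrow(ev2), 0)
  # below-threshold layer vetoes the event (threshold inclusive at 50)
  ev3 <- build_coincidences(fake_measured(c(0, 5, 10), c(1, 2, 3),
                                          c(300, 49.9, 100), c(1, 1, 1)),
                            geo)
  expect_equal(nrow(ev3), 0)
  ev4 <- build_coincidences(fake_measured(c(0, 5, 10), c(1, 2, 3),
                                          c(300, 50, 100), c(1, 1, 1)),
                            geo)
  expect_equal(length(unique(ev4$event_id)), 1)
  # interactions outside the 25 ns window do not join
  ev5 <- build_coincidences(fake_measured(c(0, 5, 40), c(1, 2, 3),
                                          c(300, 200, 100), c(1, 1, 1)),
                            geo)
  expect_equal(nrow(ev5), 0)
  expect_error(build_coincidences(fake_measured(c(10, 0, 5), c(1, 2, 3),
                                                c(300, 200, 100)), geo),
               "sorted")
})

test_that("accidental and pile-up truth flags", {
  # interactions from two decays in one window: accidental
  m <- fake_measured(c(0, 5, 10), c(1, 2, 3), c(300, 200, 100),
                     decay_id = c(1, 1, 2), photon_id = c(1, 1, 2))
  ev <- build_coincidences(m, geo)
  expect_true(all(ev$accidental))
  expect_false(any(ev$ordered))
  # two interactions in one layer pile up: energies sum
  m2 <- fake_measured(c(0, 4, 8, 12), c(1, 1, 2, 3),
                      c(300, 100, 200, 100), decay_id = c(1, 2, 1, 1),
                      photon_id = c(1, 2, 1, 1))
  ev2 <- build_coincidences(m2, geo)
  expect_equal(length(unique(ev2$event_id)), 1)
  expect_true(all(ev2$pileup))
  expect_equal(ev2$e_kev[ev2$layer == 1], 400)
  # same-photon multi-scatter merged upstream is not pile-up
  m3 <- fake_measured(c(0, 5, 10), c(1, 2, 3), c(300, 200, 100),
                      decay_id = c(1, 1, 1), photon_id = c(1, 1, 1))
  m3$seq_min <- c(1L, 2L, 3L)
  ev3 <- build_coincidences(m3, geo)
  expect_false(any(ev3$pileup))
  expect_true(all(ev3$ordered))
})

test_that("run_experiment is deterministic and writes well-formed files", {
  src <- na22_source(annihilation = FALSE)
  dir <- withr::local_tempdir()
  a <- run_experiment(geo, src, 3e6, seed = 11,
                      out_prefix = file.path(dir, "a"))
  b <- run_experiment(geo, src, 3e6, seed = 11,
                      out_prefix = file.path(dir, "b"))
  expect_identical(readLines(file.path(dir, "a_events.csv")),
                   readLines(file.path(dir, "b_events.csv")))
  expect_identical(a$counts, b$counts)
  # zero decays: empty but well-formed
  z <- run_experiment(geo, src, 0, seed = 1,
                      out_prefix = file.path(dir, "z"))
  expect_equal(z$counts$n_triples, 0)
  expect_true(file.exists(file.path(dir, "z_events.csv")))
  ev <- read_listmode(file.path(dir, "z_events.csv"))
  expect_equal(nrow(ev), 0)
  expect_true(all(c("event_id", "layer", "e_kev") %in% names(ev)))
})

test_that("triple rate scales with layer-1 solid angle", {
  src <- na22_source(annihilation = FALSE)
  a <- run_experiment(geo, src, 4e7, seed = 21)
  half <- default_prototype()
  half$layers[[1]]$size_x_mm <- half$layers[[1]]$size_x_mm / 2
  b <- run_experiment(half, src, 4e7, seed = 22)
  na <- a$counts$n_triples; nb <- b$counts$n_triples
  expect_lt(abs(nb - na / 2), 3 * sqrt(na / 2 + nb + 1))
})

test_that("without overlapping decays no event exceeds the single-photon
          sum", {
  src <- na22_source(annihilation = FALSE, activity_bq = 1) # no overlap
  sim <- run_experiment(geo, src, 4e7, seed = 31)
  if (sim$counts$n_triples > 0) {
    tr <- triples_from_events(sim$events)
    # 5 sigma of the summed blur at 1275 keV
    smax <- 1275 + 5 * comptwin:::fwhm_to_sigma(0.072 * 511 *
                                                  sqrt(1275 / 511))
    expect_true(all(tr$total_kev <= smax))
    expect_equal(sim$counts$n_accidental, 0)
    expect_equal(sim$counts$n_pileup, 0)
  } else {
    succeed()
  }
})
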