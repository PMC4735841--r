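test_that("Compton kinematics closed forms are exact", {
  expect_equal(scattered_energy(511, 1), 511)
  expect_equal(scattered_energy(511, 0), 255.5)
  # backscatter of the 1275 keV line: 1275 / (1 + 2 * 1275/511)
  expect_equal(scattered_energy(1275, -1), 1275 / (1 + 2 * 1275 / 511),
               tolerance = 1e-12)
  expect_equal(scattered_energy(1275, -1), 212.85, tolerance = 1e-4)
  expect_equal(backscatter_limit(511), 511 / 3, tolerance = 1e-12)
  expect_equal(backscatter_limit(1275), scattered_energy(1275, -1),
               tolerance = 1e-12)
  # low-energy limit: E' -> E0
  expect_equal(backscatter_limit(1e-6), 1e-6, tolerance = 1e-8)
})

test_that("cos_scatter_angle inverts scattered_energy", {
  expect_equal(cos_scatter_angle(511, 255.5), 0)
  expect_equal(cos_scatter_angle(1275, 1275 - scattered_energy(1275, -1)),
               -1, tolerance = 1e-9)
  set.seed(101)
  e0 <- runif(1000, 60, 2000)
  ct <- runif(1000, -1, 1)
  dep <- e0 - scattered_energy(e0, ct)
  expect_equal(cos_scatter_angle(e0, dep), ct, tolerance = 1e-9)
})

test_that("kinematically impossible pairs are rejected", {
  # 400 keV exceeds the 511 keV backscatter deposit limit (340.67 keV)
  expect_gt(400, 511 - backscatter_limit(511))
  expect_error(cos_scatter_angle(511, 400), "inconsistent")
  expect_true(is.na(cos_scatter_angle(511, 400, on_invalid = "na")))
  expect_error(cos_scatter_angle(511, 511), "e_dep")
  expect_error(scattered_energy(511, 1.5), "cos_theta")
  expect_error(scattered_energy(-1, 0), "e0")
})

test_that("scattered energy is bounded by the backscatter limit and e0", {
  set.seed(7)
  e0 <- runif(500, 40, 2000)
  ct <- runif(500, -1, 1)
  ep <- scattered_energy(e0, ct)
  expect_true(all(ep <= e0 + 1e-12))
  expect_true(all(ep >= backscatter_limit(e0) - 1e-12))
})

test_that("Klein-Nishina density is non-negative, normalizable and has the
          Thomson low-energy limit", {
  ct <- seq(-1, 1, length.out = 1000)
  for (e0 in c(100, 511, 1275)) {
    expect_true(all(klein_nishina_pdf(e0, ct) >= 0))
  }
  z <- integrate(function(x) klein_nishina_pdf(511, x, normalize = TRUE),
                 -1, 1, rel.tol = 1e-9)
  expect_equal(z$value, 1, tolerance = 1e-6)
  # e0 -> 0: shape approaches Thomson (1 + cos^2)/2 up to normalization
  thomson <- (1 + ct^2) / 2
  ratio <- klein_nishina_pdf(1, ct) / thomson
  expect_lt(max(abs(ratio / mean(ratio) - 1)), 0.01)
})

test_that("Klein-Nishina sampler matches the analytic density", {
  set.seed(11)
  s <- sample_scatter_angle(rep(511, 1e5))
  expect_true(all(s >= -1 & s <= 1))
  # chi-square against the binned analytic pdf
  brk <- seq(-1, 1, length.out = 41)
  obs <- table(cut(s, brk))
  p <- vapply(seq_len(40), function(i) {
    integrate(function(x) klein_nishina_pdf(511, x, normalize = TRUE),
              brk[i], brk[i + 1])$value
  }, numeric(1))
  chi <- suppressWarnings(chisq.test(as.numeric(obs), p = p / sum(p)))
  expect_gt(chi$p.value, 0.001)
  # sampler mean matches the numerical expectation of the density
  m_th <- integrate(function(x) x * klein_nishina_pdf(511, x,
                                                      normalize = TRUE),
                    -1, 1)$value
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - m_th), 3 * se)
  # reproducibility under a fixed seed
  set.seed(42); a <- sample_scatter_angle(rep(662, 100))
  set.seed(42); b <- sample_scatter_angle(rep(662, 100))
  expect_identical(a, b)
})

test_that("attenuation interpolation is exact at nodes and log-log between",
          {
  att <- labr3_attenuation()
  e <- att$energy_kev
  expect_equal(mu(att, e, "compton"), att$mu_compton_mm, tolerance = 1e-12)
  expect_equal(mu(att, e, "photoelectric"), att$mu_pe_mm,
               tolerance = 1e-12)
  expect_equal(mu(att, e, "total"), att$mu_compton_mm + att$mu_pe_mm,
               tolerance = 1e-12)
  # Beer-Lambert consistency over a 5 mm crystal
  mt <- mu(att, 511, "total")
  expect_equal(exp(-mt * 5), exp(-(mu(att, 511, "compton") +
                                     mu(att, 511, "photoelectric")) * 5),
               tolerance = 1e-12)
  # monotone between nodes and within node bounds
  ee <- seq(200, 300, by = 1)
  v <- mu(att, ee, "compton")
  expect_true(all(diff(v) < 0))
  expect_error(mu(att, 10), "range")
  expect_error(mu(att, 5000), "range")
})

test_that("attenuation table round-trips through delimited text", {
  att <- labr3_attenuation()
  path <- withr::local_tempfile(fileext = ".csv")
  write_attenuation(att, path)
  back <- read_attenuation(path, material_name = "LaBr3")
  expect_equal(as.data.frame(back), as.data.frame(att), tolerance = 1e-12)
})

test_that("attenuation table constructor enforces invariants", {
  tab <- data.frame(energy_kev = c(100, 50), mu_compton_mm = c(1, 1),
                    mu_pe_mm = c(1, 1))
  expect_error(attenuation_table(tab), "ascending")
  tab2 <- data.frame(energy_kev = c(50, 100), mu_compton_mm = c(1, -1),
                     mu_pe_mm = c(1, 1))
  expect_error(attenuation_table(tab2), "> 0")
})
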