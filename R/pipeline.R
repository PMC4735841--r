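#' Deterministic per-stage child seeds
#'
#' Expands one global seed into independent stage seeds with a fixed
#' multiplicative congruential step (Park-Miller modulus), so each pipeline
#' stage is reproducible in isolation. Results stay inside the 32-bit
#' integer range.
#'
#' @param seed Global integer seed.
#' @param stage Stage index (1 = emission, 2 = transport, 3 = digitization,
#'   higher values free for analysis stages).
#' @return Integer child seed.
#' @export
child_seed <- function(seed, stage) {
  m <- 2147483647
  x <- (as.double(seed) %% m + 1) # avoid the absorbing state 0
  for (k in seq_len(stage)) {
    x <- (x * 48271) %% m
  }
  as.integer(x)
}

#' Default pipeline configuration
#'
#' Nested list mirroring the measurement: prototype geometry and response,
#' 22Na source, simulation size and seed, sum-energy selection window,
#' ML-EM settings and voxel grid. Every physical quantity carries its unit
#' in the key name. The default simulation sizes (with cone-restricted
#' emission) are chosen so the sum-energy-selected sample exceeds 500
#' triples (`n_decays_equivalent`, the 1275 keV line component with its
#' annihilation partners), the 511 keV sum photopeak holds on the order of
#' a hundred events (`n_decays_equivalent_pair`), and the single-line
#' efficiency is measured to a few percent
#' (`n_decays_equivalent_efficiency`).
#'
#' @return Named nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    geometry = list(
      spacing_mode = "face",
      source_to_layer1_mm = 35,
      layer1_to_layer2_mm = 60,
      layer2_to_layer3_mm = 65,
      coincidence_window_ns = 25,
      layers = list(
        list(size_x_mm = 27.2, size_y_mm = 26.8, thickness_mm = 5,
             energy_resolution_511 = 0.064, position_fwhm_mm = 1,
             threshold_kev = 50),
        list(size_x_mm = 32, size_y_mm = 36, thickness_mm = 5,
             energy_resolution_511 = 0.074, position_fwhm_mm = 1,
             threshold_kev = 50),
        list(size_x_mm = 32, size_y_mm = 36, thickness_mm = 10,
             energy_resolution_511 = 0.072, position_fwhm_mm = 1,
             threshold_kev = 50))),
    source = list(activity_bq = 7e5, disc_diameter_mm = 0.25,
                  annihilation = TRUE, line_energy_kev = 1275,
                  line_intensity = 0.999, pair_intensity = 0.903),
    simulation = list(seed = 1, n_decays_equivalent = 1.45e9,
                      n_decays_equivalent_pair = 3.5e8,
                      n_decays_equivalent_efficiency = 4.5e8,
                      emission = "aimed"),
    processing = list(sum_window_kev = c(800, 1400)),
    reconstruction = list(n_iterations = 30, grid_n = 80,
                          voxel_size_mm = 1, sigma_floor_rad = 0.01,
                          sensitivity = "uniform")),
    class = "run_config")
}

#' Build the geometry / source objects a config describes
#'
#' @param config A `run_config` list.
#' @return For `config_geometry()`, a [telescope_geometry()]; for
#'   `config_source()`, a [na22_source()].
#' @export
config_geometry <- function(config) {
  g <- config$geometry
  zs <- numeric(3)
  th <- vapply(g$layers, function(l) l$thickness_mm, numeric(1))
  gaps <- c(g$layer1_to_layer2_mm, g$layer2_to_layer3_mm)
  if (identical(g$spacing_mode, "center")) {
    ctr <- cumsum(c(th[1] / 2, gaps))
    zs <- ctr - th / 2
  } else {
    zs <- c(0, th[1] + gaps[1], th[1] + gaps[1] + th[2] + gaps[2])
  }
  layers <- lapply(1:3, function(i) {
    l <- g$layers[[i]]
    layer_spec(i, l$size_x_mm, l$size_y_mm, l$thickness_mm, zs[i],
               l$energy_resolution_511, l$position_fwhm_mm, l$threshold_kev)
  })
  telescope_geometry(layers, g$source_to_layer1_mm, g$coincidence_window_ns,
                     g$spacing_mode)
}

#' @rdname config_geometry
#' @export
config_source <- function(config) {
  s <- config$source
  na22_source(position_mm = c(0, 0, -config$geometry$source_to_layer1_mm),
              activity_bq = s$activity_bq,
              disc_diameter_mm = s$disc_diameter_mm,
              annihilation = s$annihilation,
              lines = tibble::tibble(energy_kev = s$line_energy_kev,
                                     intensity = s$line_intensity),
              pair_intensity = s$pair_intensity)
}

#' Read / write a run configuration as YAML
#'
#' Configurations round-trip: `read_run_config(write_run_config(cfg))`
#' reproduces the list content.
#'
#' @param config A `run_config`.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$processing$sum_window_kev <- as.numeric(cfg$processing$sum_window_kev)
  validate_run_config(structure(cfg, class = "run_config"))
}

#' @rdname write_run_config
#' @export
validate_run_config <- function(config) {
  stopifnot(length(config$geometry$layers) == 3,
            config$source$activity_bq > 0,
            config$simulation$n_decays_equivalent >= 0,
            length(config$processing$sum_window_kev) == 2,
            config$reconstruction$n_iterations >= 1)
  config_geometry(config) # runs the geometry invariants
  config
}

#' Run the full simulation-to-analysis pipeline
#'
#' simulate -> process (sum-energy selection, cone building) ->
#' reconstruct (list-mode ML-EM) -> analyze (sum-spectrum photopeaks,
#' image-profile FWHM, efficiency). Fully deterministic given
#' `config$simulation$seed`. When `out_dir` is given, all intermediate
#' files (events, truth, cones, image, report JSON) are written there.
#'
#' @param config A `run_config` (default [default_config()]).
#' @param out_dir Optional output directory.
#' @param verbose Log stage progress to stderr.
#' @return List with `counts`, `triples`, `selected`, `cones`, `image`,
#'   `spectrum`, `photopeaks`, `profile_x`, `profile_y`, `efficiency`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         verbose = TRUE) {
  config <- validate_run_config(config)
  log_stage <- function(...) if (verbose) message("[comptwin] ", ...)
  geometry <- config_geometry(config)
  source <- config_source(config)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  prefix <- if (is.null(out_dir)) NULL else file.path(out_dir, "run")

  n_line <- config$simulation$n_decays_equivalent
  n_pair <- config$simulation$n_decays_equivalent_pair %||% 0
  if (config$simulation$emission == "isotropic") {
    log_stage("simulate: ", format(n_line, scientific = TRUE),
              " isotropic decays")
    sim <- run_experiment(geometry, source, n_decays = n_line,
                          seed = config$simulation$seed,
                          emission = "isotropic")
  } else {
    # the two emission strata are simulated with independent statistics:
    # the 1275 keV line component (with its annihilation pile-up partners)
    # sized for the imaging targets, the 511 keV pair component sized for
    # the low sum-energy photopeak. Cross-component accidentals are the
    # one coincidence class this allocation does not form.
    log_stage("simulate: line component, ",
              format(n_line, scientific = TRUE), " equivalent decays")
    simA <- run_experiment(geometry, source, n_decays = n_line,
                           seed = config$simulation$seed,
                           emission = "aimed", strata = "line")
    log_stage("simulate: line component, ", simA$counts$n_triples,
              " triples")
    sim <- simA
    if (n_pair > 0 && isTRUE(source$annihilation)) {
      log_stage("simulate: pair component, ",
                format(n_pair, scientific = TRUE), " equivalent decays")
      simB <- run_experiment(geometry, source, n_decays = n_pair,
                             seed = child_seed(config$simulation$seed, 7),
                             emission = "aimed", strata = "pair")
      log_stage("simulate: pair component, ", simB$counts$n_triples,
                " triples")
      off_ev <- max(c(0L, simA$events$event_id))
      off_t <- n_line / source$activity_bq * 1e9
      for (col in c("events", "truth")) {
        simB[[col]]$event_id <- simB[[col]]$event_id + off_ev
      }
      simB$events$t_ns <- simB$events$t_ns + off_t
      simB$truth$window_start_ns <- simB$truth$window_start_ns + off_t
      sim <- list(events = dplyr::bind_rows(simA$events, simB$events),
                  truth = dplyr::bind_rows(simA$truth, simB$truth),
                  counts = simA$counts)
      sim$counts$n_triples_pair <- simB$counts$n_triples
      sim$counts$n_triples <- simA$counts$n_triples + simB$counts$n_triples
      sim$counts$n_decays_equivalent_pair <- n_pair
      for (f in c("n_accidental", "n_pileup", "n_ordered",
                  "n_photons_transported")) {
        sim$counts[[f]] <- simA$counts[[f]] + simB$counts[[f]]
      }
      sim$counts$n_triples_line <- simA$counts$n_triples
    }
  }
  log_stage("simulate: ", sim$counts$n_triples, " triple coincidences")
  if (!is.null(prefix)) {
    readr::write_csv(sim$events, paste0(prefix, "_events.csv"))
    readr::write_csv(sim$truth, paste0(prefix, "_truth.csv"))
  }

  triples <- triples_from_events(sim$events)
  selected <- select_events(triples, config$processing$sum_window_kev)
  cones <- cone_from_triples(selected, geometry)
  log_stage("process: ", nrow(cones), " cones from ", nrow(selected),
            " selected triples")
  if (!is.null(out_dir)) write_cones(cones, file.path(out_dir, "cones.csv"))

  grid <- default_grid(geometry, config$reconstruction$grid_n,
                       config$reconstruction$voxel_size_mm)
  if (nrow(cones) > 0) {
    image <- mlem_reconstruct(cones, grid,
                              n_iterations =
                                config$reconstruction$n_iterations,
                              sensitivity =
                                config$reconstruction$sensitivity,
                              sigma_floor =
                                config$reconstruction$sigma_floor_rad)
    if (!is.null(out_dir)) write_image(image, file.path(out_dir, "image"))
    slice <- extract_plane(image, -geometry$source_to_layer1_mm)
    profile_x <- profile_fwhm(slice, "x")
    profile_y <- profile_fwhm(slice, "y")
  } else {
    log_stage("process: no usable cones; skipping reconstruction")
    image <- NULL
    profile_x <- NULL
    profile_y <- NULL
  }

  spectrum <- sum_spectrum(triples)
  # search windows of about 3.5 expected peak sigma (the summed-energy blur
  # is ~14 keV at 511 and ~24 keV at 1275)
  photopeaks <- find_photopeaks(spectrum, c(511, 1275),
                                search_half_width_kev = c(50, 85))
  # the efficiency quantity is defined for 1275 keV photons alone, so it
  # gets its own annihilation-free run (the imaging components contain
  # cascade-summing triples that a single-line experiment would not)
  n_eff <- config$simulation$n_decays_equivalent_efficiency %||% 0
  if (config$simulation$emission != "isotropic" && n_eff > 0) {
    log_stage("simulate: efficiency component, ",
              format(n_eff, scientific = TRUE), " equivalent decays")
    eff_source <- source
    eff_source$annihilation <- FALSE
    sim_eff <- run_experiment(geometry, eff_source, n_decays = n_eff,
                              seed = child_seed(config$simulation$seed, 8),
                              emission = "aimed", strata = "line")
    efficiency <- compute_efficiency(
      sim_eff$counts, triples_from_events(sim_eff$events),
      config$processing$sum_window_kev)
  } else {
    efficiency <- compute_efficiency(sim$counts, triples,
                                     config$processing$sum_window_kev)
  }
  log_stage("analyze: x-profile FWHM ", round(profile_x$fwhm_mm, 2), " mm")

  report <- list(counts = sim$counts,
                 photopeaks = photopeaks,
                 fwhm_x_mm = if (is.null(profile_x)) NA else
                   profile_x$fwhm_mm,
                 fwhm_y_mm = if (is.null(profile_y)) NA else
                   profile_y$fwhm_mm,
                 efficiency = as.list(efficiency))
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  list(counts = sim$counts, events = sim$events, truth = sim$truth,
       triples = triples, selected = selected, cones = cones, image = image,
       spectrum = spectrum, photopeaks = photopeaks, profile_x = profile_x,
       profile_y = profile_y, efficiency = efficiency, report = report)
}

#' Generate deterministic test fixtures
#'
#' Three oracle-style fixtures used throughout the test-suite:
#' `noise_free_triples` runs the simulator with all blurs off, thresholds at
#' zero and depth reported exactly, keeping only correctly ordered
#' single-photon 1275 keV triples (exact Compton kinematics hold on these);
#' `analytic_cones` builds cones whose surfaces pass exactly through a given
#' point; `gaussian_image` is an image with a known Gaussian profile.
#'
#' @param kind One of `"noise_free_triples"`, `"analytic_cones"`,
#'   `"gaussian_image"`.
#' @param params Named list of parameters: `n_decays` (noise-free),
#'   `point_mm` and `n` (analytic cones), `sigma_mm` and `grid`
#'   (gaussian image).
#' @param seed Integer seed.
#' @return Fixture object (tibble or `mlem_image`-shaped list).
#' @export
make_fixture <- function(kind = c("noise_free_triples", "analytic_cones",
                                  "gaussian_image"),
                         params = list(), seed = 1) {
  kind <- match.arg(kind)
  switch(kind,
    noise_free_triples = {
      n <- params$n_decays %||% 2e7
      geometry <- ideal_geometry()
      # a true point source: the oracle checks exact kinematic identities
      source <- na22_source(annihilation = FALSE, disc_diameter_mm = 0)
      sim <- run_experiment(geometry, source, n_decays = n, seed = seed,
                            emission = "aimed")
      # single-photon events in layer order with exactly one interaction
      # per layer: the exact-kinematics subset
      tr <- sim$truth
      single <- tapply(tr$n_merged == 1, tr$event_id, all)
      keep <- tr$event_id[tr$ordered & !duplicated(tr$event_id)]
      keep <- keep[single[as.character(keep)]]
      triples_from_events(sim$events[sim$events$event_id %in% keep, ])
    },
    analytic_cones = {
      point <- params$point_mm %||% c(0, 0, -35)
      n <- params$n %||% 100
      set.seed(seed)
      apex <- cbind(stats::runif(n, -12, 12), stats::runif(n, -12, 12),
                    stats::runif(n, 0, 5))
      w <- point - t(apex) # 3 x n, apex -> point
      w <- t(w) / sqrt(colSums(w^2))
      half <- stats::runif(n, 0.2, 0.7)
      phi <- stats::runif(n, 0, 2 * pi)
      axis <- rotate_dirs(w, cos(half), phi)
      tibble::tibble(event_id = seq_len(n),
                     apex_x_mm = apex[, 1], apex_y_mm = apex[, 2],
                     apex_z_mm = apex[, 3],
                     axis_x = axis[, 1], axis_y = axis[, 2],
                     axis_z = axis[, 3],
                     half_angle_rad = half,
                     sigma_rad = params$sigma_rad %||% 0.02,
                     e0_kev = 1275)
    },
    gaussian_image = {
      sigma <- params$sigma_mm %||% 3.312
      grid <- params$grid %||% default_grid()
      ctr <- params$center_mm %||% c(0, 0)
      cen <- voxel_centers(grid)
      vals <- exp(-((cen[, 1] - ctr[1])^2 + (cen[, 2] - ctr[2])^2) /
                    (2 * sigma^2))
      structure(list(values = array(vals, dim = grid$dims), grid = grid,
                     iteration_count = 0, loglik = NULL,
                     n_events = 0, usable = NULL),
                class = "mlem_image")
    })
}

#' Blur-free variant of the default prototype (oracle runs)
#'
#' The default geometry with energy resolution effectively zero, perfect
#' position readout (including true depth) and thresholds at zero; used to
#' validate exact kinematic identities.
#'
#' @return A [telescope_geometry()] whose layers carry an `ideal = TRUE`
#'   marker honoured by [digitize()]-level responses.
#' @export
ideal_geometry <- function() {
  g <- default_prototype()
  g$layers <- lapply(g$layers, function(l) {
    l$energy_resolution_511 <- 1e-12
    l$position_fwhm_mm <- 1e-12
    l$threshold_kev <- 0
    l$ideal <- TRUE
    l
  })
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
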