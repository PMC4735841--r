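#' A 22Na point-source specification
#'
#' Default emission model: back-to-back 511 keV annihilation pairs with
#' intensity 0.903 per decay (isotropic common axis) and one 1275 keV photon
#' with intensity 0.999 per decay (the 1274.5 keV line rounded to 1275).
#' The active spot is a 0.25 mm diameter disc perpendicular to the optical
#' axis.
#'
#' @param position_mm Source centre, telescope frame (mm). The default puts
#'   it 35 mm upstream of the layer-1 entrance face, on the axis.
#' @param activity_bq Source activity in becquerel.
#' @param disc_diameter_mm Active-spot diameter in mm.
#' @param annihilation Emit the 511 keV pair component?
#' @param lines Tibble of single-photon lines with columns `energy_kev`,
#'   `intensity` (photons per decay).
#' @param pair_intensity Pairs per decay when `annihilation` is `TRUE`.
#' @return Object of class `source_spec`.
#' @export
na22_source <- function(position_mm = c(0, 0, -35), activity_bq = 7e5,
                        disc_diameter_mm = 0.25, annihilation = TRUE,
                        lines = tibble::tibble(energy_kev = 1275,
                                               intensity = 0.999),
                        pair_intensity = 0.903) {
  stopifnot(activity_bq > 0, length(position_mm) == 3)
  structure(list(position_mm = position_mm, activity_bq = activity_bq,
                 disc_diameter_mm = disc_diameter_mm,
                 annihilation = annihilation, lines = lines,
                 pair_intensity = pair_intensity),
            class = "source_spec")
}

# isotropic unit vectors (n x 3)
iso_dirs <- function(n) {
  uz <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  st <- sqrt(pmax(1 - uz^2, 0))
  cbind(st * cos(phi), st * sin(phi), uz)
}

# unit vectors uniform on the spherical cap cos(theta) in [cos_min, hi]
# around +z
cap_dirs <- function(n, cos_min, hi = 1) {
  uz <- stats::runif(n, cos_min, hi)
  phi <- stats::runif(n, 0, 2 * pi)
  st <- sqrt(pmax(1 - uz^2, 0))
  cbind(st * cos(phi), st * sin(phi), uz)
}

disc_origins <- function(source, n) {
  r <- source$disc_diameter_mm / 2 * sqrt(stats::runif(n))
  phi <- stats::runif(n, 0, 2 * pi)
  cbind(source$position_mm[1] + r * cos(phi),
        source$position_mm[2] + r * sin(phi),
        rep(source$position_mm[3], n))
}

photon_tibble <- function(decay_id, e_kev, origin, dir, t_ns) {
  tibble::tibble(decay_id = decay_id, e_kev = e_kev,
                 x_mm = origin[, 1], y_mm = origin[, 2], z_mm = origin[, 3],
                 ux = dir[, 1], uy = dir[, 2], uz = dir[, 3], t_ns = t_ns)
}

#' Emit primary photons for a batch of decays
#'
#' Fully isotropic emission: each decay produces, with probability
#' `pair_intensity`, two antiparallel 511 keV photons with an isotropic
#' common axis and, with probability `intensity`, one isotropic photon per
#' configured line. Decay times follow a Poisson process at the source
#' activity. Uses the global RNG stream.
#'
#' @param source A [na22_source()].
#' @param n_decays Number of decays to emit.
#' @return Tibble of photons with columns `decay_id`, `e_kev`,
#'   `x_mm,y_mm,z_mm` (origin), `ux,uy,uz` (direction), `t_ns`.
#' @export
emit_decays <- function(source, n_decays) {
  if (n_decays == 0) return(photon_tibble(integer(), numeric(),
                                          matrix(0, 0, 3), matrix(0, 0, 3),
                                          numeric()))
  t_ns <- cumsum(stats::rexp(n_decays, source$activity_bq)) * 1e9
  parts <- list()
  if (source$annihilation) {
    has_pair <- stats::runif(n_decays) < source$pair_intensity
    idx <- which(has_pair)
    if (length(idx) > 0) {
      d <- iso_dirs(length(idx))
      o <- disc_origins(source, length(idx))
      parts$pair <- photon_tibble(rep(idx, 2), rep(511, 2 * length(idx)),
                                  rbind(o, o), rbind(d, -d),
                                  rep(t_ns[idx], 2))
    }
  }
  for (k in seq_len(nrow(source$lines))) {
    has <- stats::runif(n_decays) < source$lines$intensity[k]
    idx <- which(has)
    if (length(idx) > 0) {
      parts[[paste0("line", k)]] <-
        photon_tibble(idx, rep(source$lines$energy_kev[k], length(idx)),
                      disc_origins(source, length(idx)),
                      iso_dirs(length(idx)), t_ns[idx])
    }
  }
  out <- dplyr::bind_rows(parts)
  out <- out[order(out$t_ns, out$decay_id), ]
  attr(out, "n_decays") <- n_decays
  attr(out, "n_emitted_1275") <-
    sum(out$e_kev == 1275)
  out
}

#' Emit decays with cone-restricted (importance-sampled) directions
#'
#' Variance-reduction emitter for the default acceptance geometry: a triple
#' coincidence requires a layer-1 deposit, and every layer lies inside the
#' cone of half-angle `half_angle_deg` around +z as seen from the source, so
#' only decays sending a photon into that cone can contribute events. Decays
#' are stratified: stratum A (probability `0.999 f`, with
#' `f = (1 - cos(half_angle))/2`) has its 1275 keV photon aimed uniformly
#' into the cone, annihilation pair isotropic; stratum B (probability
#' `2 * 0.903 f`) has one 511 keV photon aimed into the cone (partner
#' antiparallel) and its 1275 keV photon isotropic outside the cone. The
#' (negligible, order f^2) both-in-cone overlap is assigned to stratum A.
#' Decay times are the physical Poisson thinning at the source activity, so
#' accidental-coincidence rates are preserved. The tibble carries
#' `n_decays_equivalent` and `n_emitted_1275_equivalent` attributes for
#' efficiency bookkeeping on the 4-pi scale.
#'
#' @param source A [na22_source()].
#' @param n_decays_equivalent Number of physical decays the emitted batch
#'   represents.
#' @param half_angle_deg Cone half-angle; the default 30 degrees
#'   circumscribes layer 1 (half-diagonal 19.1 mm at 35 mm) with margin.
#' @param geometry Optional [telescope_geometry()]. When given, photons
#'   whose straight-line path misses every crystal are dropped at emission
#'   (they can never deposit energy, so this is exact variance reduction),
#'   and the `n_incident_1275` attribute (line photons geometrically
#'   crossing layer 1) is recorded.
#' @param strata `"both"` (default), `"line"` (stratum A only) or
#'   `"pair"` (stratum B only); single-stratum batches let a pipeline
#'   allocate statistics between the line and annihilation components
#'   independently.
#' @return Photon tibble as in [emit_decays()].
#' @export
emit_decays_aimed <- function(source, n_decays_equivalent,
                              half_angle_deg = 30, geometry = NULL,
                              strata = c("both", "line", "pair")) {
  strata <- match.arg(strata)
  cmin <- cos(half_angle_deg * pi / 180)
  f <- (1 - cmin) / 2
  p1275 <- if (nrow(source$lines) > 0) source$lines$intensity[1] else 0
  ppair <- if (source$annihilation) source$pair_intensity else 0
  # stratum weights select which photon must fall inside the cone; the
  # decay still emits its other photons with the physical intensities
  w_line <- if (strata == "pair") 0 else p1275
  w_pair <- if (strata == "line") 0 else ppair
  n_a <- stats::rbinom(1, n_decays_equivalent, w_line * f)
  n_b <- stats::rbinom(1, n_decays_equivalent, w_pair * 2 * f)
  n_rel <- n_a + n_b
  span_ns <- n_decays_equivalent / source$activity_bq * 1e9
  t_ns <- sort(stats::runif(n_rel, 0, span_ns))
  is_a <- sample(rep(c(TRUE, FALSE), c(n_a, n_b)))
  # matrix-level geometric prefilter: drop photons whose straight-line
  # path misses every crystal (they can never deposit energy)
  hits_any <- function(o, d) {
    if (is.null(geometry)) return(rep(TRUE, nrow(o)))
    hit <- rep(FALSE, nrow(o))
    for (l in geometry$layers) {
      b <- layer_bounds(l)
      rb <- ray_box(o, d, b$lo, b$hi)
      hit <- hit | (rb$t_far > pmax(rb$t_near, 0) & rb$t_near > 0)
    }
    hit
  }
  n_incident <- if (is.null(geometry)) NA_real_ else 0
  parts <- list()
  ida <- which(is_a)
  if (n_a > 0) {
    o <- disc_origins(source, n_a)
    d <- cap_dirs(n_a, cmin)
    if (!is.null(geometry)) {
      b1 <- layer_bounds(geometry$layers[[1]])
      rb <- ray_box(o, d, b1$lo, b1$hi)
      n_incident <- sum(rb$t_far > pmax(rb$t_near, 0) & rb$t_near > 0)
    }
    keep <- hits_any(o, d)
    parts$a1275 <- photon_tibble(ida[keep], rep(1275, sum(keep)),
                                 o[keep, , drop = FALSE],
                                 d[keep, , drop = FALSE], t_ns[ida][keep])
    # isotropic annihilation partners of the stratum-A decays
    haspair <- stats::runif(n_a) < ppair
    np <- sum(haspair)
    if (np > 0) {
      d2 <- iso_dirs(np)
      o2 <- disc_origins(source, np)
      idx <- ida[haspair]
      tt <- t_ns[idx]
      k1 <- hits_any(o2, d2)
      k2 <- hits_any(o2, -d2)
      parts$a511 <- photon_tibble(c(idx[k1], idx[k2]),
                                  rep(511, sum(k1) + sum(k2)),
                                  rbind(o2[k1, , drop = FALSE],
                                        o2[k2, , drop = FALSE]),
                                  rbind(d2[k1, , drop = FALSE],
                                        -d2[k2, , drop = FALSE]),
                                  c(tt[k1], tt[k2]))
    }
  }
  idb <- which(!is_a)
  if (n_b > 0) {
    d <- cap_dirs(n_b, cmin)
    o <- disc_origins(source, n_b)
    k1 <- hits_any(o, d)
    k2 <- hits_any(o, -d)
    tt <- t_ns[idb]
    parts$b511 <- photon_tibble(c(idb[k1], idb[k2]),
                                rep(511, sum(k1) + sum(k2)),
                                rbind(o[k1, , drop = FALSE],
                                      o[k2, , drop = FALSE]),
                                rbind(d[k1, , drop = FALSE],
                                      -d[k2, , drop = FALSE]),
                                c(tt[k1], tt[k2]))
    has1275 <- stats::runif(n_b) < p1275
    n1 <- sum(has1275)
    if (n1 > 0) {
      # isotropic outside the cone: uz uniform on [-1, cmin]
      o3 <- disc_origins(source, n1)
      d3 <- cap_dirs(n1, -1, cmin)
      k3 <- hits_any(o3, d3)
      parts$b1275 <- photon_tibble(idb[has1275][k3], rep(1275, sum(k3)),
                                   o3[k3, , drop = FALSE],
                                   d3[k3, , drop = FALSE],
                                   t_ns[idb[has1275]][k3])
    }
  }
  out <- dplyr::bind_rows(parts)
  if (nrow(out) == 0) {
    out <- photon_tibble(integer(), numeric(), matrix(0, 0, 3),
                         matrix(0, 0, 3), numeric())
  } else {
    out <- out[order(out$t_ns, out$decay_id), ]
  }
  attr(out, "n_decays") <- n_rel
  attr(out, "n_decays_equivalent") <- n_decays_equivalent
  attr(out, "n_emitted_1275_equivalent") <- p1275 * n_decays_equivalent
  attr(out, "n_incident_1275") <- n_incident
  attr(out, "cone_fraction") <- f
  out
}

# does the straight-line path of each photon cross the box ahead of it?
hits_box <- function(photons, bounds) {
  rb <- ray_box(cbind(photons$x_mm, photons$y_mm, photons$z_mm),
                cbind(photons$ux, photons$uy, photons$uz),
                bounds$lo, bounds$hi)
  rb$t_far > pmax(rb$t_near, 0) & rb$t_near > 0
}

# vectorized per-group merge of interaction rows on a numeric key:
# energy-weighted centroid, summed energy, earliest time, attributes of the
# highest-energy contributor, and contributor counts. Group order of the
# output is sorted key order.
merge_by_key <- function(key, x) {
  sums <- rowsum(cbind(e = x$e_kev, xe = x$x_mm * x$e_kev,
                       ye = x$y_mm * x$e_kev, ze = x$z_mm * x$e_kev,
                       n = 1), key)
  o_e <- order(key, -x$e_kev)
  rmax <- o_e[!duplicated(key[o_e])]
  o_t <- order(key, x$t_ns)
  rt <- o_t[!duplicated(key[o_t])]
  o_s <- order(key, x$seq)
  rs <- o_s[!duplicated(key[o_s])]
  pk <- key * 2^24 + x$photon_id
  nph <- rowsum(as.numeric(!duplicated(pk)), key)
  tibble::tibble(key = key[rt],
                 true_x_mm = unname(sums[, "xe"] / sums[, "e"]),
                 true_y_mm = unname(sums[, "ye"] / sums[, "e"]),
                 true_z_mm = unname(sums[, "ze"] / sums[, "e"]),
                 true_e_kev = unname(sums[, "e"]),
                 t_ns = x$t_ns[rt],
                 photon_id = x$photon_id[rmax],
                 seq_min = x$seq[rs],
                 n_merged = as.integer(sums[, "n"]),
                 n_photons = as.integer(nph[, 1]))
}

# ray/axis-aligned-box intersection: returns entry and exit distances
# (t_near, t_far); miss when t_far <= max(t_near, eps)
ray_box <- function(p, u, lo, hi) {
  n <- nrow(p)
  tn <- rep(-Inf, n); tf <- rep(Inf, n)
  for (ax in 1:3) {
    ua <- u[, ax]; pa <- p[, ax]
    t1 <- (lo[ax] - pa) / ua
    t2 <- (hi[ax] - pa) / ua
    lo_t <- pmin(t1, t2); hi_t <- pmax(t1, t2)
    par <- ua == 0
    if (any(par)) {
      inside <- pa[par] >= lo[ax] & pa[par] <= hi[ax]
      lo_t[par] <- ifelse(inside, -Inf, Inf)
      hi_t[par] <- ifelse(inside, Inf, -Inf)
    }
    tn <- pmax(tn, lo_t); tf <- pmin(tf, hi_t)
  }
  list(t_near = tn, t_far = tf)
}

layer_bounds <- function(layer) {
  list(lo = c(-layer$size_x_mm / 2, -layer$size_y_mm / 2, layer$z_entry_mm),
       hi = c(layer$size_x_mm / 2, layer$size_y_mm / 2,
              layer$z_entry_mm + layer$thickness_mm))
}

#' Transport photons through the layered detector stack
#'
#' Sequential Monte Carlo photon transport: inside a crystal, free paths are
#' sampled from the total attenuation coefficient; at an interaction the
#' photoelectric branch (probability mu_pe/mu_total) deposits the full
#' remaining energy, otherwise a Compton scatter samples the Klein-Nishina
#' angle, deposits the recoil energy and continues with the scattered energy
#' and direction. Inter-layer space is treated as vacuum; photons may exit
#' sideways, pass through, or scatter back into a previous layer. A photon
#' whose scattered energy falls below `e_cut_kev` (the attenuation-table
#' floor) deposits it locally and terminates, so energy is conserved exactly
#' on every history. Uses the global RNG stream.
#'
#' @param photons Photon tibble from [emit_decays()] (columns `decay_id`,
#'   `e_kev`, `x_mm,y_mm,z_mm`, `ux,uy,uz`, `t_ns`).
#' @param geometry A [telescope_geometry()].
#' @param attenuation An [attenuation_table()].
#' @param e_cut_kev Local-deposit cutoff in keV (must be >= the table floor).
#' @param keep_escapes If `TRUE`, attach a tibble of escaping energies as the
#'   `escapes` attribute (for energy-conservation audits).
#' @return Tibble of true interactions: `decay_id`, `photon_id`, `seq`
#'   (interaction order within the photon history), `layer`,
#'   `x_mm,y_mm,z_mm`, `e_kev` (deposited), `t_ns`, `process`.
#' @export
transport_photons <- function(photons, geometry,
                              attenuation = labr3_attenuation(),
                              e_cut_kev = 30, keep_escapes = FALSE) {
  n <- nrow(photons)
  empty <- tibble::tibble(decay_id = integer(), photon_id = integer(),
                          seq = integer(), layer = integer(),
                          x_mm = numeric(), y_mm = numeric(),
                          z_mm = numeric(), e_kev = numeric(),
                          t_ns = numeric(), process = character())
  if (keep_escapes) {
    attr(empty, "escapes") <- tibble::tibble(photon_id = integer(),
                                             e_kev = numeric())
  }
  if (n == 0) return(empty)
  rng <- range(attenuation$energy_kev)
  if (any(photons$e_kev > rng[2]) || any(photons$e_kev < e_cut_kev)) {
    stop("photon energy outside attenuation table range", call. = FALSE)
  }
  boxes <- do.call(rbind, lapply(geometry$layers, function(l) {
    b <- layer_bounds(l)
    c(b$lo, b$hi)
  }))
  res <- .cpp_transport(cbind(photons$x_mm, photons$y_mm, photons$z_mm,
                              photons$ux, photons$uy, photons$uz,
                              photons$e_kev),
                        boxes, attenuation$energy_kev,
                        attenuation$mu_compton_mm, attenuation$mu_pe_mm,
                        e_cut_kev)
  out <- tibble::tibble(decay_id = photons$decay_id[res$photon_id],
                        photon_id = res$photon_id,
                        seq = res$seq, layer = res$layer,
                        x_mm = res$x_mm, y_mm = res$y_mm, z_mm = res$z_mm,
                        e_kev = res$e_kev,
                        t_ns = photons$t_ns[res$photon_id],
                        process = c("photoelectric", "compton")[res$proc])
  out <- out[order(out$t_ns, out$photon_id, out$seq), ]
  if (keep_escapes) {
    esc <- which(!is.na(res$escape_kev))
    attr(out, "escapes") <- tibble::tibble(photon_id = esc,
                                           e_kev = res$escape_kev[esc])
  }
  out
}

# reference R implementation of the transport stepper (kept as the slow
# cross-check oracle for the compiled kernel; same physics, independent code
# path)
transport_photons_r <- function(photons, geometry,
                                attenuation = labr3_attenuation(),
                                e_cut_kev = 30, keep_escapes = FALSE) {
  n <- nrow(photons)
  empty <- tibble::tibble(decay_id = integer(), photon_id = integer(),
                          seq = integer(), layer = integer(),
                          x_mm = numeric(), y_mm = numeric(),
                          z_mm = numeric(), e_kev = numeric(),
                          t_ns = numeric(), process = character())
  if (n == 0) return(empty)
  eps <- 1e-9
  p <- cbind(photons$x_mm, photons$y_mm, photons$z_mm)
  u <- cbind(photons$ux, photons$uy, photons$uz)
  E <- photons$e_kev
  t_ns <- photons$t_ns
  decay_id <- photons$decay_id
  photon_id <- seq_len(n)
  seq_ct <- integer(n)
  alive <- rep(TRUE, n)
  bounds <- lapply(geometry$layers, layer_bounds)
  nl <- length(bounds)
  rec <- list(); ri <- 0
  esc <- list()
  add_rec <- function(idx, layer, pos, e, process) {
    ri <<- ri + 1
    rec[[ri]] <<- tibble::tibble(decay_id = decay_id[idx],
                                 photon_id = photon_id[idx],
                                 seq = seq_ct[idx],
                                 layer = layer,
                                 x_mm = pos[, 1], y_mm = pos[, 2],
                                 z_mm = pos[, 3], e_kev = e,
                                 t_ns = t_ns[idx], process = process)
  }
  steps <- 0
  while (any(alive)) {
    steps <- steps + 1
    if (steps > 10000) stop("transport did not terminate", call. = FALSE)
    act <- which(alive)
    pa <- p[act, , drop = FALSE]
    # which layer is each active photon inside (0 = none)
    in_layer <- integer(length(act))
    for (l in seq_len(nl)) {
      b <- bounds[[l]]
      ins <- pa[, 1] > b$lo[1] & pa[, 1] < b$hi[1] &
        pa[, 2] > b$lo[2] & pa[, 2] < b$hi[2] &
        pa[, 3] > b$lo[3] & pa[, 3] < b$hi[3]
      in_layer[ins] <- l
    }
    # --- photons in vacuum: advance to the nearest layer or escape ---
    vac <- act[in_layer == 0]
    if (length(vac) > 0) {
      pv <- p[vac, , drop = FALSE]; uv <- u[vac, , drop = FALSE]
      best <- rep(Inf, length(vac))
      for (l in seq_len(nl)) {
        b <- bounds[[l]]
        rb <- ray_box(pv, uv, b$lo, b$hi)
        hit <- rb$t_far > pmax(rb$t_near, eps) & rb$t_near > eps
        best[hit] <- pmin(best[hit], rb$t_near[hit])
      }
      gone <- !is.finite(best)
      if (any(gone)) {
        idx <- vac[gone]
        if (keep_escapes) {
          esc[[length(esc) + 1]] <- tibble::tibble(photon_id = photon_id[idx],
                                                   e_kev = E[idx])
        }
        alive[idx] <- FALSE
      }
      mv <- which(!gone)
      if (length(mv) > 0) {
        p[vac[mv], ] <- pv[mv, , drop = FALSE] +
          uv[mv, , drop = FALSE] * (best[mv] + eps)
      }
    }
    # --- photons inside a crystal: sample a free path ---
    for (l in seq_len(nl)) {
      inl <- act[in_layer == l]
      if (length(inl) == 0) next
      b <- bounds[[l]]
      pl <- p[inl, , drop = FALSE]; ul <- u[inl, , drop = FALSE]
      mu_t <- mu(attenuation, E[inl], "total")
      mu_pe <- mu(attenuation, E[inl], "photoelectric")
      rb <- ray_box(pl, ul, b$lo, b$hi)
      d_exit <- rb$t_far
      s <- stats::rexp(length(inl)) / mu_t
      through <- s >= d_exit
      if (any(through)) {
        i <- which(through)
        p[inl[i], ] <- pl[i, , drop = FALSE] +
          ul[i, , drop = FALSE] * (d_exit[i] + eps)
      }
      hit <- which(!through)
      if (length(hit) > 0) {
        idx <- inl[hit]
        pos <- pl[hit, , drop = FALSE] + ul[hit, , drop = FALSE] * s[hit]
        p[idx, ] <- pos
        seq_ct[idx] <- seq_ct[idx] + 1
        pe <- stats::runif(length(idx)) < mu_pe[hit] / mu_t[hit]
        if (any(pe)) {
          i <- idx[pe]
          add_rec(i, l, pos[pe, , drop = FALSE], E[i], "photoelectric")
          alive[i] <- FALSE
        }
        co <- which(!pe)
        if (length(co) > 0) {
          i <- idx[co]
          ct <- sample_scatter_angle(E[i])
          ep <- scattered_energy(E[i], ct)
          dep <- E[i] - ep
          stopp <- ep < e_cut_kev
          # below-cutoff photons deposit everything locally and terminate
          dep[stopp] <- E[i][stopp]
          add_rec(i, l, pos[co, , drop = FALSE], dep, "compton")
          alive[i[stopp]] <- FALSE
          go <- !stopp
          if (any(go)) {
            ig <- i[go]
            E[ig] <- ep[go]
            phi <- stats::runif(length(ig), 0, 2 * pi)
            u[ig, ] <- rotate_dirs(u[ig, , drop = FALSE], ct[go], phi)
          }
        }
      }
    }
  }
  out <- if (ri > 0) dplyr::bind_rows(rec[seq_len(ri)]) else empty
  out <- out[order(out$t_ns, out$photon_id, out$seq), ]
  if (keep_escapes) {
    attr(out, "escapes") <- if (length(esc) > 0) dplyr::bind_rows(esc) else
      tibble::tibble(photon_id = integer(), e_kev = numeric())
  }
  out
}

# rotate unit vectors u (n x 3) by polar angle acos(ct) about themselves
# with azimuth phi
rotate_dirs <- function(u, ct, phi) {
  n <- nrow(u)
  # build an orthonormal frame (a, b) perpendicular to u
  use_z <- abs(u[, 3]) < 0.9
  h <- cbind(ifelse(use_z, 0, 1), 0, ifelse(use_z, 1, 0))
  a <- cbind(u[, 2] * h[, 3] - u[, 3] * h[, 2],
             u[, 3] * h[, 1] - u[, 1] * h[, 3],
             u[, 1] * h[, 2] - u[, 2] * h[, 1])
  a <- a / sqrt(rowSums(a^2))
  b <- cbind(u[, 2] * a[, 3] - u[, 3] * a[, 2],
             u[, 3] * a[, 1] - u[, 1] * a[, 3],
             u[, 1] * a[, 2] - u[, 2] * a[, 1])
  st <- sqrt(pmax(1 - ct^2, 0))
  v <- u * ct + (a * cos(phi) + b * sin(phi)) * st
  v / sqrt(rowSums(v^2))
}

#' Digitize the true interactions of a simulated batch
#'
#' Models the detector readout at summed-signal level: all true deposits of
#' one decay in one layer are merged (summed energy, energy-weighted centroid
#' position) because the detector integrates them in a single readout frame;
#' the merged deposit is then passed through the layer's energy and position
#' response. The reported z is the layer mid-plane. True (pre-blur) merged
#' quantities are carried along for truth matching.
#'
#' @param interactions Tibble from [transport_photons()].
#' @param geometry A [telescope_geometry()].
#' @return Tibble of measured interactions: `decay_id`, `layer`,
#'   `x_mm,y_mm,z_mm`, `e_kev` (measured), `t_ns`, plus truth columns
#'   `true_x_mm,true_y_mm,true_z_mm,true_e_kev`, `photon_id`, `seq_min`,
#'   `n_merged`.
#' @export
digitize <- function(interactions, geometry) {
  empty <- tibble::tibble(decay_id = integer(), layer = integer(),
                          x_mm = numeric(), y_mm = numeric(),
                          z_mm = numeric(), e_kev = numeric(),
                          t_ns = numeric(), true_x_mm = numeric(),
                          true_y_mm = numeric(), true_z_mm = numeric(),
                          true_e_kev = numeric(), photon_id = integer(),
                          seq_min = integer(), n_merged = integer(),
                          n_photons = integer())
  if (nrow(interactions) == 0) return(empty)
  merged <- merge_by_key(interactions$decay_id * 4 + interactions$layer,
                         interactions)
  merged$decay_id <- merged$key %/% 4
  merged$layer <- merged$key %% 4
  out <- vector("list", length(geometry$layers))
  for (l in seq_along(geometry$layers)) {
    m <- merged[merged$layer == l, ]
    if (nrow(m) == 0) next
    lay <- geometry$layers[[l]]
    pos <- apply_position_response(lay,
                                   cbind(m$true_x_mm, m$true_y_mm,
                                         m$true_z_mm))
    out[[l]] <- tibble::tibble(
      decay_id = m$decay_id, layer = l,
      x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3],
      e_kev = apply_energy_response(lay, m$true_e_kev),
      t_ns = m$t_ns,
      true_x_mm = m$true_x_mm, true_y_mm = m$true_y_mm,
      true_z_mm = m$true_z_mm, true_e_kev = m$true_e_kev,
      photon_id = m$photon_id, seq_min = m$seq_min, n_merged = m$n_merged,
      n_photons = m$n_photons)
  }
  res <- dplyr::bind_rows(out)
  res[order(res$t_ns, res$decay_id, res$layer), ]
}

#' Build triple-coincidence events from a measured interaction stream
#'
#' Emulates the hardware trigger: a greedy, non-overlapping coincidence
#' window of the configured width opens at the first unconsumed interaction;
#' an event is emitted when all three layers carry an above-threshold signal
#' inside the window. Two interactions in the same layer inside one window
#' pile up (energies summed, energy-weighted centroid) before the threshold
#' is applied. Truth flags: `accidental` when interactions from different
#' decays share the window, `pileup` when any layer merged more than one
#' interaction, `ordered` when a single photon produced the three deposits
#' in layer order 1-2-3 (the assumption the cone builder makes).
#'
#' @param measured Tibble from [digitize()], sorted by `t_ns`.
#' @param geometry A [telescope_geometry()].
#' @return Long tibble with three rows per event: `event_id`, `layer`,
#'   `x_mm,y_mm,z_mm`, `e_kev`, `t_ns`, `window_start_ns`, truth columns
#'   (`decay_id`, `true_e_kev`, `n_merged`) and event flags (`accidental`,
#'   `pileup`, `ordered`).
#' @export
build_coincidences <- function(measured, geometry) {
  empty <- tibble::tibble(event_id = integer(), layer = integer(),
                          x_mm = numeric(), y_mm = numeric(),
                          z_mm = numeric(), e_kev = numeric(),
                          t_ns = numeric(), window_start_ns = numeric(),
                          decay_id = integer(), true_e_kev = numeric(),
                          n_merged = integer(), accidental = logical(),
                          pileup = logical(), ordered = logical())
  if (nrow(measured) == 0) return(empty)
  t <- measured$t_ns
  if (is.unsorted(t)) stop("interaction stream must be time-sorted",
                           call. = FALSE)
  w <- geometry$coincidence_window_ns
  # cluster by gaps; clusters spanning more than one window are subdivided
  # greedily from their first interaction
  cl <- cumsum(c(TRUE, diff(t) > w))
  i_first <- which(!duplicated(cl))
  i_last <- c(i_first[-1] - 1L, length(t))
  span <- t[i_last] - t[i_first]
  win <- cl
  long <- which(span > w) # rare chained-overlap clusters: greedy subdivision
  if (length(long) > 0) {
    offset <- max(cl)
    for (k in long) {
      ids <- i_first[k]:i_last[k]
      start <- t[ids[1]]
      sub <- 0L
      wsub <- integer(length(ids))
      for (j in seq_along(ids)) {
        if (t[ids[j]] - start > w) { sub <- sub + 1L; start <- t[ids[j]] }
        wsub[j] <- sub
      }
      win[ids] <- offset + wsub
      offset <- offset + sub + 1L
    }
  }
  thr <- vapply(geometry$layers, function(l) l$threshold_kev, numeric(1))
  # merge per (window, layer): window-level pile-up sums energies and takes
  # the energy-weighted measured centroid
  key <- win * 4 + measured$layer
  sums <- rowsum(cbind(e = measured$e_kev,
                       xe = measured$x_mm * measured$e_kev,
                       ye = measured$y_mm * measured$e_kev,
                       ze = measured$z_mm * measured$e_kev,
                       te = measured$true_e_kev,
                       nm = measured$n_merged, n = 1), key)
  o_e <- order(key, -measured$e_kev)
  rmax <- o_e[!duplicated(key[o_e])]
  o_t <- order(key, measured$t_ns)
  rt <- o_t[!duplicated(key[o_t])]
  o_s <- order(key, measured$seq_min)
  rs <- o_s[!duplicated(key[o_s])]
  dk <- key * 2^26 + measured$decay_id
  nd <- rowsum(as.numeric(!duplicated(dk)), key)[, 1]
  o_p <- order(key, -measured$n_photons)
  rph <- o_p[!duplicated(key[o_p])]
  ukey <- key[rt]
  pl <- tibble::tibble(
    window = ukey %/% 4, layer = as.integer(ukey %% 4),
    x_mm = unname(sums[, "xe"] / sums[, "e"]),
    y_mm = unname(sums[, "ye"] / sums[, "e"]),
    z_mm = unname(sums[, "ze"] / sums[, "e"]),
    e_kev = unname(sums[, "e"]), t_ns = measured$t_ns[rt],
    decay_id = measured$decay_id[rmax],
    true_e_kev = unname(sums[, "te"]),
    photon_id = measured$photon_id[rmax],
    seq_min = measured$seq_min[rs],
    n_merged = as.integer(sums[, "nm"]), n_in_layer = as.integer(sums[, "n"]),
    n_decays = as.integer(nd),
    n_photons_max = measured$n_photons[rph])
  pl$above <- pl$e_kev >= thr[pl$layer]
  # candidate windows: all three layers present and above threshold
  wstat <- rowsum(cbind(n = rep(1, nrow(pl)), above = pl$above), pl$window)
  good <- as.numeric(rownames(wstat))[wstat[, "n"] == 3 &
                                        wstat[, "above"] == 3]
  if (length(good) == 0) return(empty)
  ev <- pl[pl$window %in% good, ]
  # rows arrive sorted by (window, layer): exactly three per event
  i1 <- seq(1, nrow(ev), by = 3); i2 <- i1 + 1L; i3 <- i1 + 2L
  accidental <- ev$decay_id[i1] != ev$decay_id[i2] |
    ev$decay_id[i2] != ev$decay_id[i3] |
    ev$n_decays[i1] > 1 | ev$n_decays[i2] > 1 | ev$n_decays[i3] > 1
  # pile-up: more than one photon contributed to the event, whether inside
  # one layer (merged signals) or across layers (coincidence summing of the
  # 22Na cascade)
  pileup <- ev$n_in_layer[i1] > 1 | ev$n_in_layer[i2] > 1 |
    ev$n_in_layer[i3] > 1 | ev$n_photons_max[i1] > 1 |
    ev$n_photons_max[i2] > 1 | ev$n_photons_max[i3] > 1 |
    ev$photon_id[i1] != ev$photon_id[i2] |
    ev$photon_id[i2] != ev$photon_id[i3]
  ordered <- !accidental & !pileup &
    ev$seq_min[i1] < ev$seq_min[i2] & ev$seq_min[i2] < ev$seq_min[i3]
  window_start <- pmin(ev$t_ns[i1], ev$t_ns[i2], ev$t_ns[i3])
  ev$event_id <- rep(seq_along(i1), each = 3)
  ev$window_start_ns <- rep(window_start, each = 3)
  ev$accidental <- rep(accidental, each = 3)
  ev$pileup <- rep(pileup, each = 3)
  ev$ordered <- rep(ordered, each = 3)
  ev[, c("event_id", "layer", "x_mm", "y_mm", "z_mm", "e_kev", "t_ns",
         "window_start_ns", "decay_id", "true_e_kev", "n_merged",
         "accidental", "pileup", "ordered")]
}

#' Run a full simulated measurement
#'
#' Drives emission, transport, digitization and coincidence building, and
#' optionally writes the list-mode event file and its truth sidecar as CSV.
#' All randomness derives from `seed` through the package's per-stage seed
#' scheme, so a fixed seed reproduces the output byte for byte.
#'
#' @param geometry A [telescope_geometry()].
#' @param source A [na22_source()].
#' @param n_decays Number of decays to simulate. In `"aimed"` mode this is
#'   the 4-pi-equivalent number of decays represented by the importance-
#'   sampled batch (see [emit_decays_aimed()]).
#' @param seed Integer seed.
#' @param emission `"aimed"` (cone importance sampling with geometric
#'   prefiltering, default) or `"isotropic"`.
#' @param strata Emission strata in aimed mode (see [emit_decays_aimed()]):
#'   `"both"`, `"line"` or `"pair"`.
#' @param chunk_size Photons transported per chunk (memory control).
#' @param decay_chunk Decays emitted and processed per streaming block;
#'   blocks are concatenated on the time axis. Results are deterministic
#'   for a fixed seed and block size.
#' @param out_prefix If non-`NULL`, write `<prefix>_events.csv` and
#'   `<prefix>_truth.csv`.
#' @param attenuation Attenuation table (default embedded LaBr3).
#' @return List with `events` (long list-mode tibble, measured columns
#'   only), `truth` (per-interaction truth sidecar), and `counts` (named
#'   list: `n_decays_equivalent`, `n_emitted_1275_equivalent`,
#'   `n_incident_1275` (primary line photons whose straight-line path
#'   crosses the layer-1 crystal), `n_photons_transported`, `n_triples`,
#'   `n_accidental`, `n_pileup`, `n_ordered`).
#' @export
run_experiment <- function(geometry, source, n_decays, seed = 1,
                           emission = c("aimed", "isotropic"),
                           strata = c("both", "line", "pair"),
                           chunk_size = 1e6, decay_chunk = 1e7,
                           out_prefix = NULL,
                           attenuation = labr3_attenuation()) {
  emission <- match.arg(emission)
  strata <- match.arg(strata)
  set.seed(child_seed(seed, 1))
  n_left <- n_decays
  t_offset <- 0
  ev_list <- list(); ev_offset <- 0L
  n_1275_eq <- 0; np <- 0; n_incident <- 0
  b1 <- layer_bounds(geometry$layers[[1]])
  line1 <- if (nrow(source$lines) > 0) source$lines$energy_kev[1] else NA
  while (n_left > 0 || (n_decays == 0 && t_offset == 0)) {
    nc <- min(n_left, decay_chunk)
    photons <- if (emission == "aimed") {
      emit_decays_aimed(source, nc, geometry = geometry, strata = strata)
    } else {
      emit_decays(source, nc)
    }
    photons$t_ns <- photons$t_ns + t_offset
    t_offset <- t_offset + nc / source$activity_bq * 1e9
    n_1275_eq <- n_1275_eq + if (emission == "aimed") {
      attr(photons, "n_emitted_1275_equivalent")
    } else {
      attr(photons, "n_emitted_1275")
    }
    # geometric incidence of primary line photons on layer 1
    sel <- which(photons$e_kev == line1)
    if (length(sel) > 0) {
      rb <- ray_box(cbind(photons$x_mm, photons$y_mm, photons$z_mm)[sel, ,
                                                                    drop = FALSE],
                    cbind(photons$ux, photons$uy, photons$uz)[sel, ,
                                                              drop = FALSE],
                    b1$lo, b1$hi)
      n_incident <- n_incident + sum(rb$t_far > pmax(rb$t_near, 0) &
                                       rb$t_near > 0)
    }
    np <- np + nrow(photons)
    pchunks <- if (nrow(photons) == 0) list() else
      split(seq_len(nrow(photons)),
            ceiling(seq_len(nrow(photons)) / chunk_size))
    inter <- vector("list", length(pchunks))
    for (i in seq_along(pchunks)) {
      inter[[i]] <- transport_photons(photons[pchunks[[i]], ], geometry,
                                      attenuation)
    }
    interactions <- dplyr::bind_rows(inter)
    measured <- digitize(interactions, geometry)
    coinc <- build_coincidences(measured, geometry)
    if (nrow(coinc) > 0) {
      coinc$event_id <- coinc$event_id + ev_offset
      ev_offset <- ev_offset + max(coinc$event_id - ev_offset)
      ev_list[[length(ev_list) + 1]] <- coinc
    }
    n_left <- n_left - nc
    if (n_decays == 0) break
  }
  coinc <- if (length(ev_list) > 0) dplyr::bind_rows(ev_list) else
    build_coincidences(digitize(
      transport_photons(emit_decays(source, 0), geometry, attenuation),
      geometry), geometry)
  events <- coinc[, c("event_id", "layer", "x_mm", "y_mm", "z_mm", "e_kev",
                      "t_ns")]
  truth <- coinc[, c("event_id", "layer", "decay_id", "true_e_kev",
                     "n_merged", "accidental", "pileup", "ordered",
                     "window_start_ns")]
  counts <- list(
    n_decays_equivalent = n_decays,
    n_emitted_1275_equivalent = n_1275_eq,
    n_incident_1275 = n_incident,
    n_photons_transported = np,
    n_triples = length(unique(events$event_id)),
    n_accidental = sum(truth$accidental[!duplicated(truth$event_id)]),
    n_pileup = sum(truth$pileup[!duplicated(truth$event_id)]),
    n_ordered = sum(truth$ordered[!duplicated(truth$event_id)]))
  if (!is.null(out_prefix)) {
    readr::write_csv(events, paste0(out_prefix, "_events.csv"))
    readr::write_csv(truth, paste0(out_prefix, "_truth.csv"))
  }
  list(events = events, truth = truth, counts = counts)
}
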