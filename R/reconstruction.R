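#' Reconstruction voxel grid
#'
#' Isotropic voxels; `origin_mm` is the centre of voxel (1, 1, 1). The axis
#' convention matches the telescope frame (z along the optical axis; the
#' source plane of the default prototype sits at z = -35 mm).
#'
#' @param origin_mm Centre of the first voxel (length-3, mm).
#' @param voxel_size_mm Voxel pitch (> 0), mm.
#' @param dims Integer triple `(nx, ny, nz)`, each >= 1.
#' @return Object of class `voxel_grid`.
#' @export
voxel_grid <- function(origin_mm, voxel_size_mm, dims) {
  stopifnot(voxel_size_mm > 0, length(dims) == 3, all(dims >= 1))
  structure(list(origin_mm = as.numeric(origin_mm),
                 voxel_size_mm = voxel_size_mm,
                 dims = as.integer(dims)),
            class = "voxel_grid")
}

#' Default imaging grid: 80 x 80 x 1 voxels of 1 mm at the source plane
#'
#' @param geometry A [telescope_geometry()]; the single z plane is placed at
#'   the source distance.
#' @param n Transverse voxel count per side.
#' @param voxel_size_mm Voxel pitch in mm.
#' @return A [voxel_grid()].
#' @export
default_grid <- function(geometry = default_prototype(), n = 80,
                         voxel_size_mm = 1) {
  half <- (n - 1) / 2 * voxel_size_mm
  voxel_grid(c(-half, -half, -geometry$source_to_layer1_mm),
             voxel_size_mm, c(n, n, 1))
}

#' Voxel-centre coordinates of a grid
#'
#' @param grid A [voxel_grid()].
#' @return Matrix (n_voxels x 3) in column-major voxel order (x fastest).
#' @export
voxel_centers <- function(grid) {
  gx <- grid$origin_mm[1] + grid$voxel_size_mm * (seq_len(grid$dims[1]) - 1)
  gy <- grid$origin_mm[2] + grid$voxel_size_mm * (seq_len(grid$dims[2]) - 1)
  gz <- grid$origin_mm[3] + grid$voxel_size_mm * (seq_len(grid$dims[3]) - 1)
  as.matrix(expand.grid(x = gx, y = gy, z = gz))
}

#' System-model row of one Compton cone
#'
#' Weight of voxel j for cone i:
#' `exp(-(alpha_j - half_angle)^2 / (2 sigma^2)) / d_j^2`, where `alpha_j`
#' is the angle at the apex between the cone axis and the voxel-centre
#' direction and `d_j` the apex-voxel distance; `sigma` is the per-event
#' `sigma_rad` floored at `sigma_floor`. Weights below `trunc * max(weight)`
#' are truncated to zero (sparse row). A row with no surviving weight marks
#' the event unusable.
#'
#' @param cone One-row slice of a `cone_set` (or a list with the same
#'   fields).
#' @param grid A [voxel_grid()].
#' @param sigma_floor Minimum angular sigma in rad (guards degenerate rows).
#' @param trunc Relative truncation threshold.
#' @param centers Optional precomputed [voxel_centers()] matrix.
#' @return Numeric vector of length `prod(dims)` (zeros where truncated);
#'   attribute `usable` is `FALSE` when the row is empty.
#' @export
system_row <- function(cone, grid, sigma_floor = 0.01, trunc = 1e-6,
                       centers = voxel_centers(grid)) {
  dx <- centers[, 1] - cone$apex_x_mm
  dy <- centers[, 2] - cone$apex_y_mm
  dz <- centers[, 3] - cone$apex_z_mm
  d2 <- dx^2 + dy^2 + dz^2
  d <- sqrt(d2)
  ca <- (dx * cone$axis_x + dy * cone$axis_y + dz * cone$axis_z) / d
  alpha <- acos(pmin(pmax(ca, -1), 1))
  sg <- max(cone$sigma_rad, sigma_floor)
  w <- exp(-(alpha - cone$half_angle_rad)^2 / (2 * sg^2)) / d2
  w[w < trunc * max(w)] <- 0
  structure(w, usable = any(w > 0))
}

#' Sparse system matrix for a set of cones
#'
#' @param cones A `cone_set` tibble.
#' @inheritParams system_row
#' @return List with `W` (sparse dgCMatrix, usable events x voxels) and
#'   `usable` (logical per input cone).
#' @export
system_matrix <- function(cones, grid, sigma_floor = 0.01, trunc = 1e-6) {
  centers <- voxel_centers(grid)
  n <- nrow(cones)
  usable <- logical(n)
  ii <- vector("list", n); jj <- vector("list", n); xx <- vector("list", n)
  row <- 0L
  for (i in seq_len(n)) {
    w <- system_row(cones[i, ], grid, sigma_floor, trunc, centers)
    nz <- which(w > 0)
    if (length(nz) == 0) next
    row <- row + 1L
    usable[i] <- TRUE
    ii[[i]] <- rep.int(row, length(nz))
    jj[[i]] <- nz
    xx[[i]] <- w[nz]
  }
  if (row == 0L) stop("no usable cones: grid outside every cone's support",
                      call. = FALSE)
  W <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(row, nrow(centers)))
  list(W = W, usable = usable)
}

#' List-mode ML-EM reconstruction from Compton cones
#'
#' Standard list-mode maximum-likelihood expectation-maximization:
#' `lambda_j <- (lambda_j / s_j) * sum_i w_ij / (sum_k w_ik lambda_k)`,
#' initialized uniform at 1, run for exactly `n_iterations` (no stopping
#' rule). Non-negativity is preserved by construction; the list-mode
#' log-likelihood `sum_i log(p_i) - sum_j s_j lambda_j` is recorded per
#' iteration and is non-decreasing.
#'
#' @param cones A `cone_set` tibble (or a precomputed [system_matrix()]
#'   list).
#' @param grid A [voxel_grid()].
#' @param n_iterations Number of EM iterations (>= 1), default 30.
#' @param sensitivity `"uniform"` (s_j = 1, the default for the small
#'   near-axis field of view) or `"event_sum"` (s_j = column sums of the
#'   system matrix, a data-driven approximation).
#' @param sigma_floor,trunc Passed to [system_matrix()].
#' @return Object of class `mlem_image`: `values` (array `dims`), `grid`,
#'   `iteration_count`, `loglik` (per iteration), `n_events`.
#' @export
mlem_reconstruct <- function(cones, grid, n_iterations = 30,
                             sensitivity = c("uniform", "event_sum"),
                             sigma_floor = 0.01, trunc = 1e-6) {
  sensitivity <- match.arg(sensitivity)
  stopifnot(n_iterations >= 1)
  sm <- if (is.list(cones) && !is.null(cones[["W"]])) cones else
    system_matrix(cones, grid, sigma_floor, trunc)
  W <- sm$W
  nv <- ncol(W)
  s <- if (sensitivity == "uniform") rep(1, nv) else {
    cs <- Matrix::colSums(W)
    cs[cs == 0] <- Inf # voxels never seen stay at zero update
    cs
  }
  lambda <- rep(1, nv)
  loglik <- numeric(n_iterations)
  guard <- function(p) {
    # events whose support carries no remaining intensity cannot update
    p[p <= 0] <- .Machine$double.xmin
    p
  }
  for (it in seq_len(n_iterations)) {
    p <- guard(as.numeric(W %*% lambda))
    back <- as.numeric(Matrix::crossprod(W, 1 / p))
    lambda <- lambda / s * back
    lambda[!is.finite(lambda)] <- 0
    stopifnot(all(lambda >= 0))
    # log-likelihood of the updated estimate
    p2 <- guard(as.numeric(W %*% lambda))
    loglik[it] <- sum(log(p2)) - sum(s[is.finite(s)] *
                                       lambda[is.finite(s)])
  }
  structure(list(values = array(lambda, dim = grid$dims), grid = grid,
                 iteration_count = n_iterations, loglik = loglik,
                 n_events = nrow(W), usable = sm$usable),
            class = "mlem_image")
}

#' @export
print.mlem_image <- function(x, ...) {
  cat(sprintf(
    "<mlem_image> %d x %d x %d voxels (%.2f mm), %d events, %d iterations\n",
    x$grid$dims[1], x$grid$dims[2], x$grid$dims[3], x$grid$voxel_size_mm,
    x$n_events, x$iteration_count))
  invisible(x)
}

#' Extract the image plane nearest to a z position
#'
#' @param image An [mlem_reconstruct()] image.
#' @param z_mm Requested plane position; must lie within the grid extent
#'   (half a voxel of slack).
#' @return Tibble with `x_mm`, `y_mm`, `value` for the nearest z plane;
#'   attributes `z_mm` (actual plane) and `matrix` (the nx x ny slice).
#' @export
extract_plane <- function(image, z_mm) {
  g <- image$grid
  zs <- g$origin_mm[3] + g$voxel_size_mm * (seq_len(g$dims[3]) - 1)
  if (z_mm < zs[1] - g$voxel_size_mm / 2 ||
      z_mm > zs[g$dims[3]] + g$voxel_size_mm / 2) {
    stop("z outside grid extent", call. = FALSE)
  }
  k <- which.min(abs(zs - z_mm))
  slice <- image$values[, , k]
  gx <- g$origin_mm[1] + g$voxel_size_mm * (seq_len(g$dims[1]) - 1)
  gy <- g$origin_mm[2] + g$voxel_size_mm * (seq_len(g$dims[2]) - 1)
  out <- tibble::tibble(x_mm = rep(gx, times = g$dims[2]),
                        y_mm = rep(gy, each = g$dims[1]),
                        value = as.numeric(slice))
  attr(out, "z_mm") <- zs[k]
  attr(out, "matrix") <- slice
  attr(out, "x_mm") <- gx
  attr(out, "y_mm") <- gy
  out
}

#' Write / read an image as delimited text with a JSON sidecar header
#'
#' @param image An `mlem_image`.
#' @param prefix Output prefix: writes `<prefix>.csv` (long table
#'   `ix, iy, iz, value`) and `<prefix>.json` (grid metadata).
#' @export
write_image <- function(image, prefix) {
  g <- image$grid
  idx <- as.matrix(expand.grid(ix = seq_len(g$dims[1]),
                               iy = seq_len(g$dims[2]),
                               iz = seq_len(g$dims[3])))
  readr::write_csv(tibble::tibble(ix = idx[, 1], iy = idx[, 2],
                                  iz = idx[, 3],
                                  value = as.numeric(image$values)),
                   paste0(prefix, ".csv"))
  jsonlite::write_json(list(origin_mm = g$origin_mm,
                            voxel_size_mm = g$voxel_size_mm,
                            dims = g$dims,
                            iteration_count = image$iteration_count,
                            n_events = image$n_events),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_image
#' @export
read_image <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  tab <- readr::read_csv(paste0(prefix, ".csv"), show_col_types = FALSE)
  g <- voxel_grid(meta$origin_mm, meta$voxel_size_mm, meta$dims)
  structure(list(values = array(tab$value, dim = g$dims), grid = g,
                 iteration_count = meta$iteration_count, loglik = NULL,
                 n_events = meta$n_events, usable = NULL),
            class = "mlem_image")
}
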