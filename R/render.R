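#' TIRF acquisition parameters
#'
#' Optical and acquisition constants of the synthetic imaging model:
#' camera pixel size (107 nm by default), frame interval (2-60 s), an
#' isotropic Gaussian point-spread function (sigma 130 nm by default,
#' roughly lambda/2NA for far-red emission through a 1.46 NA objective),
#' the photon budget per micrometre of labelled polymer per frame, a flat
#' fluorescent background, and camera read noise.
#'
#' @param pixel_size_nm Pixel size in nm (> 0).
#' @param frame_interval_s Frame interval in seconds (2 to 60).
#' @param psf_sigma_nm PSF standard deviation in nm (>= 0).
#' @param photons_per_um Expected photons per um of polymer per frame (> 0).
#' @param background_photons Expected background photons per pixel per frame.
#' @param read_noise_sd Gaussian read noise SD in counts.
#' @param channels Ordered channel labels.
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(pixel_size_nm = 107, frame_interval_s = 5,
                          psf_sigma_nm = 130, photons_per_um = 400,
                          background_photons = 20, read_noise_sd = 2,
                          channels = c("seed", "lattice")) {
  stopifnot(
    pixel_size_nm > 0, frame_interval_s >= 2, frame_interval_s <= 60,
    psf_sigma_nm >= 0, photons_per_um > 0, background_photons >= 0,
    read_noise_sd >= 0, length(channels) >= 1
  )
  structure(
    list(pixel_size_nm = pixel_size_nm, frame_interval_s = frame_interval_s,
         psf_sigma_nm = psf_sigma_nm, photons_per_um = photons_per_um,
         background_photons = background_photons,
         read_noise_sd = read_noise_sd, channels = channels),
    class = "optics_config"
  )
}

#' @export
print.optics_config <- function(x, ...) {
  cat(sprintf(
    "Optics: %g nm pixels, %g s frames, PSF sigma %g nm, %g photons/um, bg %g/px, read noise %g\n",
    x$pixel_size_nm, x$frame_interval_s, x$psf_sigma_nm, x$photons_per_um,
    x$background_photons, x$read_noise_sd
  ))
  invisible(x)
}

# Column-normalized 1-D Gaussian blur operator (n x n). Normalizing columns
# keeps the total photon count exactly conserved inside the image, so
# integrated signal stays proportional to polymer length in view.
gaussian_blur_operator <- function(n, sigma_px) {
  if (sigma_px <= 0) return(diag(n))
  half <- max(1, ceiling(4 * sigma_px))
  idx <- seq_len(n)
  K <- matrix(0, n, n)
  for (j in idx) {
    lo <- max(1, j - half)
    hi <- min(n, j + half)
    w <- exp(-((lo:hi - j)^2) / (2 * sigma_px^2))
    K[lo:hi, j] <- w / sum(w)
  }
  K
}

# Expected photons per pixel for a polymer segment [a_um, b_um): photon
# density photons_per_um, pixels are half-open [(i-1)p, ip).
segment_photons <- function(a_um, b_um, n_px, pixel_um, photons_per_um) {
  out <- numeric(n_px)
  if (b_um <= a_um) return(out)
  edges <- (0:n_px) * pixel_um
  overlap <- pmin(edges[-1], b_um) - pmax(edges[-(n_px + 1)], a_um)
  out <- pmax(overlap, 0) * photons_per_um
  out
}

apply_noise <- function(expected, optics, noise, nr, nc) {
  if (!noise) return(expected)
  counts <- matrix(stats::rpois(nr * nc, lambda = expected), nr, nc)
  if (optics$read_noise_sd > 0) {
    counts <- counts + matrix(stats::rnorm(nr * nc, sd = optics$read_noise_sd),
                              nr, nc)
  }
  counts
}

#' Render a synthetic kymograph from a filament trajectory
#'
#' Produces a space-time intensity image per channel: rows are frames,
#' columns are position along the filament axis with the origin at the seed
#' minus end (0-based, half-open pixel intervals: position x falls in
#' column `floor(x / pixel_size)`). At each frame the dynamic polymer
#' occupies the interval from the seed plus end to the current tip; the
#' seed channel covers the seed extent only. Line photon density is blurred
#' with the PSF, then Poisson shot noise, Gaussian read noise and a flat
#' background are applied. For trajectories with origin `"gmpcpp_seed"` the
#' shrinking seed itself is the (single-channel) subject and the position
#' origin is its minus end.
#'
#' @param traj A `filament_trajectory`.
#' @param optics An [optics_config()].
#' @param seed_length_um Length of the stabilized seed (ignored for
#'   `gmpcpp_seed` trajectories).
#' @param max_width_um Field limit; a filament extending beyond it is an
#'   overflow error.
#' @param margin_um Background margin beyond the longest extent.
#' @param noise Logical; apply shot/read noise (default `TRUE`).
#' @param seed Optional RNG seed.
#' @return An object of class `kymograph`: named list of channel matrices
#'   (`ceiling(duration / frame_interval)` rows), the optics, frame times,
#'   and the seed extent in um.
#' @export
render_kymograph <- function(traj, optics = optics_config(),
                             seed_length_um = 3, max_width_um = 110,
                             margin_um = 2, noise = TRUE, seed = NULL) {
  stopifnot(inherits(traj, "filament_trajectory"))
  if (!is.null(seed)) set.seed(seed)
  duration <- max(traj$times_s)
  dt <- optics$frame_interval_s
  if (duration < dt) stop("trajectory shorter than one frame interval")
  n_frames <- ceiling(duration / dt)
  frame_times <- (seq_len(n_frames) - 1) * dt
  len <- stats::approx(traj$times_s, traj$lengths_um, xout = frame_times,
                       rule = 2)$y
  pixel_um <- optics$pixel_size_nm / 1000
  gmpcpp <- identical(traj$origin, "gmpcpp_seed")
  seed_len <- if (gmpcpp) 0 else seed_length_um
  extent <- seed_len + max(len) + margin_um + 4 * optics$psf_sigma_nm / 1000
  if (extent > max_width_um) {
    stop(sprintf("filament overflow: extent %.1f um exceeds field width %.1f um",
                 extent, max_width_um))
  }
  n_px <- ceiling(extent / pixel_um)
  K <- gaussian_blur_operator(n_px, optics$psf_sigma_nm / 1000 / pixel_um)

  render_channel <- function(starts, ends) {
    E <- matrix(0, n_frames, n_px)
    for (i in seq_len(n_frames)) {
      E[i, ] <- segment_photons(starts[i], ends[i], n_px, pixel_um,
                                optics$photons_per_um)
    }
    E <- E %*% K
    apply_noise(E + optics$background_photons, optics, noise, n_frames, n_px)
  }

  channels <- if (gmpcpp) {
    list(seed = render_channel(rep(0, n_frames), len))
  } else {
    list(
      seed = render_channel(rep(0, n_frames), rep(seed_len, n_frames)),
      lattice = render_channel(rep(seed_len, n_frames), seed_len + len)
    )
  }
  structure(
    list(channels = channels, optics = optics, frame_times_s = frame_times,
         seed_extent_um = c(0, seed_len), origin = traj$origin),
    class = "kymograph"
  )
}

#' @export
print.kymograph <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "Kymograph: %d frames x %d pixels (%g s, %g nm), channels: %s; seed extent %g-%g um\n",
    d[1], d[2], x$optics$frame_interval_s, x$optics$pixel_size_nm,
    paste(names(x$channels), collapse = ", "),
    x$seed_extent_um[1], x$seed_extent_um[2]
  ))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, channel = length(x$channels), ...) {
  img <- x$channels[[channel]]
  pixel_um <- x$optics$pixel_size_nm / 1000
  graphics::image(
    x = (seq_len(ncol(img)) - 0.5) * pixel_um,
    y = x$frame_times_s,
    z = t(img)[, rev(seq_len(nrow(img))), drop = FALSE],
    col = grDevices::gray.colors(256, start = 0, end = 1),
    xlab = "position (um)", ylab = "time (s, top to bottom)", ...
  )
  invisible(x)
}

#' Points on a circular arc with uniform arc-length spacing
#'
#' Fixture generator for curvature analysis: a chain of `n_points` on a
#' circle of radius `radius_um`, spanning `arc_span_rad` radians. The
#' analytic curvature of the chain is `1 / radius_um` everywhere; large
#' radii approximate straight segments.
#'
#' @param radius_um Radius in um (> 0).
#' @param arc_span_rad Arc span in radians (> 0).
#' @param n_points Number of points (>= 3).
#' @param center Circle center, um.
#' @param theta0 Starting angle, radians.
#' @return A two-column matrix of (x, y) coordinates in um.
#' @export
make_arc_filament <- function(radius_um, arc_span_rad = pi, n_points = 50,
                              center = c(0, 0), theta0 = 0) {
  stopifnot(radius_um > 0, arc_span_rad > 0)
  if (n_points < 3) stop("n_points must be at least 3")
  theta <- theta0 + seq(0, arc_span_rad, length.out = n_points)
  cbind(x = center[1] + radius_um * cos(theta),
        y = center[2] + radius_um * sin(theta))
}

# Resample a point chain at uniform arc-length spacing step_um.
resample_chain <- function(chain, step_um) {
  d <- sqrt(diff(chain[, 1])^2 + diff(chain[, 2])^2)
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate chain: zero total length")
  grid <- seq(0, total, by = step_um)
  cbind(x = stats::approx(s, chain[, 1], xout = grid)$y,
        y = stats::approx(s, chain[, 2], xout = grid)$y,
        s = grid)
}

#' Render a synthetic field of view
#'
#' Rasterizes filament point chains into a square fluorescence image:
#' each chain is resampled with arc-length-uniform density, photons are
#' deposited proportionally to polymer length per pixel, blurred with the
#' PSF, and shot/read noise plus flat background are applied. Coordinates
#' are in um with the origin at the field corner; pixel (row, col) covers
#' the half-open square `[(col-1)p, col p) x [(row-1)p, row p)` with x
#' along columns and y along rows.
#'
#' @param chains List of two-column coordinate matrices (um). An empty list
#'   yields a background-only image.
#' @param optics An [optics_config()].
#' @param field_size_um Side of the square field (default 110 um).
#' @param labels Per-chain channel labels (default all `"lattice"`).
#' @param noise Logical; apply noise.
#' @param seed Optional RNG seed.
#' @return An object of class `field_image`: named list of channel
#'   matrices plus calibration.
#' @export
render_field <- function(chains, optics = optics_config(),
                         field_size_um = 110, labels = NULL, noise = TRUE,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pixel_um <- optics$pixel_size_nm / 1000
  n_px <- ceiling(field_size_um / pixel_um)
  if (is.null(labels)) labels <- rep("lattice", length(chains))
  stopifnot(length(labels) == length(chains))
  channel_names <- unique(c(labels, if (length(chains) == 0) "lattice"))
  acc <- stats::setNames(
    lapply(channel_names, function(ch) matrix(0, n_px, n_px)), channel_names
  )
  step <- pixel_um / 5
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    if (any(ch[, 1] < 0 | ch[, 1] > field_size_um |
            ch[, 2] < 0 | ch[, 2] > field_size_um)) {
      stop(sprintf("filament %d extends outside the field", i))
    }
    pts <- resample_chain(ch, step)
    col <- pmin(pmax(floor(pts[, "x"] / pixel_um) + 1, 1), n_px)
    row <- pmin(pmax(floor(pts[, "y"] / pixel_um) + 1, 1), n_px)
    idx <- (col - 1) * n_px + row
    photons <- optics$photons_per_um * step
    tab <- tabulate(idx, nbins = n_px * n_px) * photons
    acc[[labels[i]]] <- acc[[labels[i]]] + matrix(tab, n_px, n_px)
  }
  K <- gaussian_blur_operator(n_px, optics$psf_sigma_nm / 1000 / pixel_um)
  channels <- lapply(acc, function(E) {
    E <- t(K) %*% E %*% K
    apply_noise(E + optics$background_photons, optics, noise, n_px, n_px)
  })
  structure(
    list(channels = channels, optics = optics,
         field_size_um = field_size_um),
    class = "field_image"
  )
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("Field image: %d x %d pixels (%g um, %g nm/px), channels: %s\n",
              d[1], d[2], x$field_size_um, x$optics$pixel_size_nm,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}
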