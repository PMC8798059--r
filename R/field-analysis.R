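# Shift a matrix by (dr, dc), zero-filling. Used by the thinning iteration.
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  rok <- rs >= 1 & rs <= nr
  cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Iterative two-subfield thinning reducing connected foreground regions to
#' one-pixel-wide 8-connected skeletons, used to measure filament length
#' and detect junctions in field images.
#'
#' @param mask Logical or 0/1 matrix.
#' @return A logical matrix of the same dimension.
#' @export
skeletonize <- function(mask) {
  m <- (mask > 0) * 1
  # neighbours P2..P9: N, NE, E, SE, S, SW, W, NW
  offsets <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                  c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P <- lapply(offsets, function(o) shift_matrix(m, o[1], o[2]))
      B <- Reduce(`+`, P)
      ring <- c(P, P[1])
      A <- Reduce(`+`, lapply(seq_len(8), function(i) {
        (ring[[i]] == 0) * (ring[[i + 1]] == 1)
      }))
      if (step == 1) {
        c3 <- P[[1]] * P[[3]] * P[[5]]  # P2*P4*P6
        c4 <- P[[3]] * P[[5]] * P[[7]]  # P4*P6*P8
      } else {
        c3 <- P[[1]] * P[[3]] * P[[7]]  # P2*P4*P8
        c4 <- P[[1]] * P[[5]] * P[[7]]  # P2*P6*P8
      }
      del <- m == 1 & B >= 2 & B <= 6 & A == 1 & c3 == 0 & c4 == 0
      if (any(del)) {
        m[del] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m > 0
}

# Connected components of skeleton pixels under 8-connectivity, as an
# igraph graph; vertices are pixel linear indices.
skeleton_graph <- function(skel) {
  idx <- which(skel)
  if (length(idx) == 0) return(NULL)
  nr <- nrow(skel)
  pos <- match(idx, idx)
  edges <- integer(0)
  coords <- arrayInd(idx, dim(skel))
  lookup <- new.env(hash = TRUE)
  key <- function(r, c) paste0(r, ",", c)
  for (i in seq_along(idx)) assign(key(coords[i, 1], coords[i, 2]), i, lookup)
  for (i in seq_along(idx)) {
    r <- coords[i, 1]; c <- coords[i, 2]
    for (o in list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))) {
      k <- key(r + o[1], c + o[2])
      j <- mget(k, lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(j)) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  igraph::set_vertex_attr(g, "row", value = coords[, 1]) -> g
  igraph::set_vertex_attr(g, "col", value = coords[, 2]) -> g
  g
}

#' Count microtubules in a field of view
#'
#' Smooths the image with a small Gaussian (a matched filter for
#' diffraction-limited filaments, which recovers the per-pixel SNR that
#' the two-dimensional PSF spreads away), thresholds at
#' `background + k * SD` (robust median/MAD estimate on the smoothed
#' image), skeletonizes the mask, and counts connected skeleton components
#' whose path length is at least `min_length_um`. Components with more
#' than two skeleton endpoints are treated as crossings of several
#' filaments and contribute `round(endpoints / 2)` microtubules.
#'
#' @param field A `field_image` (or a plain intensity matrix plus
#'   `pixel_size_nm`).
#' @param channel Channel name or index.
#' @param min_length_um Minimum skeleton length to count (default 1 um).
#' @param k Threshold in background SDs (default 3).
#' @param smooth_sigma_px Matched-filter Gaussian SD in pixels (default 1.2,
#'   about one PSF width; 0 disables smoothing).
#' @param pixel_size_nm Pixel size when `field` is a plain matrix.
#' @return Integer count of microtubules.
#' @export
count_field_microtubules <- function(field, channel = 1, min_length_um = 1,
                                     k = 3, smooth_sigma_px = 1.2,
                                     pixel_size_nm = 107) {
  if (inherits(field, "field_image")) {
    img <- field$channels[[channel]]
    pixel_size_nm <- field$optics$pixel_size_nm
  } else {
    img <- field
  }
  pixel_um <- pixel_size_nm / 1000
  if (smooth_sigma_px > 0) {
    Kr <- gaussian_blur_operator(nrow(img), smooth_sigma_px)
    Kc <- gaussian_blur_operator(ncol(img), smooth_sigma_px)
    img <- t(Kr) %*% img %*% Kc
  }
  thr <- stats::median(img) + k * stats::mad(img)
  mask <- img > thr
  if (!any(mask)) return(0L)
  skel <- skeletonize(mask)
  g <- skeleton_graph(skel)
  if (is.null(g)) return(0L)
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  total <- 0L
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    if (length(vs) < 2) next
    sub <- igraph::induced_subgraph(g, vs)
    # geodesic diameter of the skeleton = filament path length
    rows <- igraph::vertex_attr(sub, "row")
    cols <- igraph::vertex_attr(sub, "col")
    el <- igraph::as_edgelist(sub, names = FALSE)
    w <- sqrt((rows[el[, 1]] - rows[el[, 2]])^2 +
              (cols[el[, 1]] - cols[el[, 2]])^2)
    len_um <- max(igraph::distances(sub, weights = w)) * pixel_um
    if (len_um < min_length_um) next
    endpoints <- sum(deg[vs] == 1)
    total <- total + if (endpoints > 2) as.integer(round(endpoints / 2)) else 1L
  }
  total
}

# Bilinear interpolation of matrix img at fractional (row, col) positions.
bilinear_sample <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- pmin(pmax(floor(row), 1), nr - 1)
  c0 <- pmin(pmax(floor(col), 1), nc - 1)
  fr <- pmin(pmax(row - r0, 0), 1)
  fc <- pmin(pmax(col - c0, 0), 1)
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Averaged, normalized intensity line profiles
#'
#' Samples image intensity along scan lines (bilinear interpolation),
#' subtracts the mean background, averages across lines, and normalizes
#' the peak of the mean profile to 1. The per-offset standard error is
#' scaled by the same normalization. If the mean profile is flat
#' (degenerate normalization) the profile is returned un-normalized with
#' `constant = TRUE`.
#'
#' @param image Intensity matrix.
#' @param lines List of scan lines, each `list(start = c(row, col),
#'   end = c(row, col))` in (possibly fractional) pixel coordinates; all
#'   lines are resampled to `n_samples` points.
#' @param background Logical mask of background pixels, or a numeric
#'   background level. A mask overlapping any scan line is an error.
#' @param n_samples Number of samples per line (default: rounded length of
#'   the first line in pixels, at least 2).
#' @param pixel_size_nm Pixel size for the offset axis.
#' @return An object of class `line_profile` with `offsets_um`,
#'   `mean_intensity`, `sem`, `n_profiles`, `constant`.
#' @export
average_line_profiles <- function(image, lines, background = 0,
                                  n_samples = NULL, pixel_size_nm = 107) {
  stopifnot(length(lines) >= 1)
  line_len <- function(l) sqrt(sum((l$end - l$start)^2))
  if (is.null(n_samples)) n_samples <- max(2, round(line_len(lines[[1]])) + 1)
  if (is.matrix(background) || is.logical(background)) {
    bg_mask <- background > 0
    for (l in lines) {
      tt <- seq(0, 1, length.out = n_samples)
      rr <- round(l$start[1] + tt * (l$end[1] - l$start[1]))
      cc <- round(l$start[2] + tt * (l$end[2] - l$start[2]))
      if (any(bg_mask[cbind(rr, cc)])) {
        stop("background region overlaps a scan line")
      }
    }
    bg <- mean(image[bg_mask])
  } else {
    bg <- background
  }
  prof <- matrix(NA_real_, length(lines), n_samples)
  for (i in seq_along(lines)) {
    l <- lines[[i]]
    tt <- seq(0, 1, length.out = n_samples)
    rr <- l$start[1] + tt * (l$end[1] - l$start[1])
    cc <- l$start[2] + tt * (l$end[2] - l$start[2])
    prof[i, ] <- bilinear_sample(image, rr, cc) - bg
  }
  mean_prof <- colMeans(prof)
  sem <- apply(prof, 2, stats::sd) / sqrt(nrow(prof))
  sem[is.na(sem)] <- 0
  peak <- max(mean_prof)
  constant <- (max(mean_prof) - min(mean_prof)) < 1e-12 || peak <= 0
  if (!constant) {
    mean_prof <- mean_prof / peak
    sem <- sem / peak
  }
  structure(
    list(offsets_um = seq(0, 1, length.out = n_samples) *
           line_len(lines[[1]]) * pixel_size_nm / 1000,
         mean_intensity = mean_prof, sem = sem,
         n_profiles = length(lines), constant = constant),
    class = "line_profile"
  )
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf(
    "Line profile: %d samples over %.2f um, n = %d lines%s\n",
    length(x$offsets_um), max(x$offsets_um), x$n_profiles,
    if (x$constant) " (flat; normalization skipped)" else ""
  ))
  invisible(x)
}

#' @export
plot.line_profile <- function(x, xlab = "offset (um)",
                              ylab = "normalized intensity", type = "l", ...) {
  graphics::plot(x$offsets_um, x$mean_intensity, type = type, xlab = xlab,
                 ylab = ylab, ...)
  graphics::arrows(x$offsets_um, x$mean_intensity - x$sem,
                   x$offsets_um, x$mean_intensity + x$sem,
                   length = 0.02, angle = 90, code = 3, col = "grey50")
  invisible(x)
}

#' Recruitment ratio of signal on a lattice over background
#'
#' Mean intensity within the lattice mask divided by the mean within the
#' background mask. Masks must be disjoint and contain at least 10 pixels
#' each.
#'
#' @param image Intensity matrix.
#' @param lattice_mask,background_mask Logical masks.
#' @return The ratio (a single number).
#' @export
recruitment_ratio <- function(image, lattice_mask, background_mask) {
  stopifnot(sum(lattice_mask) >= 10, sum(background_mask) >= 10)
  if (any(lattice_mask & background_mask)) stop("masks must be disjoint")
  bg <- mean(image[background_mask])
  if (bg == 0) stop("zero background mean")
  mean(image[lattice_mask]) / bg
}

#' Curvature along a filament, optionally paired with image intensity
#'
#' Fits smoothing splines x(s), y(s) to the point chain (chord-length
#' parametrization) and evaluates the signed-magnitude curvature
#' `kappa = |x'y'' - y'x''| / (x'^2 + y'^2)^(3/2)` at arc-length-uniform
#' interior samples. When an image is supplied, each sample is paired with
#' the background-subtracted intensity at that position and the samples
#' are binned by curvature (mean +/- SD per bin).
#'
#' @param chain Two-column coordinate matrix in um (>= 5 distinct points).
#' @param image Optional intensity matrix.
#' @param pixel_size_nm Pixel size mapping um coordinates to the image.
#' @param background Background level to subtract (default: image median).
#' @param n_samples Number of arc-length samples (default 100).
#' @param n_bins Number of curvature bins (default 8).
#' @param trim Fraction of arc length trimmed at each end where spline
#'   derivatives are unreliable (default 0.05).
#' @return With `image = NULL`, a data frame of `s_um` and `kappa_per_um`;
#'   otherwise a list with that data frame (`samples`, including
#'   `intensity`) and a `bins` data frame (`kappa_mid`, `mean_intensity`,
#'   `sd_intensity`, `n`).
#' @export
curvature_intensity <- function(chain, image = NULL, pixel_size_nm = 107,
                                background = NULL, n_samples = 100,
                                n_bins = 8, trim = 0.05) {
  chain <- as.matrix(chain)
  if (nrow(chain) < 5) stop("chain must have at least 5 points")
  d <- sqrt(diff(chain[, 1])^2 + diff(chain[, 2])^2)
  if (any(d == 0)) stop("degenerate chain: repeated points")
  s <- c(0, cumsum(d))
  fx <- stats::smooth.spline(s, chain[, 1])
  fy <- stats::smooth.spline(s, chain[, 2])
  total <- max(s)
  grid <- seq(trim * total, (1 - trim) * total, length.out = n_samples)
  x1 <- stats::predict(fx, grid, deriv = 1)$y
  x2 <- stats::predict(fx, grid, deriv = 2)$y
  y1 <- stats::predict(fy, grid, deriv = 1)$y
  y2 <- stats::predict(fy, grid, deriv = 2)$y
  kappa <- abs(x1 * y2 - y1 * x2) / (x1^2 + y1^2)^1.5
  samples <- data.frame(s_um = grid, kappa_per_um = kappa)
  if (is.null(image)) return(samples)
  pixel_um <- pixel_size_nm / 1000
  px <- stats::predict(fx, grid)$y / pixel_um + 0.5
  py <- stats::predict(fy, grid)$y / pixel_um + 0.5
  if (is.null(background)) background <- stats::median(image)
  samples$intensity <- bilinear_sample(image, py, px) - background
  breaks <- seq(min(kappa), max(kappa), length.out = n_bins + 1)
  breaks[1] <- breaks[1] - 1e-9
  bin <- cut(kappa, breaks)
  bins <- data.frame(
    kappa_mid = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
    mean_intensity = as.numeric(tapply(samples$intensity, bin, mean)),
    sd_intensity = as.numeric(tapply(samples$intensity, bin, stats::sd)),
    n = as.integer(table(bin))
  )
  list(samples = samples, bins = bins)
}
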