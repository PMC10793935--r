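# Seedable toy-model generators. Each one emulates a geometry with a known
# feature layout so the expected structure is known by construction: gradients
# should score near 1, shuffled features near 0, locally repeating patterns
# should collapse as the neighborhood grows. Every generator is a pure
# function of (parameters, seed).

#' Uniform random point cloud
#'
#' @param n_points Number of points.
#' @param dim Ambient dimension; points are uniform on the unit hypercube.
#' @param seed Integer seed.
#' @return N x dim numeric matrix.
#' @export
random_cloud <- function(n_points, dim = 2L, seed) {
  stopifnot(n_points >= 10L, dim >= 1L)
  withr::with_seed(seed, {
    matrix(stats::runif(n_points * dim), nrow = n_points, ncol = dim)
  })
}

#' 2D ellipsoid cloud with a feature gradient along the major axis
#'
#' Points uniform inside a 2:1 ellipse; the feature is the position along the
#' major axis rescaled to `[0, 1]` and passed through the monotone power
#' transform `f^exp(skewness)`, so `skewness = 0` is the identity and any
#' skewness preserves the rank order (the bin boundaries move but the
#' gradient stays a gradient).
#'
#' @param n_points Number of points (the reference configuration uses 40000;
#'   a few thousand suffice for a stable SI).
#' @param skewness Real; exponent of the transform is `exp(skewness)`.
#' @param noise_sd Standard deviation of Gaussian jitter added to the
#'   coordinates after the feature is computed.
#' @param seed Integer seed.
#' @return List with `points` (N x 2), `feature` (length N) and `params`.
#' @export
gradient_ellipsoid <- function(n_points = 40000L, skewness = 0,
                               noise_sd = 0, seed) {
  stopifnot(n_points >= 10L, noise_sd >= 0)
  withr::with_seed(seed, {
    a <- 2; b <- 1
    pts <- matrix(NA_real_, 0L, 2L)
    while (nrow(pts) < n_points) {  # rejection sampling in the bounding box
      cand <- cbind(stats::runif(2L * n_points, -a, a),
                    stats::runif(2L * n_points, -b, b))
      keep <- (cand[, 1L] / a)^2 + (cand[, 2L] / b)^2 <= 1
      pts <- rbind(pts, cand[keep, , drop = FALSE])
    }
    pts <- pts[seq_len(n_points), , drop = FALSE]
    f01 <- (pts[, 1L] + a) / (2 * a)
    feature <- f01^exp(skewness)
    if (noise_sd > 0) {
      pts <- pts + matrix(stats::rnorm(length(pts), sd = noise_sd),
                          nrow = n_points)
    }
    list(points = pts, feature = feature,
         params = list(kind = "gradient_ellipsoid", n_points = n_points,
                       skewness = skewness, noise_sd = noise_sd, seed = seed))
  })
}

#' 3D solid ball with the feature along the radius
#'
#' Angles and radius sampled uniformly, mapped to Euclidean coordinates,
#' Gaussian noise added to the points. The feature is the radius before
#' noise, so at zero noise it equals the Euclidean norm of each point and
#' the bin-groups are concentric shells.
#'
#' @inheritParams gradient_ellipsoid
#' @return List with `points` (N x 3), `feature` (radius, length N), `params`.
#' @export
radial_ball <- function(n_points = 40000L, noise_sd = 0, seed) {
  stopifnot(n_points >= 10L, noise_sd >= 0)
  withr::with_seed(seed, {
    r <- stats::runif(n_points)
    theta <- stats::runif(n_points, 0, pi)
    phi <- stats::runif(n_points, 0, 2 * pi)
    pts <- cbind(r * sin(theta) * cos(phi),
                 r * sin(theta) * sin(phi),
                 r * cos(theta))
    if (noise_sd > 0) {
      pts <- pts + matrix(stats::rnorm(length(pts), sd = noise_sd),
                          nrow = n_points)
    }
    list(points = pts, feature = r,
         params = list(kind = "radial_ball", n_points = n_points,
                       noise_sd = noise_sd, seed = seed))
  })
}

#' Unit sphere in D dimensions with its generating angles as vector feature
#'
#' Standard hyperspherical coordinates with unit radius: angles
#' `theta_1..theta_{D-2}` uniform on `[0, pi]`, the last angle uniform on
#' `[0, 2*pi)`, Euclidean coordinates by the trigonometric recursion
#' `x_1 = cos(theta_1)`, `x_2 = sin(theta_1) cos(theta_2)`, ...,
#' `x_D = sin(theta_1)...sin(theta_{D-1})`, plus per-coordinate Gaussian
#' noise. The first angle fully determines `x_1`, so its structure over the
#' cloud exceeds that of the last angle, and the full angle vector is more
#' structured than any single angle.
#'
#' @param dim Ambient (and sphere) dimension, >= 2.
#' @param n_points Number of points.
#' @param noise_sd Gaussian noise per coordinate; 0.05 (5% of the radius) is
#'   the default working level.
#' @param seed Integer seed.
#' @return List with `points` (N x dim), `feature` (N x (dim - 1) matrix of
#'   angles, columns named `theta1..`), `params`.
#' @export
ndim_sphere <- function(dim, n_points = 40000L, noise_sd = 0.05, seed) {
  dim <- as.integer(dim)
  stopifnot(dim >= 2L, n_points >= 10L, noise_sd >= 0)
  withr::with_seed(seed, {
    n_ang <- dim - 1L
    ang <- matrix(NA_real_, n_points, n_ang)
    if (n_ang > 1L) {
      for (d in seq_len(n_ang - 1L)) ang[, d] <- stats::runif(n_points, 0, pi)
    }
    ang[, n_ang] <- stats::runif(n_points, 0, 2 * pi)
    pts <- matrix(NA_real_, n_points, dim)
    sin_prod <- rep(1, n_points)
    for (d in seq_len(n_ang)) {
      pts[, d] <- sin_prod * cos(ang[, d])
      sin_prod <- sin_prod * sin(ang[, d])
    }
    pts[, dim] <- sin_prod
    if (noise_sd > 0) {
      pts <- pts + matrix(stats::rnorm(length(pts), sd = noise_sd),
                          nrow = n_points)
    }
    colnames(ang) <- paste0("theta", seq_len(n_ang))
    list(points = pts, feature = ang,
         params = list(kind = "ndim_sphere", dim = dim, n_points = n_points,
                       noise_sd = noise_sd, seed = seed))
  })
}

#' One 2D cloud, two feature layouts: locally repeating vs global gradient
#'
#' A single elongated 2D cloud split into `n_tiles` spatial regions along its
#' long axis. The local feature ramps 0 to 1 within each region independently
#' (the same bin-groups recur in every region); the global feature ramps 0 to
#' 1 once across the whole cloud. Both layouts share identical coordinates,
#' so any difference in their SI profiles over k comes from the feature
#' organization alone: the local pattern collapses sharply as the
#' neighborhood outgrows a region, the global one decays smoothly.
#'
#' @param n_points Number of points (reference configuration: 9000).
#' @param n_tiles Number of regions, >= 2.
#' @param seed Integer seed.
#' @return List with `points` (N x 2), `feature_local`, `feature_global`
#'   (each length N), `tile` (region index per point) and `params`.
#' @export
local_and_global_patterns <- function(n_points = 9000L, n_tiles = 4L, seed) {
  n_tiles <- as.integer(n_tiles)
  stopifnot(n_points >= 10L, n_tiles >= 2L)
  withr::with_seed(seed, {
    x <- stats::runif(n_points)
    y <- stats::runif(n_points, 0, 1 / n_tiles)  # elongated: n_tiles:1 aspect
    tile <- pmin(floor(x * n_tiles), n_tiles - 1L)
    local_f <- x * n_tiles - tile
    list(points = cbind(x, y),
         feature_local = local_f,
         feature_global = x,
         tile = as.integer(tile) + 1L,
         params = list(kind = "local_and_global", n_points = n_points,
                       n_tiles = n_tiles, seed = seed))
  })
}

#' 2D cloud positioned by two latent features with tunable interdependence
#'
#' Latent features `a, b ~ Uniform(0, 1)`; the coordinates are
#' `(x, y) = (b, alpha * a)` plus Gaussian noise. `b`'s impact on position is
#' constant while `a`'s is scaled by `alpha`: at `alpha = 0` the cloud is
#' defined entirely by `b` (SI(b) maximal, SI(a) at chance); as `alpha`
#' grows, `a` gains structure and the joint vector `(a, b)` approaches
#' perfect separation.
#'
#' @param n_points Number of points (reference configuration: 20000).
#' @param alpha Non-negative scale of `a`'s contribution.
#' @param noise_sd Gaussian coordinate noise; default 0.01 (1% of the unit
#'   square).
#' @param seed Integer seed.
#' @return List with `points` (N x 2), `feature` (N x 2 matrix, columns `a`,
#'   `b`), `params`.
#' @export
two_feature_cloud <- function(n_points = 20000L, alpha = 1, noise_sd = 0.01,
                              seed) {
  stopifnot(n_points >= 10L, alpha >= 0, noise_sd >= 0)
  withr::with_seed(seed, {
    a <- stats::runif(n_points)
    b <- stats::runif(n_points)
    pts <- cbind(b, alpha * a)
    if (noise_sd > 0) {
      pts <- pts + matrix(stats::rnorm(length(pts), sd = noise_sd),
                          nrow = n_points)
    }
    list(points = unname(pts), feature = cbind(a = a, b = b),
         params = list(kind = "two_feature", n_points = n_points,
                       alpha = alpha, noise_sd = noise_sd, seed = seed))
  })
}

#' Embed a cloud into a higher dimension by noise plus random rotation
#'
#' Zero-pads the coordinates to `target_dim`, adds white Gaussian noise on
#' every coordinate, then applies a uniformly random orthogonal rotation (QR
#' of a Gaussian matrix with the sign convention fixed). The intrinsic
#' dimension of the object is preserved while the information is spread
#' along all ambient dimensions; at zero noise the map is an exact isometry.
#'
#' @param cloud N x D numeric matrix.
#' @param target_dim Ambient dimension, `>= ncol(cloud)`.
#' @param noise_sd Gaussian noise per coordinate.
#' @param seed Integer seed.
#' @return N x target_dim numeric matrix.
#' @export
embed_and_rotate <- function(cloud, target_dim, noise_sd = 0, seed) {
  cloud <- validate_cloud(cloud)
  target_dim <- as.integer(target_dim)
  if (target_dim < ncol(cloud)) {
    stop("target_dim must be >= the cloud dimension", call. = FALSE)
  }
  stopifnot(noise_sd >= 0)
  withr::with_seed(seed, {
    n <- nrow(cloud)
    x <- cbind(cloud, matrix(0, n, target_dim - ncol(cloud)))
    if (noise_sd > 0) {
      x <- x + matrix(stats::rnorm(length(x), sd = noise_sd), nrow = n)
    }
    rot <- random_rotation(target_dim)
    unname(x %*% rot)
  })
}

# Haar-ish random orthogonal matrix: QR of a Gaussian matrix, columns
# sign-fixed by the diagonal of R so the result is deterministic.
random_rotation <- function(d) {
  qr_dec <- qr(matrix(stats::rnorm(d * d), d, d))
  q <- qr.Q(qr_dec)
  q %*% diag(sign(diag(qr.R(qr_dec))), d, d)
}

#' Add isotropic Gaussian noise at a target signal-to-noise ratio
#'
#' The SNR convention is the per-coordinate variance ratio: the noise
#' variance on every coordinate equals the mean per-coordinate variance of
#' the input divided by `snr`. Users with a different SNR convention can
#' convert and call with the equivalent ratio.
#'
#' @param cloud N x D numeric matrix.
#' @param snr Positive signal-to-noise ratio; large values leave the cloud
#'   nearly untouched, `snr = 1` adds noise as strong as the signal.
#' @param seed Integer seed.
#' @return N x D numeric matrix.
#' @export
add_noise_snr <- function(cloud, snr, seed) {
  cloud <- validate_cloud(cloud)
  if (!is.numeric(snr) || length(snr) != 1L || !is.finite(snr) || snr <= 0) {
    stop("snr must be a positive number", call. = FALSE)
  }
  signal_var <- mean(apply(cloud, 2L, stats::var))
  noise_sd <- sqrt(signal_var / snr)
  withr::with_seed(seed, {
    cloud + matrix(stats::rnorm(length(cloud), sd = noise_sd),
                   nrow = nrow(cloud))
  })
}

#' Discontinuous multi-part 3D cloud with a continuous feature across parts
#'
#' A stack of `n_parts` spatially disjoint solid discs (lamp-like: radii
#' alternate wide/narrow) separated by gaps along the z axis, with one
#' continuous feature ramping monotonically along the stacking coordinate
#' across all parts. Exercises the metric on clouds whose support is
#' disconnected while the feature is globally ordered.
#'
#' @param n_points Total number of points (reference configuration: 32000).
#' @param n_parts Number of parts, >= 2.
#' @param seed Integer seed.
#' @return List with `points` (N x 3), `feature` (length N, in `[0, 1]`),
#'   `part` (component index per point) and `params`.
#' @export
discontinuous_multipart <- function(n_points = 32000L, n_parts = 3L, seed) {
  n_parts <- as.integer(n_parts)
  stopifnot(n_points >= 10L, n_parts >= 2L)
  withr::with_seed(seed, {
    height <- 0.3; gap <- 0.5
    radii <- rep(c(1, 0.35, 0.7), length.out = n_parts)
    part <- rep(seq_len(n_parts), length.out = n_points)
    part <- sort(part)
    n <- n_points
    u <- stats::runif(n); ang <- stats::runif(n, 0, 2 * pi)
    rad <- radii[part] * sqrt(u)
    z0 <- (part - 1L) * (height + gap)
    z <- z0 + stats::runif(n, 0, height)
    z_max <- (n_parts - 1L) * (height + gap) + height
    list(points = cbind(rad * cos(ang), rad * sin(ang), z),
         feature = z / z_max,
         part = part,
         params = list(kind = "discontinuous_multipart", n_points = n_points,
                       n_parts = n_parts, seed = seed))
  })
}
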