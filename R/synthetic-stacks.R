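#' Ground-truth scene for a simulated two-channel image stack
#'
#' @param spots `data.frame` with one row per diffraction-limited spot:
#'   `x`, `y`, `z` (voxel-centered, 0-based coordinates), `copy_number`
#'   (positive integer), `amp_ref`, `amp_tgt` (integrated photon amplitude
#'   per channel, >= 0) and `region` (`expressing` / `nonexpressing`).
#' @param dim Stack dimensions `c(nx, ny, nz)` in voxels.
#' @param seed Integer seed recorded verbatim with the scene.
#' @return An object of class `scene_truth`.
#' @seealso [gen_scene_truth()], [gen_image_stack()]
#' @export
scene_truth <- function(spots, dim, seed) {
  stopifnot(is.data.frame(spots),
            all(c("x", "y", "z", "copy_number", "amp_ref", "amp_tgt",
                  "region") %in% names(spots)))
  stopifnot(length(dim) == 3L, all(dim >= 1))
  if (nrow(spots) > 0) {
    if (any(spots$copy_number < 1)) stop("copy_number must be >= 1")
    if (any(spots$x < 0 | spots$x >= dim[1] |
            spots$y < 0 | spots$y >= dim[2] |
            spots$z < 0 | spots$z >= dim[3])) {
      stop("every spot center must lie inside the stack bounds")
    }
  }
  structure(list(spots = spots, dim = as.integer(dim),
                 seed = as.integer(seed)),
            class = "scene_truth")
}

#' Generate a random planted-spot scene
#'
#' Places `n_spots` diffraction-limited spots uniformly in the stack (with a
#' border margin and a minimum pairwise separation enforced by rejection
#' sampling, so planted spots are individually resolvable), assigns each a
#' copy number from `copy_weights`, and sets per-channel integrated
#' amplitudes: `amp_ref = copy_number * amp_per_copy` and
#' `amp_tgt = beta * amp_ref` gated by a Bernoulli(`p_codetect`) detection
#' event.
#'
#' @param n_spots Number of spots.
#' @param dim Stack dimensions `c(nx, ny, nz)`.
#' @param amp_per_copy Integrated reference-channel photons per mRNA copy.
#' @param copy_weights Copy-number class probabilities.
#' @param beta Target/reference brightness ratio.
#' @param p_codetect Per-spot target-channel detection probability.
#' @param margin Minimum distance of spot centers from stack faces (voxels);
#'   keeps the full three-slice support of each spot inside the stack.
#' @param min_sep Minimum pairwise 3D center separation (voxels).
#' @param region Compartment label stored with every spot.
#' @param seed Integer seed.
#' @return A [scene_truth()] object (truth columns include `detected`).
#' @export
gen_scene_truth <- function(n_spots, dim = c(64, 64, 32), amp_per_copy = 1000,
                            copy_weights = 1, beta = 0.8, p_codetect = 1,
                            margin = 5, min_sep = 8,
                            region = "expressing", seed = 1L) {
  stopifnot(n_spots >= 0, all(dim >= 1), amp_per_copy >= 0, min_sep >= 0)
  with_stream(seed, "scene", {
    xs <- ys <- zs <- numeric(0)
    tries <- 0L
    while (length(xs) < n_spots) {
      x <- runif(1, margin, dim[1] - 1 - margin)
      y <- runif(1, margin, dim[2] - 1 - margin)
      z <- runif(1, margin, dim[3] - 1 - margin)
      ok <- length(xs) == 0 ||
        min(sqrt((xs - x)^2 + (ys - y)^2 + (zs - z)^2)) >= min_sep
      if (ok) {
        xs <- c(xs, x); ys <- c(ys, y); zs <- c(zs, z)
      }
      tries <- tries + 1L
      if (tries > 10000L * max(1L, n_spots)) {
        stop("could not place ", n_spots, " spots with min_sep = ", min_sep)
      }
    }
    k <- sample.int(length(copy_weights), n_spots, replace = TRUE,
                    prob = copy_weights)
    det <- runif(n_spots) < p_codetect
    spots <- data.frame(
      x = xs, y = ys, z = zs, copy_number = k,
      amp_ref = k * amp_per_copy,
      amp_tgt = beta * k * amp_per_copy * det,
      detected = det,
      region = rep(region, length.out = n_spots),
      stringsAsFactors = FALSE
    )
    scene_truth(spots, dim, seed)
  })
}

# Render one channel of the scene: each spot deposits `amp` photons as a
# 3D Gaussian, integrated exactly over voxels (difference of pnorm at voxel
# edges) and truncated at +/- 4 sigma per axis (< 0.01% mass loss).
render_channel <- function(truth, amp_col, psf_sigma_xy, psf_sigma_z,
                           background) {
  d <- truth$dim
  img <- array(background, dim = d)
  spots <- truth$spots
  if (nrow(spots) == 0) return(img)
  axis_weights <- function(center, sigma, n) {
    lo <- max(1L, floor(center - 4 * sigma) + 1L)
    hi <- min(n, ceiling(center + 4 * sigma) + 1L)
    if (lo > hi) return(NULL)
    idx <- lo:hi
    # voxel i (1-based) is centered at i - 1 and spans [i - 1.5, i - 0.5]
    w <- pnorm(idx - 0.5, center, sigma) - pnorm(idx - 1.5, center, sigma)
    list(idx = idx, w = w)
  }
  for (i in seq_len(nrow(spots))) {
    amp <- spots[[amp_col]][i]
    if (amp == 0) next
    wx <- axis_weights(spots$x[i], psf_sigma_xy, d[1])
    wy <- axis_weights(spots$y[i], psf_sigma_xy, d[2])
    wz <- axis_weights(spots$z[i], psf_sigma_z, d[3])
    if (is.null(wx) || is.null(wy) || is.null(wz)) next
    contrib <- amp * (wx$w %o% wy$w %o% wz$w)
    img[wx$idx, wy$idx, wz$idx] <- img[wx$idx, wy$idx, wz$idx] + contrib
  }
  img
}

#' Render a two-channel 3D image stack from a ground-truth scene
#'
#' Each spot is rendered as an isotropic-in-xy 3D Gaussian whose integrated
#' photon count equals its amplitude (copy number times per-copy
#' brightness), on a uniform background. Voxel values are then Poisson
#' draws of the expected photon count, matching the photon-count semantics
#' of photon-counting confocal acquisition; set `poisson = FALSE` for the
#' noiseless expectation.
#'
#' Both channels share the spot geometry and PSF; they differ only through
#' the per-spot target amplitudes (brightness ratio and detection events)
#' recorded in the scene.
#'
#' @param truth A [scene_truth()] object.
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF standard deviations in
#'   voxels (> 0).
#' @param background Expected background photons per voxel (>= 0).
#' @param poisson Apply Poisson shot noise? Default `TRUE`.
#' @param seed Integer seed for the shot noise; defaults to the scene seed.
#' @return A list of class `smfish_stack` with elements `ref`, `tgt`
#'   (numeric arrays `dim(truth)`), and `truth`.
#' @examples
#' sc <- gen_scene_truth(5, dim = c(32, 32, 16), seed = 2)
#' st <- gen_image_stack(sc, background = 5)
#' dim(st$ref)
#' @export
gen_image_stack <- function(truth, psf_sigma_xy = 1.3, psf_sigma_z = 1.5,
                            background = 0, poisson = TRUE,
                            seed = truth$seed) {
  stopifnot(inherits(truth, "scene_truth"),
            psf_sigma_xy > 0, psf_sigma_z > 0, background >= 0)
  if (nrow(truth$spots) > 0 &&
      (any(truth$spots$amp_ref < 0) || any(truth$spots$amp_tgt < 0))) {
    stop("spot amplitudes must be >= 0")
  }
  ref <- render_channel(truth, "amp_ref", psf_sigma_xy, psf_sigma_z,
                        background)
  tgt <- render_channel(truth, "amp_tgt", psf_sigma_xy, psf_sigma_z,
                        background)
  if (poisson) {
    with_stream(seed, "image_stack", {
      ref[] <- rpois(length(ref), ref)
      tgt[] <- rpois(length(tgt), tgt)
    })
  }
  structure(list(ref = ref, tgt = tgt, truth = truth),
            class = "smfish_stack")
}
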