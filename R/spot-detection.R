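# 3D smFISH object detection: per-slice local maxima in the reference
# channel, greedy z-linking of 2D peaks into 3D objects of >= 3 slices,
# aperture photometry in both channels, and compartment density statistics.

#' Detect 2D peaks in one image slice
#'
#' A peak is a pixel that is a strict maximum of its 8-neighborhood and
#' whose value reaches the `(100 - top_percentile)`-th percentile of the
#' slice's pixel value distribution, i.e. lies in the upper
#' `top_percentile` percent of the slice. Thresholding is per slice, so
#' the detector adapts to slice-to-slice background variation.
#'
#' @param slice Numeric matrix (rows = x, columns = y) of photon counts.
#' @param top_percentile Upper percentile `q` defining the intensity
#'   threshold, `0 < q < 50`; default 1.
#' @return A `data.frame` with columns `x`, `y` (0-based pixel
#'   coordinates) and `value`, ordered by decreasing value.
#' @export
detect_slice_maxima <- function(slice, top_percentile = 1) {
  if (!is.matrix(slice) || length(slice) == 0) {
    stop("`slice` must be a non-empty numeric matrix")
  }
  if (top_percentile <= 0 || top_percentile >= 50) {
    stop("`top_percentile` must lie in (0, 50)")
  }
  thr <- quantile(slice, 1 - top_percentile / 100, names = FALSE)
  nr <- nrow(slice); nc <- ncol(slice)
  padded <- matrix(-Inf, nr + 2, nc + 2)
  padded[2:(nr + 1), 2:(nc + 1)] <- slice
  padded_hi <- matrix(Inf, nr + 2, nc + 2)
  padded_hi[2:(nr + 1), 2:(nc + 1)] <- slice
  is_max <- slice >= thr
  any_lower <- matrix(FALSE, nr, nc)
  for (dx in -1:1) {
    for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      neigh <- padded[(2 + dx):(nr + 1 + dx), (2 + dy):(nc + 1 + dy)]
      # photon counts are integers, so equal-valued plateaus at a spot's
      # peak are common; require strict dominance only over neighbors
      # that precede the pixel in column-major order, so a flat-topped
      # peak yields exactly one maximum and a constant image yields none
      if (dy < 0 || (dy == 0 && dx < 0)) {
        is_max <- is_max & (slice > neigh)
      } else {
        is_max <- is_max & (slice >= neigh)
      }
      # a peak must dominate at least one in-image neighbor strictly,
      # otherwise border pixels of a flat region would qualify
      neigh_hi <- padded_hi[(2 + dx):(nr + 1 + dx), (2 + dy):(nc + 1 + dy)]
      any_lower <- any_lower | (slice > neigh_hi)
    }
  }
  is_max <- is_max & any_lower
  idx <- which(is_max, arr.ind = TRUE)
  out <- data.frame(x = idx[, 1] - 1L, y = idx[, 2] - 1L,
                    value = slice[idx])
  out <- out[order(-out$value, out$x, out$y), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Link per-slice 2D peaks into 3D objects along z
#'
#' Peaks in adjacent slices are chained by greedy nearest-neighbor
#' matching of their xy centers: candidate pairs with center distance at
#' most `r_xy` are assigned in order of increasing distance (ties by
#' smaller x, then y), each peak joining at most one chain. Chains
#' spanning fewer than `min_depth` slices are discarded; three slices is
#' the canonical minimum for a diffraction-limited spot sampled at typical
#' confocal z-steps.
#'
#' @param peaks_by_slice List of per-slice peak `data.frame`s (as returned
#'   by [detect_slice_maxima()]), ordered by z; element `i` is slice
#'   `z = i - 1`.
#' @param r_xy Maximum xy center distance (voxels) for linking across
#'   adjacent slices; default 2.
#' @param min_depth Minimum number of slices per emitted object; default 3.
#' @return A `data.frame` with one row per 3D object: `object_id`, `x`,
#'   `y`, `z` (centroid of member peaks), `z_min`, `z_max`, `n_slices`,
#'   `peak_value` (maximum member peak value).
#' @export
link_z <- function(peaks_by_slice, r_xy = 2, min_depth = 3) {
  stopifnot(is.list(peaks_by_slice), r_xy >= 0, min_depth >= 1)
  chains <- list()    # each: list(xs, ys, zs, vals, open)
  active <- integer(0)  # indices into `chains` with head in previous slice
  for (zi in seq_along(peaks_by_slice)) {
    pk <- peaks_by_slice[[zi]]
    z <- zi - 1L
    n_new <- if (is.null(pk)) 0L else nrow(pk)
    assigned_chain <- rep(FALSE, length(active))
    assigned_peak <- rep(FALSE, n_new)
    if (length(active) > 0 && n_new > 0) {
      heads_x <- vapply(chains[active], function(ch) ch$xs[length(ch$xs)], 0)
      heads_y <- vapply(chains[active], function(ch) ch$ys[length(ch$ys)], 0)
      dx <- outer(heads_x, pk$x, "-")
      dy <- outer(heads_y, pk$y, "-")
      dist <- sqrt(dx^2 + dy^2)
      cand <- which(dist <= r_xy, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        ord <- order(dist[cand], pk$x[cand[, 2]], pk$y[cand[, 2]])
        for (ci in ord) {
          a <- cand[ci, 1]; p <- cand[ci, 2]
          if (assigned_chain[a] || assigned_peak[p]) next
          assigned_chain[a] <- TRUE
          assigned_peak[p] <- TRUE
          ch <- chains[[active[a]]]
          ch$xs <- c(ch$xs, pk$x[p]); ch$ys <- c(ch$ys, pk$y[p])
          ch$zs <- c(ch$zs, z); ch$vals <- c(ch$vals, pk$value[p])
          chains[[active[a]]] <- ch
        }
      }
    }
    next_active <- active[assigned_chain]
    if (n_new > 0) {
      for (p in which(!assigned_peak)) {
        chains[[length(chains) + 1L]] <- list(
          xs = pk$x[p], ys = pk$y[p], zs = z, vals = pk$value[p])
        next_active <- c(next_active, length(chains))
      }
    }
    active <- next_active
  }
  keep <- vapply(chains, function(ch) length(ch$zs) >= min_depth, TRUE)
  chains <- chains[keep]
  if (length(chains) == 0) {
    return(data.frame(object_id = integer(0), x = numeric(0),
                      y = numeric(0), z = numeric(0), z_min = integer(0),
                      z_max = integer(0), n_slices = integer(0),
                      peak_value = numeric(0)))
  }
  out <- do.call(rbind, lapply(seq_along(chains), function(i) {
    ch <- chains[[i]]
    data.frame(object_id = i, x = mean(ch$xs), y = mean(ch$ys),
               z = mean(ch$zs), z_min = min(ch$zs), z_max = max(ch$zs),
               n_slices = length(ch$zs), peak_value = max(ch$vals))
  }))
  rownames(out) <- NULL
  out
}

# pixels (1-based indices) within radius r of 0-based center (cx, cy);
# returns a two-column index matrix, clipped to the image, plus a flag
aperture_pixels <- function(cx, cy, r, nr, nc) {
  clipped <- cx - r < 0 || cx + r > nr - 1 || cy - r < 0 || cy + r > nc - 1
  ix <- max(1L, floor(cx - r) + 1L):min(nr, ceiling(cx + r) + 1L)
  iy <- max(1L, floor(cy - r) + 1L):min(nc, ceiling(cy + r) + 1L)
  grid <- expand.grid(i = ix, j = iy)
  d2 <- (grid$i - 1 - cx)^2 + (grid$j - 1 - cy)^2
  sel <- grid[d2 <= r^2, , drop = FALSE]
  list(idx = as.matrix(sel), clipped = clipped)
}

#' Measure object intensities in both channels
#'
#' For every linked 3D object, intensities are background-subtracted sums
#' over a cylindrical aperture: a disk of radius `aperture_radius_xy`
#' around the object centroid, on the object's member slices only, with
#' identical geometry in both channels. The per-slice background is the
#' median of the pixels outside all apertures on that slice, estimated
#' separately per channel.
#'
#' @param objects 3D objects from [link_z()].
#' @param ref_stack,tgt_stack Numeric arrays `(nx, ny, nz)`; `tgt_stack`
#'   may be `NULL`, in which case `tgt_intensity` is `NA`.
#' @param aperture_radius_xy Aperture radius in voxels; default 2.
#' @param region_mask Optional integer array (same dimensions, or a single
#'   matrix applied to every slice) labeling compartments; values are
#'   mapped through `region_labels` at the object centroid.
#' @param region_labels Named character vector mapping mask values to
#'   region names; default ``c(`1` = "expressing", `2` = "nonexpressing")``,
#'   other values giving `"unassigned"`.
#' @return A `data.frame` of class `smfish_objects` with columns
#'   `object_id`, `region`, `x`, `y`, `z`, `n_slices`, `ref_intensity`,
#'   `tgt_intensity`. Negative background-subtracted sums are clamped at
#'   zero (photon counts are non-negative).
#' @export
measure_objects <- function(objects, ref_stack, tgt_stack = NULL,
                            aperture_radius_xy = 2, region_mask = NULL,
                            region_labels = c(`1` = "expressing",
                                              `2` = "nonexpressing")) {
  stopifnot(is.array(ref_stack), length(dim(ref_stack)) == 3L)
  d <- dim(ref_stack)
  if (!is.null(tgt_stack)) stopifnot(all(dim(tgt_stack) == d))
  n_obj <- nrow(objects)
  if (n_obj == 0) {
    return(structure(data.frame(object_id = integer(0),
                                region = character(0), x = numeric(0),
                                y = numeric(0), z = numeric(0),
                                n_slices = integer(0),
                                ref_intensity = numeric(0),
                                tgt_intensity = numeric(0)),
                     class = c("smfish_objects", "data.frame")))
  }
  aps <- lapply(seq_len(n_obj), function(i) {
    ap <- aperture_pixels(objects$x[i], objects$y[i], aperture_radius_xy,
                          d[1], d[2])
    if (ap$clipped) {
      warning(sprintf("aperture of object %d clipped at image bounds",
                      objects$object_id[i]))
    }
    ap$idx
  })
  # per-slice exclusion mask for background estimation
  in_aperture <- vector("list", d[3])
  for (z in seq_len(d[3])) in_aperture[[z]] <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(n_obj)) {
    for (z in (objects$z_min[i]:objects$z_max[i]) + 1L) {
      in_aperture[[z]][aps[[i]]] <- TRUE
    }
  }
  slice_bg <- function(stack, z) {
    sl <- stack[, , z]
    outside <- sl[!in_aperture[[z]]]
    if (length(outside) == 0) 0 else median(outside)
  }
  sum_channel <- function(stack, i) {
    total <- 0
    for (z in (objects$z_min[i]:objects$z_max[i]) + 1L) {
      sl <- stack[, , z]
      total <- total + sum(sl[aps[[i]]]) -
        slice_bg(stack, z) * nrow(aps[[i]])
    }
    max(0, total)
  }
  ref_int <- vapply(seq_len(n_obj), function(i) sum_channel(ref_stack, i), 0)
  tgt_int <- if (is.null(tgt_stack)) rep(NA_real_, n_obj) else
    vapply(seq_len(n_obj), function(i) sum_channel(tgt_stack, i), 0)
  region <- rep("unassigned", n_obj)
  if (!is.null(region_mask)) {
    for (i in seq_len(n_obj)) {
      ix <- min(d[1], max(1L, round(objects$x[i]) + 1L))
      iy <- min(d[2], max(1L, round(objects$y[i]) + 1L))
      iz <- min(d[3], max(1L, round(objects$z[i]) + 1L))
      val <- if (length(dim(region_mask)) == 3L) {
        region_mask[ix, iy, iz]
      } else {
        region_mask[ix, iy]
      }
      lab <- region_labels[as.character(val)]
      region[i] <- if (is.na(lab)) "unassigned" else lab
    }
  }
  out <- data.frame(object_id = objects$object_id, region = region,
                    x = objects$x, y = objects$y, z = objects$z,
                    n_slices = objects$n_slices,
                    ref_intensity = ref_int, tgt_intensity = tgt_int,
                    stringsAsFactors = FALSE)
  class(out) <- c("smfish_objects", "data.frame")
  out
}

#' Full smFISH object detection pipeline on a two-channel stack
#'
#' Runs [detect_slice_maxima()] on every reference-channel slice,
#' [link_z()] to build 3D objects of at least `min_depth` slices, and
#' [measure_objects()] for aperture photometry in both channels.
#'
#' @param ref_stack Reference-channel array `(nx, ny, nz)`; detection runs
#'   on this channel only.
#' @param tgt_stack Optional target-channel array, measured with identical
#'   aperture geometry.
#' @param top_percentile Per-slice intensity threshold percentile
#'   (see [detect_slice_maxima()]).
#' @param r_xy,min_depth z-linking parameters (see [link_z()]).
#' @param aperture_radius_xy,region_mask,region_labels Photometry
#'   parameters (see [measure_objects()]).
#' @return An `smfish_objects` `data.frame`; every emitted object has
#'   `n_slices >= min_depth`.
#' @examples
#' sc <- gen_scene_truth(5, dim = c(48, 48, 16), amp_per_copy = 800,
#'                       seed = 4)
#' st <- gen_image_stack(sc, background = 0, poisson = FALSE)
#' nrow(detect_objects(st$ref, st$tgt))
#' @export
detect_objects <- function(ref_stack, tgt_stack = NULL, top_percentile = 1,
                           r_xy = 2, min_depth = 3, aperture_radius_xy = 2,
                           region_mask = NULL,
                           region_labels = c(`1` = "expressing",
                                             `2` = "nonexpressing")) {
  stopifnot(is.array(ref_stack), length(dim(ref_stack)) == 3L)
  peaks <- lapply(seq_len(dim(ref_stack)[3]), function(z) {
    detect_slice_maxima(ref_stack[, , z], top_percentile)
  })
  objects <- link_z(peaks, r_xy = r_xy, min_depth = min_depth)
  out <- measure_objects(objects, ref_stack, tgt_stack,
                         aperture_radius_xy, region_mask, region_labels)
  stopifnot(all(out$n_slices >= min_depth))
  out
}

#' Compartment density statistics and false-positive detection rate
#'
#' Compares the density of detected smFISH objects between a
#' transcript-expressing compartment (e.g. nurse cells) and a
#' non-expressing compartment (e.g. follicle cells). Because the
#' non-expressing compartment contains no target transcript, its object
#' density estimates the false-positive density, and the false-positive
#' detection rate is the reciprocal of the density fold excess:
#' `fpdr_pct = 100 / fold`. A 20- to 100-fold excess thus corresponds to
#' an FPDR of 5% down to 1%.
#'
#' @param objects An `smfish_objects` `data.frame` with a `region` column,
#'   or a named vector of object counts.
#' @param volumes Named numeric vector with analyzed volumes (voxels or
#'   any common unit) for `expressing` and `nonexpressing`.
#' @return A list of class `density_result`: `counts`, `volumes`,
#'   `density`, `fold` (expressing/nonexpressing density), `fpdr_pct`.
#' @examples
#' density_fpdr(c(expressing = 2000, nonexpressing = 100),
#'              c(expressing = 1e6, nonexpressing = 1e6))$fpdr_pct  # 5
#' @export
density_fpdr <- function(objects, volumes) {
  need <- c("expressing", "nonexpressing")
  if (!all(need %in% names(volumes))) {
    stop("`volumes` must be named with 'expressing' and 'nonexpressing'")
  }
  if (volumes[["nonexpressing"]] <= 0 || volumes[["expressing"]] <= 0) {
    stop("analyzed volumes must be > 0")
  }
  counts <- if (is.data.frame(objects)) {
    c(expressing = sum(objects$region == "expressing"),
      nonexpressing = sum(objects$region == "nonexpressing"))
  } else {
    stopifnot(all(need %in% names(objects)))
    c(expressing = as.numeric(objects[["expressing"]]),
      nonexpressing = as.numeric(objects[["nonexpressing"]]))
  }
  density <- counts / volumes[need]
  fold <- if (density[["nonexpressing"]] > 0) {
    density[["expressing"]] / density[["nonexpressing"]]
  } else {
    Inf
  }
  structure(list(counts = counts, volumes = volumes[need],
                 density = density, fold = fold,
                 fpdr_pct = if (is.finite(fold) && fold > 0) 100 / fold
                            else 0),
            class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf(
    "smFISH object density: %.3g (expressing) vs %.3g (nonexpressing)\n",
    x$density[["expressing"]], x$density[["nonexpressing"]]))
  cat(sprintf("fold excess: %.1f  =>  FPDR = %.2f%%\n", x$fold, x$fpdr_pct))
  invisible(x)
}
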