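## ---------------------------------------------------------------------------
## SLAM: short/long-axis merging.  Builds an isotropic "artificial" image on
## the short-axis bounding box; each output voxel is the weighted average of
## the nearest voxel of every source slice, with weights a decreasing
## function of the voxel-to-voxel distance d^V.
## ---------------------------------------------------------------------------

#' SLAM configuration
#'
#' @param spacing_mm target isotropic spacing of the merged image (mm).
#' @param kernel weighting kernel in the distance `d` to the nearest source
#'   voxel; `"gaussian"` (default) or `"inverse"` (1/(1+(d/scale)^2)).
#' @param scale_mm kernel scale; default half the cross-slice spacing of the
#'   short-axis stack (set when merging).
#' @param cutoff_mm hard support cutoff; default 1.5 x the cross-slice
#'   spacing.
#' @return object of class `slam_config`.
#' @export
slam_config <- function(spacing_mm = 1, kernel = c("gaussian", "inverse"),
                        scale_mm = NULL, cutoff_mm = NULL) {
  kernel <- match.arg(kernel)
  stopifnot(spacing_mm > 0, is.null(scale_mm) || scale_mm > 0)
  structure(list(spacing_mm = spacing_mm, kernel = kernel,
                 scale_mm = scale_mm, cutoff_mm = cutoff_mm),
            class = "slam_config")
}

#' SLAM distance weight
#'
#' Non-negative, equal to 1 at `d = 0`, strictly decreasing, with a hard
#' cutoff beyond `cutoff_mm`.
#'
#' @param d distances (mm), `d >= 0`.
#' @param cfg a [slam_config()] with `scale_mm` and `cutoff_mm` resolved.
#' @return weights in `[0, 1]`.
#' @export
slam_weight <- function(d, cfg) {
  stopifnot(all(d >= 0), !is.null(cfg$scale_mm), !is.null(cfg$cutoff_mm))
  w <- switch(cfg$kernel,
              gaussian = exp(-0.5 * (d / cfg$scale_mm)^2),
              inverse = 1 / (1 + (d / cfg$scale_mm)^2))
  w[d > cfg$cutoff_mm] <- 0
  w
}

## Decompose a voxel series into its slices (one per index along the axis
## with the largest spacing, assumed to be the slice axis for stacks; a
## single-slice series contributes its one slice).
slam_slices <- function(vs) {
  k3 <- vs$dim[3L]
  lapply(seq_len(k3), function(k) {
    list(origin = vs$origin + (k - 1) * vs$spacing[3L] * vs$axes[, 3L],
         e1 = vs$axes[, 1L], e2 = vs$axes[, 2L],
         sp = vs$spacing[1:2], n = vs$dim[1:2], k = k)
  })
}

#' Merge short-axis and long-axis series into an isotropic image (SLAM)
#'
#' Creates an artificial image covering the short-axis bounding box at a
#' uniform target spacing.  For every voxel of the new image and every slice
#' of every source series, the nearest source voxel (in-plane nearest grid
#' point of the projection onto the slice plane) is found, its distance
#' `d^V` computed, and the output value is the weighted average of those
#' source values with weights `slam_weight(d^V)`.  Frames are processed
#' independently.
#'
#' @param short_axis a `voxel_series` (the anisotropic short-axis stack).
#' @param long_axis_list list of `voxel_series` long-axis single slices
#'   (may be empty).
#' @param cfg a [slam_config()].
#' @return an isotropic `voxel_series`; voxels with zero total weight are
#'   marked background (0) and flagged in attribute `background`.
#' @export
slam_merge <- function(short_axis, long_axis_list = list(), cfg = slam_config()) {
  sax <- short_axis
  if (is.null(cfg$scale_mm)) cfg$scale_mm <- sax$spacing[3L] / 2
  if (is.null(cfg$cutoff_mm)) cfg$cutoff_mm <- 1.5 * sax$spacing[3L]
  nfr <- length(sax$frames)
  for (la in long_axis_list) {
    if (length(la$frames) != nfr)
      stop("all series must share the frame count")
  }
  h <- cfg$spacing_mm
  ## output grid spans the short-axis bounding box (axis-aligned in the
  ## short-axis frame)
  ext <- (sax$dim - 1L) * sax$spacing
  ng <- pmax(2L, floor(ext / h) + 1L)
  ## world coordinates of output voxel centers
  i1 <- (seq_len(ng[1L]) - 1L) * h
  i2 <- (seq_len(ng[2L]) - 1L) * h
  i3 <- (seq_len(ng[3L]) - 1L) * h
  grid <- as.matrix(expand.grid(a = i1, b = i2, c = i3))
  pts <- sweep(grid %*% t(sax$axes), 2L, sax$origin, "+")
  nv <- nrow(pts)

  series <- c(list(sax), long_axis_list)
  out_frames <- vector("list", nfr)
  bg <- NULL
  for (fi in seq_len(nfr)) {
    acc <- numeric(nv)
    wacc <- numeric(nv)
    for (vs in series) {
      fr <- vs$frames[[fi]]
      for (sl in slam_slices(vs)) {
        rel <- sweep(pts, 2L, sl$origin, "-")
        u <- as.numeric(rel %*% sl$e1)
        v <- as.numeric(rel %*% sl$e2)
        iu <- round(u / sl$sp[1L]) ; iv <- round(v / sl$sp[2L])
        ok <- iu >= 0 & iu < sl$n[1L] & iv >= 0 & iv < sl$n[2L]
        if (!any(ok)) next
        ## nearest voxel center of this slice
        near <- sweep(outer(iu * sl$sp[1L], sl$e1) + outer(iv * sl$sp[2L], sl$e2),
                      2L, sl$origin, "+")
        d <- sqrt(rowSums((pts - near)^2))
        w <- slam_weight(d, cfg)
        w[!ok] <- 0
        sel <- w > 0
        if (!any(sel)) next
        vals <- fr[cbind(iu[sel] + 1L, iv[sel] + 1L, sl$k)]
        acc[sel] <- acc[sel] + w[sel] * vals
        wacc[sel] <- wacc[sel] + w[sel]
      }
    }
    val <- ifelse(wacc > 0, acc / pmax(wacc, .Machine$double.eps), 0)
    if (fi == 1L) bg <- wacc == 0
    out_frames[[fi]] <- array(val, dim = ng)
  }
  out <- voxel_series(out_frames, spacing = rep(h, 3L), origin = sax$origin,
                      axes = sax$axes, times = sax$times)
  attr(out, "background") <- array(bg, dim = ng)
  out
}

#' Nearest-slice replication of an anisotropic stack
#'
#' Baseline against which SLAM is compared: resamples the stack on the same
#' isotropic grid as [slam_merge()] by in-plane nearest voxel of the nearest
#' slice only.
#'
#' @param short_axis a `voxel_series`.
#' @param spacing_mm target isotropic spacing.
#' @return an isotropic `voxel_series`.
#' @export
nearest_slice_replication <- function(short_axis, spacing_mm = 1) {
  sax <- short_axis
  h <- spacing_mm
  ext <- (sax$dim - 1L) * sax$spacing
  ng <- pmax(2L, floor(ext / h) + 1L)
  i3 <- (seq_len(ng[3L]) - 1L) * h
  k_near <- pmin(pmax(round(i3 / sax$spacing[3L]), 0L), sax$dim[3L] - 1L) + 1L
  i1 <- (seq_len(ng[1L]) - 1L) * h
  i2 <- (seq_len(ng[2L]) - 1L) * h
  iu <- pmin(pmax(round(i1 / sax$spacing[1L]), 0L), sax$dim[1L] - 1L) + 1L
  iv <- pmin(pmax(round(i2 / sax$spacing[2L]), 0L), sax$dim[2L] - 1L) + 1L
  frames <- lapply(sax$frames, function(fr) {
    arr <- fr[iu, iv, k_near, drop = FALSE]
    array(arr, dim = ng)
  })
  voxel_series(frames, spacing = rep(h, 3L), origin = sax$origin,
               axes = sax$axes, times = sax$times)
}
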