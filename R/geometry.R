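#' Pinhole camera intrinsics
#'
#' Pixel coordinates are 0-based: pixel `(u, v)` is column `u`, row `v`,
#' with `u = 0, v = 0` the top-left pixel centre. The camera looks along +z
#' into the scene; stored depth values are multiplied by `depth_scale` to
#' obtain millimetres.
#'
#' @param fx,fy focal lengths in pixels (> 0).
#' @param cx,cy principal point in 0-based pixel coordinates; must lie
#'   inside the image.
#' @param width,height image size in pixels.
#' @param depth_scale millimetres per stored depth unit (default 1).
#' @return A `camera_intrinsics` object.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height, depth_scale = 1) {
  stopifnot(fx > 0, fy > 0, width >= 1, height >= 1, depth_scale > 0)
  if (cx < 0 || cx > width - 1 || cy < 0 || cy > height - 1)
    stop("principal point must lie inside the image")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height),
                 depth_scale = depth_scale),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("camera_intrinsics %dx%d  fx=%.6g fy=%.6g cx=%.6g cy=%.6g  depth_scale=%g mm/unit\n",
              x$width, x$height, x$fx, x$fy, x$cx, x$cy, x$depth_scale))
  invisible(x)
}

#' Back-project a depth raster to 3-D points
#'
#' Each valid pixel `(u, v)` with depth `z` (mm, after unit scaling) maps to
#' the camera-frame point `((u - cx) z / fx, (v - cy) z / fy, z)`. Pixels
#' with zero, negative or missing depth are invalid and omitted.
#'
#' @param depth numeric matrix of depths in stored units (rows x cols).
#' @param cam a [camera_intrinsics()]; its size must match `depth`.
#' @return A `point_cloud`: list with `xyz` (n x 3 matrix, mm), `row`, `col`
#'   (1-based pixel indices of each point) and `dim` (raster size).
#' @export
backproject <- function(depth, cam) {
  stopifnot(is.matrix(depth), inherits(cam, "camera_intrinsics"))
  if (nrow(depth) != cam$height || ncol(depth) != cam$width)
    stop("depth raster size does not match the intrinsics")
  z <- depth * cam$depth_scale
  valid <- is.finite(z) & z > 0
  if (!any(valid)) stop("no valid depth pixels to back-project")
  idx <- which(valid, arr.ind = TRUE)
  zv <- z[valid]
  u <- idx[, 2L] - 1  # 0-based pixel coords
  v <- idx[, 1L] - 1
  xyz <- cbind(x = (u - cam$cx) * zv / cam$fx,
               y = (v - cam$cy) * zv / cam$fy,
               z = zv)
  structure(list(xyz = xyz, row = idx[, 1L], col = idx[, 2L],
                 dim = dim(depth)),
            class = "point_cloud")
}

#' Project 3-D points to pixel coordinates
#'
#' Inverse of [backproject()]: `u = x fx / z + cx`, `v = y fy / z + cy`
#' (0-based, not rounded).
#'
#' @param xyz n x 3 matrix of camera-frame points (mm), z > 0.
#' @param cam a [camera_intrinsics()].
#' @return n x 2 matrix of `(u, v)` pixel coordinates.
#' @export
project_points <- function(xyz, cam) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3, all(xyz[, 3] > 0))
  cbind(u = xyz[, 1] * cam$fx / xyz[, 3] + cam$cx,
        v = xyz[, 2] * cam$fy / xyz[, 3] + cam$cy)
}

# Total-least-squares plane through points: unit normal + offset (n.p = d).
# The normal is the singular vector of the centred cloud with the smallest
# singular value; degenerate (collinear/coincident) support gives NULL.
plane_lsq <- function(xyz) {
  if (nrow(xyz) < 3) return(NULL)
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr), nu = 0, nv = 3)
  # collinear support: the two smallest singular values both ~ 0
  if (sv$d[2] <= max(sv$d[1], 1) * 1e-12) return(NULL)
  n <- sv$v[, 3]
  list(normal = n, d = sum(n * ctr), centroid = ctr)
}

orient_toward_camera <- function(plane) {
  # camera sits at the origin; signed distance of the origin must be positive
  if (-plane$d < 0) {
    plane$normal <- -plane$normal
    plane$d <- -plane$d
  }
  plane
}

#' Fit the ground plane with RANSAC
#'
#' Fits a plane `n . p = d` (unit normal, oriented toward the camera)
#' through a point cloud, robust to points that do not belong to the ground
#' (young plants, gutter edges, depth artefacts). Intended use: fit once per
#' batch on the non-lettuce pixels of the planting-day frame, then reuse for
#' all later height measurements -- this compensates slight skewness in
#' camera mounting and assumes the camera does not move after planting.
#'
#' Classic RANSAC: random minimal samples of 3 points propose planes, the
#' plane with most points within `threshold` mm wins, and is refined by a
#' total-least-squares fit on its inlier set.
#'
#' @param points a `point_cloud` from [backproject()], or an n x 3 matrix of
#'   mm coordinates.
#' @param iterations number of random samples (default 1000).
#' @param threshold inlier distance threshold in mm (default 5).
#' @param seed integer seed making the fit deterministic; `NULL` uses (and
#'   advances) the session RNG.
#' @param max_candidates at most this many points are used while scoring
#'   candidate planes (a uniform subsample); the final refinement always
#'   uses every inlier of the full cloud.
#' @return A `ground_plane`: list with `normal` (unit, toward camera), `d`
#'   (mm), `inliers` (count in the full cloud), `residual_mm` (RMS distance
#'   of inliers) and the fit parameters.
#' @export
fit_ground_plane <- function(points, iterations = 1000, threshold = 5,
                             seed = NULL, max_candidates = 4000) {
  xyz <- if (inherits(points, "point_cloud")) points$xyz else points
  stopifnot(is.matrix(xyz), ncol(xyz) == 3)
  if (nrow(xyz) < 3)
    stop("ground-plane fit needs at least 3 points")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }

  n_pts <- nrow(xyz)
  score_idx <- if (n_pts > max_candidates) sample.int(n_pts, max_candidates) else seq_len(n_pts)
  sxyz <- xyz[score_idx, , drop = FALSE]

  best <- NULL
  best_count <- -1L
  for (i in seq_len(iterations)) {
    tri <- xyz[sample.int(n_pts, 3L), , drop = FALSE]
    e1 <- tri[2L, ] - tri[1L, ]
    e2 <- tri[3L, ] - tri[1L, ]
    nrm <- c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
             e1[3L] * e2[1L] - e1[1L] * e2[3L],
             e1[1L] * e2[2L] - e1[2L] * e2[1L])
    len <- sqrt(sum(nrm^2))
    if (len < 1e-9) next  # collinear sample
    nrm <- nrm / len
    d <- sum(nrm * tri[1L, ])
    cnt <- sum(abs(sxyz %*% nrm - d) < threshold)
    if (cnt > best_count) {
      best_count <- cnt
      best <- list(normal = nrm, d = d)
    }
  }
  if (is.null(best))
    stop("ground-plane fit failed: all minimal samples were degenerate")

  # refine on the inliers of the full cloud
  resid <- abs(xyz %*% best$normal - best$d)
  inl <- resid < threshold
  refined <- plane_lsq(xyz[inl, , drop = FALSE])
  if (is.null(refined))
    stop("ground-plane fit failed: inlier support is degenerate (collinear)")
  refined <- orient_toward_camera(refined)
  resid <- xyz %*% refined$normal - refined$d
  inl <- abs(resid) < threshold
  structure(list(normal = as.numeric(refined$normal), d = as.numeric(refined$d),
                 inliers = sum(inl),
                 residual_mm = sqrt(mean(resid[inl]^2)),
                 iterations = iterations, threshold = threshold, seed = seed),
            class = "ground_plane")
}

#' @export
print.ground_plane <- function(x, ...) {
  cat(sprintf("ground_plane  n = (%.5f, %.5f, %.5f)  d = %.2f mm  inliers = %d  rms = %.3f mm\n",
              x$normal[1], x$normal[2], x$normal[3], x$d, x$inliers, x$residual_mm))
  invisible(x)
}

#' Angle between a fitted plane normal and a reference normal
#'
#' @param plane a `ground_plane`.
#' @param reference unit reference normal (sign-insensitive).
#' @return Angle in degrees.
#' @export
plane_normal_error <- function(plane, reference) {
  reference <- reference / sqrt(sum(reference^2))
  acos(min(1, abs(sum(plane$normal * reference)))) * 180 / pi
}

#' Per-pixel canopy heights above the ground plane
#'
#' Canopy height of each lettuce pixel is the distance between its
#' back-projected point and the batch's planting-day ground plane, reported
#' in centimetres. The default is the point-to-plane distance (positive
#' toward the camera); `method = "vertical"` instead takes the difference
#' along the camera z-axis between the plane and the point. Heights that
#' come out negative (sensor noise below the plane) are clipped to 0 so
#' noise cannot bias volume sums downward.
#'
#' @param points a `point_cloud` from [backproject()] (pixel indices are
#'   needed to place heights in the raster).
#' @param plane a `ground_plane` fitted on the same batch's planting-day
#'   frame.
#' @param mask a logical lettuce mask (same raster size); only lettuce
#'   pixels get a height, all others are `NA`.
#' @param method `"point_to_plane"` (default) or `"vertical"`.
#' @return A `height_map`: numeric matrix of heights in cm (`NA` outside
#'   the mask) with the method stored as an attribute.
#' @export
height_map <- function(points, plane, mask, method = c("point_to_plane", "vertical")) {
  method <- match.arg(method)
  stopifnot(inherits(points, "point_cloud"), inherits(plane, "ground_plane"))
  mask <- as_seg_mask(mask)
  if (!all(dim(mask) == points$dim))
    stop("mask size does not match the depth raster")
  xyz <- points$xyz
  h_mm <- if (method == "point_to_plane") {
    as.numeric(xyz %*% plane$normal - plane$d)
  } else {
    n <- plane$normal
    if (abs(n[3]) < 1e-9) stop("vertical heights are undefined for a plane parallel to z")
    z_plane <- (plane$d - xyz[, 1] * n[1] - xyz[, 2] * n[2]) / n[3]
    z_plane - xyz[, 3]
  }
  hm <- matrix(NA_real_, points$dim[1], points$dim[2])
  keep <- mask[cbind(points$row, points$col)]
  hm[cbind(points$row[keep], points$col[keep])] <- pmax(h_mm[keep], 0) / 10
  structure(hm, class = c("height_map", "matrix"), method = method)
}

#' Canopy volume per plant
#'
#' The canopy volume is the sum over lettuce pixels of height times pixel
#' ground area; dividing by the number of heads in the imaged area (density
#' times imaged ground area) corrects for the plant density in force and
#' yields cm^3 per plant, comparable across spacing stages. Overlapping
#' leaves are counted once (the mask is flat), so volume under-reads true
#' biomass at high density.
#'
#' @param hm a [height_map()] (cm; `NA` outside lettuce).
#' @param gsd ground sampling distance, mm per pixel at the canopy.
#' @param density plant density in force, heads/m^2 (> 0).
#' @param ground_area imaged ground area in m^2; defaults to
#'   `nrow * ncol * (gsd/1000)^2`.
#' @return Volume in cm^3 per plant.
#' @export
volume_per_plant <- function(hm, gsd, density, ground_area = NULL) {
  stopifnot(inherits(hm, "height_map") || is.matrix(hm), gsd > 0)
  if (density <= 0) stop("plant density must be positive")
  if (is.null(ground_area))
    ground_area <- nrow(hm) * ncol(hm) * (gsd / 1000)^2
  heads <- density * ground_area
  h <- hm[!is.na(hm)]
  if (length(h) == 0) return(0)
  sum(h) * (gsd / 10)^2 / heads  # cm * cm^2 per pixel
}

#' Maximum (or upper-quantile) canopy height
#'
#' @param hm a [height_map()].
#' @param prob quantile of the lettuce-pixel heights to report; 1 (default)
#'   is the maximum. Lower values (e.g. 0.99) are robust to single-pixel
#'   depth spikes.
#' @return Height in cm, or `NA` with a warning when no lettuce pixel has a
#'   height.
#' @export
max_height <- function(hm, prob = 1) {
  stopifnot(prob > 0, prob <= 1)
  h <- hm[!is.na(hm)]
  if (length(h) == 0) {
    warning("no lettuce pixels: maximum height is undefined")
    return(NA_real_)
  }
  if (prob == 1) max(h) else unname(quantile(h, prob, type = 1))
}
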