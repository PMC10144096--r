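#' @title 3D localization from a bounding box and depth
#'
#' @description
#' Geometry used to place a detected animal in the world frame from an
#' aerial stereo camera: the detector's 2D bounding box is contracted by a
#' scaling factor, valid depth readings inside the contracted region of
#' interest are averaged to a single range, the box center is
#' back-projected through the camera intrinsics, and the camera-frame point
#' is carried to the world frame through the fixed camera-to-body transform
#' and the observer (platform) pose.
#'
#' Pixel convention: origin at the image top-left, `u` increases rightward,
#' `v` downward, units are pixels; `(cx, cy)` is the box center.
#'
#' @name geometry3d
NULL

stop_lstmkf <- function(msg, class) {
  stop(structure(class = c(class, "lstmkf_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Construct a 2D bounding box
#'
#' @param cx,cy Pixel coordinates of the box center.
#' @param w,h Box width and height in pixels; must be positive.
#' @return An object of class `bbox2d`.
#' @export
#' @examples
#' bbox2d(100, 50, 40, 20)
bbox2d <- function(cx, cy, w, h) {
  if (!all(is.finite(c(cx, cy, w, h))))
    stop_lstmkf("bounding box fields must be finite", "lstmkf_invalid_parameter")
  if (w <= 0 || h <= 0)
    stop_lstmkf("bounding box width and height must be positive",
                "lstmkf_invalid_parameter")
  structure(list(cx = cx, cy = cy, w = w, h = h), class = "bbox2d")
}

#' Contract a bounding box about its center
#'
#' The detector's box usually includes background pixels whose depth does
#' not belong to the animal; averaging depth over a centrally contracted
#' region of interest suppresses them. The center is unchanged and both
#' sides are scaled by `theta`.
#'
#' @param box A [bbox2d()].
#' @param theta Scaling factor in (0, 1].
#' @return A `bbox2d` with an added `theta` field (class `scaled_roi`).
#' @export
#' @examples
#' shrink_roi(bbox2d(100, 50, 40, 20), 0.5)
shrink_roi <- function(box, theta) {
  stopifnot(inherits(box, "bbox2d"))
  if (!is.finite(theta) || theta <= 0 || theta > 1)
    stop_lstmkf("theta must lie in (0, 1]", "lstmkf_invalid_parameter")
  structure(list(cx = box$cx, cy = box$cy, w = theta * box$w,
                 h = theta * box$h, theta = theta),
            class = c("scaled_roi", "bbox2d"))
}

#' Construct a depth patch
#'
#' A rectangular crop of the depth image. `origin` gives the image pixel
#' column/row of the patch's top-left pixel so the patch can be indexed in
#' image coordinates; pixel `(i, j)` of the patch has its center at image
#' coordinates `(origin[1] + j - 0.5, origin[2] + i - 0.5)`.
#'
#' @param values Numeric matrix of depth readings in meters (rows = image
#'   rows / v, columns = image columns / u).
#' @param valid Logical matrix of the same shape; `FALSE` marks unfilled
#'   stereo pixels. Defaults to finiteness and positivity of `values`.
#' @param origin Length-2 numeric, image (x, y) of the patch top-left corner.
#' @return An object of class `depth_patch`.
#' @export
depth_patch <- function(values, valid = NULL, origin = c(0, 0)) {
  values <- as.matrix(values)
  if (is.null(valid)) valid <- is.finite(values) & values > 0
  valid <- as.matrix(valid)
  if (!identical(dim(values), dim(valid)))
    stop_lstmkf("values and valid mask must have the same shape",
                "lstmkf_invalid_parameter")
  if (any(valid & (!is.finite(values) | values <= 0)))
    stop_lstmkf("valid depths must be finite and positive",
                "lstmkf_invalid_parameter")
  structure(list(values = values, valid = valid, origin = as.numeric(origin)),
            class = "depth_patch")
}

#' Average the valid depth readings of a patch
#'
#' @param patch A [depth_patch()].
#' @return Mean depth in meters over pixels whose mask is `TRUE`.
#' @export
#' @examples
#' mean_valid_depth(depth_patch(matrix(c(2, 4, 9, 6), 2, 2),
#'                              matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)))
mean_valid_depth <- function(patch) {
  stopifnot(inherits(patch, "depth_patch"))
  if (!any(patch$valid))
    stop_lstmkf("no valid depth pixels in patch", "lstmkf_no_depth")
  mean(patch$values[patch$valid])
}

#' Camera intrinsics
#'
#' @param K 3x3 intrinsic matrix (focal lengths and principal point in
#'   pixels); must be invertible with `K[3,3] == 1`.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(K) {
  K <- as.matrix(K)
  if (!identical(dim(K), c(3L, 3L)) || abs(K[3, 3] - 1) > 1e-12)
    stop_lstmkf("K must be 3x3 with K[3,3] = 1", "lstmkf_invalid_parameter")
  if (abs(det(K)) < 1e-12)
    stop_lstmkf("K must be invertible", "lstmkf_linalg_error")
  structure(list(K = K), class = "camera_intrinsics")
}

#' Back-project a pixel with known depth to a camera-frame point
#'
#' Inverts the pinhole projection `s [u, v, 1]' = K X_C`: with the range
#' `s` known from the depth sensor, the 3D camera-frame point is
#' `X_C = K^{-1} (s [u, v, 1]')`.
#'
#' @param u,v Pixel coordinates.
#' @param s Depth in meters; must be positive.
#' @param K A [camera_intrinsics()] or plain 3x3 matrix.
#' @return Numeric length-3 camera-frame point.
#' @export
#' @examples
#' backproject(4, 2, 3, camera_intrinsics(diag(c(2, 2, 1))))
backproject <- function(u, v, s, K) {
  if (inherits(K, "camera_intrinsics")) K <- K$K
  if (!is.finite(s) || s <= 0)
    stop_lstmkf("depth must be positive and finite", "lstmkf_invalid_parameter")
  if (abs(det(K)) < 1e-12)
    stop_lstmkf("singular intrinsic matrix", "lstmkf_linalg_error")
  as.numeric(solve(K, s * c(u, v, 1)))
}

#' Convert a unit quaternion (w, x, y, z) to a rotation matrix
#'
#' The quaternion is normalized on ingest.
#'
#' @param q Numeric length-4, scalar-first.
#' @return 3x3 rotation matrix.
#' @export
quat_to_rotmat <- function(q) {
  if (length(q) != 4 || !all(is.finite(q)) || sum(q^2) < 1e-12)
    stop_lstmkf("quaternion must be finite, length 4, non-zero",
                "lstmkf_invalid_parameter")
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Observer (platform) pose in the world frame
#'
#' @param R 3x3 rotation matrix (world-from-body), or `NULL` if `q` given.
#' @param o Numeric length-3 observer position in meters, world frame.
#' @param q Optional unit quaternion (w, x, y, z) used instead of `R`.
#' @param tol Orthonormality tolerance for a supplied rotation matrix.
#' @return An object of class `observer_pose`.
#' @export
observer_pose <- function(R = NULL, o = c(0, 0, 0), q = NULL, tol = 1e-8) {
  if (is.null(R)) {
    if (is.null(q)) R <- diag(3) else R <- quat_to_rotmat(q)
  }
  R <- as.matrix(R)
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop_lstmkf("R is not a proper rotation (orthonormal, det +1)",
                "lstmkf_invalid_pose")
  structure(list(R = R, o = as.numeric(o)), class = "observer_pose")
}

#' The fixed camera-to-body rigid transform
#'
#' Maps optical-frame coordinates (z forward, x right, y down) to the
#' body frame (x forward, y left, z up).
#'
#' @return A 4x4 homogeneous matrix of class `rigid_transform`.
#' @export
camera_to_body <- function() {
  M <- matrix(c(0, 0, 1, 0,
                -1, 0, 0, 0,
                0, -1, 0, 0,
                0, 0, 0, 1), 4, 4, byrow = TRUE)
  structure(M, class = "rigid_transform")
}

#' Body-to-world rigid transform from an observer pose
#'
#' @param pose An [observer_pose()].
#' @return A 4x4 homogeneous matrix of class `rigid_transform`: rotation
#'   block is `pose$R`, last column the observer position.
#' @export
body_to_world <- function(pose) {
  stopifnot(inherits(pose, "observer_pose"))
  M <- diag(4)
  M[1:3, 1:3] <- pose$R
  M[1:3, 4] <- pose$o
  structure(M, class = "rigid_transform")
}

#' Apply a rigid transform to a 3D point
#'
#' @param M A 4x4 `rigid_transform` (or plain matrix).
#' @param x Numeric length-3 point.
#' @return Transformed length-3 point.
#' @export
apply_rigid <- function(M, x) {
  y <- unclass(M) %*% c(x, 1)
  as.numeric(y[1:3])
}

#' Invert a rigid transform
#' @param M A 4x4 `rigid_transform`.
#' @return The inverse transform.
#' @export
invert_rigid <- function(M) {
  R <- unclass(M)[1:3, 1:3]; t0 <- unclass(M)[1:3, 4]
  Mi <- diag(4)
  Mi[1:3, 1:3] <- t(R)
  Mi[1:3, 4] <- -t(R) %*% t0
  structure(Mi, class = "rigid_transform")
}

# integer pixel (row, col) indices of the patch whose centers fall inside
# the contracted box (half-open rectangle), in the patch's own indexing
roi_pixel_mask <- function(patch, roi) {
  nr <- nrow(patch$values); nc <- ncol(patch$values)
  ucent <- patch$origin[1] + (seq_len(nc) - 0.5)
  vcent <- patch$origin[2] + (seq_len(nr) - 0.5)
  uin <- ucent >= roi$cx - roi$w / 2 & ucent < roi$cx + roi$w / 2
  vin <- vcent >= roi$cy - roi$h / 2 & vcent < roi$cy + roi$h / 2
  outer(vin, uin)
}

#' Localize a detection in the world frame
#'
#' Full chain: contract the box by `theta`, average valid depth readings
#' whose pixel centers fall inside the contracted region, back-project the
#' box center at that depth, then map camera -> body -> world.
#'
#' @param box A [bbox2d()].
#' @param patch A [depth_patch()] covering (at least) the box.
#' @param K A [camera_intrinsics()].
#' @param pose An [observer_pose()].
#' @param theta ROI contraction factor in (0, 1]; default 0.5.
#' @return Numeric length-3 world-frame position in meters.
#' @export
localize <- function(box, patch, K, pose, theta = 0.5) {
  roi <- shrink_roi(box, theta)
  m <- roi_pixel_mask(patch, roi)
  sub <- depth_patch(patch$values, patch$valid & m, patch$origin)
  s <- mean_valid_depth(sub)
  xc <- backproject(box$cx, box$cy, s, K)
  apply_rigid(body_to_world(pose), apply_rigid(camera_to_body(), xc))
}
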