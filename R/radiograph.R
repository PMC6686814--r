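# Disc height index radiogrammetry from landmark coordinates placed on
# lateral radiographs. All distances are measured along the local spine
# axis (the line joining the two vertebral-body centroids), and the disc
# height index normalises disc height to the adjacent vertebral-body
# heights, so the result is invariant to radiographic magnification,
# rotation and translation.

# required landmark names for one disc level at one timepoint
LANDMARK_POINTS <- c(
  "cran_vb_ant_sup", "cran_vb_ant_inf", "cran_vb_post_sup", "cran_vb_post_inf",
  "caud_vb_ant_sup", "caud_vb_ant_inf", "caud_vb_post_sup", "caud_vb_post_inf",
  "disc_ant_sup", "disc_ant_inf", "disc_mid_sup", "disc_mid_inf",
  "disc_post_sup", "disc_post_inf")

landmark_xy <- function(landmarks, point) {
  i <- match(point, landmarks$point)
  if (anyNA(i)) stop("missing landmark point: ",
                     paste(point[is.na(i)], collapse = ", "), call. = FALSE)
  cbind(landmarks$x[i], landmarks$y[i])
}

# unit vector of the local spine axis (caudal centroid -> cranial centroid)
spine_axis <- function(landmarks) {
  cran <- colMeans(landmark_xy(landmarks, grep("^cran_vb", LANDMARK_POINTS,
                                               value = TRUE)))
  caud <- colMeans(landmark_xy(landmarks, grep("^caud_vb", LANDMARK_POINTS,
                                               value = TRUE)))
  v <- cran - caud
  n <- sqrt(sum(v^2))
  if (n == 0) stop("degenerate landmark set: coincident vertebral bodies",
                   call. = FALSE)
  v / n
}

axial_gap <- function(landmarks, sup, inf, axis) {
  d <- landmark_xy(landmarks, sup) - landmark_xy(landmarks, inf)
  abs(drop(d %*% axis))
}

#' Disc height from radiograph landmarks
#'
#' Mean of the anterior, middle and posterior disc-space distances measured
#' along the local spine axis.
#'
#' @param landmarks Data frame with columns `point`, `x`, `y` holding the
#'   named landmarks of one disc level at one timepoint (vertebral-body
#'   corners `cran_vb_*`/`caud_vb_*` and disc-margin pairs `disc_*`).
#' @return Disc height in image units.
#' @export
disc_height <- function(landmarks) {
  axis <- spine_axis(landmarks)
  gaps <- vapply(c("ant", "mid", "post"), function(pos) {
    axial_gap(landmarks, paste0("disc_", pos, "_sup"),
              paste0("disc_", pos, "_inf"), axis)
  }, numeric(1))
  mean(gaps)
}

vb_height <- function(landmarks, which = c("cran", "caud")) {
  which <- match.arg(which)
  axis <- spine_axis(landmarks)
  mean(vapply(c("ant", "post"), function(pos) {
    axial_gap(landmarks, paste0(which, "_vb_", pos, "_sup"),
              paste0(which, "_vb_", pos, "_inf"), axis)
  }, numeric(1)))
}

#' Disc height index (DHI)
#'
#' Disc height (mean of three axial disc-space distances) normalised to the
#' mean of the adjacent cranial and caudal vertebral-body heights:
#' `dhi = 2 * disc_height / (vb_cranial + vb_caudal)`. Dimensionless, and
#' invariant under similarity transforms (magnification, rotation,
#' translation) of the landmark set.
#'
#' @inheritParams disc_height
#' @return A list: `disc_height`, `vb_height_cranial`, `vb_height_caudal`
#'   (image units) and `dhi`.
#' @examples
#' lm <- synthetic_landmark_set(disc_height = 2, vb_height = 20)
#' dhi(lm)$dhi   # 2 * 2 / (20 + 20) = 0.1
#' @export
dhi <- function(landmarks) {
  dh <- disc_height(landmarks)
  h_cr <- vb_height(landmarks, "cran")
  h_cd <- vb_height(landmarks, "caud")
  if (h_cr <= 0 || h_cd <= 0) stop("zero vertebral height", call. = FALSE)
  list(disc_height = dh, vb_height_cranial = h_cr, vb_height_caudal = h_cd,
       dhi = 2 * dh / (h_cr + h_cd))
}

#' Percent of pre-lesion disc height index
#'
#' @param endpoint,pre Landmark sets (see [dhi()]) for the endpoint and the
#'   pre-surgery reference radiograph of the same disc.
#' @return `100 * dhi(endpoint) / dhi(pre)`.
#' @export
percent_dhi <- function(endpoint, pre) {
  100 * dhi(endpoint)$dhi / dhi(pre)$dhi
}

#' Canonical synthetic landmark set
#'
#' Builds the landmark table of an idealised lateral view of one disc:
#' rectangular vertebral bodies of height `vb_height` and width `vb_width`
#' stacked along the y axis with a disc space of height `disc_height`
#' (optionally three different anterior/middle/posterior gaps). Used by the
#' synthetic-study generator and as a fixture base in tests.
#'
#' @param disc_height Disc-space height, or a vector of three
#'   anterior/middle/posterior gaps (image units).
#' @param vb_height,vb_width Vertebral-body dimensions (image units).
#' @return Tibble with columns `point`, `x`, `y`.
#' @export
synthetic_landmark_set <- function(disc_height = 6, vb_height = 30,
                                   vb_width = 35) {
  gaps <- if (length(disc_height) == 3) disc_height else rep(disc_height, 3)
  half <- vb_width / 2
  g_mid <- gaps[2]
  pts <- rbind(
    cran_vb_ant_sup  = c(half,  g_mid / 2 + vb_height),
    cran_vb_ant_inf  = c(half,  g_mid / 2),
    cran_vb_post_sup = c(-half, g_mid / 2 + vb_height),
    cran_vb_post_inf = c(-half, g_mid / 2),
    caud_vb_ant_sup  = c(half,  -g_mid / 2),
    caud_vb_ant_inf  = c(half,  -g_mid / 2 - vb_height),
    caud_vb_post_sup = c(-half, -g_mid / 2),
    caud_vb_post_inf = c(-half, -g_mid / 2 - vb_height),
    disc_ant_sup  = c(half,  gaps[1] / 2),
    disc_ant_inf  = c(half,  -gaps[1] / 2),
    disc_mid_sup  = c(0,     gaps[2] / 2),
    disc_mid_inf  = c(0,     -gaps[2] / 2),
    disc_post_sup = c(-half, gaps[3] / 2),
    disc_post_inf = c(-half, -gaps[3] / 2))
  tibble::tibble(point = rownames(pts), x = pts[, 1], y = pts[, 2])
}

#' Apply a similarity transform to a landmark set
#'
#' Uniform scaling, rotation and translation -- the acquisition nuisances
#' (magnification, film orientation) that the disc height index must
#' cancel.
#'
#' @param landmarks Landmark table (`point`, `x`, `y`).
#' @param scale Uniform magnification factor (> 0).
#' @param angle_deg Rotation (degrees, counterclockwise).
#' @param shift Length-2 translation.
#' @return Transformed landmark table.
#' @export
transform_landmarks <- function(landmarks, scale = 1, angle_deg = 0,
                                shift = c(0, 0)) {
  stopifnot(scale > 0, length(shift) == 2)
  a <- angle_deg * pi / 180
  rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  xy <- scale * cbind(landmarks$x, landmarks$y) %*% t(rot)
  landmarks$x <- xy[, 1] + shift[1]
  landmarks$y <- xy[, 2] + shift[2]
  landmarks
}
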