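# Facial-geometry feature space: 30 interpretable physical/geometric
# measures computed from a 68-point landmark set plus a precomputed median
# skin-luminance scalar. Faces are canonicalized (rotated so the line
# between the two pupil proxies is horizontal) before measurement; all
# measures are distances or ratios of distances, so they are invariant to
# translation and rotation, and the ratio-type measures are additionally
# invariant to uniform scaling.
#
# The 30 measure names follow the facial-geometry conventions of the
# social-perception literature; the exact formulas are this package's
# documented definitions, centralized in one registry (see
# `geometry_feature_registry()`) so they can be revised without touching
# the rest of the pipeline. Pupils are approximated by the centroid of the
# six landmarks of each eye.

dist2 <- function(p, q) sqrt(sum((p - q)^2))

# Rotate points so the pupil-to-pupil line is horizontal (about the pupil
# midpoint); no scaling or reflection.
canonicalize_landmarks <- function(pts) {
  pl <- colMeans(pts[37:42, , drop = FALSE])
  pr <- colMeans(pts[43:48, , drop = FALSE])
  ang <- atan2(pr[2] - pl[2], pr[1] - pl[1])
  ctr <- (pl + pr) / 2
  rot <- matrix(c(cos(-ang), sin(-ang), -sin(-ang), cos(-ang)), 2, 2)
  sweep(pts, 2, ctr) %*% t(rot)
}

# Primitive measurements every registry formula is built from.
geometry_primitives <- function(pts) {
  pupil_l <- colMeans(pts[37:42, , drop = FALSE])
  pupil_r <- colMeans(pts[43:48, , drop = FALSE])
  upper_lip <- pts[52, ]
  brow_mid <- colMeans(pts[18:27, , drop = FALSE])
  list(
    pupil_l = pupil_l, pupil_r = pupil_r,
    pupil_mid = (pupil_l + pupil_r) / 2,
    upper_lip = upper_lip, brow_mid = brow_mid,
    chin = pts[9, ],
    eye_w_l = dist2(pts[37, ], pts[40, ]),
    eye_w_r = dist2(pts[43, ], pts[46, ]),
    eye_h_l = (dist2(pts[38, ], pts[42, ]) + dist2(pts[39, ], pts[41, ])) / 2,
    eye_h_r = (dist2(pts[44, ], pts[48, ]) + dist2(pts[45, ], pts[47, ])) / 2,
    nose_w = dist2(pts[32, ], pts[36, ]),
    nose_l = dist2(pts[28, ], pts[34, ]),
    lip_t = dist2(pts[52, ], pts[63, ]) + dist2(pts[58, ], pts[67, ]),
    face_w_cheek = dist2(pts[2, ], pts[16, ]),
    face_w_mouth = dist2(pts[5, ], pts[13, ]),
    face_l = dist2(brow_mid, pts[9, ]),
    chin_l = dist2(pts[58, ], pts[9, ]),
    cheek_chin_l = dist2(pts[2, ], pts[9, ]),
    cheek_chin_r = dist2(pts[16, ], pts[9, ]),
    cheek_mid_y = (pts[2, 2] + pts[16, 2]) / 2,
    pupil_lip_l = dist2(pupil_l, upper_lip),
    pupil_lip_r = dist2(pupil_r, upper_lip),
    pupil_dist = dist2(pupil_l, pupil_r),
    midface_l = dist2((pupil_l + pupil_r) / 2, upper_lip)
  )
}

#' The facial-geometry formula registry
#'
#' Returns the ordered, named list of the 30 facial-geometry measures and
#' the function computing each from the primitive landmark distances.
#' Distances are in pixels; ratio measures are unitless. The registry is
#' the single source of truth for the feature definitions:
#'
#' * `skin_luminance` — median skin luminance (consumed as an input scalar).
#' * `nose_width` — distance between outer nostril landmarks (32, 36);
#'   `nose_length` — nasion (28) to nose base (34).
#' * `lip_thickness` — upper (52-63) plus lower (58-67) lip depth.
#' * `face_length` — brow-line midpoint to chin (9).
#' * `eye_height_l/r` — mean lid-to-lid distance; `eye_width_l/r` — corner
#'   to corner.
#' * `face_width_cheek` — jaw points 2-16; `face_width_mouth` — jaw points
#'   5-13.
#' * `pupil_distance` — eye-centroid to eye-centroid;
#'   `pupil_upperlip_l/r` — pupil to upper-lip midpoint (52);
#'   `pupil_upperlip_asym` — absolute left/right difference.
#' * `chin_length` — lower-lip bottom (58) to chin; `cheek_chin_l/r` — jaw
#'   point 2/16 to chin.
#' * `face_shape` — face length / cheek width; `heartshapeness` — cheek
#'   width / mouth-level width; `nose_shape` — nose width / nose length;
#'   `lip_fullness` — lip thickness / face length; `eye_shape` — mean eye
#'   height / mean eye width; `eye_size` — mean of the two height x width
#'   box areas; `midface_length` — pupil midpoint to upper lip;
#'   `chin_size` — chin length / face length; `cheekbone_height` —
#'   (cheek-line to chin drop) / face length; `cheekbone_prominence` —
#'   (cheek width - mouth-level width) / face length; `face_roundness` —
#'   cheek width / face length; `fwhr` — facial width-to-height ratio,
#'   cheek width / midface length.
#'
#' @return Named list of functions, each taking the primitive-measure list.
#' @export
geometry_feature_registry <- function() {
  list(
    skin_luminance = function(g, lum) lum,
    nose_width = function(g, lum) g$nose_w,
    nose_length = function(g, lum) g$nose_l,
    lip_thickness = function(g, lum) g$lip_t,
    face_length = function(g, lum) g$face_l,
    eye_height_l = function(g, lum) g$eye_h_l,
    eye_height_r = function(g, lum) g$eye_h_r,
    eye_width_l = function(g, lum) g$eye_w_l,
    eye_width_r = function(g, lum) g$eye_w_r,
    face_width_cheek = function(g, lum) g$face_w_cheek,
    face_width_mouth = function(g, lum) g$face_w_mouth,
    pupil_distance = function(g, lum) g$pupil_dist,
    pupil_upperlip_l = function(g, lum) g$pupil_lip_l,
    pupil_upperlip_r = function(g, lum) g$pupil_lip_r,
    pupil_upperlip_asym = function(g, lum) abs(g$pupil_lip_l - g$pupil_lip_r),
    chin_length = function(g, lum) g$chin_l,
    cheek_chin_l = function(g, lum) g$cheek_chin_l,
    cheek_chin_r = function(g, lum) g$cheek_chin_r,
    face_shape = function(g, lum) g$face_l / g$face_w_cheek,
    heartshapeness = function(g, lum) g$face_w_cheek / g$face_w_mouth,
    nose_shape = function(g, lum) g$nose_w / g$nose_l,
    lip_fullness = function(g, lum) g$lip_t / g$face_l,
    eye_shape = function(g, lum) ((g$eye_h_l + g$eye_h_r) / 2) / ((g$eye_w_l + g$eye_w_r) / 2),
    eye_size = function(g, lum) (g$eye_h_l * g$eye_w_l + g$eye_h_r * g$eye_w_r) / 2,
    midface_length = function(g, lum) g$midface_l,
    chin_size = function(g, lum) g$chin_l / g$face_l,
    cheekbone_height = function(g, lum) (g$chin[2] - g$cheek_mid_y) / g$face_l,
    cheekbone_prominence = function(g, lum) (g$face_w_cheek - g$face_w_mouth) / g$face_l,
    face_roundness = function(g, lum) g$face_w_cheek / g$face_l,
    fwhr = function(g, lum) g$face_w_cheek / g$midface_l
  )
}

#' Names of the 30 facial-geometry features, in registry order
#' @return Character vector of length 30.
#' @export
geometry_feature_names <- function() names(geometry_feature_registry())

#' Compute the 30 facial-geometry features of one face
#'
#' A deterministic, pure function of the landmark set: canonicalizes the
#' pose (eye line horizontal), measures the primitive distances, and
#' evaluates every formula in [geometry_feature_registry()].
#'
#' @param landmarks A [landmark_set()]; `skin_luminance` must be present
#'   because the luminance feature is part of the standard 30-feature set.
#' @return Named numeric vector of length 30 with attribute `face_id`.
#' @export
compute_geometry_features <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  if (is.null(landmarks$skin_luminance)) {
    fj_stop("skin_luminance is required for the facial-geometry feature set ",
            "(face '", landmarks$face_id, "')")
  }
  pts <- canonicalize_landmarks(landmarks$points)
  g <- geometry_primitives(pts)
  for (nm in c("face_w_cheek", "face_w_mouth", "face_l", "nose_l",
               "midface_l", "eye_w_l", "eye_w_r")) {
    if (g[[nm]] <= 0) {
      fj_stop("degenerate geometry for face '", landmarks$face_id,
              "': measure '", nm, "' is zero")
    }
  }
  reg <- geometry_feature_registry()
  vals <- vapply(reg, function(f) f(g, landmarks$skin_luminance), numeric(1))
  attr(vals, "face_id") <- landmarks$face_id
  vals
}

#' Compute a facial-geometry feature table for many faces
#'
#' @param landmark_sets Non-empty list of [landmark_set()] objects with
#'   unique face ids.
#' @return A [feature_table()] named `"facial-geometry"` with 30 columns,
#'   rows in input order.
#' @export
batch_geometry_table <- function(landmark_sets) {
  if (!is.list(landmark_sets) || length(landmark_sets) == 0L) {
    fj_stop("landmark_sets must be a non-empty list")
  }
  ids <- vapply(landmark_sets, `[[`, character(1), "face_id")
  if (anyDuplicated(ids)) {
    fj_stop("duplicate face_id: ", ids[duplicated(ids)][1])
  }
  rows <- t(vapply(landmark_sets, compute_geometry_features,
                   numeric(length(geometry_feature_names()))))
  feature_table("facial-geometry", rows, ids, geometry_feature_names())
}
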