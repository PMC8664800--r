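# 68-point facial landmark sets (iBUG 300-W ordering, 1-based in R):
# jaw 1-17, right-of-image brow 23-27 / left 18-22, nose bridge 28-31,
# nostril line 32-36, left eye 37-42, right eye 43-48, outer mouth 49-60,
# inner mouth 61-68. "Left"/"right" are in image coordinates (viewer's
# left = smaller x); y increases downwards as in image pixels.

#' Construct a landmark set
#'
#' @param face_id Face identifier.
#' @param points A 68 x 2 numeric matrix of (x, y) pixel coordinates in
#'   iBUG 300-W order.
#' @param skin_luminance Optional scalar in `[0, 255]`: median luminance of
#'   the skin region, measured upstream from a segmentation mask.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(face_id, points, skin_luminance = NULL) {
  points <- as.matrix(points)
  if (!is.numeric(points) || !all(dim(points) == c(68L, 2L))) {
    fj_stop("points must be a 68 x 2 numeric matrix")
  }
  if (!all(is.finite(points))) fj_stop("landmark coordinates must be finite")
  if (!is.null(skin_luminance)) {
    stopifnot(is.numeric(skin_luminance), length(skin_luminance) == 1L)
    if (skin_luminance < 0 || skin_luminance > 255) {
      fj_stop("skin_luminance must lie in [0, 255]")
    }
  }
  pl <- colMeans(points[37:42, , drop = FALSE])
  pr <- colMeans(points[43:48, , drop = FALSE])
  if (sqrt(sum((pl - pr)^2)) <= 0) fj_stop("interocular distance must be > 0")
  colnames(points) <- c("x", "y")
  structure(list(face_id = as.character(face_id), points = points,
                 skin_luminance = skin_luminance),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> face '%s', 68 points%s\n", x$face_id,
              if (is.null(x$skin_luminance)) "" else
                sprintf(", skin luminance %.1f", x$skin_luminance)))
  invisible(x)
}

# Bilateral symmetry structure of the 68-point layout: (left, right) pairs
# and midline points.
landmark_symmetry <- function() {
  pairs <- rbind(
    cbind(1:8, 17:10),                       # jaw
    cbind(18:22, 27:23),                     # brows
    cbind(c(32L, 33L), c(36L, 35L)),         # nostril line
    cbind(37:42, c(46L, 45L, 44L, 43L, 48L, 47L)),  # eyes
    cbind(c(49L, 50L, 51L, 56L, 57L), c(55L, 54L, 53L, 60L, 59L)),  # outer mouth
    cbind(c(61L, 62L, 66L), c(65L, 64L, 68L))        # inner mouth
  )
  list(pairs = pairs,
       centers = c(9L, 28L, 29L, 30L, 31L, 34L, 52L, 58L, 63L, 67L))
}

# A symmetric 68-point template face centred on x = 0, roughly 170 px wide,
# eye line at y = 0, chin at y = 110.
face_template <- function() {
  u <- (seq_len(17) - 9) / 8
  jaw <- cbind(85 * sin(u * pi / 2), 30 + 80 * cos(u * pi / 2))
  arc <- c(0, 4, 6, 4, 0)
  brow_l <- cbind(seq(-55, -15, by = 10), -25 - arc)
  brow_r <- cbind(seq(15, 55, by = 10), -25 - rev(arc))
  bridge <- cbind(rep(0, 4), c(-15, 0, 15, 30))
  nostrils <- cbind(c(-12, -6, 0, 6, 12), c(40, 43, 45, 43, 40))
  eye_l <- cbind(c(-45, -38, -30, -23, -30, -38), c(0, -4, -4, 0, 4, 4))
  eye_r <- cbind(c(23, 30, 38, 45, 38, 30), c(0, -4, -4, 0, 4, 4))
  outer <- cbind(c(-25, -15, -7, 0, 7, 15, 25, 15, 7, 0, -7, -15),
                 c(75, 70, 68, 67, 68, 70, 75, 82, 85, 86, 85, 82))
  inner <- cbind(c(-20, -7, 0, 7, 20, 7, 0, -7),
                 c(75, 73, 72, 73, 75, 79, 80, 79))
  pts <- rbind(jaw, brow_l, brow_r, bridge, nostrils, eye_l, eye_r, outer, inner)
  colnames(pts) <- c("x", "y")
  pts
}

#' Generate synthetic landmark sets
#'
#' Builds faces from a bilaterally symmetric 68-point template plus seeded
#' per-face shape variation (overall size, aspect ratio, and symmetric
#' feature jitter applied in mirrored left/right pairs) and, optionally,
#' independent left/right asymmetry noise. A synthetic median
#' skin-luminance scalar accompanies each face. These are fixtures for the
#' geometry-feature extractor; no images are involved.
#'
#' @param n_faces Number of faces (>= 1).
#' @param asymmetry_sd SD (pixels) of independent per-landmark asymmetry
#'   noise; 0 yields exactly bilaterally symmetric faces.
#' @param seed Integer seed.
#' @param shape_sd SD (pixels) of the symmetric per-feature jitter.
#' @return A list of [landmark_set()] objects with ids `face_0001`, ...
#' @export
generate_landmarks <- function(n_faces, asymmetry_sd = 0.5, seed = 1L,
                               shape_sd = 2) {
  n_faces <- assert_count(n_faces, "n_faces")
  if (!is.numeric(asymmetry_sd) || asymmetry_sd < 0) {
    fj_stop("asymmetry_sd must be >= 0")
  }
  template <- face_template()
  sym <- landmark_symmetry()
  withr::with_seed(seed, {
    lapply(seq_len(n_faces), function(i) {
      pts <- template
      scale <- exp(stats::rnorm(1, 0, 0.08))
      width_factor <- exp(stats::rnorm(1, 0, 0.05))
      for (k in seq_len(nrow(sym$pairs))) {
        d <- stats::rnorm(2, 0, shape_sd)
        l <- sym$pairs[k, 1]; r <- sym$pairs[k, 2]
        pts[r, ] <- pts[r, ] + d
        pts[l, ] <- pts[l, ] + c(-d[1], d[2])
      }
      pts[sym$centers, 2] <- pts[sym$centers, 2] +
        stats::rnorm(length(sym$centers), 0, shape_sd)
      pts[, 1] <- pts[, 1] * scale * width_factor
      pts[, 2] <- pts[, 2] * scale
      if (asymmetry_sd > 0) {
        pts <- pts + matrix(stats::rnorm(68 * 2, 0, asymmetry_sd), 68, 2)
      }
      pts[, 1] <- pts[, 1] + 256
      pts[, 2] <- pts[, 2] + 180
      lum <- min(255, max(0, stats::rnorm(1, 128, 20)))
      landmark_set(sprintf("face_%04d", i), pts, skin_luminance = lum)
    })
  })
}

#' Read and write landmark sets as JSON
#'
#' JSON layout: an object mapping each `face_id` to
#' `{"points": [[x, y], ...68 pairs...], "skin_luminance": value}`.
#'
#' @param landmark_sets A list of [landmark_set()] objects.
#' @param path JSON file path.
#' @return The list of landmark sets (reader) or the path, invisibly
#'   (writer).
#' @export
write_landmarks_json <- function(landmark_sets, path) {
  obj <- lapply(landmark_sets, function(lm) {
    out <- list(points = unname(lm$points))
    if (!is.null(lm$skin_luminance)) out$skin_luminance <- lm$skin_luminance
    out
  })
  names(obj) <- vapply(landmark_sets, `[[`, character(1), "face_id")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(names(obj), function(id) {
    landmark_set(id, obj[[id]]$points,
                 skin_luminance = obj[[id]]$skin_luminance)
  })
}
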