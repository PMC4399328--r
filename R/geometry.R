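#' The canonical 16-speaker array
#'
#' Builds the spherical loudspeaker array used throughout the package: sixteen
#' speakers on an 80 cm sphere around the listener's head, with one speaker at
#' the zenith (elevation 90 degrees), four at elevation 45 (azimuth 0, +-90,
#' 180), eight on the horizontal ring (azimuth 0, +-45, +-90, +-135, 180) and
#' three at elevation -45 (azimuth 0, +-90). Azimuth is 0 straight ahead,
#' negative to the listener's left, and lies in (-180, 180].
#'
#' Rows are ordered by elevation then azimuth (both ascending) and assigned
#' stable `location_id`s 0..15, so ids mean the same thing in every module.
#'
#' @param radius_cm Sphere radius in centimetres (default 80).
#' @return A data frame of class `speaker_array` with columns `location_id`,
#'   `azimuth_deg`, `elevation_deg`, `radius_cm`.
#' @examples
#' arr <- build_speaker_array()
#' table(arr$elevation_deg)
#' @export
build_speaker_array <- function(radius_cm = 80) {
  stopifnot(radius_cm > 0)
  rows <- rbind(
    data.frame(azimuth_deg = c(-90, 0, 90), elevation_deg = -45),
    data.frame(azimuth_deg = c(-135, -90, -45, 0, 45, 90, 135, 180),
               elevation_deg = 0),
    data.frame(azimuth_deg = c(-90, 0, 90, 180), elevation_deg = 45),
    data.frame(azimuth_deg = 0, elevation_deg = 90)
  )
  rows <- rows[order(rows$elevation_deg, rows$azimuth_deg), , drop = FALSE]
  arr <- data.frame(location_id = seq_len(nrow(rows)) - 1L,
                    azimuth_deg = rows$azimuth_deg,
                    elevation_deg = rows$elevation_deg,
                    radius_cm = radius_cm)
  rownames(arr) <- NULL
  class(arr) <- c("speaker_array", "data.frame")
  arr
}

#' Convert spherical speaker coordinates to Cartesian
#'
#' Frame convention: x points to the front, y to the listener's right, z up.
#' Positive azimuth is to the right, so negative azimuth maps to negative y.
#'
#' @param azimuth_deg Azimuth in degrees, in (-180, 180].
#' @param elevation_deg Elevation in degrees, in \[-90, 90\].
#' @param radius_cm Radius in centimetres.
#' @return A matrix with columns `x_cm`, `y_cm`, `z_cm`.
#' @export
spherical_to_cartesian <- function(azimuth_deg, elevation_deg, radius_cm) {
  stopifnot(all(azimuth_deg > -180 & azimuth_deg <= 180),
            all(abs(elevation_deg) <= 90), all(radius_cm > 0))
  az <- azimuth_deg * pi / 180
  el <- elevation_deg * pi / 180
  cbind(x_cm = radius_cm * cos(el) * cos(az),
        y_cm = radius_cm * cos(el) * sin(az),
        z_cm = radius_cm * sin(el))
}

#' Convert Cartesian coordinates back to spherical
#'
#' Inverse of [spherical_to_cartesian()]. At the poles (x = y = 0) azimuth is
#' degenerate and reported as 0.
#'
#' @param x_cm,y_cm,z_cm Cartesian coordinates in centimetres.
#' @return A matrix with columns `azimuth_deg`, `elevation_deg`, `radius_cm`.
#' @export
cartesian_to_spherical <- function(x_cm, y_cm, z_cm) {
  r <- sqrt(x_cm^2 + y_cm^2 + z_cm^2)
  stopifnot(all(r > 0))
  el <- asin(pmin(pmax(z_cm / r, -1), 1)) * 180 / pi
  az <- atan2(y_cm, x_cm) * 180 / pi
  az[abs(x_cm) < 1e-12 & abs(y_cm) < 1e-12] <- 0
  az[az <= -180] <- az[az <= -180] + 360
  cbind(azimuth_deg = az, elevation_deg = el, radius_cm = r)
}

#' Radius of the horizontal hoop holding the speakers at a given elevation
#'
#' Speakers at a fixed elevation on a sphere of radius `sphere_radius_cm` sit
#' on a circular hoop of radius `sphere_radius_cm * cos(elevation)`; at 45
#' degrees on an 80 cm sphere this is 56.6 cm.
#'
#' @param elevation_deg Elevation in degrees, |elevation| <= 90.
#' @param sphere_radius_cm Sphere radius in centimetres.
#' @return Hoop radius in centimetres.
#' @export
hoop_radius <- function(elevation_deg, sphere_radius_cm) {
  stopifnot(all(abs(elevation_deg) <= 90), all(sphere_radius_cm > 0))
  sphere_radius_cm * cos(elevation_deg * pi / 180)
}

#' Class memberships for one binary discrimination condition
#'
#' Splits the sixteen locations into two decodable classes plus an excluded
#' set for one of the three discrimination conditions:
#' * `left_vs_right`: negative azimuth vs positive azimuth; the midline
#'   (azimuth 0 or 180) and the zenith speaker are excluded.
#' * `up_vs_down`: elevation > 0 vs elevation < 0; the horizontal ring is
#'   excluded. Whether the zenith speaker counts as "up" is controlled by
#'   `include_pole_in_up` (default TRUE: it is maximally up).
#' * `front_vs_back`: |azimuth| < 90 vs |azimuth| > 90; the +-90-degree cone
#'   and the zenith are excluded.
#'
#' The three labelings each partition all 16 ids; class sizes are (5, 5),
#' (5, 3) and (5, 4).
#'
#' @param array A `speaker_array` from [build_speaker_array()].
#' @param condition One of `"left_vs_right"`, `"up_vs_down"`,
#'   `"front_vs_back"`.
#' @param include_pole_in_up Logical; see above.
#' @return A list of class `condition_labeling` with elements `condition`,
#'   `class_a`, `class_b`, `excluded` (integer location_id vectors).
#' @export
condition_labels <- function(array, condition, include_pole_in_up = TRUE) {
  stopifnot(inherits(array, "speaker_array"))
  condition <- match.arg(condition,
                         c("left_vs_right", "up_vs_down", "front_vs_back"))
  az <- array$azimuth_deg
  el <- array$elevation_deg
  id <- array$location_id
  if (condition == "left_vs_right") {
    # azimuth 0 and 180 are on the median plane: neither left nor right
    a <- az < 0 & az > -180
    b <- az > 0 & az < 180
  } else if (condition == "up_vs_down") {
    a <- if (include_pole_in_up) el > 0 else el > 0 & el < 90
    b <- el < 0
  } else {
    a <- abs(az) < 90 & el < 90
    b <- abs(az) > 90
  }
  if (condition != "up_vs_down") {
    # zenith speaker: azimuth is degenerate there, never a lateral member
    a <- a & el < 90
    b <- b & el < 90
  }
  out <- list(condition = condition,
              class_a = sort(id[a]),
              class_b = sort(id[b]),
              excluded = sort(id[!a & !b]))
  stopifnot(length(intersect(out$class_a, out$class_b)) == 0,
            length(out$class_a) > 0, length(out$class_b) > 0)
  class(out) <- "condition_labeling"
  out
}

#' Behavioral response label (left / middle / right) for a speaker
#'
#' @param azimuth_deg,elevation_deg Speaker position in degrees (vectorized).
#' @return Character vector with values `"left"`, `"middle"`, `"right"`.
#' @export
behavioral_label <- function(azimuth_deg, elevation_deg) {
  out <- rep("middle", length(azimuth_deg))
  lateral <- elevation_deg < 90 & !(azimuth_deg %in% c(0, 180))
  out[lateral & azimuth_deg < 0] <- "left"
  out[lateral & azimuth_deg > 0] <- "right"
  out
}

#' @export
print.condition_labeling <- function(x, ...) {
  cat(sprintf("condition '%s': %d vs %d locations (%d excluded)\n",
              x$condition, length(x$class_a), length(x$class_b),
              length(x$excluded)))
  invisible(x)
}

#' Write / read a speaker array as a tab-separated table
#'
#' @param array A `speaker_array`.
#' @param path File path.
#' @return `read_speaker_array` returns a `speaker_array`.
#' @export
write_speaker_array <- function(array, path) {
  stopifnot(inherits(array, "speaker_array"))
  write_tsv_exact(as.data.frame(array), path)
  invisible(path)
}

#' @rdname write_speaker_array
#' @export
read_speaker_array <- function(path) {
  df <- read_tsv_exact(path)
  need <- c("location_id", "azimuth_deg", "elevation_deg", "radius_cm")
  if (!all(need %in% names(df))) {
    stop_sl("speaker array table %s lacks columns: %s", path,
            paste(setdiff(need, names(df)), collapse = ", "))
  }
  df$location_id <- as.integer(df$location_id)
  class(df) <- c("speaker_array", "data.frame")
  df
}

#' Write a condition labeling as JSON
#'
#' @param labeling A `condition_labeling`.
#' @param path File path.
#' @export
write_condition_labels <- function(labeling, path) {
  stopifnot(inherits(labeling, "condition_labeling"))
  jsonlite::write_json(unclass(labeling), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_condition_labels
#' @export
read_condition_labels <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$class_a <- as.integer(x$class_a)
  x$class_b <- as.integer(x$class_b)
  x$excluded <- as.integer(x$excluded)
  class(x) <- "condition_labeling"
  x
}

sl_conditions <- function() c("left_vs_right", "up_vs_down", "front_vs_back")
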