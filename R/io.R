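# File formats: frame-series CSV, trial-schedule CSV, camera and
# face-metrics YAML configs, JSON summaries.  CSV uses a header row,
# UTF-8, '.' decimal; timestamps are float seconds from session start.

FRAME_SERIES_COLS <- c("camera_id", "timestamp",
                       "left_eye_u", "left_eye_v", "right_eye_u",
                       "right_eye_v", "mouth_u", "mouth_v", "nose_u",
                       "nose_v", "pupil_left_u", "pupil_left_v",
                       "pupil_right_u", "pupil_right_v",
                       "iris_left_u", "iris_left_v", "iris_left_a",
                       "iris_left_b", "iris_left_theta",
                       "iris_right_u", "iris_right_v", "iris_right_a",
                       "iris_right_b", "iris_right_theta",
                       "eye_open_likelihood_left",
                       "eye_open_likelihood_right", "detection_confidence")

#' Read / write a per-frame detection series
#'
#' One row per (camera, frame); missing detections are empty fields.
#'
#' @param path CSV file.
#' @return data frame with the documented frame-series columns.
#' @export
read_frame_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(FRAME_SERIES_COLS, names(df))
  if (length(missing) > 0)
    stop("frame series ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  if (any(diff(df$timestamp) <= 0))
    stop("frame series ", path, ": timestamps must strictly increase")
  df
}

#' @rdname read_frame_series
#' @param obs frame-series data frame.
#' @export
write_frame_series <- function(obs, path) {
  utils::write.csv(obs[, FRAME_SERIES_COLS], path, row.names = FALSE)
  invisible(path)
}

#' Read / write a trial schedule (condition,start_s,duration_s CSV)
#' @param path CSV file.
#' @return a [trial_schedule()].
#' @export
read_trial_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "start_s", "duration_s")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("schedule ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  trial_schedule(df$condition, df$start_s, df$duration_s)
}

#' @rdname read_trial_schedule
#' @param schedule a [trial_schedule()].
#' @export
write_trial_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' Read / write camera configurations (YAML)
#'
#' The file maps camera ids to `fx`, `fy`, `cx`, `cy`, `rotation`
#' (row-major 9 floats, world-to-camera) and `translation` (3 floats, cm).
#'
#' @param path YAML file.
#' @return named list of [camera_model()]s.
#' @export
read_camera_config <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(stats::setNames(names(y), names(y)), function(id) {
    c_ <- y[[id]]
    camera_model(id, c_$fx, c_$fy, c_$cx, c_$cy,
                 matrix(as.numeric(c_$rotation), 3, 3, byrow = TRUE),
                 as.numeric(c_$translation))
  })
}

#' @rdname read_camera_config
#' @param cameras named list of [camera_model()]s.
#' @export
write_camera_config <- function(cameras, path) {
  y <- lapply(cameras, function(cm)
    list(fx = cm$fx, fy = cm$fy, cx = cm$cx, cy = cm$cy,
         rotation = as.numeric(t(cm$rotation)),
         translation = cm$translation))
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' Read / write per-person face metrics and eye-model parameters (YAML)
#'
#' @param path YAML file.
#' @return list with `metrics` (a [face_metrics()]) and `eye_params`
#'   (an [eye_model_params()]; defaults used for absent fields).
#' @export
read_face_metrics <- function(path) {
  y <- yaml::read_yaml(path)
  metrics <- face_metrics(y$person_id, y$head_width,
                          lapply(y$landmarks, as.numeric))
  defaults <- eye_model_params()
  eye_params <- eye_model_params(
    eyeball_radius = y$eyeball_radius %||% defaults$eyeball_radius,
    iris_radius = y$iris_radius %||% defaults$iris_radius,
    eye_center_offsets = if (is.null(y$eye_center_offsets))
      defaults$eye_center_offsets
    else lapply(y$eye_center_offsets, as.numeric))
  list(metrics = metrics, eye_params = eye_params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_face_metrics
#' @param metrics a [face_metrics()].
#' @param eye_params an [eye_model_params()] (optional).
#' @export
write_face_metrics <- function(metrics, path, eye_params = NULL) {
  y <- list(person_id = metrics$person_id, head_width = metrics$head_width,
            landmarks = lapply(metrics$landmark_offsets, as.numeric))
  if (!is.null(eye_params)) {
    y$eyeball_radius <- eye_params$eyeball_radius
    y$iris_radius <- eye_params$iris_radius
    y$eye_center_offsets <- lapply(eye_params$eye_center_offsets, as.numeric)
  }
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' Write an analysis summary as JSON
#' @param x named list of results.
#' @param path output file.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
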