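# File dialects: comma-separated, header row, UTF-8, units encoded in the
# column names (_mm, _s, _rad). Angles are stored in radians; human-facing
# summaries print degrees.

.traj_cols <- c("frame", "time_s", "fish_id", "x_mm", "y_mm", "heading_rad")

.check_header <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("malformed ", what, " file: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Read and write trajectory files
#'
#' Trajectory CSV dialect: columns `frame`, `time_s`, `fish_id`, `x_mm`,
#' `y_mm`, `heading_rad`.
#'
#' @param traj trajectory data frame.
#' @param path file path.
#' @return `read_trajectory()` returns the validated data frame;
#'   `write_trajectory()` returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  .check_header(traj, .traj_cols, "trajectory")
  utils::write.csv(traj[, .traj_cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  .check_header(utils::read.csv(path), .traj_cols, "trajectory")
}

#' Read and write kick tables
#'
#' Kick CSV dialect: `fish_id`, `t_start`, `tau`, `length`, `v_peak`,
#' `r_w`, `theta_w`, `dphi`, plus `d`, `psi`, `delta_phi` for pairs.
#'
#' @param kicks kick table data frame.
#' @param path file path.
#' @return `read_kicks()` returns the validated data frame;
#'   `write_kicks()` returns `path` invisibly.
#' @export
write_kicks <- function(kicks, path) {
  .check_header(kicks, c("fish_id", "t_start", "tau", "length"), "kick")
  utils::write.csv(kicks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kicks
#' @export
read_kicks <- function(path) {
  .check_header(utils::read.csv(path), c("fish_id", "t_start", "tau", "length"),
                "kick")
}

#' Read tracker output
#'
#' Tracker CSV dialect: `frame`, `id`, `x_px`, `y_px` (positions in pixels).
#'
#' @param path file path.
#' @return data frame with the four tracker columns.
#' @export
read_tracker <- function(path) {
  .check_header(utils::read.csv(path), c("frame", "id", "x_px", "y_px"),
                "tracker")
}

#' Write a reconstruction fit as JSON
#'
#' @param fit an [fs_fit()] object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fs_fit"))
  jsonlite::write_json(
    list(params = as.list(fit$params), residual_norm = fit$residual_norm,
         converged = fit$converged, method = fit$method, n = fit$n),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @return `read_fit_json()`: the fit as an [fs_fit()] object.
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fs_fit(unlist(x$params), residual_norm = x$residual_norm,
         converged = x$converged, method = x$method, n = x$n)
}
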