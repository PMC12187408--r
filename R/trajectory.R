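#' Trajectory container
#'
#' A uniformly sampled time series from one of the simulators: a data frame
#' whose first column is `time` (min) followed by concentration channels
#' (cu) and, where applicable, promoter-state channels (0/1). Metadata
#' (model tier, parameters, seed) is kept in the `meta` attribute.
#'
#' @param times numeric vector, strictly increasing uniform grid, min.
#' @param channels named list of numeric vectors, same length as `times`.
#' @param meta named list of metadata (tier, seed, params, ...).
#' @return An object of class `burst_trajectory` (also a data frame).
#' @export
new_trajectory <- function(times, channels, meta = list()) {
  stopifnot(is.numeric(times), length(times) >= 2L,
            is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)))
  dtv <- diff(times)
  if (any(dtv <= 0) || (max(dtv) - min(dtv)) > 1e-8 * dtv[1])
    stop("`times` must be a strictly increasing uniform grid", call. = FALSE)
  for (ch in channels) stopifnot(length(ch) == length(times))
  df <- data.frame(time = times, channels, check.names = FALSE)
  attr(df, "meta") <- meta
  class(df) <- c("burst_trajectory", "data.frame")
  df
}

#' @export
print.burst_trajectory <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<burst_trajectory> tier = %s, %d points, t in [%g, %g] min\n",
              if (is.null(meta$tier)) "?" else meta$tier,
              nrow(x), x$time[1], x$time[nrow(x)]))
  cat("channels:", paste(setdiff(names(x), "time"), collapse = ", "), "\n")
  invisible(x)
}

#' Trajectory metadata
#' @param traj a `burst_trajectory`.
#' @return the metadata list.
#' @export
trajectory_meta <- function(traj) attr(traj, "meta")

#' Grid step of a trajectory
#' @param traj a `burst_trajectory`.
#' @return the (uniform) sampling interval in minutes.
#' @export
trajectory_dt <- function(traj) traj$time[2] - traj$time[1]
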