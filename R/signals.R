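#' Subtract the freestream baseline from root signals
#'
#' Removes the moments induced by the freestream alone so that the
#' remaining signal reflects only the wake disturbance. Both inputs must
#' share the whisker set and time grid.
#'
#' @param signal,baseline [signal_time_series()] results.
#' @return A `root_signals` object.
#' @export
subtract_baseline <- function(signal, baseline) {
  stopifnot(inherits(signal, "root_signals"), inherits(baseline, "root_signals"))
  if (!identical(signal$ids, baseline$ids)) stop("whisker sets differ")
  if (length(signal$times) != length(baseline$times) ||
      any(abs(signal$times - baseline$times) > 1e-12))
    stop("time grids differ")
  structure(list(times = signal$times, ids = signal$ids,
                 Mx = signal$Mx - baseline$Mx,
                 My = signal$My - baseline$My),
            class = "root_signals")
}

#' DC/AC decomposition of root signals
#'
#' Splits each whisker's moment history over a window into its time mean
#' (DC, the slowly-adapting channel) and the zero-mean remainder (AC, the
#' rapidly-adapting channel). By construction `DC + AC(t)` reconstructs the
#' windowed input exactly and the AC mean vanishes to machine precision.
#'
#' @param signals a `root_signals` object.
#' @param window integer index range into `signals$times` (default: all).
#' @return A list of class `channel_vectors`: `times` (window times),
#'   `ids`, vectors `DC_x`, `DC_y` (per whisker) and matrices `AC_x`,
#'   `AC_y` (`length(window) x n_whiskers`).
#' @export
decompose_dc_ac <- function(signals, window = seq_along(signals$times)) {
  stopifnot(inherits(signals, "root_signals"))
  if (!length(window)) stop("empty window")
  Mx <- signals$Mx[window, , drop = FALSE]
  My <- signals$My[window, , drop = FALSE]
  dc_x <- colMeans(Mx); dc_y <- colMeans(My)
  structure(list(times = signals$times[window], ids = signals$ids,
                 DC_x = dc_x, DC_y = dc_y,
                 AC_x = sweep(Mx, 2, dc_x),
                 AC_y = sweep(My, 2, dc_y)),
            class = "channel_vectors")
}

#' Assemble the four-channel sensing video
#'
#' Maps each whisker's channel vector onto its grid pixel to build the
#' `T' x 9 x 22 x 4` network input, channels ordered (DC_x, AC_x, DC_y,
#' AC_y). The AC channels are resampled from the window time base to `t_frames`
#' frames by linear interpolation; DC channels are constant per video and
#' replicated across frames. Unmapped (null) pixels are exactly zero in all
#' channels and frames.
#'
#' @param channels a [decompose_dc_ac()] result.
#' @param grid_map a [map_to_grid()] result.
#' @param t_frames number of output frames.
#' @return An object of class `signal_video`: `video` array
#'   `t_frames x rows x cols x 4`, `frame_times`, and the `grid_map`.
#' @export
assemble_video <- function(channels, grid_map, t_frames = 80) {
  stopifnot(inherits(channels, "channel_vectors"), inherits(grid_map, "grid_map"))
  asg <- grid_map$assignment
  missing_ids <- setdiff(asg$id, channels$ids)
  if (length(missing_ids))
    stop("whiskers missing a channel vector: ", paste(missing_ids, collapse = ", "))
  tw <- channels$times
  ft <- seq(min(tw), max(tw), length.out = t_frames)
  vid <- array(0, c(t_frames, grid_map$rows, grid_map$cols, 4))
  col_of <- match(asg$id, channels$ids)
  for (k in seq_len(nrow(asg))) {
    j <- col_of[k]
    r <- asg$row[k]; cc <- asg$col[k]
    vid[, r, cc, 1] <- channels$DC_x[j]
    vid[, r, cc, 2] <- stats::approx(tw, channels$AC_x[, j], xout = ft)$y
    vid[, r, cc, 3] <- channels$DC_y[j]
    vid[, r, cc, 4] <- stats::approx(tw, channels$AC_y[, j], xout = ft)$y
  }
  structure(list(video = vid, frame_times = ft, grid_map = grid_map),
            class = "signal_video")
}

#' @export
print.signal_video <- function(x, ...) {
  d <- dim(x$video)
  cat("Sensing video: ", paste(d, collapse = " x "),
      " (frames x rows x cols x channels)\n", sep = "")
  invisible(x)
}

#' Phase-average a periodic signal
#'
#' Folds time modulo the period into `bins` phase bins and averages within
#' each bin. The signal must span at least two periods.
#'
#' @param times sample times, s.
#' @param values signal samples.
#' @param period fold period, s.
#' @param bins number of phase bins.
#' @return Numeric vector of length `bins` (bin centres at phases
#'   `(seq_len(bins) - 0.5) / bins`).
#' @export
phase_average <- function(times, values, period, bins = 40) {
  if (period <= 0) stop("period must be > 0")
  if (diff(range(times)) < 2 * period)
    stop("signal must span at least 2 periods")
  phase <- (times %% period) / period
  # guard against samples sitting exactly on bin boundaries
  bin <- (floor(phase * bins + 1e-8) %% bins) + 1
  out <- rep(NA_real_, bins)
  agg <- tapply(values, bin, mean)
  out[as.integer(names(agg))] <- agg
  out
}

#' Quadrant-averaged phase signals
#'
#' Splits the array into the four muzzle regions (left/right side crossed
#' with above/below the side's median base elevation), phase-averages each
#' whisker's Mx' and My', and averages within regions. This is the regional
#' diagnostic used to relate signal strength to where the wake strikes the
#' array.
#'
#' @param signals a `root_signals` object.
#' @param array the originating [build_array()].
#' @param period shedding period, s.
#' @param bins phase bins.
#' @return A list of class `region_signals` with one element per region
#'   (`LT`, `LB`, `RT`, `RB`), each holding `Mx` and `My` phase profiles.
#' @export
region_average <- function(signals, array, period, bins = 40) {
  stopifnot(inherits(signals, "root_signals"), inherits(array, "whisker_array"))
  tab <- array$whiskers
  regions <- list()
  for (s in c("left", "right")) {
    side <- tab[tab$side == s, ]
    zmed <- stats::median(side$base_z)
    top_ids <- side$id[side$base_z > zmed]
    bot_ids <- side$id[side$base_z <= zmed]
    regions[[paste0(toupper(substr(s, 1, 1)), "T")]] <- top_ids
    regions[[paste0(toupper(substr(s, 1, 1)), "B")]] <- bot_ids
  }
  out <- lapply(regions, function(ids) {
    if (!length(ids)) stop("empty region")
    cols <- match(ids, signals$ids)
    pm <- function(M) {
      prof <- sapply(cols, function(j)
        phase_average(signals$times, M[, j], period, bins))
      rowMeans(prof)
    }
    list(Mx = pm(signals$Mx), My = pm(signals$My))
  })
  structure(out[c("LT", "LB", "RT", "RB")], class = "region_signals")
}

#' Read pixel series back out of a video
#'
#' Inverse of [assemble_video()] for a mapped whisker: returns the DC
#' values and AC series stored at its pixel.
#'
#' @param video a [assemble_video()] result.
#' @param whisker_id whisker to read.
#' @return List with `DC_x`, `AC_x`, `DC_y`, `AC_y`.
#' @export
read_pixel <- function(video, whisker_id) {
  asg <- video$grid_map$assignment
  k <- match(whisker_id, asg$id)
  if (is.na(k)) stop("whisker ", whisker_id, " is not mapped")
  list(DC_x = video$video[1, asg$row[k], asg$col[k], 1],
       AC_x = video$video[, asg$row[k], asg$col[k], 2],
       DC_y = video$video[1, asg$row[k], asg$col[k], 3],
       AC_y = video$video[, asg$row[k], asg$col[k], 4])
}
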