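#' Parametric plate grid
#'
#' Cartesian product of plate locations and orientations. The defaults are
#' the full study grid: X in -120..120 mm by 60, Y in 0..200 mm by 50,
#' alpha and beta in -45..45 degrees by 22.5, i.e. 5^4 = 625 cases.
#'
#' @param X,Y offsets in mm; @param alpha,beta tilts in degrees.
#' @return A data.frame of class `param_grid` with one row per case.
#' @export
param_grid <- function(X = seq(-120, 120, by = 60),
                       Y = seq(0, 200, by = 50),
                       alpha = seq(-45, 45, by = 22.5),
                       beta = seq(-45, 45, by = 22.5)) {
  g <- expand.grid(X = X, Y = Y, alpha = alpha, beta = beta,
                   KEEP.OUT.ATTRS = FALSE)
  g$case <- seq_len(nrow(g))
  class(g) <- c("param_grid", "data.frame")
  g
}

# spans used as the Range of the accuracy metric (full-grid spans)
.grid_spans <- c(X = 240, Y = 200, alpha = 90, beta = 90)

#' Simulate the sensing video for one plate case
#'
#' Runs the full forward pipeline for a single plate configuration:
#' synthetic wake, segment loads, root moments, freestream-baseline
#' subtraction, DC/AC decomposition over the analysis window and video
#' assembly. The analysis window starts after `washout_periods` shedding
#' periods (so only the developed wake is seen) and covers
#' `window_periods` periods sampled `samples_per_period` times per period;
#' steady-regime cases use the untilted-plate period as the reference
#' clock.
#'
#' @param plate a [plate_config()].
#' @param disc an [discretize_array()] result.
#' @param grid_map the array's [map_to_grid()].
#' @param flow,st,coeff flow, wake and coefficient models.
#' @param frames output video frames.
#' @param washout_periods,window_periods,samples_per_period time-window
#'   layout.
#' @param baseline optionally a precomputed freestream-only `root_signals`
#'   row (list with `Mx`, `My` single-row matrices) to avoid recomputation.
#' @return A [assemble_video()] result, with the case's shedding frequency
#'   and period attached as attributes `frequency` and `period`.
#' @export
simulate_case <- function(plate, disc, grid_map, flow = flow_config(),
                          st = strouhal_model(), coeff = default_coeff_table(),
                          frames = 80, washout_periods = 2,
                          window_periods = 3, samples_per_period = 32,
                          baseline = NULL) {
  f <- shedding_frequency(plate, flow, st)
  f_ref <- if (f > 0) f else
    shedding_frequency(plate_config(diameter = plate$diameter,
                                    standoff = plate$standoff), flow, st)
  period <- 1 / f_ref
  dt <- period / samples_per_period
  n_t <- (washout_periods + window_periods) * samples_per_period
  times <- seq(0, by = dt, length.out = n_t + 1)
  wake_fn <- function(pts, t) induced_velocity(evolve_wake(plate, flow, st, t), pts)
  sig <- signal_time_series(disc, wake_fn, flow, times, TRUE, coeff)
  if (is.null(baseline)) baseline <- freestream_baseline(disc, flow, coeff)
  base <- structure(list(times = times, ids = sig$ids,
                         Mx = matrix(baseline$Mx, length(times),
                                     length(sig$ids), byrow = TRUE),
                         My = matrix(baseline$My, length(times),
                                     length(sig$ids), byrow = TRUE)),
                    class = "root_signals")
  sub <- subtract_baseline(sig, base)
  window <- which(times >= washout_periods * period - 1e-9)
  ch <- decompose_dc_ac(sub, window)
  video <- assemble_video(ch, grid_map, frames)
  attr(video, "frequency") <- f
  attr(video, "period") <- period
  video
}

#' Freestream-only baseline root moments
#'
#' The baseline (no plate) flow is steady, so its root moments are a single
#' row per whisker.
#'
#' @param disc,flow,coeff as in [simulate_case()].
#' @return List with per-whisker `Mx` and `My` vectors and `ids`.
#' @export
freestream_baseline <- function(disc, flow = flow_config(),
                                coeff = default_coeff_table()) {
  sig <- signal_time_series(disc, NULL, flow, c(0, 1), TRUE, coeff)
  list(ids = sig$ids, Mx = sig$Mx[1, ], My = sig$My[1, ])
}

#' Build the labeled video dataset over a parameter grid
#'
#' Generates one sensing video per grid case, deterministically given the
#' case parameters (the pipeline itself has no stochastic component; the
#' seed is recorded for provenance and threaded to any downstream
#' consumer). A pipeline failure on any case aborts with the case id.
#'
#' @param grid a [param_grid()].
#' @param array a [build_array()] result.
#' @param n_segments whisker discretization for the load model.
#' @param flow,st,coeff,frames,washout_periods,window_periods,samples_per_period
#'   passed to [simulate_case()].
#' @param seed recorded seed.
#' @param verbose print progress.
#' @return An object of class `wvt_dataset`: `videos` array
#'   `n x frames x 9 x 22 x 4`, `labels` data.frame, `grid_map`, and
#'   `meta`.
#' @export
build_dataset <- function(grid = param_grid(), array = build_array(),
                          n_segments = 12, flow = flow_config(),
                          st = strouhal_model(), coeff = default_coeff_table(),
                          frames = 80, washout_periods = 2,
                          window_periods = 3, samples_per_period = 32,
                          seed = 1, verbose = FALSE) {
  disc <- discretize_array(array, n_segments)
  gm <- map_to_grid(array)
  base <- freestream_baseline(disc, flow, coeff)
  n <- nrow(grid)
  videos <- array(0, c(n, frames, gm$rows, gm$cols, 4))
  freq <- period <- numeric(n)
  for (i in seq_len(n)) {
    vid <- tryCatch(
      simulate_case(plate_config(grid$X[i], grid$Y[i], grid$alpha[i],
                                 grid$beta[i]),
                    disc, gm, flow, st, coeff, frames, washout_periods,
                    window_periods, samples_per_period, baseline = base),
      error = function(e) stop("pipeline failed on case ", grid$case[i],
                               ": ", conditionMessage(e)))
    videos[i, , , , ] <- vid$video
    freq[i] <- attr(vid, "frequency")
    period[i] <- attr(vid, "period")
    if (verbose && i %% 10 == 0) message("case ", i, "/", n)
  }
  labels <- data.frame(X = grid$X, Y = grid$Y,
                       alpha = grid$alpha, beta = grid$beta)
  structure(list(videos = videos, labels = labels, grid_map = gm,
                 frequency = freq, period = period,
                 meta = list(seed = seed, n_segments = n_segments,
                             frames = frames,
                             washout_periods = washout_periods,
                             window_periods = window_periods,
                             samples_per_period = samples_per_period,
                             flow = flow, st = st,
                             created = "whiskerVT build_dataset")),
            class = "wvt_dataset")
}

#' @export
print.wvt_dataset <- function(x, ...) {
  d <- dim(x$videos)
  cat("Sensing-video dataset: ", d[1], " cases, videos ",
      paste(d[-1], collapse = " x "), "\n", sep = "")
  invisible(x)
}

#' Save / load a dataset container
#'
#' The container is an RDS serialization of the dataset object; a JSON
#' sidecar manifest (same path with extension `.manifest.json`) records the
#' content hash, seed and generation parameters.
#'
#' @param dataset a `wvt_dataset`; @param path output path.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "wvt_dataset"))
  saveRDS(dataset, path, version = 3)
  manifest <- list(class = "wvt_dataset",
                   n_cases = nrow(dataset$labels),
                   dims = dim(dataset$videos),
                   seed = dataset$meta$seed,
                   content_hash = content_hash(dataset))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  ds <- readRDS(path)
  if (!inherits(ds, "wvt_dataset")) stop("not a wvt_dataset container")
  ds
}

#' Content hash of an R object
#'
#' FNV-1a hash over the canonical serialization; used to stamp run
#' manifests so a run is reconstructible and verifiable from its outputs.
#'
#' @param x any serializable object.
#' @return Hex string.
#' @export
content_hash <- function(x) {
  raw <- serialize(x, NULL, version = 3)
  h <- 2166136261
  p <- 16777619
  step <- max(1L, length(raw) %/% 65536L)  # sample long payloads
  for (b in as.integer(raw[seq(1L, length(raw), by = step)])) {
    h <- h - h %% 256 + bitwXor(h %% 256, b)  # b < 256: xor touches low byte
    # h * p mod 2^32 in double-safe halves
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  # h may exceed .Machine$integer.max; format the two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
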