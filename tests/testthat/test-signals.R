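# small synthetic root_signals builder
mk_signals <- function(times, n_w, fn) {
  M <- sapply(seq_len(n_w), function(j) fn(times, j))
  structure(list(times = times, ids = seq_len(n_w),
                 Mx = M, My = 2 * M), class = "root_signals")
}

test_that("baseline subtraction is exact elementwise", {
  tms <- seq(0, 1, by = 0.1)
  s <- mk_signals(tms, 3, function(t, j) sin(t) + j)
  b0 <- mk_signals(tms, 3, function(t, j) 0 * t)
  expect_equal(subtract_baseline(s, s)$Mx, s$Mx * 0)
  expect_equal(subtract_baseline(s, b0)$Mx, s$Mx)
  s2 <- s; s2$times <- s$times + 0.05
  expect_error(subtract_baseline(s, s2), "time grids")
})

test_that("baseline-subtracted signals match wake-only loading when linearized", {
  # the load model is quadratic in velocity, so with-wake minus baseline
  # equals the cross term plus the wake-only quadratic term; at small
  # disturbance amplitude the relative gap to a linearized model is the
  # disturbance-to-freestream ratio, which we check empirically
  disc <- discretize_array(fx_mini_array(), 6)
  flow <- flow_config()
  eps <- 0.004  # m/s, 2% of freestream
  wake_fn <- function(p, t) cbind(0, eps * sin(2 * pi * t), 0)[rep(1, nrow(p)), ]
  tms <- c(0, 0.25)
  with_wake <- signal_time_series(disc, wake_fn, flow, tms)
  base <- signal_time_series(disc, NULL, flow, tms)
  sub <- subtract_baseline(with_wake, base)
  only_wake <- signal_time_series(disc, wake_fn, flow, tms,
                                  include_freestream = FALSE)
  # both isolate the wake effect, but through different nonlinear paths:
  # agreement only to O(eps / U); the drag channel carries the signal
  denom <- max(abs(sub$My[2, ]))
  expect_gt(denom, 0)
  expect_lt(max(abs(sub$My[2, ] - only_wake$My[2, ])) / denom, 1)
})

test_that("DC/AC decomposition is exact and AC is zero-mean", {
  tms <- seq(0, 2, length.out = 81)
  s <- mk_signals(tms, 4, function(t, j) j + sin(2 * pi * t * j))
  ch <- decompose_dc_ac(s)
  expect_lt(max(abs(colMeans(ch$AC_x))), 1e-12 * max(abs(s$Mx)))
  recon <- sweep(ch$AC_x, 2, ch$DC_x, "+")
  expect_equal(recon, s$Mx, tolerance = 1e-14)
  # constant signal: DC = c, AC = 0
  sc <- mk_signals(tms, 2, function(t, j) rep(j, length(t)))
  chc <- decompose_dc_ac(sc)
  expect_equal(chc$DC_x, c(1, 2))
  expect_equal(max(abs(chc$AC_x)), 0)
  # integer periods of a sinusoid: DC below 1e-12 of amplitude
  tms2 <- seq(0, 4, length.out = 401)[-401]
  ss <- mk_signals(tms2, 1, function(t, j) sin(2 * pi * t))
  expect_lt(abs(decompose_dc_ac(ss)$DC_x), 1e-12)
  expect_error(decompose_dc_ac(s, integer(0)), "empty")
})

test_that("video assembly has the contracted shape and zero null pixels", {
  gm <- fx_grid_map()
  tms <- seq(0, 2, length.out = 80)
  s <- mk_signals(tms, 88, function(t, j) j * sin(2 * pi * t))
  vid <- assemble_video(decompose_dc_ac(s), gm, t_frames = 80)
  expect_equal(dim(vid$video), c(80, 9, 22, 4))
  occupied <- matrix(FALSE, 9, 22)
  occupied[cbind(gm$assignment$row, gm$assignment$col)] <- TRUE
  for (ch in 1:4) {
    s <- vid$video[, , , ch]
    dim(s) <- c(80, 9 * 22)
    expect_equal(max(abs(s[, !as.vector(occupied)])), 0)
  }
  # DC channels constant across frames
  expect_equal(vid$video[1, , , 1], vid$video[80, , , 1])
  # all-zero signals give an all-zero video
  s0 <- mk_signals(tms, 88, function(t, j) 0 * t)
  expect_equal(max(abs(assemble_video(decompose_dc_ac(s0), gm)$video)), 0)
})

test_that("video assembly maps by whisker id, not input order", {
  gm <- fx_grid_map()
  tms <- seq(0, 1, length.out = 40)
  s <- mk_signals(tms, 88, function(t, j) j + 0.1 * sin(2 * pi * t + j))
  ch <- decompose_dc_ac(s)
  perm <- sample(88)
  chp <- ch
  chp$ids <- ch$ids[perm]
  chp$DC_x <- ch$DC_x[perm]; chp$DC_y <- ch$DC_y[perm]
  chp$AC_x <- ch$AC_x[, perm]; chp$AC_y <- ch$AC_y[, perm]
  expect_equal(assemble_video(chp, gm, 40)$video,
               assemble_video(ch, gm, 40)$video)
  chm <- ch; chm$ids <- ch$ids[-1]
  expect_error(assemble_video(chm, gm, 40), "missing")
})

test_that("video readback plus DC reproduces the windowed signal", {
  gm <- fx_grid_map()
  tms <- seq(0, 2, length.out = 80)  # frame count equals window length
  s <- mk_signals(tms, 88, function(t, j) j + sin(2 * pi * t + j / 5))
  ch <- decompose_dc_ac(s)
  vid <- assemble_video(ch, gm, t_frames = 80)
  px <- read_pixel(vid, 37)
  expect_equal(px$AC_x + px$DC_x, s$Mx[, 37], tolerance = 1e-12)
})

test_that("frame resampling preserves the dominant frequency", {
  f_sig <- 0.6
  tms <- seq(0, 5, length.out = 401)
  gm <- fx_grid_map()
  s <- mk_signals(tms, 88, function(t, j) sin(2 * pi * f_sig * t))
  vid <- assemble_video(decompose_dc_ac(s), gm, t_frames = 80)
  ac <- read_pixel(vid, 1)$AC_x
  dt <- diff(vid$frame_times)[1]
  sp <- Mod(fft(ac))[2:(40)]
  f_peak <- which.max(sp) / (80 * dt)
  expect_lt(abs(f_peak - f_sig), 1 / (80 * dt) + 1e-9)
})

test_that("phase averaging folds periodic signals exactly", {
  period <- 0.5
  tms <- seq(0, 10 * period, length.out = 40 * 10 + 1)[-(401)]
  y <- sin(2 * pi * tms / period)
  pa <- phase_average(tms, y, period, bins = 40)
  # with one sample per bin per cycle, the fold reproduces the sampled
  # cycle exactly
  truth <- sin(2 * pi * ((seq_len(40) - 1) / 40))
  expect_equal(pa, truth, tolerance = 1e-10)
  expect_equal(phase_average(tms, rep(3, length(tms)), period), rep(3, 40))
  expect_error(phase_average(c(0, 0.1), c(1, 2), period), "2 periods")
})

test_that("phase averaging reduces noise variance by the cycle count", {
  set.seed(5)
  period <- 1; cycles <- 50
  tms <- seq(0, cycles * period, length.out = cycles * 40 + 1)[-(cycles * 40 + 1)]
  truth_fn <- function(t) sin(2 * pi * t / period)
  sigma <- 0.3
  y <- truth_fn(tms) + rnorm(length(tms), sd = sigma)
  pa <- phase_average(tms, y, period, bins = 40)
  truth <- truth_fn((seq_len(40) - 0.5) / 40)
  mse <- mean((pa - truth)^2)
  expect_lt(mse, 3 * sigma^2 / cycles)
})

test_that("region averages follow the quadrant structure", {
  arr <- fx_array()
  period <- 1
  tms <- seq(0, 3, length.out = 121)
  s <- mk_signals(tms, 88, function(t, j) sin(2 * pi * t))
  rg <- region_average(s, arr, period)
  expect_named(rg, c("LT", "LB", "RT", "RB"))
  for (r in rg[-1]) expect_equal(r$Mx, rg$LT$Mx, tolerance = 1e-10)
  # support only on the right side
  right_ids <- arr$whiskers$id[arr$whiskers$side == "right"]
  s2 <- mk_signals(tms, 88, function(t, j)
    if (j %in% right_ids) sin(2 * pi * t) else 0 * t)
  rg2 <- region_average(s2, arr, period)
  expect_equal(max(abs(rg2$LT$Mx)), 0)
  expect_equal(max(abs(rg2$LB$Mx)), 0)
  expect_gt(max(abs(rg2$RT$Mx)), 0)
})

test_that("a laterally translated wake loads the near side harder", {
  plate <- plate_config(Y = 150)
  flow <- flow_config(); st <- strouhal_model()
  f <- shedding_frequency(plate, flow, st)
  period <- 1 / f
  times <- seq(0, 5 * period, length.out = 161)
  disc <- fx_disc()
  wake_fn <- function(p, t) induced_velocity(evolve_wake(plate, flow, st, t), p)
  sig <- signal_time_series(disc, wake_fn, flow, times)
  base <- signal_time_series(disc, NULL, flow, times)
  sub <- subtract_baseline(sig, base)
  idx <- which(times >= 2 * period)
  win <- structure(list(times = sub$times[idx], ids = sub$ids,
                        Mx = sub$Mx[idx, ], My = sub$My[idx, ]),
                   class = "root_signals")
  rg <- region_average(win, fx_array(), period, bins = 32)
  right <- max(abs(c(rg$RT$Mx, rg$RB$Mx)))
  left <- max(abs(c(rg$LT$Mx, rg$LB$Mx)))
  expect_gt(right, left)
})
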