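test_that("hydraulic diameter of the untilted plate is the diameter", {
  expect_equal(hydraulic_diameter(0, 0, 40), 40, tolerance = 1e-12)
})

test_that("hydraulic diameter matches quadrature of the ellipse perimeter", {
  # independent perimeter oracle: arc-length quadrature
  perim <- function(a, b) {
    4 * integrate(function(th) sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2),
                  0, pi / 2, rel.tol = 1e-10)$value
  }
  for (ab in list(c(45, 0), c(30, 10), c(45, 45))) {
    a <- 20 * cos(ab[2] * pi / 180)
    b <- 20 * cos(ab[1] * pi / 180)
    oracle <- 4 * pi * a * b / perim(a, b)
    expect_rel_equal(hydraulic_diameter(ab[1], ab[2], 40), oracle, 1e-3)
  }
})

test_that("hydraulic diameter is symmetric under swapping the tilts", {
  for (a in c(0, 15, 30, 45)) for (b in c(0, 22.5, 45)) {
    expect_equal(hydraulic_diameter(a, b, 40), hydraulic_diameter(b, a, 40))
  }
})

test_that("untilted shedding frequency follows St0 U / L'", {
  # St0 = 0.12, U = 0.2 m/s, L' = 0.04 m -> 0.6 Hz by hand
  expect_equal(shedding_frequency(plate_config()), 0.6, tolerance = 1e-12)
})

test_that("extreme tilt with non-zero second angle suppresses shedding", {
  expect_equal(shedding_frequency(plate_config(alpha = 45, beta = 22.5)), 0)
  expect_equal(shedding_frequency(plate_config(alpha = 22.5, beta = -45)), 0)
  expect_gt(shedding_frequency(plate_config(alpha = 45, beta = 0)), 0)
  expect_gt(shedding_frequency(plate_config(alpha = 22.5, beta = 22.5)), 0)
})

test_that("shedding frequency is symmetric in the sign of either tilt", {
  angles <- seq(-45, 45, by = 22.5)
  for (a in angles) for (b in angles) {
    f <- shedding_frequency(plate_config(alpha = a, beta = b))
    expect_equal(f, shedding_frequency(plate_config(alpha = -a, beta = b)))
    expect_equal(f, shedding_frequency(plate_config(alpha = a, beta = -b)))
  }
})

test_that("maximum Strouhal increase over the shedding regime is 80%", {
  angles <- seq(-45, 45, by = 22.5)
  flow <- flow_config()
  st_of <- function(a, b) {
    f <- shedding_frequency(plate_config(alpha = a, beta = b), flow)
    f * hydraulic_diameter(a, b, 40) * 1e-3 / flow$U_inf
  }
  st0 <- st_of(0, 0)
  ratios <- c()
  for (a in angles) for (b in angles) {
    f <- shedding_frequency(plate_config(alpha = a, beta = b), flow)
    if (f > 0) ratios <- c(ratios, st_of(a, b) / st0)
  }
  expect_equal(max(ratios) - 1, 0.8, tolerance = 1e-9)
})

test_that("rings are shed every half period with alternating tags", {
  f <- shedding_frequency(plate_config())
  w <- evolve_wake(plate_config(), t = 1.6 / f)
  # shed events at 0, 1/2f, 1/f, 3/2f; default cutoff (3 periods) keeps all
  expect_equal(nrow(w$rings), 4)
  expect_equal(unname(table(w$rings$side_tag))[1], 2)
  tags <- w$rings$side_tag[order(w$rings$shed_time)]
  expect_true(all(tags[-1] != tags[-length(tags)]))
  expect_setequal(unique(w$rings$side_tag), c("top", "bottom"))
})

test_that("plate translation rigidly translates the wake", {
  t <- 2.5
  w0 <- evolve_wake(plate_config(), t = t)
  wX <- evolve_wake(plate_config(X = 60), t = t)
  wY <- evolve_wake(plate_config(Y = 50), t = t)
  expect_equal(wX$rings$cz, w0$rings$cz + 60)
  expect_equal(wX$rings$cx, w0$rings$cx)
  expect_equal(wX$rings$cy, w0$rings$cy)
  expect_equal(wY$rings$cy, w0$rings$cy + 50)
  expect_equal(wX$rings$circulation, w0$rings$circulation)
})

test_that("yaw tilt makes the left-edge ring stronger and inclines the wake", {
  w <- evolve_wake(plate_config(alpha = 22.5), t = 3)
  expect_setequal(unique(w$rings$side_tag), c("left", "right"))
  gl <- abs(w$rings$circulation[w$rings$side_tag == "left"])
  gr <- abs(w$rings$circulation[w$rings$side_tag == "right"])
  expect_gt(min(gl), max(gr))
  # wake axis has a lateral component with the sign of the tilt
  expect_gt(abs(w$rings$ny[1]), 0)
})

test_that("steady regime replaces rings by two counter-rotating legs", {
  w <- evolve_wake(plate_config(alpha = 45, beta = 22.5), t = 2)
  expect_equal(w$regime, "steady")
  expect_null(w$rings)
  expect_length(w$legs, 2)
  expect_equal(w$legs[[1]]$circulation, -w$legs[[2]]$circulation)
})

test_that("ring emission pattern is periodic once the cutoff window is full", {
  f <- shedding_frequency(plate_config())
  w1 <- evolve_wake(plate_config(), t = 10 / f)
  w2 <- evolve_wake(plate_config(), t = 11 / f)
  expect_equal(nrow(w1$rings), nrow(w2$rings))
  o1 <- order(w1$rings$shed_time)
  o2 <- order(w2$rings$shed_time)
  for (col in c("cx", "cy", "cz", "circulation", "side_tag")) {
    expect_equal(w1$rings[[col]][o1], w2$rings[[col]][o2], tolerance = 1e-9)
  }
})

test_that("induced velocity of an empty wake is zero", {
  w <- evolve_wake(plate_config(), t = 0)
  w$rings <- NULL
  u <- induced_velocity(w, rbind(c(0, 0, 0), c(10, 20, 30)))
  expect_equal(u, matrix(0, 2, 3))
})

test_that("on-axis ring velocity matches the closed form within 1%", {
  st <- strouhal_model(n_filament = 256)
  w <- evolve_wake(plate_config(), st = st, t = 0)
  w$rings <- w$rings[1, , drop = FALSE]
  r <- w$rings[1, ]
  R <- r$radius * 1e-3
  for (z_mm in c(0, 5, 15, 40)) {
    p <- c(r$cx, r$cy, r$cz) + z_mm * c(r$nx, r$ny, r$nz)
    u <- induced_velocity(w, p)
    z <- z_mm * 1e-3
    u_exact <- r$circulation * R^2 / (2 * (R^2 + z^2)^1.5)
    expect_rel_equal(sqrt(sum(u^2)), abs(u_exact), 0.01)
  }
})

test_that("opposite coincident rings cancel and contributions are additive", {
  st <- strouhal_model()
  w <- evolve_wake(plate_config(), st = st, t = 2)
  w$rings <- w$rings[1:2, , drop = FALSE]
  pts <- rbind(c(0, 10, 0), c(-50, 0, 20), c(-250, 5, 5))
  u12 <- induced_velocity(w, pts)
  w1 <- w; w1$rings <- w$rings[1, , drop = FALSE]
  w2 <- w; w2$rings <- w$rings[2, , drop = FALSE]
  expect_equal(u12, induced_velocity(w1, pts) + induced_velocity(w2, pts),
               tolerance = 1e-12)
  wc <- w
  wc$rings <- rbind(w$rings[1, ], w$rings[1, ])
  wc$rings$circulation[2] <- -wc$rings$circulation[1]
  expect_lt(max(abs(induced_velocity(wc, pts))), 1e-12)
})

test_that("regularization keeps the field finite on the filament", {
  w <- evolve_wake(plate_config(), t = 0)
  r <- w$rings[1, ]
  on_core <- c(r$cx + r$radius, r$cy, r$cz)  # a point on the ring circle
  u <- induced_velocity(w, on_core)
  expect_true(all(is.finite(u)))
})

test_that("disturbance field shifts rigidly with plate translation", {
  t <- 2.5
  pts <- rbind(c(0, 10, 5), c(-100, -15, 10))
  u0 <- induced_velocity(evolve_wake(plate_config(), t = t), pts)
  shift <- matrix(c(0, 50, 60), nrow(pts), 3, byrow = TRUE)
  u1 <- induced_velocity(evolve_wake(plate_config(X = 60, Y = 50), t = t),
                         pts + shift)
  expect_equal(u1, u0, tolerance = 1e-12)
})

test_that("Biot-Savart field is numerically divergence-free", {
  w <- evolve_wake(plate_config(), t = 2)
  div_at <- function(p, h) {
    d <- diag(3) * h
    sum(vapply(1:3, function(i)
      (induced_velocity(w, p + d[i, ])[1, i] -
         induced_velocity(w, p - d[i, ])[1, i]) / (2 * h * 1e-3), numeric(1)))
  }
  p <- c(-50, 10, 15)
  u_scale <- max(abs(induced_velocity(w, p)))
  d1 <- abs(div_at(p, 2))
  d2 <- abs(div_at(p, 1))
  expect_lt(d1, 1e-3 * u_scale / 0.002)  # small against u / h
  expect_lt(d2, d1 / 2)                  # second-order decay
})

test_that("lambda2 is zero for uniform flow and -omega^2 for rigid rotation", {
  x <- seq(-10, 10, length.out = 5)
  uni <- lambda2_field(function(p) matrix(0.2, nrow(p), 3), x, x, x)
  expect_lt(max(abs(uni)), 1e-12)
  om <- 3  # rad/s about z; positions mm -> m
  rot <- lambda2_field(function(p) {
    cbind(-om * p[, 2], om * p[, 1], 0) * 1e-3
  }, x, x, x)
  expect_equal(max(abs(rot + om^2)), 0, tolerance = 1e-6)
})

test_that("lambda2 minimum localizes a synthetic ring core", {
  w <- evolve_wake(plate_config(), t = 0)
  w$rings <- w$rings[1, , drop = FALSE]
  r <- w$rings[1, ]
  gx <- seq(r$cx - 2, r$cx + 2, length.out = 3)
  gy <- seq(r$cy - 35, r$cy + 35, length.out = 29)
  gz <- seq(r$cz - 35, r$cz + 35, length.out = 29)
  lam <- lambda2_field(function(p) induced_velocity(w, p), gx, gy, gz)
  idx <- which(lam == min(lam), arr.ind = TRUE)[1, ]
  pos <- c(gx[idx[1]], gy[idx[2]], gz[idx[3]])
  rad_dist <- sqrt(sum((pos[2:3] - c(r$cy, r$cz))^2))
  cell <- diff(gy)[1]
  expect_lt(abs(rad_dist - r$radius), 1.5 * cell)
  expect_lt(min(lam), 0)
  expect_error(lambda2_field(function(p) p, gx, gy, numeric(1)), "at least 3")
})
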