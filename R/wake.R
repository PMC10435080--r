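#' Upstream plate configuration
#'
#' Location and orientation of the circular plate whose wake the whisker
#' array senses. `X` moves the plate vertically (head-frame z), `Y`
#' laterally (head-frame y); `alpha` yaws the plate about the vertical axis
#' and `beta` pitches it about the lateral axis. The plate sits `standoff`
#' mm upstream of the nose tip.
#'
#' @param X vertical offset, mm in \[-120, 120\].
#' @param Y lateral offset, mm in \[0, 200\].
#' @param alpha yaw tilt, deg in \[-45, 45\].
#' @param beta pitch tilt, deg in \[-45, 45\].
#' @param diameter plate diameter, mm.
#' @param standoff upstream distance from the nose, mm.
#' @param allow_out_of_range disable the range checks.
#' @return An object of class `plate_config`.
#' @export
plate_config <- function(X = 0, Y = 0, alpha = 0, beta = 0,
                         diameter = 40, standoff = 300,
                         allow_out_of_range = FALSE) {
  if (!allow_out_of_range) {
    if (abs(X) > 120) stop("X outside [-120, 120] mm")
    if (Y < 0 || Y > 200) stop("Y outside [0, 200] mm")
    if (abs(alpha) > 45 || abs(beta) > 45) stop("tilt angles outside [-45, 45] deg")
  }
  structure(list(X = X, Y = Y, alpha = alpha, beta = beta,
                 diameter = diameter, standoff = standoff),
            class = "plate_config")
}

#' Flow configuration
#'
#' @param U_inf freestream speed, m/s.
#' @param nu kinematic viscosity, m^2/s (the default matches a plate
#'   Reynolds number of 200 at the default speed and diameter).
#' @param rho fluid density, kg/m^3.
#' @return An object of class `flow_config`.
#' @export
flow_config <- function(U_inf = 0.2, nu = 4e-5, rho = 998) {
  stopifnot(U_inf > 0, nu > 0, rho > 0)
  structure(list(U_inf = U_inf, nu = nu, rho = rho), class = "flow_config")
}

#' Hydraulic diameter of the plate's projected frontal ellipse
#'
#' A circular plate of diameter `D` tilted by (`alpha`, `beta`) projects
#' onto the inflow plane as an ellipse with semi-axes `(D/2) cos(beta)` and
#' `(D/2) cos(alpha)`. The hydraulic diameter is `4 A / P` with the
#' perimeter from Ramanujan's approximation, which is accurate to well below
#' 0.1% for these aspect ratios.
#'
#' @param alpha,beta tilt angles in degrees (|angle| <= 90).
#' @param diameter plate diameter in mm.
#' @return Hydraulic diameter in mm.
#' @export
hydraulic_diameter <- function(alpha, beta, diameter = 40) {
  if (any(abs(c(alpha, beta)) > 90)) stop("|alpha|, |beta| must be <= 90 deg")
  a <- diameter / 2 * cos(beta * pi / 180)
  b <- diameter / 2 * cos(alpha * pi / 180)
  A <- pi * a * b
  P <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  4 * A / P
}

#' Strouhal / wake model constants
#'
#' Kinematic constants of the synthetic wake. The Strouhal law is
#' `St(alpha, beta) = St0 (1 + c_tilt (sin^2 alpha + sin^2 beta))`; with the
#' default `c_tilt = 1.6` the largest Strouhal increase over the shedding
#' part of the tilt grid (attained at |alpha| = 45, beta = 0 or the
#' converse) is 80% above the untilted value. Ring strength asymmetry under
#' tilt is linear in sin(tilt): the edge farther from the inflow sheds a
#' ring stronger by a factor `(1 + s_asym sin|tilt|)` and the near edge a
#' weaker one. Rings advect at `kappa U_inf` along the tilted wake axis.
#'
#' @param St0 Strouhal number of the untilted plate.
#' @param c_tilt tilt sensitivity of the Strouhal number.
#' @param s_asym ring-strength asymmetry slope.
#' @param kappa advection speed factor (fraction of `U_inf`).
#' @param gamma_factor circulation scale: `Gamma0 = gamma_factor U_inf D/2`.
#' @param ring_radius_factor ring radius as a fraction of plate diameter.
#' @param core_radius_factor core radius as a fraction of plate diameter.
#' @param cutoff_periods rings older than this many shedding periods are
#'   dropped.
#' @param n_filament filament segments per ring for Biot-Savart evaluation.
#' @return An object of class `strouhal_model`.
#' @export
strouhal_model <- function(St0 = 0.12, c_tilt = 1.6, s_asym = 0.6,
                           kappa = 0.9, gamma_factor = 1.0,
                           ring_radius_factor = 0.55,
                           core_radius_factor = 0.15,
                           cutoff_periods = 3, n_filament = 128) {
  structure(list(St0 = St0, c_tilt = c_tilt, s_asym = s_asym, kappa = kappa,
                 gamma_factor = gamma_factor,
                 ring_radius_factor = ring_radius_factor,
                 core_radius_factor = core_radius_factor,
                 cutoff_periods = cutoff_periods, n_filament = n_filament),
            class = "strouhal_model")
}

.is_steady <- function(alpha, beta) {
  (abs(abs(alpha) - 45) < 1e-9 & abs(beta) > 1e-9) |
    (abs(abs(beta) - 45) < 1e-9 & abs(alpha) > 1e-9)
}

#' Vortex-shedding frequency of the tilted plate
#'
#' `f = St(alpha, beta) U_inf / L'` with `L'` the hydraulic diameter of the
#' projected frontal ellipse. When one tilt angle is at its 45 degree
#' extreme while the other is non-zero the wake is steady (two streamwise
#' vortex legs instead of shedding) and the frequency is 0.
#'
#' @param plate a [plate_config()].
#' @param flow a [flow_config()].
#' @param st a [strouhal_model()].
#' @return Shedding frequency in Hz (0 in the steady regime).
#' @export
shedding_frequency <- function(plate, flow = flow_config(),
                               st = strouhal_model()) {
  if (.is_steady(plate$alpha, plate$beta)) return(0)
  sa <- sin(plate$alpha * pi / 180)^2
  sb <- sin(plate$beta * pi / 180)^2
  St <- st$St0 * (1 + st$c_tilt * (sa + sb))
  Lp <- hydraulic_diameter(plate$alpha, plate$beta, plate$diameter) * 1e-3
  St * flow$U_inf / Lp
}

# rotation taking the untilted plate frame into the head frame:
# yaw alpha about z, then pitch beta about y (applied to the downstream axis)
.plate_rotation <- function(alpha, beta) {
  ca <- cos(alpha * pi / 180); sa <- sin(alpha * pi / 180)
  cb <- cos(beta * pi / 180); sb <- sin(beta * pi / 180)
  Rz <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  Rz %*% Ry
}

#' Evolve the synthetic wake to time t
#'
#' Emulates the documented wake phenomenology of the plate. In the shedding
#' regime, vortex rings are emitted every half period, alternating between
#' the two plate edges perpendicular to the dominant tilt axis (top/bottom
#' by default and when |beta| >= |alpha|, left/right when |alpha| > |beta|),
#' with a 180 degree phase difference and opposite circulation signs. Rings
#' advect downstream at `kappa U_inf` along the wake axis, which is tilted
#' with the plate, so tilting inclines the whole wake while translating the
#' plate rigidly translates it. Under tilt the edge farther from the inflow
#' sheds the stronger ring. In the steady regime (one tilt angle extreme,
#' the other non-zero) the wake consists of two counter-rotating streamwise
#' vortex legs attached to the plate's lateral edges.
#'
#' @param plate a [plate_config()].
#' @param flow a [flow_config()].
#' @param st a [strouhal_model()].
#' @param t time in seconds (first ring shed at t = 0).
#' @return An object of class `wake_state`: `regime` (`"shedding"` or
#'   `"steady"`), a data.frame `rings` (centre, normal, radius, core,
#'   circulation, shed time, side tag) and, in the steady regime, a list
#'   `legs` of straight filaments.
#' @export
evolve_wake <- function(plate, flow = flow_config(), st = strouhal_model(),
                        t = 0) {
  stopifnot(t >= 0)
  D <- plate$diameter
  Rm <- .plate_rotation(plate$alpha, plate$beta)
  axis_w <- as.vector(Rm %*% c(1, 0, 0))     # wake axis, downstream
  e_lat <- as.vector(Rm %*% c(0, 1, 0))      # plate lateral edge direction
  e_up <- as.vector(Rm %*% c(0, 0, 1))       # plate top edge direction
  centre <- c(-plate$standoff, plate$Y, plate$X)

  if (.is_steady(plate$alpha, plate$beta)) {
    leg_len <- 1.2 * (plate$standoff + 600)
    mk_leg <- function(sign_side) {
      start <- centre + sign_side * (D / 2) * e_lat
      list(start = start, end = start + leg_len * axis_w,
           circulation = sign_side * st$gamma_factor * flow$U_inf * (D / 2) * 1e-3,
           core = st$core_radius_factor * D)
    }
    return(structure(list(regime = "steady",
                          rings = NULL,
                          legs = list(mk_leg(1), mk_leg(-1)),
                          plate = plate, st = st),
                     class = "wake_state"))
  }

  f <- shedding_frequency(plate, flow, st)
  period <- 1 / f
  # dominant tilt axis picks the shedding edges
  if (abs(plate$alpha) > abs(plate$beta)) {
    edge_dir <- e_lat
    tags <- c("left", "right")
    tilt <- plate$alpha
  } else {
    edge_dir <- e_up
    tags <- c("top", "bottom")
    tilt <- plate$beta
  }
  k_max <- floor(t * 2 * f + 1e-9)
  shed_times <- (0:k_max) * (period / 2)
  age <- t - shed_times
  keep <- age <= st$cutoff_periods * period * (1 + 1e-9)
  shed_times <- shed_times[keep]
  if (!length(shed_times)) {
    rings <- NULL
  } else {
    k <- round(shed_times * 2 * f)           # 0, 1, 2, ...
    first <- k %% 2 == 0                     # first tag sheds at t = 0
    side_sign <- ifelse(first, 1, -1)
    # positive tilt moves the first-tag edge farther from the inflow
    strength <- 1 + side_sign * st$s_asym * sin(tilt * pi / 180)
    gamma0 <- st$gamma_factor * flow$U_inf * (D / 2) * 1e-3
    adv <- st$kappa * flow$U_inf * 1e3       # mm/s
    pos0 <- matrix(centre, length(shed_times), 3, byrow = TRUE) +
      outer(side_sign * 0.25 * D, edge_dir)
    pos <- pos0 + outer(adv * (t - shed_times), axis_w)
    rings <- data.frame(
      cx = pos[, 1], cy = pos[, 2], cz = pos[, 3],
      nx = axis_w[1], ny = axis_w[2], nz = axis_w[3],
      radius = st$ring_radius_factor * D,
      core = st$core_radius_factor * D,
      circulation = side_sign * gamma0 * strength,
      shed_time = shed_times,
      side_tag = ifelse(first, tags[1], tags[2]),
      stringsAsFactors = FALSE)
  }
  structure(list(regime = "shedding", rings = rings, legs = NULL,
                 frequency = f, plate = plate, st = st),
            class = "wake_state")
}

#' @export
print.wake_state <- function(x, ...) {
  if (x$regime == "steady") {
    cat("Wake state: steady regime, two streamwise vortex legs\n")
  } else {
    cat("Wake state: shedding at", signif(x$frequency, 4), "Hz,",
        if (is.null(x$rings)) 0 else nrow(x$rings), "rings alive\n")
  }
  invisible(x)
}

# discretize all filaments of a wake state into straight segments (metres)
.wake_filaments <- function(wake) {
  n_f <- wake$st$n_filament
  seg_a <- seg_b <- NULL
  gam <- core <- NULL
  if (!is.null(wake$rings) && nrow(wake$rings)) {
    th <- seq(0, 2 * pi, length.out = n_f + 1)
    for (i in seq_len(nrow(wake$rings))) {
      r <- wake$rings[i, ]
      nrm <- .unit(c(r$nx, r$ny, r$nz))
      u <- .unit(if (abs(nrm[3]) < 0.9) c(-nrm[2], nrm[1], 0) else c(1, 0, 0) -
                   nrm[1] * nrm)
      v <- .unit(c(nrm[2] * u[3] - nrm[3] * u[2],
                   nrm[3] * u[1] - nrm[1] * u[3],
                   nrm[1] * u[2] - nrm[2] * u[1]))
      pts <- (matrix(c(r$cx, r$cy, r$cz), n_f + 1, 3, byrow = TRUE) +
                r$radius * (outer(cos(th), u) + outer(sin(th), v))) * 1e-3
      seg_a <- rbind(seg_a, pts[-(n_f + 1), ])
      seg_b <- rbind(seg_b, pts[-1, ])
      gam <- c(gam, rep(r$circulation, n_f))
      core <- c(core, rep(r$core * 1e-3, n_f))
    }
  }
  if (!is.null(wake$legs)) {
    for (leg in wake$legs) {
      n_l <- max(16, n_f %/% 2)
      s <- seq(0, 1, length.out = n_l + 1)
      pts <- (matrix(leg$start, n_l + 1, 3, byrow = TRUE) +
                outer(s, leg$end - leg$start)) * 1e-3
      seg_a <- rbind(seg_a, pts[-(n_l + 1), ])
      seg_b <- rbind(seg_b, pts[-1, ])
      gam <- c(gam, rep(leg$circulation, n_l))
      core <- c(core, rep(leg$core * 1e-3, n_l))
    }
  }
  list(seg_a = seg_a, seg_b = seg_b, gamma = gam, core = core)
}

#' Wake-induced disturbance velocity
#'
#' Biot-Savart velocity induced by all vortex filaments of a wake state at
#' the given points, using a Gaussian (Lamb-Oseen-type) core regularization
#' so the field stays finite on the filaments. The freestream is NOT
#' included: this is the disturbance field; callers add `U_inf` along x when
#' they need the total velocity.
#'
#' @param wake a [evolve_wake()] result.
#' @param points n x 3 matrix of head-frame positions in mm.
#' @return n x 3 matrix of velocities in m/s.
#' @export
induced_velocity <- function(wake, points) {
  stopifnot(inherits(wake, "wake_state"))
  if (is.vector(points)) points <- matrix(points, 1)
  fil <- .wake_filaments(wake)
  if (is.null(fil$seg_a)) return(matrix(0, nrow(points), 3))
  .bs_velocity_cpp(points * 1e-3, fil$seg_a, fil$seg_b, fil$gamma, fil$core)
}

#' Lambda2 vortex-identification field
#'
#' Computes the lambda2 criterion on a rectilinear lattice: the middle
#' eigenvalue of `S^2 + Omega^2`, with `S` and `Omega` the symmetric and
#' antisymmetric parts of the velocity gradient estimated by central
#' differences. Vortex cores appear where lambda2 < 0.
#'
#' @param sampler function taking an n x 3 matrix of positions (mm) and
#'   returning an n x 3 matrix of velocities (m/s).
#' @param x,y,z lattice coordinates (mm); each needs at least 3 points.
#' @return A 3-d array `length(x) x length(y) x length(z)` of lambda2
#'   values (1/s^2), with attributes `x`, `y`, `z`.
#' @export
lambda2_field <- function(sampler, x, y, z) {
  if (length(x) < 3 || length(y) < 3 || length(z) < 3)
    stop("lambda2_field needs at least 3 lattice points per direction")
  grid <- as.matrix(expand.grid(x = x, y = y, z = z))
  u <- sampler(grid)
  nx <- length(x); ny <- length(y); nz <- length(z)
  U <- array(u, c(nx, ny, nz, 3))
  # central differences (one-sided at the boundary), spacing in metres
  d1 <- function(A, h, dim) {
    n <- dim(A)[dim]
    idx <- function(k) switch(dim,
                              A[k, , , drop = FALSE],
                              A[, k, , drop = FALSE],
                              A[, , k, drop = FALSE])
    out <- A
    hm <- h * 1e-3
    fwd <- idx(c(2:n, n)); bwd <- idx(c(1, 1:(n - 1)))
    span <- c(1, rep(2, n - 2), 1)
    sp <- switch(dim,
                 array(span, dim(A)),
                 aperm(array(span, dim(A)[c(2, 1, 3)]), c(2, 1, 3)),
                 aperm(array(span, dim(A)[c(3, 1, 2)]), c(2, 3, 1)))
    (fwd - bwd) / (sp * hm)
  }
  lam <- array(NA_real_, c(nx, ny, nz))
  # velocity gradient tensors at every node
  G <- array(0, c(nx, ny, nz, 3, 3))
  hx <- if (nx > 1) diff(x)[1] else 1
  hy <- if (ny > 1) diff(y)[1] else 1
  hz <- if (nz > 1) diff(z)[1] else 1
  for (cmp in 1:3) {
    G[, , , cmp, 1] <- d1(U[, , , cmp], hx, 1)
    G[, , , cmp, 2] <- d1(U[, , , cmp], hy, 2)
    G[, , , cmp, 3] <- d1(U[, , , cmp], hz, 3)
  }
  for (i in seq_len(nx)) for (j in seq_len(ny)) for (k in seq_len(nz)) {
    J <- matrix(G[i, j, k, , ], 3, 3)
    S <- (J + t(J)) / 2
    Om <- (J - t(J)) / 2
    M <- S %*% S + Om %*% Om
    lam[i, j, k] <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)[2]
  }
  attr(lam, "x") <- x; attr(lam, "y") <- y; attr(lam, "z") <- z
  lam
}
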