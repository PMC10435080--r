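#' Drag/lift coefficient table
#'
#' Coefficients of the quasi-steady segment load model as functions of the
#' local Reynolds number and the angle of attack between the cross-flow and
#' the segment's major axis. Queries use bilinear interpolation inside the
#' table and nearest-edge clamping outside.
#'
#' @param Re increasing Reynolds-number grid.
#' @param AoA increasing angle-of-attack grid in degrees (0 to 90).
#' @param CD,CL matrices `length(Re) x length(AoA)`; `CD >= 0` everywhere
#'   and `CL = 0` at zero angle of attack.
#' @return An object of class `coeff_table`.
#' @export
coeff_table <- function(Re, AoA, CD, CL) {
  if (!length(Re) || !length(AoA)) stop("empty coefficient table")
  stopifnot(all(diff(Re) > 0), all(diff(AoA) > 0),
            all(dim(CD) == c(length(Re), length(AoA))),
            all(dim(CL) == c(length(Re), length(AoA))))
  if (any(CD < 0)) stop("CD must be nonnegative")
  if (!all(is.finite(CD)) || !all(is.finite(CL))) stop("coefficients must be finite")
  structure(list(Re = Re, AoA = AoA, CD = CD, CL = CL),
            class = "coeff_table")
}

#' Default coefficient table
#'
#' A smooth-cylinder-style parameterization covering the low Reynolds
#' numbers (order 1-10) whisker segments see here: the drag coefficient
#' follows `(1 + 10 Re^(-2/3))` scaled by a mild angle-of-attack factor
#' (bluffer when the flow meets the minor axis), and the lift coefficient is
#' sinusoidal in twice the angle of attack, vanishing at 0 and 90 degrees.
#' Any measured table can replace it via [read_coeff_csv()].
#'
#' @return A [coeff_table()].
#' @export
default_coeff_table <- function() {
  Re <- c(0.5, 1, 2, 5, 10, 20, 50, 100, 200, 500)
  AoA <- seq(0, 90, by = 15)
  cd_re <- 1 + 10 * Re^(-2 / 3)
  cd <- outer(cd_re, 0.75 + 0.35 * sin(AoA * pi / 180))
  cl <- outer(Re / (Re + 10), 0.6 * sin(2 * AoA * pi / 180))
  coeff_table(Re, AoA, cd, cl)
}

#' Read a coefficient table from long-format CSV
#' @param path CSV with columns Re, AoA_deg, CD, CL on a full grid.
#' @return A [coeff_table()].
#' @export
read_coeff_csv <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("Re", "AoA_deg", "CD", "CL")
  if (!all(need %in% names(tab))) stop("coefficient CSV needs columns Re, AoA_deg, CD, CL")
  Re <- sort(unique(tab$Re)); AoA <- sort(unique(tab$AoA_deg))
  idx <- cbind(match(tab$Re, Re), match(tab$AoA_deg, AoA))
  CD <- CL <- matrix(NA_real_, length(Re), length(AoA))
  CD[idx] <- tab$CD; CL[idx] <- tab$CL
  if (anyNA(CD) || anyNA(CL)) stop("coefficient CSV does not cover a full grid")
  coeff_table(Re, AoA, CD, CL)
}

#' Interpolate drag/lift coefficients
#'
#' Vectorized bilinear interpolation in a [coeff_table()] with clamping at
#' the table edges; exact at the table nodes.
#'
#' @param Re_local Reynolds numbers (vector).
#' @param AoA angles of attack in degrees (vector, recycled against
#'   `Re_local`).
#' @param table a [coeff_table()].
#' @return A list with vectors `CD` and `CL`.
#' @export
local_coefficients <- function(Re_local, AoA, table = default_coeff_table()) {
  stopifnot(inherits(table, "coeff_table"))
  n <- max(length(Re_local), length(AoA))
  Re_local <- rep_len(pmin(pmax(Re_local, min(table$Re)), max(table$Re)), n)
  AoA <- rep_len(pmin(pmax(AoA, min(table$AoA)), max(table$AoA)), n)
  i <- findInterval(Re_local, table$Re, rightmost.closed = TRUE)
  j <- findInterval(AoA, table$AoA, rightmost.closed = TRUE)
  i <- pmin(i, length(table$Re) - 1)
  j <- pmin(j, length(table$AoA) - 1)
  tx <- (Re_local - table$Re[i]) / (table$Re[i + 1] - table$Re[i])
  ty <- (AoA - table$AoA[j]) / (table$AoA[j + 1] - table$AoA[j])
  bil <- function(M) {
    M[cbind(i, j)] * (1 - tx) * (1 - ty) +
      M[cbind(i + 1, j)] * tx * (1 - ty) +
      M[cbind(i, j + 1)] * (1 - tx) * ty +
      M[cbind(i + 1, j + 1)] * tx * ty
  }
  list(CD = bil(table$CD), CL = bil(table$CL))
}

# Vectorized drag/lift forces for many segments at once.
# u: n x 3 local velocities (m/s); tangent, major_axis: n x 3 unit vectors;
# A_ref (m^2), d_major (m) per segment. Returns n x 3 force matrix (N) and
# components for diagnostics.
.segment_forces <- function(u, tangent, major_axis, A_ref, d_major,
                            table, rho, nu) {
  u_par <- rowSums(u * tangent)
  u_perp <- u - u_par * tangent
  U <- .row_norms(u_perp)
  ok <- U > 0
  Fm <- matrix(0, nrow(u), 3)
  if (!any(ok)) return(list(F = Fm, U = U))
  uhat <- u_perp[ok, , drop = FALSE] / U[ok]
  cosA <- pmin(1, abs(rowSums(uhat * major_axis[ok, , drop = FALSE])))
  AoA <- acos(cosA) * 180 / pi
  Re <- U[ok] * d_major[ok] / nu
  cf <- local_coefficients(Re, AoA, table)
  q <- 0.5 * rho * U[ok]^2 * A_ref[ok]
  lhat <- .cross_rows(tangent[ok, , drop = FALSE], uhat)
  Fm[ok, ] <- (cf$CD * q) * uhat + (cf$CL * q) * lhat
  list(F = Fm, U = U)
}

#' Force on a single whisker segment
#'
#' Quasi-steady drag-lift load: the local velocity is split into components
#' parallel and perpendicular to the segment axis; drag `CD q A_ref` acts
#' along the perpendicular (cross-flow) direction and lift `CL q A_ref`
#' along `tangent x u_perp_hat`, with `q = rho U^2 / 2` the cross-flow
#' dynamic pressure. The angle of attack is measured between the cross-flow
#' and the segment's major axis (0-90 degrees); the local Reynolds number
#' uses the local major diameter.
#'
#' @param u_local velocity at the segment centroid, m/s (length-3).
#' @param tangent,major_axis unit vectors of the segment axis and local
#'   major axis.
#' @param A_ref reference area, m^2.
#' @param d_major local major diameter, m.
#' @param table a [coeff_table()].
#' @param rho density kg/m^3; @param nu kinematic viscosity m^2/s.
#' @return List with `F` (force vector, N), `F_D`, `F_L` (magnitudes, N).
#' @export
segment_force <- function(u_local, tangent, major_axis, A_ref, d_major,
                          table = default_coeff_table(),
                          rho = 998, nu = 4e-5) {
  if (A_ref <= 0) stop("A_ref must be > 0")
  res <- .segment_forces(matrix(u_local, 1), matrix(tangent, 1),
                         matrix(major_axis, 1), A_ref, d_major,
                         table, rho, nu)
  u_perp <- u_local - sum(u_local * tangent) * tangent
  U <- sqrt(sum(u_perp^2))
  if (U == 0) return(list(F = c(0, 0, 0), F_D = 0, F_L = 0))
  uhat <- u_perp / U
  list(F = drop(res$F),
       F_D = sum(drop(res$F) * uhat),
       F_L = sum(drop(res$F) * .unit(.cross_rows(matrix(tangent, 1),
                                                 matrix(uhat, 1)))))
}

#' Root bending moment of one whisker
#'
#' Quasi-static reduction of segment loads to the clamped base: the root
#' reaction moment of a clamped cantilever equals the moment resultant of
#' the applied loads about the base, independent of stiffness. The head
#' frame moment is projected onto the body-fixed root axes: `Mx'` (the
#' lift-moment channel) and `My'` (the drag-moment channel).
#'
#' @param centroids n x 3 segment centroids, mm (head frame).
#' @param forces n x 3 segment forces, N.
#' @param base length-3 base point, mm.
#' @param body_x,body_y body-fixed unit axes at the root.
#' @return List with `M` (head-frame moment, N mm), `Mx_prime`, `My_prime`.
#' @export
root_moment <- function(centroids, forces, base, body_x, body_y) {
  if (nrow(centroids) != nrow(forces)) stop("mismatched segment/load lists")
  r <- centroids - matrix(base, nrow(centroids), 3, byrow = TRUE)
  M <- colSums(.cross_rows(r, forces))
  list(M = M,
       Mx_prime = sum(M * body_x),
       My_prime = sum(M * body_y))
}

#' Root bending-moment time series for a whisker array
#'
#' Samples the local flow at every segment centroid and every time, applies
#' the drag-lift model, and reduces the loads of each whisker to its root
#' moment. The flow is the sum of the freestream (optional) and a wake
#' disturbance sampler (optional), so the same routine produces both the
#' with-wake signals and the freestream-only baseline.
#'
#' @param disc an [discretize_array()] result.
#' @param wake_fn `NULL`, or a function `(points_mm, t)` returning n x 3
#'   disturbance velocities in m/s.
#' @param flow a [flow_config()].
#' @param times strictly increasing vector of sample times, s.
#' @param include_freestream add `U_inf` along +x to the sampled flow.
#' @param table a [coeff_table()].
#' @return An object of class `root_signals`: `times`, `ids` and matrices
#'   `Mx` and `My` (`length(times) x n_whiskers`, N mm).
#' @export
signal_time_series <- function(disc, wake_fn = NULL, flow = flow_config(),
                               times = 0, include_freestream = TRUE,
                               table = default_coeff_table()) {
  stopifnot(inherits(disc, "array_discretization"))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  tab <- disc$array$whiskers
  ids <- tab$id
  n_w <- length(ids)
  grp <- match(disc$whisker_id, ids)
  base <- as.matrix(tab[, c("base_x", "base_y", "base_z")])[grp, , drop = FALSE]
  bx <- as.matrix(tab[, c("bx_x", "bx_y", "bx_z")])[grp, , drop = FALSE]
  by <- as.matrix(tab[, c("by_x", "by_y", "by_z")])[grp, , drop = FALSE]
  r_rel <- disc$centroid - base

  Mx <- My <- matrix(0, length(times), n_w)
  u_free <- if (include_freestream) c(flow$U_inf, 0, 0) else c(0, 0, 0)
  n_seg <- nrow(disc$centroid)
  for (k in seq_along(times)) {
    u <- matrix(u_free, n_seg, 3, byrow = TRUE)
    if (!is.null(wake_fn)) u <- u + wake_fn(disc$centroid, times[k])
    Fm <- .segment_forces(u, disc$tangent, disc$major_axis, disc$A_ref,
                          disc$d_major, table, flow$rho, flow$nu)$F
    Mseg <- .cross_rows(r_rel, Fm)             # N mm per segment
    Mx[k, ] <- rowsum(rowSums(Mseg * bx), grp)[, 1]
    My[k, ] <- rowsum(rowSums(Mseg * by), grp)[, 1]
  }
  structure(list(times = times, ids = ids, Mx = Mx, My = My),
            class = "root_signals")
}

#' Export root signals as long-format CSV
#' @param signals a [signal_time_series()] result.
#' @param path output path.
#' @export
write_root_signals <- function(signals, path) {
  long <- data.frame(
    whisker_id = rep(signals$ids, each = length(signals$times)),
    time = rep(signals$times, length(signals$ids)),
    Mx_prime = as.vector(signals$Mx),
    My_prime = as.vector(signals$My))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
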