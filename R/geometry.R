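#' Parametric undulated whisker shape
#'
#' Describes a single seal whisker as a tapered elliptical cylinder whose
#' cross-section half-axes are modulated by two sinusoidal envelopes with a
#' 180 degree phase shift between the major and minor axis: where the major
#' axis peaks the minor axis is at its trough and vice versa. This phase
#' opposition is the geometric feature credited with suppressing
#' vortex-induced vibration of real seal whiskers.
#'
#' @param length whisker length in mm.
#' @param taper_ratio tip/base scale factor in (0, 1]; 1 means no taper.
#' @param undulation_wavelength wavelength of the axis envelopes in mm; must
#'   be smaller than `length`.
#' @param undulation_amplitude relative amplitude of the envelopes
#'   (dimensionless fraction of the local half-axis; 0 disables undulation).
#' @param mean_diameter mean of the major and minor cross-section diameters
#'   in mm. The default 0.66 mm is a typical harbor-seal value.
#' @param aspect_ratio ratio of major to minor half-axis at the envelope
#'   mean.
#' @return An object of class `whisker_shape`.
#' @export
whisker_shape <- function(length,
                          taper_ratio = 0.4,
                          undulation_wavelength = 3.64,
                          undulation_amplitude = 0.1,
                          mean_diameter = 0.66,
                          aspect_ratio = 2.0) {
  if (!is.numeric(length) || length <= 0) stop("invalid shape: length must be > 0")
  if (taper_ratio <= 0 || taper_ratio > 1) stop("invalid shape: taper_ratio must be in (0, 1]")
  if (undulation_wavelength <= 0) stop("invalid shape: wavelength must be > 0")
  if (undulation_wavelength >= length) stop("invalid shape: wavelength must be < length")
  if (undulation_amplitude < 0 || undulation_amplitude >= 1)
    stop("invalid shape: undulation_amplitude must be in [0, 1)")
  if (mean_diameter <= 0) stop("invalid shape: mean_diameter must be > 0")
  if (aspect_ratio < 1) stop("invalid shape: aspect_ratio must be >= 1")
  structure(list(length = length,
                 taper_ratio = taper_ratio,
                 undulation_wavelength = undulation_wavelength,
                 undulation_amplitude = undulation_amplitude,
                 axis_phase_shift = pi,
                 mean_diameter = mean_diameter,
                 aspect_ratio = aspect_ratio),
            class = "whisker_shape")
}

# Envelope of the cross-section half-axes at arc position s (mm from base).
# Returns list(a, b) in mm. The two envelopes are sinusoids offset by the
# fixed pi phase shift; a linear taper from 1 at the base to taper_ratio at
# the tip multiplies both.
.shape_half_axes <- function(shape, s) {
  # mean half-axes from mean_diameter and aspect_ratio:
  # (2a + 2b)/2 = mean_diameter, a/b = aspect_ratio
  b0 <- shape$mean_diameter / (1 + shape$aspect_ratio)
  a0 <- shape$aspect_ratio * b0
  phase <- 2 * pi * s / shape$undulation_wavelength
  taper <- 1 + (shape$taper_ratio - 1) * s / shape$length
  amp <- shape$undulation_amplitude
  list(a = a0 * taper * (1 + amp * cos(phase)),
       b = b0 * taper * (1 + amp * cos(phase + shape$axis_phase_shift)))
}

#' Discretize a whisker into loaded segments
#'
#' Splits the whisker centerline into `n_segments` equal-arc-length
#' segments and evaluates the local cross-section at each segment midpoint.
#' Each segment carries the reference area used by the drag-lift load
#' model: local major diameter times arc length.
#'
#' @param shape a [whisker_shape()].
#' @param n_segments number of segments (>= 2).
#' @return An object of class `whisker_discretization` with components
#'   `s_mid` (arc positions, mm), `arc_length` (mm, per segment), `a`, `b`
#'   (local half-axes, mm), `A_ref` (reference areas, m^2) and the
#'   originating `shape`.
#' @export
build_whisker <- function(shape, n_segments) {
  stopifnot(inherits(shape, "whisker_shape"))
  if (n_segments < 2) stop("n_segments must be >= 2")
  ds <- shape$length / n_segments
  s_mid <- (seq_len(n_segments) - 0.5) * ds
  ax <- .shape_half_axes(shape, s_mid)
  structure(list(s_mid = s_mid,
                 arc_length = rep(ds, n_segments),
                 a = ax$a, b = ax$b,
                 A_ref = (2 * ax$a * 1e-3) * (ds * 1e-3),
                 shape = shape),
            class = "whisker_discretization")
}

#' Default two-sided whisker array specification
#'
#' The per-whisker geometry of real arrays is only available graphically in
#' the literature, so the default is a parametric stand-in: 44 whiskers per
#' side arranged in 9 horizontal rows on each cheek, mirror-symmetric about
#' the head mid-plane, with whisker length increasing caudally from
#' `length_range[1]` to `length_range[2]` mm. Any field can be overridden,
#' and a per-whisker CSV (columns id, side, base_x, base_y, base_z, length,
#' azimuth, elevation) can replace the parametric layout entirely via
#' [read_array_csv()].
#'
#' @param row_counts whiskers per row (top to bottom); must sum to the side
#'   count and have at most 9 rows of at most 11 whiskers.
#' @param length_range rostral and caudal whisker lengths in mm.
#' @param z_spacing vertical row spacing in mm.
#' @param x_spacing axial in-row spacing in mm.
#' @param cheek_offset lateral distance of the whisker pads from the head
#'   mid-plane in mm.
#' @param shape_defaults list of [whisker_shape()] arguments shared by all
#'   whiskers (length is set per whisker).
#' @return A list of class `array_spec`.
#' @export
array_spec <- function(row_counts = c(2, 4, 6, 6, 7, 7, 6, 4, 2),
                       length_range = c(20, 80),
                       z_spacing = 6,
                       x_spacing = 6,
                       cheek_offset = 22,
                       shape_defaults = list()) {
  if (length(row_counts) > 9 || any(row_counts > 11) || any(row_counts < 0))
    stop("row_counts must fit a 9 x 11 half grid")
  structure(list(row_counts = row_counts,
                 length_range = length_range,
                 z_spacing = z_spacing,
                 x_spacing = x_spacing,
                 cheek_offset = cheek_offset,
                 shape_defaults = shape_defaults),
            class = "array_spec")
}

# base-point / orientation table for one side ("left" or "right")
.side_table <- function(spec, side) {
  nrows <- length(spec$row_counts)
  rows <- list()
  z_top <- (nrows - 1) / 2 * spec$z_spacing
  for (k in seq_len(nrows)) {
    m <- spec$row_counts[k]
    if (m == 0) next
    z <- z_top - (k - 1) * spec$z_spacing
    # center each row axially on the pad
    x0 <- (max(spec$row_counts) - m) / 2 * spec$x_spacing
    x <- x0 + (seq_len(m) - 1) * spec$x_spacing
    rows[[k]] <- data.frame(row = k, base_x = x, base_z = z)
  }
  tab <- do.call(rbind, rows)
  x_max <- (max(spec$row_counts) - 1) * spec$x_spacing
  tab$base_y <- spec$cheek_offset + 0.1 * tab$base_x
  # caudal (large x) whiskers are longer
  tab$length <- spec$length_range[1] +
    diff(spec$length_range) * tab$base_x / x_max
  # orientation: mostly lateral, slightly upstream, rows fan vertically
  tab$azimuth <- 100
  z_scale <- max(abs(tab$base_z), 1)
  tab$elevation <- -10 + 20 * tab$base_z / z_scale
  if (side == "left") {
    tab$base_y <- -tab$base_y
    tab$azimuth <- -tab$azimuth
  }
  tab$side <- side
  tab
}

#' Read a per-whisker array override table
#'
#' @param path CSV with columns id, side, base_x, base_y, base_z, length,
#'   azimuth, elevation (mm and degrees).
#' @return A data.frame usable as the `table` argument of [build_array()].
#' @export
read_array_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "side", "base_x", "base_y", "base_z", "length",
            "azimuth", "elevation")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("array CSV missing columns: ", paste(miss, collapse = ", "))
  tab
}

#' Build the two-sided whisker array
#'
#' Assembles the 2 x 44 whisker array: base points, orientations, body-fixed
#' root axes and per-whisker shapes. The two sides are mirror images through
#' the head mid-plane (y = 0). The body-fixed axes at each root are chosen so
#' that drag-direction loading (streamwise) projects onto the My' channel and
#' lift-direction loading onto the Mx' channel: `x'` is the unit vector
#' opposing the streamwise direction projected into the root cross-section
#' plane, and `y' = tangent x x'`.
#'
#' @param spec an [array_spec()]; ignored when `table` is given.
#' @param table optional per-whisker data.frame (see [read_array_csv()]).
#' @param allow_nonstandard allow side counts other than 44 (reduced arrays
#'   for testing).
#' @return An object of class `whisker_array`: a data.frame `whiskers` (one
#'   row per whisker: id, side, base point, direction, length) plus the list
#'   of shapes.
#' @export
build_array <- function(spec = array_spec(), table = NULL,
                        allow_nonstandard = FALSE) {
  if (is.null(table)) {
    stopifnot(inherits(spec, "array_spec"))
    tab <- rbind(.side_table(spec, "left"), .side_table(spec, "right"))
    tab$id <- seq_len(nrow(tab))
  } else {
    tab <- table
    spec <- if (inherits(spec, "array_spec")) spec else array_spec()
  }
  for (s in c("left", "right")) {
    n_side <- sum(tab$side == s)
    if (n_side != 44 && !allow_nonstandard)
      stop("side '", s, "' has ", n_side,
           " whiskers; expected 44 (set allow_nonstandard = TRUE to override)")
  }
  key <- paste(tab$base_x, tab$base_y, tab$base_z)
  if (anyDuplicated(key)) stop("duplicate whisker base points")

  az <- tab$azimuth * pi / 180
  el <- tab$elevation * pi / 180
  dir <- cbind(cos(el) * cos(az), cos(el) * sin(az), sin(el))

  shapes <- lapply(seq_len(nrow(tab)), function(i) {
    args <- c(list(length = tab$length[i]), spec$shape_defaults)
    do.call(whisker_shape, args)
  })

  # body-fixed root axes (see description)
  xhat <- c(1, 0, 0)
  bx <- t(apply(dir, 1, function(d) {
    p <- xhat - sum(xhat * d) * d
    -.unit(p)
  }))
  by <- .cross_rows(dir, bx)

  tab$dir_x <- dir[, 1]; tab$dir_y <- dir[, 2]; tab$dir_z <- dir[, 3]
  tab$bx_x <- bx[, 1]; tab$bx_y <- bx[, 2]; tab$bx_z <- bx[, 3]
  tab$by_x <- by[, 1]; tab$by_y <- by[, 2]; tab$by_z <- by[, 3]
  structure(list(whiskers = tab, shapes = shapes), class = "whisker_array")
}

#' @export
print.whisker_array <- function(x, ...) {
  tab <- x$whiskers
  cat("Whisker array:", nrow(tab), "whiskers (",
      sum(tab$side == "left"), "left /", sum(tab$side == "right"), "right )\n")
  cat("  length range:", round(min(tab$length), 1), "-",
      round(max(tab$length), 1), "mm\n")
  invisible(x)
}

#' Discretize every whisker of an array into head-frame segments
#'
#' @param array a [build_array()] result.
#' @param n_segments segments per whisker.
#' @return A list of class `array_discretization` holding, for all segments
#'   of all whiskers stacked: centroids (mm, head frame), tangents, local
#'   major-axis directions, reference areas (m^2), local major diameters
#'   (m), arc lengths (mm), the owning whisker id, and per-whisker base
#'   points and body axes.
#' @export
discretize_array <- function(array, n_segments = 12) {
  stopifnot(inherits(array, "whisker_array"))
  tab <- array$whiskers
  n_w <- nrow(tab)
  xhat <- c(1, 0, 0)
  cen <- tan_m <- amaj <- NULL
  aref <- dmaj <- dsl <- wid <- NULL
  for (i in seq_len(n_w)) {
    d <- c(tab$dir_x[i], tab$dir_y[i], tab$dir_z[i])
    disc <- build_whisker(array$shapes[[i]], n_segments)
    base <- c(tab$base_x[i], tab$base_y[i], tab$base_z[i])
    cen_i <- outer(disc$s_mid, d) + matrix(base, n_segments, 3, byrow = TRUE)
    a_dir <- .unit(xhat - sum(xhat * d) * d)  # major axis faces the flow
    cen <- rbind(cen, cen_i)
    tan_m <- rbind(tan_m, matrix(d, n_segments, 3, byrow = TRUE))
    amaj <- rbind(amaj, matrix(a_dir, n_segments, 3, byrow = TRUE))
    aref <- c(aref, disc$A_ref)
    dmaj <- c(dmaj, 2 * disc$a * 1e-3)
    dsl <- c(dsl, disc$arc_length)
    wid <- c(wid, rep(tab$id[i], n_segments))
  }
  structure(list(centroid = cen, tangent = tan_m, major_axis = amaj,
                 A_ref = aref, d_major = dmaj, arc_length = dsl,
                 whisker_id = wid, n_segments = n_segments,
                 array = array),
            class = "array_discretization")
}

#' Map whisker base points onto the 9 x 22 sensing grid
#'
#' Each side occupies a 9 x 11 half grid: the row is the rank of the base
#' elevation within the side (top row first), the column the rank of the
#' axial base position within the row. Looking at the face from the front,
#' columns run across both cheeks, so the left half grid is the mirror image
#' of the right one: left columns count 11..1 rostral-to-caudal and right
#' columns 12..22. Ties in elevation are broken by axial position, then by
#' whisker id, making the assignment deterministic. Cells without a whisker
#' are null pixels (88 whiskers leave 110 of the 198 cells empty).
#'
#' @param array a [build_array()] result.
#' @param z_tol elevations closer than this (mm) share a row.
#' @return An object of class `grid_map`: data.frame `assignment` (id, row,
#'   col) plus `rows`, `cols` and the null-pixel count.
#' @export
map_to_grid <- function(array, z_tol = 1e-6) {
  stopifnot(inherits(array, "whisker_array"))
  tab <- array$whiskers
  out <- NULL
  for (s in unique(tab$side)) {
    side <- tab[tab$side == s, c("id", "base_x", "base_z")]
    levels_z <- sort(unique(round(side$base_z / z_tol) * z_tol),
                     decreasing = TRUE)
    if (length(levels_z) > 9)
      stop("side '", s, "' has more than 9 distinct elevation rows")
    row_of <- match(round(side$base_z / z_tol) * z_tol, levels_z)
    cols <- integer(nrow(side))
    for (r in unique(row_of)) {
      in_row <- which(row_of == r)
      ord <- in_row[order(side$base_x[in_row], side$id[in_row])]
      rank_x <- seq_along(ord)
      if (length(ord) > 11) stop("more than 11 whiskers in one row")
      cols[ord] <- if (s == "left") 12 - rank_x else 11 + rank_x
    }
    out <- rbind(out, data.frame(id = side$id, row = row_of, col = cols))
  }
  out <- out[order(out$id), ]
  rownames(out) <- NULL
  if (anyDuplicated(out[c("row", "col")])) stop("grid assignment not injective")
  structure(list(assignment = out, rows = 9, cols = 22,
                 n_null = 9 * 22 - nrow(out)),
            class = "grid_map")
}

#' @export
print.grid_map <- function(x, ...) {
  cat("Grid map: ", nrow(x$assignment), " whiskers on a ", x$rows, "x",
      x$cols, " grid (", x$n_null, " null pixels)\n", sep = "")
  invisible(x)
}

#' Export a grid map as CSV
#' @param grid_map a [map_to_grid()] result.
#' @param path output CSV path.
#' @export
write_grid_map <- function(grid_map, path) {
  utils::write.csv(grid_map$assignment, path, row.names = FALSE)
  invisible(path)
}
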