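#' Atom map for attack-geometry analysis
#'
#' Maps the four named atoms used by the geometry module to row indices in
#' each frame's coordinate matrix: the SAM sulfur (`s_sam`), the SAM methyl
#' carbon (`c_sam`), the nucleophilic atom (`nucleophile`; the deprotonated
#' sulfur S1 of a persulfide, or Se of a selenide), and its substituent
#' (`substituent`; the protonated sulfur S2, or the methyl carbon of
#' methylselenide).
#'
#' @param s_sam,c_sam,nucleophile,substituent Row indices (distinct, >= 1).
#' @param ligand_kind Free-text tag ("HSS", "MeSe", ...).
#' @return An object of class `atom_map`.
#' @export
atom_map <- function(s_sam, c_sam, nucleophile, substituent,
                     ligand_kind = "other") {
  idx <- c(s_sam = s_sam, c_sam = c_sam, nucleophile = nucleophile,
           substituent = substituent)
  if (any(idx != round(idx)) || any(idx < 1) || anyDuplicated(idx)) {
    stop("atom map needs four distinct positive indices", call. = FALSE)
  }
  structure(list(s_sam = as.integer(s_sam), c_sam = as.integer(c_sam),
                 nucleophile = as.integer(nucleophile),
                 substituent = as.integer(substituent),
                 ligand_kind = ligand_kind),
            class = "atom_map")
}

#' Attack geometry of a single frame
#'
#' From one frame's coordinates (Angstrom), computes the nucleophile-C_SAM
#' distance `d1`, the substituent-C_SAM distance `d2`, their difference
#' `d_diff = d1 - d2`, the alignment angle `theta` at C_SAM between the SAM
#' sulfur and the nucleophile (near 180 degrees = in-line attack), the
#' analogous `theta2` for the substituent (reported, not used for filtering),
#' and the hindrance angle `phi` at the nucleophile between its substituent
#' and C_SAM (100-180 degrees = unhindered). Angles are computed with the
#' atan2 form of the vector angle, which keeps full precision near 0 and 180
#' degrees.
#'
#' @param coords Numeric matrix (atoms x 3), Angstrom.
#' @param map An [atom_map()].
#' @param frame_index Frame label stored in the result.
#' @param scale Multiplier applied to coordinates before analysis; use
#'   `scale = 10` for input in nm.
#' @return One-row data frame: frame, d1, d2, d_diff, theta, theta2, phi.
#' @export
frame_geometry <- function(coords, map, frame_index = 1L, scale = 1) {
  stopifnot(inherits(map, "atom_map"))
  coords <- as.matrix(coords) * scale
  if (ncol(coords) != 3 || any(!is.finite(coords))) {
    stop("coords must be a finite (atoms x 3) matrix", call. = FALSE)
  }
  need <- max(map$s_sam, map$c_sam, map$nucleophile, map$substituent)
  if (nrow(coords) < need) {
    stop("coords has fewer rows than the atom map requires", call. = FALSE)
  }
  s_sam <- coords[map$s_sam, ]
  c_sam <- coords[map$c_sam, ]
  nuc <- coords[map$nucleophile, ]
  sub <- coords[map$substituent, ]

  d1 <- sqrt(sum((nuc - c_sam)^2))
  d2 <- sqrt(sum((sub - c_sam)^2))
  if (d1 == 0 || d2 == 0 || sqrt(sum((s_sam - c_sam)^2)) == 0) {
    stop("coincident atoms at an angle vertex: geometry undefined", call. = FALSE)
  }
  theta <- angle_deg(s_sam, c_sam, nuc)
  theta2 <- angle_deg(s_sam, c_sam, sub)
  phi <- angle_deg(sub, nuc, c_sam)
  data.frame(frame = frame_index, d1 = d1, d2 = d2, d_diff = d1 - d2,
             theta = theta, theta2 = theta2, phi = phi)
}

#' Attack geometry of every frame in a trajectory
#'
#' @param traj A `trajectory` (from [gen_trajectory()] or [read_xyz()]).
#' @param map An [atom_map()]; by default the four atoms in their trajectory
#'   order (SAM sulfur, SAM methyl carbon, nucleophile, substituent).
#' @param scale Coordinate multiplier (10 for nm input).
#' @return Data frame with one row per frame (columns as [frame_geometry()]).
#' @export
trajectory_geometry <- function(traj, map = atom_map(1, 2, 3, 4), scale = 1) {
  stopifnot(inherits(traj, "trajectory"), inherits(map, "atom_map"))
  n <- length(traj$frames)
  if (n == 0) {
    return(data.frame(frame = integer(0), d1 = numeric(0), d2 = numeric(0),
                      d_diff = numeric(0), theta = numeric(0),
                      theta2 = numeric(0), phi = numeric(0)))
  }
  # Vectorized across frames: pull each mapped atom into an n x 3 matrix.
  pull <- function(i) {
    t(vapply(traj$frames, function(fr) fr[i, 1:3], numeric(3))) * scale
  }
  s_sam <- pull(map$s_sam)
  c_sam <- pull(map$c_sam)
  nuc <- pull(map$nucleophile)
  sub <- pull(map$substituent)

  rownorm <- function(m) sqrt(rowSums(m^2))
  vangle <- function(u, v) {
    cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                u[, 1] * v[, 2] - u[, 2] * v[, 1])
    atan2(rownorm(cr), rowSums(u * v)) * 180 / pi
  }
  d1 <- rownorm(nuc - c_sam)
  d2 <- rownorm(sub - c_sam)
  if (any(d1 == 0) || any(d2 == 0) || any(rownorm(s_sam - c_sam) == 0) ||
      any(rownorm(sub - nuc) == 0)) {
    stop("coincident atoms at an angle vertex: geometry undefined", call. = FALSE)
  }
  data.frame(frame = seq_len(n),
             d1 = d1, d2 = d2, d_diff = d1 - d2,
             theta = vangle(s_sam - c_sam, nuc - c_sam),
             theta2 = vangle(s_sam - c_sam, sub - c_sam),
             phi = vangle(sub - nuc, c_sam - nuc))
}

#' Extract reaction-competent frames
#'
#' Keeps frames whose nucleophile-C_SAM distance is at most `d_max` and whose
#' alignment angle theta lies in `theta_range`. All bounds are inclusive. An
#' empty result is valid.
#'
#' @param geometry Data frame from [trajectory_geometry()] (needs columns
#'   `d1`, `theta`).
#' @param d_max Maximum attack distance, Angstrom.
#' @param theta_range Closed interval of acceptable theta, degrees.
#' @return The qualifying subset of `geometry`.
#' @export
extract_reactive_frames <- function(geometry, d_max = 4.0,
                                    theta_range = c(150, 180)) {
  stopifnot(is.data.frame(geometry), all(c("d1", "theta") %in% names(geometry)))
  stop_if_not_scalar_num(d_max, "d_max", lower = 0, allow_equal_lower = FALSE)
  if (length(theta_range) != 2 || theta_range[1] > theta_range[2]) {
    stop("theta_range must be an ordered pair", call. = FALSE)
  }
  keep <- geometry$d1 <= d_max &
    geometry$theta >= theta_range[1] & geometry$theta <= theta_range[2]
  geometry[keep, , drop = FALSE]
}

#' Histogram of the hindrance angle phi
#'
#' Counts phi over [0, 180) degrees in bins of `bin_width`, the last bin
#' closed at 180 so the counts always sum to the number of frames.
#'
#' @param geometry Data frame with a `phi` column (typically the output of
#'   [extract_reactive_frames()]).
#' @param bin_width Bin width in degrees; must divide 180 evenly.
#' @return Data frame: `lower`, `upper` (bin edges, degrees), `count`.
#' @export
phi_histogram <- function(geometry, bin_width = 10) {
  stopifnot(is.data.frame(geometry), "phi" %in% names(geometry))
  stop_if_not_scalar_num(bin_width, "bin_width", lower = 0,
                         allow_equal_lower = FALSE)
  if (abs(180 / bin_width - round(180 / bin_width)) > 1e-12) {
    stop("bin_width must divide 180 evenly", call. = FALSE)
  }
  nbin <- as.integer(round(180 / bin_width))
  edges <- seq(0, 180, by = bin_width)
  phi <- geometry$phi
  if (any(phi < 0 | phi > 180)) {
    stop("phi values outside [0, 180] degrees", call. = FALSE)
  }
  idx <- pmin(floor(phi / bin_width) + 1L, nbin)  # 180 falls in the last bin
  data.frame(lower = edges[-length(edges)], upper = edges[-1],
             count = tabulate(idx, nbins = nbin))
}

#' Optimal-phi fraction and geometry summary
#'
#' The fraction (percent) of extracted frames whose hindrance angle phi lies
#' in the optimal range — by default [100, 180] degrees, where nucleophilic
#' attack is sterically unhindered. Undefined (NA) when no frames survive
#' extraction.
#'
#' @param geometry The extracted subset (data frame with `phi`).
#' @param phi_range Closed optimal interval, degrees.
#' @param n_frames_total Total frames before extraction (defaults to
#'   `nrow(geometry)` when the unfiltered count is unknown).
#' @param bin_width Histogram bin width, degrees.
#' @return An object of class `geometry_summary`: list with `n_frames_total`,
#'   `n_extracted`, `phi_histogram`, `n_optimal`, `optimal_fraction`
#'   (percent, `NA` if `n_extracted` is 0), and `phi_range`.
#' @export
optimal_phi_fraction <- function(geometry, phi_range = c(100, 180),
                                 n_frames_total = nrow(geometry),
                                 bin_width = 10) {
  stopifnot(is.data.frame(geometry), "phi" %in% names(geometry))
  if (length(phi_range) != 2 || phi_range[1] > phi_range[2]) {
    stop("phi_range must be an ordered pair", call. = FALSE)
  }
  n_ext <- nrow(geometry)
  n_opt <- sum(geometry$phi >= phi_range[1] & geometry$phi <= phi_range[2])
  structure(list(
    n_frames_total = n_frames_total,
    n_extracted = n_ext,
    phi_histogram = phi_histogram(geometry, bin_width = bin_width),
    n_optimal = n_opt,
    optimal_fraction = if (n_ext > 0) 100 * n_opt / n_ext else NA_real_,
    phi_range = phi_range
  ), class = "geometry_summary")
}

#' @export
print.geometry_summary <- function(x, ...) {
  cat(sprintf("Attack-geometry summary: %d/%d frames reaction-competent\n",
              x$n_extracted, x$n_frames_total))
  if (is.na(x$optimal_fraction)) {
    cat("  optimal-phi fraction undefined (no extracted frames)\n")
  } else {
    cat(sprintf("  %d frames (%.1f%%) with phi in [%g, %g] degrees\n",
                x$n_optimal, x$optimal_fraction, x$phi_range[1], x$phi_range[2]))
  }
  invisible(x)
}

#' One-call steric accessibility analysis
#'
#' Chains [extract_reactive_frames()], [phi_histogram()] and
#' [optimal_phi_fraction()] over a per-frame geometry table.
#'
#' @param geometry Data frame from [trajectory_geometry()].
#' @inheritParams extract_reactive_frames
#' @inheritParams optimal_phi_fraction
#' @return A `geometry_summary`.
#' @export
steric_summary <- function(geometry, d_max = 4.0, theta_range = c(150, 180),
                           phi_range = c(100, 180), bin_width = 10) {
  sub <- extract_reactive_frames(geometry, d_max = d_max,
                                 theta_range = theta_range)
  optimal_phi_fraction(sub, phi_range = phi_range,
                       n_frames_total = nrow(geometry), bin_width = bin_width)
}
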