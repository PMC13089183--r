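#' Kinetic experiment design
#'
#' Describes the substrate concentrations, replication, and additive rate
#' noise of a simulated initial-rate experiment. The default design points
#' (0, 20, 200, 2000 uM, 3 replicates) follow the assay layout used for the
#' disulfide/persulfide methylation measurements.
#'
#' @param concentrations Substrate concentrations, uM (>= 0, non-empty).
#' @param n_rep Replicates per concentration (integer >= 1).
#' @param noise_sd Standard deviation of additive Gaussian rate noise,
#'   nmol/min/mg (>= 0).
#' @param seed Integer RNG seed; every generator call with the same design and
#'   truth is bit-reproducible.
#' @return An object of class `kinetic_design`.
#' @export
kinetic_design <- function(concentrations = c(0, 20, 200, 2000),
                           n_rep = 3L, noise_sd = 0, seed = 1L) {
  if (!is.numeric(concentrations) || length(concentrations) == 0 ||
      any(!is.finite(concentrations)) || any(concentrations < 0)) {
    stop("concentrations must be a non-empty vector of finite values >= 0",
         call. = FALSE)
  }
  if (!is.numeric(n_rep) || length(n_rep) != 1L || n_rep < 1 ||
      n_rep != round(n_rep)) {
    stop("n_rep must be a single integer >= 1", call. = FALSE)
  }
  stop_if_not_scalar_num(noise_sd, "noise_sd", lower = 0)
  stop_if_not_scalar_num(seed, "seed")
  structure(list(concentrations = as.numeric(concentrations),
                 n_rep = as.integer(n_rep),
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "kinetic_design")
}

# Shared sampler: mean rates per row + additive homoscedastic Gaussian noise.
gen_rates_from_mean <- function(mean_fun, design, condition) {
  s <- rep(design$concentrations, each = design$n_rep)
  rep_id <- rep(seq_len(design$n_rep), times = length(design$concentrations))
  mu <- mean_fun(s)
  eps <- if (design$noise_sd > 0) {
    with_seed(design$seed, stats::rnorm(length(s), 0, design$noise_sd))
  } else {
    numeric(length(s))
  }
  data.frame(substrate_uM = s,
             rate_nmol_min_mg = mu + eps,
             replicate = rep_id,
             condition = condition,
             stringsAsFactors = FALSE)
}

#' Simulate initial rates from the single-substrate Michaelis-Menten model
#'
#' Rates are `Vmax * S / (Km + S)` plus independent additive Gaussian noise
#' of standard deviation `design$noise_sd`, reproducible from `design$seed`.
#' At `S = 0` the mean rate is exactly zero.
#'
#' @param truth An [mm_truth()] parameter pair.
#' @param design A [kinetic_design()].
#' @param condition Free-text condition label stored with each row.
#' @return A kinetic dataset data frame (see [validate_kinetic_dataset()]).
#' @examples
#' gen_mm_rates(mm_truth(331, 260),
#'              kinetic_design(c(20, 200, 2000), n_rep = 1, noise_sd = 0))
#' @export
gen_mm_rates <- function(truth, design, condition = "mm") {
  stopifnot(inherits(truth, "mm_truth"), inherits(design, "kinetic_design"))
  gen_rates_from_mean(function(s) predict_mm(truth, s), design, condition)
}

#' Simulate initial rates from the dual Michaelis-Menten model
#'
#' Mean rates follow the piecewise dual-substrate model (see
#' [predict_dual_mm()]); noise as in [gen_mm_rates()].
#'
#' @param gss,h2s Branch parameters ([mm_truth()]).
#' @param c1 Breakpoint concentration, uM (>= 0).
#' @param design A [kinetic_design()].
#' @param condition Free-text condition label.
#' @return A kinetic dataset data frame.
#' @export
gen_dual_mm_rates <- function(gss, h2s, c1, design, condition = "dual_mm") {
  model <- dual_mm_model(gss, h2s, c1)
  stopifnot(inherits(design, "kinetic_design"))
  gen_rates_from_mean(function(s) predict_dual_mm(model, s), design, condition)
}

#' Planted-cluster specification for synthetic PIE matrices
#'
#' @param cluster_mean_profiles A list (one element per cluster) of numeric
#'   vectors of per-fragment mean pair interaction energies, kJ/mol; all the
#'   same length.
#' @param cluster_sizes Integer vector (>= 1) of conformations per cluster.
#' @param within_sd Within-cluster per-fragment noise SD, kJ/mol (>= 0).
#' @param seed Integer RNG seed.
#' @param fragment_labels Optional fragment labels; defaults to
#'   `frag_1 ... frag_p`.
#' @return An object of class `pie_cluster_spec`.
#' @export
pie_cluster_spec <- function(cluster_mean_profiles, cluster_sizes,
                             within_sd = 1, seed = 1L,
                             fragment_labels = NULL) {
  if (!is.list(cluster_mean_profiles) || length(cluster_mean_profiles) == 0) {
    stop("cluster_mean_profiles must be a non-empty list of numeric vectors",
         call. = FALSE)
  }
  p <- length(cluster_mean_profiles[[1]])
  ok <- vapply(cluster_mean_profiles,
               function(x) is.numeric(x) && length(x) == p && all(is.finite(x)),
               logical(1))
  if (!all(ok)) {
    stop("all cluster mean profiles must be finite numeric vectors of equal length",
         call. = FALSE)
  }
  if (length(cluster_sizes) != length(cluster_mean_profiles) ||
      any(cluster_sizes < 1) || any(cluster_sizes != round(cluster_sizes))) {
    stop("cluster_sizes must be integers >= 1, one per mean profile",
         call. = FALSE)
  }
  stop_if_not_scalar_num(within_sd, "within_sd", lower = 0)
  if (is.null(fragment_labels)) fragment_labels <- paste0("frag_", seq_len(p))
  if (length(fragment_labels) != p || anyDuplicated(fragment_labels)) {
    stop("fragment_labels must be unique and match the profile length",
         call. = FALSE)
  }
  structure(list(n_fragments = p,
                 cluster_mean_profiles = lapply(cluster_mean_profiles, as.numeric),
                 cluster_sizes = as.integer(cluster_sizes),
                 within_sd = within_sd,
                 seed = as.integer(seed),
                 fragment_labels = as.character(fragment_labels)),
            class = "pie_cluster_spec")
}

#' Generate a PIE matrix with planted clusters
#'
#' Each conformation (row) in cluster `c` is that cluster's mean profile plus
#' independent Gaussian noise of SD `within_sd` per fragment. The true cluster
#' labels are returned for recovery scoring.
#'
#' @param spec A [pie_cluster_spec()].
#' @return A list with `matrix` (a [pie_matrix()]) and `true_labels`
#'   (integer vector, 1-based cluster ids per conformation).
#' @export
gen_pie_matrix <- function(spec) {
  stopifnot(inherits(spec, "pie_cluster_spec"))
  k <- length(spec$cluster_sizes)
  n <- sum(spec$cluster_sizes)
  p <- spec$n_fragments
  labels <- rep(seq_len(k), times = spec$cluster_sizes)
  mu <- do.call(rbind, spec$cluster_mean_profiles)[labels, , drop = FALSE]
  noise <- if (spec$within_sd > 0) {
    with_seed(spec$seed,
              matrix(stats::rnorm(n * p, 0, spec$within_sd), n, p))
  } else {
    matrix(0, n, p)
  }
  values <- mu + noise
  m <- pie_matrix(values,
                  conformation_ids = paste0("conf_", seq_len(n)),
                  fragment_labels = spec$fragment_labels)
  list(matrix = m, true_labels = labels)
}

# A distribution spec is list(dist = "constant"|"uniform"|"normal", ...):
#   constant: value; uniform: min, max; normal: mean, sd.
sample_dist <- function(spec, n, lower = -Inf, upper = Inf, what = "value") {
  if (!is.list(spec) || is.null(spec$dist)) {
    stop(sprintf("%s distribution spec must be a list with a `dist` element", what),
         call. = FALSE)
  }
  draw <- switch(spec$dist,
    constant = function(m) rep(spec$value, m),
    uniform = function(m) stats::runif(m, spec$min, spec$max),
    normal = function(m) stats::rnorm(m, spec$mean, spec$sd),
    stop(sprintf("unknown distribution kind '%s' for %s", spec$dist, what),
         call. = FALSE)
  )
  if (spec$dist == "constant" &&
      (spec$value < lower || spec$value > upper)) {
    stop(sprintf("%s constant %g outside [%g, %g]", what, spec$value, lower, upper),
         call. = FALSE)
  }
  if (spec$dist == "uniform" && (spec$min < lower || spec$max > upper)) {
    stop(sprintf("%s uniform bounds outside [%g, %g]", what, lower, upper),
         call. = FALSE)
  }
  x <- draw(n)
  # Truncation by resampling preserves the distribution shape on the domain.
  bad <- which(x < lower | x > upper)
  guard <- 0L
  while (length(bad) > 0) {
    x[bad] <- draw(length(bad))
    bad <- bad[x[bad] < lower | x[bad] > upper]
    guard <- guard + 1L
    if (guard > 10000L) {
      stop(sprintf("%s distribution has negligible mass on its domain", what),
           call. = FALSE)
    }
  }
  x
}

#' Geometry specification for synthetic attack trajectories
#'
#' Distribution specs are lists: `list(dist = "constant", value = )`,
#' `list(dist = "uniform", min = , max = )`, or
#' `list(dist = "normal", mean = , sd = )`. Angles are truncated to
#' [0, 180] degrees by resampling; distances to (0, Inf).
#'
#' @param n_frames Number of frames (integer >= 0).
#' @param d_dist Distribution of the nucleophile-C_SAM distance, Angstrom.
#' @param theta_dist Distribution of the attack-alignment angle theta, degrees.
#' @param phi_dist Distribution of the steric-hindrance angle phi, degrees.
#' @param seed Integer RNG seed.
#' @return An object of class `geom_spec`.
#' @export
geom_spec <- function(n_frames,
                      d_dist = list(dist = "constant", value = 3.5),
                      theta_dist = list(dist = "constant", value = 170),
                      phi_dist = list(dist = "constant", value = 135),
                      seed = 1L) {
  if (!is.numeric(n_frames) || length(n_frames) != 1L || n_frames < 0 ||
      n_frames != round(n_frames)) {
    stop("n_frames must be a single integer >= 0", call. = FALSE)
  }
  for (d in list(theta_dist, phi_dist)) {
    if (identical(d$dist, "constant") && (d$value < 0 || d$value > 180)) {
      stop("constant angle outside [0, 180] degrees", call. = FALSE)
    }
    if (identical(d$dist, "uniform") && (d$min < 0 || d$max > 180)) {
      stop("uniform angle bounds outside [0, 180] degrees", call. = FALSE)
    }
  }
  structure(list(n_frames = as.integer(n_frames), d_dist = d_dist,
                 theta_dist = theta_dist, phi_dist = phi_dist,
                 seed = as.integer(seed)),
            class = "geom_spec")
}

#' Generate a synthetic trajectory realizing sampled attack geometry
#'
#' For each frame, samples a nucleophile-C_SAM distance `d`, an alignment
#' angle `theta` (at C_SAM, between the SAM sulfur and the nucleophile), and a
#' hindrance angle `phi` (at the nucleophile, between its substituent and
#' C_SAM), then constructs Cartesian coordinates realizing exactly those
#' internal coordinates: C_SAM at the origin, S_SAM along -z at the S-C bond
#' length, the nucleophile at distance `d` making angle `theta`, and the
#' substituent placed at a random dihedral making angle `phi`. Each frame then
#' receives a random rigid-body rotation and translation, so recovering the
#' internal coordinates genuinely exercises frame-invariant geometry code.
#'
#' @param spec A [geom_spec()].
#' @param atom_names Names of the four atoms, in the order SAM sulfur, SAM
#'   methyl carbon, nucleophile, substituent.
#' @return An object of class `trajectory`: list with `frames` (list of 4x3
#'   coordinate matrices, Angstrom, rows named by `atom_names`), `atom_names`,
#'   and `truth` (data frame of the sampled `d`, `theta`, `phi` per frame).
#' @export
gen_trajectory <- function(spec,
                           atom_names = c("S_SAM", "C_SAM", "S1", "S2")) {
  stopifnot(inherits(spec, "geom_spec"))
  if (length(atom_names) != 4L || anyDuplicated(atom_names)) {
    stop("atom_names must be four distinct names (SAM sulfur, SAM methyl carbon, nucleophile, substituent)",
         call. = FALSE)
  }
  n <- spec$n_frames
  if (n == 0L) {
    return(structure(list(frames = list(), atom_names = atom_names,
                          truth = data.frame(frame = integer(0), d = numeric(0),
                                             theta = numeric(0), phi = numeric(0))),
                     class = "trajectory"))
  }
  sc_bond <- 1.81   # S-C single bond, Angstrom
  sub_bond <- 2.05  # nucleophile-substituent bond, Angstrom

  res <- with_seed(spec$seed, {
    d <- sample_dist(spec$d_dist, n, lower = 1e-6, what = "distance")
    theta <- sample_dist(spec$theta_dist, n, lower = 0, upper = 180, what = "theta")
    phi <- sample_dist(spec$phi_dist, n, lower = 0, upper = 180, what = "phi")
    psi <- stats::runif(n, 0, 2 * pi)  # free dihedral of the substituent
    frames <- vector("list", n)
    for (i in seq_len(n)) {
      th <- theta[i] * pi / 180
      ph <- phi[i] * pi / 180
      c_sam <- c(0, 0, 0)
      s_sam <- c(0, 0, -sc_bond)
      nuc <- d[i] * c(sin(th), 0, -cos(th))
      # Basis at the nucleophile: u points back to C_SAM; w1, w2 span its
      # orthogonal plane (u lies in the xz-plane, so (0,1,0) is orthogonal).
      u <- -nuc / d[i]
      w1 <- c(0, 1, 0)
      w2 <- c(u[2] * w1[3] - u[3] * w1[2],
              u[3] * w1[1] - u[1] * w1[3],
              u[1] * w1[2] - u[2] * w1[1])
      perp <- cos(psi[i]) * w1 + sin(psi[i]) * w2
      sub <- nuc + sub_bond * (cos(ph) * u + sin(ph) * perp)
      coords <- rbind(s_sam, c_sam, nuc, sub)
      rot <- random_rotation()
      shift <- stats::runif(3, -10, 10)
      coords <- coords %*% t(rot) + matrix(shift, 4, 3, byrow = TRUE)
      rownames(coords) <- atom_names
      colnames(coords) <- c("x", "y", "z")
      frames[[i]] <- coords
    }
    list(frames = frames,
         truth = data.frame(frame = seq_len(n), d = d, theta = theta, phi = phi))
  })
  structure(list(frames = res$frames, atom_names = atom_names,
                 truth = res$truth),
            class = "trajectory")
}
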