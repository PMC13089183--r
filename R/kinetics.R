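#' Michaelis-Menten parameter pair
#'
#' Bundles a Michaelis constant and a maximal velocity, the two parameters of
#' the hyperbolic saturation model \eqn{v_0(S) = V_{max} S / (K_m + S)}.
#'
#' @param km Michaelis constant, uM. Must be > 0.
#' @param vmax Maximal velocity, nmol/min/mg. Must be >= 0.
#' @return An object of class `mm_truth`: a list with elements `km`, `vmax`.
#' @examples
#' mm_truth(km = 331, vmax = 260)
#' @export
mm_truth <- function(km, vmax) {
  stop_if_not_scalar_num(km, "km", lower = 0, allow_equal_lower = FALSE)
  stop_if_not_scalar_num(vmax, "vmax", lower = 0)
  structure(list(km = km, vmax = vmax), class = "mm_truth")
}

#' @export
print.mm_truth <- function(x, ...) {
  cat(sprintf("Michaelis-Menten parameters: Km = %g uM, Vmax = %g nmol/min/mg\n",
              x$km, x$vmax))
  invisible(x)
}

#' Predicted initial rate under the Michaelis-Menten model
#'
#' @param params An [mm_truth()] object.
#' @param s Substrate concentration(s), uM. Must be >= 0.
#' @return Initial rate(s), nmol/min/mg.
#' @examples
#' predict_mm(mm_truth(331, 260), c(20, 200, 2000))
#' @export
predict_mm <- function(params, s) {
  stopifnot(inherits(params, "mm_truth"))
  if (!is.numeric(s) || any(!is.finite(s)) || any(s < 0)) {
    stop("substrate concentrations must be finite and >= 0", call. = FALSE)
  }
  params$vmax * s / (params$km + s)
}

#' Catalytic efficiency Vmax/Km
#'
#' With rates in nmol/min/mg and concentrations in uM, the ratio is
#' numerically L/min/g: (nmol min^-1 mg^-1) / (nmol/uL) = uL min^-1 mg^-1
#' = L min^-1 g^-1. Computed at full precision; printed values in the
#' literature are typically rounded to two significant figures.
#'
#' @param vmax Maximal velocity, nmol/min/mg. >= 0.
#' @param km Michaelis constant, uM. > 0.
#' @return Catalytic efficiency, L/min/g.
#' @examples
#' catalytic_efficiency(vmax = 260, km = 331) # ~0.785
#' @export
catalytic_efficiency <- function(vmax, km) {
  stop_if_not_scalar_num(vmax, "vmax", lower = 0)
  stop_if_not_scalar_num(km, "km", lower = 0, allow_equal_lower = FALSE)
  vmax / km
}

#' Validate a kinetic dataset
#'
#' A kinetic dataset is a data frame of replicated initial-rate observations
#' with columns `substrate_uM` (>= 0), `rate_nmol_min_mg`, `replicate`, and
#' `condition`.
#'
#' @param data A data frame.
#' @param for_fitting If `TRUE`, additionally require at least two distinct
#'   positive concentrations (identifiability of a two-parameter fit).
#' @return `data`, invisibly, if valid; otherwise an error.
#' @export
validate_kinetic_dataset <- function(data, for_fitting = FALSE) {
  if (!is.data.frame(data)) stop("kinetic dataset must be a data frame", call. = FALSE)
  need <- c("substrate_uM", "rate_nmol_min_mg")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("kinetic dataset is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  s <- data$substrate_uM
  if (!is.numeric(s) || any(!is.finite(s)) || any(s < 0)) {
    stop("substrate_uM must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(data$rate_nmol_min_mg) || any(!is.finite(data$rate_nmol_min_mg))) {
    stop("rate_nmol_min_mg must be finite numeric", call. = FALSE)
  }
  if (for_fitting && length(unique(s[s > 0])) < 2L) {
    stop("at least 2 distinct positive concentrations are required for fitting",
         call. = FALSE)
  }
  invisible(data)
}

#' Fit the Michaelis-Menten model by bounded nonlinear least squares
#'
#' Minimizes the residual sum of squares of observed rates against
#' \eqn{V_{max} S / (K_m + S)} over `km > 0`, `vmax >= 0` using
#' Levenberg-Marquardt with box bounds. Zero-concentration rows are retained
#' as blank anchors: the model passes through the origin, so they inform the
#' residual scale without biasing the parameters.
#'
#' Default initialization sets `vmax0` to the maximum observed rate and `km0`
#' to the concentration whose mean rate is nearest `vmax0 / 2`; two further
#' starts at `km0/4` and `4 km0` guard against the shallow-Km pathology when
#' saturation is weak.
#'
#' @param data A kinetic dataset (see [validate_kinetic_dataset()]).
#' @param init Optional [mm_truth()] used as the single starting point.
#' @return An object of class `mm_fit`: list with `km`, `vmax`, `efficiency`
#'   (`vmax/km`, L/min/g), `residual_ss`, `converged`, `n_obs`,
#'   `standard_errors` (named, possibly `NA`), and `km_identifiable`.
#' @examples
#' d <- gen_mm_rates(mm_truth(331, 260),
#'                   kinetic_design(c(20, 200, 2000), n_rep = 1, noise_sd = 0))
#' fit_mm(d)
#' @export
fit_mm <- function(data, init = NULL) {
  validate_kinetic_dataset(data, for_fitting = FALSE)
  s <- data$substrate_uM
  v <- data$rate_nmol_min_mg

  # Degenerate input: all rates zero -> Vmax = 0, Km unidentifiable.
  if (all(v == 0)) {
    return(structure(list(
      km = NA_real_, vmax = 0, efficiency = NA_real_,
      residual_ss = 0, converged = TRUE, n_obs = length(v),
      standard_errors = c(km = NA_real_, vmax = NA_real_),
      km_identifiable = FALSE
    ), class = "mm_fit"))
  }
  validate_kinetic_dataset(data, for_fitting = TRUE)

  starts <- if (!is.null(init)) {
    stopifnot(inherits(init, "mm_truth"))
    list(c(km = init$km, vmax = init$vmax))
  } else {
    vmax0 <- max(v)
    pos <- s > 0
    mean_by_s <- tapply(v[pos], s[pos], mean)
    conc <- as.numeric(names(mean_by_s))
    km0 <- conc[which.min(abs(mean_by_s - vmax0 / 2))]
    if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(conc)
    list(c(km = km0, vmax = vmax0),
         c(km = km0 / 4, vmax = vmax0),
         c(km = km0 * 4, vmax = vmax0))
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        rate ~ vmax * conc / (km + conc),
        data = data.frame(conc = s, rate = v),
        start = as.list(st),
        lower = c(km = 1e-9, vmax = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("Michaelis-Menten fit failed to converge from all starting points",
         call. = FALSE)
  }

  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) c(km = NA_real_, vmax = NA_real_))
  structure(list(
    km = unname(cf["km"]), vmax = unname(cf["vmax"]),
    efficiency = unname(cf["vmax"] / cf["km"]),
    residual_ss = best$rss,
    converged = best$fit$convInfo$isConv,
    n_obs = length(v),
    standard_errors = c(km = unname(se["km"]), vmax = unname(se["vmax"])),
    km_identifiable = TRUE
  ), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("MM fit: Km = %.6g uM, Vmax = %.6g nmol/min/mg, Vmax/Km = %.4g L/min/g\n",
              x$km, x$vmax, x$efficiency))
  cat(sprintf("  residual SS = %.6g over %d observations (converged: %s)\n",
              x$residual_ss, x$n_obs, x$converged))
  invisible(x)
}

#' Piecewise dual-substrate Michaelis-Menten model
#'
#' Combines two Michaelis-Menten branches through a breakpoint concentration
#' `c1`: below `c1` all added substrate is converted in situ to the persulfide
#' species (the "gss" branch); above `c1` the persulfide branch saturates at
#' its `c1` value and the excess `S - c1` reacts as free H2S (the "h2s"
#' branch). The predicted rate is continuous at `S = c1` because the H2S
#' branch starts from zero there.
#'
#' @param gss [mm_truth()] for the persulfide branch.
#' @param h2s [mm_truth()] for the free-H2S branch.
#' @param c1 Breakpoint concentration, uM. Must be >= 0.
#' @return An object of class `dual_mm_model`.
#' @export
dual_mm_model <- function(gss, h2s, c1) {
  stopifnot(inherits(gss, "mm_truth"), inherits(h2s, "mm_truth"))
  stop_if_not_scalar_num(c1, "c1", lower = 0)
  structure(list(gss = gss, h2s = h2s, c1 = c1), class = "dual_mm_model")
}

#' Predicted rate under the dual Michaelis-Menten model
#'
#' @param model A [dual_mm_model()].
#' @param s Substrate concentration(s), uM, >= 0.
#' @return Apparent initial rate(s): the sum of the persulfide-branch and
#'   H2S-branch contributions.
#' @examples
#' m <- dual_mm_model(mm_truth(209, 392), mm_truth(1978, 5.37), c1 = 50)
#' predict_dual_mm(m, 2000)
#' @export
predict_dual_mm <- function(model, s) {
  stopifnot(inherits(model, "dual_mm_model"))
  if (!is.numeric(s) || any(!is.finite(s)) || any(s < 0)) {
    stop("substrate concentrations must be finite and >= 0", call. = FALSE)
  }
  c1 <- model$c1
  v_gss <- ifelse(s < c1,
                  predict_mm(model$gss, s),
                  predict_mm(model$gss, rep(c1, length(s))))
  v_h2s <- ifelse(s < c1, 0, predict_mm(model$h2s, pmax(s - c1, 0)))
  v_gss + v_h2s
}

#' Estimate the breakpoint concentration C1
#'
#' With the two branch parameter pairs fixed (they are estimated beforehand
#' from single-substrate experiments), the apparent-rate model has a single
#' free parameter `c1`, constrained to `[0, max(S)]`. The objective is
#' piecewise smooth with potential kinks at observed concentrations, so a
#' dense grid scan locates the basin and golden-section refinement polishes
#' the minimizer.
#'
#' @param data A kinetic dataset.
#' @param gss,h2s Fixed branch parameters ([mm_truth()]).
#' @param grid_n Number of grid points in the initial scan.
#' @param tol Absolute refinement tolerance on `c1`, uM.
#' @return An object of class `dual_mm_fit`: list with `model` (the fitted
#'   [dual_mm_model()]), `c1`, `residual_ss`, `converged`.
#' @export
fit_c1 <- function(data, gss, h2s, grid_n = 512L, tol = 1e-6) {
  validate_kinetic_dataset(data)
  stopifnot(inherits(gss, "mm_truth"), inherits(h2s, "mm_truth"))
  s <- data$substrate_uM
  v <- data$rate_nmol_min_mg
  s_max <- max(s)
  if (s_max <= 0) stop("fit_c1 requires at least one positive concentration", call. = FALSE)

  rss <- function(c1) {
    m <- dual_mm_model(gss, h2s, c1)
    sum((v - predict_dual_mm(m, s))^2)
  }
  grid <- seq(0, s_max, length.out = grid_n)
  vals <- vapply(grid, rss, numeric(1))
  i <- which.min(vals)

  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  if (lo < hi) {
    opt <- stats::optimize(rss, lower = lo, upper = hi, tol = tol)
    c1_hat <- opt$minimum
    rss_hat <- opt$objective
  } else {
    c1_hat <- grid[i]
    rss_hat <- vals[i]
  }
  # The interior optimum can be masked by the golden-section bracket when the
  # true minimizer sits at a boundary of [0, s_max]; check both ends.
  for (b in c(0, s_max)) {
    rb <- rss(b)
    if (rb < rss_hat) {
      c1_hat <- b
      rss_hat <- rb
    }
  }
  structure(list(
    model = dual_mm_model(gss, h2s, c1_hat),
    c1 = c1_hat,
    residual_ss = rss_hat,
    converged = TRUE
  ), class = "dual_mm_fit")
}

#' @export
print.dual_mm_fit <- function(x, ...) {
  cat(sprintf("Dual-MM breakpoint fit: C1 = %.4f uM (residual SS = %.6g)\n",
              x$c1, x$residual_ss))
  invisible(x)
}
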