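#' Demo pipeline configuration
#'
#' A self-contained configuration that simulates all three input families and
#' runs every analysis stage. Kinetic truths use the published parameter pairs
#' for the disulfide substrate (Km 331 uM, Vmax 260 nmol/min/mg), the
#' persulfide branch (209, 392) and the free-H2S branch (1978, 5.37); the
#' PIE fixture plants four strong and two weak clusters; the trajectories
#' emulate the unhindered (phi near 135 degrees) and hindered (phi near 75
#' degrees) ligands.
#'
#' @param out_dir Output directory for stage envelopes.
#' @param seed Master seed; each stage derives its own sub-seed.
#' @return A named list understood by [run_pipeline()].
#' @export
demo_config <- function(out_dir = tempfile("rssmet_demo_"), seed = 1L) {
  list(
    stages = c("simulate", "fit_kinetics", "cluster_pie", "geometry"),
    out_dir = out_dir,
    seed = as.integer(seed),
    kinetics = list(
      mm_truth = list(km = 331, vmax = 260),
      gss = list(km = 209, vmax = 392),
      h2s = list(km = 1978, vmax = 5.37),
      c1 = 50,
      concentrations = c(0, 20, 200, 2000),
      n_rep = 3L,
      noise_sd = 5
    ),
    cluster = list(
      n_fragments = 12L,
      n_strong = 4L, n_weak = 2L,
      strong_mean_total = -260, weak_mean_total = -120,
      cluster_size = 20L, within_sd = 2,
      alpha = 0.05
    ),
    geometry = list(
      n_frames = 2000L,
      unhindered_phi = list(dist = "normal", mean = 135, sd = 15),
      hindered_phi = list(dist = "normal", mean = 75, sd = 15),
      d_dist = list(dist = "normal", mean = 3.6, sd = 0.3),
      theta_dist = list(dist = "normal", mean = 165, sd = 10),
      d_max = 4.0, theta_range = c(150, 180),
      phi_range = c(100, 180), bin_width = 10
    )
  )
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path", call. = FALSE)
  known <- c("simulate", "fit_kinetics", "cluster_pie", "geometry")
  if (is.null(config$stages) || !all(config$stages %in% known)) {
    bad <- setdiff(config$stages, known)
    stop("unknown pipeline stage(s): ",
         if (length(bad)) paste(bad, collapse = ", ") else "(none given)",
         call. = FALSE)
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) stop("config must name an out_dir", call. = FALSE)
  config
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the requested stages in order — `simulate` (synthetic kinetic
#' table, PIE matrix, trajectories), `fit_kinetics` (single-substrate MM fit
#' and C1 breakpoint fit), `cluster_pie` (clustering + Tukey-Kramer + stable
#' set), `geometry` (reactive-frame extraction and optimal-phi fractions) —
#' writing one JSON result envelope per stage into `config$out_dir`. Fully
#' deterministic given identical configuration and seed.
#'
#' @param config A configuration list (see [demo_config()]) or path to a YAML
#'   file with the same structure.
#' @return Named list of `result_envelope` objects, invisibly; envelopes are
#'   also written as `<stage>.json` under `config$out_dir`.
#' @export
run_pipeline <- function(config = demo_config()) {
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  envelopes <- list()
  state <- new.env(parent = emptyenv())

  for (stage in config$stages) {
    env <- switch(stage,
      simulate = stage_simulate(config, state),
      fit_kinetics = stage_fit_kinetics(config, state),
      cluster_pie = stage_cluster_pie(config, state),
      geometry = stage_geometry(config, state)
    )
    write_result_json(env, file.path(config$out_dir, paste0(stage, ".json")))
    envelopes[[stage]] <- env
  }
  invisible(envelopes)
}

stage_simulate <- function(config, state) {
  kc <- config$kinetics
  seed <- config$seed
  design <- kinetic_design(kc$concentrations, n_rep = kc$n_rep,
                           noise_sd = kc$noise_sd, seed = seed)
  state$mm_truth <- mm_truth(kc$mm_truth$km, kc$mm_truth$vmax)
  state$gss <- mm_truth(kc$gss$km, kc$gss$vmax)
  state$h2s <- mm_truth(kc$h2s$km, kc$h2s$vmax)
  state$kinetic_mm <- gen_mm_rates(state$mm_truth, design, condition = "Na2S2")
  dual_design <- kinetic_design(kc$concentrations, n_rep = kc$n_rep,
                                noise_sd = kc$noise_sd, seed = seed + 1L)
  state$kinetic_dual <- gen_dual_mm_rates(state$gss, state$h2s, kc$c1,
                                          dual_design, condition = "Na2S+GSH")

  cc <- config$cluster
  k <- cc$n_strong + cc$n_weak
  profiles <- lapply(seq_len(k), function(i) {
    total <- if (i <= cc$n_strong) cc$strong_mean_total else cc$weak_mean_total
    # spread the total over fragments with a rotated per-cluster shape, so
    # clusters with equal totals remain well separated in profile space
    w <- ((seq_len(cc$n_fragments) + 3L * i) %% cc$n_fragments) + 1L
    total * w / sum(w)
  })
  spec <- pie_cluster_spec(profiles, rep(cc$cluster_size, k),
                           within_sd = cc$within_sd, seed = seed + 2L)
  state$pie <- gen_pie_matrix(spec)

  gc_ <- config$geometry
  state$traj <- list(
    unhindered = gen_trajectory(geom_spec(gc_$n_frames, gc_$d_dist,
                                          gc_$theta_dist, gc_$unhindered_phi,
                                          seed = seed + 3L)),
    hindered = gen_trajectory(geom_spec(gc_$n_frames, gc_$d_dist,
                                        gc_$theta_dist, gc_$hindered_phi,
                                        seed = seed + 4L))
  )

  kin_path <- file.path(config$out_dir, "kinetics_mm.csv")
  write_kinetic_csv(state$kinetic_mm, kin_path)
  write_kinetic_csv(state$kinetic_dual, file.path(config$out_dir, "kinetics_dual.csv"))
  write_pie_tsv(state$pie$matrix, file.path(config$out_dir, "pie.tsv"))
  write_xyz(state$traj$unhindered, file.path(config$out_dir, "traj_unhindered.xyz"))
  write_xyz(state$traj$hindered, file.path(config$out_dir, "traj_hindered.xyz"))

  result_envelope("simulate",
                  parameters = list(seed = seed, kinetics = kc,
                                    cluster = cc, geometry = gc_),
                  payload = list(
                    n_kinetic_rows = nrow(state$kinetic_mm),
                    n_conformations = nrow(state$pie$matrix),
                    n_frames = gc_$n_frames))
}

stage_fit_kinetics <- function(config, state) {
  if (is.null(state$kinetic_mm)) {
    stop("fit_kinetics: no simulated kinetic data; run the simulate stage first",
         call. = FALSE)
  }
  fit <- fit_mm(state$kinetic_mm)
  c1_fit <- fit_c1(state$kinetic_dual, state$gss, state$h2s)
  result_envelope("fit_kinetics",
                  parameters = list(seed = config$seed),
                  payload = list(
                    mm = list(km = fit$km, vmax = fit$vmax,
                              efficiency = fit$efficiency,
                              residual_ss = fit$residual_ss,
                              converged = fit$converged),
                    c1 = list(c1 = c1_fit$c1,
                              residual_ss = c1_fit$residual_ss)),
                  input_paths = file.path(config$out_dir,
                                          c("kinetics_mm.csv", "kinetics_dual.csv")))
}

stage_cluster_pie <- function(config, state) {
  if (is.null(state$pie)) {
    stop("cluster_pie: no simulated PIE matrix; run the simulate stage first",
         call. = FALSE)
  }
  cc <- config$cluster
  res <- identify_stable_conformations(state$pie$matrix,
                                       n_clusters = cc$n_strong + cc$n_weak,
                                       alpha = cc$alpha)
  result_envelope("cluster_pie",
                  parameters = list(seed = config$seed, alpha = cc$alpha),
                  payload = list(
                    per_cluster_stats = res$per_cluster_stats,
                    letters = as.list(res$letters),
                    stable_ids = res$stable_ids),
                  input_paths = file.path(config$out_dir, "pie.tsv"))
}

stage_geometry <- function(config, state) {
  if (is.null(state$traj)) {
    stop("geometry: no simulated trajectories; run the simulate stage first",
         call. = FALSE)
  }
  gc_ <- config$geometry
  summarize <- function(traj) {
    geom <- trajectory_geometry(traj)
    s <- steric_summary(geom, d_max = gc_$d_max, theta_range = gc_$theta_range,
                        phi_range = gc_$phi_range, bin_width = gc_$bin_width)
    list(n_frames_total = s$n_frames_total, n_extracted = s$n_extracted,
         n_optimal = s$n_optimal, optimal_fraction = s$optimal_fraction,
         phi_histogram = s$phi_histogram)
  }
  result_envelope("geometry",
                  parameters = list(seed = config$seed, d_max = gc_$d_max,
                                    theta_range = gc_$theta_range,
                                    phi_range = gc_$phi_range),
                  payload = list(unhindered = summarize(state$traj$unhindered),
                                 hindered = summarize(state$traj$hindered)),
                  input_paths = file.path(config$out_dir,
                                          c("traj_unhindered.xyz", "traj_hindered.xyz")))
}
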