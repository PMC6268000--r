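#' Simulation-plan bookkeeping
#'
#' Records a sampling design as entries of (label, number of initial
#' conformations, replicas per conformation, run duration). Used to
#' reproduce total-sampling figures for a study plan, e.g. 16 initial
#' conformations x 6 replicas x 10 us of coarse-grained sampling.
#'
#' @param label entry labels.
#' @param n_conformations initial conformations per entry (>= 1).
#' @param n_replicas independent replicas per conformation (>= 1).
#' @param duration duration of one run.
#' @param unit time unit per entry: "ns", "us" or "ms".
#' @return object of class `simulation_plan`.
#' @export
simulation_plan <- function(label, n_conformations, n_replicas, duration,
                            unit) {
  df <- data.frame(label = label, n_conformations = n_conformations,
                   n_replicas = n_replicas, duration = duration,
                   unit = unit, stringsAsFactors = FALSE)
  if (any(df$n_conformations < 1) || any(df$n_replicas < 1))
    stop("counts must be >= 1")
  if (any(df$duration <= 0)) stop("durations must be > 0")
  bad <- setdiff(unique(df$unit), c("ns", "us", "ms"))
  if (length(bad)) stop("unknown time unit(s): ", paste(bad, collapse = ", "))
  structure(list(entries = df), class = "simulation_plan")
}

.to_us <- c(ns = 1e-3, us = 1, ms = 1e3)

#' Total sampling time of a simulation plan
#'
#' Per entry, total = conformations x replicas x duration, converted to
#' microseconds. Values are exact; rounding to 2 significant figures happens
#' only in the `display` column.
#'
#' @param plan a [simulation_plan()].
#' @return data frame with per-entry totals (us) and display strings, plus
#'   attribute `"overall_us"`.
#' @export
plan_total_time <- function(plan) {
  e <- plan$entries
  tot <- e$n_conformations * e$n_replicas * e$duration * .to_us[e$unit]
  out <- data.frame(label = e$label, total_us = unname(tot),
                    display = paste0(signif(unname(tot), 2), " us"),
                    stringsAsFactors = FALSE)
  attr(out, "overall_us") <- sum(tot)
  out
}

#' Validate a pipeline run configuration
#'
#' A configuration lists the systems (synthetic specs and/or trajectory
#' files), the stage parameters and an explicit seed for every stochastic
#' stage. Configurations without explicit seeds are refused: reproducibility
#' is not optional.
#'
#' @param systems list of systems; each a list with `label` and either
#'   `synthetic` (arguments for [synthetic_ensemble_spec()], basins given as
#'   lists of [basin_spec()] arguments) or `traj` + `format` +
#'   `linkage_spec` for [read_conjugate()].
#' @param out_dir output directory.
#' @param seeds named list; must contain `landmarks`, `fit` and, when any
#'   system is synthetic, `synth`.
#' @param rmd,sketchmap,landscape,sasa stage parameter lists (defaults
#'   applied for omitted entries).
#' @return validated config object of class `run_config`.
#' @export
run_config <- function(systems, out_dir, seeds,
                       rmd = list(), sketchmap = list(), landscape = list(),
                       sasa = list()) {
  if (!length(systems)) stop("at least one system is required")
  labels <- vapply(systems, function(s) s$label %||% "", character(1))
  if (any(labels == "")) stop("every system needs a label")
  if (anyDuplicated(labels)) stop("system labels must be unique")
  any_synth <- any(vapply(systems, function(s) !is.null(s$synthetic),
                          logical(1)))
  need <- c("landmarks", "fit", if (any_synth) "synth")
  miss <- setdiff(need, names(seeds))
  if (length(miss))
    stop("refusing to run without explicit seed(s): ",
         paste(miss, collapse = ", "))
  for (s in systems) {
    if (is.null(s$synthetic)) {
      if (is.null(s$traj) || !file.exists(s$traj))
        stop("input trajectory not found for system '", s$label, "'")
      if (is.null(s$linkage_spec))
        stop("system '", s$label, "' needs a linkage_spec")
    }
  }
  defaults <- list(
    rmd = list(stride = 1),
    sketchmap = list(n_landmarks = 200, gamma = 0.1,
                     sigma = 5.9, a_hd = 12, b_hd = 4, a_ld = 2, b_ld = 4,
                     max_iter = 1000, tol = 1e-6),
    landscape = list(bins = 100, temperature = 300, k_minima = 5,
                     min_count = 2),
    sasa = list(enabled = FALSE, probe_radius = 0.21, n_points = 240,
                stride = 1))
  merge1 <- function(d, u) { d[names(u)] <- u; d }
  structure(list(systems = systems, out_dir = out_dir, seeds = seeds,
                 rmd = merge1(defaults$rmd, rmd),
                 sketchmap = merge1(defaults$sketchmap, sketchmap),
                 landscape = merge1(defaults$landscape, landscape),
                 sasa = merge1(defaults$sasa, sasa)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.load_system <- function(s, seeds) {
  if (!is.null(s$synthetic)) {
    args <- s$synthetic
    args$basins <- lapply(args$basins, function(b)
      if (inherits(b, "basin_spec")) b else do.call(basin_spec, b))
    if (is.null(args$seed)) args$seed <- seeds$synth
    sample_conjugate_ensemble(do.call(synthetic_ensemble_spec, args))
  } else {
    list(trajectory = read_conjugate(s$traj, format = s$format %||% "pdb",
                                     linkage_spec = s$linkage_spec),
         labels = NULL)
  }
}

#' Run the full landscape-comparison pipeline
#'
#' Stages: load or generate each system, compute RMD descriptors, select
#' landmarks and fit one sketch-map on the pooled descriptors, project every
#' system, build densities and Boltzmann-inverted free-energy surfaces, find
#' minima, compute the pairwise (normalized) EMD matrix and the similarity
#' arrangement, and optionally interface SASA statistics. All artifacts are
#' written under `config$out_dir` along with a machine-readable
#' `report.json` and a provenance record (package version, seeds,
#' parameters). Payloads contain no timestamps, so a rerun with identical
#' config and seeds is byte-identical.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return the report list, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  labels <- vapply(config$systems, `[[`, character(1), "label")

  say("[1/6] loading %d system(s)", length(config$systems))
  loaded <- lapply(config$systems, .load_system, seeds = config$seeds)
  names(loaded) <- labels

  say("[2/6] RMD descriptors")
  rmds <- lapply(loaded, function(x)
    rmd_series(x$trajectory, stride = config$rmd$stride))
  for (l in labels)
    write_rmd(rmds[[l]], file.path(config$out_dir,
                                   paste0("rmd_", l, ".tsv")))

  say("[3/6] sketch-map (landmarks + fit on pooled descriptors)")
  pooled <- do.call(rbind, rmds)
  sp <- config$sketchmap
  params <- sigmoid_params(sp$sigma, sp$a_hd, sp$b_hd, sp$a_ld, sp$b_ld)
  lm <- select_landmarks(pooled, n = min(sp$n_landmarks, nrow(pooled)),
                         gamma = sp$gamma, seed = config$seeds$landmarks)
  model <- fit_sketchmap(lm, params, seed = config$seeds$fit,
                         max_iter = sp$max_iter, tol = sp$tol)
  write_sketchmap(model, file.path(config$out_dir, "sketchmap.json"))

  say("[4/6] projection, densities, free-energy surfaces")
  projs <- lapply(rmds, sketchmap_project, model = model)
  # shared grid so the landscapes are comparable
  allp <- do.call(rbind, projs)
  rng <- list(x = range(allp[, 1]), y = range(allp[, 2]))
  ls_cfg <- config$landscape
  dens <- lapply(projs, density2d, bins = ls_cfg$bins, range = rng)
  fess <- lapply(dens, free_energy_surface,
                 temperature_K = ls_cfg$temperature)
  minima <- lapply(fess, function(f)
    tryCatch(find_minima(f, k = ls_cfg$k_minima,
                         min_count = ls_cfg$min_count),
             error = function(e) NULL))
  for (l in labels) {
    write.table(data.frame(projs[[l]]),
                file.path(config$out_dir, paste0("proj_", l, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(minima[[l]]))
      write.table(minima[[l]],
                  file.path(config$out_dir, paste0("minima_", l, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }

  emd <- NULL; coords <- NULL
  if (length(dens) >= 2) {
    say("[5/6] pairwise EMD + similarity arrangement")
    emd <- pairwise_emd(dens, normalize = TRUE, labels = labels)
    coords <- arrange_by_similarity(emd)
    write.table(data.frame(system = labels, emd$m, check.names = FALSE),
                file.path(config$out_dir, "emd.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(system = labels, coords),
                file.path(config$out_dir, "similarity_coords.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else say("[5/6] single system; skipping EMD")

  iface <- NULL
  if (isTRUE(config$sasa$enabled)) {
    say("[6/6] interface SASA statistics")
    iface <- lapply(loaded, function(x)
      interface_report(x$trajectory,
                       probe_radius = config$sasa$probe_radius,
                       n_points = config$sasa$n_points,
                       stride = config$sasa$stride))
  } else say("[6/6] SASA stage disabled")

  report <- list(
    systems = labels,
    n_frames = vapply(loaded, function(x) n_frames(x$trajectory), 0),
    rmd_dim = vapply(rmds, ncol, 0L),
    sketchmap = list(n_landmarks = nrow(model$coords),
                     stress = model$stress,
                     init_stress = model$init_stress,
                     converged = model$converged),
    minima = lapply(minima, function(m)
      if (is.null(m)) NULL else m[, c("x", "y", "depth_kt", "depth_kjmol")]),
    emd = if (!is.null(emd))
      list(matrix = emd$m, normalized = emd$normalized,
           norm_const = emd$norm_const),
    similarity_coords = coords,
    interface = if (!is.null(iface))
      lapply(iface, function(r) as.list(r$mean)),
    provenance = list(
      package = "conjmap",
      version = as.character(utils::packageVersion("conjmap")),
      seeds = config$seeds,
      parameters = config[c("rmd", "sketchmap", "landscape", "sasa")]))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  invisible(report)
}
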