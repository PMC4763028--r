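#' Assemble a pipeline run configuration
#'
#' @param phantom either a `voxel_phantom` or a list
#'   `list(archetype = , seed = , spacing = )` describing one to generate.
#' @param gantry_angles numeric vector of beam angles in degrees (>= 1).
#' @param energy_mode `"auto"` for per-angle selection via the energy
#'   look-up table, or a numeric MV (scalar or one per beam) for fixed
#'   energies.
#' @param prescription prescription dose in Gy (> 0).
#' @param oar_constraints list of [dv_constraint()]s.
#' @param controls an [optimizer_controls()] list.
#' @param output_dir directory for run artifacts; `NULL` for none.
#' @param seed global seed recorded in the manifest and used for any
#'   stochastic stage.
#' @export
run_config <- function(phantom, gantry_angles, energy_mode = "auto",
                       prescription = 50, oar_constraints = list(),
                       controls = optimizer_controls(), output_dir = NULL,
                       seed = 1) {
  if (length(gantry_angles) < 1)
    .emxrt_stop("emxrt_config", "at least one beam is required")
  if (prescription <= 0)
    .emxrt_stop("emxrt_config", "prescription must be positive")
  if (!(identical(energy_mode, "auto") || is.numeric(energy_mode)))
    .emxrt_stop("emxrt_config", "energy_mode must be 'auto' or numeric MV")
  structure(list(phantom = phantom, gantry_angles = gantry_angles,
                 energy_mode = energy_mode, prescription = prescription,
                 oar_constraints = oar_constraints, controls = controls,
                 output_dir = output_dir, seed = seed),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Expected keys: `phantom` (`archetype`, `seed`, `spacing`), `beams`
#' (list of `gantry` and optional `energy`), `prescription`,
#' `constraints` (list of `structure`, `threshold`, `volume`, `direction`,
#' `weight`), `output_dir`, `seed`.
#'
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (key in c("phantom", "beams", "prescription"))
    if (is.null(y[[key]]))
      .emxrt_stop("emxrt_config", "config is missing the '%s' key", key)
  angles <- vapply(y$beams, function(b) as.numeric(b$gantry), numeric(1))
  energies <- lapply(y$beams, function(b) b$energy)
  mode <- if (all(vapply(energies, is.null, logical(1)))) "auto"
          else vapply(energies, function(e) as.numeric(e %||% NA), numeric(1))
  cons <- lapply(y$constraints %||% list(), function(cn)
    dv_constraint(cn$structure, cn$threshold, cn$volume,
                  cn$direction %||% "upper", cn$weight %||% 1))
  run_config(phantom = y$phantom, gantry_angles = angles, energy_mode = mode,
             prescription = y$prescription, oar_constraints = cons,
             output_dir = y$output_dir, seed = y$seed %||% 1)
}

# internal: materialize the phantom of a config
.resolve_phantom <- function(cfg) {
  ph <- cfg$phantom
  if (inherits(ph, "voxel_phantom")) return(ph)
  make_archetype(ph$archetype, seed = ph$seed %||% cfg$seed,
                 spacing = ph$spacing %||% 0.25)
}

#' Run the full planning pipeline
#'
#' Executes phantom generation, ray tracing, per-beam energy assignment
#' (look-up table when `energy_mode = "auto"`), dose-deposition-matrix
#' computation, beamlet-weight optimization, prescription normalization and
#' metric evaluation. Deterministic for identical configurations.
#'
#' @param config a [run_config()].
#' @param beams a `beam_set` (defaults to the packaged 2-10 MV pool).
#' @param table an `energy_table` for `"auto"` mode; built with default
#'   conventions when not supplied.
#' @return list of run artifacts: `phantom`, `assignment` (per-beam EP, TS,
#'   energy), `weights`, `state`, `dose` (normalized), `metrics`, `dvhs`,
#'   and `manifest`. When `config$output_dir` is set, `metrics.csv`,
#'   `dvh.csv`, `weights.csv`, `assignment.csv` and `manifest.json` are
#'   written there.
#' @export
run_pipeline <- function(config, beams = default_beams(), table = NULL) {
  stopifnot(inherits(config, "run_config"))
  phantom <- .resolve_phantom(config)
  iso <- phantom$isocenter %||% ptv_centroid(phantom)
  angles <- config$gantry_angles
  if (identical(config$energy_mode, "auto")) {
    if (is.null(table)) table <- build_energy_table(beams = beams)
    assignment <- assign_beam_energies(phantom, angles, table, isocenter = iso)
  } else {
    mv <- rep(config$energy_mode, length.out = length(angles))
    assignment <- do.call(rbind, lapply(seq_along(angles), function(i) {
      tr <- trace_four_points(phantom, beam_ray(angles[i], iso))
      data.frame(gantry_deg = angles[i], EP = tr$EP, TS = tr$TS,
                 energy_mv = mv[i])
    }))
  }
  ddcs <- vector("list", length(angles))
  inits <- vector("list", length(angles))
  for (i in seq_along(angles)) {
    ray <- beam_ray(angles[i], iso)
    grid <- beamlet_grid(phantom, ray)
    e <- as.character(assignment$energy_mv[i])
    ddcs[[i]] <- compute_ddc(phantom, grid, beams$curves[[e]],
                             beams$profiles[[e]])
    inits[[i]] <- ciao_init(grid, phantom)
  }
  ddc <- combine_ddc(ddcs)
  obj <- plan_objective(config$prescription,
                        oar_constraints = config$oar_constraints)
  fit <- optimize_weights(ddc, obj, phantom, unlist(inits),
                          controls = config$controls)
  dose <- accumulate_dose(ddc, fit$weights)
  dose <- normalize_plan(dose, phantom$structures$PTV, config$prescription)
  metrics <- plan_metrics(dose, phantom)
  dvhs <- lapply(setdiff(names(phantom$structures), "BODY"), function(nm)
    compute_dvh(dose, phantom$structures[[nm]], voxel_volume(phantom), nm))
  names(dvhs) <- setdiff(names(phantom$structures), "BODY")
  manifest <- list(
    package_version = as.character(utils::packageVersion("emxrt")),
    seed = config$seed,
    prescription = config$prescription,
    gantry_angles = angles,
    energy_mode = if (identical(config$energy_mode, "auto")) "auto" else
      as.numeric(config$energy_mode),
    energies_assigned = assignment$energy_mv,
    n_beamlets = ncol(ddc$A),
    stop_reason = fit$state$stop_reason,
    iterations = fit$state$iterations)
  out <- list(phantom = phantom, assignment = assignment,
              weights = fit$weights, state = fit$state, dose = dose,
              metrics = metrics, dvhs = dvhs, manifest = manifest)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    wp <- function(f) file.path(config$output_dir, f)
    write.csv(metrics, wp("metrics.csv"), row.names = FALSE)
    write.csv(assignment, wp("assignment.csv"), row.names = FALSE)
    write.csv(data.frame(beam = ddc$beam_of,
                         beamlet = seq_along(fit$weights),
                         weight = fit$weights),
              wp("weights.csv"), row.names = FALSE)
    curves <- do.call(rbind, lapply(names(dvhs), function(nm)
      cbind(structure = nm, dvh_curve(dvhs[[nm]]))))
    write.csv(curves, wp("dvh.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, wp("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(out)
}
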