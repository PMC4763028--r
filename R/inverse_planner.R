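#' Dose-volume constraint
#'
#' An upper constraint `(p, v)` asks that no more than `v`% of the structure
#' receive more than dose `p`; a lower constraint that no more than `v`%
#' receive less than `p` (i.e. at least `100 - v`% is covered by `p`).
#'
#' @param structure structure mask name in the phantom.
#' @param threshold threshold dose `p` in Gy (>= 0).
#' @param volume allowed volume fraction `v` in percent, in (0, 100).
#' @param direction "upper" or "lower".
#' @param weight nonnegative penalty weight.
#' @export
dv_constraint <- function(structure, threshold, volume,
                          direction = c("upper", "lower"), weight = 1) {
  direction <- match.arg(direction)
  stopifnot(threshold >= 0, volume > 0, volume < 100, weight >= 0)
  structure(list(structure = structure, threshold = threshold,
                 volume = volume, direction = direction, weight = weight),
            class = "dv_constraint")
}

#' Plan objective: prescription plus dose-volume penalties
#'
#' Quadratic objective over the target voxels,
#' `sum((d_i - p0)^2)`, augmented by penalty terms
#' `r * w * sum(delta_i * (d_i - p)^2)` for each dose-volume constraint of
#' the target and of every critical structure, where the flags `delta_i`
#' mark the voxels currently violating the constraint (see
#' [violation_flags()]) and `r` is a penalty factor escalated across
#' iterations.
#'
#' @param prescription prescription dose `p0` in Gy (> 0).
#' @param target name of the target mask (default `"PTV"`).
#' @param target_constraints list of up to two [dv_constraint()]s on the
#'   target; the default pair asks >= 95% coverage at `0.98 * p0` and caps
#'   hot spots at `1.08 * p0` on more than 5% of the volume.
#' @param oar_constraints list of [dv_constraint()]s on critical structures.
#' @param oar_weights optional named per-structure weights (default 1).
#' @param r0 initial penalty factor (> 0).
#' @param r_growth multiplicative escalation factor (>= 1).
#' @param r_interval iterations between escalations.
#' @export
plan_objective <- function(prescription, target = "PTV",
                           target_constraints = list(
                             dv_constraint(target, 0.98 * prescription, 5,
                                           "lower"),
                             dv_constraint(target, 1.08 * prescription, 5,
                                           "upper")),
                           oar_constraints = list(),
                           oar_weights = NULL,
                           r0 = 1, r_growth = 2, r_interval = 20) {
  stopifnot(prescription > 0, r0 > 0, r_growth >= 1,
            length(target_constraints) <= 2)
  structure(list(prescription = prescription, target = target,
                 target_constraints = target_constraints,
                 oar_constraints = oar_constraints,
                 oar_weights = oar_weights,
                 r0 = r0, r_growth = r_growth, r_interval = r_interval),
            class = "plan_objective")
}

#' Violation flags of a dose-volume constraint
#'
#' Standard DVH-penalty gating: for an upper constraint `(p, v)` let `Dv` be
#' the current dose at volume `v`% (the coolest dose of the hottest `v`%).
#' If `Dv > p` the constraint is violated and the flags mark the voxels with
#' `p < d <= Dv` — the allowed hottest fraction is left alone. Lower
#' constraints are gated symmetrically on the coldest fraction.
#'
#' @param doses numeric vector of the structure's voxel doses.
#' @param constraint a [dv_constraint()].
#' @return logical vector, `TRUE` where the constraint is violated.
#' @export
violation_flags <- function(doses, constraint) {
  p <- constraint$threshold; v <- constraint$volume
  if (constraint$direction == "upper") {
    Dv <- quantile(doses, 1 - v / 100, names = FALSE, type = 7)
    doses > p & doses <= max(Dv, p)
  } else {
    Dc <- quantile(doses, v / 100, names = FALSE, type = 7)
    doses < p & doses >= min(Dc, p)
  }
}

# internal: resolve structure voxel positions within the DDC row space
.structure_rows <- function(phantom, ddc, name) {
  m <- phantom$structures[[name]]
  if (is.null(m))
    .emxrt_stop("emxrt_config", "structure '%s' missing from phantom", name)
  rows <- match(which(m), ddc$voxel_index)
  rows[!is.na(rows)]
}

#' Evaluate the plan objective
#'
#' @param x beamlet weights.
#' @param ddc a `ddc_matrix` (typically [combine_ddc()] over all beams).
#' @param obj a [plan_objective()].
#' @param phantom the `voxel_phantom`.
#' @param r penalty factor; defaults to the objective's `r0`.
#' @param dose optional precomputed `ddc$A %*% x` (body-voxel doses).
#' @return list with `value`, the per-term breakdown `terms`, and `flags`
#'   (list of logical vectors per constraint).
#' @export
evaluate_objective <- function(x, ddc, obj, phantom, r = obj$r0,
                               dose = NULL) {
  d <- if (is.null(dose)) as.numeric(ddc$A %*% x) else dose
  rows_t <- .structure_rows(phantom, ddc, obj$target)
  dt <- d[rows_t]
  f_target <- sum((dt - obj$prescription)^2)
  flags <- list(); pen_t <- 0; pen_c <- 0
  for (k in seq_along(obj$target_constraints)) {
    cn <- obj$target_constraints[[k]]
    fl <- violation_flags(dt, cn)
    flags[[paste0("target_", k)]] <- fl
    pen_t <- pen_t + cn$weight * sum((dt[fl] - cn$threshold)^2)
  }
  for (k in seq_along(obj$oar_constraints)) {
    cn <- obj$oar_constraints[[k]]
    rows <- .structure_rows(phantom, ddc, cn$structure)
    dc <- d[rows]
    fl <- violation_flags(dc, cn)
    flags[[paste0(cn$structure, "_", k)]] <- fl
    wn <- 1
    if (!is.null(obj$oar_weights) && cn$structure %in% names(obj$oar_weights))
      wn <- obj$oar_weights[[cn$structure]]
    pen_c <- pen_c + wn * cn$weight * sum((dc[fl] - cn$threshold)^2)
  }
  list(value = f_target + r * pen_t + r * pen_c,
       terms = c(target = f_target, target_penalty = r * pen_t,
                 oar_penalty = r * pen_c),
       flags = flags)
}

#' Gradient of the plan objective with respect to the beamlet weights
#'
#' Analytic gradient with the violation flags held fixed at the current dose
#' (subgradient convention at the flag switching surfaces).
#'
#' @inheritParams evaluate_objective
#' @param flags optional flags to hold fixed; recomputed from the current
#'   dose when `NULL`.
#' @return numeric gradient, one entry per beamlet.
#' @export
objective_gradient <- function(x, ddc, obj, phantom, r = obj$r0,
                               dose = NULL, flags = NULL) {
  d <- if (is.null(dose)) as.numeric(ddc$A %*% x) else dose
  if (is.null(flags))
    flags <- evaluate_objective(x, ddc, obj, phantom, r, dose = d)$flags
  res <- numeric(length(d))
  rows_t <- .structure_rows(phantom, ddc, obj$target)
  dt <- d[rows_t]
  res[rows_t] <- res[rows_t] + 2 * (dt - obj$prescription)
  for (k in seq_along(obj$target_constraints)) {
    cn <- obj$target_constraints[[k]]
    fl <- flags[[paste0("target_", k)]]
    res[rows_t[fl]] <- res[rows_t[fl]] +
      2 * r * cn$weight * (dt[fl] - cn$threshold)
  }
  for (k in seq_along(obj$oar_constraints)) {
    cn <- obj$oar_constraints[[k]]
    rows <- .structure_rows(phantom, ddc, cn$structure)
    fl <- flags[[paste0(cn$structure, "_", k)]]
    wn <- 1
    if (!is.null(obj$oar_weights) && cn$structure %in% names(obj$oar_weights))
      wn <- obj$oar_weights[[cn$structure]]
    res[rows[fl]] <- res[rows[fl]] +
      2 * r * wn * cn$weight * (d[rows[fl]] - cn$threshold)
  }
  as.numeric(Matrix::crossprod(ddc$A, res))
}

#' Beamlet weight initialization from the target projection
#'
#' Sets the weight of every beamlet whose axis intersects the PTV to one and
#' all others to zero — the beam's-eye-view aperture fitted to the target,
#' used as the optimizer's starting point.
#'
#' @param grid a `beamlet_grid`.
#' @param phantom the `voxel_phantom`.
#' @return 0/1 weight vector, one per beamlet.
#' @export
ciao_init <- function(grid, phantom) {
  ray <- grid$ray
  x <- vapply(seq_len(nrow(grid$centers)), function(j) {
    Pj <- ray$isocenter + grid$centers[j, 1] * grid$e1 +
      grid$centers[j, 2] * grid$e2
    uj <- Pj - ray$source
    uj <- uj / sqrt(sum(uj^2))
    cr <- .grid_crossings(phantom, ray$source, uj)
    if (is.null(cr)) return(0)
    as.numeric(any(phantom$structures$PTV[cr$idx]))
  }, numeric(1))
  if (all(x == 0))
    warning("no beamlet axis intersects the PTV; all-zero initialization")
  x
}

#' Optimizer controls
#'
#' @param max_iter iteration cap.
#' @param tol relative objective-change threshold for convergence.
#' @param tol_window consecutive small-change iterations required.
#' @param time_limit wall-clock cap in seconds.
#' @param step0 fixed trial step for the line search; `NULL` (default) uses
#'   the exact minimizing step of the flag-frozen quadratic along the
#'   negative gradient.
#' @param armijo sufficient-decrease constant of the backtracking search.
#' @export
optimizer_controls <- function(max_iter = 500, tol = 1e-5, tol_window = 5,
                               time_limit = Inf, step0 = NULL,
                               armijo = 1e-4) {
  list(max_iter = max_iter, tol = tol, tol_window = tol_window,
       time_limit = time_limit, step0 = step0, armijo = armijo)
}

#' Optimize beamlet weights by dose-volume-constrained steepest descent
#'
#' Projected steepest descent on [evaluate_objective()]: each iteration
#' recomputes the violation flags, steps along the negative gradient using
#' the exact minimizing step of the flag-frozen quadratic as the trial,
#' backtracks (Armijo) where projection or flag switches spoil it, projects
#' onto the nonnegative orthant, and escalates the penalty factor `r` on
#' the objective's schedule. Stops when the relative objective change stays below `tol` for
#' `tol_window` consecutive iterations at the current `r`, at `max_iter`, or
#' at the time limit.
#'
#' @param ddc a `ddc_matrix` over all beams ([combine_ddc()]).
#' @param obj a [plan_objective()].
#' @param phantom the `voxel_phantom`.
#' @param init initial weights (e.g. concatenated [ciao_init()] vectors).
#' @param controls an [optimizer_controls()] list.
#' @param scale_init scale the initial weights so the mean target dose
#'   equals the prescription (default TRUE); the 0/1 aperture weights are in
#'   arbitrary units, so this only fixes the starting dose scale.
#' @return list with `weights` and `state` (class `optimizer_state`):
#'   iteration count, per-iteration `history` (iteration, r, objective,
#'   step), and `stop_reason` in `converged`, `max_iter`, `time_limit`.
#' @export
optimize_weights <- function(ddc, obj, phantom, init,
                             controls = optimizer_controls(),
                             scale_init = TRUE) {
  x <- pmax(as.numeric(init), 0)
  if (length(x) != ncol(ddc$A))
    .emxrt_stop("emxrt_shape", "init length %d != %d beamlets",
                length(x), ncol(ddc$A))
  t_start <- proc.time()[["elapsed"]]
  r <- obj$r0
  rows_t <- .structure_rows(phantom, ddc, obj$target)
  if (scale_init) {
    mt <- mean(as.numeric(ddc$A %*% x)[rows_t])
    if (is.finite(mt) && mt > 0) x <- x * obj$prescription / mt
  }
  d <- as.numeric(ddc$A %*% x)
  ev <- evaluate_objective(x, ddc, obj, phantom, r, dose = d)
  f <- ev$value
  if (!is.finite(f))
    .emxrt_stop("emxrt_numerical", "non-finite objective at initialization")
  hist <- matrix(NA_real_, controls$max_iter + 1, 4,
                 dimnames = list(NULL, c("iteration", "r", "objective", "step")))
  hist[1, ] <- c(0, r, f, NA)
  # exact minimizing step of the (flag-frozen) quadratic along -g:
  # alpha* = g'g / g'Hg with H = 2 A_t'A_t + 2 r sum(w A_flagged'A_flagged)
  cauchy_step <- function(g, flags, r) {
    Ag <- as.numeric(ddc$A %*% g)
    den <- 2 * sum(Ag[rows_t]^2)
    for (k in seq_along(obj$target_constraints)) {
      cn <- obj$target_constraints[[k]]
      fl <- flags[[paste0("target_", k)]]
      den <- den + 2 * r * cn$weight * sum(Ag[rows_t[fl]]^2)
    }
    for (k in seq_along(obj$oar_constraints)) {
      cn <- obj$oar_constraints[[k]]
      rows <- .structure_rows(phantom, ddc, cn$structure)
      fl <- flags[[paste0(cn$structure, "_", k)]]
      wn <- 1
      if (!is.null(obj$oar_weights) && cn$structure %in% names(obj$oar_weights))
        wn <- obj$oar_weights[[cn$structure]]
      den <- den + 2 * r * wn * cn$weight * sum(Ag[rows[fl]]^2)
    }
    if (den > 0) sum(g^2) / den else NA_real_
  }
  small <- 0; it <- 0; stop_reason <- "max_iter"
  x_prev <- NULL; g_prev <- NULL
  while (it < controls$max_iter) {
    it <- it + 1
    if (it %% obj$r_interval == 0 && obj$r_growth > 1) {
      r <- r * obj$r_growth
      ev <- evaluate_objective(x, ddc, obj, phantom, r, dose = d)
      f <- ev$value
      small <- 0  # restart the convergence window at the new penalty level
    }
    g <- objective_gradient(x, ddc, obj, phantom, r, dose = d, flags = ev$flags)
    gn2 <- sum(g^2)
    if (gn2 == 0) { stop_reason <- "converged"; hist[it + 1, ] <- c(it, r, f, 0); break }
    # spectral (Barzilai-Borwein) step when history exists, else the exact
    # Cauchy step of the flag-frozen quadratic; Armijo backtracking below
    # keeps the descent monotone either way
    step_try <- controls$step0
    if (is.null(step_try) && !is.null(x_prev)) {
      s <- x - x_prev; yv <- g - g_prev
      sy <- sum(s * yv)
      if (sy > 0) step_try <- sum(s * s) / sy
    }
    if (is.null(step_try)) step_try <- cauchy_step(g, ev$flags, r)
    if (!is.finite(step_try) || step_try <= 0) {
      stop_reason <- "converged"; hist[it + 1, ] <- c(it, r, f, 0); break
    }
    x_prev <- x; g_prev <- g
    accepted <- FALSE
    for (ls in 1:40) {
      x_new <- pmax(x - step_try * g, 0)
      d_new <- as.numeric(ddc$A %*% x_new)
      ev_new <- evaluate_objective(x_new, ddc, obj, phantom, r, dose = d_new)
      f_new <- ev_new$value
      if (!is.finite(f_new))
        .emxrt_stop("emxrt_numerical", "non-finite objective at iteration %d", it)
      decrease <- sum(g * (x - x_new))  # projected-step decrease model
      if (f_new <= f - controls$armijo * decrease && f_new <= f) {
        accepted <- TRUE
        break
      }
      step_try <- step_try / 2
    }
    if (!accepted) { stop_reason <- "converged"; hist[it + 1, ] <- c(it, r, f, 0); break }
    rel <- abs(f - f_new) / max(abs(f), .Machine$double.eps)
    x <- x_new; d <- d_new; ev <- ev_new; f <- f_new
    hist[it + 1, ] <- c(it, r, f, step_try)
    small <- if (rel < controls$tol) small + 1 else 0
    if (small >= controls$tol_window) { stop_reason <- "converged"; break }
    if (proc.time()[["elapsed"]] - t_start > controls$time_limit) {
      stop_reason <- "time_limit"; break
    }
  }
  state <- structure(list(iterations = it, stop_reason = stop_reason,
                          r_final = r, objective = f,
                          history = as.data.frame(
                            hist[!is.na(hist[, 1]), , drop = FALSE])),
                     class = "optimizer_state")
  list(weights = x, state = state)
}

#' @export
print.optimizer_state <- function(x, ...) {
  cat(sprintf("<optimizer_state> %d iterations, %s; objective %.4g (r = %g)\n",
              x$iterations, x$stop_reason, x$objective, x$r_final))
  invisible(x)
}
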