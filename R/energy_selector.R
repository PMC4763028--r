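#' Ideal four-point dose template
#'
#' The desired relative doses at the four special points of a beam: low dose
#' at the skin (point 1) and beyond the target (point 4), full dose at the
#' target entrance and exit (points 2 and 3), expressing a homogeneous
#' target dose with sparing upstream and downstream.
#'
#' @param values four positive percents; defaults 10, 100, 100, 10.
#' @export
ideal_dose_template <- function(values = c(10, 100, 100, 10)) {
  stopifnot(length(values) == 4, all(values > 0))
  structure(as.numeric(values), class = "ideal_dose_template")
}

#' Four-point importance weights
#'
#' Relative importance of the four special points in the correlation score.
#' The skin dose carries half weight by default; target entrance/exit and
#' the exit dose carry full weight.
#'
#' @param values four positive weights; defaults 0.5, 1, 1, 1.
#' @export
point_weights <- function(values = c(0.5, 1, 1, 1)) {
  stopifnot(length(values) == 4, all(values > 0))
  structure(as.numeric(values), class = "point_weights")
}

#' Doses at the four special points from a depth-dose curve
#'
#' For a water-equivalent scenario with target of size `TS` centered at
#' depth `EP`, reads the percent doses at the skin (depth 0), the target
#' entrance (`EP - TS/2`), the target exit (`EP + TS/2`) and the body exit.
#'
#' @param curve a `pdd_curve`.
#' @param EP effective path length to the target center, cm.
#' @param TS tumor size (water-equivalent target extent), cm.
#' @param exit_depth depth of the body exit point; the default `2 * EP`
#'   places the exit symmetrically about the isocenter. The true phantom
#'   thickness behind the published look-up table is not stated, so this
#'   convention is configurable.
#' @return numeric length-4 vector of percent doses.
#' @export
four_point_doses <- function(curve, EP, TS, exit_depth = 2 * EP) {
  if (EP < TS / 2)
    .emxrt_stop("emxrt_geometry",
                "EP (%.2f) must be at least the target radius TS/2 (%.2f)", EP, TS / 2)
  if (exit_depth < EP + TS / 2)
    .emxrt_stop("emxrt_geometry",
                "exit_depth (%.2f) must be at least EP + TS/2 (%.2f)",
                exit_depth, EP + TS / 2)
  pdd_at(curve, c(0, EP - TS / 2, EP + TS / 2, exit_depth))
}

#' Four-point correlation-coefficient score
#'
#' Similarity between the ideal dose template and the realistic four-point
#' doses of a candidate energy. Three conventions are provided:
#' \describe{
#'   \item{cosine}{(default) weighted uncentered correlation
#'     `sum(w * D * d) / sqrt(sum(D^2) * sum(d^2))`; scale-invariant in each
#'     argument, equal to 1 with unit weights iff `d` is proportional to `D`.}
#'   \item{literal}{same numerator over the unrooted product
#'     `sum(D^2) * sum(d^2)`.}
#'   \item{centered}{weighted Pearson-style correlation of the deviations
#'     from the point means.}
#' }
#'
#' @param ideal an [ideal_dose_template()] (or length-4 positive vector).
#' @param realistic length-4 vector of percent doses (see
#'   [four_point_doses()]).
#' @param weights a [point_weights()] (or length-4 positive vector),
#'   applied in the numerator only.
#' @param form score convention.
#' @return a single numeric score.
#' @export
cc_score <- function(ideal = ideal_dose_template(), realistic,
                     weights = point_weights(),
                     form = c("cosine", "literal", "centered")) {
  form <- match.arg(form)
  D <- as.numeric(ideal); d <- as.numeric(realistic); w <- as.numeric(weights)
  stopifnot(length(D) == 4, length(d) == 4, length(w) == 4)
  if (any(d <= 0) || any(D <= 0) || any(w <= 0))
    .emxrt_stop("emxrt_domain", "all template, dose and weight values must be positive")
  if (sum(D^2) == 0 || sum(d^2) == 0)
    .emxrt_stop("emxrt_undefined_score", "zero-norm dose vector")
  switch(form,
    cosine = sum(w * D * d) / sqrt(sum(D^2) * sum(d^2)),
    literal = sum(w * D * d) / (sum(D^2) * sum(d^2)),
    centered = {
      Dc <- D - mean(D); dc <- d - mean(d)
      if (sum(dc^2) == 0)
        .emxrt_stop("emxrt_undefined_score", "degenerate (constant) dose vector")
      sum(w * Dc * dc) / sqrt(sum(Dc^2) * sum(dc^2))
    })
}

#' Select the optimal beam energy for an (EP, TS) scenario
#'
#' Scores every energy in the pool with [cc_score()] on its four-point doses
#' and returns the energy with the maximum score. Two clinical rules are
#' applied on top of the score: deep targets (`EP >=` `deep_ep`) always
#' receive the highest pool energy, and scenarios with `EP < TS/2` (target
#' sticking out of the skin) are rejected. Ties break toward the lower
#' energy.
#'
#' @param EP,TS effective path length and tumor size in cm.
#' @param beams a `beam_set` from [default_beams()].
#' @param weights,template,form see [cc_score()].
#' @param exit_depth function of `(EP, TS)` giving the body-exit depth
#'   convention; default `2 * EP`.
#' @param deep_ep override threshold in cm (default 18): at or beyond it the
#'   highest energy is chosen regardless of score.
#' @return selected nominal energy in MV, with attributes `scores` (named
#'   per-energy scores, absent under the deep override) and `margin` (score
#'   gap between the best and second-best energy).
#' @export
select_energy <- function(EP, TS, beams = default_beams(),
                          weights = point_weights(),
                          template = ideal_dose_template(),
                          form = "cosine",
                          exit_depth = function(EP, TS) 2 * EP,
                          deep_ep = 18) {
  if (EP < TS / 2)
    .emxrt_stop("emxrt_geometry",
                "EP (%.2f) must be at least the target radius TS/2 (%.2f)", EP, TS / 2)
  pool <- sort(beams$energies)
  if (!is.null(deep_ep) && EP >= deep_ep) {
    out <- max(pool)
    attr(out, "margin") <- Inf
    attr(out, "override") <- "deep_target"
    return(out)
  }
  scores <- vapply(as.character(pool), function(e) {
    d <- four_point_doses(beams$curves[[e]], EP, TS,
                          exit_depth = exit_depth(EP, TS))
    cc_score(template, d, weights, form = form)
  }, numeric(1))
  best <- which.max(scores)  # first maximum = lowest energy on ties
  out <- pool[best]
  attr(out, "scores") <- scores
  attr(out, "margin") <- if (length(scores) > 1)
    scores[best] - max(scores[-best]) else Inf
  out
}

#' Build the EP x TS energy look-up table
#'
#' Applies [select_energy()] on a grid of effective path lengths and tumor
#' sizes. Cells where the target is not strictly inside the body
#' (`EP <= TS/2`) are geometrically invalid and left `NA`.
#'
#' @param ep_grid effective path lengths in cm (default 2 to 21 by 1).
#' @param ts_grid tumor sizes in cm (default 2 to 16 by 1).
#' @param beams a `beam_set`.
#' @param ... further conventions passed to [select_energy()].
#' @return object of class `energy_table`: an MV matrix (rows TS, columns
#'   EP) plus a parallel `margin` matrix of score gaps and the conventions
#'   used, stored as attributes.
#' @export
build_energy_table <- function(ep_grid = 2:21, ts_grid = 2:16,
                               beams = default_beams(), ...) {
  tab <- matrix(NA_real_, length(ts_grid), length(ep_grid),
                dimnames = list(TS = ts_grid, EP = ep_grid))
  marg <- tab
  for (i in seq_along(ts_grid)) for (j in seq_along(ep_grid)) {
    EP <- ep_grid[j]; TS <- ts_grid[i]
    if (EP <= TS / 2) next
    sel <- select_energy(EP, TS, beams = beams, ...)
    tab[i, j] <- as.numeric(sel)
    marg[i, j] <- attr(sel, "margin")
  }
  structure(tab, margin = marg, ep_grid = ep_grid, ts_grid = ts_grid,
            energies = sort(beams$energies),
            class = c("energy_table", "matrix"))
}

#' Load the published reference energy look-up table
#'
#' The printed EP x TS table shipped as a packaged fixture, in the same
#' matrix layout as [build_energy_table()] output (blank printed cells are
#' `NA`).
#'
#' @param path CSV with columns `ts_cm`, `ep_cm`, `energy_mv`.
#' @param ep_grid,ts_grid grids of the returned matrix.
#' @export
reference_energy_table <- function(path = system.file("extdata",
                                                      "energy_table_printed.csv",
                                                      package = "emxrt"),
                                   ep_grid = 2:21, ts_grid = 2:16) {
  cells <- read.csv(path)
  tab <- matrix(NA_real_, length(ts_grid), length(ep_grid),
                dimnames = list(TS = ts_grid, EP = ep_grid))
  tab[cbind(match(cells$ts_cm, ts_grid), match(cells$ep_cm, ep_grid))] <-
    cells$energy_mv
  structure(tab, ep_grid = ep_grid, ts_grid = ts_grid,
            class = c("energy_table", "matrix"))
}

#' Compare a generated energy table against a reference
#'
#' Cell-by-cell comparison over the cells populated in the reference, with
#' the score margin of each generated cell, for diagnosing convention
#' sensitivity of the selector.
#'
#' @param table generated `energy_table` (carrying a `margin` attribute).
#' @param reference reference `energy_table`, e.g.
#'   [reference_energy_table()].
#' @return data frame with one row per populated reference cell (`ep`, `ts`,
#'   `reference`, `generated`, `agree`, `margin`); the overall agreement
#'   fraction is attached as attribute `agreement`.
#' @export
compare_energy_table <- function(table, reference = reference_energy_table()) {
  stopifnot(identical(dim(table), dim(reference)))
  ep <- attr(table, "ep_grid"); ts <- attr(table, "ts_grid")
  marg <- attr(table, "margin")
  idx <- which(!is.na(unclass(reference)), arr.ind = TRUE)
  out <- data.frame(
    ep = ep[idx[, 2]], ts = ts[idx[, 1]],
    reference = reference[idx], generated = table[idx],
    margin = if (is.null(marg)) NA_real_ else marg[idx])
  out$agree <- !is.na(out$generated) & out$generated == out$reference
  attr(out, "agreement") <- mean(out$agree)
  out
}

#' Assign beam energies to gantry angles via the look-up table
#'
#' For each gantry angle, traces the beam through the phantom to measure
#' (EP, TS), rounds to the nearest table cell (ties toward the smaller
#' value) and looks up the energy. EP beyond the table edge falls into the
#' last column (the deep-target override region).
#'
#' @param phantom a `voxel_phantom`; its `isocenter` field (or the PTV
#'   centroid) is used as the isocenter.
#' @param gantry_angles numeric vector of gantry angles in degrees.
#' @param table an `energy_table`.
#' @param isocenter optional explicit isocenter (cm).
#' @return data frame with one row per angle: `gantry_deg`, `EP`, `TS`,
#'   `energy_mv`.
#' @export
assign_beam_energies <- function(phantom, gantry_angles,
                                 table = build_energy_table(),
                                 isocenter = NULL) {
  iso <- isocenter %||% phantom$isocenter %||% ptv_centroid(phantom)
  ep_grid <- attr(table, "ep_grid"); ts_grid <- attr(table, "ts_grid")
  snap <- function(x, grid) {
    d <- abs(grid - x)
    grid[which(d == min(d))[1]]  # ties toward the smaller grid value
  }
  rows <- lapply(gantry_angles, function(g) {
    tr <- trace_four_points(phantom, beam_ray(g, iso))
    ep <- snap(tr$EP, ep_grid); ts <- snap(tr$TS, ts_grid)
    mv <- table[as.character(ts), as.character(ep)]
    if (is.na(mv)) # geometrically invalid cell after snapping: score directly
      mv <- as.numeric(select_energy(max(tr$EP, tr$TS / 2), tr$TS))
    data.frame(gantry_deg = g, EP = tr$EP, TS = tr$TS, energy_mv = mv)
  })
  do.call(rbind, rows)
}

#' PTV centroid in cm (used as the automatic isocenter)
#' @param phantom a `voxel_phantom`.
#' @return length-3 position in cm.
#' @export
ptv_centroid <- function(phantom) {
  co <- voxel_centers(phantom)
  m <- phantom$structures$PTV
  idx <- which(m, arr.ind = TRUE)
  c(mean(co[[1]][idx[, 1]]), mean(co[[2]][idx[, 2]]), mean(co[[3]][idx[, 3]]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.energy_table <- function(x, ...) {
  cat("<energy_table> MV by TS (rows) x EP (columns), cm\n")
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  print(ifelse(is.na(m), ".", format(m)), quote = FALSE)
  invisible(x)
}

#' Write an energy table as CSV (rows TS, columns EP, blanks for invalid)
#' @param table an `energy_table`.
#' @param path output CSV path.
#' @export
write_energy_table <- function(table, path) {
  m <- unclass(table)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  df <- data.frame(TS = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
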