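#' Cumulative dose-volume histogram of a structure
#'
#' Stored exactly as the sorted voxel doses (no binning); binned curves are
#' derived on demand by [dvh_curve()].
#'
#' @param dose a `dose_grid` (or a numeric vector of voxel doses).
#' @param mask logical array selecting the structure's voxels (ignored when
#'   `dose` is already a plain vector).
#' @param voxel_volume volume of one voxel in cm3.
#' @param structure structure name carried along for reports.
#' @return object of class `dvh`.
#' @export
compute_dvh <- function(dose, mask = NULL, voxel_volume = NA_real_,
                        structure = NA_character_) {
  if (inherits(dose, "dose_grid")) {
    if (is.null(mask))
      .emxrt_stop("emxrt_empty_structure", "a structure mask is required")
    if (!any(mask))
      .emxrt_stop("emxrt_empty_structure", "structure mask is empty")
    pos <- match(which(mask), dose$voxel_index)
    vals <- numeric(length(pos))
    vals[!is.na(pos)] <- dose$values_body[pos[!is.na(pos)]]
  } else {
    vals <- as.numeric(dose)
    if (length(vals) == 0)
      .emxrt_stop("emxrt_empty_structure", "no voxel doses supplied")
  }
  structure(list(doses = sort(vals), voxel_volume = voxel_volume,
                 structure = structure),
            class = "dvh")
}

#' Dose covering a volume fraction (D2%, D50%, D95%, D98%, ...)
#'
#' The largest dose received by at least `q`% of the structure volume,
#' computed as the `(1 - q/100)` empirical quantile of the voxel doses with
#' linear interpolation between order statistics.
#'
#' @param dvh a `dvh`.
#' @param q volume percentage in (0, 100).
#' @return dose in the grid's units.
#' @export
dose_at_volume <- function(dvh, q) {
  if (q <= 0 || q >= 100)
    .emxrt_stop("emxrt_domain", "q must lie strictly between 0 and 100")
  quantile(dvh$doses, 1 - q / 100, names = FALSE, type = 7)
}

#' Volume fraction receiving at least a threshold dose (VxGy)
#'
#' @param dvh a `dvh`.
#' @param threshold dose threshold (>= 0).
#' @return percent of the structure volume receiving `>= threshold`.
#' @export
v_dose <- function(dvh, threshold) {
  if (threshold < 0)
    .emxrt_stop("emxrt_domain", "threshold must be nonnegative")
  100 * mean(dvh$doses >= threshold)
}

#' Binned DVH curve for plotting or export
#' @param dvh a `dvh`.
#' @param bin bin width in dose units (default 0.05).
#' @return data frame with columns `dose` and `volume_pct`.
#' @export
dvh_curve <- function(dvh, bin = 0.05) {
  top <- max(dvh$doses, 0)
  doses <- seq(0, top + bin, by = bin)
  data.frame(dose = doses,
             volume_pct = vapply(doses, function(t) v_dose(dvh, t), numeric(1)))
}

#' Normalize a plan so the prescription isodose covers 95% of the target
#'
#' Scales the whole dose grid by `prescription / D95%(PTV)`, after which
#' exactly 95% of the target volume receives at least the prescription.
#'
#' @param dose a `dose_grid` in relative units.
#' @param ptv_mask logical PTV mask.
#' @param prescription prescription dose in Gy.
#' @return the scaled `dose_grid` (now in Gy).
#' @export
normalize_plan <- function(dose, ptv_mask, prescription) {
  d95 <- dose_at_volume(compute_dvh(dose, ptv_mask), 95)
  if (!is.finite(d95) || d95 <= 0)
    .emxrt_stop("emxrt_normalization", "PTV D95%% of the raw plan is not positive")
  dose$values_body <- dose$values_body * (prescription / d95)
  dose
}

#' Homogeneity index
#'
#' `HI = (D2% - D98%) / D50%`; 0 for a perfectly uniform target dose,
#' larger for more heterogeneous coverage.
#'
#' @param d2,d98,d50 the corresponding coverage doses in Gy.
#' @export
homogeneity_index <- function(d2, d98, d50) {
  if (d50 <= 0)
    .emxrt_stop("emxrt_domain", "D50%% must be positive")
  if (d2 < d98)
    .emxrt_stop("emxrt_domain", "D2%% must not be smaller than D98%%")
  (d2 - d98) / d50
}

#' Integral dose to normal tissue
#'
#' Dose integrated over the patient volume excluding the target, reported
#' both as the mean normal-tissue dose (Gy) and as the volume integral
#' (Gy L).
#'
#' @param dose a `dose_grid`.
#' @param body_mask,ptv_mask logical masks.
#' @param voxel_volume voxel volume in cm3.
#' @return list with `mean_gy` and `gy_l`.
#' @export
integral_dose <- function(dose, body_mask, ptv_mask, voxel_volume) {
  region <- body_mask & !ptv_mask
  if (!any(region))
    .emxrt_stop("emxrt_empty_structure", "BODY minus PTV is empty")
  d <- compute_dvh(dose, region)$doses
  list(mean_gy = mean(d), gy_l = sum(d) * voxel_volume / 1000)
}

#' Relative difference between paired plan indices
#'
#' `100 * (index_a - index_b) / index_b`, the percent change of plan A
#' relative to plan B; reported to one decimal in comparison tables.
#'
#' @param index_a,index_b the paired index values (B is the reference).
#' @return percent difference, `NA` when the reference index is 0.
#' @export
relative_difference <- function(index_a, index_b) {
  ifelse(index_b == 0, NA_real_, 100 * (index_a - index_b) / index_b)
}

#' Standard metric panel for every structure of a plan
#'
#' Dmean, D2%, D50%, D95%, D98% and HI for the target; Dmean, Dmax and the
#' requested VxGy levels for every structure; plus the normal-tissue
#' integral dose in both conventions.
#'
#' @param dose a `dose_grid` (normalized, in Gy).
#' @param phantom the `voxel_phantom`.
#' @param v_levels dose thresholds (Gy) for VxGy columns (default 5 and 20).
#' @return data frame with one row per (structure, index).
#' @export
plan_metrics <- function(dose, phantom, v_levels = c(5, 20)) {
  vol <- voxel_volume(phantom)
  rows <- list()
  add <- function(structure, index, value)
    rows[[length(rows) + 1]] <<- data.frame(structure = structure,
                                            index = index, value = value)
  for (nm in names(phantom$structures)) {
    if (nm == "BODY") next
    dvh <- compute_dvh(dose, phantom$structures[[nm]], vol, nm)
    add(nm, "Dmean", mean(dvh$doses))
    add(nm, "Dmax", max(dvh$doses))
    if (nm == "PTV") {
      d2 <- dose_at_volume(dvh, 2); d50 <- dose_at_volume(dvh, 50)
      d98 <- dose_at_volume(dvh, 98)
      add(nm, "D2%", d2)
      add(nm, "D50%", d50)
      add(nm, "D95%", dose_at_volume(dvh, 95))
      add(nm, "D98%", d98)
      add(nm, "HI", homogeneity_index(d2, d98, d50))
    }
    for (v in v_levels) add(nm, sprintf("V%gGy", v), v_dose(dvh, v))
  }
  intd <- integral_dose(dose, phantom$structures$BODY, phantom$structures$PTV,
                        vol)
  rows[[length(rows) + 1]] <- data.frame(
    structure = "NORMAL_TISSUE",
    index = c("integral_mean_Gy", "integral_GyL"),
    value = c(intd$mean_gy, intd$gy_l))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare two plans' metric panels
#'
#' Joins two [plan_metrics()] frames on (structure, index) and adds the
#' relative-difference column of plan A versus plan B.
#'
#' @param metrics_a,metrics_b data frames from [plan_metrics()].
#' @param labels length-2 character labels for the two plans.
#' @return data frame with both values and `relative_difference_pct`.
#' @export
compare_plans <- function(metrics_a, metrics_b,
                          labels = c("plan_a", "plan_b")) {
  m <- merge(metrics_a, metrics_b, by = c("structure", "index"),
             suffixes = paste0("_", labels))
  m$relative_difference_pct <- round(
    relative_difference(m[[paste0("value_", labels[1])]],
                        m[[paste0("value_", labels[2])]]), 1)
  m[order(m$structure, m$index), ]
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> %s: %d voxels, Dmean %.2f, D2%% %.2f, D98%% %.2f\n",
              x$structure, length(x$doses), mean(x$doses),
              dose_at_volume(x, 2), dose_at_volume(x, 98)))
  invisible(x)
}
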