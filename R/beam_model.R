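#' Percent-depth-dose anchor set for one nominal beam energy
#'
#' Bundles the printed water-phantom characterization of a photon beam:
#' depth-at-percent pairs (the depths at which the central-axis dose falls to
#' a given percentage of the maximum) and percent-at-depth pairs (the dose at
#' fixed depths, including the surface at depth 0). Doses are normalized to
#' 100 at the depth of maximum dose (dmax).
#'
#' @param energy_mv nominal accelerating potential in MV (a single number).
#' @param depth_at_percent numeric vector of depths (cm) named by percent
#'   dose; must contain exactly one 100% entry (the dmax anchor).
#' @param percent_at_depth numeric vector of percent doses named by depth
#'   (cm); should include depth 0 (the surface dose).
#' @param measured optional list with the same two components holding
#'   chamber-measured values; retained as metadata only and never used by the
#'   energy selector.
#' @return an object of class `pdd_anchors`.
#' @export
pdd_anchors <- function(energy_mv, depth_at_percent, percent_at_depth,
                        measured = NULL) {
  pct <- as.numeric(names(depth_at_percent))
  dep <- as.numeric(names(percent_at_depth))
  if (any(is.na(pct)) || any(is.na(dep)))
    .emxrt_stop("emxrt_invalid_anchor", "anchor names must be numeric")
  if (any(pct <= 0 | pct > 100) || any(percent_at_depth <= 0 | percent_at_depth > 100))
    .emxrt_stop("emxrt_invalid_anchor", "percent doses must lie in (0, 100]")
  if (sum(pct == 100) != 1)
    .emxrt_stop("emxrt_invalid_anchor",
                "exactly one depth-at-percent pair must carry 100%% (the dmax anchor)")
  if (any(dep < 0) || any(depth_at_percent < 0))
    .emxrt_stop("emxrt_invalid_anchor", "depths must be nonnegative")
  structure(
    list(energy_mv = energy_mv,
         depth_at_percent = depth_at_percent,
         percent_at_depth = percent_at_depth,
         measured = measured),
    class = "pdd_anchors")
}

#' Load the packaged percent-depth-dose anchors
#'
#' Reads the benchmark Monte Carlo water-phantom beam data shipped with the
#' package (10 x 10 cm2 field, 100 cm SSD) for the default 2, 3, 4, 5, 6 and
#' 10 MV pool. Measured chamber data, where available, are attached as
#' metadata.
#'
#' @param path CSV file with columns `energy_mv`, `kind`, `key`, `value`,
#'   `source`; defaults to the packaged fixture.
#' @return named list of [pdd_anchors()] objects, one per energy, ordered by
#'   increasing MV.
#' @export
load_pdd_anchors <- function(path = system.file("extdata", "pdd_anchors.csv",
                                                package = "emxrt")) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  energies <- sort(unique(tab$energy_mv))
  out <- lapply(energies, function(e) {
    sub <- tab[tab$energy_mv == e, ]
    grab <- function(kind, src) {
      s <- sub[sub$kind == kind & sub$source == src, ]
      setNames(s$value, s$key)
    }
    meas <- NULL
    if (any(sub$source == "measured"))
      meas <- list(depth_at_percent = grab("depth_at_percent", "measured"),
                   percent_at_depth = grab("percent_at_depth", "measured"))
    pdd_anchors(e, grab("depth_at_percent", "mc"),
                grab("percent_at_depth", "mc"), measured = meas)
  })
  setNames(out, energies)
}

#' Fit a percent-depth-dose curve through its anchors
#'
#' Builds a monotone shape-preserving interpolant (Fritsch--Carlson cubic
#' Hermite) through all anchor points, rising from the surface dose to 100 at
#' dmax and falling monotonically beyond. Past the deepest anchor the curve
#' is extended by a single exponential fitted to the last two anchors, so
#' evaluation remains defined at arbitrary depth.
#'
#' @param anchors a [pdd_anchors()] object.
#' @return an object of class `pdd_curve` with fields `energy_mv`,
#'   `dmax_depth` and the evaluator used by [pdd_at()].
#' @export
#' @examples
#' beams <- load_pdd_anchors()
#' curve6 <- fit_pdd(beams[["6"]])
#' pdd_at(curve6, c(0, curve6$dmax_depth, 10, 20))
fit_pdd <- function(anchors) {
  stopifnot(inherits(anchors, "pdd_anchors"))
  depth <- c(unname(anchors$depth_at_percent), as.numeric(names(anchors$percent_at_depth)))
  pct   <- c(as.numeric(names(anchors$depth_at_percent)), unname(anchors$percent_at_depth))
  if (length(depth) < 4)
    .emxrt_stop("emxrt_insufficient_data",
                "need at least 4 anchor pairs, got %d", length(depth))
  o <- order(depth)
  depth <- depth[o]; pct <- pct[o]
  dup <- duplicated(depth)
  if (any(abs(pct[dup] - pct[which(dup) - 1]) > 1))
    .emxrt_stop("emxrt_invalid_anchor", "conflicting percent values at one depth")
  depth <- depth[!dup]; pct <- pct[!dup]
  if (length(depth) < 3)
    .emxrt_stop("emxrt_insufficient_data", "need at least 3 distinct anchor depths")
  dmax <- unname(anchors$depth_at_percent[names(anchors$depth_at_percent) == "100"])
  beyond <- depth >= dmax
  if (is.unsorted(rev(pct[beyond])))
    .emxrt_stop("emxrt_invalid_anchor", "anchors beyond dmax must be nonincreasing")
  before <- depth <= dmax
  if (is.unsorted(pct[before]))
    .emxrt_stop("emxrt_invalid_anchor", "anchors before dmax must be nondecreasing")
  # fit the buildup and falloff branches separately so each is monotone and
  # the joint value at dmax is exactly 100 (a single spline would overshoot
  # at the peak where the secant slopes change sign)
  up_i <- depth <= dmax; dn_i <- depth >= dmax
  mono_branch <- function(dd, pp) {
    if (length(dd) < 2) return(function(z) rep(pp[1], length(z)))
    splinefun(dd, pp, method = "monoH.FC")
  }
  f_up <- mono_branch(depth[up_i], pct[up_i])
  f_dn <- mono_branch(depth[dn_i], pct[dn_i])
  interp <- function(z) ifelse(z <= dmax, f_up(z), f_dn(z))
  dlast <- tail(depth, 2); plast <- tail(pct, 2)
  # exponential tail through the two deepest anchors
  mu <- if (diff(dlast) > 0 && all(plast > 0)) log(plast[1] / plast[2]) / diff(dlast) else 0
  structure(
    list(energy_mv = anchors$energy_mv,
         dmax_depth = dmax,
         max_anchor_depth = max(depth),
         tail_mu = mu,
         tail_value = plast[2],
         interp = interp,
         anchors = anchors),
    class = "pdd_curve")
}

#' Evaluate a percent-depth-dose curve
#'
#' @param curve a `pdd_curve` from [fit_pdd()].
#' @param depth depth(s) in cm, nonnegative.
#' @return percent dose(s), normalized to 100 at dmax.
#' @export
pdd_at <- function(curve, depth) {
  stopifnot(inherits(curve, "pdd_curve"))
  if (any(depth < 0))
    .emxrt_stop("emxrt_domain", "depth must be nonnegative")
  dmaxa <- curve$max_anchor_depth
  out <- numeric(length(depth))
  inside <- depth <= dmaxa
  if (any(inside)) out[inside] <- curve$interp(depth[inside])
  if (any(!inside))
    out[!inside] <- curve$tail_value * exp(-curve$tail_mu * (depth[!inside] - dmaxa))
  out
}

#' Beam-quality index TPR20,10
#'
#' Tissue-phantom ratio approximated from the depth-dose curve as the ratio
#' of the percent doses at 20 and 10 cm depth, the conventional megavoltage
#' beam-quality specifier. Strictly increasing with nominal energy across the
#' default pool.
#'
#' @param curve a `pdd_curve`.
#' @return object of class `beam_quality` with fields `energy_mv` and
#'   `tpr_20_10`.
#' @export
tpr_20_10 <- function(curve) {
  stopifnot(inherits(curve, "pdd_curve"))
  val <- pdd_at(curve, 20) / pdd_at(curve, 10)
  structure(list(energy_mv = curve$energy_mv, tpr_20_10 = val),
            class = "beam_quality")
}

#' Lateral beam profile model
#'
#' Off-axis ratio modeled as a flat core with an error-function penumbra:
#' the convolution of an ideal rectangular field edge with a Gaussian of
#' standard deviation `sigma`. Horn-shaped profile unevenness is not modeled;
#' residual in-field structure is absorbed by the beamlet weights during
#' inverse planning.
#'
#' @param energy_mv nominal energy (MV); only used to pick the default
#'   penumbra width.
#' @param sigma penumbra Gaussian sigma in cm; default 0.3 for energies
#'   up to 6 MV and 0.4 for higher energies.
#' @param reference_depth depth (cm) the profile notionally refers to.
#' @return object of class `beam_profile`.
#' @export
beam_profile <- function(energy_mv, sigma = if (energy_mv <= 6) 0.3 else 0.4,
                         reference_depth = 10) {
  stopifnot(sigma > 0)
  structure(list(energy_mv = energy_mv, sigma = sigma,
                 reference_depth = reference_depth),
            class = "beam_profile")
}

#' Off-axis ratio of a beam profile
#'
#' @param profile a [beam_profile()].
#' @param x off-axis distance(s) in cm (sign irrelevant; the profile is
#'   symmetric by construction).
#' @param half_width field half-width in cm (> 0).
#' @return ratio(s) in `[0, 1]`: 1 on the flat core, 0.5 at the field edge,
#'   rolling off to 0 outside.
#' @export
off_axis_ratio <- function(profile, x, half_width) {
  stopifnot(inherits(profile, "beam_profile"))
  if (any(half_width <= 0))
    .emxrt_stop("emxrt_domain", "half_width must be positive")
  s <- profile$sigma
  erf <- function(z) 2 * pnorm(z * sqrt(2)) - 1
  0.5 * (erf((half_width - x) / (sqrt(2) * s)) +
         erf((half_width + x) / (sqrt(2) * s)))
}

#' Default beam set for the 2-10 MV pool
#'
#' Fits depth-dose curves and lateral profiles for every energy in the
#' packaged anchor data.
#'
#' @param anchors named list from [load_pdd_anchors()].
#' @return object of class `beam_set`: named lists `curves` and `profiles`
#'   plus the numeric `energies` vector, ordered by increasing MV.
#' @export
default_beams <- function(anchors = load_pdd_anchors()) {
  curves <- lapply(anchors, fit_pdd)
  profiles <- lapply(anchors, function(a) beam_profile(a$energy_mv))
  structure(list(energies = as.numeric(names(anchors)),
                 curves = curves, profiles = profiles),
            class = "beam_set")
}

#' @export
print.pdd_curve <- function(x, ...) {
  q <- tpr_20_10(x)
  cat(sprintf("<pdd_curve> %g MV: dmax %.1f cm, surface %.1f%%, TPR20,10 %.3f\n",
              x$energy_mv, x$dmax_depth, pdd_at(x, 0), q$tpr_20_10))
  invisible(x)
}

#' @export
print.beam_quality <- function(x, ...) {
  cat(sprintf("<beam_quality> %g MV: TPR20,10 = %.3f\n", x$energy_mv, x$tpr_20_10))
  invisible(x)
}

#' @export
print.beam_set <- function(x, ...) {
  cat("<beam_set> energies (MV):", paste(x$energies, collapse = ", "), "\n")
  invisible(x)
}
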