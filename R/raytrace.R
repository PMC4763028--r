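#' Construct a treatment beam ray
#'
#' A ray from the radiation source through the isocenter. With the default
#' source-to-axis distance (SAD) of 100 cm the source sits 100 cm from the
#' isocenter opposite the beam direction. Gantry angle 0 enters anteriorly
#' (traveling +y); angles increase clockwise when viewed from the patient's
#' feet.
#'
#' @param gantry_deg gantry angle in degrees.
#' @param isocenter length-3 position (cm) of the isocenter.
#' @param sad source-to-axis distance in cm (default 100).
#' @return object of class `beam_ray` with fields `source`, `direction`
#'   (unit vector), `isocenter`, `sad`, `gantry_deg`.
#' @export
beam_ray <- function(gantry_deg, isocenter, sad = 100) {
  g <- gantry_deg * pi / 180
  direction <- c(-sin(g), cos(g), 0)
  source <- isocenter - sad * direction
  structure(list(source = source, direction = direction,
                 isocenter = isocenter, sad = sad, gantry_deg = gantry_deg),
            class = "beam_ray")
}

# internal: generic ray constructor from explicit geometry
.ray_from_points <- function(source, isocenter) {
  d <- isocenter - source
  sad <- sqrt(sum(d^2))
  structure(list(source = source, direction = d / sad,
                 isocenter = isocenter, sad = sad, gantry_deg = NA_real_),
            class = "beam_ray")
}

# internal Siddon-style voxel walk.
# Returns parametric break points t (distances from the source along the
# unit direction), the linear voxel index of each segment, and the segment
# lengths. NULL when the ray misses the grid.
.grid_crossings <- function(phantom, source, direction) {
  o <- phantom$origin; h <- phantom$spacing; n <- phantom$shape
  t0 <- -Inf; t1 <- Inf
  for (a in 1:3) {
    lo <- o[a]; hi <- o[a] + n[a] * h[a]
    if (abs(direction[a]) < 1e-12) {
      if (source[a] < lo || source[a] >= hi) return(NULL)
    } else {
      ta <- (lo - source[a]) / direction[a]
      tb <- (hi - source[a]) / direction[a]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  if (t0 >= t1) return(NULL)
  breaks <- c(t0, t1)
  for (a in 1:3) {
    if (abs(direction[a]) < 1e-12) next
    planes <- o[a] + (0:n[a]) * h[a]
    tv <- (planes - source[a]) / direction[a]
    breaks <- c(breaks, tv[tv > t0 + 1e-12 & tv < t1 - 1e-12])
  }
  breaks <- sort(unique(breaks))
  tm <- (head(breaks, -1) + tail(breaks, -1)) / 2
  idx3 <- vapply(1:3, function(a) {
    i <- floor((source[a] + tm * direction[a] - o[a]) / h[a])
    pmin(pmax(i, 0), n[a] - 1)
  }, numeric(length(tm)))
  if (length(tm) == 1) idx3 <- matrix(idx3, nrow = 1)
  lin <- 1 + idx3[, 1] + n[1] * (idx3[, 2] + n[2] * idx3[, 3])
  list(breaks = breaks, idx = as.integer(lin), len = diff(breaks))
}

#' Water-equivalent (radiological) path length along a ray segment
#'
#' Integrates relative electron density along the ray between two distances
#' from the source, by exact parametric voxel traversal. Additive over
#' subsegments; equals geometric length in uniform water.
#'
#' @param phantom a `voxel_phantom`.
#' @param ray a `beam_ray`.
#' @param from,to distances (cm) from the source along the ray direction
#'   delimiting the segment; `from <= to`.
#' @return water-equivalent length in cm.
#' @export
radiological_path <- function(phantom, ray, from, to) {
  stopifnot(inherits(ray, "beam_ray"))
  if (from > to)
    .emxrt_stop("emxrt_geometry", "from (%.2f) must not exceed to (%.2f)", from, to)
  if (from == to) return(0)
  cr <- .grid_crossings(phantom, ray$source, ray$direction)
  if (is.null(cr) || from >= cr$breaks[length(cr$breaks)] || to <= cr$breaks[1])
    .emxrt_stop("emxrt_geometry", "segment does not intersect the voxel grid")
  lo <- pmax(head(cr$breaks, -1), from)
  hi <- pmin(tail(cr$breaks, -1), to)
  ov <- pmax(hi - lo, 0)
  sum(phantom$density[cr$idx] * ov)
}

#' Trace the four special points of a beam through a phantom
#'
#' Walks the ray through the phantom and finds the body entrance (point 1),
#' target entrance (point 2), target exit (point 3) and body exit (point 4),
#' together with the effective path length EP (water-equivalent length from
#' the skin to the isocenter) and tumor size TS (water-equivalent length of
#' the in-target part of the ray between points 2 and 3).
#'
#' Depths are geometric distances along the ray measured from the body
#' entrance, so `p1_depth` is always 0. When the ray crosses the target more
#' than once, point 2 is the first entry and point 3 the last exit, and TS
#' integrates density only over the in-target subsegments.
#'
#' @param phantom a `voxel_phantom`.
#' @param ray a `beam_ray`.
#' @return object of class `four_point_trace` with fields `p1_depth`,
#'   `p2_depth`, `p3_depth`, `p4_depth`, `EP`, `TS`.
#' @export
trace_four_points <- function(phantom, ray) {
  stopifnot(inherits(ray, "beam_ray"))
  cr <- .grid_crossings(phantom, ray$source, ray$direction)
  if (is.null(cr))
    .emxrt_stop("emxrt_geometry", "ray misses the voxel grid")
  body <- phantom$structures$BODY[cr$idx]
  ptv <- phantom$structures$PTV[cr$idx]
  if (!any(body))
    .emxrt_stop("emxrt_geometry", "ray misses the BODY contour")
  if (!any(ptv))
    .emxrt_stop("emxrt_no_target", "ray misses the PTV; choose a different angle")
  nb <- length(cr$idx)
  t_lo <- head(cr$breaks, -1); t_hi <- tail(cr$breaks, -1)
  t1 <- t_lo[which(body)[1]]
  t4 <- t_hi[rev(which(body))[1]]
  t2 <- t_lo[which(ptv)[1]]
  t3 <- t_hi[rev(which(ptv))[1]]
  t_iso <- sum((ray$isocenter - ray$source) * ray$direction)
  EP <- if (t_iso > t1) radiological_path(phantom, ray, t1, t_iso) else 0
  TS <- sum(phantom$density[cr$idx[ptv]] * cr$len[ptv])
  structure(list(p1_depth = 0, p2_depth = t2 - t1, p3_depth = t3 - t1,
                 p4_depth = t4 - t1, EP = EP, TS = TS,
                 t_body = c(t1, t4), t_target = c(t2, t3)),
            class = "four_point_trace")
}

#' @export
print.four_point_trace <- function(x, ...) {
  cat(sprintf(paste0("<four_point_trace> skin 0.0, target %.2f-%.2f,",
                     " exit %.2f cm; EP %.2f, TS %.2f cm\n"),
              x$p2_depth, x$p3_depth, x$p4_depth, x$EP, x$TS))
  invisible(x)
}
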