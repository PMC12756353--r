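#' Interpolate a normalized spine with a fine 3D cubic spline
#'
#' Fits a natural cubic spline through all centroids (vertebrae and discs
#' interleaved), parameterized by cumulative chord length, and resamples it
#' at approximately uniform arc-length steps. The spline interpolates: the
#' curve passes through every centroid exactly.
#'
#' Arc-length resampling is approximate but tight: the chord-parameter
#' spline is evaluated on a fine 0.1 mm parameter grid, the cumulative
#' polyline arc of that grid is inverted by linear interpolation to find the
#' parameters of the 1 mm arc targets, and the spline is re-evaluated there.
#' The resulting sample spacing is accurate to well under 1%.
#'
#' @param spine A `spine_normalized` object (see [normalize_spine()]); a raw
#'   [spine_centroids] object is normalized first.
#' @param spacing_mm Target arc-length spacing between samples (default 1 mm).
#' @return A data frame of class `spine_curve` with columns `arc_s`, `x`,
#'   `y`, `z`, `region` (`"lumbar"` for `arc_s <= lt_arc_s`, else
#'   `"thoracic"`), and attributes `spacing_mm`, `lt_arc_s`, `node_arc`
#'   (arc positions of the input centroids) and `evaluator` (a function
#'   mapping arc positions to interpolated xyz coordinates).
#' @export
#' @examples
#' curve <- interpolate_spine(normalize_spine(generate_spine(spine_params(seed = 1))))
#' nrow(curve)  # about 501 samples for a 500 mm spine
interpolate_spine <- function(spine, spacing_mm = 1.0) {
  if (!inherits(spine, "spine_normalized")) spine <- normalize_spine(spine)
  if (spacing_mm <= 0) stop_validation("spacing_mm must be positive")
  P <- as.matrix(spine[, c("x", "y", "z")])
  seg <- sqrt(rowSums(diff(P)^2))
  if (any(seg < 1e-12)) {
    bad <- which(seg < 1e-12)[1]
    stop_geometry(sprintf("degenerate geometry: consecutive centroids %s and %s coincide",
                          spine$label[bad], spine$label[bad + 1]))
  }
  tn <- c(0, cumsum(seg))                       # chord-length parameter at nodes
  fx <- stats::splinefun(tn, P[, 1], method = "natural")
  fy <- stats::splinefun(tn, P[, 2], method = "natural")
  fz <- stats::splinefun(tn, P[, 3], method = "natural")
  tf <- seq(0, tn[length(tn)], by = 0.1)
  if (tf[length(tf)] < tn[length(tn)]) tf <- c(tf, tn[length(tn)])
  F <- cbind(fx(tf), fy(tf), fz(tf))
  cumarc <- c(0, cumsum(sqrt(rowSums(diff(F)^2))))
  total_arc <- cumarc[length(cumarc)]
  param_of_arc <- function(arc) stats::approx(cumarc, tf, xout = arc, rule = 2)$y
  evaluator <- function(arc) {
    tt <- param_of_arc(arc)
    data.frame(x = fx(tt), y = fy(tt), z = fz(tt))
  }
  s_targets <- seq(0, total_arc, by = spacing_mm)
  if (total_arc - s_targets[length(s_targets)] > 1e-9)
    s_targets <- c(s_targets, total_arc)
  pos <- evaluator(s_targets)
  node_arc <- stats::approx(tf, cumarc, xout = tn)$y
  lt_row <- which(spine$label == attr(spine, "lt_label") & spine$kind == "disc")
  lt_arc_s <- node_arc[lt_row]
  out <- data.frame(arc_s = s_targets, x = pos$x, y = pos$y, z = pos$z,
                    region = ifelse(s_targets <= lt_arc_s + 1e-9, "lumbar", "thoracic"),
                    stringsAsFactors = FALSE)
  structure(out, class = c("spine_curve", "data.frame"),
            patient_id = attr(spine, "patient_id"),
            spacing_mm = spacing_mm, lt_arc_s = lt_arc_s,
            node_arc = node_arc, node_label = spine$label,
            evaluator = evaluator)
}

#' Project an interpolated curve onto an anatomical plane
#'
#' * `frontal`: displacement = x (lateral, + = patient's right), height = y;
#' * `sagittal`: displacement = z (+ = posterior), height = y, i.e. the view
#'   from the patient's left side;
#' * `axial`: displacement = x, axis = z (top-down view).
#'
#' @param curve A `spine_curve` from [interpolate_spine()].
#' @param plane One of `"frontal"`, `"sagittal"`, `"axial"`.
#' @return A data frame of class `spine_planar` with columns `arc_s`,
#'   `displacement`, `height` (or axis coordinate for the axial plane) and
#'   `region`; attribute `plane`.
#' @export
project_curve <- function(curve, plane = c("frontal", "sagittal", "axial")) {
  plane <- match.arg(plane)
  out <- switch(plane,
    frontal  = data.frame(arc_s = curve$arc_s, displacement = curve$x,
                          height = curve$y, region = curve$region),
    sagittal = data.frame(arc_s = curve$arc_s, displacement = curve$z,
                          height = curve$y, region = curve$region),
    axial    = data.frame(arc_s = curve$arc_s, displacement = curve$x,
                          height = curve$z, region = curve$region))
  structure(out, class = c("spine_planar", "data.frame"), plane = plane)
}

# first and second derivatives of f(s) on a (possibly mildly non-uniform)
# grid: three-point central formulas inside, one-sided quadratic fits at the
# two endpoints.
deriv12 <- function(s, f) {
  n <- length(s)
  d1 <- d2 <- numeric(n)
  i <- 2:(n - 1)
  h1 <- s[i] - s[i - 1]
  h2 <- s[i + 1] - s[i]
  d1[i] <- (h1^2 * f[i + 1] + (h2^2 - h1^2) * f[i] - h2^2 * f[i - 1]) /
    (h1 * h2 * (h1 + h2))
  d2[i] <- 2 * (h1 * f[i + 1] - (h1 + h2) * f[i] + h2 * f[i - 1]) /
    (h1 * h2 * (h1 + h2))
  end_fit <- function(idx, at) {
    co <- stats::lm.fit(cbind(1, s[idx] - s[at], (s[idx] - s[at])^2), f[idx])$coefficients
    c(co[2], 2 * co[3])
  }
  e1 <- end_fit(1:3, 1); d1[1] <- e1[1]; d2[1] <- e1[2]
  e2 <- end_fit((n - 2):n, n); d1[n] <- e2[1]; d2[n] <- e2[2]
  list(d1 = d1, d2 = d2)
}

#' Unsigned curvature profile of a planar projection
#'
#' Computes the planar curvature kappa = |d'h'' - h'd''| / (d'^2 + h'^2)^(3/2)
#' per sample (1/mm) by finite differences on the arc-length grid: central
#' differences in the interior, one-sided at the two endpoints. A straight
#' segment has kappa = 0; a circle of radius R has kappa = 1/R.
#'
#' @param planar A `spine_planar` projection.
#' @param smooth_window Optional odd integer; if greater than 1, a moving
#'   average of that width is applied to the curvature values (off by
#'   default).
#' @return Numeric vector of unsigned curvature (1/mm), one per sample.
#' @export
curvature_profile <- function(planar, smooth_window = 1L) {
  if (nrow(planar) < 5L) stop_validation("curvature needs at least 5 samples")
  dd <- deriv12(planar$arc_s, planar$displacement)
  hh <- deriv12(planar$arc_s, planar$height)
  denom <- (dd$d1^2 + hh$d1^2)^1.5
  kappa <- ifelse(denom < 1e-30, 0, abs(dd$d1 * hh$d2 - hh$d1 * dd$d2) / denom)
  if (smooth_window > 1L) {
    if (smooth_window %% 2L == 0L) stop_validation("smooth_window must be odd")
    k <- stats::filter(kappa, rep(1 / smooth_window, smooth_window), sides = 2)
    kappa <- ifelse(is.na(k), kappa, as.numeric(k))
  }
  pmax(kappa, 0)
}

#' Locate apex centroids
#'
#' Apexes are the extreme *centroids* (vertebra or disc), not interpolated
#' samples. In the frontal plane, `ApexS_right` is the centroid with the
#' largest positive lateral displacement (it exists only if some centroid
#' has x > 0) and `ApexS_left` the most negative (only if some x < 0). In
#' the sagittal plane, `ApexT` / `ApexL` are the thoracic / lumbar centroids
#' of largest absolute sagittal displacement; they always exist. Ties go to
#' the more caudal centroid.
#'
#' @param spine A `spine_normalized` object.
#' @return Data frame with columns `name`, `label`, `displacement` (signed
#'   mm); zero rows for absent side apexes.
#' @export
find_apexes <- function(spine) {
  if (!inherits(spine, "spine_normalized")) spine <- normalize_spine(spine)
  region <- centroid_regions(spine)
  rows <- list()
  if (any(spine$x > 0)) {
    i <- which.max(spine$x)   # first index wins ties = more caudal
    rows[[length(rows) + 1L]] <- data.frame(name = "ApexS_right",
                                            label = spine$label[i],
                                            displacement = spine$x[i])
  }
  if (any(spine$x < 0)) {
    i <- which.min(spine$x)
    rows[[length(rows) + 1L]] <- data.frame(name = "ApexS_left",
                                            label = spine$label[i],
                                            displacement = spine$x[i])
  }
  for (reg in c("thoracic", "lumbar")) {
    idx <- which(region == reg)
    i <- idx[which.max(abs(spine$z[idx]))]
    rows[[length(rows) + 1L]] <- data.frame(
      name = if (reg == "thoracic") "ApexT" else "ApexL",
      label = spine$label[i], displacement = spine$z[i])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export an interpolated curve as CSV
#'
#' Debug helper writing `arc_s,x,y,z,region` rows.
#'
#' @param curve A `spine_curve`.
#' @param path Output path.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[, c("arc_s", "x", "y", "z", "region")],
                   path, row.names = FALSE)
  invisible(path)
}
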