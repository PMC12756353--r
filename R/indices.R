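#' Quadrant dispersion of the frontal projection
#'
#' After normalization every sample of a deformity-free spine lies on the
#' vertical line x = 0, so lateral displacement itself measures deformity.
#' The frontal samples are split into four quadrants - thoracic/lumbar by
#' region tag, left/right by the sign of the displacement (x < 0 left,
#' x > 0 right; samples exactly at 0 belong to neither side) - and each
#' quadrant's dispersion is the root-mean-square displacement about the
#' vertical reference line, in mm. An empty quadrant scores 0.
#'
#' Dispersion is deliberately taken about zero, not about the quadrant
#' mean: a uniformly offset curve is a real deformity and would score 0
#' under a mean-centred standard deviation. Set `about_mean = TRUE` (or
#' `std_about_mean` in the threshold config) for the mean-centred reading.
#'
#' @param frontal A `spine_planar` frontal projection (see [project_curve()]).
#' @param about_mean Logical; use the mean-centred population standard
#'   deviation per quadrant instead of RMS about zero.
#' @return Named numeric vector `c(tl, tr, ll, lr)` (thoracic-left,
#'   thoracic-right, lumbar-left, lumbar-right), all >= 0, in mm.
#' @export
#' @examples
#' curve <- interpolate_spine(generate_spine(spine_params(seed = 1)))
#' std_vector(project_curve(curve, "frontal"))
std_vector <- function(frontal, about_mean = FALSE) {
  stopifnot(inherits(frontal, "spine_planar"))
  if (!identical(attr(frontal, "plane"), "frontal"))
    stop_validation("std_vector expects the frontal projection")
  disp <- frontal$displacement
  quadrant <- function(reg, side) {
    d <- disp[frontal$region == reg &
                (if (side == "left") disp < 0 else disp > 0)]
    if (length(d) == 0) return(0)
    if (about_mean) sqrt(mean((d - mean(d))^2)) else sqrt(mean(d^2))
  }
  c(tl = quadrant("thoracic", "left"), tr = quadrant("thoracic", "right"),
    ll = quadrant("lumbar", "left"),   lr = quadrant("lumbar", "right"))
}

#' Sidedness index s
#'
#' s = ((std_TR + std_LR) - (std_TL + std_LL)) / (std_TR + std_LR + std_TL +
#' std_LL), in \[-1, 1\]: +1 when all lateral displacement is to the
#' patient's right, -1 when all to the left. Undefined (NA) for a perfectly
#' straight frontal projection (zero denominator).
#'
#' @param std Named quadrant dispersion vector from [std_vector()].
#' @return Numeric scalar in \[-1, 1\], or `NA` when undefined.
#' @export
#' @examples
#' sidedness_index(c(tl = 0, tr = 8, ll = 0, lr = 2))  # +1
sidedness_index <- function(std) {
  denom <- std[["tr"]] + std[["lr"]] + std[["tl"]] + std[["ll"]]
  if (denom == 0) return(NA_real_)
  ((std[["tr"]] + std[["lr"]]) - (std[["tl"]] + std[["ll"]])) / denom
}

#' Vertical index v
#'
#' v = ((std_TR + std_TL) - (std_LR + std_LL)) / (sum of all four), in
#' \[-1, 1\]: +1 for a purely thoracic deformity, -1 for purely lumbar.
#' Undefined (NA) when all four dispersions are zero.
#'
#' @inheritParams sidedness_index
#' @return Numeric scalar in \[-1, 1\], or `NA` when undefined.
#' @export
#' @examples
#' vertical_index(c(tl = 0, tr = 8, ll = 0, lr = 2))  # +0.6
vertical_index <- function(std) {
  denom <- std[["tr"]] + std[["tl"]] + std[["lr"]] + std[["ll"]]
  if (denom == 0) return(NA_real_)
  ((std[["tr"]] + std[["tl"]]) - (std[["lr"]] + std[["ll"]])) / denom
}

#' Kyphosis-lordosis index kl
#'
#' From the sagittal projection: m_T = mean sagittal displacement of the
#' thoracic samples (positive for a kyphotic, posteriorly convex thoracic
#' arc) and m_L = mean of the lumbar samples (negative for a lordotic,
#' anteriorly convex lumbar arc). Then kl = (m_T + m_L) / (m_T - m_L): 0
#' for a balanced spine, positive when kyphosis dominates, negative when
#' lordosis dominates. Undefined (NA) when m_T = m_L.
#'
#' @param sagittal A `spine_planar` sagittal projection.
#' @return List with `kl` (or NA), `m_t`, `m_l` (mm).
#' @export
#' @examples
#' # balanced arcs: m_t = 30, m_l = -30 -> kl = 0
kl_index <- function(sagittal) {
  stopifnot(inherits(sagittal, "spine_planar"))
  if (!identical(attr(sagittal, "plane"), "sagittal"))
    stop_validation("kl_index expects the sagittal projection")
  th <- sagittal$displacement[sagittal$region == "thoracic"]
  lu <- sagittal$displacement[sagittal$region == "lumbar"]
  if (length(th) == 0 || length(lu) == 0)
    stop_validation("both thoracic and lumbar regions must be non-empty")
  m_t <- mean(th); m_l <- mean(lu)
  kl <- if (m_t == m_l) NA_real_ else (m_t + m_l) / (m_t - m_l)
  list(kl = kl, m_t = m_t, m_l = m_l)
}
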