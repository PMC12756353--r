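# Label catalogs. Externalized here (single point of truth) so the wording
# can be re-targeted without touching any index computation.
SEVERITY_LABELS <- c("No scoliosis", "Mild", "Slightly significant",
                     "Very significant", "Severe", "Extremely severe")
SIDE_LABELS <- c("Left-sided", "Both-sided", "Right-sided")
VERTICAL_LABELS <- c("Lumbar", "Mainly lumbar", "Thoraco-lumbar",
                     "Mainly thoracic", "Thoracic")
SAGITTAL_LABELS <- c("Extreme lordosis", "Significant lordosis",
                     "Slight lordosis", "Normal spine", "Slight kyphosis",
                     "Significant kyphosis", "Extreme kyphosis")

#' Severity class from the quadrant dispersion vector
#'
#' The largest of the four quadrant dispersions is bucketed into half-open
#' intervals (lower bound inclusive): \[0, 2.5) no scoliosis, \[2.5, 4)
#' mild, \[4, 6.5) slightly significant, \[6.5, 10) very significant,
#' \[10, 14.5) severe, \[14.5, Inf) extremely severe (defaults; see
#' [default_thresholds()]).
#'
#' @param std Named dispersion vector from [std_vector()].
#' @param cfg A `spine_thresholds` configuration.
#' @return One of `"No scoliosis"`, `"Mild"`, `"Slightly significant"`,
#'   `"Very significant"`, `"Severe"`, `"Extremely severe"`.
#' @export
severity_class <- function(std, cfg = default_thresholds()) {
  m <- max(std)
  SEVERITY_LABELS[findInterval(m, cfg$std_severity_bounds) + 1L]
}

#' Side class from the sidedness index
#'
#' s < -bound is left-sided, |s| <= bound both-sided (boundary inclusive),
#' s > +bound right-sided; `NA` maps to `"n/a"`.
#'
#' @param s Sidedness index (may be `NA`).
#' @inheritParams severity_class
#' @return One of `"Left-sided"`, `"Both-sided"`, `"Right-sided"`, `"n/a"`.
#' @export
side_class <- function(s, cfg = default_thresholds()) {
  if (is.na(s)) return("n/a")
  if (s < -cfg$s_bound) "Left-sided"
  else if (s > cfg$s_bound) "Right-sided"
  else "Both-sided"
}

#' Vertical class from the vertical index
#'
#' Five buckets over \[-1, 1\] with the middle bucket closed on both sides:
#' \[-1, -0.6) lumbar, \[-0.6, -0.25) mainly lumbar, \[-0.25, +0.25\]
#' thoraco-lumbar, (+0.25, +0.6\] mainly thoracic, (+0.6, +1\] thoracic
#' (defaults). `NA` maps to `"n/a"`.
#'
#' @param v Vertical index (may be `NA`).
#' @inheritParams severity_class
#' @return One of the vertical labels or `"n/a"`.
#' @export
vertical_class <- function(v, cfg = default_thresholds()) {
  if (is.na(v)) return("n/a")
  b <- cfg$v_bounds
  if (v < b[1]) "Lumbar"
  else if (v < b[2]) "Mainly lumbar"
  else if (v <= b[3]) "Thoraco-lumbar"
  else if (v <= b[4]) "Mainly thoracic"
  else "Thoracic"
}

#' Sagittal class from the kyphosis-lordosis index
#'
#' Seven buckets partitioning \[-1, 1\]: \[-1, -0.35) extreme lordosis,
#' \[-0.35, -0.2) significant lordosis, \[-0.2, 0) slight lordosis,
#' \[0, 0.3\] normal spine, (0.3, 0.5\] slight kyphosis, (0.5, 0.65\]
#' significant kyphosis, (0.65, 1\] extreme kyphosis (defaults). `NA` maps
#' to `"n/a"`.
#'
#' @param kl Kyphosis-lordosis index (may be `NA`).
#' @inheritParams severity_class
#' @return One of the sagittal labels or `"n/a"`.
#' @export
sagittal_class <- function(kl, cfg = default_thresholds()) {
  if (is.na(kl)) return("n/a")
  b <- cfg$kl_bounds
  if (kl < b[1]) "Extreme lordosis"
  else if (kl < b[2]) "Significant lordosis"
  else if (kl < b[3]) "Slight lordosis"
  else if (kl <= b[4]) "Normal spine"
  else if (kl <= b[5]) "Slight kyphosis"
  else if (kl <= b[6]) "Significant kyphosis"
  else "Extreme kyphosis"
}

#' Compose the natural-language class estimation
#'
#' Template: `"<Severity> <side> <vertical> scoliosis with <sagittal>."`
#' (all but the leading word lower-cased; a comma joins the side and a
#' vertical label starting with "mainly"). The sagittal clause is omitted
#' for a normal sagittal balance. A spine with no scoliosis and normal
#' sagittal balance reads `"Normal spine."`; with no scoliosis but abnormal
#' sagittal balance the sagittal label stands alone (e.g.
#' `"Extreme kyphosis."`).
#'
#' @param severity,side,vertical,sagittal Category labels as produced by
#'   [severity_class()], [side_class()], [vertical_class()],
#'   [sagittal_class()].
#' @return A single sentence.
#' @export
#' @examples
#' compose_description("Very significant", "Left-sided", "Thoraco-lumbar",
#'                     "Extreme kyphosis")
compose_description <- function(severity, side, vertical, sagittal) {
  sag_normal <- sagittal %in% c("Normal spine", "n/a")
  if (severity == "No scoliosis") {
    return(if (sag_normal) "Normal spine." else paste0(sagittal, "."))
  }
  vert <- tolower(vertical)
  joiner <- if (startsWith(vert, "mainly")) ", " else " "
  base <- paste0(severity, " ", tolower(side), joiner, vert, " scoliosis")
  if (sag_normal) paste0(base, ".")
  else paste0(base, " with ", tolower(sagittal), ".")
}

#' Classify a patient from a centroid sequence
#'
#' Runs the full deterministic pipeline: normalize, interpolate, project,
#' compute the quadrant dispersions and the s/v/kl indices, bucket them into
#' categorical labels, compose the description, and locate the apexes.
#'
#' The sidedness and vertical indices are always computed and reported for
#' auditability, but their categorical labels are `"n/a"` (and they are
#' absent from the description) when the severity class is
#' `"No scoliosis"`: localization words are only meaningful once there is
#' at least mild scoliosis.
#'
#' @param spine A [spine_centroids] object.
#' @param cfg A `spine_thresholds` configuration.
#' @param spacing_mm Interpolation arc spacing (default 1 mm).
#' @return A `spine_classification` object: list with `patient_id`, `std`,
#'   `s`, `v`, `kl`, `m_t`, `m_l`, the four category labels, `description`,
#'   `apexes`, `scale_factor` and `config_digest`.
#' @export
#' @examples
#' cls <- classify_patient(generate_spine(spine_params(
#'   lateral_amplitude = 40, apex_level = "T8", seed = 2)))
#' cls$description
classify_patient <- function(spine, cfg = default_thresholds(), spacing_mm = 1.0) {
  norm <- normalize_spine(spine)
  curve <- interpolate_spine(norm, spacing_mm = spacing_mm)
  frontal <- project_curve(curve, "frontal")
  sagittal <- project_curve(curve, "sagittal")
  std <- std_vector(frontal, about_mean = cfg$std_about_mean)
  s <- sidedness_index(std)
  v <- vertical_index(std)
  klr <- kl_index(sagittal)
  severity <- severity_class(std, cfg)
  scoliotic <- severity != "No scoliosis"
  side <- if (scoliotic) side_class(s, cfg) else "n/a"
  vertical <- if (scoliotic) vertical_class(v, cfg) else "n/a"
  sagit <- sagittal_class(klr$kl, cfg)
  structure(list(
    patient_id = attr(spine, "patient_id"),
    std = std, s = s, v = v, kl = klr$kl, m_t = klr$m_t, m_l = klr$m_l,
    severity = severity, side = side, vertical = vertical, sagittal = sagit,
    description = compose_description(severity, side, vertical, sagit),
    apexes = find_apexes(norm),
    scale_factor = attr(norm, "scale_factor"),
    config_digest = config_digest(cfg)),
    class = "spine_classification")
}
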