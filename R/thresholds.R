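#' Default classification thresholds
#'
#' Bucket boundaries mapping the continuous indices to categorical labels.
#' Severity is decided by the largest of the four quadrant dispersion values
#' (mm); sidedness by the s index, vertical location by the v index and
#' sagittal balance by the kl index (all dimensionless in \[-1, 1\]).
#' Clinics may supply their own boundaries via [read_thresholds()]; all
#' bucket edges below follow the default interpretation table:
#'
#' * severity (mm): \[0, 2.5) no scoliosis, \[2.5, 4) mild, \[4, 6.5)
#'   slightly significant, \[6.5, 10) very significant, \[10, 14.5) severe,
#'   \[14.5, Inf) extremely severe;
#' * s: < -0.5 left-sided, |s| <= 0.5 both-sided, > +0.5 right-sided;
#' * v: \[-1, -0.6) lumbar, \[-0.6, -0.25) mainly lumbar, \[-0.25, +0.25\]
#'   thoraco-lumbar, (+0.25, +0.6\] mainly thoracic, (+0.6, +1\] thoracic;
#' * kl: \[-1, -0.35) extreme lordosis, \[-0.35, -0.2) significant lordosis,
#'   \[-0.2, 0) slight lordosis, \[0, 0.3\] normal spine, (0.3, 0.5\] slight
#'   kyphosis, (0.5, 0.65\] significant kyphosis, (0.65, 1\] extreme kyphosis.
#'
#' @param std_severity_bounds Five ascending positive numbers (mm): the inner
#'   edges of the six severity buckets.
#' @param s_bound Positive number: |s| above it is single-sided.
#' @param v_bounds Four ascending numbers: inner edges of the five vertical
#'   buckets.
#' @param kl_bounds Six ascending numbers: inner edges of the seven sagittal
#'   buckets.
#' @param std_about_mean Logical; if `TRUE`, quadrant dispersion is the
#'   mean-centred standard deviation instead of the RMS displacement about
#'   the vertical reference line (see [std_vector()]).
#' @return An object of class `spine_thresholds`.
#' @export
#' @examples
#' cfg <- default_thresholds()
#' severity_class(c(tl = 0, tr = 12, ll = 0, lr = 0), cfg)
default_thresholds <- function(std_severity_bounds = c(2.5, 4.0, 6.5, 10.0, 14.5),
                               s_bound = 0.5,
                               v_bounds = c(-0.60, -0.25, 0.25, 0.60),
                               kl_bounds = c(-0.35, -0.20, 0, 0.30, 0.50, 0.65),
                               std_about_mean = FALSE) {
  cfg <- structure(
    list(std_severity_bounds = as.numeric(std_severity_bounds),
         s_bound = as.numeric(s_bound),
         v_bounds = as.numeric(v_bounds),
         kl_bounds = as.numeric(kl_bounds),
         std_about_mean = isTRUE(std_about_mean)),
    class = "spine_thresholds")
  validate_thresholds(cfg)
  cfg
}

validate_thresholds <- function(cfg) {
  b <- cfg$std_severity_bounds
  if (length(b) != 5L || any(!is.finite(b)) || any(b <= 0) || is.unsorted(b, strictly = TRUE))
    stop_validation("std_severity_bounds must be 5 strictly ascending positive numbers")
  if (length(cfg$s_bound) != 1L || !is.finite(cfg$s_bound) || cfg$s_bound <= 0)
    stop_validation("s_bound must be a single positive number")
  if (length(cfg$v_bounds) != 4L || is.unsorted(cfg$v_bounds, strictly = TRUE))
    stop_validation("v_bounds must be 4 strictly ascending numbers")
  if (length(cfg$kl_bounds) != 6L || is.unsorted(cfg$kl_bounds, strictly = TRUE))
    stop_validation("kl_bounds must be 6 strictly ascending numbers")
  invisible(cfg)
}

#' Read or write a threshold configuration file
#'
#' Threshold files are YAML (or JSON, which YAML subsumes) with keys
#' `std_severity_bounds`, `s_bound`, `v_bounds`, `kl_bounds` and optionally
#' `std_about_mean`. Missing keys fall back to the defaults.
#'
#' @param path File path.
#' @return [read_thresholds()] returns a `spine_thresholds` object;
#'   [write_thresholds()] returns `path` invisibly.
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("threshold config not found: %s", path))
  raw <- yaml::read_yaml(path)
  base <- default_thresholds()
  for (k in intersect(names(raw), names(base))) base[[k]] <- raw[[k]]
  base$std_about_mean <- isTRUE(base$std_about_mean)
  base$std_severity_bounds <- as.numeric(base$std_severity_bounds)
  base$v_bounds <- as.numeric(base$v_bounds)
  base$kl_bounds <- as.numeric(base$kl_bounds)
  base$s_bound <- as.numeric(base$s_bound)
  validate_thresholds(base)
  base
}

#' @rdname read_thresholds
#' @param cfg A `spine_thresholds` object.
#' @export
write_thresholds <- function(cfg, path) {
  validate_thresholds(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Digest of a threshold configuration
#'
#' Short deterministic fingerprint written into every report so results can
#' be traced back to the exact boundaries that produced them.
#'
#' @param cfg A `spine_thresholds` object.
#' @return A character scalar.
#' @export
config_digest <- function(cfg) {
  validate_thresholds(cfg)
  canon <- paste(
    paste(format(cfg$std_severity_bounds, digits = 17), collapse = ","),
    format(cfg$s_bound, digits = 17),
    paste(format(cfg$v_bounds, digits = 17), collapse = ","),
    paste(format(cfg$kl_bounds, digits = 17), collapse = ","),
    cfg$std_about_mean, sep = "|")
  # base-R checksum (sum of byte values mixed by position), hex-encoded
  bytes <- as.integer(charToRaw(canon))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("cfg-%08x", h)
}

#' @export
print.spine_thresholds <- function(x, ...) {
  cat("Classification thresholds\n")
  cat("  severity bounds (mm):", paste(x$std_severity_bounds, collapse = ", "), "\n")
  cat("  |s| bound:", x$s_bound, "\n")
  cat("  v bounds:", paste(x$v_bounds, collapse = ", "), "\n")
  cat("  kl bounds:", paste(x$kl_bounds, collapse = ", "), "\n")
  cat("  dispersion about:", if (x$std_about_mean) "quadrant mean" else "vertical line (RMS)", "\n")
  invisible(x)
}
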