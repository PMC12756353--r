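# Template geometry: 18 vertebrae L5..C7 interleaved with 17 discs on a
# vertical 500 mm axis (uniform level spacing; anatomical spacing tables
# would add realism but no discriminating power for any index).
spine_template <- function() {
  vy <- seq(0, 500, length.out = length(VERTEBRA_ORDER))
  labels <- character(0); kinds <- character(0); ys <- numeric(0)
  for (i in seq_along(VERTEBRA_ORDER)) {
    labels <- c(labels, VERTEBRA_ORDER[i]); kinds <- c(kinds, "vertebra")
    ys <- c(ys, vy[i])
    if (i < length(VERTEBRA_ORDER)) {
      labels <- c(labels, paste0(VERTEBRA_ORDER[i + 1], "/", VERTEBRA_ORDER[i]))
      kinds <- c(kinds, "disc")
      ys <- c(ys, (vy[i] + vy[i + 1]) / 2)
    }
  }
  data.frame(label = labels, kind = kinds, y = ys, stringsAsFactors = FALSE)
}

#' Parameters for a synthetic spine
#'
#' Describes one simulated anatomy: a smooth kypho-lordotic sagittal profile
#' (anterior lumbar arc blended to a posterior thoracic arc) plus zero, one
#' or two lateral half-sine curves, sampled at the vertebra/disc centroids
#' of a 500 mm template with optional Gaussian jitter.
#'
#' @param lateral_amplitude Peak lateral displacement of the primary curve
#'   (mm, >= 0; 0 = no scoliosis).
#' @param apex_level Vertebral label at which the primary curve peaks
#'   (between L4 and T2).
#' @param convexity `"right"` or `"left"`: side of the curve's convexity.
#' @param n_curves 1 for a single curve, 2 to add a compensatory curve of
#'   half amplitude and opposite convexity in the other region.
#' @param curve_span Extent of the half-sine bump along the spine (mm;
#'   default 180, about six vertebral levels, a typical structural curve).
#' @param kyphosis_depth Peak posterior displacement of the thoracic arc
#'   (mm; default 30).
#' @param lordosis_depth Peak anterior displacement of the lumbar arc (mm;
#'   default 25; with the default kyphosis depth the kl index sits near
#'   +0.09, i.e. a normal sagittal balance).
#' @param noise_sd Standard deviation of independent Gaussian jitter added
#'   to every coordinate (mm; default 0.5, a sub-millimetre
#'   centroid-extraction precision).
#' @param seed Integer seed making the spine reproducible.
#' @param patient_id Identifier carried into the centroid sequence.
#' @return A list of class `spine_params`.
#' @export
spine_params <- function(lateral_amplitude = 20, apex_level = "T8",
                         convexity = c("right", "left"), n_curves = 1,
                         curve_span = 180, kyphosis_depth = 30,
                         lordosis_depth = 25, noise_sd = 0.5, seed = 1,
                         patient_id = paste0("synthetic-", seed)) {
  convexity <- match.arg(convexity)
  allowed <- VERTEBRA_ORDER[seq(match("L4", VERTEBRA_ORDER),
                                match("T2", VERTEBRA_ORDER))]
  if (!apex_level %in% allowed)
    stop_validation(sprintf("apex_level must be a vertebra between L4 and T2, got '%s'",
                            apex_level))
  if (lateral_amplitude < 0 || noise_sd < 0 || curve_span <= 0)
    stop_validation("amplitudes, noise_sd and curve_span must be non-negative")
  if (!n_curves %in% c(1, 2)) stop_validation("n_curves must be 1 or 2")
  structure(list(lateral_amplitude = lateral_amplitude, apex_level = apex_level,
                 convexity = convexity, n_curves = n_curves,
                 curve_span = curve_span, kyphosis_depth = kyphosis_depth,
                 lordosis_depth = lordosis_depth, noise_sd = noise_sd,
                 seed = as.integer(seed), patient_id = patient_id),
            class = "spine_params")
}

# lateral bump of amplitude `a` peaking exactly at `y_apex`, supported on
# [y_apex - span/2, y_apex + span/2] clipped to the spine, and zero at both
# spine endpoints so the L5-C7 chord is unaffected. Two quarter-sine lobes
# (C1 at the apex); reduces to a plain half-sine when unclipped.
half_sine_bump <- function(y, y_apex, a, span, y_min = 0, y_max = 500) {
  y0 <- max(y_apex - span / 2, y_min)
  y1 <- min(y_apex + span / 2, y_max)
  out <- numeric(length(y))
  lo <- y > y0 & y <= y_apex
  hi <- y > y_apex & y < y1
  out[lo] <- a * sin(pi / 2 * (y[lo] - y0) / (y_apex - y0))
  out[hi] <- a * cos(pi / 2 * (y[hi] - y_apex) / (y1 - y_apex))
  out
}

#' Generate a synthetic centroid sequence
#'
#' Builds the deformity described by a [spine_params()] object on the
#' 500 mm template (35 centroids: 18 vertebrae, 17 discs; LT disc
#' `"T12/L1"`). The returned object carries a `truth` attribute recording
#' the generating parameters plus two derived ground truths: `apex_region`
#' (lumbar/thoracic side of the LT disc containing the nominal apex) and
#' `realized_apex`, the label of the centroid of the simulated anatomy with
#' the largest lateral offset from the L5-C7 chord on the convex side,
#' computed here by direct vector rejection, independently of the
#' normalization pipeline. With jitter, the realized apex can sit one
#' centroid away from the nominal level; it is the correct recovery target
#' because it is a property of the anatomy actually generated.
#'
#' @param params A `spine_params` object.
#' @return A [spine_centroids] object (attribute `truth`).
#' @export
#' @examples
#' sp <- generate_spine(spine_params(lateral_amplitude = 40, apex_level = "T8",
#'                                   noise_sd = 0, seed = 7))
#' classify_patient(sp)$description
generate_spine <- function(params) {
  stopifnot(inherits(params, "spine_params"))
  tmpl <- spine_template()
  y <- tmpl$y
  y_lt <- y[tmpl$label == "T12/L1"]
  # sagittal profile: anterior (z < 0) lumbar arc, posterior (z > 0) thoracic
  z <- ifelse(y <= y_lt,
              -params$lordosis_depth * sin(pi * y / y_lt),
              params$kyphosis_depth * sin(pi * (y - y_lt) / (500 - y_lt)))
  # lateral profile
  sgn <- if (params$convexity == "right") 1 else -1
  y_apex <- y[tmpl$label == params$apex_level]
  x <- sgn * half_sine_bump(y, y_apex, params$lateral_amplitude, params$curve_span)
  apex_region <- if (y_apex <= y_lt) "lumbar" else "thoracic"
  if (params$n_curves == 2) {
    sec_level <- if (apex_region == "thoracic") "L2" else "T8"
    y_sec <- y[tmpl$label == sec_level]
    x <- x - sgn * half_sine_bump(y, y_sec, params$lateral_amplitude / 2, 150)
  }
  set.seed(params$seed)
  n <- nrow(tmpl)
  x <- x + stats::rnorm(n, 0, params$noise_sd)
  ynoisy <- y + stats::rnorm(n, 0, params$noise_sd)
  z <- z + stats::rnorm(n, 0, params$noise_sd)
  pts <- data.frame(label = tmpl$label, kind = tmpl$kind,
                    x = x, y = ynoisy, z = z, stringsAsFactors = FALSE)
  spine <- spine_centroids(pts, patient_id = params$patient_id,
                           lt_label = "T12/L1")
  attr(spine, "truth") <- c(unclass(params),
                            list(apex_region = apex_region,
                                 realized_apex = realized_apex_label(spine, sgn)))
  spine
}

# lateral offset of each centroid from the L5-C7 chord (vector rejection of
# the projection of +x onto the chord's orthogonal complement); the realized
# apex is the largest offset on the convex side
realized_apex_label <- function(spine, sgn) {
  P <- as.matrix(spine[, c("x", "y", "z")])
  p5 <- P[match("L5", spine$label), ]
  u <- P[match("C7", spine$label), ] - p5
  u <- u / sqrt(sum(u^2))
  a <- c(1, 0, 0) - sum(c(1, 0, 0) * u) * u
  a <- a / sqrt(sum(a^2))
  ell <- as.numeric(sweep(P, 2, p5) %*% a)
  if (all(sgn * ell <= 0)) return(NA_character_)
  spine$label[which.max(sgn * ell)]
}

#' Cohort mix specification
#'
#' Parameter distributions from which [generate_cohort()] draws: uniform
#' ranges for amplitude, noise and sagittal depths, uniform choice over
#' apex levels and convexity.
#'
#' @param amplitude Length-2 range of lateral amplitudes (mm).
#' @param apex_levels Pool of apex labels (kept away from the LT transition
#'   so each curve is unambiguously lumbar or thoracic).
#' @param p_right Probability of right convexity.
#' @param noise Length-2 range of per-spine `noise_sd` (mm).
#' @param kyphosis,lordosis Length-2 ranges of sagittal arc depths (mm).
#' @param p_two_curves Probability of a compensatory second curve.
#' @return A list of class `cohort_mix`.
#' @export
cohort_mix <- function(amplitude = c(0, 60),
                       apex_levels = c("L4", "L3", "L2", "L1",
                                       "T9", "T8", "T7", "T6", "T5", "T4"),
                       p_right = 0.5, noise = c(0, 1),
                       kyphosis = c(20, 45), lordosis = c(15, 35),
                       p_two_curves = 0) {
  structure(list(amplitude = amplitude, apex_levels = apex_levels,
                 p_right = p_right, noise = noise, kyphosis = kyphosis,
                 lordosis = lordosis, p_two_curves = p_two_curves),
            class = "cohort_mix")
}

#' Generate a synthetic cohort
#'
#' Draws `n` parameter sets from a [cohort_mix()] and generates the spines.
#' Fully reproducible from `seed`.
#'
#' @param n Number of spines (>= 1).
#' @param mix A `cohort_mix` specification.
#' @param seed Integer seed.
#' @return List with `spines` (list of [spine_centroids]) and `truth`
#'   (data frame of the generating parameters and derived ground truths,
#'   one row per spine).
#' @export
generate_cohort <- function(n, mix = cohort_mix(), seed = 1) {
  if (n < 1) stop_validation("n must be >= 1")
  set.seed(seed)
  draws <- data.frame(
    patient_id = sprintf("syn-%03d", seq_len(n)),
    lateral_amplitude = stats::runif(n, mix$amplitude[1], mix$amplitude[2]),
    apex_level = sample(mix$apex_levels, n, replace = TRUE),
    convexity = ifelse(stats::runif(n) < mix$p_right, "right", "left"),
    n_curves = ifelse(stats::runif(n) < mix$p_two_curves, 2, 1),
    kyphosis_depth = stats::runif(n, mix$kyphosis[1], mix$kyphosis[2]),
    lordosis_depth = stats::runif(n, mix$lordosis[1], mix$lordosis[2]),
    noise_sd = stats::runif(n, mix$noise[1], mix$noise[2]),
    seed = sample.int(2147483646L, n),
    stringsAsFactors = FALSE)
  spines <- vector("list", n)
  apex_region <- realized_apex <- character(n)
  for (i in seq_len(n)) {
    p <- spine_params(lateral_amplitude = draws$lateral_amplitude[i],
                      apex_level = draws$apex_level[i],
                      convexity = draws$convexity[i],
                      n_curves = draws$n_curves[i],
                      kyphosis_depth = draws$kyphosis_depth[i],
                      lordosis_depth = draws$lordosis_depth[i],
                      noise_sd = draws$noise_sd[i],
                      seed = draws$seed[i],
                      patient_id = draws$patient_id[i])
    spines[[i]] <- generate_spine(p)
    truth <- attr(spines[[i]], "truth")
    apex_region[i] <- truth$apex_region
    realized_apex[i] <- truth$realized_apex
  }
  draws$apex_region <- apex_region
  draws$realized_apex <- realized_apex
  list(spines = spines, truth = draws)
}

#' Write a cohort to disk
#'
#' One centroid CSV per spine plus a `truth.csv` of generating parameters.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(cohort$spines, function(sp) {
    p <- file.path(dir, paste0(attr(sp, "patient_id"), ".csv"))
    write_centroids(sp, p)
    p
  }, "")
  truth_path <- file.path(dir, "truth.csv")
  utils::write.csv(cohort$truth, truth_path, row.names = FALSE)
  invisible(c(paths, truth_path))
}
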