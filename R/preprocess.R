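# Rodrigues rotation matrix about unit axis `a` by angle `theta`.
rotation_about_axis <- function(a, theta) {
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Minimal rotation mapping unit vector `u` onto +y (axis = u x y-hat).
# Identity when u is already within 1e-9 of +y; a half-turn about x when
# u is antiparallel to y.
minimal_rotation_to_y <- function(u) {
  yhat <- c(0, 1, 0)
  cosang <- sum(u * yhat)
  if (cosang > 1 - 1e-18 || sqrt(sum((u - yhat)^2)) < 1e-9) return(diag(3))
  if (cosang < -1 + 1e-12)
    return(rotation_about_axis(c(1, 0, 0), pi))
  axis <- c(-u[3], 0, u[1])            # u x yhat
  axis <- axis / sqrt(sum(axis^2))
  rotation_about_axis(axis, acos(max(-1, min(1, cosang))))
}

#' Normalize a centroid sequence to the canonical frame
#'
#' Applies a similarity transform: translate so L5 sits at the origin,
#' rotate by the minimal rigid rotation taking the L5-C7 chord onto +y,
#' then scale uniformly so the chord length is 500 mm. Shape is preserved
#' exactly (rigid motion plus uniform scale; no shear).
#'
#' @param spine A [spine_centroids] object.
#' @return A `spine_normalized` object (same columns) with attributes
#'   `scale_factor` (dimensionless) and `applied_rotation` (3x3 orthonormal
#'   matrix). Normalizing an already-normalized spine is the identity.
#' @export
#' @examples
#' sp <- generate_spine(spine_params(seed = 1))
#' ns <- normalize_spine(sp)
#' ns[ns$label == "C7", c("x", "y", "z")]  # (0, 500, 0)
normalize_spine <- function(spine) {
  validate_centroids(spine)
  P <- as.matrix(spine[, c("x", "y", "z")])
  p5 <- P[match("L5", spine$label), ]
  p7 <- P[match("C7", spine$label), ]
  chord <- p7 - p5
  len <- sqrt(sum(chord^2))
  if (len < 1e-9)
    stop_geometry("degenerate geometry: L5 and C7 coincide")
  R <- minimal_rotation_to_y(chord / len)
  s <- 500 / len
  Q <- s * t(R %*% t(sweep(P, 2, p5)))
  out <- spine
  out$x <- Q[, 1]; out$y <- Q[, 2]; out$z <- Q[, 3]
  structure(out,
            class = c("spine_normalized", "spine_centroids", "data.frame"),
            patient_id = attr(spine, "patient_id"),
            lt_label = attr(spine, "lt_label"),
            scale_factor = s,
            applied_rotation = R)
}

# lumbar/thoracic region of each centroid, by order relative to the LT
# disc (the LT disc itself belongs to the lumbar region, matching the
# arc-length rule used on the interpolated curve).
centroid_regions <- function(spine) {
  lt_row <- which(spine$label == attr(spine, "lt_label") & spine$kind == "disc")
  ifelse(seq_len(nrow(spine)) <= lt_row, "lumbar", "thoracic")
}
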