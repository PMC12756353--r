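# Fixture builders used across the suite. Everything is generated in code;
# no binary fixtures.

# straight vertical spine on the template axis (no deformity at all)
straight_spine <- function(patient_id = "straight") {
  tmpl <- spineclass:::spine_template()
  spine_centroids(data.frame(label = tmpl$label, kind = tmpl$kind,
                             x = 0, y = tmpl$y, z = 0),
                  patient_id = patient_id)
}

# centroids on a circular arc of radius R (frontal plane), chord exactly
# 500 mm so normalization leaves the radius unchanged
arc_spine <- function(R, plane = c("frontal", "sagittal")) {
  plane <- match.arg(plane)
  tmpl <- spineclass:::spine_template()
  half <- asin(250 / R)
  th <- seq(-half, half, length.out = nrow(tmpl))
  d <- R * cos(th) - R * cos(half)
  pts <- if (plane == "frontal")
    data.frame(label = tmpl$label, kind = tmpl$kind,
               x = d, y = 250 + R * sin(th), z = 0)
  else
    data.frame(label = tmpl$label, kind = tmpl$kind,
               x = 0, y = 250 + R * sin(th), z = d)
  spine_centroids(pts, patient_id = sprintf("arc-%g", R))
}

# hand-built planar curve (bypasses the pipeline) for direct index tests
planar_curve <- function(displacement, height, region,
                         plane = "frontal", arc_s = NULL) {
  if (is.null(arc_s)) arc_s <- seq_along(displacement) - 1
  structure(data.frame(arc_s = arc_s, displacement = displacement,
                       height = height, region = region),
            class = c("spine_planar", "data.frame"), plane = plane)
}

# mirror a spine laterally (patient right <-> left)
mirror_spine <- function(spine) {
  out <- spine
  out$x <- -out$x
  out
}

# random rigid transform + uniform scale applied to a spine
rigid_transform_spine <- function(spine, angles, translation, scale = 1) {
  Rx <- spineclass:::rotation_about_axis(c(1, 0, 0), angles[1])
  Ry <- spineclass:::rotation_about_axis(c(0, 1, 0), angles[2])
  Rz <- spineclass:::rotation_about_axis(c(0, 0, 1), angles[3])
  P <- as.matrix(spine[, c("x", "y", "z")])
  Q <- scale * t(Rz %*% Ry %*% Rx %*% t(P)) +
    matrix(translation, nrow(P), 3, byrow = TRUE)
  out <- spine
  out$x <- Q[, 1]; out$y <- Q[, 2]; out$z <- Q[, 3]
  out
}

# the two published concordance count sets (94-patient AIS cohort)
vertical_concordance_fixture <- function() {
  concordance_table(c(paste("Lenke type", 1:6), "Normal"),
                    validated = c(4, 2, 29, 2, 9, 13, 9),
                    not_validated = c(4, 0, 4, 0, 0, 2, 16))
}

sagittal_concordance_fixture <- function() {
  concordance_table(c("+", "-", "N", "/"),
                    validated = c(28, 0, 36, 0),
                    not_validated = c(3, 2, 9, 16))
}

# brute-force chi-square oracle: explicit loops over cells, no vectorization
chisq_loop_oracle <- function(O) {
  N <- sum(O)
  stat <- 0
  for (i in seq_len(nrow(O))) {
    for (j in seq_len(ncol(O))) {
      E <- sum(O[i, ]) * sum(O[, j]) / N
      stat <- stat + (O[i, j] - E)^2 / E
    }
  }
  stat
}
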