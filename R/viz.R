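#' Curvature-strain color mapping
#'
#' Maps unsigned curvature monotonically onto a two-color ramp: green at
#' zero (normal segment) to yellow at `kappa_max` for the frontal plane, or
#' green to magenta for the sagittal plane. Curvatures at or above
#' `kappa_max` saturate at the extreme color.
#'
#' @param kappa Numeric vector of curvatures (1/mm).
#' @param plane `"frontal"` or `"sagittal"`.
#' @param kappa_max Curvature mapped to full saturation (default 0.02/mm,
#'   i.e. a 50 mm radius of curvature).
#' @return Vector of hex colors.
#' @export
strain_colors <- function(kappa, plane = c("frontal", "sagittal"),
                          kappa_max = 0.02) {
  plane <- match.arg(plane)
  t <- pmin(pmax(kappa / kappa_max, 0), 1)
  extreme <- if (plane == "frontal") "#FFFF00" else "#FF00FF"
  ramp <- grDevices::colorRamp(c("#00C800", extreme))
  grDevices::rgb(ramp(t), maxColorValue = 255)
}

# line widths growing with normalized curvature strain
strain_lwd <- function(kappa, kappa_max = 0.02, scale = 4) {
  1 + scale * pmin(kappa / kappa_max, 1)
}

draw_projection_panel <- function(curve, planar, spine_norm, plane, kappa_max) {
  kappa <- curvature_profile(planar)
  cols <- strain_colors(kappa, plane = plane, kappa_max = kappa_max)
  lwds <- strain_lwd(kappa, kappa_max)
  d <- planar$displacement; h <- planar$height
  graphics::plot(d, h, type = "n", asp = 1,
                 xlab = if (plane == "frontal") "lateral x (mm)" else "posterior z (mm)",
                 ylab = "cranial y (mm)",
                 main = paste(plane, "projection"))
  n <- length(d)
  graphics::segments(d[-n], h[-n], d[-1], h[-1], col = cols[-n], lwd = lwds[-n])
  graphics::abline(v = 0, col = "grey70", lty = 3)
  # centroid markers: vertebrae large, discs small; LT disc highlighted
  is_disc <- spine_norm$kind == "disc"
  px <- if (plane == "frontal") spine_norm$x else spine_norm$z
  graphics::points(px[!is_disc], spine_norm$y[!is_disc], pch = 16,
                   cex = 1.0, col = "blue")
  graphics::points(px[is_disc], spine_norm$y[is_disc], pch = 16,
                   cex = 0.45, col = "blue")
  lt <- spine_norm$label == attr(spine_norm, "lt_label")
  graphics::points(px[lt], spine_norm$y[lt], pch = 1, cex = 2, col = "red")
  graphics::text(px[lt], spine_norm$y[lt], "LT", pos = 4, col = "red", cex = 0.8)
}

#' Render the per-patient graphical report
#'
#' One composite PNG: frontal, sagittal and axial panels of the
#' interpolated curve with centroid markers (large dots = vertebrae, small
#' = discs), the LT disc highlighted, apex annotations, curve segments
#' colored and thickened by normalized curvature strain, an index box (std
#' quadrants, upper row thoracic, lower row lumbar; kl below) and the class
#' estimation text.
#'
#' @param cls A `spine_classification`.
#' @param spine The [spine_centroids] input it came from.
#' @param path Output PNG path.
#' @param kappa_max Curvature at full color saturation (1/mm).
#' @param width,height Device size in pixels.
#' @return Invisibly, `path`.
#' @export
render_report <- function(cls, spine, path, kappa_max = 0.02,
                          width = 1200, height = 700) {
  norm <- normalize_spine(spine)
  curve <- interpolate_spine(norm)
  ok <- tryCatch({
    grDevices::png(path, width = width, height = height)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io(sprintf("cannot open image device for %s", path))
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(c(1, 2, 3, 4, 4, 4), 2, 3, byrow = TRUE),
                   heights = c(3, 1))
  graphics::par(mar = c(4, 4, 3, 1))
  frontal <- project_curve(curve, "frontal")
  sagittal <- project_curve(curve, "sagittal")
  draw_projection_panel(curve, frontal, norm, "frontal", kappa_max)
  for (i in seq_len(nrow(cls$apexes))) {
    a <- cls$apexes[i, ]
    if (startsWith(a$name, "ApexS")) {
      yy <- norm$y[norm$label == a$label]
      graphics::text(a$displacement, yy, a$name, pos = if (a$displacement >= 0) 4 else 2,
                     cex = 0.8, col = "darkorange3")
    }
  }
  draw_projection_panel(curve, sagittal, norm, "sagittal", kappa_max)
  for (i in seq_len(nrow(cls$apexes))) {
    a <- cls$apexes[i, ]
    if (a$name %in% c("ApexT", "ApexL")) {
      yy <- norm$y[norm$label == a$label]
      graphics::text(a$displacement, yy, a$name, pos = 4, cex = 0.8,
                     col = "darkorange3")
    }
  }
  # axial view (top-down): combined lateral/sagittal strain in shades of red
  axial <- project_curve(curve, "axial")
  kf <- pmin(curvature_profile(frontal) / kappa_max, 1)
  ks <- pmin(curvature_profile(sagittal) / kappa_max, 1)
  comb <- pmin(kf + ks, 1)
  cols <- grDevices::rgb(comb, (1 - comb) * 0.8, 0)
  graphics::plot(axial$displacement, axial$height, type = "n", asp = 1,
                 xlab = "lateral x (mm)", ylab = "posterior z (mm)",
                 main = "axial projection")
  n <- nrow(axial)
  graphics::segments(axial$displacement[-n], axial$height[-n],
                     axial$displacement[-1], axial$height[-1],
                     col = cols[-n], lwd = strain_lwd(pmax(kf, ks) * kappa_max, kappa_max)[-n])
  # text panel: index box + class estimation
  graphics::par(mar = c(1, 2, 1, 1))
  graphics::plot.new()
  sag_dev <- if (is.na(cls$kl)) 0 else min(abs(cls$kl) / 1, 1)
  bg <- grDevices::rgb(1, 1 - 0.5 * sag_dev, 1 - min(max(cls$std) / 14.5, 1))
  graphics::rect(0, 0, 1, 1, col = bg, border = NA)
  graphics::text(0.02, 0.80, adj = 0, cex = 1.1, labels = sprintf(
    "std (mm):   TL %.2f   TR %.2f", cls$std[["tl"]], cls$std[["tr"]]))
  graphics::text(0.02, 0.55, adj = 0, cex = 1.1, labels = sprintf(
    "            LL %.2f   LR %.2f", cls$std[["ll"]], cls$std[["lr"]]))
  graphics::text(0.02, 0.30, adj = 0, cex = 1.1, labels = sprintf(
    "kl: %s    s: %s    v: %s",
    format(cls$kl, digits = 3), format(cls$s, digits = 3),
    format(cls$v, digits = 3)))
  graphics::text(0.5, 0.08, adj = 0.5, cex = 1.3, font = 2,
                 labels = cls$description)
  invisible(path)
}

#' Concordance charts
#'
#' Writes a stacked bar chart of observed validated / not-validated counts
#' per group and a heat map of the expected frequencies under independence.
#'
#' @param table A `concordance_table`.
#' @param dir Output directory (created on demand).
#' @param prefix File name prefix.
#' @return Character vector of the two file paths.
#' @export
concordance_charts <- function(table, dir, prefix = "concordance") {
  if (!dir.exists(dir)) {
    ok <- tryCatch(dir.create(dir, recursive = TRUE),
                   warning = function(w) FALSE, error = function(e) FALSE)
    if (!isTRUE(ok) && !dir.exists(dir))
      stop_io(sprintf("cannot create output directory %s", dir))
  }
  bar_path <- file.path(dir, paste0(prefix, "_stacked_bar.png"))
  heat_path <- file.path(dir, paste0(prefix, "_expected_heatmap.png"))
  O <- t(cbind(table$validated, table$not_validated))
  grDevices::png(bar_path, width = 900, height = 600)
  graphics::barplot(O, names.arg = table$group, col = c("#2c7fb8", "#fdae61"),
                    legend.text = c("validated", "not validated"),
                    ylab = "patients", las = 2,
                    main = "Observed validation counts by group")
  grDevices::dev.off()
  row_tot <- rowSums(t(O)); col_tot <- colSums(t(O)); N <- sum(O)
  E <- outer(row_tot, col_tot) / N
  grDevices::png(heat_path, width = 900, height = 600)
  graphics::image(seq_len(ncol(E)), seq_len(nrow(E)), t(E),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "Expected frequencies under independence")
  graphics::axis(1, at = 1:2, labels = c("validated", "not validated"))
  graphics::axis(2, at = seq_len(nrow(E)), labels = table$group, las = 2)
  for (i in seq_len(nrow(E))) for (j in seq_len(ncol(E)))
    graphics::text(j, i, sprintf("%.1f", E[i, j]))
  grDevices::dev.off()
  c(bar_path, heat_path)
}
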