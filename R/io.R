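# Canonical caudal->cranial ordering of vertebral labels used for sanity
# checks and by the synthetic generator.
VERTEBRA_ORDER <- c(paste0("L", 5:1), paste0("T", 12:1), "C7")

#' Construct a centroid sequence
#'
#' An ordered, labeled set of 3D centroids (vertebral bodies and
#' intervertebral discs) running caudal to cranial from L5 to C7, in
#' millimetres. Coordinate convention (right-handed): +x patient's right,
#' +y cranial, +z posterior. Optional per-point rotation angles are carried
#' as metadata and never used in any computation.
#'
#' @param points Data frame with columns `label`, `kind` (`"vertebra"` or
#'   `"disc"`), `x`, `y`, `z` and optionally `rot_x`, `rot_y`, `rot_z`,
#'   ordered caudal to cranial.
#' @param patient_id Identifier string.
#' @param lt_label Label of the disc at the lumbar-to-thoracic transition
#'   (the LT disc), which splits the curve into lumbar and thoracic regions.
#' @return A data frame of class `spine_centroids` with attributes
#'   `patient_id` and `lt_label`.
#' @export
#' @examples
#' sp <- generate_spine(spine_params(lateral_amplitude = 0, noise_sd = 0))
#' head(sp)
spine_centroids <- function(points, patient_id = "unknown", lt_label = "T12/L1") {
  pts <- as.data.frame(points, stringsAsFactors = FALSE)
  need <- c("label", "kind", "x", "y", "z")
  miss <- setdiff(need, names(pts))
  if (length(miss))
    stop_validation(paste("centroid table lacks column(s):", paste(miss, collapse = ", ")))
  pts$label <- as.character(pts$label)
  pts$kind <- as.character(pts$kind)
  for (cc in intersect(c("x", "y", "z", "rot_x", "rot_y", "rot_z"), names(pts)))
    pts[[cc]] <- as.numeric(pts[[cc]])
  obj <- structure(pts, class = c("spine_centroids", "data.frame"),
                   patient_id = as.character(patient_id),
                   lt_label = lt_label)
  validate_centroids(obj)
  obj
}

validate_centroids <- function(spine) {
  pts <- spine
  n <- nrow(pts)
  if (n < 4L)
    stop_validation("a centroid sequence needs at least 4 points for cubic interpolation")
  bad <- which(!is.finite(pts$x) | !is.finite(pts$y) | !is.finite(pts$z))
  if (length(bad))
    stop_validation(sprintf("non-finite coordinates at row %d (label '%s')",
                            bad[1], pts$label[bad[1]]))
  if (!all(pts$kind %in% c("vertebra", "disc"))) {
    bad <- which(!pts$kind %in% c("vertebra", "disc"))[1]
    stop_validation(sprintf("row %d: kind must be 'vertebra' or 'disc', got '%s'",
                            bad, pts$kind[bad]))
  }
  dup <- which(duplicated(pts$label))
  if (length(dup))
    stop_validation(sprintf("duplicate label '%s' at row %d", pts$label[dup[1]], dup[1]))
  if (any(pts$kind[-1] == pts$kind[-n])) {
    bad <- which(pts$kind[-1] == pts$kind[-n])[1] + 1L
    stop_validation(sprintf("row %d: vertebra and disc labels must alternate", bad))
  }
  if (!"L5" %in% pts$label || !"C7" %in% pts$label)
    stop_validation("centroid sequence must contain vertebrae labeled 'L5' and 'C7'")
  lt <- attr(spine, "lt_label")
  if (sum(pts$label == lt & pts$kind == "disc") != 1L)
    stop_validation(sprintf("exactly one disc labeled '%s' (the LT disc) is required", lt))
  # when all vertebra labels are standard, their file order must be anatomical
  vlab <- pts$label[pts$kind == "vertebra"]
  if (all(vlab %in% VERTEBRA_ORDER)) {
    idx <- match(vlab, VERTEBRA_ORDER)
    if (is.unsorted(idx, strictly = TRUE)) {
      bad <- which(diff(idx) <= 0)[1] + 1L
      row <- which(pts$label == vlab[bad])
      stop_validation(sprintf("row %d (label '%s'): vertebrae are not ordered caudal to cranial",
                              row, vlab[bad]))
    }
  }
  invisible(spine)
}

#' Read a centroid table from CSV
#'
#' Expects a comma-separated file (dot decimal separator, mandatory header)
#' with columns `label,kind,x_mm,y_mm,z_mm` and optionally
#' `rot_x,rot_y,rot_z`, rows ordered L5 to C7 (caudal to cranial).
#'
#' @param path CSV file path.
#' @param patient_id Identifier; defaults to the file name without extension.
#' @param lt_label Label of the lumbar-to-thoracic transition disc.
#' @return A [spine_centroids] object.
#' @export
read_centroids <- function(path, patient_id = NULL, lt_label = "T12/L1") {
  if (!file.exists(path)) stop_io(sprintf("centroid file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "kind", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_validation(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  pts <- data.frame(label = df$label, kind = df$kind,
                    x = df$x_mm, y = df$y_mm, z = df$z_mm,
                    stringsAsFactors = FALSE)
  for (rc in c("rot_x", "rot_y", "rot_z"))
    if (rc %in% names(df)) pts[[rc]] <- df[[rc]]
  if (is.null(patient_id))
    patient_id <- tools::file_path_sans_ext(basename(path))
  spine_centroids(pts, patient_id = patient_id, lt_label = lt_label)
}

#' Write a centroid table to CSV
#'
#' Inverse of [read_centroids()]; the written file round-trips losslessly.
#'
#' @param spine A [spine_centroids] object.
#' @param path Output file path.
#' @export
write_centroids <- function(spine, path) {
  out <- data.frame(label = spine$label, kind = spine$kind,
                    x_mm = spine$x, y_mm = spine$y, z_mm = spine$z)
  for (rc in c("rot_x", "rot_y", "rot_z"))
    if (rc %in% names(spine)) out[[rc]] <- spine[[rc]]
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parse a Lenke classification code
#'
#' Accepts codes of the form `<type><lumbar><sagittal>` where type is 1-6,
#' the lumbar modifier is A/B/C and the sagittal modifier is `+`, `-`
#' (ASCII hyphen or Unicode minus) or `N`; or the literal `"Normal"` /
#' `"Normal spine"`. The lumbar modifier is parsed but plays no role in the
#' concordance analysis (it references the central sacral vertical line,
#' which is not computable from centroid data).
#'
#' @param code Character scalar, e.g. `"6BN"`, `"5B+"`, `"Normal spine"`.
#' @return A list with `curve_type` (`"1"`..`"6"` or `"Normal"`),
#'   `lumbar_modifier` (`"A"/"B"/"C"` or `NA`) and `sagittal_modifier`
#'   (`"+"/"-"/"N"` or `NA`).
#' @export
#' @examples
#' parse_lenke_code("6BN")
#' parse_lenke_code("5B+")
parse_lenke_code <- function(code) {
  if (length(code) != 1L || !is.character(code))
    stop_validation("lenke code must be a single string")
  raw <- trimws(code)
  if (raw %in% c("Normal", "Normal spine"))
    return(list(curve_type = "Normal",
                lumbar_modifier = NA_character_,
                sagittal_modifier = NA_character_))
  # normalize Unicode minus/dashes to ASCII hyphen
  canon <- gsub("−|–|—", "-", raw)
  if (!grepl("^[1-6][ABC][+N-]$", canon))
    stop_validation(sprintf("unparseable Lenke code: '%s'", code))
  list(curve_type = substr(canon, 1, 1),
       lumbar_modifier = substr(canon, 2, 2),
       sagittal_modifier = substr(canon, 3, 3))
}

#' Read a table of Lenke codes
#'
#' @param path CSV with header `patient_id,lenke_code`.
#' @return A data frame with columns `patient_id`, `curve_type`,
#'   `lumbar_modifier`, `sagittal_modifier` (one row per patient).
#' @export
read_lenke_labels <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("Lenke file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("patient_id", "lenke_code") %in% names(df)))
    stop_validation(sprintf("%s: header must be patient_id,lenke_code", path))
  if (nrow(df) == 0L)
    return(data.frame(patient_id = character(), curve_type = character(),
                      lumbar_modifier = character(), sagittal_modifier = character(),
                      stringsAsFactors = FALSE))
  dup <- which(duplicated(df$patient_id))
  if (length(dup))
    stop_validation(sprintf("duplicate patient_id '%s' at row %d",
                            df$patient_id[dup[1]], dup[1]))
  parsed <- lapply(df$lenke_code, parse_lenke_code)
  data.frame(patient_id = df$patient_id,
             curve_type = vapply(parsed, `[[`, "", "curve_type"),
             lumbar_modifier = vapply(parsed, `[[`, "", "lumbar_modifier"),
             sagittal_modifier = vapply(parsed, `[[`, "", "sagittal_modifier"),
             stringsAsFactors = FALSE)
}

#' Write a classification report to JSON
#'
#' Serializes a [classify_patient()] result. Undefined indices are written
#' as explicit JSON `null` (never 0). The file re-reads losslessly with
#' [read_report()].
#'
#' @param cls A `spine_classification` object.
#' @param path Output path.
#' @export
write_report <- function(cls, path) {
  stopifnot(inherits(cls, "spine_classification"))
  num_or_null <- function(x) if (is.null(x) || is.na(x)) NULL else unname(x)
  apexes <- cls$apexes
  apex_list <- if (nrow(apexes) == 0) list() else
    lapply(seq_len(nrow(apexes)), function(i)
      list(name = apexes$name[i], label = apexes$label[i],
           displacement = apexes$displacement[i]))
  payload <- list(
    patient_id = cls$patient_id,
    std = list(tl = unname(cls$std[["tl"]]), tr = unname(cls$std[["tr"]]),
               ll = unname(cls$std[["ll"]]), lr = unname(cls$std[["lr"]])),
    s = num_or_null(cls$s), v = num_or_null(cls$v), kl = num_or_null(cls$kl),
    m_t = num_or_null(cls$m_t), m_l = num_or_null(cls$m_l),
    severity = cls$severity, side = cls$side, vertical = cls$vertical,
    sagittal = cls$sagittal, description = cls$description,
    apexes = apex_list,
    scale_factor = num_or_null(cls$scale_factor),
    config_digest = cls$config_digest)
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         null = "null")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io(sprintf("cannot write report to %s", path))
  invisible(path)
}

#' @rdname write_report
#' @return [read_report()] returns a `spine_classification` object.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("report not found: %s", path))
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  apexes <- if (length(p$apexes) == 0)
    data.frame(name = character(), label = character(),
               displacement = numeric(), stringsAsFactors = FALSE)
  else
    do.call(rbind, lapply(p$apexes, function(a)
      data.frame(name = a$name, label = a$label,
                 displacement = as.numeric(a$displacement),
                 stringsAsFactors = FALSE)))
  structure(list(
    patient_id = p$patient_id,
    std = c(tl = as.numeric(p$std$tl), tr = as.numeric(p$std$tr),
            ll = as.numeric(p$std$ll), lr = as.numeric(p$std$lr)),
    s = num_or_na(p$s), v = num_or_na(p$v), kl = num_or_na(p$kl),
    m_t = num_or_na(p$m_t), m_l = num_or_na(p$m_l),
    severity = p$severity, side = p$side, vertical = p$vertical,
    sagittal = p$sagittal, description = p$description,
    apexes = apexes,
    scale_factor = num_or_na(p$scale_factor),
    config_digest = p$config_digest),
    class = "spine_classification")
}

#' @export
print.spine_classification <- function(x, ...) {
  cat(sprintf("Patient %s: %s\n", x$patient_id, x$description))
  cat(sprintf("  std (mm)  TL %.2f  TR %.2f  LL %.2f  LR %.2f\n",
              x$std[["tl"]], x$std[["tr"]], x$std[["ll"]], x$std[["lr"]]))
  cat(sprintf("  s %s  v %s  kl %s\n",
              format(x$s, digits = 3), format(x$v, digits = 3),
              format(x$kl, digits = 3)))
  if (nrow(x$apexes))
    cat("  apexes:", paste(sprintf("%s=%s (%.1f mm)", x$apexes$name,
                                   x$apexes$label, x$apexes$displacement),
                           collapse = ", "), "\n")
  invisible(x)
}
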