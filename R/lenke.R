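# Row orders of the two concordance tables.
VERTICAL_GROUPS <- c(paste("Lenke type", 1:6), "Normal")
SAGITTAL_GROUPS <- c("+", "-", "N", "/")

#' Expected vertical categories for a Lenke curve type
#'
#' Correspondence between Lenke's anatomical curve regions and the
#' vertical-index categories: types 1-2 (main / double thoracic) map to
#' thoracic or mainly thoracic; types 3-4 (double / triple major) to mainly
#' thoracic or thoraco-lumbar; type 5 (thoracolumbar/lumbar) to lumbar,
#' mainly lumbar or thoraco-lumbar; type 6 (thoracolumbar/lumbar - main
#' thoracic) to thoraco-lumbar or mainly lumbar. A Lenke-normal spine is
#' expected to classify as no scoliosis (vertical label `"n/a"`).
#'
#' @param curve_type `"1"`..`"6"` (or the integer) or `"Normal"`.
#' @return Character vector of acceptable vertical labels.
#' @export
expected_vertical_categories <- function(curve_type) {
  switch(as.character(curve_type),
    "1" = , "2" = c("Thoracic", "Mainly thoracic"),
    "3" = , "4" = c("Mainly thoracic", "Thoraco-lumbar"),
    "5" = c("Lumbar", "Mainly lumbar", "Thoraco-lumbar"),
    "6" = c("Thoraco-lumbar", "Mainly lumbar"),
    "Normal" = "n/a",
    stop_validation(sprintf("unknown Lenke curve type: '%s'", curve_type)))
}

#' Expected sagittal categories for a Lenke sagittal modifier
#'
#' `+` (hyperkyphotic) corresponds to significant or extreme kyphosis; `N`
#' (normal kyphosis) to a normal spine, slight kyphosis or slight lordosis;
#' `-` (hypokyphotic) has no corresponding category and is never validated.
#'
#' @param modifier `"+"`, `"-"` (ASCII hyphen or Unicode minus) or `"N"`.
#' @return Character vector of acceptable sagittal labels (empty for `-`).
#' @export
expected_sagittal_categories <- function(modifier) {
  mod <- gsub("−|–|—", "-", as.character(modifier))
  switch(mod,
    "+" = c("Significant kyphosis", "Extreme kyphosis"),
    "-" = character(0),
    "N" = c("Normal spine", "Slight kyphosis", "Slight lordosis"),
    stop_validation(sprintf("unknown Lenke sagittal modifier: '%s'", modifier)))
}

#' Validate one classification against its Lenke record
#'
#' Frontal axis: the vertical-index label must fall in
#' [expected_vertical_categories()] for the patient's Lenke type; a
#' Lenke-normal patient is validated iff the severity class is
#' `"No scoliosis"`. Sagittal axis: the kl label must fall in
#' [expected_sagittal_categories()] for the sagittal modifier (a
#' Lenke-normal patient is held to the `N` expectation). Patients whose kl
#' label is extreme or significant lordosis form the `"/"` group - lordosis
#' has no Lenke counterpart - and are never validated on the sagittal axis.
#'
#' @param cls A `spine_classification`.
#' @param lenke One row of [read_lenke_labels()] output (as a list or
#'   one-row data frame).
#' @return List with `v_group`, `v_status`, `kl_group`, `kl_status`
#'   (statuses are `"validated"` / `"not_validated"`).
#' @export
validate_patient <- function(cls, lenke) {
  if (!identical(as.character(cls$patient_id), as.character(lenke$patient_id)))
    stop_validation(sprintf("patient id mismatch: classification '%s' vs Lenke '%s'",
                            cls$patient_id, lenke$patient_id))
  type <- as.character(lenke$curve_type)
  if (type == "Normal") {
    v_group <- "Normal"
    v_ok <- cls$severity == "No scoliosis"
  } else {
    v_group <- paste("Lenke type", type)
    v_ok <- cls$vertical %in% expected_vertical_categories(type)
  }
  lordotic <- cls$sagittal %in% c("Extreme lordosis", "Significant lordosis")
  mod <- if (type == "Normal") "N" else as.character(lenke$sagittal_modifier)
  kl_group <- if (lordotic) "/" else mod
  kl_ok <- !lordotic && cls$sagittal %in% expected_sagittal_categories(mod)
  list(v_group = v_group,
       v_status = if (v_ok) "validated" else "not_validated",
       kl_group = kl_group,
       kl_status = if (kl_ok) "validated" else "not_validated")
}

#' Aggregate per-patient validation statuses into a concordance table
#'
#' @param records Data frame with columns `group` and `status`
#'   (`"validated"` / `"not_validated"`).
#' @param groups Optional fixed row order; defaults to the groups present,
#'   in order of first appearance.
#' @return A data frame of class `concordance_table` with columns `group`,
#'   `validated`, `not_validated`.
#' @export
build_concordance <- function(records, groups = NULL) {
  if (nrow(records) == 0) stop_validation("no validation records to aggregate")
  if (!all(records$status %in% c("validated", "not_validated")))
    stop_validation("status must be 'validated' or 'not_validated'")
  if (is.null(groups)) groups <- unique(records$group)
  out <- data.frame(
    group = groups,
    validated = vapply(groups, function(g)
      sum(records$group == g & records$status == "validated"), 0L),
    not_validated = vapply(groups, function(g)
      sum(records$group == g & records$status == "not_validated"), 0L),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("concordance_table", "data.frame"))
}

#' Build a concordance table directly from counts
#'
#' @param group Character vector of group labels.
#' @param validated,not_validated Non-negative integer counts per group.
#' @return A `concordance_table`.
#' @export
#' @examples
#' concordance_table(c("+", "-", "N", "/"), c(28, 0, 36, 0), c(3, 2, 9, 16))
concordance_table <- function(group, validated, not_validated) {
  if (any(validated < 0) || any(not_validated < 0))
    stop_validation("counts must be non-negative")
  if (sum(validated) + sum(not_validated) == 0)
    stop_validation("grand total must be positive")
  structure(data.frame(group = as.character(group),
                       validated = as.numeric(validated),
                       not_validated = as.numeric(not_validated),
                       stringsAsFactors = FALSE),
            class = c("concordance_table", "data.frame"))
}

#' Read a concordance table from CSV
#'
#' @param path CSV with header `group,validated,not_validated`.
#' @return A `concordance_table`.
#' @export
read_concordance <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("concordance file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("group", "validated", "not_validated") %in% names(df)))
    stop_validation(sprintf("%s: header must be group,validated,not_validated", path))
  concordance_table(df$group, df$validated, df$not_validated)
}

#' Pearson chi-square test of a concordance table
#'
#' Tests independence of validation status and group: expected counts
#' E = row total x column total / grand total, statistic
#' sum((O - E)^2 / E) over all cells, df = (rows - 1) x (cols - 1), p =
#' upper-tail chi-square probability.
#'
#' @param table A `concordance_table`.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' tab <- concordance_table(c("+", "-", "N", "/"), c(28, 0, 36, 0), c(3, 2, 9, 16))
#' pearson_chi_square(tab)  # statistic 48.39, df 3
pearson_chi_square <- function(table) {
  O <- cbind(table$validated, table$not_validated)
  row_tot <- rowSums(O)
  col_tot <- colSums(O)
  N <- sum(O)
  if (any(row_tot == 0) || any(col_tot == 0))
    stop_validation("degenerate table: a zero row or column total gives expected count 0")
  E <- outer(row_tot, col_tot) / N
  stat <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Overall percent agreement of a concordance table
#'
#' @param table A `concordance_table`.
#' @return Percentage in \[0, 100\]: 100 x validated / grand total.
#' @export
percent_agreement <- function(table) {
  tot <- sum(table$validated) + sum(table$not_validated)
  if (tot == 0) stop_validation("grand total must be positive")
  100 * sum(table$validated) / tot
}

#' Run the full concordance analysis on a cohort
#'
#' Joins classifications with Lenke records by patient id, validates each
#' patient on the requested axis, and aggregates.
#'
#' @param classifications List of `spine_classification` objects.
#' @param lenke Data frame from [read_lenke_labels()].
#' @param axis `"vertical"` (Lenke type vs v-index categories) or
#'   `"sagittal"` (sagittal modifier vs kl-index categories).
#' @return List with `table` (a `concordance_table`), `chi_square` (from
#'   [pearson_chi_square()]), `agreement_pct` and `unmatched` (patient ids
#'   present on only one side).
#' @export
concordance_analysis <- function(classifications, lenke,
                                 axis = c("vertical", "sagittal")) {
  axis <- match.arg(axis)
  ids <- vapply(classifications, function(c) as.character(c$patient_id), "")
  matched <- intersect(ids, lenke$patient_id)
  unmatched <- union(setdiff(ids, lenke$patient_id),
                     setdiff(lenke$patient_id, ids))
  if (length(matched) == 0) stop_validation("no patients in common")
  recs <- do.call(rbind, lapply(matched, function(id) {
    cls <- classifications[[match(id, ids)]]
    lk <- lenke[lenke$patient_id == id, ]
    v <- validate_patient(cls, lk)
    if (axis == "vertical")
      data.frame(group = v$v_group, status = v$v_status)
    else
      data.frame(group = v$kl_group, status = v$kl_status)
  }))
  groups <- if (axis == "vertical") VERTICAL_GROUPS else SAGITTAL_GROUPS
  tab <- build_concordance(recs, groups = intersect(groups, recs$group))
  # a cohort with an empty status column has no independence test to run
  chi <- tryCatch(pearson_chi_square(tab),
                  spineclass_validation_error = function(e) NULL)
  list(table = tab, chi_square = chi,
       agreement_pct = percent_agreement(tab), unmatched = unmatched)
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Concordance table (validated / not validated)\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-14s %4d / %d\n", x$group[i], as.integer(x$validated[i]),
                as.integer(x$not_validated[i])))
  invisible(x)
}
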