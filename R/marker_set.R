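#' Define a marker set
#'
#' A marker set is the ordered list of body-landmark labels carried by every
#' trial, kinectome and network in an analysis, together with each marker's
#' body side and anatomical group. The default is a 21-marker configuration
#' in the spirit of the Davis clinical gait protocol, covering head, trunk,
#' arms, pelvis, legs and feet, with the 10th thoracic vertebra marker
#' (`T10`) on the trunk.
#'
#' @param labels character vector of unique marker names.
#' @param side character vector, one of `"left"`, `"right"`, `"midline"` per
#'   marker. Left/right markers must come in matched pairs (same label after
#'   stripping the `L_`/`R_` prefix).
#' @param anatomical_group character vector, one of `"head"`, `"trunk"`,
#'   `"upper_arm"`, `"forearm"`, `"pelvis"`, `"leg"`, `"foot"` per marker.
#' @return An object of class `marker_set`: a data frame with columns
#'   `label`, `side`, `anatomical_group`.
#' @examples
#' ms <- default_marker_set()
#' nrow(ms)        # 21
#' subset(ms, anatomical_group == "trunk")
#' @export
marker_set <- function(labels, side, anatomical_group) {
  labels <- as.character(labels)
  side <- match.arg(side, c("left", "right", "midline"), several.ok = TRUE)
  groups <- c("head", "trunk", "upper_arm", "forearm", "pelvis", "leg", "foot")
  anatomical_group <- match.arg(anatomical_group, groups, several.ok = TRUE)
  if (length(side) != length(labels) || length(anatomical_group) != length(labels)) {
    stop_kin("labels, side and anatomical_group must have equal length")
  }
  if (anyDuplicated(labels)) {
    stop_kin("marker labels must be unique")
  }
  # left/right markers must pair up by stem
  stem <- sub("^[LR]_", "", labels)
  for (s in unique(stem[side != "midline"])) {
    sides <- sort(side[stem == s & side != "midline"])
    if (!identical(sides, c("left", "right"))) {
      stop_kin("marker '", s, "' does not have a matched left/right pair")
    }
  }
  out <- data.frame(
    label = labels, side = side, anatomical_group = anatomical_group,
    stringsAsFactors = FALSE
  )
  class(out) <- c("marker_set", "data.frame")
  out
}

#' @rdname marker_set
#' @export
default_marker_set <- function() {
  marker_set(
    labels = c(
      "HEAD_F", "HEAD_B", "C7", "T10",
      "R_SHO", "L_SHO", "R_ELB", "L_ELB", "R_WRI", "L_WRI",
      "SACR", "R_ASIS", "L_ASIS",
      "R_KNE", "L_KNE", "R_ANK", "L_ANK",
      "R_HEE", "L_HEE", "R_TOE", "L_TOE"
    ),
    side = c(
      "midline", "midline", "midline", "midline",
      "right", "left", "right", "left", "right", "left",
      "midline", "right", "left",
      "right", "left", "right", "left",
      "right", "left", "right", "left"
    ),
    anatomical_group = c(
      "head", "head", "trunk", "trunk",
      "upper_arm", "upper_arm", "upper_arm", "upper_arm", "forearm", "forearm",
      "pelvis", "pelvis", "pelvis",
      "leg", "leg", "leg", "leg",
      "foot", "foot", "foot", "foot"
    )
  )
}

#' Read a marker set from a CSV marker-map file
#'
#' The file must have columns `label`, `side`, `anatomical_group`.
#'
#' @param path path to the CSV file.
#' @return A [marker_set()].
#' @export
read_marker_set <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "side", "anatomical_group")
  if (!all(need %in% names(df))) {
    stop_kin("marker-map file must have columns: ", paste(need, collapse = ", "))
  }
  marker_set(df$label, df$side, df$anatomical_group)
}

validate_marker_set <- function(ms, require_t10 = FALSE, n_required = NULL) {
  if (!inherits(ms, "marker_set")) stop_kin("not a marker_set")
  if (!is.null(n_required) && nrow(ms) != n_required) {
    stop_kin("marker set has ", nrow(ms), " markers; expected ", n_required)
  }
  if (require_t10 && !"T10" %in% ms$label) {
    stop_kin("marker set must contain a 'T10' (10th thoracic vertebra) marker")
  }
  invisible(ms)
}
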