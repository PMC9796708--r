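#' Construct a marker trial
#'
#' A trial is one gait-cycle recording: a `frames x markers x 3` array of
#' 3D positions (meters), the sampling rate and an axis map declaring which
#' coordinate column is mediolateral (ML), anteroposterior (AP) and
#' vertical (V).
#'
#' @param positions numeric array `frames x markers x 3`. The third
#'   dimension is stored internally in (ML, AP, V) order.
#' @param marker_set a [marker_set()]; its labels name the second dimension.
#' @param subject_id subject identifier.
#' @param session `"test"` or `"retest"`.
#' @param sampling_rate frames per second (default 120).
#' @param gap_fill if `TRUE`, runs of up to `max_gap` consecutive missing
#'   frames per series are filled by cubic spline interpolation; otherwise
#'   any `NA` is an error.
#' @param max_gap longest fillable gap, in frames.
#' @return An object of class `marker_trial`.
#' @export
marker_trial <- function(positions, marker_set, subject_id, session,
                         sampling_rate = 120, gap_fill = FALSE, max_gap = 5) {
  session <- match.arg(session, c("test", "retest"))
  if (length(dim(positions)) != 3L || dim(positions)[3] != 3L) {
    stop_kin("positions must be a frames x markers x 3 array")
  }
  if (dim(positions)[1] < 5L) {
    stop_kin("trial has ", dim(positions)[1], " frames; at least 5 required")
  }
  validate_marker_set(marker_set)
  if (dim(positions)[2] != nrow(marker_set)) {
    stop_kin(
      "positions have ", dim(positions)[2], " markers but marker set has ",
      nrow(marker_set)
    )
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop_kin("sampling_rate must be > 0")
  }
  if (anyNA(positions)) {
    if (!gap_fill) {
      stop_kin(
        "trial for subject '", subject_id,
        "' contains missing frames; enable gap_fill or clean the data"
      )
    }
    positions <- fill_gaps(positions, max_gap = max_gap)
  }
  if (!all(is.finite(positions))) {
    stop_kin("trial positions contain non-finite values")
  }
  dimnames(positions) <- list(NULL, marker_set$label, c("ML", "AP", "V"))
  structure(
    list(
      subject_id = as.character(subject_id), session = session,
      positions = positions, sampling_rate = sampling_rate,
      marker_set = marker_set
    ),
    class = "marker_trial"
  )
}

#' @export
print.marker_trial <- function(x, ...) {
  d <- dim(x$positions)
  cat(
    "<marker_trial> subject", x$subject_id, "(", x$session, "):",
    d[1], "frames x", d[2], "markers @", x$sampling_rate, "Hz\n"
  )
  invisible(x)
}

# Cubic-spline fill of short interior NA runs, one series at a time.
fill_gaps <- function(positions, max_gap = 5) {
  d <- dim(positions)
  for (m in seq_len(d[2])) {
    for (a in seq_len(d[3])) {
      y <- positions[, m, a]
      if (!anyNA(y)) next
      r <- rle(is.na(y))
      if (any(r$lengths[r$values] > max_gap)) {
        stop_kin(
          "gap of ", max(r$lengths[r$values]), " frames exceeds max_gap = ",
          max_gap, " for marker column ", m
        )
      }
      ok <- !is.na(y)
      if (is.na(y[1]) || is.na(y[length(y)])) {
        stop_kin("missing frames at trial boundary cannot be interpolated")
      }
      positions[, m, a] <- stats::spline(
        x = which(ok), y = y[ok], xout = seq_along(y), method = "natural"
      )$y
    }
  }
  positions
}

normalize_axis_map <- function(axis_map) {
  if (is.null(axis_map)) axis_map <- c(ML = 1L, AP = 2L, V = 3L)
  if (is.character(axis_map)) {
    # e.g. c("ML","AP","V") meaning column i carries axis axis_map[i]
    axis_map <- stats::setNames(seq_along(axis_map), toupper(axis_map))
  }
  axis_map <- axis_map[c("ML", "AP", "V")]
  if (anyNA(axis_map) || !setequal(axis_map, 1:3)) {
    stop_kin("axis_map must assign columns 1:3 to ML, AP and V exactly once")
  }
  as.integer(axis_map)
}

#' Read a marker trial from disk
#'
#' Supports two on-disk forms: delimited text with a header row
#' `frame,<label>_x,<label>_y,<label>_z,...` (one row per frame), and the
#' C3D binary motion-capture format (point data and frame-rate header).
#' Coordinates are converted to meters when the file declares millimeters
#' (C3D `POINT:UNITS`, or `units = "mm"` for delimited files).
#'
#' @param path file path.
#' @param format `"delimited"` or `"c3d"`; guessed from the file extension
#'   by default.
#' @param marker_set a [marker_set()]; every label must be present in the
#'   file, and output markers follow the marker-set order.
#' @param axis_map named vector mapping `ML`, `AP`, `V` to file coordinate
#'   columns (x = 1, y = 2, z = 3). Default: x = ML, y = AP, z = V.
#' @param subject_id,session trial metadata.
#' @param sampling_rate frames per second for delimited files (C3D files
#'   carry their own rate).
#' @param units `"m"` or `"mm"` for delimited files.
#' @param gap_fill,max_gap see [marker_trial()].
#' @return A [marker_trial()].
#' @export
read_trial <- function(path, format = c("auto", "delimited", "c3d"),
                       marker_set = default_marker_set(),
                       axis_map = NULL, subject_id = "S1", session = "test",
                       sampling_rate = 120, units = "m",
                       gap_fill = FALSE, max_gap = 5) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.c3d$", path, ignore.case = TRUE)) "c3d" else "delimited"
  }
  if (!file.exists(path)) stop_kin("file not found: ", path)
  am <- normalize_axis_map(axis_map)

  if (format == "c3d") {
    raw <- read_c3d(path)
    pos <- raw$positions
    sampling_rate <- raw$sampling_rate
    if (identical(raw$units, "mm")) pos <- pos / 1000
    found <- dimnames(pos)[[2]]
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    cn <- names(df)
    found <- unique(sub("_[xyz]$", "", cn[grepl("_[xyz]$", cn)]))
    n_frames <- nrow(df)
    pos <- array(NA_real_, c(n_frames, length(found), 3),
                 dimnames = list(NULL, found, c("x", "y", "z")))
    for (lab in found) {
      for (k in 1:3) {
        col <- paste0(lab, "_", c("x", "y", "z")[k])
        if (!col %in% cn) stop_kin("column '", col, "' missing in ", path)
        pos[, lab, k] <- df[[col]]
      }
    }
    if (identical(units, "mm")) pos <- pos / 1000
  }

  missing <- setdiff(marker_set$label, found)
  if (length(missing)) {
    stop_kin(
      "marker label(s) absent from file: ", paste(missing, collapse = ", ")
    )
  }
  pos <- pos[, marker_set$label, , drop = FALSE]
  pos <- pos[, , am, drop = FALSE] # file columns -> internal (ML, AP, V)
  marker_trial(
    pos, marker_set, subject_id = subject_id, session = session,
    sampling_rate = sampling_rate, gap_fill = gap_fill, max_gap = max_gap
  )
}

#' Write a marker trial as delimited text
#'
#' Inverse of [read_trial()] for the delimited format: header
#' `frame,<label>_x,<label>_y,<label>_z,...`, one row per frame, full
#' double precision. Axis columns are written in internal (ML, AP, V)
#' order under the x/y/z names, i.e. with the identity axis map.
#'
#' @param trial a [marker_trial()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "marker_trial"))
  pos <- trial$positions
  labs <- dimnames(pos)[[2]]
  cols <- lapply(labs, function(l) {
    stats::setNames(
      list(pos[, l, 1], pos[, l, 2], pos[, l, 3]),
      paste0(l, "_", c("x", "y", "z"))
    )
  })
  df <- data.frame(
    frame = seq_len(dim(pos)[1]),
    do.call(cbind.data.frame, unlist(cols, recursive = FALSE)),
    check.names = FALSE
  )
  utils::write.csv(
    format(df, digits = 17, trim = TRUE, scientific = FALSE),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a subject metadata table
#'
#' @param path CSV with columns `subject_id`, `group` (HS, HC or PD),
#'   `age`, `sex`, `education`, `motor_score`.
#' @return A validated data frame, one row per subject.
#' @export
read_subjects <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_subjects(df)
}

validate_subjects <- function(df) {
  need <- c("subject_id", "group", "age", "sex", "education", "motor_score")
  if (!all(need %in% names(df))) {
    stop_kin(
      "subject table must have columns: ", paste(need, collapse = ", ")
    )
  }
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) {
    stop_kin("duplicate subject_id in subject table")
  }
  if (!all(df$group %in% c("HS", "HC", "PD"))) {
    stop_kin("group must be one of HS, HC, PD")
  }
  if (any(!is.na(df$motor_score) & df$motor_score < 0)) {
    stop_kin("motor_score must be non-negative")
  }
  df
}

#' Pair test and retest trials per subject
#'
#' Verifies that every subject has exactly one test and one retest trial,
#' recorded with identical marker sets and sampling rates, and that every
#' trial's subject appears in the metadata table.
#'
#' @param trials list of [marker_trial()] objects.
#' @param subjects subject metadata data frame (see [read_subjects()]).
#' @return A data frame with one row per subject: `subject_id`, `test`
#'   and `retest` (indices into `trials`).
#' @export
validate_session <- function(trials, subjects) {
  subjects <- validate_subjects(subjects)
  ids <- vapply(trials, function(t) t$subject_id, character(1))
  sess <- vapply(trials, function(t) t$session, character(1))
  unknown <- setdiff(unique(ids), subjects$subject_id)
  if (length(unknown)) {
    stop_kin(
      "trial(s) reference unknown subject(s): ", paste(unknown, collapse = ", ")
    )
  }
  bad <- character(0)
  out <- data.frame(
    subject_id = character(0), test = integer(0), retest = integer(0)
  )
  for (sid in unique(ids)) {
    idx <- which(ids == sid)
    if (length(idx) != 2L || !setequal(sess[idx], c("test", "retest"))) {
      bad <- c(bad, sid)
      next
    }
    i_test <- idx[sess[idx] == "test"]
    i_re <- idx[sess[idx] == "retest"]
    if (!identical(trials[[i_test]]$marker_set$label,
                   trials[[i_re]]$marker_set$label)) {
      stop_kin("subject '", sid, "': test and retest marker sets differ")
    }
    if (trials[[i_test]]$sampling_rate != trials[[i_re]]$sampling_rate) {
      stop_kin("subject '", sid, "': test and retest sampling rates differ")
    }
    out <- rbind(out, data.frame(subject_id = sid, test = i_test, retest = i_re))
  }
  if (length(bad)) {
    stop_kin(
      "subject(s) without exactly one test and one retest trial: ",
      paste(bad, collapse = ", ")
    )
  }
  out
}
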