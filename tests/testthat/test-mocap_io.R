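test_that("delimited trials read back with marker ordering and axis remapping", {
  ms <- tiny_marker_set()
  tr <- function_trial(
    fun_ml = function(t, m) m * t,
    fun_ap = function(t, m) sin(2 * pi * t) + m,
    fun_v = function(t, m) cos(2 * pi * t) - m,
    n_frames = 10
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(tr, path)

  rt <- read_trial(path, format = "delimited", marker_set = ms,
                   subject_id = "S1", session = "test")
  expect_equal(dim(rt$positions), c(10, 3, 3))
  expect_equal(rt$positions, tr$positions, tolerance = 1e-12)

  # axis_map swapping ML and AP: the ML series of the output must equal the
  # file's second coordinate column
  swapped <- read_trial(path, marker_set = ms,
                        axis_map = c(ML = 2, AP = 1, V = 3))
  expect_equal(swapped$positions[, , "ML"], tr$positions[, , "AP"])
  expect_equal(swapped$positions[, , "AP"], tr$positions[, , "ML"])
  # applying the inverse map restores the original order (involution)
  expect_equal(swapped$positions[, , c(2, 1, 3)], tr$positions,
               ignore_attr = TRUE)
})

test_that("missing marker labels are reported by name", {
  tr <- function_trial(function(t, m) t + m, n_frames = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(tr, path)
  ms4 <- marker_set(
    labels = c("T10", "R_ANK", "L_ANK", "SACR"),
    side = c("midline", "right", "left", "midline"),
    anatomical_group = c("trunk", "leg", "leg", "pelvis")
  )
  expect_error(read_trial(path, marker_set = ms4), "SACR")
})

test_that("C3D round trip preserves float32 coordinates, labels and rate", {
  ms <- tiny_marker_set()
  n_frames <- 12
  # coordinates exactly representable in float32
  pos <- array(
    round(stats::runif(n_frames * 3 * 3, -2, 2) * 64) / 64,
    c(n_frames, 3, 3)
  )
  dimnames(pos) <- list(NULL, ms$label, c("x", "y", "z"))
  path <- withr::local_tempfile(fileext = ".c3d")
  write_c3d(pos, path, sampling_rate = 120, units = "m")

  raw <- read_c3d(path)
  expect_identical(dimnames(raw$positions)[[2]], ms$label)
  expect_equal(raw$sampling_rate, 120)
  expect_identical(raw$units, "m")
  expect_identical(raw$positions, pos, ignore_attr = TRUE)

  tr <- read_trial(path, format = "c3d", marker_set = ms)
  expect_equal(tr$positions[, , 1], pos[, , 1], ignore_attr = TRUE)
  expect_equal(tr$sampling_rate, 120)
})

test_that("C3D millimeter files are converted to meters", {
  ms <- tiny_marker_set()
  pos <- array(1000, c(8, 3, 3), dimnames = list(NULL, ms$label, NULL))
  path <- withr::local_tempfile(fileext = ".c3d")
  write_c3d(pos, path, sampling_rate = 100, units = "mm")
  tr <- read_trial(path, format = "c3d", marker_set = ms)
  expect_equal(unname(tr$positions[1, 1, 1]), 1)
})

test_that("session validation pairs 23 subjects and rejects broken sessions", {
  spec <- cohort_spec(n_subjects = 23, mode = "healthy", seed = 4)
  ch <- generate_cohort(spec)
  idx <- validate_session(ch$trials, ch$subjects)
  expect_equal(nrow(idx), 23)
  expect_setequal(idx$subject_id, ch$subjects$subject_id)

  # single trial for one subject
  expect_error(
    validate_session(ch$trials[-2], ch$subjects),
    ch$subjects$subject_id[1]
  )
  # mismatched sampling rates
  trials <- ch$trials
  trials[[2]]$sampling_rate <- 60
  expect_error(validate_session(trials, ch$subjects), "sampling rates")
  # unknown subject
  trials <- ch$trials
  trials[[1]]$subject_id <- "GHOST"
  expect_error(validate_session(trials, ch$subjects), "GHOST")
})

test_that("gap filling interpolates short gaps and rejects long ones", {
  ms <- tiny_marker_set()
  tt <- (0:59) / 120
  pos <- array(rep(sin(2 * pi * tt), 9), c(60, 3, 3))
  pos[10:12, 1, 1] <- NA
  tr <- marker_trial(pos, ms, "S1", "test", gap_fill = TRUE)
  expect_false(anyNA(tr$positions))
  expect_equal(tr$positions[10:12, 1, 1], sin(2 * pi * tt[10:12]),
               tolerance = 1e-3)

  pos[10:17, 1, 1] <- NA
  expect_error(marker_trial(pos, ms, "S1", "test", gap_fill = TRUE), "max_gap")
  expect_error(marker_trial(pos, ms, "S1", "test"), "missing")
})

test_that("marker sets enforce pairing, uniqueness and T10 presence", {
  expect_equal(nrow(default_marker_set()), 21)
  expect_true("T10" %in% default_marker_set()$label)

  # the shipped marker-map file reproduces the default set
  path <- system.file("extdata", "davis21_markers.csv", package = "kinectome")
  expect_equal(read_marker_set(path), default_marker_set())
  expect_error(
    marker_set("R_ANK", "right", "leg"),
    "left/right pair"
  )
  expect_error(
    marker_set(c("A", "A"), c("midline", "midline"), c("head", "head")),
    "unique"
  )
  ms_no_t10 <- marker_set("C7", "midline", "trunk")
  expect_error(
    kinectome:::validate_marker_set(ms_no_t10, require_t10 = TRUE),
    "T10"
  )
})
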