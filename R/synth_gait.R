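#' Specification of a synthetic gait cohort
#'
#' The generator emulates the statistical structure the downstream network
#' analyses rely on: quasi-periodic marker trajectories built from a small
#' number of gait harmonics, a stable subject-specific signature shared by
#' the two trials of each subject, trial-to-trial noise, and - in
#' parkinsonian mode - left/right asymmetry, an elevated trunk-limb
#' coupling centred on the T10 marker, inflated between-subject
#' variability on the anteroposterior axis, and a clinical motor score
#' driven by the coupling strength.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param mode `"healthy"` or `"parkinsonian"`.
#' @param cycle_duration gait-cycle length in seconds (default 1.1).
#' @param sampling_rate frames per second (default 120).
#' @param n_harmonics harmonics of the stride frequency (default 3).
#' @param signature_scale SD of the subject-specific multiplicative
#'   amplitude and additive phase (radians) perturbations (default 0.15).
#' @param trial_noise_scale per-trial white-noise SD relative to each
#'   series' amplitude (default 0.05).
#' @param phase_jitter per-trial stride-to-stride phase jitter SD in
#'   radians (default `0.8 * trial_noise_scale`, about 2.3 degrees).
#' @param asymmetry left-right imbalance: the affected side's amplitudes
#'   shrink by this fraction and lag in phase by `0.5 * asymmetry` rad
#'   (default 0 healthy, 0.25 parkinsonian).
#' @param trunk_coupling mean of the per-subject trunk-limb coupling
#'   weight; a T10-specific movement component is injected into all limb
#'   ML/AP channels at this fraction of their amplitude (default 0
#'   healthy, 0.3 parkinsonian). Exactly 0 disables coupling.
#' @param coupling_sd between-subject SD of the coupling weight
#'   (default 0.3, reflecting the large clinical heterogeneity of axial
#'   involvement; couplings are truncated at 0).
#' @param between_subject_ap_var_inflation variance-inflation factor for
#'   the AP-axis subject signatures (default 1 healthy, 2 parkinsonian).
#' @param score_slope,score_noise motor score = max(0, round(8 +
#'   score_slope * coupling + N(0, score_noise))) in parkinsonian mode
#'   (defaults 40 and 2); healthy scores are small near-zero values.
#' @param group_label group code for the subject table; defaults to
#'   `"HS"` (healthy) or `"PD"` (parkinsonian). Use `"HC"` for a healthy
#'   cohort serving as matched controls.
#' @param seed RNG seed (the whole cohort is a deterministic function of
#'   the spec).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 23,
                        mode = c("healthy", "parkinsonian"),
                        cycle_duration = 1.1,
                        sampling_rate = 120,
                        n_harmonics = 3,
                        signature_scale = 0.15,
                        trial_noise_scale = 0.05,
                        phase_jitter = NULL,
                        asymmetry = NULL,
                        trunk_coupling = NULL,
                        coupling_sd = 0.3,
                        between_subject_ap_var_inflation = NULL,
                        score_slope = 40,
                        score_noise = 2,
                        group_label = NULL,
                        seed = 1) {
  mode <- match.arg(mode)
  pd <- mode == "parkinsonian"
  spec <- list(
    n_subjects = as.integer(n_subjects), mode = mode,
    cycle_duration = cycle_duration, sampling_rate = sampling_rate,
    n_harmonics = as.integer(n_harmonics),
    signature_scale = signature_scale, trial_noise_scale = trial_noise_scale,
    phase_jitter = phase_jitter %||% (0.8 * trial_noise_scale),
    asymmetry = asymmetry %||% (if (pd) 0.25 else 0),
    trunk_coupling = trunk_coupling %||% (if (pd) 0.3 else 0),
    coupling_sd = coupling_sd,
    between_subject_ap_var_inflation =
      between_subject_ap_var_inflation %||% (if (pd) 2 else 1),
    score_slope = score_slope, score_noise = score_noise,
    group_label = group_label %||% (if (pd) "PD" else "HS"),
    seed = as.integer(seed)
  )
  if (spec$n_subjects < 2) stop_kin("n_subjects must be >= 2")
  scales <- c(
    spec$signature_scale, spec$trial_noise_scale, spec$asymmetry,
    spec$trunk_coupling, spec$coupling_sd,
    spec$between_subject_ap_var_inflation, spec$score_noise
  )
  if (any(scales < 0)) stop_kin("all scales must be >= 0")
  if (spec$sampling_rate * spec$cycle_duration < 60) {
    stop_kin("cycle must span at least 60 frames")
  }
  class(spec) <- "cohort_spec"
  spec
}

# Harmonic gait template for the default 21-marker set.
#
# One dominant harmonic of the stride frequency per marker and axis, with
# module-coherent phases:
#   ML  - axial markers sway at h1; arms swing at h1 in quadrature to the
#         axial sway (opposite signs left/right); legs and feet oscillate
#         at h2 (step frequency), antiphase left/right.
#   AP  - arms and legs progress at h1 with contralateral arm-leg pairing;
#         axial markers bounce at h2 (one per step).
#   V   - whole body oscillates at h2 with distinct axial/arm/foot phases.
# In parkinsonian mode the T10 marker is additionally entrained by the
# limb rhythm (see `coupling_design`): it receives an h2 component at the
# leg phase on ML and an h1 component at the limb phase on AP, scaled by
# the per-subject coupling weight.
synth_template <- function(ms, n_harmonics = 3) {
  n <- nrow(ms)
  amp <- array(0, c(n, 3, n_harmonics), dimnames = list(ms$label, c("ML", "AP", "V"), NULL))
  phase <- array(0, c(n, 3, n_harmonics), dimnames = dimnames(amp))
  axial <- ms$anatomical_group %in% c("head", "trunk", "pelvis")
  arms <- ms$anatomical_group %in% c("upper_arm", "forearm")
  legs <- ms$anatomical_group %in% c("leg", "foot")
  right <- ms$side == "right"
  left <- ms$side == "left"
  j_ax <- cumsum(axial) - 1 # within-group index, 0-based
  j_ar <- cumsum(arms) - 1
  j_lg <- cumsum(legs) - 1

  amp_by_group <- c(
    head = 0.020, trunk = 0.028, pelvis = 0.029,
    upper_arm = 0.045, forearm = 0.060, leg = 0.025, foot = 0.032
  )
  a0 <- unname(amp_by_group[ms$anatomical_group])

  # Every marker also carries a smaller higher-harmonic "impact" component
  # (heel-strike transients), phased so that modules stay mutually
  # orthogonal; without it the jerk of h1-dominated series would be
  # noise-limited, since differentiation re-weights harmonic h by h^3.

  # --- ML ---
  amp[axial, "ML", 1] <- a0[axial]
  phase[axial, "ML", 1] <- 0.04 * j_ax[axial]
  amp[axial, "ML", 2] <- 0.15 * a0[axial] # quadrature to the leg step
  phase[axial, "ML", 2] <- pi / 2 + 0.04 * j_ax[axial]
  amp[arms, "ML", 1] <- a0[arms] * 0.9
  phase[arms, "ML", 1] <- ifelse(right[arms], pi / 2, -pi / 2) + 0.05 * j_ar[arms]
  amp[arms, "ML", 3] <- 0.09 * a0[arms]
  phase[arms, "ML", 3] <- ifelse(right[arms], 0.5, 0.5 + pi) + 0.05 * j_ar[arms]
  amp[legs, "ML", 2] <- a0[legs]
  phase[legs, "ML", 2] <- ifelse(right[legs], 0, pi) + 0.04 * j_lg[legs]

  # --- AP ---
  amp[arms, "AP", 1] <- a0[arms] * 0.8
  phase[arms, "AP", 1] <- ifelse(right[arms], 0, pi) + 0.05 * j_ar[arms]
  amp[arms, "AP", 3] <- 0.12 * a0[arms] * 0.8
  phase[arms, "AP", 3] <- ifelse(right[arms], 1.2, 1.2 + pi) + 0.05 * j_ar[arms]
  amp[legs, "AP", 1] <- a0[legs] * 1.6
  phase[legs, "AP", 1] <- ifelse(right[legs], pi, 0) + 0.04 * j_lg[legs]
  amp[legs, "AP", 2] <- 0.18 * a0[legs] * 1.6 # quadrature to the axial bounce
  phase[legs, "AP", 2] <- 0.6 + pi / 2 + 0.04 * j_lg[legs]
  amp[axial, "AP", 2] <- a0[axial] * 0.7
  phase[axial, "AP", 2] <- 0.6 + 0.04 * j_ax[axial]

  # --- V ---
  amp[axial, "V", 2] <- 0.020
  phase[axial, "V", 2] <- 0.10 * j_ax[axial]
  amp[arms, "V", 2] <- 0.012
  phase[arms, "V", 2] <- 0.9 + 0.10 * j_ar[arms]
  amp[legs, "V", 2] <- ifelse(ms$anatomical_group[legs] == "foot", 0.040, 0.030)
  phase[legs, "V", 2] <- 1.8 + 0.10 * j_lg[legs]

  # planted ML community structure (axial / arms / legs+feet)
  modules <- integer(n)
  modules[axial] <- 0L
  modules[arms] <- 1L
  modules[legs] <- 2L
  list(amp = amp, phase = phase, t10 = which(ms$label == "T10"),
       ml_modules = modules)
}

# Trunk-limb coupling received by T10 when coupling weight c > 0.
# Amplitude ratios are relative to T10's own dominant harmonic on that
# axis; the harmonic mismatch (h2 into an h1 channel and vice versa)
# makes the entrained component orthogonal to T10's healthy motion and
# visible to the acceleration/jerk correlations at a comparable weight
# (differentiation re-weights harmonic h by h^order).
coupling_design <- function() {
  list(
    ML = list(h = 2L, ref_h = 1L, amp_ratio = 0.25, phase = 0.45),
    AP = list(h = 1L, ref_h = 2L, amp_ratio = 4.0, phase = 0.05)
  )
}

#' Generate a synthetic test-retest gait cohort
#'
#' Produces two [marker_trial()]s (test and retest) per subject plus a
#' subject metadata table, following a [cohort_spec()]. The whole output
#' is a deterministic function of the spec (including its seed).
#'
#' @param spec a [cohort_spec()].
#' @param marker_set marker set to simulate (default [default_marker_set()];
#'   must contain `T10`).
#' @return List with `trials` (2 per subject: test then retest),
#'   `subjects` (metadata data frame) and `truth` (see [planted_truth()]).
#' @export
generate_cohort <- function(spec, marker_set = default_marker_set()) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_marker_set(marker_set, require_t10 = TRUE)
  ms <- marker_set
  n <- nrow(ms)
  tmpl <- synth_template(ms, spec$n_harmonics)
  n_frames <- round(spec$cycle_duration * spec$sampling_rate)
  tt <- (seq_len(n_frames) - 1) / spec$sampling_rate
  f0 <- 1 / spec$cycle_duration
  pd <- spec$mode == "parkinsonian"
  H <- spec$n_harmonics
  axes <- c("ML", "AP", "V")

  with_seed(spec$seed, {
    trials <- vector("list", 2L * spec$n_subjects)
    ids <- sprintf("%s%02d", spec$group_label, seq_len(spec$n_subjects))
    coupling <- numeric(spec$n_subjects)
    side_aff <- character(spec$n_subjects)
    sig_amp <- vector("list", spec$n_subjects)
    sig_phase <- vector("list", spec$n_subjects)

    for (s in seq_len(spec$n_subjects)) {
      # subject signature, shared by both trials
      amp_mult <- array(
        pmax(0.2, 1 + stats::rnorm(n * 3 * H, 0, spec$signature_scale)),
        c(n, 3, H)
      )
      phase_add <- array(stats::rnorm(n * 3 * H, 0, spec$signature_scale), c(n, 3, H))
      infl <- sqrt(spec$between_subject_ap_var_inflation)
      amp_mult[, 2, ] <- pmax(0.2, 1 + (amp_mult[, 2, ] - 1) * infl)
      phase_add[, 2, ] <- phase_add[, 2, ] * infl

      coupling[s] <- if (spec$trunk_coupling == 0) 0 else {
        max(0, stats::rnorm(1, spec$trunk_coupling, spec$coupling_sd))
      }
      side_aff[s] <- sample(c("left", "right"), 1)
      aff <- ms$side == side_aff[s]

      amp_s <- tmpl$amp * amp_mult
      phase_s <- tmpl$phase + phase_add
      if (spec$asymmetry > 0) {
        amp_s[aff, , ] <- amp_s[aff, , ] * (1 - spec$asymmetry)
        phase_s[aff, , ] <- phase_s[aff, , ] + 0.5 * spec$asymmetry
      }
      sig_amp[[s]] <- amp_mult
      sig_phase[[s]] <- phase_add

      for (trial_k in 1:2) {
        # stride-to-stride timing variability
        jitter <- array(
          stats::rnorm(n * 3 * H, 0, spec$phase_jitter), c(n, 3, H)
        )
        pos <- array(0, c(n_frames, n, 3), dimnames = list(NULL, ms$label, axes))
        for (a in 1:3) {
          for (h in seq_len(H)) {
            for (m in which(amp_s[, a, h] > 0)) {
              pos[, m, a] <- pos[, m, a] + amp_s[m, a, h] *
                sin(2 * pi * h * f0 * tt + phase_s[m, a, h] + jitter[m, a, h])
            }
          }
        }
        # trunk-limb coupling: T10 entrained by the limb rhythm on ML/AP
        if (coupling[s] > 0) {
          cd <- coupling_design()
          t10 <- tmpl$t10
          for (a in c("ML", "AP")) {
            ai <- match(a, axes)
            d <- cd[[a]]
            amp_c <- d$amp_ratio * coupling[s] * amp_s[t10, ai, d$ref_h]
            ph_c <- d$phase + phase_add[t10, ai, d$h] + jitter[t10, ai, d$h]
            pos[, t10, ai] <- pos[, t10, ai] +
              amp_c * sin(2 * pi * d$h * f0 * tt + ph_c)
          }
        }
        # additive white measurement/variability noise
        if (spec$trial_noise_scale > 0) {
          sds <- apply(pos, c(2, 3), stats::sd)
          noise <- array(stats::rnorm(length(pos)), dim(pos))
          for (a in 1:3) {
            noise[, , a] <- sweep(noise[, , a], 2, spec$trial_noise_scale * sds[, a], "*")
          }
          pos <- pos + noise
        }
        trials[[2L * (s - 1L) + trial_k]] <- marker_trial(
          pos, ms, subject_id = ids[s],
          session = c("test", "retest")[trial_k],
          sampling_rate = spec$sampling_rate
        )
      }
    }

    subjects <- data.frame(
      subject_id = ids,
      group = spec$group_label,
      age = round(pmin(85, pmax(40, stats::rnorm(
        spec$n_subjects, if (pd) 65.3 else 58.7, if (pd) 11.6 else 12.7
      )))),
      sex = sample(c("M", "F"), spec$n_subjects, replace = TRUE),
      education = round(pmin(20, pmax(5, stats::rnorm(spec$n_subjects, 13, 3)))),
      motor_score = if (pd) {
        pmax(0, round(8 + spec$score_slope * coupling +
                        stats::rnorm(spec$n_subjects, 0, spec$score_noise)))
      } else {
        pmax(0, round(stats::rnorm(spec$n_subjects, 2, 1)))
      },
      stringsAsFactors = FALSE
    )

    list(
      trials = trials,
      subjects = subjects,
      truth = structure(
        list(
          coupling = stats::setNames(coupling, ids),
          affected_side = stats::setNames(side_aff, ids),
          ml_modules = stats::setNames(tmpl$ml_modules, ms$label),
          signature_amp = sig_amp, signature_phase = sig_phase,
          score_slope = spec$score_slope, score_noise = spec$score_noise
        ),
        class = "planted_truth"
      )
    )
  })
}

#' Ground truth planted in a synthetic cohort
#'
#' Regenerates the cohort and returns only its planted parameters:
#' per-subject trunk-limb couplings and affected sides, the subject
#' signature arrays, the template ML community labels and the score model.
#' Intended as the recovery target in tests.
#'
#' @param spec a [cohort_spec()].
#' @param marker_set see [generate_cohort()].
#' @return A `planted_truth` list (see [generate_cohort()]'s `truth`).
#' @export
planted_truth <- function(spec, marker_set = default_marker_set()) {
  generate_cohort(spec, marker_set)$truth
}

#' Write a synthetic cohort to disk in the package's exchange formats
#'
#' Trials go to `<dir>/<subject>_<session>.csv` (delimited trial format),
#' metadata to `<dir>/subjects.csv`, and the generating spec to
#' `<dir>/cohort_spec.json`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @param spec the generating [cohort_spec()], stored for reproducibility.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tr in cohort$trials) {
    write_trial(tr, file.path(dir, paste0(tr$subject_id, "_", tr$session, ".csv")))
  }
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  if (!is.null(spec)) {
    jsonlite::write_json(
      unclass(spec), file.path(dir, "cohort_spec.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}

#' Planted-signature edge cohort
#'
#' Directly simulates test/retest edge matrices (bypassing trajectories):
#' `n_signature` edges carry a stable subject-specific offset (SD
#' `signature_sd`) while the rest are pure session noise. Used to probe
#' ICC-based edge selection: the signature edges are exactly the ones a
#' reliable ranking must find.
#'
#' @param n_subjects subjects (default 23).
#' @param n_edges total edges (default 210).
#' @param n_signature edges with subject-specific signal (default 20).
#' @param signature_sd between-subject SD on signature edges (default 1).
#' @param noise_sd within-subject session noise SD on all edges
#'   (default 0.25).
#' @param seed RNG seed.
#' @return List with `test`, `retest` (subjects x edges matrices) and
#'   `signature_edges` (integer index).
#' @export
simulate_planted_edges <- function(n_subjects = 23, n_edges = 210,
                                   n_signature = 20, signature_sd = 1,
                                   noise_sd = 0.25, seed = 1) {
  with_seed(seed, {
    sig_idx <- sort(sample.int(n_edges, n_signature))
    base <- stats::rnorm(n_edges) # common edge means
    offsets <- matrix(0, n_subjects, n_edges)
    offsets[, sig_idx] <- stats::rnorm(n_subjects * n_signature, 0, signature_sd)
    noise <- function() matrix(stats::rnorm(n_subjects * n_edges, 0, noise_sd),
                               n_subjects, n_edges)
    test <- sweep(offsets, 2, base, "+") + noise()
    retest <- sweep(offsets, 2, base, "+") + noise()
    rownames(test) <- rownames(retest) <- sprintf("S%02d", seq_len(n_subjects))
    list(test = test, retest = retest, signature_edges = sig_idx)
  })
}
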