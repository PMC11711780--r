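# Synthetic measurement generation. The study design is emulated with five
# analysis occasions per subject: two blinded analyses by observer 1
# (observer1_a/b), one by observer 2, and one analysis of each of the two
# acquisition sequences (sgre at 40 ms, epi at 30 ms temporal resolution).
# Scalar and net-flow noise levels are calibrated so that each PAIRED
# comparison reproduces the study's coefficients of variation:
#   intra-observer  A_LVOT 2.8%, ESV 3.0%, EOA 1.5%; net flow MV 4.1%,
#                   AV 1.2%, AA 1.8%
#   inter-observer  A_LVOT 12%, ESV 3.8%, EOA 8.6%; net flow MV 9.1%,
#                   AV 2.7%, AA 3.4%
#   inter-sequence  A_LVOT 12%, EOA 8.6%, cycle length 3.7%; net flow
#                   MV 13%, AV 9.1%, AA 4.2% (no ESV term: the morphological
#                   images, and hence the ESV, are shared between sequences)
# Because the paired CoV statistic equals sqrt((sd_a^2 + sd_b^2)/2) for
# independent per-occasion noise, observer-2 noise is set to
# sqrt(2*inter^2 - intra^2) so that the observer1_a-vs-observer2 pair lands
# on the inter-observer values while observer1_a/b pairs land on the
# intra-observer values.

#' Noise model for one analysis occasion
#'
#' Fractional standard deviations applied by [observe()]: per-scalar CoVs,
#' per-site net-flow CoVs, smooth waveform shape noise (amplitude as a
#' fraction of peak flow, with a stated correlation time), heart-rate CoV
#' (inter-sequence occasions only) and the resampling interval of the
#' acquisition.
#'
#' @param cov_a_lvot,cov_esv,cov_eoa fractional CoVs of the scalar measures.
#' @param cov_flow named fractional net-flow CoVs (`mitral_valve`,
#'   `aortic_valve`, `ascending_aorta`).
#' @param shape_amp smooth shape-noise amplitude, fraction of peak flow.
#' @param shape_tau shape-noise correlation time (s).
#' @param cov_hr fractional heart-rate CoV (re-simulation at perturbed T).
#' @param dt resampling interval (s).
#' @return a `noise_model` object.
#' @export
noise_model <- function(cov_a_lvot = 0, cov_esv = 0, cov_eoa = 0,
                        cov_flow = c(mitral_valve = 0, aortic_valve = 0,
                                     ascending_aorta = 0),
                        shape_amp = 0, shape_tau = 0.06, cov_hr = 0,
                        dt = 0.04) {
  stopifnot(cov_a_lvot >= 0, cov_esv >= 0, cov_eoa >= 0, all(cov_flow >= 0),
            shape_amp >= 0, shape_tau > 0, cov_hr >= 0, dt > 0)
  structure(list(cov_a_lvot = cov_a_lvot, cov_esv = cov_esv, cov_eoa = cov_eoa,
                 cov_flow = cov_flow, shape_amp = shape_amp,
                 shape_tau = shape_tau, cov_hr = cov_hr, dt = dt),
            class = "noise_model")
}

# per-occasion noise sd that makes the (occasion, reference) pair land on the
# target paired CoV when the reference occasion has sd `ref`
.pair_sd <- function(target, ref) sqrt(pmax(2 * target^2 - ref^2, 0))

#' Study noise-model presets per occasion
#'
#' Per-occasion noise levels calibrated so that the three paired comparisons
#' (observer1_a vs observer1_b; observer1_a vs observer2; sgre vs epi)
#' reproduce the study's input CoVs (see the file-level notes).
#'
#' @param occasion one of `"observer1_a"`, `"observer1_b"`, `"observer2"`,
#'   `"sgre"`, `"epi"`.
#' @return a [noise_model()].
#' @export
study_noise_model <- function(occasion = c("observer1_a", "observer1_b",
                                           "observer2", "sgre", "epi")) {
  occasion <- match.arg(occasion)
  intra <- list(a_lvot = 0.028, esv = 0.030, eoa = 0.015,
                flow = c(mitral_valve = 0.041, aortic_valve = 0.012,
                         ascending_aorta = 0.018))
  inter <- list(a_lvot = 0.12, esv = 0.038, eoa = 0.086,
                flow = c(mitral_valve = 0.091, aortic_valve = 0.027,
                         ascending_aorta = 0.034))
  seqv <- list(a_lvot = 0.12, eoa = 0.086, t = 0.037,
               flow = c(mitral_valve = 0.13, aortic_valve = 0.091,
                        ascending_aorta = 0.042))
  switch(occasion,
    observer1_a = ,
    observer1_b = noise_model(cov_a_lvot = intra$a_lvot, cov_esv = intra$esv,
                              cov_eoa = intra$eoa, cov_flow = intra$flow,
                              shape_amp = 0.03, dt = 0.04),
    observer2 = noise_model(
      cov_a_lvot = .pair_sd(inter$a_lvot, intra$a_lvot),
      cov_esv = .pair_sd(inter$esv, intra$esv),
      cov_eoa = .pair_sd(inter$eoa, intra$eoa),
      cov_flow = stats::setNames(.pair_sd(inter$flow, intra$flow),
                                 names(inter$flow)),
      shape_amp = 0.05, dt = 0.04),
    sgre = noise_model(cov_a_lvot = seqv$a_lvot, cov_esv = 0,
                       cov_eoa = seqv$eoa, cov_flow = seqv$flow,
                       shape_amp = 0.08, cov_hr = seqv$t, dt = 0.04),
    epi = noise_model(cov_a_lvot = seqv$a_lvot, cov_esv = 0,
                      cov_eoa = seqv$eoa, cov_flow = seqv$flow,
                      shape_amp = 0.08, cov_hr = seqv$t, dt = 0.03))
}

# multiplicative Gaussian perturbation, truncated at +/- 3 SD to keep the
# bundle invariants satisfiable; redrawn (max 10 times) if a constraint
# predicate fails
.perturb <- function(x, cov, ok = function(z) TRUE) {
  if (cov == 0) return(x)
  for (i in 1:10) {
    z <- stats::rnorm(1)
    z <- max(min(z, 3), -3)
    out <- x * (1 + cov * z)
    if (ok(out)) return(out)
  }
  stop_hemofit("could not draw a perturbation satisfying the invariants")
}

# smooth zero-mean waveform noise: white noise filtered with a moving-average
# kernel of width ~ tau, cycle mean removed so net flow is unaffected
.shape_noise <- function(n, dt, amp_abs, tau) {
  if (amp_abs == 0) return(numeric(n))
  k <- max(1L, round(tau / dt))
  z <- stats::rnorm(n + 2 * k)
  sm <- stats::filter(z, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2,
                      circular = TRUE)
  sm <- as.numeric(sm)[k + seq_len(n)]
  sm <- sm - mean(sm)
  if (stats::sd(sm) < 1e-12) return(numeric(n))
  amp_abs * sm / stats::sd(sm)
}

#' Draw a synthetic ground-truth subject
#'
#' Uniform draw of the 23 subject-specific parameters within physiological
#' healthy ranges (defaults: modest windows around the package defaults).
#' The LV and LA `t_max` are then set to the actual activation peak time of
#' the drawn shape so elastance stays within its bounds, and the draw is
#' rejected (and resampled, max 10 attempts) unless the forward simulation
#' converges.
#'
#' @param seed integer seed.
#' @param ranges named list of `c(lower, upper)` ranges overriding the
#'   default draw windows.
#' @param defaults base parameter set.
#' @return a `model_parameters` object whose simulation converges.
#' @export
draw_subject <- function(seed = 1, ranges = list(),
                         defaults = default_parameters()) {
  base <- subject_ranges()
  for (nm in names(ranges)) base[[nm]] <- ranges[[nm]]
  bad <- vapply(names(base), function(nm) {
    i <- match(nm, defaults$name)
    base[[nm]][1] < defaults$lower[i] || base[[nm]][2] > defaults$upper[i]
  }, TRUE)
  if (any(bad))
    stop_hemofit("draw range(s) outside parameter bounds: %s",
                 paste(names(base)[bad], collapse = ", "))
  set.seed(seed)
  for (attempt in 1:10) {
    vals <- vapply(base, function(r) stats::runif(1, r[1], r[2]), 0)
    p <- set_parameters(defaults, vals)
    # keep the activation self-consistent: t_max at the shape's true peak
    Tc <- parameter_values(p)[["t_cycle"]]
    p <- set_parameters(p, c(
      lv_tmax = activation_peak_time(chamber_elastance(p, "lv"), Tc),
      la_tmax = activation_peak_time(chamber_elastance(p, "la"), Tc)))
    sim <- tryCatch(simulate_model(p), error = function(e) NULL)
    if (!is.null(sim) && sim$converged) return(p)
  }
  stop_hemofit("no converging subject in 10 draws; offending ranges: %s",
               paste(names(base), collapse = ", "))
}

#' Default healthy draw ranges for the subject-specific parameters
#'
#' @return named list of `c(lower, upper)` windows.
#' @export
subject_ranges <- function() {
  list(t_cycle = c(0.85, 1.10),
       eoa = c(3.0, 4.0), a_lvot = c(6.2, 7.8),
       lv_emax = c(2.0, 2.9), lv_emin = c(0.05, 0.08),
       lv_rc = c(1.7, 2.4), lv_rr = c(18, 26),
       lv_alpha_s = c(0.28, 0.36), lv_alpha_d = c(0.41, 0.50),
       la_emax = c(0.28, 0.42), la_emin = c(0.12, 0.18),
       la_rc = c(1.7, 2.4), la_rr = c(16, 24),
       la_alpha_s = c(0.065, 0.095), la_alpha_d = c(0.13, 0.19),
       la_onset = c(0.72, 0.82),
       c_aa = c(0.08, 0.16), r_ao = c(0.025, 0.05),
       c_per = c(1.4, 2.0), r_per = c(0.85, 1.2),
       r_mv = c(0.003, 0.006), l_mv = c(3e-4, 8e-4))
}

#' Observe a ground-truth subject on one analysis occasion
#'
#' Simulates the true physiology to periodic steady state and produces the
#' measurement bundle an observer would have extracted: scalars multiplied by
#' `(1 + CoV z)` with truncated standard-normal `z`; waveforms scaled by the
#' site's net-flow factor plus smooth zero-mean shape noise, then resampled
#' to the occasion's acquisition interval. For occasions with a heart-rate
#' CoV (inter-sequence), the cycle length is perturbed first and the true
#' model re-simulated at the new `T` — a physiological change between scans,
#' not an analysis error. The cuff pressures are shared by all occasions.
#' The paired velocity trace is consistent with the stored EOA
#' (`v = q_av / EOA`), so re-deriving EOA from the waveform recovers it.
#'
#' @param truth a `model_parameters` object (the subject's physiology).
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param occasion occasion tag stored in the bundle.
#' @param subject_id subject identifier.
#' @param esv_override optional pre-drawn ESV (mL), used to share the
#'   morphological-image analysis between the two sequence occasions.
#' @param sim optional precomputed `simulate_model(truth)` result, reused
#'   when the occasion has no heart-rate perturbation (which would require
#'   re-simulation at the new cycle length).
#' @return a [measurement_bundle()].
#' @export
observe <- function(truth, noise = noise_model(), seed = 1,
                    occasion = "observer1_a", subject_id = "S1",
                    esv_override = NULL, sim = NULL) {
  set.seed(seed)
  v <- parameter_values(truth)
  Tc <- unname(v["t_cycle"])
  if (noise$cov_hr > 0) {
    Tc <- .perturb(Tc, noise$cov_hr, ok = function(x) x > 0.4 && x < 2)
    truth <- rescale_cycle(truth, Tc)
    v <- parameter_values(truth)
    sim <- NULL  # physiology changed: the cached simulation no longer applies
  }
  sim <- sim %||% simulate_model(truth)
  if (!sim$converged) stop_hemofit("truth simulation did not converge")

  esv_true <- min(sim$v_lv)
  esv <- esv_override %||%
    .perturb(esv_true, noise$cov_esv, ok = function(x) x > v[["lv_v0"]])
  a_lvot <- .perturb(unname(v["a_lvot"]), noise$cov_a_lvot,
                     ok = function(x) x > 0)
  eoa <- .perturb(unname(v["eoa"]), noise$cov_eoa,
                  ok = function(x) x > 0 && x < a_lvot)

  waveforms <- list()
  for (site in c("mitral_valve", "aortic_valve", "ascending_aorta")) {
    w <- sim_waveform(sim, site, dt = noise$dt)
    scale <- .perturb(1, unname(noise$cov_flow[site]), ok = function(x) x > 0)
    q <- w$flow * scale +
      .shape_noise(length(w$flow), noise$dt,
                   noise$shape_amp * max(abs(w$flow)), noise$shape_tau)
    waveforms[[site]] <- flow_waveform(site, w$time, q, Tc)
  }
  velocity <- velocity_trace(waveforms$aortic_valve$time,
                             waveforms$aortic_valve$flow / eoa)

  measurement_bundle(subject_id = subject_id, occasion = occasion,
                     T_cycle = Tc, esv = esv, eoa = eoa, a_lvot = a_lvot,
                     sbp = max(sim$p_aa), dbp = min(sim$p_aa),
                     waveforms = waveforms, velocity = velocity)
}

#' Build a synthetic cohort with the full occasion design
#'
#' For each subject: a ground-truth parameter draw and five observation
#' occasions (`observer1_a`, `observer1_b`, `observer2`, `sgre`, `epi`)
#' covering the three paired comparisons (intra-observer, inter-observer,
#' inter-sequence). The two sequence occasions share one ESV analysis.
#' Regeneration with the same seed is bit-identical.
#'
#' @param n_subjects number of subjects (study default 10).
#' @param seed integer seed.
#' @param design named list of [noise_model()]s per occasion; defaults to
#'   [study_noise_model()] presets.
#' @param ranges draw ranges forwarded to [draw_subject()].
#' @param defaults base parameters forwarded to [draw_subject()].
#' @return a `synthetic_cohort`: list of subjects, each with `truth` and
#'   `bundles` (named by occasion), plus the generation `seed` and `design`.
#' @export
build_cohort <- function(n_subjects = 10, seed = 1, design = NULL,
                         ranges = list(), defaults = default_parameters()) {
  occasions <- c("observer1_a", "observer1_b", "observer2", "sgre", "epi")
  if (is.null(design))
    design <- stats::setNames(lapply(occasions, study_noise_model), occasions)
  if (!all(names(design) %in% occasions))
    stop_hemofit("unknown occasion(s) in design: %s",
                 paste(setdiff(names(design), occasions), collapse = ", "))
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    truth <- draw_subject(seed = seed + 1000L * s, ranges = ranges,
                          defaults = defaults)
    truth_sim <- simulate_model(truth)
    bundles <- list()
    esv_seq <- NULL
    for (i in seq_along(design)) {
      occ <- names(design)[i]
      b <- observe(truth, design[[occ]], seed = seed + 1000L * s + i,
                   occasion = occ, subject_id = sprintf("S%02d", s),
                   esv_override = if (occ == "epi") esv_seq else NULL,
                   sim = truth_sim)
      if (occ == "sgre") esv_seq <- b$esv
      bundles[[occ]] <- b
    }
    subjects[[s]] <- list(truth = truth, bundles = bundles)
  }
  structure(list(subjects = subjects, seed = seed, design = design),
            class = "synthetic_cohort")
}
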