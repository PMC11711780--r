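#' Paired per-subject values of one quantity
#'
#' @param name quantity name.
#' @param units unit string.
#' @param a,b per-subject values on the two occasions (same order).
#' @return a `paired_series` object.
#' @export
paired_series <- function(name, units, a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop_hemofit("need >= 2 complete pairs for '%s'", name)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop_hemofit("non-finite values in paired series '%s'", name)
  structure(list(name = name, units = units, a = as.numeric(a),
                 b = as.numeric(b)), class = "paired_series")
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences `d_i = a_i - b_i`; bias is `mean(d)` and the limits of
#' agreement are `bias +/- 1.96 sd(d)` (sample SD, n-1 denominator).
#'
#' @param pairs a [paired_series()].
#' @return list with `bias`, `loa_low`, `loa_high`, `sd_diff`.
#' @examples
#' bland_altman(paired_series("x", "-", c(1, 2, 3), c(2, 2, 5)))
#' @export
bland_altman <- function(pairs) {
  stopifnot(inherits(pairs, "paired_series"))
  d <- pairs$a - pairs$b
  s <- stats::sd(d)
  list(bias = mean(d), loa_low = mean(d) - 1.96 * s,
       loa_high = mean(d) + 1.96 * s, sd_diff = s)
}

#' Repeatability coefficient of variation
#'
#' Within-subject variance of a duplicate pair is `d_i^2 / 2`; the CoV is the
#' root-mean-square within-subject SD divided by the grand mean of all
#' values, in percent. The pairwise alternative (SD of the differences over
#' the grand mean, divided by sqrt(2)) is available for sensitivity.
#'
#' @param pairs a [paired_series()].
#' @param method `"rms"` (default) or `"sd_diff"`.
#' @return CoV in percent.
#' @examples
#' cov_repeatability(paired_series("x", "-", c(10, 20), c(12, 20)))  # ~6.45
#' @export
cov_repeatability <- function(pairs, method = c("rms", "sd_diff")) {
  stopifnot(inherits(pairs, "paired_series"))
  method <- match.arg(method)
  gm <- mean(c(pairs$a, pairs$b))
  if (gm <= 0) stop_hemofit("grand mean must be positive for a CoV")
  d <- pairs$a - pairs$b
  s <- switch(method,
              rms = sqrt(mean(d^2 / 2)),
              sd_diff = stats::sd(d) / sqrt(2))
  100 * s / gm
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Compares the occasion-A values against the occasion-B values. For a
#' combined sample size up to 20 the p-value is computed by exact enumeration
#' of all rank assignments (ties handled through average ranks); above that a
#' normal approximation with tie correction and continuity correction is
#' used. If every value is tied across both sides the p-value is 1 and the
#' result carries a `degenerate` flag.
#'
#' @param pairs a [paired_series()] (sides may also be unpaired vectors via
#'   `a`/`b`).
#' @param a,b alternative raw-vector interface (used when `pairs` is missing).
#' @return list with `p_value`, `statistic` (rank sum of side A),
#'   `significant` (p < 0.05), `method`, `degenerate`.
#' @export
rank_test <- function(pairs = NULL, a = NULL, b = NULL) {
  if (!is.null(pairs)) {
    stopifnot(inherits(pairs, "paired_series"))
    a <- pairs$a; b <- pairs$b
  }
  if (length(a) < 2 || length(b) < 2)
    stop_hemofit("need >= 2 values per side")
  n_a <- length(a); n <- n_a + length(b)
  x <- c(a, b)
  if (max(x) - min(x) <= 0) {
    return(list(p_value = 1, statistic = n_a * (n + 1) / 2,
                significant = FALSE, method = "degenerate", degenerate = TRUE))
  }
  r <- rank(x)
  w <- sum(r[seq_len(n_a)])
  mu <- n_a * (n + 1) / 2
  if (n <= 20) {
    sums <- utils::combn(r, n_a, FUN = sum)
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    n_b <- n - n_a
    sig2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(w - mu) - 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-max(z, 0))
    method <- "normal approximation"
  }
  list(p_value = min(p, 1), statistic = w, significant = p < 0.05,
       method = method, degenerate = FALSE)
}

#' Closed-cycle integral of a flow waveform
#'
#' Trapezoidal integral over one full cycle, closing the periodic gap between
#' the last sample and `T` with the first sample's value.
#'
#' @param w a [flow_waveform()].
#' @return volume per cycle (mL).
#' @export
net_flow <- function(w) {
  stopifnot(inherits(w, "flow_waveform"))
  trapz_(c(w$time, w$time[1] + w$T_cycle), c(w$flow, w$flow[1]))
}

#' RMSE between two flow waveforms at the same site
#'
#' Time is normalized to cycle fraction (so occasions with different cycle
#' lengths are comparable), both waveforms are resampled by periodic linear
#' interpolation onto a common uniform grid with `max(length(a), length(b))`
#' points, and the root-mean-square difference is returned.
#'
#' @param a,b [flow_waveform()] objects with the same site tag.
#' @return RMSE (mL/s).
#' @export
waveform_rmse <- function(a, b) {
  stopifnot(inherits(a, "flow_waveform"), inherits(b, "flow_waveform"))
  if (a$site != b$site)
    stop_hemofit("site mismatch: %s vs %s", a$site, b$site)
  n <- max(length(a$time), length(b$time))
  phase <- seq(0, 1 - 1 / n, length.out = n)
  qa <- periodic_interp(a$time / a$T_cycle, a$flow, 1, phase)
  qb <- periodic_interp(b$time / b$T_cycle, b$flow, 1, phase)
  sqrt(mean((qa - qb)^2))
}

# occasion pair per comparison
.COMPARISONS <- list(intra    = c("observer1_a", "observer1_b"),
                     inter    = c("observer1_a", "observer2"),
                     sequence = c("sgre", "epi"))

# the seven reported model-derived parameters
.HEADLINE <- c(lv_emin = "Passive LV elastance (mmHg/mL)",
               lv_emax = "Maximal LV elastance (mmHg/mL)",
               lv_rc = "Rate of ventricular contraction (-)",
               lv_rr = "Rate of ventricular relaxation (-)",
               lv_alpha_s = "Ventricular systolic time constant (-)",
               lv_alpha_d = "Ventricular diastolic time constant (-)",
               c_aa = "Compliance of the ascending aorta (mL/mmHg)")

#' Personalize every requested occasion of a cohort
#'
#' Runs [estimate()] on each subject's bundle for the given occasions.
#'
#' @param cohort a `synthetic_cohort` from [build_cohort()].
#' @param occasions occasion tags to fit (default: all present).
#' @param ... passed to [estimate()] (e.g. `n_starts`, `maxiter`).
#' @return nested list `estimates[[occasion]][[subject]]`, each an
#'   `estimation_result`.
#' @export
fit_cohort <- function(cohort, occasions = NULL, ...) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  occasions <- occasions %||% names(cohort$subjects[[1]]$bundles)
  est <- list()
  for (occ in occasions) {
    est[[occ]] <- lapply(cohort$subjects, function(s) {
      estimate(s$bundles[[occ]], ...)
    })
  }
  est
}

#' Repeatability analysis of one paired comparison
#'
#' Applies [bland_altman()], [cov_repeatability()] and [rank_test()] to every
#' input measure (and, when estimates are supplied, to the seven reported
#' model-derived parameters), and computes the per-site, per-subject waveform
#' RMSE — one table per comparison, mirroring the repeatability-study layout.
#'
#' @param cohort a `synthetic_cohort`.
#' @param comparison `"intra"`, `"inter"` or `"sequence"`.
#' @param estimates optional output of [fit_cohort()] covering both occasions
#'   of the comparison.
#' @return a `variability_report`: `table` (columns `quantity`, `units`,
#'   `bias`, `loa_low`, `loa_high`, `p_value`, `cov_percent`), `rmse`
#'   (site x subject), and `comparison`.
#' @export
run_variability_study <- function(cohort,
                                  comparison = c("intra", "inter", "sequence"),
                                  estimates = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  comparison <- match.arg(comparison)
  occ <- .COMPARISONS[[comparison]]
  for (o in occ)
    if (is.null(cohort$subjects[[1]]$bundles[[o]]))
      stop_hemofit("cohort is missing occasion '%s'", o)

  grab <- function(o, f) vapply(cohort$subjects, function(s) f(s$bundles[[o]]), 0)
  inputs <- list(
    list("A_LVOT (cm^2)", "cm^2", function(b) b$a_lvot),
    list("ESV (mL)", "mL", function(b) b$esv),
    list("EOA (cm^2)", "cm^2", function(b) b$eoa),
    list("T (s)", "s", function(b) b$T_cycle))
  series <- lapply(inputs, function(q)
    paired_series(q[[1]], q[[2]], grab(occ[1], q[[3]]), grab(occ[2], q[[3]])))

  if (!is.null(estimates)) {
    for (o in occ)
      if (is.null(estimates[[o]]))
        stop_hemofit("estimates are missing occasion '%s'", o)
    for (i in seq_along(.HEADLINE)) {
      nm <- names(.HEADLINE)[i]
      val <- function(o) vapply(estimates[[o]], function(e)
        parameter_values(e$params)[[nm]], 0)
      units <- sub(".*\\((.*)\\)$", "\\1", .HEADLINE[i])
      series[[length(series) + 1]] <-
        paired_series(unname(.HEADLINE[i]), units, val(occ[1]), val(occ[2]))
    }
  }

  tab <- do.call(rbind, lapply(series, function(s) {
    ba <- bland_altman(s)
    data.frame(quantity = s$name, units = s$units, bias = ba$bias,
               loa_low = ba$loa_low, loa_high = ba$loa_high,
               p_value = rank_test(s)$p_value,
               cov_percent = cov_repeatability(s),
               stringsAsFactors = FALSE)
  }))

  sites <- c("mitral_valve", "aortic_valve", "ascending_aorta")
  rmse <- do.call(rbind, lapply(sites, function(site) {
    data.frame(site = site,
               subject = vapply(cohort$subjects,
                                function(s) s$bundles[[occ[1]]]$subject_id, ""),
               rmse = vapply(cohort$subjects, function(s)
                 waveform_rmse(s$bundles[[occ[1]]]$waveforms[[site]],
                               s$bundles[[occ[2]]]$waveforms[[site]]), 0),
               stringsAsFactors = FALSE)
  }))

  structure(list(table = tab, rmse = rmse, comparison = comparison),
            class = "variability_report")
}

#' @export
print.variability_report <- function(x, ...) {
  cat(sprintf("<variability_report> comparison: %s\n", x$comparison))
  print(x$table, row.names = FALSE, digits = 3)
  cat("\nwaveform RMSE (mL/s), mean per site:\n")
  print(stats::aggregate(rmse ~ site, data = x$rmse, FUN = mean), digits = 3)
  invisible(x)
}

#' Write a variability report as CSV
#'
#' @param report a `variability_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}
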