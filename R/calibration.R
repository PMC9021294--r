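# Spike-in-normalized cloning frequency and the mismatch-vs-stoichiometry
# calibration with stoichiometry inversion.

#' Spike-in-normalized cloning frequency
#'
#' Frequency of each RNA group relative to the total count mapped to the QC
#' spike-ins of its library, making cloning frequencies comparable across
#' libraries and RTs (library depth cancels).
#'
#' @param count_table a [make_count_table()] result for one library.
#' @param ref the [reference_set()]; its QC-flagged spike-ins define the
#'   denominator. Alternatively pass `qc_names` directly.
#' @param qc_names character vector of QC spike-in reference names.
#' @return `count_table` with an added `spike_norm_freq` column.
#' @export
spikein_normalized_frequency <- function(count_table, ref = NULL,
                                         qc_names = NULL) {
  qc_names <- qc_names %||% ref$spikeins$name[ref$spikeins$is_qc]
  if (!length(qc_names)) stop("no QC spike-ins defined")
  denom <- sum(count_table$count[count_table$group %in% qc_names])
  if (denom <= 0)
    stop("zero QC spike-in counts in this library; cannot normalize")
  count_table$spike_norm_freq <- count_table$count / denom
  count_table
}

#' Zero-intercept calibration of mismatch rate against known stoichiometry
#'
#' Linear fit forced through the origin, `mismatch% = slope *
#' stoichiometry%`, as used to benchmark an RT on synthetic m1A oligos
#' mixed at known ratios. R^2 follows the uncentered (zero-intercept)
#' convention, `1 - sum((y - yhat)^2) / sum(y^2)`, which is what
#' `summary.lm` reports for intercept-free fits. The background mismatch
#' rate is *not* subtracted inside the fit; it is estimated separately from
#' the 0% points and used only when inverting the curve.
#'
#' @param points data.frame with columns `stoichiometry` (known m1A%,
#'   0-100) and `mismatch` (observed mismatch%, 0-100). At least one
#'   nonzero stoichiometry required.
#' @return list of class `calibration_fit` with `slope`
#'   (mismatch%-per-stoichiometry%), `r2`, `background` (mean mismatch% at
#'   stoichiometry 0, `NA` if absent), `points`, and the underlying `lm`
#'   fit.
#' @export
fit_calibration <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("stoichiometry", "mismatch") %in% names(points)))
  if (nrow(points) < 1L || all(points$stoichiometry == 0))
    stop("calibration requires points with nonzero stoichiometry")
  fit <- stats::lm(mismatch ~ 0 + stoichiometry, data = points)
  zero <- points$stoichiometry == 0
  structure(list(slope = unname(stats::coef(fit)[1L]),
                 r2 = 1 - sum(stats::residuals(fit)^2) /
                   sum(points$mismatch^2),
                 background = if (any(zero)) mean(points$mismatch[zero])
                 else NA_real_,
                 points = points, fit = fit),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "calibration_fit: slope=%.4f %%/%%, R2=%.4f, background=%s%% (%d points)\n",
    x$slope, x$r2,
    if (is.na(x$background)) "NA" else sprintf("%.3f", x$background),
    nrow(x$points)))
  invisible(x)
}

#' Invert a calibration curve into a stoichiometry estimate
#'
#' Semi-quantitative stoichiometry estimate `p_hat = (observed -
#' background) / slope`, clamped to `[0, 1]` on the proportion scale, with
#' a percentile bootstrap confidence interval over read resampling when the
#' read depth behind the observed rate is supplied.
#'
#' @param observed observed mismatch index in percent.
#' @param fit a [fit_calibration()] result.
#' @param background background mismatch percent (defaults to the fit's; 0
#'   when that is `NA`).
#' @param n_reads read depth behind `observed`; enables the bootstrap CI.
#' @param n_boot bootstrap resamples.
#' @param conf CI level.
#' @param seed RNG seed for the bootstrap.
#' @return list with `p_hat` (proportion in `[0, 1]`), `ci` (or `NULL`),
#'   `observed`, `background`, `slope`.
#' @export
estimate_stoichiometry <- function(observed, fit, background = NULL,
                                   n_reads = NULL, n_boot = 1000,
                                   conf = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "calibration_fit"), fit$slope > 0)
  background <- background %||% fit$background
  if (is.na(background)) background <- 0
  invert <- function(obs)
    pmin(pmax((obs - background) / fit$slope, 0), 100) / 100
  if (observed < background)
    warning("observed mismatch below background; estimate clamped to 0")
  ci <- NULL
  if (!is.null(n_reads)) {
    set_seed_if(seed)
    k <- stats::rbinom(n_boot, n_reads, observed / 100)
    ci <- unname(stats::quantile(invert(100 * k / n_reads),
                                 c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  list(p_hat = invert(observed), ci = ci, observed = observed,
       background = background, slope = fit$slope)
}
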