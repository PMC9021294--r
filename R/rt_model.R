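#' Reverse-transcriptase error model
#'
#' Describes how a given RT behaves when it reaches an m1A: it either stalls
#' (probability `p_stall`; in a ligation-first library preparation the
#' stalled cDNA can never be amplified, so the molecule is lost), reads
#' through with a misincorporation (`p_mis`, substituted base drawn from
#' `mis_spectrum`), or reads through faithfully. Every position of every
#' emitted read is additionally substituted with the background error rate
#' `eps_bg`, uniformly over the three non-reference bases.
#'
#' Three named presets are provided. TGIRT reads through m1A with a high
#' misincorporation rate and a low (~0.2%) background error rate, which is
#' what makes the mismatch signature usable for site calling; ProtoScriptII
#' (an M-MuLV RT) predominantly stalls, so m1A-containing molecules are
#' under-represented in its libraries; RT-1306 (engineered HIV RT) is
#' intermediate. The preset numbers are configuration defaults shaped by the
#' qualitative behavior of the three enzymes, not fitted constants, and every
#' field can be overridden.
#'
#' @param name `"TGIRT"`, `"PSII"`, `"RT1306"`, or `"custom"`.
#' @param p_mis probability of misincorporation at a modified base, per
#'   molecule.
#' @param p_stall probability of truncation at a modified base (molecule
#'   discarded). `p_mis + p_stall` must not exceed 1.
#' @param eps_bg per-base background substitution probability.
#' @param mis_spectrum named numeric over `C`, `G`, `T`: distribution of the
#'   substituted base at the modified adenosine. Normalized to sum to 1.
#' @return a list of class `RTModel`.
#' @examples
#' rt_model("TGIRT")
#' rt_model("TGIRT", p_mis = 0.9)  # preset with one field overridden
#' @export
rt_model <- function(name = c("TGIRT", "PSII", "RT1306", "custom"),
                     p_mis = NULL, p_stall = NULL, eps_bg = NULL,
                     mis_spectrum = NULL) {
  name <- match.arg(name)
  presets <- list(
    TGIRT  = list(p_mis = 0.85, p_stall = 0.05, eps_bg = 0.002),
    PSII   = list(p_mis = 0.05, p_stall = 0.90, eps_bg = 0.005),
    RT1306 = list(p_mis = 0.70, p_stall = 0.10, eps_bg = 0.005),
    custom = list(p_mis = NA_real_, p_stall = NA_real_, eps_bg = NA_real_)
  )
  def <- presets[[name]]
  p_mis <- p_mis %||% def$p_mis
  p_stall <- p_stall %||% def$p_stall
  eps_bg <- eps_bg %||% def$eps_bg
  mis_spectrum <- mis_spectrum %||% c(C = 1, G = 1, T = 1) / 3

  if (anyNA(c(p_mis, p_stall, eps_bg)))
    stop("custom RT models require p_mis, p_stall and eps_bg")
  stopifnot(p_mis >= 0, p_mis <= 1, p_stall >= 0, p_stall <= 1,
            eps_bg >= 0, eps_bg <= 1)
  if (p_mis + p_stall > 1)
    stop("p_mis + p_stall must not exceed 1")
  if (!setequal(names(mis_spectrum), c("C", "G", "T")) ||
      any(mis_spectrum < 0) || sum(mis_spectrum) <= 0)
    stop("mis_spectrum must be a nonnegative vector over C, G, T")
  mis_spectrum <- mis_spectrum[c("C", "G", "T")] / sum(mis_spectrum)

  structure(list(name = name, p_mis = p_mis, p_stall = p_stall,
                 eps_bg = eps_bg, mis_spectrum = mis_spectrum),
            class = "RTModel")
}

#' @export
print.RTModel <- function(x, ...) {
  cat(sprintf("RTModel %s: p_mis=%.3g p_stall=%.3g eps_bg=%.3g\n",
              x$name, x$p_mis, x$p_stall, x$eps_bg))
  invisible(x)
}

#' Expected mismatch rate at a modified site
#'
#' Closed form of the RT model at an annotated site with stoichiometry `p`:
#' among emitted (non-stalled) reads, the fraction with a misincorporation at
#' the site is `p * p_mis / (1 - p * p_stall)`; the remaining reads pick up a
#' background substitution at the site with probability `eps_bg`. Used as the
#' convergence oracle for the simulator and to predict calibration slopes.
#'
#' @param p modification stoichiometry in `[0, 1]` (fraction of molecules
#'   carrying the modification).
#' @param rt an [rt_model()].
#' @return expected mismatch rate at the site, in percent (0-100 scale).
#' @export
expected_mismatch_rate <- function(p, rt) {
  stopifnot(inherits(rt, "RTModel"), all(p >= 0 & p <= 1))
  attributable <- p * rt$p_mis / (1 - p * rt$p_stall)
  100 * (attributable + (1 - attributable) * rt$eps_bg)
}
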