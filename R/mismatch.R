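# Per-position mismatch pileups, the mismatch index and its variants,
# substitution spectra, and cross-condition mismatch comparisons.

#' Per-position mismatch pileup for a fragment group
#'
#' Sums fractional-weighted coverage and substitution counts per position
#' over the hits selected by the filters. Soft-clipped miRNA tail bases are
#' never part of the alignment core, so they are excluded by construction.
#' Multi-mapping reads contribute their per-hit weight to each hit's
#' profile.
#'
#' @param hits an [align_reads()] result.
#' @param frame `"fragment"` (position 1..fragment length; the frame in
#'   which all tRF-3bs are pooled, where the A58-equivalent sits at
#'   position 4) or `"mature"` (position on the parent reference).
#' @param parent,trf_class,isoform,category optional filters; `NULL` keeps
#'   everything.
#' @param ref optional [reference_set()]; when the selected hits share a
#'   single parent the profile gains a `ref_base` column.
#' @return data.frame of class `mismatch_profile` with `position`,
#'   `ref_base`, `coverage`, `sub_A`, `sub_C`, `sub_G`, `sub_T`,
#'   `mismatches`.
#' @export
pileup <- function(hits, frame = c("fragment", "mature"), parent = NULL,
                   trf_class = NULL, isoform = NULL, category = NULL,
                   ref = NULL) {
  frame <- match.arg(frame)
  keep <- rep(TRUE, nrow(hits))
  if (!is.null(parent)) keep <- keep & hits$parent %in% parent
  if (!is.null(trf_class)) keep <- keep & hits$class %in% trf_class
  if (!is.null(isoform)) keep <- keep & hits$isoform %in% isoform
  if (!is.null(category)) keep <- keep & hits$category %in% category
  h <- hits[keep, , drop = FALSE]
  if (!nrow(h)) {
    warning("no aligned reads match the requested group; empty profile")
    return(structure(
      data.frame(position = integer(0), ref_base = character(0),
                 coverage = numeric(0), sub_A = numeric(0),
                 sub_C = numeric(0), sub_G = numeric(0), sub_T = numeric(0),
                 mismatches = numeric(0)),
      frame = frame, class = c("mismatch_profile", "data.frame")))
  }

  pos_of <- function(start, end, i) if (frame == "fragment") i else
    start + i - 1L
  maxpos <- if (frame == "fragment") max(h$end - h$start + 1L) else max(h$end)
  cov <- numeric(maxpos)
  subs <- matrix(0, nrow = maxpos, ncol = 4L,
                 dimnames = list(NULL, DNA_BASES))
  for (i in seq_len(nrow(h))) {
    w <- h$count[i] * h$weight[i]
    core_len <- h$end[i] - h$start[i] + 1L
    span <- pos_of(h$start[i], h$end[i], seq_len(core_len))
    cov[span] <- cov[span] + w
    if (h$n_mm[i] > 0L) {
      mp <- as.integer(strsplit(h$mm_pos[i], ",")[[1]])
      mb <- strsplit(h$mm_read[i], ",")[[1]]
      at <- pos_of(h$start[i], h$end[i], mp)
      for (j in seq_along(at))
        subs[at[j], mb[j]] <- subs[at[j], mb[j]] + w
    }
  }

  ref_base <- rep(NA_character_, maxpos)
  if (!is.null(ref) && length(unique(h$parent)) == 1L) {
    pseq <- ref_sequence(ref, h$parent[1L])
    if (frame == "mature") {
      ref_base <- substring(pseq, seq_len(maxpos), seq_len(maxpos))
    } else if (length(unique(h$start)) == 1L) {
      span <- h$start[1L]:(h$start[1L] + maxpos - 1L)
      ref_base <- substring(pseq, span, span)
    }
  }

  structure(
    data.frame(position = seq_len(maxpos), ref_base = ref_base,
               coverage = cov, sub_A = subs[, "A"], sub_C = subs[, "C"],
               sub_G = subs[, "G"], sub_T = subs[, "T"],
               mismatches = rowSums(subs)),
    frame = frame, class = c("mismatch_profile", "data.frame"))
}

#' Mismatch index at a position
#'
#' Percent of reads carrying any non-reference base at the position:
#' `100 * substitutions / coverage`. Undefined (`NA`, not 0) unless
#' coverage strictly exceeds `min_reads` (default 50), so no statistic is
#' ever reported from thinly covered positions.
#'
#' @param profile a [pileup()] result.
#' @param position 1-based position in the profile's frame.
#' @param min_reads coverage must be > `min_reads` for the index to be
#'   defined.
#' @return one-row data.frame with `position`, `coverage`, `mismatches`,
#'   `index` (percent, or `NA` when undefined).
#' @export
mismatch_index <- function(profile, position, min_reads = 50) {
  row <- profile[profile$position == position, , drop = FALSE]
  if (nrow(row) != 1L) stop("position ", position, " not in profile")
  idx <- if (row$coverage > min_reads)
    100 * row$mismatches / row$coverage else NA_real_
  data.frame(position = position, coverage = row$coverage,
             mismatches = row$mismatches, index = idx)
}

#' @rdname mismatch_index
#' @export
mismatch_index_profile <- function(profile, min_reads = 50) {
  do.call(rbind, lapply(profile$position, mismatch_index,
                        profile = profile, min_reads = min_reads))
}

#' Substitution spectrum at a position
#'
#' Fractions of substitutions toward each base (A entries are zero at
#' reference adenosines). Flagged empty when the position has no
#' substitutions.
#'
#' @inheritParams mismatch_index
#' @return named numeric over A/C/G/T summing to 1 (attribute
#'   `empty = TRUE` and all zeros when no substitutions).
#' @export
substitution_spectrum <- function(profile, position) {
  row <- profile[profile$position == position, , drop = FALSE]
  if (nrow(row) != 1L) stop("position ", position, " not in profile")
  v <- c(A = row$sub_A, C = row$sub_C, G = row$sub_G, T = row$sub_T)
  tot <- sum(v)
  if (tot == 0) return(structure(v, empty = TRUE))
  structure(v / tot, empty = FALSE)
}

#' Share of mismatches occurring at reference adenosines
#'
#' Group-level aggregate reported next to substitution spectra: the
#' fraction of all substitutions that sit at reference-A positions. Close
#' to 1 when m1A-driven misincorporation dominates; close to the A
#' composition of the reference when background error dominates. Requires
#' a profile with resolved `ref_base`.
#'
#' @param profile a [pileup()] result with non-`NA` `ref_base`.
#' @return fraction in `[0, 1]` (`NA` when the profile has no mismatches).
#' @export
a_mismatch_share <- function(profile) {
  if (all(is.na(profile$ref_base)))
    stop("profile has no reference bases; pass `ref` to pileup()")
  tot <- sum(profile$mismatches)
  if (tot == 0) return(NA_real_)
  sum(profile$mismatches[profile$ref_base == "A"], na.rm = TRUE) / tot
}

#' Normalized mismatch index
#'
#' Mismatch percent divided by non-mismatch percent: `value / (100 -
#' value)`. Useful when comparing conditions because it grows without
#' bound as a site saturates.
#'
#' @param value mismatch index in percent, `0 <= value <= 100`.
#' @return the ratio; `Inf` with a warning at `value = 100`.
#' @export
normalized_mismatch_index <- function(value) {
  stopifnot(all(value >= 0 & value <= 100))
  out <- value / (100 - value)
  if (any(value == 100)) warning("mismatch index saturated at 100%")
  out
}

#' Compare mismatch rates between two conditions at a position
#'
#' Difference and pseudocounted log2 fold change of the mismatch index
#' between two profiles (e.g. control vs writer-enzyme knockdown).
#' Undefined coverage in either profile propagates `NA` with the reason.
#'
#' @param profile_a,profile_b [pileup()] results for the two conditions
#'   (A is the numerator, e.g. knockdown over control puts the knockdown
#'   first).
#' @param position position in the shared frame.
#' @param pseudocount added to both rates (percentage points) before the
#'   log ratio.
#' @param min_reads coverage threshold for [mismatch_index()].
#' @return one-row data.frame with `position`, `index_a`, `index_b`,
#'   `delta`, `log2fc`, `reason` (`NA` unless undefined).
#' @export
compare_mismatch <- function(profile_a, profile_b, position,
                             pseudocount = 0.1, min_reads = 50) {
  ia <- mismatch_index(profile_a, position, min_reads)
  ib <- mismatch_index(profile_b, position, min_reads)
  if (is.na(ia$index) || is.na(ib$index)) {
    side <- c(if (is.na(ia$index)) "A", if (is.na(ib$index)) "B")
    return(data.frame(position = position, index_a = ia$index,
                      index_b = ib$index, delta = NA_real_,
                      log2fc = NA_real_,
                      reason = paste0("coverage <= ", min_reads,
                                      " in profile ",
                                      paste(side, collapse = "+"))))
  }
  data.frame(position = position, index_a = ia$index, index_b = ib$index,
             delta = ia$index - ib$index,
             log2fc = log2((ia$index + pseudocount) /
                             (ib$index + pseudocount)),
             reason = NA_character_)
}
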