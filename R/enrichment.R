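# RIP-vs-input enrichment statistics, class-level comparisons, and the
# two-antibody m1A candidate call.

#' Log2 fold enrichment of RIP over input
#'
#' `log2((rip_rpm + pseudo) / (input_rpm + pseudo))`. When libraries carry
#' QC spike-ins, pass the spike-in totals as the normalizers with
#' `scale = 1` to use spike-in-normalized frequencies instead of RPM
#' (recommended for RIP arms, where antibody capture distorts the mapped
#' total).
#'
#' @param input_count,rip_count counts (fractional allowed) for the RNA.
#' @param input_norm,rip_norm normalization denominators: total mapped
#'   reads (RPM; use `scale = 1e6`) or total QC spike-in counts (`scale =
#'   1`).
#' @param pseudocount added to both normalized abundances (default 0.5, on
#'   the scale in use).
#' @param scale abundance scale factor (1e6 for RPM).
#' @return numeric log2 fold enrichment (vectorized).
#' @export
log2_fold_enrichment <- function(input_count, rip_count, input_norm,
                                 rip_norm, pseudocount = 0.5, scale = 1e6) {
  stopifnot(all(input_norm > 0), all(rip_norm > 0))
  log2((scale * rip_count / rip_norm + pseudocount) /
         (scale * input_count / input_norm + pseudocount))
}

#' Binomial enrichment test of RIP against input
#'
#' Two-sided exact binomial test of the RIP count against the combined
#' count, with null proportion equal to the RIP share of the combined
#' library depth. A deliberately simple replacement for a negative-binomial
#' engine, valid for the simulator's Poisson-like (multinomial) counts.
#' Records with fewer than `min_count` combined reads are excluded
#' (`NA`).
#'
#' @param input_count,rip_count per-RNA counts (vectorized; rounded to
#'   integers for testing).
#' @param input_lib_size,rip_lib_size library totals.
#' @param min_count minimum combined count to be tested (default 10).
#' @return numeric p-values (`NA` for excluded records).
#' @export
enrichment_test <- function(input_count, rip_count, input_lib_size,
                            rip_lib_size, min_count = 10) {
  stopifnot(input_lib_size > 0, rip_lib_size > 0)
  p0 <- rip_lib_size / (rip_lib_size + input_lib_size)
  x <- round(rip_count)
  n <- round(rip_count) + round(input_count)
  vapply(seq_along(x), function(i) {
    if (n[i] < min_count) return(NA_real_)
    stats::binom.test(x[i], n[i], p = p0)$p.value
  }, numeric(1))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (wraps
#' [stats::p.adjust()] with `method = "BH"`), applied over the tested
#' (non-`NA`) records.
#'
#' @param p numeric p-values in `[0, 1]` (`NA` allowed, passed through).
#' @return adjusted p-values.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")

#' Build per-RNA enrichment records for one RIP arm
#'
#' Joins the input and RIP count tables on group, computes log2 fold
#' enrichment (spike-in normalized when QC spike-ins are present in both
#' tables), the binomial enrichment p-value and its BH adjustment.
#'
#' @param input_counts,rip_counts [make_count_table()] results for the two
#'   libraries.
#' @param ref optional [reference_set()] supplying QC spike-in names.
#' @param pseudocount pseudocount for the fold enrichment.
#' @param min_count minimum combined count for testing.
#' @return data.frame with `group`, `input_count`, `rip_count`,
#'   `input_rpm`, `rip_rpm`, `log2fe`, `p`, `padj`, `meets_min_count`.
#' @export
enrichment_records <- function(input_counts, rip_counts, ref = NULL,
                               pseudocount = 0.5, min_count = 10) {
  m <- merge(input_counts[, c("group", "count")],
             rip_counts[, c("group", "count")],
             by = "group", all = TRUE, suffixes = c("_input", "_rip"))
  m$count_input[is.na(m$count_input)] <- 0
  m$count_rip[is.na(m$count_rip)] <- 0
  in_total <- sum(input_counts$count)
  rip_total <- sum(rip_counts$count)

  qc <- if (!is.null(ref)) ref$spikeins$name[ref$spikeins$is_qc] else
    character(0)
  in_qc <- sum(input_counts$count[input_counts$group %in% qc])
  rip_qc <- sum(rip_counts$count[rip_counts$group %in% qc])
  spike_norm <- length(qc) > 0 && in_qc > 0 && rip_qc > 0

  # pseudocount stated in RPM of the input library; convert to spike-in
  # frequency units so both normalizations use the same effective prior
  log2fe <- if (spike_norm)
    log2_fold_enrichment(m$count_input, m$count_rip, in_qc, rip_qc,
                         pseudocount = pseudocount * in_total / 1e6 / in_qc,
                         scale = 1)
  else
    log2_fold_enrichment(m$count_input, m$count_rip, in_total, rip_total,
                         pseudocount = pseudocount)
  p <- enrichment_test(m$count_input, m$count_rip, in_total, rip_total,
                       min_count = min_count)
  data.frame(group = m$group,
             input_count = m$count_input, rip_count = m$count_rip,
             input_rpm = 1e6 * m$count_input / in_total,
             rip_rpm = 1e6 * m$count_rip / rip_total,
             log2fe = log2fe, p = p, padj = adjust_bh(p),
             meets_min_count = !is.na(p),
             stringsAsFactors = FALSE)
}

#' Class-level enrichment comparison against the miRNA class
#'
#' Pairwise two-sided Wilcoxon rank-sum tests of per-RNA log2 fold
#' enrichments of each class against the reference class (miRNAs). Classes
#' with fewer than `min_n` members are skipped with a note.
#'
#' @param log2fe numeric vector of per-RNA log2 fold enrichments.
#' @param class character vector of RNA classes, parallel to `log2fe`.
#' @param ref_class the comparison baseline.
#' @param min_n minimum class size to test.
#' @return data.frame with `class`, `n`, `p`, `note`.
#' @export
class_enrichment_comparison <- function(log2fe, class, ref_class = "miR",
                                        min_n = 3L) {
  stopifnot(length(log2fe) == length(class))
  base <- log2fe[class == ref_class]
  if (length(base) < min_n)
    stop("reference class '", ref_class, "' has fewer than ", min_n,
         " members")
  out <- lapply(setdiff(unique(class), ref_class), function(cl) {
    x <- log2fe[class == cl]
    if (length(x) < min_n)
      return(data.frame(class = cl, n = length(x), p = NA_real_,
                        note = "skipped: below minimum class size"))
    p <- suppressWarnings(stats::wilcox.test(x, base)$p.value)
    data.frame(class = cl, n = length(x), p = p, note = NA_character_)
  })
  do.call(rbind, out)
}

#' Two-antibody m1A candidate call
#'
#' An RNA is a `candidate` m1A carrier iff it is significantly enriched
#' (padj < `padj_cut` and positive log2 fold enrichment, with enough
#' counts) in *every* antibody arm, not significantly enriched in the IgG
#' control arm, and shows a defined mismatch index above
#' `mismatch_cut` percent at at least one annotated site (the independent
#' misincorporation evidence). RNAs with antibody enrichment but no
#' mismatch evidence are `antibody-only`; mismatch without reproducible
#' antibody enrichment is `mismatch-only`; the rest are `negative`.
#'
#' @param antibody_records named list of [enrichment_records()] results,
#'   one per antibody.
#' @param igg_records [enrichment_records()] for the IgG arm, or `NULL`.
#' @param site_mismatch data.frame with `group` and `index` (the maximal
#'   defined mismatch index in percent across the group's annotated
#'   sites); groups absent from it count as having no mismatch evidence.
#' @param padj_cut adjusted-p threshold (default 0.1).
#' @param mismatch_cut mismatch-index evidence threshold in percent.
#' @return data.frame with per-rule flags and a `verdict` column.
#' @export
call_m1a_candidates <- function(antibody_records, igg_records = NULL,
                                site_mismatch = NULL, padj_cut = 0.1,
                                mismatch_cut = 10) {
  stopifnot(length(antibody_records) >= 1)
  enriched <- function(rec, g) {
    i <- match(g, rec$group)
    ok <- !is.na(i) & !is.na(rec$padj[i]) & rec$padj[i] < padj_cut &
      rec$log2fe[i] > 0 & rec$meets_min_count[i]
    ok[is.na(ok)] <- FALSE
    ok
  }
  groups <- sort(unique(unlist(lapply(antibody_records, `[[`, "group"))))
  ab <- vapply(antibody_records, enriched, logical(length(groups)),
               g = groups)
  ab <- matrix(ab, nrow = length(groups))
  ab_all <- apply(ab, 1L, all)
  igg <- if (is.null(igg_records)) rep(FALSE, length(groups)) else
    enriched(igg_records, groups)
  mis <- if (is.null(site_mismatch)) rep(FALSE, length(groups)) else {
    i <- match(groups, site_mismatch$group)
    ok <- !is.na(i) & !is.na(site_mismatch$index[i]) &
      site_mismatch$index[i] > mismatch_cut
    ok[is.na(ok)] <- FALSE
    ok
  }
  verdict <- ifelse(ab_all & !igg & mis, "candidate",
                    ifelse(ab_all & !igg, "antibody-only",
                           ifelse(mis & !ab_all, "mismatch-only",
                                  "negative")))
  out <- data.frame(group = groups, enriched_all_antibodies = ab_all,
                    enriched_igg = igg, has_site_mismatch = mis,
                    verdict = verdict, stringsAsFactors = FALSE)
  for (nm in names(antibody_records))
    out[[paste0("enriched_", nm)]] <- enriched(antibody_records[[nm]],
                                               groups)
  out
}
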