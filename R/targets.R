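# Seed extraction and clustering of tRF-3bs, 3' UTR target-site scanning
# with the four canonical site types, highest-rank gene classification, and
# the centered-CDF / one-sided Kolmogorov-Smirnov repression analysis.

#' Extract the seed (guide positions 2-8) of a small RNA
#'
#' @param guide character vector of guide sequences (DNA alphabet), each at
#'   least 8 nt.
#' @return 7-nt seed strings.
#' @examples
#' extract_seed("TAGCTTATCAGACTGATGTTGA")  # "AGCTTAT"
#' @export
extract_seed <- function(guide) {
  guide <- toupper(guide)
  if (any(nchar(guide) < 8L))
    stop("guide shorter than 8 nt has no seed")
  substr(guide, 2L, 8L)
}

#' Cluster guide RNAs into seed families
#'
#' Groups guides by identical seed (positions 2-8) and reports each
#' family's share of the total (e.g. Ago-bound) read count, plus the
#' minimal number of families whose cumulative share exceeds
#' `coverage_threshold`. Optionally carries a per-guide m1A-responsiveness
#' value (log2 fold change of the site mismatch rate upon writer-enzyme
#' knockdown, from [compare_mismatch()]) aggregated as a count-weighted
#' mean per family.
#'
#' @param guides data.frame with columns `sequence` (or `seed`) and
#'   `count`; optionally `name` and `m1a_response`.
#' @param coverage_threshold cumulative-share threshold (default 0.90).
#' @return data.frame of families sorted by coverage share (`seed`,
#'   `members`, `count`, `coverage_share`, `cum_share`, and
#'   `m1a_response` when supplied), with attribute `k_covering` = minimal
#'   family count reaching the threshold.
#' @export
cluster_seeds <- function(guides, coverage_threshold = 0.90) {
  stopifnot(any(c("sequence", "seed") %in% names(guides)),
            "count" %in% names(guides), all(guides$count >= 0))
  total <- sum(guides$count)
  if (total == 0)
    return(structure(data.frame(seed = character(0), members = character(0),
                                count = numeric(0), coverage_share = numeric(0),
                                cum_share = numeric(0)),
                     k_covering = NA_integer_))
  seed <- if ("seed" %in% names(guides)) guides$seed else
    extract_seed(guides$sequence)
  nm <- if ("name" %in% names(guides)) guides$name else
    (if ("sequence" %in% names(guides)) guides$sequence else seed)
  fam <- lapply(split(seq_along(seed), seed), function(i) {
    out <- data.frame(seed = seed[i[1L]],
                      members = paste(nm[i], collapse = ","),
                      count = sum(guides$count[i]),
                      stringsAsFactors = FALSE)
    if ("m1a_response" %in% names(guides))
      out$m1a_response <- sum(guides$m1a_response[i] * guides$count[i]) /
        sum(guides$count[i])
    out
  })
  fam <- do.call(rbind, fam)
  fam <- fam[order(-fam$count), , drop = FALSE]
  fam$coverage_share <- fam$count / total
  fam$cum_share <- cumsum(fam$coverage_share)
  rownames(fam) <- NULL
  structure(fam, k_covering = match(TRUE, fam$cum_share >=
                                      coverage_threshold - 1e-12))
}

#' Scan a 3' UTR for seed-match target sites
#'
#' The four canonical site types, written 5'->3' on the mRNA with `core7 =
#' reverse-complement(seed)` (pairs guide positions 2-8) and `core6 =
#' core7[2..7]` (pairs guide positions 2-7):
#' * `8mer-A1`: core7 immediately followed by an A (the adenosine opposite
#'   guide position 1);
#' * `7mer-m8`: core7 not followed by an A;
#' * `7mer-A1`: core6 followed by an A, not part of a core7 match;
#' * `6mer`: core6 alone, qualifying for no higher type.
#' Each core6 occurrence resolves to exactly one (the highest-ranking)
#' type. `N` never matches.
#'
#' @param seed 7-nt seed (guide positions 2-8).
#' @param utr UTR sequence, alphabet `A/C/G/T/N`.
#' @return data.frame with `position` (1-based start of the site on the
#'   UTR) and `site_type`.
#' @export
scan_utr <- function(seed, utr) {
  stopifnot(nchar(seed) == 7L)
  utr <- toupper(utr)
  core7 <- revcomp(seed)
  core6 <- substr(core7, 2L, 7L)
  L <- nchar(utr)
  empty <- data.frame(position = integer(0), site_type = character(0),
                      stringsAsFactors = FALSE)
  if (L < 6L) return(empty)
  s6 <- seq_len(L - 5L)
  i6 <- s6[substring(utr, s6, s6 + 5L) == core6]
  if (!length(i6)) return(empty)
  has7 <- i6 >= 2L & substring(utr, i6 - 1L, i6 + 5L) == core7
  nxt <- ifelse(i6 + 6L <= L, substring(utr, i6 + 6L, i6 + 6L), "")
  type <- ifelse(has7,
                 ifelse(nxt == "A", "8mer-A1", "7mer-m8"),
                 ifelse(nxt == "A", "7mer-A1", "6mer"))
  data.frame(position = as.integer(ifelse(has7, i6 - 1L, i6)),
             site_type = type, stringsAsFactors = FALSE)
}

#' @noRd
site_rank <- function(type) match(type, SITE_TYPES)

#' Label expressed genes by their best seed-match site type
#'
#' Genes without a 3' UTR or with expression at or below `min_expr`
#' normalized counts are excluded entirely (neither target nor
#' non-target; the "higher than 100" filter is strict). Each remaining
#' gene is labeled by the highest-ranking site type among its sites
#' (8mer-A1 > 7mer-m8 > 7mer-A1 > 6mer), or `non-target` when it has
#' none.
#'
#' @param sites data.frame with columns `gene`, `position`, `site_type`
#'   (e.g. stacked [scan_utr()] results over the responsive seeds).
#' @param expression data.frame with `gene`, `log2FC`, `baseMean`
#'   (normalized mean count); duplicate gene ids are an error.
#' @param utr_genes genes that have a 3' UTR sequence.
#' @param min_expr strict lower expression bound (default 100).
#' @return data.frame with `gene`, `best_type` (site type or
#'   `"non-target"`), `site_count`, `multi_site`, `log2FC`, `baseMean`.
#' @export
classify_gene_targets <- function(sites, expression, utr_genes,
                                  min_expr = 100) {
  if (anyDuplicated(expression$gene))
    stop("duplicate gene ids in expression table")
  keep <- expression$baseMean > min_expr & expression$gene %in% utr_genes
  expr <- expression[keep, , drop = FALSE]
  sites <- sites[sites$gene %in% expr$gene, , drop = FALSE]
  best <- if (nrow(sites))
    vapply(split(sites$site_type, sites$gene),
           function(t) SITE_TYPES[min(site_rank(t))], "")
  else stats::setNames(character(0), character(0))
  n_sites <- if (nrow(sites)) lengths(split(sites$site_type, sites$gene)) else
    integer(0)
  bt <- unname(best[match(expr$gene, names(best))])
  sc <- unname(n_sites[match(expr$gene, names(n_sites))])
  sc[is.na(sc)] <- 0L
  data.frame(gene = expr$gene,
             best_type = ifelse(is.na(bt), "non-target", bt),
             site_count = as.integer(sc),
             multi_site = as.integer(sc) > 1L,
             log2FC = expr$log2FC, baseMean = expr$baseMean,
             stringsAsFactors = FALSE)
}

#' Centered-CDF repression analysis with one-sided Kolmogorov-Smirnov tests
#'
#' All log2 fold changes are centered by the non-target median (so the
#' non-target centered median is exactly 0), then each site-type class is
#' compared to the non-targets with a one-sided two-sample K-S test in the
#' stated direction: `"repressed"` tests whether the class distribution is
#' shifted toward lower log2FC than the non-targets, `"derepressed"` the
#' opposite. No multiple-testing adjustment is applied across the (at
#' most four) class tests; per-class p-values are reported as such.
#'
#' @param targets a [classify_gene_targets()] result (includes the
#'   non-target rows).
#' @param direction `"repressed"` or `"derepressed"`; always explicit,
#'   never inferred.
#' @param min_n minimum class size; smaller classes report `p = NA`.
#' @return list of class `repression_result`: `classes` (per class `n`,
#'   K-S `D`, `p`), `centered` (per-gene centered log2FC for ECDF plots),
#'   `direction`, `nontarget_median`.
#' @export
repression_analysis <- function(targets,
                                direction = c("repressed", "derepressed"),
                                min_n = 10L) {
  direction <- match.arg(direction)
  nt <- targets$log2FC[targets$best_type == "non-target"]
  if (length(nt) < min_n)
    stop("need at least ", min_n, " non-target genes")
  med <- stats::median(nt)
  centered <- data.frame(gene = targets$gene, class = targets$best_type,
                         centered_lfc = targets$log2FC - med,
                         stringsAsFactors = FALSE)
  nt_c <- centered$centered_lfc[centered$class == "non-target"]
  # alternative = "greater": CDF of x lies above that of y, i.e. x shifted low
  alt <- if (direction == "repressed") "greater" else "less"
  cls <- do.call(rbind, lapply(SITE_TYPES, function(t) {
    x <- centered$centered_lfc[centered$class == t]
    if (length(x) < min_n)
      return(data.frame(class = t, n = length(x), D = NA_real_,
                        p = NA_real_))
    ks <- suppressWarnings(stats::ks.test(x, nt_c, alternative = alt))
    data.frame(class = t, n = length(x), D = unname(ks$statistic),
               p = ks$p.value)
  }))
  structure(list(classes = cls, centered = centered, direction = direction,
                 nontarget_median = med,
                 n_nontarget = length(nt_c),
                 adjustment = "none (per-class p-values reported)"),
            class = "repression_result")
}

#' @export
print.repression_result <- function(x, ...) {
  cat("Repression analysis (", x$direction, "), ", x$n_nontarget,
      " non-targets\n", sep = "")
  print(x$classes, row.names = FALSE)
  invisible(x)
}

#' Does a tRF seed collide with an expressed miRNA seed?
#'
#' Exact 7-mer identity with the seed (positions 2-8) of any miRNA whose
#' read count strictly exceeds `min_count`.
#'
#' @param seed 7-nt seed(s) to check (vectorized).
#' @param mirnas data.frame with `sequence` and `count` per miRNA.
#' @param min_count expression threshold (strict, default 10).
#' @return logical vector.
#' @export
seed_overlap_with_mirnas <- function(seed, mirnas, min_count = 10) {
  expressed <- mirnas[mirnas$count > min_count &
                        nchar(mirnas$sequence) >= 8L, , drop = FALSE]
  if (!nrow(expressed)) return(rep(FALSE, length(seed)))
  seed %in% extract_seed(expressed$sequence)
}
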