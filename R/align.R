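# Annotation module: mismatch-tolerant hierarchical mapping of trimmed
# small-RNA reads over a small reference space, and tRF classification.
#
# The reference space here is a few kilobases, so the aligner is a
# transparent exact-candidate + Hamming-verify scheme rather than a genome
# aligner: with at most one substitution and no indels allowed, one of two
# disjoint anchor k-mers at the 5' end of the read must be error-free, so a
# k-mer hash lookup enumerates every candidate placement exactly.

#' Mapping policy
#'
#' Hierarchical category order with per-category mismatch allowances:
#' miRNAs may carry up to `mir_max_tail` non-templated 3' bases (soft
#' clipped, excluded from mismatch counting) and 1 internal mismatch; tRNA
#' space (mature tRNAs + trailers) and spike-ins allow 1 mismatch, 0
#' indels, no clipping. A read with any hit in an earlier category is not
#' searched in later ones. Reads shorter than `min_len` or longer than
#' `max_len` are discarded and tallied.
#'
#' @param order reference categories in priority order.
#' @param mir_max_mismatch,mir_max_tail miRNA-category limits.
#' @param trf_max_mismatch tRNA-space / spike-in mismatch limit.
#' @param min_len,max_len read length window in nt.
#' @return a list of class `MappingPolicy`.
#' @export
mapping_policy <- function(order = c("miR", "tRNA", "spikeIn"),
                           mir_max_mismatch = 1L, mir_max_tail = 2L,
                           trf_max_mismatch = 1L,
                           min_len = 15L, max_len = 50L) {
  stopifnot(length(order) > 0, mir_max_mismatch >= 0, mir_max_tail >= 0,
            trf_max_mismatch >= 0, min_len >= 1, max_len >= min_len)
  structure(list(order = order, mir_max_mismatch = mir_max_mismatch,
                 mir_max_tail = mir_max_tail,
                 trf_max_mismatch = trf_max_mismatch,
                 min_len = min_len, max_len = max_len),
            class = "MappingPolicy")
}

#' Build a k-mer index over a reference set
#'
#' Hash from every reference k-mer to its occurrences; supports exact
#' all-occurrence lookup of longer k-mers by prefix candidacy plus
#' verification.
#'
#' @param ref a [reference_set()].
#' @param k anchor k-mer size (6 allows two disjoint anchors inside the
#'   shortest accepted read core of 13 nt).
#' @return a list of class `kmer_index`.
#' @export
build_index <- function(ref, k = 6L) {
  seqs <- ref$seqs
  if (anyDuplicated(names(seqs)))
    stop("duplicate reference names")
  kmers <- character(0)
  codes <- integer(0)
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    if (L < k) next
    starts <- 1:(L - k + 1L)
    kmers <- c(kmers, substring(seqs[i], starts, starts + k - 1L))
    codes <- c(codes, i * 100000L + starts)
  }
  env <- list2env(split(codes, kmers), hash = TRUE)
  structure(list(k = k, env = env, seqs = seqs,
                 category = ref$category, ref = ref),
            class = "kmer_index")
}

#' Exact all-occurrence lookup of a k-mer in the index
#'
#' @param index a [build_index()] result.
#' @param kmer query of length >= the index k.
#' @return data.frame with columns `ref`, `pos` (1-based), possibly empty.
#' @export
lookup_kmer <- function(index, kmer) {
  klen <- nchar(kmer)
  if (klen < index$k) stop("query shorter than index k")
  codes <- index$env[[substr(kmer, 1L, index$k)]]
  if (is.null(codes))
    return(data.frame(ref = character(0), pos = integer(0)))
  ri <- codes %/% 100000L
  pos <- codes %% 100000L
  keep <- substring(index$seqs[ri], pos, pos + klen - 1L) == kmer
  data.frame(ref = names(index$seqs)[ri[keep]], pos = pos[keep],
             stringsAsFactors = FALSE)
}

# all candidate (ref_i, start) placements of `core` with <= 1 mismatch,
# restricted to references of the given categories
#' @noRd
candidate_starts <- function(core, index, cats) {
  k <- index$k
  cand_ri <- integer(0)
  cand_st <- integer(0)
  for (a in c(1L, k + 1L)) {
    codes <- index$env[[substr(core, a, a + k - 1L)]]
    if (is.null(codes)) next
    ri <- codes %/% 100000L
    st <- codes %% 100000L - a + 1L
    cand_ri <- c(cand_ri, ri)
    cand_st <- c(cand_st, st)
  }
  if (!length(cand_ri)) return(NULL)
  keep <- !duplicated(cand_ri * 100000L + cand_st) &
    cand_st >= 1L &
    cand_st + nchar(core) - 1L <= nchar(index$seqs)[cand_ri] &
    index$category[cand_ri] %in% cats
  list(ri = cand_ri[keep], start = cand_st[keep])
}

# align one read following the category priority; NULL when unmapped
#' @noRd
align_read_one <- function(seq, index, policy) {
  L <- nchar(seq)
  for (cat in policy$order) {
    cats <- if (cat == "tRNA") c("tRNA", "trailer") else cat
    clips <- if (cat == "miR") 0:policy$mir_max_tail else 0L
    maxmm <- if (cat == "miR") policy$mir_max_mismatch else
      policy$trf_max_mismatch
    hits <- list()
    for (clip in clips) {
      core_len <- L - clip
      if (core_len < 2L * index$k) break
      core <- substr(seq, 1L, core_len)
      cand <- candidate_starts(core, index, cats)
      if (is.null(cand)) next
      for (j in seq_along(cand$ri)) {
        ri <- cand$ri[j]
        st <- cand$start[j]
        key <- paste0(ri, ":", st)
        if (!is.null(hits[[key]])) next   # keep the smallest clip per locus
        refsub <- substr(index$seqs[ri], st, st + core_len - 1L)
        mm <- hamming_positions(core, refsub)
        if (length(mm) <= maxmm)
          hits[[key]] <- list(
            ref = names(index$seqs)[ri], start = st,
            end = st + core_len - 1L, clip = clip,
            mm_pos = mm,
            mm_ref = if (length(mm)) substring(refsub, mm, mm)
                     else character(0),
            mm_read = if (length(mm)) substring(core, mm, mm)
                      else character(0))
      }
    }
    if (length(hits))
      return(list(category = cat, hits = unname(hits)))
  }
  NULL
}

#' Align a read multiset against the reference space
#'
#' Reads are collapsed to unique sequences before alignment (counts carried
#' as weights). Every hit of a read receives an equal fractional weight
#' (`1 / n_hits`) so multi-mapping reads are never double counted. Reads
#' outside the 15-50 nt window, and reads with no hit in any category, are
#' tallied in the attached summary.
#'
#' @param reads a read multiset data.frame (`sequence`, `count`) or a
#'   character vector of read sequences.
#' @param ref a [reference_set()].
#' @param policy a [mapping_policy()].
#' @param index optionally a prebuilt [build_index()] for `ref`.
#' @return data.frame of per-hit alignments: `sequence`, `count`,
#'   `category`, `parent`, `class`, `isoform`, `start`, `end`, `clip`,
#'   `n_mm`, `mm_pos`, `mm_ref`, `mm_read` (comma-joined), `weight`.
#'   Attribute `summary` tallies input/mapped/unmapped/length-filtered
#'   reads.
#' @export
align_reads <- function(reads, ref, policy = mapping_policy(),
                        index = NULL) {
  if (is.character(reads)) {
    tab <- table(reads)
    reads <- data.frame(sequence = names(tab), count = as.integer(tab),
                        stringsAsFactors = FALSE)
  }
  reads <- stats::aggregate(count ~ sequence, data = reads, FUN = sum)
  index <- index %||% build_index(ref)

  len <- nchar(reads$sequence)
  in_window <- len >= policy$min_len & len <= policy$max_len
  n_lenfilt <- sum(reads$count[!in_window])
  reads <- reads[in_window, , drop = FALSE]

  rows <- list()
  n_unmapped <- 0L
  for (i in seq_len(nrow(reads))) {
    aln <- align_read_one(reads$sequence[i], index, policy)
    if (is.null(aln)) {
      n_unmapped <- n_unmapped + reads$count[i]
      next
    }
    w <- 1 / length(aln$hits)
    for (h in aln$hits) {
      cls <- classify_trf(h$ref, h$start, h$end, index$ref)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = reads$sequence[i], count = reads$count[i],
        category = aln$category, parent = h$ref,
        class = cls$class, isoform = cls$isoform,
        start = h$start, end = h$end, clip = h$clip,
        n_mm = length(h$mm_pos),
        mm_pos = paste(h$mm_pos, collapse = ","),
        mm_ref = paste(h$mm_ref, collapse = ","),
        mm_read = paste(h$mm_read, collapse = ","),
        weight = w, stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(0), count = integer(0),
               category = character(0), parent = character(0),
               class = character(0), isoform = character(0),
               start = integer(0), end = integer(0), clip = integer(0),
               n_mm = integer(0), mm_pos = character(0),
               mm_ref = character(0), mm_read = character(0),
               weight = numeric(0), stringsAsFactors = FALSE)
  structure(hits,
            summary = list(n_input = sum(reads$count) + n_lenfilt,
                           n_length_filtered = n_lenfilt,
                           n_mapped = sum(reads$count) - n_unmapped,
                           n_unmapped = n_unmapped),
            class = c("aligned_reads", class(hits)))
}

#' Classify a tRNA-space hit into tRF taxonomy
#'
#' tRF-3 requires the alignment to end exactly at the mature 3' terminus
#' (full CCA; reads stopping at CC are classified `other`); tRF-5 starts at
#' mature position 1; tRF-1 starts at position 1 of a trailer reference.
#' Fragments of >= 30 nt anchored at the 5'/3' end are `5'half`/`3'half`
#' instead of tRF-5/tRF-3. tRF-3s of exactly 22 nt are isoform `3b`,
#' exactly 18 nt `3a`. Internal fragments are `other`. Hits on miRNA or
#' spike-in references pass through with class `miR`/`spikeIn`.
#'
#' @param parent reference name of the hit.
#' @param start,end 1-based alignment coordinates on the parent.
#' @param ref the [reference_set()].
#' @param half_cutoff length (nt) at which an end-anchored fragment becomes
#'   a half.
#' @return list with `class` and `isoform`.
#' @export
classify_trf <- function(parent, start, end, ref, half_cutoff = 30L) {
  cat <- ref$category[parent]
  if (is.na(cat)) stop("unknown reference: ", parent)
  if (cat == "miR") return(list(class = "miR", isoform = "none"))
  if (cat == "spikeIn") return(list(class = "spikeIn", isoform = "none"))
  len <- end - start + 1L
  if (cat == "trailer")
    return(list(class = if (start == 1L) "tRF-1" else "other",
                isoform = "none"))
  L <- nchar(ref$seqs[[parent]])
  if (end == L) {
    if (len >= half_cutoff) return(list(class = "3'half", isoform = "none"))
    iso <- if (len == 22L) "3b" else if (len == 18L) "3a" else "none"
    return(list(class = "tRF-3", isoform = iso))
  }
  if (start == 1L) {
    if (len >= half_cutoff) return(list(class = "5'half", isoform = "none"))
    return(list(class = "tRF-5", isoform = "none"))
  }
  list(class = "other", isoform = "none")
}

#' Group fractional counts into a count table
#'
#' tRF reads are grouped by parental tRNA, tRF class and size isoform;
#' miRNA and spike-in reads by reference name. Counts are fractional,
#' collapsed-count-weighted sums, so the grand total equals the number of
#' mapped reads. Groups below `min_count` are flagged excluded from
#' differential testing.
#'
#' @param hits an [align_reads()] result.
#' @param min_count minimum fractional count to enter testing (default 10).
#' @return data.frame with `group`, `category`, `parent`, `class`,
#'   `isoform`, `count`, `rpm`, `excluded`.
#' @export
make_count_table <- function(hits, min_count = 10) {
  if (!nrow(hits))
    return(data.frame(group = character(0), category = character(0),
                      parent = character(0), class = character(0),
                      isoform = character(0), count = numeric(0),
                      rpm = numeric(0), excluded = logical(0)))
  key <- ifelse(hits$category %in% c("miR", "spikeIn"), hits$parent,
                sprintf("%s/%s%s", hits$parent, hits$class,
                        ifelse(hits$isoform == "none", "",
                               paste0("-", hits$isoform))))
  frac <- hits$count * hits$weight
  agg <- stats::aggregate(
    frac,
    by = list(group = key, category = hits$category, parent = hits$parent,
              class = hits$class, isoform = hits$isoform),
    FUN = sum)
  names(agg)[ncol(agg)] <- "count"
  total <- sum(agg$count)
  agg$rpm <- 1e6 * agg$count / total
  agg$excluded <- agg$count < min_count
  agg <- agg[order(-agg$count), ]
  rownames(agg) <- NULL
  attr(agg, "total_mapped") <- total
  agg
}
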