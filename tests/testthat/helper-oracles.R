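# Independent oracles used across the suite. Each reimplements the checked
# operation by direct enumeration, without touching the package internals.

# exhaustive aligner: every reference, every offset, every allowed clip,
# substitutions counted by per-character comparison
brute_force_align <- function(seq, ref, policy = mapping_policy()) {
  L <- nchar(seq)
  for (cat in policy$order) {
    cats <- if (cat == "tRNA") c("tRNA", "trailer") else cat
    clips <- if (cat == "miR") 0:policy$mir_max_tail else 0L
    maxmm <- if (cat == "miR") policy$mir_max_mismatch else
      policy$trf_max_mismatch
    found <- list()
    for (clip in clips) {
      core <- substr(seq, 1L, L - clip)
      cl <- nchar(core)
      cv <- strsplit(core, "")[[1]]
      for (rn in names(ref$seqs)[ref$category %in% cats]) {
        rs <- ref$seqs[[rn]]
        if (nchar(rs) < cl) next
        for (st in 1:(nchar(rs) - cl + 1L)) {
          key <- paste0(rn, ":", st)
          if (!is.null(found[[key]])) next
          nmm <- sum(cv != strsplit(substr(rs, st, st + cl - 1L), "")[[1]])
          if (nmm <= maxmm)
            found[[key]] <- data.frame(ref = rn, start = st,
                                       end = st + cl - 1L, clip = clip,
                                       n_mm = nmm,
                                       stringsAsFactors = FALSE)
        }
      }
    }
    if (length(found)) {
      h <- do.call(rbind, found)
      h <- h[order(h$ref, h$start), , drop = FALSE]
      rownames(h) <- NULL
      return(list(category = cat, hits = h))
    }
  }
  NULL
}

# site scanner oracle working in guide/target base-pairing space
oracle_sites <- function(seed, utr) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  g <- strsplit(seed, "")[[1]]   # g[k-1] is guide position k (k = 2..8)
  u <- strsplit(utr, "")[[1]]
  L <- length(u)
  out <- NULL
  if (L >= 6) for (i in 1:(L - 5L)) {
    ok6 <- TRUE
    for (k in 2:7)                     # u[i + 7 - k] pairs guide position k
      if (u[i + 7L - k] != comp[[g[k - 1L]]] ||
          is.null(comp[[g[k - 1L]]])) { ok6 <- FALSE; break }
    if (!ok6) next
    ok8 <- i >= 2L && u[i - 1L] == comp[[g[7L]]]
    hasA <- (i + 6L) <= L && u[i + 6L] == "A"
    type <- if (ok8) (if (hasA) "8mer-A1" else "7mer-m8")
    else (if (hasA) "7mer-A1" else "6mer")
    out <- rbind(out, data.frame(position = if (ok8) i - 1L else i,
                                 site_type = type,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out))
    data.frame(position = integer(0), site_type = character(0),
               stringsAsFactors = FALSE)
  else out
}

# step-up Benjamini-Hochberg, written out longhand
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(ranked))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# two-sided exact binomial p by summing all outcomes at most as probable
binom_two_sided_oracle <- function(x, n, p0) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[x + 1L] * (1 + 1e-7)])
}

# naive per-read mismatch recount at one profile position
naive_mismatch_index <- function(hits, frame, position, min_reads = 50,
                                 ...) {
  filt <- list(...)
  keep <- rep(TRUE, nrow(hits))
  if (!is.null(filt$trf_class)) keep <- keep & hits$class %in% filt$trf_class
  if (!is.null(filt$isoform)) keep <- keep & hits$isoform %in% filt$isoform
  if (!is.null(filt$parent)) keep <- keep & hits$parent %in% filt$parent
  h <- hits[keep, , drop = FALSE]
  cov <- 0
  mis <- 0
  for (i in seq_len(nrow(h))) {
    w <- h$count[i] * h$weight[i]
    span <- if (frame == "fragment") seq_len(h$end[i] - h$start[i] + 1L)
    else h$start[i]:h$end[i]
    if (!position %in% span) next
    cov <- cov + w
    if (h$n_mm[i] > 0) {
      mp <- as.integer(strsplit(h$mm_pos[i], ",")[[1]])
      at <- if (frame == "fragment") mp else h$start[i] + mp - 1L
      if (position %in% at) mis <- mis + w
    }
  }
  if (cov > min_reads) 100 * mis / cov else NA_real_
}

# small fixed reference used by several alignment tests
tiny_reference <- function(seed = 42L) build_reference(seed, n_trna = 5,
                                                       n_mir = 6,
                                                       n_spike = 3,
                                                       n_mito = 1)
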