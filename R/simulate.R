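# Synthetic-data module: references, molecule pools, RT-processed reads,
# RIP fractions and planted-effect expression tables with known ground truth.

#' Generate a synthetic reference set
#'
#' Builds a randomized but structurally faithful reference space: mature
#' tRNAs of 72-90 nt ending in CCA, each nuclear tRNA carrying an annotated
#' m1A site at position `L - 18` (the A58 equivalent: position 4 of the
#' 22-nt 3' fragment), mitochondrial tRNAs carrying m1A at position 9,
#' a poly-U-ending 3' trailer per nuclear tRNA, mature miRNAs, and spike-in
#' controls guaranteed not to map anywhere else (a dedicated `ctrl-m1A`
#' calibration oligo with a central m1A site, plus QC spike-ins used as the
#' normalization denominator). Deterministic under a fixed seed.
#'
#' @param seed RNG seed (required: reference generation is always seeded).
#' @param n_trna number of mature tRNAs (including `n_mito`).
#' @param n_mir number of miRNAs.
#' @param n_spike number of spike-ins (>= 2: one calibration oligo plus QC
#'   spike-ins).
#' @param n_mito how many of the tRNAs are mitochondrial.
#' @param trna_len length range for nuclear tRNAs.
#' @return a [reference_set()].
#' @export
build_reference <- function(seed, n_trna = 10, n_mir = 20, n_spike = 4,
                            n_mito = max(0L, round(n_trna / 5)),
                            trna_len = c(72L, 90L)) {
  stopifnot(n_trna >= 1, n_mir >= 1, n_spike >= 2, n_mito <= n_trna)
  set_seed_if(seed)
  aa <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
          "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
          "Tyr", "Val")
  n_nuc <- n_trna - n_mito

  make_trna <- function(i, mito) {
    L <- if (mito) sample(66:75, 1L) else sample(trna_len[1]:trna_len[2], 1L)
    s <- strsplit(random_dna(L), "")[[1]]
    s[(L - 2L):L] <- c("C", "C", "A")
    if (mito) s[9L] <- "A" else s[L - 18L] <- "A"
    prefix <- if (mito) "mt-tRNA" else "tRNA"
    list(name = sprintf("%s-%s-%s-%d", prefix, aa[(i - 1L) %% 20L + 1L],
                        random_dna(3L), i),
         compartment = if (mito) "mitochondrial" else "nuclear",
         sequence = paste(s, collapse = ""), length = L)
  }
  tr <- lapply(seq_len(n_trna), function(i) make_trna(i, mito = i > n_nuc))
  trnas <- data.frame(name = vapply(tr, `[[`, "", "name"),
                      anticodon = vapply(tr, function(x)
                        substr(x$sequence, 34, 36), ""),
                      compartment = vapply(tr, `[[`, "", "compartment"),
                      sequence = vapply(tr, `[[`, "", "sequence"),
                      stringsAsFactors = FALSE)
  trnas$length <- nchar(trnas$sequence)

  nuc <- trnas[trnas$compartment == "nuclear", ]
  trailers <- data.frame(
    name = paste0(nuc$name, "-trailer"),
    parent = nuc$name,
    sequence = vapply(seq_len(nrow(nuc)), function(i)
      paste0(random_dna(sample(12:24, 1L)), "TTTT"), ""),
    stringsAsFactors = FALSE)

  mirnas <- data.frame(
    name = sprintf("miR-sim-%d", seq_len(n_mir)),
    sequence = vapply(seq_len(n_mir), function(i)
      random_dna(sample(20:23, 1L)), ""),
    stringsAsFactors = FALSE)

  # spike-ins must not share even a 15-mer with the biological references
  bio <- c(trnas$sequence, trailers$sequence, mirnas$sequence)
  shares_kmer <- function(s, k = 15L) {
    n <- nchar(s)
    if (n < k) return(FALSE)
    kmers <- substring(s, 1:(n - k + 1L), k:n)
    any(vapply(bio, function(b)
      any(vapply(kmers, function(km) grepl(km, b, fixed = TRUE), TRUE)),
      TRUE))
  }
  draw_spike <- function(len) {
    for (i in 1:100) {
      s <- random_dna(len)
      if (!shares_kmer(s)) return(s)
      message("regenerating spike-in that mapped to the reference space")
    }
    stop("could not generate a non-mapping spike-in")
  }
  ctrl <- strsplit(draw_spike(24L), "")[[1]]
  ctrl[12L] <- "A"
  spikeins <- data.frame(
    name = c("ctrl-m1A", sprintf("qc-spike-%d", seq_len(n_spike - 1L))),
    sequence = c(paste(ctrl, collapse = ""),
                 vapply(seq_len(n_spike - 1L), function(i)
                   draw_spike(sample(22:28, 1L)), "")),
    is_qc = c(FALSE, rep(TRUE, n_spike - 1L)),
    stringsAsFactors = FALSE)

  mod_sites <- rbind(
    data.frame(reference = nuc$name, position = nuc$length - 18L,
               modification = "m1A", writer = "TRMT6/61A",
               stringsAsFactors = FALSE),
    if (n_mito > 0)
      data.frame(reference = trnas$name[trnas$compartment == "mitochondrial"],
                 position = 9L, modification = "m1A", writer = "TRMT10C",
                 stringsAsFactors = FALSE),
    data.frame(reference = "ctrl-m1A", position = 12L, modification = "m1A",
               writer = NA_character_, stringsAsFactors = FALSE))

  reference_set(trnas, trailers, mirnas, spikeins, mod_sites)
}

# default per-class abundance mix: tRF-3b-heavy tRF pool alongside miRNAs,
# matching the composition the analysis is designed to resolve
DEFAULT_CLASS_PROFILE <- c("tRF-3b" = 0.30, "tRF-3a" = 0.12, "tRF-5" = 0.15,
                           "tRF-1" = 0.08, "5'half" = 0.05, "miR" = 0.25,
                           "spikeIn" = 0.05)

#' Simulate a fragment molecule pool with per-molecule m1A status
#'
#' Enumerates the fragment species implied by the reference set (exact 22-nt
#' and 18-nt tRF-3 suffixes, tRF-5 prefixes, 5' halves, trailer-derived
#' tRF-1s, full-length miRNAs and spike-ins), draws copy numbers from a
#' multinomial over the class abundance profile, and assigns each molecule's
#' modification status Bernoulli(p) at every annotated site it covers.
#'
#' @param ref a [reference_set()].
#' @param profile named per-class abundance weights over `tRF-3b`, `tRF-3a`,
#'   `tRF-5`, `tRF-1`, `5'half`, `miR`, `spikeIn`. Classes absent from the
#'   profile get weight 0.
#' @param stoich modification stoichiometry: a single probability applied to
#'   every annotated site, or a named vector keyed `"<reference>:<position>"`
#'   (unnamed sites default to 0).
#' @param n_molecules total molecules in the pool.
#' @param seed RNG seed.
#' @param trf5_length length of tRF-5 species (< 30 nt).
#' @param half_length length of 5'-half species (>= 30 nt).
#' @return list with `pool` (a `MoleculePool` data.frame: one row per
#'   species x modification pattern, with fragment coordinates, covered site
#'   positions in fragment coordinates, 0/1 modification pattern, and copy
#'   number) and `truth` (per-species true stoichiometry, class and input
#'   abundance).
#' @export
simulate_fragment_pool <- function(ref, profile = DEFAULT_CLASS_PROFILE,
                                   stoich = 0.8, n_molecules = 50000,
                                   seed = NULL, trf5_length = 18L,
                                   half_length = 34L) {
  if (length(profile) == 0 || all(profile <= 0))
    stop("empty class abundance profile")
  if (any(profile < 0)) stop("profile weights must be nonnegative")
  p_ok <- if (is.null(names(stoich))) length(stoich) == 1L else TRUE
  if (!p_ok || any(stoich < 0 | stoich > 1))
    stop("stoich must be a probability or a named vector of probabilities")
  set_seed_if(seed)

  species <- list()
  add <- function(parent, class, isoform, start, end, sequence) {
    species[[length(species) + 1L]] <<- data.frame(
      parent = parent, class = class, isoform = isoform,
      start = start, end = end, sequence = sequence,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(ref$trnas))) {
    t <- ref$trnas[i, ]
    L <- t$length
    if (t$compartment == "nuclear") {
      add(t$name, "tRF-3", "3b", L - 21L, L, substr(t$sequence, L - 21L, L))
      add(t$name, "tRF-3", "3a", L - 17L, L, substr(t$sequence, L - 17L, L))
    }
    add(t$name, "tRF-5", "none", 1L, trf5_length,
        substr(t$sequence, 1L, trf5_length))
    add(t$name, "5'half", "none", 1L, half_length,
        substr(t$sequence, 1L, half_length))
  }
  for (i in seq_len(nrow(ref$trailers))) {
    tl <- ref$trailers[i, ]
    add(tl$name, "tRF-1", "none", 1L, nchar(tl$sequence), tl$sequence)
  }
  for (i in seq_len(nrow(ref$mirnas)))
    add(ref$mirnas$name[i], "miR", "none", 1L,
        nchar(ref$mirnas$sequence[i]), ref$mirnas$sequence[i])
  for (i in seq_len(nrow(ref$spikeins)))
    add(ref$spikeins$name[i], "spikeIn", "none", 1L,
        nchar(ref$spikeins$sequence[i]), ref$spikeins$sequence[i])
  sp <- do.call(rbind, species)
  sp$species <- sprintf("%s/%s%s", sp$parent, sp$class,
                        ifelse(sp$isoform == "none", "",
                               paste0("-", sp$isoform)))

  class_key <- ifelse(sp$class == "tRF-3", paste0("tRF-", sp$isoform),
                      sp$class)
  w <- unname(profile[class_key])
  w[is.na(w)] <- 0
  tab <- table(class_key)
  w <- w / as.numeric(tab[class_key])
  if (all(w == 0)) stop("profile assigns zero weight to every species")
  counts <- drop(stats::rmultinom(1L, n_molecules, w))

  resolve_p <- function(key) {
    if (is.null(names(stoich))) return(unname(stoich))
    if (key %in% names(stoich)) unname(stoich[key]) else 0
  }

  ms <- ref$mod_sites
  rows <- vector("list", nrow(sp))
  truth <- vector("list", nrow(sp))
  for (i in seq_len(nrow(sp))) {
    r <- sp[i, ]
    sites <- ms[ms$reference == r$parent &
                ms$position >= r$start & ms$position <= r$end, , drop = FALSE]
    fpos <- sites$position - r$start + 1L
    pvec <- vapply(sprintf("%s:%d", sites$reference, sites$position),
                   resolve_p, 0)
    k <- length(fpos)
    base <- data.frame(species = r$species, parent = r$parent,
                       class = r$class, isoform = r$isoform,
                       start = r$start, end = r$end, sequence = r$sequence,
                       stringsAsFactors = FALSE)
    if (k == 0L) {
      out <- cbind(base, site_pos = "", site_mod = "", count = counts[i])
    } else {
      patterns <- as.matrix(expand.grid(rep(list(0:1), k)))
      pr <- apply(patterns, 1L, function(b)
        prod(ifelse(b == 1, pvec, 1 - pvec)))
      n_pat <- drop(stats::rmultinom(1L, counts[i], pr))
      out <- do.call(rbind, lapply(seq_len(nrow(patterns)), function(j)
        cbind(base, site_pos = paste(fpos, collapse = ","),
              site_mod = paste(patterns[j, ], collapse = ","),
              count = n_pat[j])))
    }
    rows[[i]] <- out
    truth[[i]] <- cbind(base,
                        p = if (k) pvec[1L] else NA_real_,
                        input_count = counts[i])
  }
  pool <- do.call(rbind, rows)
  pool <- pool[pool$count > 0, , drop = FALSE]
  rownames(pool) <- NULL
  class(pool) <- c("MoleculePool", class(pool))
  list(pool = pool, truth = do.call(rbind, truth))
}

#' @noRd
pool_modified <- function(pool) {
  vapply(strsplit(pool$site_mod, ","), function(m) any(m == "1"), TRUE)
}

# per-base background substitution over a read multiset (exact Bernoulli
# model: event total ~ Binom(reads x positions, eps), uniform placement)
#' @noRd
apply_background_errors <- function(reads, eps) {
  if (eps > 0 && nrow(reads)) {
    extra <- list()
    for (i in seq_len(nrow(reads))) {
      s <- reads$sequence[i]
      n <- reads$count[i]
      L <- nchar(s)
      nerr <- stats::rbinom(1L, n * L, eps)
      if (nerr == 0L) next
      cells <- sample.int(n * L, nerr)
      by_read <- split((cells - 1L) %% L + 1L, (cells - 1L) %/% L)
      reads$count[i] <- n - length(by_read)
      chars <- strsplit(s, "")[[1]]
      mut <- vapply(by_read, function(pp) {
        v <- chars
        for (p in pp) v[p] <- sample(setdiff(DNA_BASES, v[p]), 1L)
        paste(v, collapse = "")
      }, "")
      extra[[length(extra) + 1L]] <-
        data.frame(species = reads$species[i], sequence = mut, count = 1L,
                   stringsAsFactors = FALSE)
    }
    if (length(extra)) reads <- rbind(reads, do.call(rbind, extra))
  }
  reads <- reads[reads$count > 0, , drop = FALSE]
  if (!nrow(reads)) {
    rownames(reads) <- NULL
    return(reads)
  }
  agg <- stats::aggregate(count ~ species + sequence, data = reads, FUN = sum)
  agg <- agg[order(agg$species, agg$sequence),
             c("species", "sequence", "count")]
  rownames(agg) <- NULL
  agg
}

#' Pass a molecule pool through a reverse-transcriptase error model
#'
#' Per molecule: at each modified site the RT stalls with `p_stall` (the
#' molecule is discarded entirely -- in a ligation-first protocol truncated
#' cDNAs lack the 5' priming site and are never amplified), misincorporates
#' with `p_mis` (substituted base from the model's spectrum), or reads
#' through faithfully. Every position of every emitted read is then
#' substituted independently with `eps_bg`. Reads carry no indels.
#'
#' @param pool a `MoleculePool` from [simulate_fragment_pool()].
#' @param rt an [rt_model()].
#' @param seed RNG seed.
#' @return a read multiset: data.frame with columns `species` (provenance,
#'   for truth-aware tests only), `sequence`, `count`; attributes
#'   `n_molecules`, `n_stalled`, `n_emitted`.
#' @export
apply_rt_model <- function(pool, rt, seed = NULL) {
  stopifnot(inherits(rt, "RTModel"))
  set_seed_if(seed)
  spec_names <- names(rt$mis_spectrum)

  out <- list()
  n_stalled <- 0L
  for (i in seq_len(nrow(pool))) {
    row <- pool[i, ]
    n <- row$count
    if (n == 0L) next
    fpos <- as.integer(strsplit(row$site_pos, ",")[[1]])
    mod <- as.integer(strsplit(row$site_mod, ",")[[1]])
    msites <- fpos[mod == 1L]
    emit <- function(sequence, count)
      data.frame(species = row$species, sequence = sequence, count = count,
                 stringsAsFactors = FALSE)
    if (length(msites) == 0L) {
      out[[length(out) + 1L]] <- emit(row$sequence, n)
    } else if (length(msites) == 1L) {
      d <- drop(stats::rmultinom(1L, n, c(rt$p_stall, rt$p_mis,
                                          1 - rt$p_stall - rt$p_mis)))
      n_stalled <- n_stalled + d[1L]
      if (d[3L] > 0L) out[[length(out) + 1L]] <- emit(row$sequence, d[3L])
      if (d[2L] > 0L) {
        bases <- drop(stats::rmultinom(1L, d[2L], rt$mis_spectrum))
        for (b in which(bases > 0L)) {
          v <- strsplit(row$sequence, "")[[1]]
          v[msites] <- spec_names[b]
          out[[length(out) + 1L]] <- emit(paste(v, collapse = ""), bases[b])
        }
      }
    } else {
      # rare multi-site fragments: per-molecule, per-site outcomes
      for (m in seq_len(n)) {
        oc <- sample(c("stall", "mis", "clean"), length(msites),
                     replace = TRUE,
                     prob = c(rt$p_stall, rt$p_mis,
                              1 - rt$p_stall - rt$p_mis))
        if (any(oc == "stall")) { n_stalled <- n_stalled + 1L; next }
        v <- strsplit(row$sequence, "")[[1]]
        hit <- msites[oc == "mis"]
        for (p in hit)
          v[p] <- sample(spec_names, 1L, prob = rt$mis_spectrum)
        out[[length(out) + 1L]] <- emit(paste(v, collapse = ""), 1L)
      }
    }
  }
  reads <- if (length(out)) do.call(rbind, out) else
    data.frame(species = character(0), sequence = character(0),
               count = integer(0), stringsAsFactors = FALSE)
  reads <- apply_background_errors(reads, rt$eps_bg)
  structure(reads,
            n_molecules = sum(pool$count),
            n_stalled = n_stalled,
            n_emitted = sum(reads$count),
            class = c("read_set", class(reads)))
}

#' RIP configuration
#'
#' @param enrichment_factor fold sampling preference, in the antibody
#'   fraction, for molecules carrying at least one modified site (>= 1).
#' @param igg_capture nonspecific capture fraction of the IgG control arm
#'   (scales its library depth).
#' @param lib_depth molecules sampled per library.
#' @return a list of class `RIPConfig`.
#' @export
rip_config <- function(enrichment_factor = 8, igg_capture = 0.25,
                       lib_depth = 50000) {
  stopifnot(enrichment_factor >= 1, igg_capture >= 0, igg_capture <= 1,
            lib_depth >= 1)
  structure(list(enrichment_factor = enrichment_factor,
                 igg_capture = igg_capture, lib_depth = lib_depth),
            class = "RIPConfig")
}

#' Simulate input / m1A-RIP / IgG-RIP libraries from one molecule pool
#'
#' The antibody fraction samples molecules with their pool abundance times
#' `enrichment_factor` when they carry at least one modified site; the input
#' and IgG fractions sample by abundance alone, the IgG arm at
#' `igg_capture`-scaled depth. Each sampled fraction is then reverse
#' transcribed with [apply_rt_model()].
#'
#' @param pool a `MoleculePool`.
#' @param rip a [rip_config()].
#' @param rt an [rt_model()].
#' @param seed RNG seed (sub-seeds for the three arms are derived from it).
#' @return list of read multisets `input`, `rip`, `igg`.
#' @export
simulate_rip <- function(pool, rip, rt, seed = NULL) {
  stopifnot(inherits(rip, "RIPConfig"))
  set_seed_if(seed)
  w_base <- pool$count
  w_rip <- w_base * ifelse(pool_modified(pool), rip$enrichment_factor, 1)
  resample <- function(w, depth) {
    p2 <- pool
    p2$count <- drop(stats::rmultinom(1L, depth, w))
    p2
  }
  arms <- list(input = resample(w_base, rip$lib_depth),
               rip = resample(w_rip, rip$lib_depth),
               igg = resample(w_base, round(rip$lib_depth * rip$igg_capture)))
  lapply(arms, apply_rt_model, rt = rt)
}

SITE_TYPES <- c("8mer-A1", "7mer-m8", "7mer-A1", "6mer")

#' Simulate a gene-level expression table with planted seed-target effects
#'
#' Non-targets draw log2 fold changes from Normal(0, sigma); targets of site
#' type `t` from Normal(shift_t, sigma). Genes belonging to several target
#' sets are resolved to the strongest site type (8mer-A1 > 7mer-m8 >
#' 7mer-A1 > 6mer). Normalized mean counts (`baseMean`) are drawn
#' log-uniform, with a configurable fraction below the 100-count expression
#' filter used downstream.
#'
#' @param genes gene identifiers (character), or an integer count.
#' @param target_sets named list mapping site type to a character vector of
#'   target genes.
#' @param shifts named numeric of planted log2FC shifts per site type.
#' @param sigma log2FC standard deviation (> 0).
#' @param frac_low_expr fraction of genes drawn below 100 normalized counts.
#' @param seed RNG seed.
#' @return data.frame with `gene`, `log2FC`, `baseMean`, `true_type`.
#' @export
simulate_expression_table <- function(genes, target_sets = list(),
                                      shifts = c("8mer-A1" = -0.5,
                                                 "7mer-m8" = -0.3,
                                                 "7mer-A1" = -0.2,
                                                 "6mer" = -0.1),
                                      sigma = 0.4, frac_low_expr = 0.2,
                                      seed = NULL) {
  stopifnot(sigma > 0, all(is.finite(shifts)))
  if (is.numeric(genes) && length(genes) == 1L)
    genes <- sprintf("gene%05d", seq_len(genes))
  set_seed_if(seed)
  type <- rep("non-target", length(genes))
  names(type) <- genes
  for (t in rev(SITE_TYPES))            # weakest first; strongest overwrites
    if (!is.null(target_sets[[t]]))
      type[intersect(target_sets[[t]], genes)] <- t
  mu <- ifelse(type == "non-target", 0, shifts[type])
  low <- stats::rbinom(length(genes), 1L, frac_low_expr) == 1L
  base_mean <- ifelse(low, 10^stats::runif(length(genes), 0, 2),
                      10^stats::runif(length(genes), 2, 5))
  data.frame(gene = genes, log2FC = stats::rnorm(length(genes), mu, sigma),
             baseMean = base_mean, true_type = unname(type),
             stringsAsFactors = FALSE)
}

#' Simulate 3' UTR sequences with planted seed-match sites
#'
#' Random-background UTRs into which exact target sites of the four types
#' are written at well-separated positions. The background of every UTR is
#' scrubbed so that, for the supplied seeds, the realized site list equals
#' exactly what was planted (chance seed matches are regenerated away),
#' making the planted truth usable for exact recovery tests.
#'
#' @param genes character vector of gene ids.
#' @param planted data.frame with columns `gene`, `seed` (7-nt), `site_type`,
#'   `n_sites`; genes absent from it get site-free UTRs.
#' @param seeds all seeds that must not occur by chance (defaults to those
#'   in `planted`).
#' @param utr_length UTR length in nt.
#' @param seed RNG seed.
#' @param max_tries redraw budget per UTR.
#' @return named character vector of UTR sequences.
#' @export
simulate_utrs <- function(genes, planted = NULL, seeds = NULL,
                          utr_length = 600L, seed = NULL, max_tries = 200L) {
  planted <- planted %||% data.frame(gene = character(0), seed = character(0),
                                     site_type = character(0),
                                     n_sites = integer(0),
                                     stringsAsFactors = FALSE)
  seeds <- unique(c(seeds, planted$seed))
  set_seed_if(seed)

  motif <- function(sd, type) {
    core7 <- revcomp(sd)
    core6 <- substr(core7, 2L, 7L)
    not <- function(b) sample(setdiff(DNA_BASES, b), 1L)
    switch(type,
           "8mer-A1" = paste0(core7, "A"),
           "7mer-m8" = paste0(core7, not("A")),
           "7mer-A1" = paste0(not(substr(core7, 1L, 1L)), core6, "A"),
           "6mer"    = paste0(not(substr(core7, 1L, 1L)), core6, not("A")),
           stop("unknown site type: ", type))
  }

  build_one <- function(g) {
    pl <- planted[planted$gene == g, , drop = FALSE]
    want <- if (nrow(pl))
      stats::setNames(pl$n_sites, paste(pl$seed, pl$site_type)) else integer(0)
    for (try in seq_len(max_tries)) {
      s <- random_dna(utr_length)
      if (nrow(pl)) {
        n_tot <- sum(pl$n_sites)
        slots <- 2L + (seq_len(n_tot) - 1L) * floor((utr_length - 12L) /
                                                      max(n_tot, 1L))
        k <- 0L
        for (j in seq_len(nrow(pl))) {
          for (r in seq_len(pl$n_sites[j])) {
            k <- k + 1L
            m <- motif(pl$seed[j], pl$site_type[j])
            substr(s, slots[k], slots[k] + nchar(m) - 1L) <- m
          }
        }
      }
      got <- do.call(rbind, lapply(seeds, function(sd) {
        hits <- scan_utr(sd, s)
        if (nrow(hits)) cbind(seed = sd, hits) else NULL
      }))
      realized <- if (is.null(got)) integer(0) else
        table(paste(got$seed, got$site_type))
      ok <- length(realized) == length(want) &&
        setequal(names(realized), names(want)) &&
        all(realized[names(want)] == want)
      if (ok) return(s)
    }
    stop("could not build a clean UTR for gene ", g,
         " within ", max_tries, " tries")
  }
  stats::setNames(vapply(genes, build_one, ""), genes)
}

#' Write / read a read multiset as FASTQ
#'
#' Reads are expanded to one record per molecule with constant quality "I"
#' (qualities are not used downstream).
#'
#' @param reads a read multiset (`sequence`, `count`).
#' @param path FASTQ file path.
#' @export
write_read_fastq <- function(reads, path) {
  seqs <- rep(reads$sequence, reads$count)
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sprintf("read%07d", seq_along(x))
  q <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname write_read_fastq
#' @export
read_read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tab <- table(as.character(x))
  data.frame(species = NA_character_, sequence = names(tab),
             count = as.integer(tab), stringsAsFactors = FALSE)
}
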