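# Orchestration: configuration, reproducible end-to-end simulate/analyze
# runs with stage-level logging and conservation checkpoints.

#' Default run configuration
#'
#' Nested list of every tunable the pipeline exposes, with the thresholds
#' the analysis is built around: mismatch-index coverage > 50 reads,
#' differential-testing minimum of 10 counts, RIP candidate padj < 0.1
#' (and a stricter 1e-5 for volcano-style coloring), expression filter >
#' 100 normalized counts, halves cutoff 30 nt, size isoforms 18/22 nt,
#' seed-family coverage threshold 0.90. Every stochastic stage must carry
#' an explicit seed; [run_simulate()] refuses configs with missing seeds.
#'
#' @param ... named overrides merged over the defaults (nested lists are
#'   merged recursively).
#' @return configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seeds = list(reference = 101L, pool = 102L, rt = 103L, rip = 104L,
                 calibration = 105L, expression = 106L, utr = 107L),
    reference = list(n_trna = 8L, n_mir = 12L, n_spike = 4L, n_mito = 2L),
    pool = list(n_molecules = 30000L, stoich = 0.8,
                profile = as.list(DEFAULT_CLASS_PROFILE)),
    rt = list(name = "TGIRT"),
    rip = list(enabled = TRUE, enrichment_factor = 8, igg_capture = 0.25,
               lib_depth = 30000L, n_antibodies = 2L),
    calibration = list(enabled = TRUE,
                       levels = c(0, 20, 40, 60, 80, 100),
                       reads_per_level = 10000L),
    expression = list(enabled = TRUE, n_genes = 400L,
                      n_targets_per_type = 40L,
                      shifts = list("8mer-A1" = -0.5, "7mer-m8" = -0.3,
                                    "7mer-A1" = -0.2, "6mer" = -0.1),
                      sigma = 0.4, utr_length = 400L,
                      direction = "repressed"),
    thresholds = list(min_reads = 50, min_count = 10, padj_rip = 0.1,
                      padj_volcano = 1e-5, min_expr = 100,
                      halves_cutoff = 30L, iso_3a = 18L, iso_3b = 22L,
                      seed_coverage = 0.90, mismatch_evidence = 10))
  ov <- list(...)
  if (length(ov)) cfg <- utils::modifyList(cfg, ov)
  cfg
}

#' @rdname default_config
#' @param path YAML file with (a subset of) the configuration keys.
#' @export
load_run_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' @noRd
check_seeds <- function(cfg) {
  need <- c("reference", "pool", "rt",
            if (isTRUE(cfg$rip$enabled)) "rip",
            if (isTRUE(cfg$calibration$enabled)) "calibration",
            if (isTRUE(cfg$expression$enabled)) c("expression", "utr"))
  miss <- setdiff(need, names(Filter(Negate(is.null), cfg$seeds)))
  if (length(miss))
    stop("configuration error: missing seed(s) for stage(s): ",
         paste(miss, collapse = ", "))
  invisible(cfg)
}

#' @noRd
rt_from_config <- function(cfg) {
  do.call(rt_model, cfg$rt)
}

#' Simulate a complete synthetic dataset
#'
#' Runs the generators in order (reference, fragment pool, RT reads, RIP
#' arms, calibration mixes, expression table + UTRs) and writes a dataset
#' directory of FASTA/FASTQ/TSV files plus truth tables and a manifest
#' recording seeds, thresholds and the configuration hash. Deterministic:
#' the same configuration produces identical files.
#'
#' @param config a [default_config()]-style list (or path via
#'   [load_run_config()]).
#' @param out_dir dataset directory to create.
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- load_run_config(config)
  check_seeds(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[simulate] ", ...)

  log_stage("reference")
  ref <- build_reference(config$seeds$reference,
                         n_trna = config$reference$n_trna,
                         n_mir = config$reference$n_mir,
                         n_spike = config$reference$n_spike,
                         n_mito = config$reference$n_mito)
  write_reference_set(ref, file.path(out_dir, "reference"))

  log_stage("fragment pool (", config$pool$n_molecules, " molecules)")
  sim <- simulate_fragment_pool(
    ref, profile = unlist(config$pool$profile),
    stoich = config$pool$stoich,
    n_molecules = config$pool$n_molecules, seed = config$seeds$pool)
  utils::write.table(sim$truth, file.path(out_dir, "truth_pool.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rt <- rt_from_config(config)

  if (isTRUE(config$rip$enabled)) {
    rip <- rip_config(config$rip$enrichment_factor, config$rip$igg_capture,
                      config$rip$lib_depth)
    for (a in seq_len(config$rip$n_antibodies)) {
      log_stage("RIP arm antibody ", a)
      arms <- simulate_rip(sim$pool, rip, rt,
                           seed = config$seeds$rip + 10L * a)
      if (a == 1L) {
        write_read_fastq(arms$input, file.path(out_dir, "input.fastq"))
        write_read_fastq(arms$igg, file.path(out_dir, "igg.fastq"))
      }
      write_read_fastq(arms$rip,
                       file.path(out_dir, sprintf("rip_ab%d.fastq", a)))
    }
  } else {
    log_stage("input reads (no RIP)")
    reads <- apply_rt_model(sim$pool, rt, seed = config$seeds$rt)
    write_read_fastq(reads, file.path(out_dir, "input.fastq"))
  }

  if (isTRUE(config$calibration$enabled)) {
    log_stage("calibration mixes")
    dir.create(file.path(out_dir, "calibration"), showWarnings = FALSE)
    ctrl <- ref$spikeins[!ref$spikeins$is_qc, ][1L, ]
    site <- ref$mod_sites[ref$mod_sites$reference == ctrl$name, ]
    set_seed_if(config$seeds$calibration)
    for (lv in config$calibration$levels) {
      n <- config$calibration$reads_per_level
      n_mod <- stats::rbinom(1L, n, lv / 100)
      pool_lv <- data.frame(
        species = paste0(ctrl$name, "/spikeIn"), parent = ctrl$name,
        class = "spikeIn", isoform = "none", start = 1L,
        end = nchar(ctrl$sequence), sequence = ctrl$sequence,
        site_pos = as.character(site$position), site_mod = c("1", "0"),
        count = c(n_mod, n - n_mod), stringsAsFactors = FALSE)
      reads <- apply_rt_model(pool_lv, rt,
                              seed = config$seeds$calibration + lv)
      write_read_fastq(reads, file.path(out_dir, "calibration",
                                        sprintf("level_%03d.fastq", lv)))
    }
  }

  if (isTRUE(config$expression$enabled)) {
    log_stage("expression table and UTRs")
    exp_cfg <- config$expression
    trf3b <- with(ref$trnas[ref$trnas$compartment == "nuclear", ],
                  substr(sequence, length - 21L, length))
    seeds7 <- unique(extract_seed(trf3b))[1:min(5L, length(unique(
      extract_seed(trf3b))))]
    genes <- sprintf("gene%05d", seq_len(exp_cfg$n_genes))
    set_seed_if(config$seeds$expression)
    n_t <- exp_cfg$n_targets_per_type
    pick <- sample(genes, n_t * length(SITE_TYPES))
    target_sets <- split(pick, rep(SITE_TYPES, each = n_t))
    planted <- do.call(rbind, lapply(SITE_TYPES, function(t)
      data.frame(gene = target_sets[[t]],
                 seed = sample(seeds7, n_t, replace = TRUE),
                 site_type = t,
                 n_sites = sample(1:2, n_t, replace = TRUE),
                 stringsAsFactors = FALSE)))
    expr <- simulate_expression_table(
      genes, target_sets, shifts = unlist(exp_cfg$shifts),
      sigma = exp_cfg$sigma, seed = config$seeds$expression + 1L)
    utrs <- simulate_utrs(genes, planted, seeds = seeds7,
                          utr_length = exp_cfg$utr_length,
                          seed = config$seeds$utr)
    x <- Biostrings::DNAStringSet(utrs)
    Biostrings::writeXStringSet(x, file.path(out_dir, "utrs.fa"))
    utils::write.table(expr[, c("gene", "log2FC", "baseMean")],
                       file.path(out_dir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cbind(expr[, c("gene", "true_type")]),
                       file.path(out_dir, "truth_targets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(planted, file.path(out_dir, "truth_planted_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(package = "trfm1a",
                   version = as.character(utils::packageVersion("trfm1a")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   config = config, config_hash = config_hash(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @noRd
read_fastq_checked <- function(path) {
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines %% 4L != 0L)
    stop("corrupted FASTQ ", path, ": truncated record near line ", n_lines,
         call. = FALSE)
  reads <- tryCatch(read_read_fastq(path),
                    error = function(e)
                      stop("corrupted FASTQ ", path, ": ",
                           conditionMessage(e), call. = FALSE))
  if (n_lines > 0L && sum(reads$count) != n_lines %/% 4L)
    stop("corrupted FASTQ ", path, ": record count mismatch", call. = FALSE)
  reads
}

#' Analyze a dataset directory end to end
#'
#' Stages run in order annotation -> mismatch -> calibration (if
#' calibration mixes are present) -> enrichment (if RIP arms are present)
#' -> seed/target analysis (if UTRs and an expression table are present);
#' partial inputs run partial pipelines with explicit skip notes in the
#' summary. Stage-contract violations (e.g. fractional-count conservation)
#' abort with the violated invariant named. Outputs are TSV/JSON files
#' carrying the configuration hash.
#'
#' @param config a [default_config()]-style list.
#' @param dataset_dir a [run_simulate()] output (or user files matching
#'   its layout).
#' @param out_dir results directory to create.
#' @return `out_dir`, invisibly; the summary is written to
#'   `summary.json`.
#' @export
run_analyze <- function(config = default_config(), dataset_dir, out_dir) {
  if (is.character(config)) config <- load_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  notes <- character(0)
  log_stage <- function(...) message("[analyze] ", ...)

  ref <- read_reference_set(file.path(dataset_dir, "reference"))
  index <- build_index(ref)
  policy <- mapping_policy()

  arms <- c("input", "igg",
            sprintf("rip_ab%d", seq_len(config$rip$n_antibodies %||% 2L)))
  arm_files <- file.path(dataset_dir, paste0(arms, ".fastq"))
  names(arm_files) <- arms
  arm_files <- arm_files[file.exists(arm_files)]
  if (!"input" %in% names(arm_files))
    stop("dataset has no input.fastq")

  log_stage("annotation (", length(arm_files), " libraries)")
  hits <- list()
  counts <- list()
  tallies <- list()
  for (a in names(arm_files)) {
    h <- align_reads(read_fastq_checked(arm_files[[a]]), ref, policy, index)
    ct <- make_count_table(h, min_count = th$min_count)
    s <- attr(h, "summary")
    if (abs(sum(ct$count) - s$n_mapped) > 1e-6)
      stop("invariant violated in arm ", a,
           ": sum of fractional counts != mapped reads")
    hits[[a]] <- h
    counts[[a]] <- ct
    tallies[[a]] <- s
    utils::write.table(ct, file.path(out_dir, sprintf("counts_%s.tsv", a)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(h),
                       file.path(out_dir, sprintf("annotation_%s.tsv", a)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  log_stage("mismatch statistics")
  prof3b <- pileup(hits$input, frame = "fragment", trf_class = "tRF-3",
                   isoform = "3b")
  mi3b <- mismatch_index_profile(prof3b, min_reads = th$min_reads)
  utils::write.table(cbind(group = "tRF-3b(pooled)", frame = "fragment",
                           mi3b),
                     file.path(out_dir, "mismatch_trf3b_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  site_report <- site_mismatch_report(hits$input, ref,
                                      min_reads = th$min_reads)
  utils::write.table(site_report, file.path(out_dir, "site_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cal_dir <- file.path(dataset_dir, "calibration")
  if (dir.exists(cal_dir)) {
    log_stage("calibration")
    ctrl <- ref$spikeins$name[!ref$spikeins$is_qc][1L]
    site <- ref$mod_sites$position[ref$mod_sites$reference == ctrl][1L]
    files <- list.files(cal_dir, pattern = "^level_\\d+\\.fastq$",
                        full.names = TRUE)
    pts <- do.call(rbind, lapply(files, function(f) {
      lv <- as.numeric(sub("level_(\\d+)\\.fastq", "\\1", basename(f)))
      h <- align_reads(read_fastq_checked(f), ref, policy, index)
      pr <- pileup(h, frame = "mature", parent = ctrl, ref = ref)
      mi <- mismatch_index(pr, site, min_reads = th$min_reads)
      data.frame(stoichiometry = lv, mismatch = mi$index,
                 coverage = mi$coverage)
    }))
    fit <- fit_calibration(pts)
    jsonlite::write_json(list(slope = fit$slope, r2 = fit$r2,
                              background = fit$background, points = pts,
                              config_hash = config_hash(config)),
                         file.path(out_dir, "calibration_fit.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else notes <- c(notes, "calibration skipped: no calibration mixes")

  rip_arms <- grep("^rip_ab", names(arm_files), value = TRUE)
  if (length(rip_arms)) {
    log_stage("enrichment (", length(rip_arms), " antibody arms)")
    ab_records <- lapply(rip_arms, function(a)
      enrichment_records(counts$input, counts[[a]], ref = ref,
                         min_count = th$min_count))
    names(ab_records) <- rip_arms
    igg_records <- if ("igg" %in% names(arm_files))
      enrichment_records(counts$input, counts$igg, ref = ref,
                         min_count = th$min_count) else NULL
    for (a in rip_arms)
      utils::write.table(ab_records[[a]],
                         file.path(out_dir,
                                   sprintf("enrichment_%s.tsv", a)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    calls <- call_m1a_candidates(ab_records, igg_records,
                                 site_mismatch = site_report,
                                 padj_cut = th$padj_rip,
                                 mismatch_cut = th$mismatch_evidence)
    utils::write.table(calls, file.path(out_dir, "m1a_candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else notes <- c(notes, "enrichment skipped: no RIP arms")

  utr_file <- file.path(dataset_dir, "utrs.fa")
  expr_file <- file.path(dataset_dir, "expression.tsv")
  if (file.exists(utr_file) && file.exists(expr_file)) {
    log_stage("seed/target analysis")
    utrs <- Biostrings::readDNAStringSet(utr_file)
    expr <- utils::read.table(expr_file, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    g3b <- hits$input[hits$input$class == "tRF-3" &
                        hits$input$isoform == "3b", , drop = FALSE]
    g3b$frac <- g3b$count * g3b$weight
    guide_counts <- stats::aggregate(frac ~ sequence, data = g3b,
                                     FUN = sum)
    names(guide_counts)[2L] <- "count"
    fams <- cluster_seeds(guide_counts,
                          coverage_threshold = th$seed_coverage)
    utils::write.table(fams, file.path(out_dir, "seed_families.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    k <- attr(fams, "k_covering")
    use_seeds <- fams$seed[seq_len(min(k %||% nrow(fams), nrow(fams)))]
    sites <- do.call(rbind, lapply(use_seeds, function(sd) {
      do.call(rbind, lapply(names(utrs), function(g) {
        s <- scan_utr(sd, as.character(utrs[[g]]))
        if (nrow(s)) cbind(gene = g, seed = sd, s) else NULL
      }))
    }))
    sites <- sites %||% data.frame(gene = character(0), seed = character(0),
                                   position = integer(0),
                                   site_type = character(0))
    tg <- classify_gene_targets(sites, expr, names(utrs),
                                min_expr = th$min_expr)
    utils::write.table(tg, file.path(out_dir, "target_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rep_res <- repression_analysis(
      tg, direction = config$expression$direction %||% "repressed")
    utils::write.table(rep_res$centered,
                       file.path(out_dir, "ecdf_centered_lfc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(direction = rep_res$direction,
                              nontarget_median = rep_res$nontarget_median,
                              classes = rep_res$classes,
                              adjustment = rep_res$adjustment,
                              config_hash = config_hash(config)),
                         file.path(out_dir, "ks_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else notes <- c(notes, "target analysis skipped: no UTRs/expression")

  summary <- list(config_hash = config_hash(config),
                  libraries = lapply(tallies, function(s) s),
                  skip_notes = as.list(notes))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Mismatch evidence at annotated modification sites
#'
#' For every count-table group on a reference with annotated sites,
#' reports the maximal defined mismatch index across the sites the group
#' covers (mature frame).
#'
#' @param hits an [align_reads()] result.
#' @param ref the [reference_set()].
#' @param min_reads coverage threshold.
#' @return data.frame with `group`, `reference`, `site`, `coverage`,
#'   `index`.
#' @export
site_mismatch_report <- function(hits, ref, min_reads = 50) {
  ms <- ref$mod_sites
  out <- list()
  tr_hits <- hits[hits$category %in% c("tRNA", "spikeIn"), , drop = FALSE]
  if (!nrow(tr_hits) || !nrow(ms))
    return(data.frame(group = character(0), reference = character(0),
                      site = integer(0), coverage = numeric(0),
                      index = numeric(0)))
  groups <- unique(tr_hits[, c("parent", "class", "isoform")])
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    sites <- ms[ms$reference == g$parent, , drop = FALSE]
    if (!nrow(sites)) next
    pr <- suppressWarnings(pileup(tr_hits, frame = "mature",
                                  parent = g$parent, trf_class = g$class,
                                  isoform = g$isoform, ref = ref))
    for (s in sites$position) {
      if (!s %in% pr$position) next
      mi <- mismatch_index(pr, s, min_reads)
      key <- sprintf("%s/%s%s", g$parent, g$class,
                     ifelse(g$isoform == "none", "",
                            paste0("-", g$isoform)))
      if (g$class == "spikeIn") key <- g$parent
      out[[length(out) + 1L]] <-
        data.frame(group = key, reference = g$parent, site = s,
                   coverage = mi$coverage, index = mi$index,
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out) %||%
    data.frame(group = character(0), reference = character(0),
               site = integer(0), coverage = numeric(0), index = numeric(0))
  # one row per group: strongest defined site evidence
  best <- lapply(split(res, res$group), function(d) {
    if (all(is.na(d$index))) d[1L, ] else d[which.max(d$index), ]
  })
  res <- do.call(rbind, best) %||% res
  rownames(res) <- NULL
  res
}
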