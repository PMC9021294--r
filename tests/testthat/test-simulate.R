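ref <- build_reference(21, n_trna = 6, n_mir = 8, n_spike = 3, n_mito = 1)

test_that("fragment pools respect stoichiometry limits and geometry", {
  # p = 0: no modified molecules anywhere
  s0 <- simulate_fragment_pool(ref, stoich = 0, n_molecules = 5000,
                               seed = 1)
  expect_false(any(grepl("1", s0$pool$site_mod)))
  # p = 1, tRF-3b only: every molecule modified at fragment position 4
  s1 <- simulate_fragment_pool(ref, profile = c("tRF-3b" = 1), stoich = 1,
                               n_molecules = 5000, seed = 2)
  expect_true(all(s1$pool$class == "tRF-3"))
  expect_true(all(s1$pool$site_pos == "4"))
  expect_true(all(s1$pool$site_mod == "1"))
  # tRF-3s are exact suffixes, tRF-5s exact prefixes of their parent
  sall <- simulate_fragment_pool(ref, n_molecules = 2000, seed = 3)
  pool <- sall$pool
  for (i in which(pool$class == "tRF-3")) {
    pseq <- ref_sequence(ref, pool$parent[i])
    expect_identical(pool$sequence[i],
                     substr(pseq, nchar(pseq) - (pool$end[i] -
                                                   pool$start[i]),
                            nchar(pseq)))
  }
  for (i in which(pool$class == "tRF-5")) {
    pseq <- ref_sequence(ref, pool$parent[i])
    expect_identical(pool$sequence[i],
                     substr(pseq, 1, pool$end[i]))
  }
  expect_error(simulate_fragment_pool(ref, profile = numeric(0), seed = 1),
               "empty")
})

test_that("realized modified fraction matches the drawn stoichiometry", {
  p <- 0.6
  n <- 10000
  s <- simulate_fragment_pool(ref, profile = c("tRF-3b" = 1), stoich = p,
                              n_molecules = n, seed = 4)
  n_mod <- sum(s$pool$count[s$pool$site_mod == "1"])
  # the realized count must be consistent with Binomial(n, p)
  expect_gt(stats::binom.test(n_mod, n, p)$p.value, 1e-3)
  expect_lt(abs(n_mod / n - p), 4 * sqrt(p * (1 - p) / n))
})

test_that("RT model limit cases behave as the ligation-first design implies", {
  pool <- simulate_fragment_pool(ref, profile = c("tRF-3b" = 1), stoich = 1,
                                 n_molecules = 3000, seed = 5)$pool
  # full stalling: modified molecules vanish from the library
  stall <- rt_model("custom", p_mis = 0, p_stall = 1, eps_bg = 0)
  reads <- apply_rt_model(pool, stall, seed = 6)
  expect_identical(attr(reads, "n_emitted"), 0L)
  expect_identical(attr(reads, "n_stalled"), sum(pool$count))
  # guaranteed read-through misincorporation: every read mismatched at site 4
  mis <- rt_model("custom", p_mis = 1, p_stall = 0, eps_bg = 0)
  reads <- apply_rt_model(pool, mis, seed = 7)
  clean <- setNames(pool$sequence, pool$species)
  expect_true(all(vapply(seq_len(nrow(reads)), function(i)
    identical(which(utf8ToInt(reads$sequence[i]) !=
                      utf8ToInt(clean[[reads$species[i]]])), 4L), TRUE)))
})

test_that("background error rate matches eps_bg at zero stoichiometry", {
  rt <- rt_model("TGIRT")
  s <- simulate_fragment_pool(ref, stoich = 0, n_molecules = 20000,
                              seed = 8)
  reads <- apply_rt_model(s$pool, rt, seed = 9)
  clean <- setNames(s$pool$sequence, s$pool$species)
  nerr <- sum(vapply(seq_len(nrow(reads)), function(i)
    reads$count[i] * sum(utf8ToInt(reads$sequence[i]) !=
                           utf8ToInt(clean[[reads$species[i]]])), 0))
  nbase <- sum(reads$count * nchar(reads$sequence))
  rate <- nerr / nbase
  expect_lt(abs(rate - rt$eps_bg),
            3 * sqrt(rt$eps_bg * (1 - rt$eps_bg) / nbase))
})

test_that("read counts are conserved: emitted = molecules - stalled", {
  rt <- rt_model("TGIRT")
  for (seed in 1:3) {
    s <- simulate_fragment_pool(ref, n_molecules = 8000, seed = seed)
    reads <- apply_rt_model(s$pool, rt, seed = seed + 100)
    expect_identical(attr(reads, "n_emitted") + attr(reads, "n_stalled"),
                     attr(reads, "n_molecules"))
    expect_identical(sum(reads$count), attr(reads, "n_emitted"))
  }
})

test_that("site mismatch rate converges to the closed-form model", {
  rt <- rt_model("TGIRT")
  p <- 0.8
  s <- simulate_fragment_pool(ref, profile = c("tRF-3b" = 1), stoich = p,
                              n_molecules = 100000, seed = 10)
  reads <- apply_rt_model(s$pool, rt, seed = 11)
  clean <- setNames(s$pool$sequence, s$pool$species)
  mis <- sum(reads$count[vapply(seq_len(nrow(reads)), function(i)
    substr(reads$sequence[i], 4, 4) !=
      substr(clean[[reads$species[i]]], 4, 4), TRUE)])
  obs <- 100 * mis / sum(reads$count)
  want <- expected_mismatch_rate(p, rt)
  se <- 100 * sqrt(want / 100 * (1 - want / 100) / sum(reads$count))
  expect_lt(abs(obs - want), 3 * se)
})

test_that("expected mismatch rate is nondecreasing in stoichiometry", {
  rt <- rt_model("TGIRT")
  grid <- seq(0, 1, by = 0.1)
  expect_true(all(diff(expected_mismatch_rate(grid, rt)) >= 0))
  # and the simulator follows it over a coarse grid
  obs <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(p) {
    s <- simulate_fragment_pool(ref, profile = c("tRF-3b" = 1), stoich = p,
                                n_molecules = 4000, seed = round(100 * p))
    reads <- apply_rt_model(s$pool, rt, seed = round(100 * p) + 1)
    clean <- setNames(s$pool$sequence, s$pool$species)
    mis <- sum(reads$count[vapply(seq_len(nrow(reads)), function(i)
      substr(reads$sequence[i], 4, 4) !=
        substr(clean[[reads$species[i]]], 4, 4), TRUE)])
    100 * mis / sum(reads$count)
  }, 0)
  expect_true(all(diff(obs) > 0))
})

test_that("simulation output is deterministic under a fixed seed", {
  rt <- rt_model("TGIRT")
  go <- function() {
    s <- simulate_fragment_pool(ref, n_molecules = 3000, seed = 12)
    apply_rt_model(s$pool, rt, seed = 13)
  }
  r1 <- go()
  r2 <- go()
  expect_identical(r1$sequence, r2$sequence)
  expect_identical(r1$count, r2$count)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_read_fastq(r1, f1)
  write_read_fastq(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("RIP arms recover the planted enrichment factor", {
  rt <- rt_model("TGIRT")
  # only the control oligo is modified (p = 1); it is a small pool fraction
  s <- simulate_fragment_pool(ref, stoich = c("ctrl-m1A:12" = 1),
                              n_molecules = 20000, seed = 14)
  lfe <- vapply(1:3, function(rep) {
    arms <- simulate_rip(s$pool, rip_config(8, 0.25, 20000), rt,
                         seed = 20 + rep)
    cts <- lapply(arms[c("input", "rip")], function(a)
      make_count_table(align_reads(a[, c("sequence", "count")], ref)))
    rec <- enrichment_records(cts$input, cts$rip, ref = ref)
    rec$log2fe[rec$group == "ctrl-m1A"]
  }, 0)
  expect_lt(abs(mean(lfe) - 3), 3 * max(sd(lfe) / sqrt(3), 0.05))
  # enrichment factor 1: no fragment should drift from log2FE ~ 0
  arms <- simulate_rip(s$pool, rip_config(1, 0.25, 20000), rt, seed = 30)
  cts <- lapply(arms[c("input", "rip")], function(a)
    make_count_table(align_reads(a[, c("sequence", "count")], ref)))
  rec <- enrichment_records(cts$input, cts$rip, ref = ref)
  expect_lt(abs(rec$log2fe[rec$group == "ctrl-m1A"]), 0.5)
})

test_that("expression tables plant the requested shifts", {
  genes <- sprintf("g%04d", 1:3000)
  tgt <- list("8mer-A1" = genes[1:300])
  e <- simulate_expression_table(genes, tgt, sigma = 0.4, seed = 31)
  expect_identical(nrow(e), 3000L)
  expect_lt(abs(mean(e$log2FC[e$true_type == "8mer-A1"]) - (-0.5)),
            3 * 0.4 / sqrt(300))
  expect_lt(abs(mean(e$log2FC[e$true_type == "non-target"])),
            3 * 0.4 / sqrt(2700))
  # no targets: a pure null table
  e0 <- simulate_expression_table(genes, list(), sigma = 0.4, seed = 32)
  expect_true(all(e0$true_type == "non-target"))
  # overlapping sets resolve to the strongest site type
  e2 <- simulate_expression_table(genes,
                                  list("6mer" = genes[1:10],
                                       "8mer-A1" = genes[1:10]),
                                  seed = 33)
  expect_true(all(e2$true_type[1:10] == "8mer-A1"))
})

test_that("planted UTRs contain exactly the planted sites", {
  genes <- sprintf("g%02d", 1:25)
  planted <- data.frame(gene = genes[1:10],
                        seed = c(rep("AGCTTAT", 5), rep("TCAAATC", 5)),
                        site_type = rep(c("8mer-A1", "7mer-m8", "7mer-A1",
                                          "6mer", "8mer-A1"), 2),
                        n_sites = rep(c(1, 2), 5),
                        stringsAsFactors = FALSE)
  utrs <- simulate_utrs(genes, planted, utr_length = 400, seed = 34)
  for (g in genes) {
    for (sd in unique(planted$seed)) {
      got <- scan_utr(sd, utrs[[g]])
      want <- planted[planted$gene == g & planted$seed == sd, ]
      if (nrow(want)) {
        expect_identical(nrow(got), as.integer(sum(want$n_sites)))
        expect_setequal(unique(got$site_type), want$site_type)
      } else {
        expect_identical(nrow(got), 0L)
      }
    }
  }
})
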