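test_that("seed extraction takes guide positions 2-8", {
  expect_identical(extract_seed("TAGCTTATCAGACTGATGTTGA"), "AGCTTAT")
  # guides differing outside 2-8 share a seed
  expect_identical(extract_seed("TAGCTTATCAGAC"),
                   extract_seed("GAGCTTATTTTTT"))
  expect_error(extract_seed("TAGCTTA"), "seed")
})

test_that("seed families aggregate counts, shares and the covering k", {
  guides <- data.frame(
    name = c("trf_a", "trf_b", "trf_c"),
    sequence = c("TAGCTTATCAGACTGATGTTGA",   # seed AGCTTAT
                 "GAGCTTATCCCCCTGATGTTGA",   # same seed
                 "TTCAAATCTTGGGTGATGTTGA"),  # seed TCAAATC
    count = c(60, 30, 10), stringsAsFactors = FALSE)
  fam <- cluster_seeds(guides)
  expect_equal(fam$coverage_share, c(0.9, 0.1))
  expect_identical(fam$seed, c("AGCTTAT", "TCAAATC"))
  expect_identical(attr(fam, "k_covering"), 1L)
  expect_match(fam$members[1], "trf_a")
  expect_match(fam$members[1], "trf_b")
  # equal counts, all-distinct seeds: shares 1/n
  g2 <- data.frame(sequence = c("AACGTACGTA", "CCGTAACGTA", "GGTACCATTA"),
                   count = 5)
  expect_equal(cluster_seeds(g2)$coverage_share, rep(1 / 3, 3))
  # single guide: one family with full share
  g1 <- cluster_seeds(data.frame(sequence = "TAGCTTATCA", count = 7))
  expect_equal(g1$coverage_share, 1)
  # empty input
  expect_identical(nrow(cluster_seeds(data.frame(sequence = character(0),
                                                 count = numeric(0)))), 0L)
})

test_that("site definitions resolve per occurrence to the highest type", {
  # reverse complement of guide 2-8 (seed AGCTTAT) is ATAAGCT
  s <- scan_utr("AGCTTAT", "GGATAAGCTAGG")
  expect_identical(s$site_type, "8mer-A1")
  expect_identical(s$position, 3L)
  # terminal A mutated: 7mer-m8
  s <- scan_utr("AGCTTAT", "GGATAAGCTGGG")
  expect_identical(s$site_type, "7mer-m8")
  # core6 with A1 but broken m8 pairing: 7mer-A1
  s <- scan_utr("AGCTTAT", "GGCTAAGCTAGG")
  expect_identical(s$site_type, "7mer-A1")
  # bare core6: 6mer
  s <- scan_utr("AGCTTAT", "GGCTAAGCTGGG")
  expect_identical(s$site_type, "6mer")
  # N never matches
  expect_identical(nrow(scan_utr("AGCTTAT", "GGATANGCTAGG")), 0L)
})

test_that("the scanner agrees with the pairing-space oracle", {
  set.seed(101)
  bases <- c("A", "C", "G", "T")
  for (i in 1:100) {
    seed7 <- paste(sample(bases, 7, TRUE), collapse = "")
    utr <- paste(sample(bases, sample(50:400, 1), TRUE), collapse = "")
    # spike in a few motifs so matches are not vanishingly rare
    core <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seed7)))
    for (j in 1:2) {
      at <- sample(nchar(utr) - 10, 1)
      substr(utr, at, at + 7) <- paste0(core, sample(bases, 1))
    }
    got <- scan_utr(seed7, utr)
    want <- oracle_sites(seed7, utr)
    got <- got[order(got$position), ]
    want <- want[order(want$position), ]
    expect_equal(got$position, want$position, info = seed7)
    expect_equal(got$site_type, want$site_type, info = seed7)
  }
})

test_that("gene classification applies rank, filters, and partitions", {
  expr <- data.frame(gene = sprintf("g%d", 1:6),
                     log2FC = rnorm(6),
                     baseMean = c(500, 500, 500, 100, 99, 500))
  utr_genes <- sprintf("g%d", 1:5)  # g6 expressed but has no UTR
  sites <- data.frame(
    gene = c(rep("g1", 4), "g2", "g4", "g5"),
    position = 1:7,
    site_type = c("8mer-A1", "6mer", "6mer", "6mer", "7mer-m8",
                  "8mer-A1", "8mer-A1"),
    stringsAsFactors = FALSE)
  tg <- classify_gene_targets(sites, expr, utr_genes)
  # g4 (baseMean exactly 100: strict filter), g5 (<100) and g6 (no UTR)
  # are excluded entirely
  expect_setequal(tg$gene, c("g1", "g2", "g3"))
  g1 <- tg[tg$gene == "g1", ]
  expect_identical(g1$best_type, "8mer-A1")
  expect_identical(g1$site_count, 4L)
  expect_true(g1$multi_site)
  expect_identical(tg$best_type[tg$gene == "g2"], "7mer-m8")
  expect_identical(tg$best_type[tg$gene == "g3"], "non-target")
  # partition: every retained gene has exactly one label
  expect_identical(anyDuplicated(tg$gene), 0L)
  expect_true(all(tg$best_type %in% c("8mer-A1", "7mer-m8", "7mer-A1",
                                      "6mer", "non-target")))
  expect_error(classify_gene_targets(sites, rbind(expr, expr[1, ]),
                                     utr_genes), "duplicate")
})

test_that("repression analysis centers on the non-target median", {
  genes <- sprintf("g%04d", 1:1500)
  e <- simulate_expression_table(genes,
                                 list("8mer-A1" = genes[1:300]),
                                 shifts = c("8mer-A1" = -0.5),
                                 sigma = 0.4, seed = 103)
  tg <- data.frame(gene = e$gene, best_type = e$true_type,
                   site_count = as.integer(e$true_type != "non-target"),
                   multi_site = FALSE, log2FC = e$log2FC,
                   baseMean = e$baseMean, stringsAsFactors = FALSE)
  rr <- repression_analysis(tg, "repressed")
  nt <- rr$centered$centered_lfc[rr$centered$class == "non-target"]
  expect_equal(median(nt), 0)
  expect_lt(rr$classes$p[rr$classes$class == "8mer-A1"], 1e-10)
  # the same planted shift is invisible to the wrong-direction test
  rr_wrong <- repression_analysis(tg, "derepressed")
  expect_gt(rr_wrong$classes$p[rr_wrong$classes$class == "8mer-A1"], 0.5)
  # classes below the minimum size report NA
  expect_true(all(is.na(
    rr$classes$p[rr$classes$class %in% c("7mer-m8", "7mer-A1", "6mer")])))
})

test_that("seed/miRNA overlap respects the expression threshold", {
  mirnas <- data.frame(sequence = c("TAGCTTATCAGACTGATGTTGA",
                                    "TTCAAATCTGGGGGGGGGGGGG"),
                       count = c(50, 10), stringsAsFactors = FALSE)
  # expressed miRNA seed collides
  expect_true(seed_overlap_with_mirnas("AGCTTAT", mirnas))
  # count exactly 10 does not pass the strict > 10 filter
  expect_false(seed_overlap_with_mirnas("TCAAATC", mirnas))
  expect_false(seed_overlap_with_mirnas("AGCTTAT",
                                        mirnas[0, , drop = FALSE]))
})

test_that("planted sites, classification and repression recover end to end", {
  genes <- sprintf("g%03d", 1:120)
  seeds <- c("AGCTTAT", "TCAAATC")
  planted <- data.frame(
    gene = genes[1:40],
    seed = rep(seeds, 20),
    site_type = rep(c("8mer-A1", "7mer-m8", "7mer-A1", "6mer"), 10),
    n_sites = rep(c(1, 2), 20), stringsAsFactors = FALSE)
  utrs <- simulate_utrs(genes, planted, utr_length = 400, seed = 104)
  expr <- simulate_expression_table(
    genes, split(planted$gene, planted$site_type), sigma = 0.4,
    frac_low_expr = 0, seed = 105)
  sites <- do.call(rbind, lapply(seeds, function(sd)
    do.call(rbind, lapply(genes, function(g) {
      x <- scan_utr(sd, utrs[[g]])
      if (nrow(x)) cbind(gene = g, x) else NULL
    }))))
  tg <- classify_gene_targets(sites, expr, genes, min_expr = 100)
  truth <- setNames(expr$true_type, expr$gene)
  expect_identical(setNames(tg$best_type, tg$gene)[tg$gene],
                   truth[tg$gene])
})
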