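ref <- tiny_reference()
index <- build_index(ref)

# one simulated library reused across blocks
rt <- rt_model("TGIRT")
sim <- simulate_fragment_pool(ref, stoich = 0.8, n_molecules = 20000,
                              seed = 61)
reads <- apply_rt_model(sim$pool, rt, seed = 62)
hits <- align_reads(reads[, c("sequence", "count")], ref,
                    mapping_policy(), index)

test_that("pileups count coverage and substitutions position by position", {
  trna <- ref$trnas$name[1]
  suffix <- substr(ref_sequence(ref, trna),
                   ref_length(ref, trna) - 21, ref_length(ref, trna))
  mut <- suffix
  substr(mut, 4, 4) <- "C"
  h <- align_reads(data.frame(sequence = c(suffix, mut),
                              count = c(70L, 30L)),
                   ref, mapping_policy(), index)
  pr <- pileup(h, frame = "fragment", parent = trna, trf_class = "tRF-3",
               isoform = "3b", ref = ref)
  expect_equal(pr$coverage, rep(100, 22))
  expect_equal(pr$mismatches[4], 30)
  expect_equal(sum(pr$mismatches[-4]), 0)
  expect_equal(pr$sub_C[4], 30)
  expect_identical(pr$ref_base, strsplit(suffix, "")[[1]])
  # mature frame puts the same event at the A58-equivalent position
  prm <- pileup(h, frame = "mature", parent = trna, trf_class = "tRF-3",
                isoform = "3b", ref = ref)
  site <- ref_length(ref, trna) - 18L
  expect_equal(prm$mismatches[site], 30)
  expect_warning(pileup(h, parent = "absent-group"), "empty")
})

test_that("mismatch index equals a naive per-read recount everywhere", {
  pr <- pileup(hits, frame = "fragment", trf_class = "tRF-3",
               isoform = "3b")
  for (pos in c(1, 4, 10, 22)) {
    mi <- mismatch_index(pr, pos)
    expect_equal(mi$index,
                 naive_mismatch_index(hits, "fragment", pos,
                                      trf_class = "tRF-3",
                                      isoform = "3b"))
  }
  # per-parent mature-frame indices agree too
  for (parent in ref$trnas$name[1:2]) {
    prm <- pileup(hits, frame = "mature", parent = parent, ref = ref)
    site <- ref$mod_sites$position[ref$mod_sites$reference == parent][1]
    expect_equal(mismatch_index(prm, site)$index,
                 naive_mismatch_index(hits, "mature", site,
                                      parent = parent))
  }
})

test_that("the index is undefined at or below 50 reads of coverage", {
  prof <- structure(data.frame(position = 1:3,
                               ref_base = NA_character_,
                               coverage = c(50, 51, 100),
                               sub_A = 0, sub_C = c(10, 0, 30),
                               sub_G = 0, sub_T = 0,
                               mismatches = c(10, 0, 30)),
                    class = c("mismatch_profile", "data.frame"))
  expect_true(is.na(mismatch_index(prof, 1)$index))
  expect_equal(mismatch_index(prof, 2)$index, 0)
  expect_equal(mismatch_index(prof, 3)$index, 30)
  # undefined coverage propagates through comparisons with a reason
  cmp <- compare_mismatch(prof, prof, 1)
  expect_true(is.na(cmp$log2fc))
  expect_match(cmp$reason, "coverage")
})

test_that("substitution spectra normalize and flag empties", {
  prof <- structure(data.frame(position = 1:2, ref_base = "A",
                               coverage = 100, sub_A = 0,
                               sub_C = c(6, 0), sub_G = c(3, 0),
                               sub_T = c(1, 0), mismatches = c(10, 0)),
                    class = c("mismatch_profile", "data.frame"))
  sp <- substitution_spectrum(prof, 1)
  expect_equal(unname(sp[c("C", "G", "T")]), c(0.6, 0.3, 0.1))
  expect_false(attr(sp, "empty"))
  sp0 <- substitution_spectrum(prof, 2)
  expect_true(attr(sp0, "empty"))
  expect_equal(sum(sp0), 0)
})

test_that("the A-share separates modification signal from background", {
  # m1A-driven errors only: all mismatches at the reference adenosine
  clean_rt <- rt_model("custom", p_mis = 1, p_stall = 0, eps_bg = 0)
  s <- simulate_fragment_pool(ref, profile = c("tRF-3b" = 1), stoich = 1,
                              n_molecules = 4000, seed = 63)
  r <- apply_rt_model(s$pool, clean_rt, seed = 64)
  h <- align_reads(r[, c("sequence", "count")], ref, mapping_policy(),
                   index)
  parent <- h$parent[1]
  pr <- pileup(h, frame = "mature", parent = parent, ref = ref)
  expect_equal(a_mismatch_share(pr), 1)
  # background-dominated errors: A-share near the A fraction of the span
  bg_rt <- rt_model("custom", p_mis = 0, p_stall = 0, eps_bg = 0.05)
  s0 <- simulate_fragment_pool(ref, profile = c("tRF-3b" = 1), stoich = 0,
                               n_molecules = 20000, seed = 65)
  r0 <- apply_rt_model(s0$pool, bg_rt, seed = 66)
  h0 <- align_reads(r0[, c("sequence", "count")], ref, mapping_policy(),
                    index)
  parent <- names(sort(table(h0$parent), decreasing = TRUE))[1]
  pr0 <- pileup(h0, frame = "mature", parent = parent, ref = ref)
  span <- pr0$ref_base[pr0$coverage > 0]
  expect_lt(abs(a_mismatch_share(pr0) - mean(span == "A")), 0.1)
})

test_that("normalized mismatch index is mismatch over non-mismatch", {
  expect_equal(normalized_mismatch_index(50), 1)
  expect_equal(normalized_mismatch_index(20), 0.25)
  expect_equal(normalized_mismatch_index(0), 0)
  expect_warning(out <- normalized_mismatch_index(100), "saturated")
  expect_identical(out, Inf)
  expect_error(normalized_mismatch_index(101))
})

test_that("condition comparisons recover a planted knockdown", {
  expect_equal(compare_mismatch(
    structure(data.frame(position = 1, ref_base = NA, coverage = 1000,
                         sub_A = 0, sub_C = 400, sub_G = 0, sub_T = 0,
                         mismatches = 400),
              class = c("mismatch_profile", "data.frame")),
    structure(data.frame(position = 1, ref_base = NA, coverage = 1000,
                         sub_A = 0, sub_C = 100, sub_G = 0, sub_T = 0,
                         mismatches = 100),
              class = c("mismatch_profile", "data.frame")),
    1, pseudocount = 0)[, c("delta", "log2fc")],
    data.frame(delta = 30, log2fc = 2))
  # halving stoichiometry halves the attributable mismatch rate (~ -1 log2)
  mk <- function(p, seed) {
    s <- simulate_fragment_pool(ref, profile = c("tRF-3b" = 1), stoich = p,
                                n_molecules = 30000, seed = seed)
    r <- apply_rt_model(s$pool, rt, seed = seed + 1)
    h <- align_reads(r[, c("sequence", "count")], ref, mapping_policy(),
                     index)
    pileup(h, frame = "fragment", trf_class = "tRF-3", isoform = "3b")
  }
  cmp <- compare_mismatch(mk(0.4, 67), mk(0.8, 69), 4, pseudocount = 0)
  want <- log2(expected_mismatch_rate(0.4, rt) /
                 expected_mismatch_rate(0.8, rt))
  expect_lt(abs(cmp$log2fc - want), 0.15)
})
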