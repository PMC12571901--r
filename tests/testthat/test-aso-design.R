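test_that("candidate enumeration tiles every start position", {
  sg <- synth_genome(synth_spec(n_genes = 2, seed = 4))
  tir <- extract_tir(sg$genome, offset_from = -37, offset_to = 44)
  cands <- enumerate_candidates(tir, length = 11)
  expect_equal(nrow(cands), 2L * (81L - 11L + 1L))  # 71 per gene
  # every aso is the exact reverse complement of its recorded site
  expect_true(all(cands$aso_seq == revcomp(cands$target_site_seq)))
  # and every site occurs in the TIR at the recorded offsets
  for (i in seq_len(nrow(cands))) {
    w <- tir[tir$gene == cands$gene[i], ]
    at <- (if (cands$site_from[i] > 0) cands$site_from[i] else
      cands$site_from[i] + 1L) - (if (w$offset_from > 0) w$offset_from else
        w$offset_from + 1L) + 1L
    expect_equal(substr(w$seq, at, at + 10L), cands$target_site_seq[i])
  }
  # a window exactly as long as the oligomer yields a single candidate
  one <- enumerate_candidates(tibble::tibble(
    gene = "g", offset_from = -5L, offset_to = 6L, seq = "ACAATTATGTC",
    truncated = FALSE), length = 11)
  expect_equal(nrow(one), 1L)
  expect_equal(one$target_site_seq, "ACAATTATGTC")
  expect_equal(one$aso_seq, "GACATAATTGT")  # reverse complement by hand
  # shorter window: empty result with a warning
  expect_warning(
    none <- enumerate_candidates(tibble::tibble(
      gene = "g", offset_from = -2L, offset_to = 3L, seq = "ACGTA",
      truncated = TRUE), length = 11),
    "shorter")
  expect_equal(nrow(none), 0L)
})

test_that("purine fraction counts A+G over length", {
  expect_equal(purine_fraction("GACATAATTGT"), 6 / 11)
  expect_equal(purine_fraction("CCCC"), 0)
  expect_equal(purine_fraction("AGAGAG"), 1)
  expect_error(purine_fraction(""), "empty")
  expect_error(purine_fraction("ACGU"), "alphabet")
})

test_that("self-complementarity equals the exhaustive brute-force oracle", {
  expect_equal(self_complementarity("GAATTC"), 6L)       # palindrome
  expect_equal(self_complementarity("AAAAAAAAAAA"), 0L)  # no TT anywhere
  set.seed(21)
  for (i in 1:25) {
    s <- random_dna_str(11)
    expect_equal(self_complementarity(s), r_selfcomp_bruteforce(s), info = s)
  }
})

test_that("filter pass set equals brute-force re-evaluation of the predicate", {
  sg <- synth_genome(synth_spec(n_genes = 20, seed = 1))
  cfg <- design_config()
  d <- suppressWarnings(design_asos(sg$genome, config = cfg))
  manual <- !d$has_n &
    d$tm_c >= cfg$tm_min & d$tm_c <= cfg$tm_max &
    d$purine_frac >= cfg$purine_min & d$purine_frac <= cfg$purine_max &
    d$cum_mm2 < cfg$max_offtarget_tirs &
    d$selfcomp <= cfg$selfcomp_max
  expect_equal(d$passes, manual)
  # boundary behaviour: Tm out of band fails even if everything else passes
  row <- tibble::tibble(gene = "g", has_n = FALSE, tm_c = c(50, 60),
                        purine_frac = 0.27, selfcomp = 4, site_center = 0,
                        site_from = -10L, aso_seq = c("A", "B"), cum_mm2 = 0L)
  out <- suppressWarnings(apply_filters(row, cfg))
  expect_equal(out$passes[match(c("A", "B"), out$aso_seq)], c(TRUE, FALSE))
})

test_that("apply_filters is idempotent and flags under-designed genes", {
  sg <- synth_genome(synth_spec(n_genes = 8, seed = 9))
  d <- suppressWarnings(design_asos(sg$genome))
  cfg <- attr(d, "config")
  once <- suppressWarnings(apply_filters(tibble::as_tibble(d), cfg))
  twice <- suppressWarnings(apply_filters(once, cfg))
  expect_equal(twice, once)
  # an impossible Tm band leaves every gene under-designed
  strict <- design_config(tm_min = 98, tm_max = 99)
  expect_warning(u <- apply_filters(tibble::as_tibble(d), strict),
                 "under-designed")
  expect_true(all(u$under_designed))
})

test_that("identical inputs give byte-identical design TSV output", {
  sg <- synth_genome(synth_spec(n_genes = 5, seed = 13))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_design_table(suppressWarnings(design_asos(sg$genome)), f1)
  write_design_table(suppressWarnings(design_asos(sg$genome)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("tiling a -37..+44 window yields 71 scored, unfiltered candidates", {
  sg <- synth_genome(synth_spec(n_genes = 3, seed = 6))
  tiles <- tile_window(sg$genome, "SYNG0002")
  expect_equal(nrow(tiles), 71L)
  expect_false("passes" %in% names(tiles))
  expect_true(all(!is.na(tiles$tm_c)))
  expect_true(all(c("site_center", "cum_mm2") %in% names(tiles)))
  # a +1..+11 window is the single candidate sitting on the start codon
  over_start <- tile_window(sg$genome, "SYNG0002", offset_from = 1,
                            offset_to = 11)
  expect_equal(nrow(over_start), 1L)
  expect_equal(substr(over_start$target_site_seq, 1, 3), "ATG")
})

test_that("central mismatch controls have exact distance and central positions", {
  hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  aso <- "GACATAATTGT"
  for (k in 1:9) {
    ctrl <- make_mismatch_control(aso, k)
    expect_equal(hamming(aso, ctrl), k)
    diffs <- which(strsplit(aso, "")[[1]] != strsplit(ctrl, "")[[1]])
    centre_rank <- order(abs(seq_len(11) - 6), seq_len(11))
    if (k %% 2 == 1) {
      expect_true(all(diffs %in% centre_rank[seq_len(k)]))
    }
  }
  ctrl2 <- make_mismatch_control(aso, 2)
  diffs <- which(strsplit(aso, "")[[1]] != strsplit(ctrl2, "")[[1]])
  expect_true(all(diffs %in% c(5L, 6L, 7L)))
  expect_error(make_mismatch_control(aso, 0), "k must")
  expect_error(make_mismatch_control(aso, 10), "k must")
})

test_that("mismatch controls never match the target TIR exactly", {
  sg <- synth_genome(synth_spec(n_genes = 2, seed = 8))
  tir <- extract_tir(sg$genome, offset_from = -30, offset_to = 15)
  cands <- enumerate_candidates(tir, length = 11)
  for (i in seq(1, nrow(cands), by = 7)) {
    ctrl <- make_mismatch_control(cands$aso_seq[i], k = 2)
    site_of_ctrl <- revcomp(ctrl)
    for (w in tir$seq) {
      expect_false(grepl(site_of_ctrl, w, fixed = TRUE))
    }
  }
})

test_that("the printed non-targeting control fails the purine design filter", {
  ctrl <- "GACATAATTGT"
  expect_equal(purine_fraction(ctrl), 6 / 11, tolerance = 1e-12)
  cfg <- design_config()
  expect_gt(purine_fraction(ctrl), cfg$purine_max)
})
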