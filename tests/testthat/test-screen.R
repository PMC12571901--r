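spot_series <- function(counts, exponents = seq_along(counts) - 1,
                        gene = "g1", condition = "targeting", assay = "PFU") {
  tibble::tibble(gene = gene, aso_id = paste0(gene, "_a"),
                 condition = condition, assay = assay,
                 dilution_exponent = exponents, count = counts)
}

test_that("titer arithmetic: 12 plaques at 1e-5 in 5 ul is 2.4e8 PFU/ml", {
  sp <- spot_series(c(1200, 130, 12), exponents = c(3, 4, 5))
  expect_equal(titer_from_spots(sp, method = "single")$titer, 2.4e8)
  expect_equal(titer_from_spots(sp, method = "pooled")$titer, 2.4e8)
})

test_that("all-zero series are censored at the detection limit", {
  sp <- spot_series(c(0, 0, 0), exponents = c(2, 3, 4))
  out <- titer_from_spots(sp)
  expect_true(out$censored)
  expect_equal(out$titer, 1 * 10^2 / 0.005)
  # non-zero but sub-countable counts are ambiguous, not censorable
  bad <- spot_series(c(130, 2, 0), exponents = c(0, 1, 2))
  expect_error(titer_from_spots(bad, method = "single"), "countable")
})

test_that("titers are equivariant to rescaling counts against dilution", {
  # counts chosen so rescaling does not move any spot across the countable
  # bounds (the observation process itself is range-limited)
  for (counts in list(list(c(10, 5, 0), c(3, 4, 5)),
                      list(c(9, 0), c(4, 5)))) {
    sp <- spot_series(counts[[1]], exponents = counts[[2]])
    shifted <- sp
    shifted$count <- sp$count * 10
    shifted$dilution_exponent <- sp$dilution_exponent - 1
    for (m in c("single", "pooled")) {
      expect_equal(titer_from_spots(shifted, method = m)$titer,
                   titer_from_spots(sp, method = m)$titer)
    }
  }
})

test_that("Poisson counts at adjacent dilutions give concordant titers", {
  set.seed(41)
  done <- 0
  while (done < 20) {
    n_hi <- rpois(1, 80)
    n_lo <- rpois(1, 8)
    if (n_hi < 3 || n_hi > 100 || n_lo < 3) next  # both spots countable
    done <- done + 1
    t_hi <- titer_from_spots(spot_series(c(n_hi, 0), exponents = c(4, 6)),
                             method = "single")$titer
    t_lo <- titer_from_spots(spot_series(c(n_lo, 0), exponents = c(5, 7)),
                             method = "single")$titer
    # Poisson sd of the log10 difference is ~0.15; 0.6 is a 4 sigma band
    expect_lt(abs(log10(t_lo) - log10(t_hi)), 0.6)
  }
})

test_that("effect categories follow the log10-reduction thresholds", {
  expect_equal(as.character(effect_category(1e9, 1e9)$category), "none")
  expect_equal(as.character(effect_category(10^7.5, 1e9)$category), "+")
  expect_equal(as.character(effect_category(10^6.5, 1e9)$category), "++")
  expect_equal(as.character(effect_category(1e4, 1e9)$category), "+++")
  expect_equal(as.character(effect_category(1e10, 1e9)$category), "-")
  # censored target below detection, bound >= 4 logs: definitive "+++"
  out <- effect_category(1e3, 1e9, target_censored = TRUE)
  expect_equal(as.character(out$category), "+++")
  expect_false(out$censored)
  # censored with a weaker bound: call at the bound, flagged censored
  out <- effect_category(1e7, 1e9, target_censored = TRUE)
  expect_equal(as.character(out$category), "++")
  expect_true(out$censored)
})

test_that("effect categories are monotone in the titer reduction", {
  deltas <- seq(-3, 6, by = 0.25)
  cats <- effect_category(1e9 / 10^deltas, 1e9)$category
  reduction_side <- cats[deltas >= 0]
  expect_true(all(diff(as.integer(reduction_side)) >= 0))
  expect_true(all(cats[deltas <= -1] == "-"))
})

test_that("analyze_screen pairs targeting with control and scores PFU deltas", {
  sp <- dplyr::bind_rows(
    spot_series(c(5000, 450, 55, 5), exponents = 4:7, gene = "gA",
                condition = "control"),
    spot_series(c(45, 6, 0, 0), exponents = 4:7, gene = "gA",
                condition = "targeting"),
    spot_series(c(5000, 450, 55, 5), exponents = 4:7, gene = "gB",
                condition = "control"),
    spot_series(c(4800, 520, 48, 6), exponents = 4:7, gene = "gB",
                condition = "targeting"))
  out <- analyze_screen(sp)
  expect_s3_class(out, "aso_screen")
  expect_equal(as.character(out$category[out$gene == "gA"]), "++")
  expect_equal(as.character(out$category[out$gene == "gB"]), "none")
  g <- glance(out)
  expect_equal(g$n, 2L)
  expect_equal(g$n_effective, 1L)
})

test_that("temporal classification applies the printed thresholds exactly", {
  expr <- tibble::tibble(
    gene = c("up_sig", "down_sig", "up_notsig", "weak_sig", "down_notsig"),
    log2fc = c(3.0, -2.5, 5.0, 1.5, -4.0),
    padj = c(1e-12, 1e-11, 1e-5, 1e-15, 1e-9))
  out <- classify_temporal(expr)
  expect_equal(as.character(out$class),
               c("middle_late", "early", "unclassified", "unclassified",
                 "unclassified"))
  expect_error(classify_temporal(tibble::tibble(gene = "x", log2fc = 1,
                                                padj = 0)),
               "padj")
})

test_that("temporal classes partition any table and match brute-force counts", {
  set.seed(53)
  expr <- tibble::tibble(gene = sprintf("g%04d", 1:400),
                         log2fc = rnorm(400, 0, 3),
                         padj = 10^-runif(400, 0, 20))
  out <- classify_temporal(expr)
  expect_equal(sum(table(out$class)), 400L)  # disjoint and exhaustive
  sig <- -log10(expr$padj) > 10
  expect_equal(sum(out$class == "middle_late"), sum(expr$log2fc > 2 & sig))
  expect_equal(sum(out$class == "early"), sum(expr$log2fc < -2 & sig))
})

test_that("knockdown profile matrix assembles columns and applies the NA policy", {
  tab <- tibble::tibble(gene = c("a", "b", "c"), log2fc = c(1, -2, 3),
                        padj = 1e-3)
  m <- knockdown_profile_matrix(list(k1 = tab, k2 = tab))
  expect_equal(m[, "k1"], m[, "k2"])
  # a gene missing from 1 of 2 knockdowns (50% > 20%) is dropped
  tab2 <- tab[tab$gene != "c", ]
  m2 <- knockdown_profile_matrix(list(k1 = tab, k2 = tab2))
  expect_false("c" %in% rownames(m2))
  # with many knockdowns the same gene is kept and imputed to 0
  ks <- c(list(short = tab2), rep(list(tab), 9))
  names(ks) <- c("short", paste0("k", 1:9))
  m3 <- knockdown_profile_matrix(ks)
  expect_true("c" %in% rownames(m3))
  expect_equal(m3["c", "short"], 0)
  expect_error(knockdown_profile_matrix(list(k1 = tab[0, ], k2 = tab[0, ])),
               "no gene")
})

test_that("planted profile groups are recovered by hierarchical clustering", {
  set.seed(61)
  centers <- list(g1 = c(rep(4, 10), rep(0, 20)),
                  g2 = c(rep(0, 10), rep(-4, 10), rep(0, 10)),
                  g3 = c(rep(0, 20), rep(4, 10)))
  kds <- list()
  truth <- integer(0)
  for (grp in 1:3) {
    for (rep in 1:4) {
      nm <- sprintf("grp%d_rep%d", grp, rep)
      kds[[nm]] <- tibble::tibble(
        gene = sprintf("g%02d", 1:30),
        log2fc = centers[[grp]] + rnorm(30, 0, 0.3))
      truth <- c(truth, grp)
    }
  }
  m <- knockdown_profile_matrix(kds)
  hc <- stats::hclust(stats::dist(t(m)), method = "average")
  found <- stats::cutree(hc, k = 3)
  # same planted group <=> same cluster
  expect_equal(outer(found, found, "=="), outer(truth, truth, "=="),
               ignore_attr = TRUE)
})
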