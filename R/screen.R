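#' Titers from serial-dilution spot counts
#'
#' Converts spot counts at serial dilutions into CFU/PFU titers per ml.
#' Each (gene, aso_id, condition, assay) series must contain at least one
#' countable spot (count within `countable`). The default `"pooled"`
#' estimator is the Poisson maximum-likelihood titer over the informative
#' tail of the series -- the sum of all counts at dilutions at or beyond the
#' least dilute countable spot (spots above the countable cap are saturated
#' and excluded), divided by the summed effective volume. `"single"` uses
#' only the most dilute countable spot,
#' `titer = count * 10^dilution_exponent / (spot_volume_ul * 1e-3 ml)`;
#' both agree in expectation, the pooled estimate has smaller variance.
#' Series that are below detection at every dilution (all counts 0 or
#' `"below-detection"`) are censored at the detection limit, one unit in the
#' least dilute spot. `"lawn-cleared"` spots (confluent lysis) are treated
#' as uncountably high.
#'
#' @param spots Tibble with columns `gene`, `aso_id`, `condition`
#'   (`"targeting"`/`"control"`), `assay` (`"CFU"`/`"PFU"`),
#'   `dilution_exponent` (non-negative integer `e` meaning a `10^-e`
#'   dilution) and `count` (number, or `"lawn-cleared"`/`"below-detection"`).
#' @param spot_volume_ul Spotted volume in microlitres (default 5).
#' @param countable Countable range per spot, inclusive (default `c(3, 100)`).
#' @param method `"pooled"` (Poisson MLE over the informative dilutions,
#'   default) or `"single"` (most dilute countable spot only).
#' @return Tibble with one row per series: the grouping columns plus
#'   `titer` (per ml) and `censored`.
#' @examples
#' spots <- tibble::tibble(gene = "g1", aso_id = "a1",
#'   condition = "targeting", assay = "PFU",
#'   dilution_exponent = c(3, 4, 5), count = c(1200, 130, 12))
#' titer_from_spots(spots)  # 12 plaques at 1e-5 in 5 ul -> 2.4e8 PFU/ml
#' @export
titer_from_spots <- function(spots, spot_volume_ul = 5, countable = c(3, 100),
                             method = c("pooled", "single")) {
  method <- match.arg(method)
  spots <- as_tibble(spots)
  req <- c("gene", "aso_id", "condition", "assay", "dilution_exponent", "count")
  miss <- setdiff(req, names(spots))
  if (length(miss)) abort(paste0("spot table lacks column(s): ",
                                 paste(miss, collapse = ", ")))
  vol_ml <- spot_volume_ul * 1e-3
  cnt_chr <- as.character(spots$count)
  lawn <- cnt_chr == "lawn-cleared"
  below <- cnt_chr == "below-detection"
  num <- suppressWarnings(as.numeric(cnt_chr))
  if (any(is.na(num) & !lawn & !below)) {
    abort("count must be a number, 'lawn-cleared' or 'below-detection'")
  }
  if (any(num < 0, na.rm = TRUE)) abort("negative spot count")
  spots$.count <- num
  spots$.lawn <- lawn
  spots$.below <- below | (!is.na(num) & num == 0)
  one <- function(d, key) {
    d <- d[order(d$dilution_exponent), ]
    if (anyDuplicated(d$dilution_exponent)) {
      abort("dilution exponents must be strictly increasing within a series")
    }
    ok <- !d$.lawn & !d$.below & d$.count >= countable[1] &
      d$.count <= countable[2]
    if (any(ok)) {
      if (method == "single") {
        i <- max(which(ok))  # most dilute countable spot
        titer <- d$.count[i] * 10^d$dilution_exponent[i] / vol_ml
      } else {
        ## pool every spot from the least dilute countable one outward;
        ## saturated spots (over the cap or lawn-cleared) are excluded
        i0 <- min(which(ok))
        use <- seq(i0, nrow(d))
        use <- use[!d$.lawn[use] & d$.count[use] <= countable[2]]
        titer <- sum(d$.count[use]) /
          sum(vol_ml / 10^d$dilution_exponent[use])
      }
      tibble(titer = titer, censored = FALSE)
    } else if (all(d$.below)) {
      tibble(titer = 1 * 10^min(d$dilution_exponent) / vol_ml,
             censored = TRUE)
    } else {
      abort(sprintf("no countable spot and not censorable for %s",
                    paste(unlist(key), collapse = "/")))
    }
  }
  spots |>
    group_by(.data$gene, .data$aso_id, .data$condition, .data$assay) |>
    dplyr::group_modify(one) |>
    ungroup()
}

#' Effect-category thresholds
#'
#' Numeric cut-offs, in log10 units of titer reduction, behind the ordinal
#' effect labels: `none` below `weak`; `+` from `weak`; `++` from
#' `effective`; `+++` from `very_effective`; `-` (increased titer) at or
#' below `increase`. Defaults 1 / 2 / 4 / -1 separate "multiple logs" of
#' reduction from two-to-three-order effects and from order-of-magnitude
#' increases.
#'
#' @param weak,effective,very_effective,increase Cut-offs in log10 units.
#' @return Named list of class `effect_thresholds`.
#' @export
effect_thresholds <- function(weak = 1, effective = 2, very_effective = 4,
                              increase = -1) {
  stopifnot(weak < effective, effective < very_effective, increase < 0)
  structure(list(weak = weak, effective = effective,
                 very_effective = very_effective, increase = increase),
            class = "effect_thresholds")
}

#' Ordinal effect category from paired titers
#'
#' `delta = log10(control) - log10(target)`; the category is a pure function
#' of `delta` and the thresholds. A censored target titer makes `delta` a
#' lower bound: the call is made at the bound and flagged `censored` (a
#' bound at or above the `very_effective` cut-off is a definitive `+++`).
#'
#' @param target,control Titers per ml (vectors recycle).
#' @param target_censored Logical; target titer is a detection-limit bound.
#' @param thresholds An [effect_thresholds()].
#' @return Tibble with `delta_log10`, `category` (ordered factor
#'   `-`, `none`, `+`, `++`, `+++`) and `censored`.
#' @examples
#' effect_category(target = 10^6.5, control = 1e9)   # delta 2.5 -> "++"
#' @export
effect_category <- function(target, control, target_censored = FALSE,
                            thresholds = effect_thresholds()) {
  stopifnot(all(target > 0), all(control > 0))
  n <- max(length(target), length(control))
  target <- rep_len(target, n); control <- rep_len(control, n)
  target_censored <- rep_len(target_censored, n)
  delta <- log10(control) - log10(target)
  th <- thresholds
  category <- dplyr::case_when(
    delta >= th$very_effective ~ "+++",
    delta >= th$effective ~ "++",
    delta >= th$weak ~ "+",
    delta <= th$increase ~ "-",
    TRUE ~ "none")
  tibble(delta_log10 = delta,
         category = factor(category,
                           levels = c("-", "none", "+", "++", "+++"),
                           ordered = TRUE),
         censored = target_censored & delta < th$very_effective)
}

#' Score a knockdown screen from spot counts
#'
#' Full screen read-out: spot counts to titers ([titer_from_spots()]), then
#' targeting-vs-control titer deltas and ordinal effect categories per gene.
#' Categories are assigned from the PFU delta (plaque efficiency); the CFU
#' delta (host survival) is reported alongside when present.
#'
#' @inheritParams titer_from_spots
#' @param thresholds An [effect_thresholds()].
#' @return Tibble of class `aso_screen`: one row per (gene, aso_id) with
#'   `delta_log10_pfu`, `delta_log10_cfu` (NA if no CFU assay), `category`
#'   and `censored`.
#' @export
analyze_screen <- function(spots, thresholds = effect_thresholds(),
                           spot_volume_ul = 5, countable = c(3, 100),
                           method = c("pooled", "single")) {
  titers <- titer_from_spots(spots, spot_volume_ul = spot_volume_ul,
                             countable = countable, method = method)
  wide <- titers |>
    tidyr::pivot_wider(names_from = c("condition", "assay"),
                       values_from = c("titer", "censored"),
                       names_sep = "_")
  need <- c("titer_targeting_PFU", "titer_control_PFU")
  miss <- setdiff(need, names(wide))
  if (length(miss)) {
    abort("screen needs PFU titers for both targeting and control conditions")
  }
  calls <- effect_category(wide$titer_targeting_PFU, wide$titer_control_PFU,
                           target_censored = wide$censored_targeting_PFU,
                           thresholds = thresholds)
  dcfu <- if (all(c("titer_targeting_CFU", "titer_control_CFU") %in%
                  names(wide))) {
    log10(wide$titer_control_CFU) - log10(wide$titer_targeting_CFU)
  } else {
    rep(NA_real_, nrow(wide))
  }
  out <- tibble(gene = wide$gene, aso_id = wide$aso_id,
                delta_log10_pfu = calls$delta_log10,
                delta_log10_cfu = dcfu,
                category = calls$category, censored = calls$censored)
  structure(out, class = c("aso_screen", class(out)), thresholds = thresholds)
}

#' Classify transcripts as early vs middle/late
#'
#' Applies the published differential-expression thresholds to a
#' late-vs-early contrast (e.g. 35 min vs 10 min post infection, control
#' condition): `middle_late` if `log2fc > lfc_cutoff` and
#' `-log10(padj) > sig_cutoff`; `early` if `log2fc < -lfc_cutoff` at the
#' same significance; `unclassified` otherwise. The three classes are
#' disjoint and exhaustive.
#'
#' @param expr Tibble with columns `gene`, `log2fc`, `padj`
#'   (`padj` in `(0, 1]`).
#' @param lfc_cutoff Absolute log2-fold-change cut-off (default 2).
#' @param sig_cutoff `-log10(padj)` cut-off (default 10).
#' @return The tibble with a `class` factor column
#'   (`early`, `middle_late`, `unclassified`) appended.
#' @examples
#' classify_temporal(tibble::tibble(gene = "g", log2fc = 3, padj = 1e-12))
#' @export
classify_temporal <- function(expr, lfc_cutoff = 2, sig_cutoff = 10) {
  expr <- as_tibble(expr)
  miss <- setdiff(c("gene", "log2fc", "padj"), names(expr))
  if (length(miss)) abort(paste0("expression table lacks column(s): ",
                                 paste(miss, collapse = ", ")))
  if (any(!is.finite(expr$padj) | expr$padj <= 0 | expr$padj > 1)) {
    abort("padj must lie in (0, 1]")
  }
  sig <- -log10(expr$padj) > sig_cutoff
  cls <- dplyr::case_when(
    expr$log2fc > lfc_cutoff & sig ~ "middle_late",
    expr$log2fc < -lfc_cutoff & sig ~ "early",
    TRUE ~ "unclassified")
  mutate(expr, class = factor(cls, levels = c("early", "middle_late",
                                              "unclassified")))
}

#' Gene-by-knockdown log2-fold-change matrix
#'
#' Assembles per-knockdown expression tables into a dense gene x knockdown
#' matrix of log2 fold changes for external clustering. Genes missing from
#' more than `max_missing` of the knockdowns are dropped; remaining missing
#' entries are imputed as 0 (no change).
#'
#' @param tables Named list of expression tibbles (`gene`, `log2fc`, ...)
#'   or a long tibble with columns `knockdown`, `gene`, `log2fc`.
#' @param max_missing Highest tolerated fraction of knockdowns a gene may be
#'   missing from (default 0.2).
#' @return Numeric matrix, genes in rows, knockdowns in columns.
#' @export
knockdown_profile_matrix <- function(tables, max_missing = 0.2) {
  if (is.data.frame(tables)) {
    long <- as_tibble(tables)
    miss <- setdiff(c("knockdown", "gene", "log2fc"), names(long))
    if (length(miss)) abort(paste0("long table lacks column(s): ",
                                   paste(miss, collapse = ", ")))
  } else {
    if (is.null(names(tables))) names(tables) <- paste0("kd", seq_along(tables))
    long <- purrr::imap(tables, function(tab, nm) {
      tibble(knockdown = nm, gene = tab$gene, log2fc = tab$log2fc)
    }) |> bind_rows()
  }
  wide <- long |>
    tidyr::pivot_wider(id_cols = "gene", names_from = "knockdown",
                       values_from = "log2fc")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene
  frac_na <- rowMeans(is.na(m))
  m <- m[frac_na <= max_missing, , drop = FALSE]
  if (nrow(m) == 0L) abort("no gene satisfies the missingness policy")
  m[is.na(m)] <- 0
  m
}
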