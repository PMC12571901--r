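#' Design configuration
#'
#' Collects every tunable threshold of the antisense design filter. Defaults
#' follow the published screening practice for 11-mer antisense PNAs:
#' duplex melting temperature between 45 and 55 deg C, purine fraction of the
#' oligomer between 25 and 35 percent, fewer than 3 off-target translation
#' initiation regions, and at least two accepted oligomers per gene.
#' Off-target counts are always reported up to `report_mm` mismatches; the
#' "< max_offtarget_tirs" rule is applied at `offtarget_criterion_mm`
#' mismatches (default 2), where chance hits across a few hundred random
#' TIRs are rare enough for the criterion to discriminate (at 4 allowed
#' mismatches an 11-mer hits tens of random TIRs by chance alone).
#'
#' @param length Oligomer length in nucleobases (default 11).
#' @param tm_min,tm_max Melting-temperature bounds in deg C (defaults 45/55).
#' @param purine_min,purine_max Purine-fraction bounds (defaults 0.25/0.35).
#' @param max_offtarget_tirs Pass iff distinct off-target TIRs at the
#'   criterion level are strictly below this count (default 3).
#' @param offtarget_criterion_mm Mismatch level at which the off-target rule
#'   is applied (default 2).
#' @param report_mm Highest mismatch level reported (default 4).
#' @param selfcomp_max Longest tolerated internal reverse-complementary
#'   match, nt (default 5).
#' @param min_asos_per_gene Accepted oligomers requested per gene; genes
#'   with fewer passing candidates are flagged under-designed (default 2).
#' @param tm_model A [tm_model()].
#' @return A list of class `design_config`.
#' @export
design_config <- function(length = 11L, tm_min = 45, tm_max = 55,
                          purine_min = 0.25, purine_max = 0.35,
                          max_offtarget_tirs = 3L,
                          offtarget_criterion_mm = 2L, report_mm = 4L,
                          selfcomp_max = 5L, min_asos_per_gene = 2L,
                          tm_model = asodesignr::tm_model()) {
  stopifnot(length >= 6L, tm_min < tm_max, purine_min < purine_max,
            offtarget_criterion_mm <= report_mm, max_offtarget_tirs >= 1L,
            selfcomp_max >= 0L, min_asos_per_gene >= 1L)
  structure(list(length = as.integer(length), tm_min = tm_min, tm_max = tm_max,
                 purine_min = purine_min, purine_max = purine_max,
                 max_offtarget_tirs = as.integer(max_offtarget_tirs),
                 offtarget_criterion_mm = as.integer(offtarget_criterion_mm),
                 report_mm = as.integer(report_mm),
                 selfcomp_max = as.integer(selfcomp_max),
                 min_asos_per_gene = as.integer(min_asos_per_gene),
                 tm_model = tm_model),
            class = "design_config")
}

#' Purine fraction of a sequence
#'
#' Fraction of A and G bases. Scored on the antisense oligomer itself: a
#' low-purine oligomer is the complement of a purine-rich target such as a
#' Shine-Dalgarno site.
#'
#' @param seq Character vector over `{A,C,G,T}`.
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' purine_fraction("GACATAATTGT")  # 6/11
#' @export
purine_fraction <- function(seq) {
  if (any(!nzchar(seq))) abort("empty sequence")
  assert_dna(seq, allow_n = FALSE)
  (stringr::str_count(seq, "A") + stringr::str_count(seq, "G")) / nchar(seq)
}

#' Self-complementarity of a sequence
#'
#' Length of the longest substring (length >= 2) whose reverse complement
#' also occurs in the sequence, possibly overlapping the substring itself;
#' 0 when no such substring exists. A substring's reverse complement occurs
#' in the sequence exactly when the substring itself occurs in the reverse
#' complement of the sequence, so this is the longest common substring of
#' the two -- computed exactly by dynamic programming and equivalent to an
#' exhaustive scan over all substrings.
#'
#' @param seq Character vector over `{A,C,G,T}`, each of length >= 2.
#' @return Integer vector.
#' @examples
#' self_complementarity("GAATTC")       # palindrome: 6
#' self_complementarity("AAAAAAAAAAA")  # no TT anywhere: 0
#' @export
self_complementarity <- function(seq) {
  assert_dna(seq, allow_n = FALSE)
  if (any(nchar(seq) < 2L)) abort("sequence shorter than 2 nt")
  one <- function(s) {
    a <- strsplit(s, "")[[1]]
    b <- rev(chartr("ACGT", "TGCA", a))
    n <- length(a)
    prev <- integer(n)
    best <- 0L
    for (i in seq_len(n)) {
      cur <- integer(n)
      hit <- which(b == a[i])
      cur[hit] <- prev[pmax(hit - 1L, 1L)] + 1L
      cur[hit[hit == 1L]] <- 1L
      best <- max(best, cur)
      prev <- cur
    }
    if (best >= 2L) best else 0L
  }
  vapply(seq, one, integer(1), USE.NAMES = FALSE)
}

#' Enumerate candidate antisense oligomers along a TIR window
#'
#' One candidate per start position of the window: `length(seq) - length + 1`
#' per non-truncated window. Each candidate's `aso_seq` is the reverse
#' complement of its mRNA-sense target site, written 5'->3'. Site offsets
#' use the zeroless mRNA coordinate convention of [extract_tir()];
#' `site_center` is the signed distance of the site midpoint from the
#' junction between positions -1 and +1 (0 = centred on the start-codon
#' boundary).
#'
#' @param tirs Tibble from [extract_tir()] (columns `gene`, `offset_from`,
#'   `offset_to`, `seq`, ...).
#' @param length Oligomer length (default 11, minimum 6).
#' @return Tibble with one row per candidate: `gene`, `site_from`, `site_to`,
#'   `site_center`, `target_site_seq`, `aso_seq`, `length`, `has_n`.
#' @examples
#' g <- synth_genome(synth_spec(n_genes = 1, seed = 1))$genome
#' tir <- extract_tir(g, offset_from = -37, offset_to = 44)
#' nrow(enumerate_candidates(tir))  # 81 - 11 + 1 = 71
#' @export
enumerate_candidates <- function(tirs, length = 11L) {
  length <- as.integer(length)
  if (length < 6L) abort("oligomer length must be >= 6")
  tirs <- as_tibble(tirs)
  rows <- lapply(seq_len(nrow(tirs)), function(i) {
    w <- tirs[i, ]
    n <- nchar(w$seq)
    if (n < length) {
      warn(sprintf("window for %s (%d nt) shorter than oligomer length %d",
                   w$gene, n, length))
      return(NULL)
    }
    starts <- 1:(n - length + 1L)
    axis0 <- off2idx(w$offset_from)
    site <- substring(w$seq, starts, starts + length - 1L)
    a_from <- axis0 + starts - 1L
    a_to <- a_from + length - 1L
    tibble(gene = w$gene,
           site_from = idx2off(a_from), site_to = idx2off(a_to),
           site_center = (a_from + a_to) / 2 - 0.5,
           target_site_seq = site, aso_seq = revcomp(site),
           length = length, has_n = grepl("N", site, fixed = TRUE))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(gene = character(), site_from = integer(),
                  site_to = integer(), site_center = numeric(),
                  target_site_seq = character(), aso_seq = character(),
                  length = integer(), has_n = logical())
  }
  out
}

#' Score candidate oligomers
#'
#' Adds predicted melting temperature (`tm_c`), purine fraction of the
#' oligomer (`purine_frac`) and self-complementarity (`selfcomp`).
#' Candidates whose site contains `N` get `NA` scores and are excluded from
#' design by default downstream.
#'
#' @param candidates Tibble from [enumerate_candidates()].
#' @param config A [design_config()].
#' @return The candidate tibble with score columns appended.
#' @export
score_candidates <- function(candidates, config = design_config()) {
  candidates <- as_tibble(candidates)
  ok <- !candidates$has_n
  tm <- purine <- rep(NA_real_, nrow(candidates))
  sc <- rep(NA_integer_, nrow(candidates))
  if (any(ok)) {
    tm[ok] <- melting_temperature(candidates$aso_seq[ok],
                                  candidates$target_site_seq[ok],
                                  model = config$tm_model)
    purine[ok] <- purine_fraction(candidates$aso_seq[ok])
    sc[ok] <- self_complementarity(candidates$aso_seq[ok])
  }
  mutate(candidates, tm_c = tm, purine_frac = purine, selfcomp = sc)
}

#' Filter and rank scored candidates
#'
#' A candidate passes iff its melting temperature, purine fraction and
#' self-complementarity are within the configured bounds and its distinct
#' off-target TIR count at the criterion mismatch level (own gene excluded)
#' is strictly below `max_offtarget_tirs`; sites containing `N` never pass.
#' Candidates are ranked within each gene by a stable composite:
#' fewest off-targets first, then smallest distance of the melting
#' temperature from the band midpoint, then smallest distance of the site
#' centre from the start-codon junction, then 5'-most site, then sequence.
#' Genes with fewer than `min_asos_per_gene` passing candidates are flagged
#' `under_designed`. Re-applying the filter to its own output is a no-op.
#'
#' @param candidates Scored candidates with off-target columns attached
#'   (see [count_offtargets()]).
#' @param config A [design_config()].
#' @return The tibble with `passes`, `rank_score`, `rank` and
#'   `under_designed` columns (re)computed.
#' @export
apply_filters <- function(candidates, config = design_config()) {
  candidates <- as_tibble(candidates)
  crit_col <- paste0("cum_mm", config$offtarget_criterion_mm)
  need <- c("tm_c", "purine_frac", "selfcomp", crit_col)
  miss <- setdiff(need, names(candidates))
  if (length(miss)) {
    abort(paste0("candidates lack column(s) ", paste(miss, collapse = ", "),
                 "; run score_candidates() and count_offtargets() first"))
  }
  ot <- candidates[[crit_col]]
  passes <- !candidates$has_n &
    !is.na(candidates$tm_c) &
    candidates$tm_c >= config$tm_min & candidates$tm_c <= config$tm_max &
    candidates$purine_frac >= config$purine_min &
    candidates$purine_frac <= config$purine_max &
    ot < config$max_offtarget_tirs &
    candidates$selfcomp <= config$selfcomp_max
  tm_mid <- (config$tm_min + config$tm_max) / 2
  tm_dist <- abs(candidates$tm_c - tm_mid)
  tm_dist[is.na(tm_dist)] <- Inf
  ot_key <- ifelse(is.na(ot), Inf, ot)
  rank_score <- ot_key * 1e4 + pmin(tm_dist, 99) * 1e2 +
    pmin(abs(candidates$site_center), 99)
  candidates$passes <- passes
  candidates$rank_score <- rank_score
  out <- candidates |>
    group_by(.data$gene) |>
    arrange(dplyr::desc(.data$passes), .data$rank_score, .data$site_from,
            .data$aso_seq, .by_group = TRUE) |>
    mutate(rank = row_number(),
           under_designed = sum(.data$passes) < config$min_asos_per_gene) |>
    ungroup()
  if (any(out$under_designed)) {
    genes <- unique(out$gene[out$under_designed])
    warn(sprintf("under-designed gene(s) (< %d passing candidates): %s",
                 config$min_asos_per_gene, paste(genes, collapse = ", ")))
  }
  out
}

#' Design antisense oligomers for genes of a genome
#'
#' End-to-end pipeline: extract TIR windows, enumerate and score candidate
#' oligomers, count mismatch-tolerant off-targets across every TIR of the
#' phage (and optionally the host), then filter and rank. Windows containing
#' `N` yield flagged, excluded candidates.
#'
#' @param genome A [genome_record] (the phage).
#' @param genes Locus tags to design for (default: all CDS genes).
#' @param host Optional [genome_record] whose TIRs are added to the
#'   off-target search space.
#' @param offset_from,offset_to Design window in mRNA offsets (default
#'   `-30..+15`).
#' @param config A [design_config()].
#' @return A tibble of class `aso_design` (one row per candidate) carrying
#'   the configuration and per-genome off-target profiles as attributes.
#' @examples
#' g <- synth_genome(synth_spec(n_genes = 5, seed = 1))$genome
#' design <- design_asos(g)
#' glance(design)
#' @export
design_asos <- function(genome, genes = NULL, host = NULL,
                        offset_from = -30L, offset_to = 15L,
                        config = design_config()) {
  tirs <- extract_tir(genome, genes = genes, offset_from = offset_from,
                      offset_to = offset_to)
  cands <- enumerate_candidates(tirs, length = config$length) |>
    score_candidates(config = config)
  scan_tirs <- stats::setNames(
    list(extract_tir(genome, offset_from = offset_from,
                     offset_to = offset_to)),
    genome$id)
  if (!is.null(host)) {
    scan_tirs[[host$id]] <- extract_tir(host, offset_from = offset_from,
                                        offset_to = offset_to)
  }
  cands <- count_offtargets(cands, scan_tirs, report_mm = config$report_mm)
  out <- apply_filters(cands, config = config)
  structure(out, class = c("aso_design", class(out)),
            config = config, genome_id = genome$id,
            window = c(offset_from, offset_to),
            offtarget_by_genome = attr(cands, "offtarget_by_genome"))
}

#' Tile a wide window with scored oligomers
#'
#' Enumerates and scores one candidate per start position across a wide
#' window (default `-37..+44`, the empirical tiling window around a start
#' codon) without applying any design filter -- tiling sets are meant for
#' empirical testing, not selection. Off-target profiles are computed
#' against all TIRs of the genome.
#'
#' @inheritParams design_asos
#' @param gene Single locus tag to tile.
#' @return Tibble of scored candidates annotated with `site_center`.
#' @export
tile_window <- function(genome, gene, offset_from = -37L, offset_to = 44L,
                        length = 11L, config = design_config(length = length)) {
  stopifnot(is.character(gene), length(gene) == 1L)
  tir <- extract_tir(genome, genes = gene, offset_from = offset_from,
                     offset_to = offset_to)
  cands <- enumerate_candidates(tir, length = config$length) |>
    score_candidates(config = config)
  scan_tirs <- stats::setNames(list(extract_tir(genome)), genome$id)
  count_offtargets(cands, scan_tirs, report_mm = config$report_mm)
}

## Maximally central substitution positions: odd k takes the centre base and
## adjacent flanks; even k leaves the centre base paired and fills outward
## symmetrically (k = 2 on an 11-mer -> positions 5 and 7). Ties on even
## lengths break toward the 5' end.
central_positions <- function(len, k) {
  c0 <- (len + 1L) %/% 2L
  if (k %% 2L == 1L) {
    half <- (k - 1L) %/% 2L
    pos <- (c0 - half):(c0 + half)
  } else {
    half <- k %/% 2L
    pos <- c(c0 - seq_len(half), c0 + seq_len(half))
  }
  sort(pos)
}

#' Central-mismatch negative control for an oligomer
#'
#' Returns a sequence at Hamming distance exactly `k` from `aso_seq` with the
#' substituted positions placed maximally centrally (central mismatches
#' abolish antisense activity, making such sequences matched negative
#' controls). Substitutions are transversions, so the new base can neither
#' Watson-Crick nor wobble pair with the target base at that position.
#'
#' @param aso_seq Oligomer sequence (single string) or a one-row candidate
#'   tibble with an `aso_seq` column.
#' @param k Number of mismatches, `1 <= k <= length - 2`.
#' @return The control sequence (character scalar).
#' @examples
#' make_mismatch_control("GACATAATTGT", k = 2)
#' @export
make_mismatch_control <- function(aso_seq, k = 2L) {
  if (is.data.frame(aso_seq)) {
    stopifnot(nrow(aso_seq) == 1L, "aso_seq" %in% names(aso_seq))
    aso_seq <- aso_seq$aso_seq
  }
  stopifnot(is.character(aso_seq), length(aso_seq) == 1L)
  assert_dna(aso_seq, allow_n = FALSE, arg = "aso_seq")
  k <- as.integer(k)
  len <- nchar(aso_seq)
  if (k < 1L || k > len - 2L) {
    abort(sprintf("k must satisfy 1 <= k <= length - 2 (= %d)", len - 2L))
  }
  bases <- strsplit(aso_seq, "")[[1]]
  transversion <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))
  for (p in central_positions(len, k)) {
    bases[p] <- transversion[[bases[p]]][1]
  }
  paste(bases, collapse = "")
}

#' Write a candidate table to TSV
#'
#' Stable column order and candidate ranking make the output byte-identical
#' across runs for identical inputs and configuration.
#'
#' @param candidates Candidate tibble (e.g. from [design_asos()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_design_table <- function(candidates, path) {
  first <- intersect(c("gene", "site_from", "site_to", "target_site_seq",
                       "aso_seq", "tm_c", "purine_frac", "selfcomp",
                       paste0("ot_mm", 0:9), paste0("cum_mm", 0:9),
                       "passes", "rank"), names(candidates))
  out <- candidates[, c(first, setdiff(names(candidates), first))]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
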