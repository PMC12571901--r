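#' Mismatch-tolerant sites of a query in a subject sequence
#'
#' Every start position at which the ungapped Hamming distance between the
#' query and the subject window is at most `max_mm`, with the exact distance
#' recorded. `"sliding"` is the defining sliding comparison (implemented in
#' C); `"seed"` is a pigeonhole-seeded accelerator (any hit with `<= max_mm`
#' mismatches contains at least one of `max_mm + 1` exact query chunks) that
#' returns the identical hit set. `N` positions never match.
#'
#' @param query,subject DNA strings; `nchar(query) <= nchar(subject)`.
#' @param max_mm Maximum Hamming distance.
#' @param method `"sliding"` (default) or `"seed"`.
#' @return Tibble with columns `position` (1-based start in `subject`) and
#'   `mismatches`.
#' @examples
#' hamming_sites("AAAAAAAAAAA", "AAAAACAAAAAAA", max_mm = 1)
#' @export
hamming_sites <- function(query, subject, max_mm,
                          method = c("sliding", "seed")) {
  method <- match.arg(method)
  stopifnot(is.character(query), length(query) == 1L,
            is.character(subject), length(subject) == 1L)
  query <- normalize_dna(query); subject <- normalize_dna(subject)
  assert_dna(query, arg = "query"); assert_dna(subject, arg = "subject")
  if (nchar(query) > nchar(subject)) {
    abort("query longer than subject")
  }
  max_mm <- as.integer(max_mm)
  hits <- switch(method,
    sliding = .cpp_hamming_scan(query, subject, max_mm),
    seed = seed_hamming_scan(query, subject, max_mm))
  tibble(position = as.integer(hits$position),
         mismatches = as.integer(hits$mismatches))
}

## Pigeonhole accelerator: split the query into max_mm + 1 chunks; any
## window within max_mm mismatches matches >= 1 chunk exactly. Exact chunk
## hits (overlapping, via lookahead regex) seed candidate start positions,
## which are then verified by direct comparison.
seed_hamming_scan <- function(query, subject, max_mm) {
  q <- nchar(query); s <- nchar(subject)
  nchunk <- max_mm + 1L
  bounds <- floor(seq(0, q, length.out = nchunk + 1L))
  starts <- integer(0)
  for (i in seq_len(nchunk)) {
    from <- bounds[i] + 1L; to <- bounds[i + 1L]
    if (to < from) next
    chunk <- substr(query, from, to)
    m <- gregexpr(sprintf("(?=%s)", chunk), subject, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    starts <- c(starts, as.integer(m) - from + 1L)
  }
  starts <- sort(unique(starts))
  starts <- starts[starts >= 1L & starts + q - 1L <= s]
  pos <- integer(0); mm <- integer(0)
  qb <- strsplit(query, "")[[1]]
  for (p in starts) {
    wb <- strsplit(substr(subject, p, p + q - 1L), "")[[1]]
    d <- sum(qb != wb | qb == "N")
    if (d <= max_mm) {
      pos <- c(pos, p); mm <- c(mm, d)
    }
  }
  list(position = pos, mismatches = mm)
}

## Normalize TIR input: a single tibble becomes a one-genome list.
as_tir_sets <- function(tirs) {
  if (is.data.frame(tirs)) tirs <- list(genome = tirs)
  if (!is.list(tirs) || !all(vapply(tirs, is.data.frame, logical(1)))) {
    abort("`tirs` must be a TIR tibble or a named list of TIR tibbles")
  }
  if (is.null(names(tirs)) || any(!nzchar(names(tirs)))) {
    names(tirs) <- paste0("genome", seq_along(tirs))
  }
  tirs
}

#' Off-target profiles of candidate oligomers across TIR sets
#'
#' For every candidate and every TIR other than its own gene's, the minimum
#' ungapped Hamming distance of the candidate's target-site sequence over
#' all positions of the TIR is computed; each TIR contributes once, at its
#' minimum distance (distinct-TIR counting). Counts are reported per genome;
#' [count_offtargets()] attaches the combined counts to the candidate table.
#'
#' @param candidates Candidate tibble (needs `gene` and `target_site_seq`).
#' @param tirs A TIR tibble ([extract_tir()]) or a named list of them, one
#'   per genome searched (e.g. phage and host).
#' @param report_mm Highest mismatch level reported (default 4).
#' @return Long tibble: `cand`, `gene`, `genome`, `ot_mm0..ot_mm<m>` (exact),
#'   `cum_mm0..cum_mm<m>` (cumulative, non-decreasing).
#' @export
offtarget_profiles <- function(candidates, tirs, report_mm = 4L) {
  candidates <- as_tibble(candidates)
  tirs <- as_tir_sets(tirs)
  report_mm <- as.integer(report_mm)
  nq <- nrow(candidates)
  target_found <- rep(FALSE, nq)
  out <- vector("list", length(tirs))
  for (gi in seq_along(tirs)) {
    tt <- as_tibble(tirs[[gi]])
    dmat <- .cpp_min_hamming(candidates$target_site_seq, tt$seq)
    ## exclude each candidate's own gene from its counts
    own <- outer(candidates$gene, tt$gene, "==")
    target_found <- target_found | rowSums(own) > 0
    dmat[own] <- NA_integer_
    counts <- t(vapply(seq_len(nq), function(i) {
      d <- dmat[i, ]
      vapply(0:report_mm, function(m) sum(d == m, na.rm = TRUE), integer(1))
    }, integer(report_mm + 1L)))
    exact <- as.data.frame(counts)
    names(exact) <- paste0("ot_mm", 0:report_mm)
    cum <- as.data.frame(t(apply(counts, 1, cumsum)))
    names(cum) <- paste0("cum_mm", 0:report_mm)
    out[[gi]] <- dplyr::bind_cols(
      tibble(cand = seq_len(nq), gene = candidates$gene,
             genome = names(tirs)[gi]),
      as_tibble(exact), as_tibble(cum))
  }
  if (!all(target_found)) {
    warn(sprintf("target gene absent from every TIR set (no self-exclusion): %s",
                 paste(unique(candidates$gene[!target_found]), collapse = ", ")))
  }
  bind_rows(out)
}

#' Attach combined off-target counts to a candidate table
#'
#' Sums the per-genome distinct-TIR counts from [offtarget_profiles()] over
#' all searched genomes and appends `ot_mm*` (exact) and `cum_mm*`
#' (cumulative) columns. The per-genome long profile is kept as the
#' `offtarget_by_genome` attribute.
#'
#' @inheritParams offtarget_profiles
#' @return The candidate tibble with off-target count columns.
#' @export
count_offtargets <- function(candidates, tirs, report_mm = 4L) {
  prof <- offtarget_profiles(candidates, tirs, report_mm = report_mm)
  exact_cols <- paste0("ot_mm", 0:report_mm)
  combined <- prof |>
    group_by(.data$cand) |>
    summarise(across(all_of(exact_cols), sum), .groups = "drop") |>
    arrange(.data$cand)
  cum <- t(apply(as.matrix(combined[, exact_cols]), 1, cumsum))
  colnames(cum) <- paste0("cum_mm", 0:report_mm)
  out <- dplyr::bind_cols(
    as_tibble(candidates)[, setdiff(names(candidates),
                                    c(exact_cols, colnames(cum)))],
    combined[, exact_cols], as_tibble(as.data.frame(cum)))
  attr(out, "offtarget_by_genome") <- prof
  out
}
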