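# Independent brute-force oracles and fixture builders used across tests.

# Sliding Hamming scan, plain R (the defining computation, independent of
# the package's C implementation).
r_hamming_scan <- function(query, subject, max_mm) {
  qb <- strsplit(query, "")[[1]]
  q <- length(qb); s <- nchar(subject)
  pos <- integer(0); mm <- integer(0)
  if (q > s) return(data.frame(position = pos, mismatches = mm))
  for (p in 1:(s - q + 1)) {
    wb <- strsplit(substr(subject, p, p + q - 1), "")[[1]]
    d <- sum(qb != wb | qb == "N" | wb == "N")
    if (d <= max_mm) {
      pos <- c(pos, p); mm <- c(mm, d)
    }
  }
  data.frame(position = pos, mismatches = mm)
}

# Minimum Hamming distance of query over all windows of subject (NA if the
# subject is shorter than the query).
r_min_hamming <- function(query, subject) {
  q <- nchar(query); s <- nchar(subject)
  if (s < q) return(NA_integer_)
  scan <- r_hamming_scan(query, subject, max_mm = q)
  min(scan$mismatches)
}

# Distinct-TIR off-target counts for one query against a TIR table,
# excluding `own` locus tags; returns exact counts at 0..report_mm.
r_offtarget_counts <- function(query, tir_tab, own, report_mm = 4) {
  keep <- tir_tab$gene != own
  d <- vapply(tir_tab$seq[keep], function(s) r_min_hamming(query, s),
              integer(1))
  vapply(0:report_mm, function(m) sum(d == m, na.rm = TRUE), integer(1))
}

# O(L^4) self-complementarity oracle: for every substring pair, check
# reverse-complement identity.
r_selfcomp_bruteforce <- function(seq) {
  n <- nchar(seq)
  best <- 0L
  for (len in 2:n) {
    for (i in 1:(n - len + 1)) {
      a <- substr(seq, i, i + len - 1)
      ra <- revcomp(a)
      for (j in 1:(n - len + 1)) {
        if (substr(seq, j, j + len - 1) == ra) best <- max(best, len)
      }
    }
  }
  best
}

# Gotoh global alignment score with affine gaps (gap run of length k costs
# open + k * extend), matching pairwiseAlignment's penalty convention.
r_global_align_score <- function(a, b, submat, open = 10, extend = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - (i - 1) * extend
  for (j in 2:(m + 1)) Y[1, j] <- -open - (j - 1) * extend
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Place a gene with a given mRNA-sense upstream context and CDS on either
# strand of a padded contig; returns a genome_record with one CDS.
fixture_gene_genome <- function(upstream, cds, strand = "+",
                                pad5 = 30, pad10 = 30, id = "FIXT") {
  set.seed(99)
  left <- random_dna_str(pad5); right <- random_dna_str(pad10)
  sense_block <- paste0(upstream, cds)
  if (strand == "+") {
    seqs <- paste0(left, sense_block, right)
    start <- nchar(left) + nchar(upstream) + 1
    end <- start + nchar(cds) - 1
  } else {
    seqs <- paste0(left, revcomp(sense_block), right)
    start <- nchar(left) + 1
    end <- nchar(left) + nchar(cds)
  }
  genome_record(id, seqs, tibble::tibble(
    locus_tag = "gene1", start = start, end = end, strand = strand))
}

# Same genome mirrored: reverse-complement the contig and flip every gene,
# which must leave all mRNA-sense extractions unchanged.
flip_genome <- function(genome) {
  L <- nchar(genome$sequence)
  g <- genome$genes
  genome_record(genome$id, revcomp(genome$sequence), tibble::tibble(
    locus_tag = g$locus_tag, name = g$name,
    start = L - g$end + 1L, end = L - g$start + 1L,
    strand = ifelse(g$strand == "+", "-", "+"), is_cds = g$is_cds))
}

# Two-gene GenBank fixture (one CDS per strand plus a tRNA), built from its
# parts so the printed coordinates are self-consistent by construction.
genbank_fixture_parts <- function() {
  up1 <- "ACGTACGTACGTAGGAGGTTTACCT"          # 1..25, SD at 14..19
  cds1 <- "ATGAAACGTGCTGAATAA"                # 26..43, plus strand
  mid <- "ACGTACGTACGTACGTACGT"               # 44..63
  cds2 <- "ATGCGTAAAGAATCATAA"                # sense of the minus-strand CDS
  tail <- paste(rep("ACGTTGCAAC", 4), collapse = "")  # 82..121
  seqs <- paste0(up1, cds1, mid, revcomp(cds2), tail)
  list(seq = seqs, cds1 = cds1, cds2 = cds2,
       cds1_start = 26L, cds1_end = 43L, cds2_start = 64L, cds2_end = 81L)
}

genbank_fixture_text <- function() {
  p <- genbank_fixture_parts()
  stopifnot(nchar(p$seq) == 121L)
  low <- tolower(p$seq)
  c("LOCUS       TESTREC              121 bp    DNA     linear   PHG 01-JAN-2026",
    "DEFINITION  synthetic two-gene test record.",
    "ACCESSION   TESTREC",
    "VERSION     TESTREC.1",
    "FEATURES             Location/Qualifiers",
    "     source          1..121",
    "                     /organism=\"synthetic construct\"",
    "     gene            26..43",
    "                     /locus_tag=\"TG_0001\"",
    "     CDS             26..43",
    "                     /locus_tag=\"TG_0001\"",
    "                     /gene=\"alpA\"",
    "                     /product=\"test protein A\"",
    "     CDS             complement(64..81)",
    "                     /locus_tag=\"TG_0002\"",
    "                     /product=\"test protein B\"",
    "     tRNA            100..110",
    "                     /locus_tag=\"TG_t001\"",
    "ORIGIN",
    paste0("        1 ", substr(low, 1, 60)),
    paste0("       61 ", substr(low, 61, 121)),
    "//")
}
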