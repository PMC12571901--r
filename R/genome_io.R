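#' Genome records
#'
#' A `genome_record` bundles one nucleotide sequence with its gene models.
#' Gene models live in a tibble with columns `locus_tag`, `name`, `start`,
#' `end`, `strand` and `is_cds`; coordinates are 1-based inclusive
#' (GenBank/GFF3 convention) and, on the minus strand, the start codon begins
#' at `end` and runs inward (reverse-complement convention).
#'
#' @param id Accession-like identifier of the contig.
#' @param sequence Nucleotide string over `{A,C,G,T,N}`; lower-case bases are
#'   upper-cased and `U` converted to `T`.
#' @param genes Data frame of gene models (see Details). Missing `name` and
#'   `is_cds` columns are filled with `NA` and `TRUE`.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, genes) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- normalize_dna(sequence)
  if (nchar(sequence) == 0L) abort("genome sequence is empty")
  assert_dna(sequence, allow_n = TRUE, arg = "sequence")
  genes <- as_tibble(genes)
  if (!"name" %in% names(genes)) genes$name <- NA_character_
  if (!"is_cds" %in% names(genes)) genes$is_cds <- TRUE
  if (!"joined" %in% names(genes)) genes$joined <- FALSE
  req <- c("locus_tag", "start", "end", "strand")
  miss <- setdiff(req, names(genes))
  if (length(miss)) abort(paste0("gene table lacks column(s): ",
                                 paste(miss, collapse = ", ")))
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (any(genes$start > genes$end)) abort("gene with start > end")
  if (!all(genes$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (any(genes$start < 1L) || any(genes$end > nchar(sequence))) {
    bad <- genes$locus_tag[genes$start < 1L | genes$end > nchar(sequence)]
    abort(sprintf("gene interval outside sequence bounds [1, %d]: %s",
                  nchar(sequence), paste(head(bad, 3), collapse = ", ")))
  }
  if (anyDuplicated(genes$locus_tag)) abort("duplicated locus_tag in gene table")
  genes <- genes[, c(req[1], "name", req[2:4], "is_cds", "joined")]
  structure(list(id = id, sequence = sequence, genes = genes),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp, %d gene model(s) (%d CDS)\n",
              x$id, format(nchar(x$sequence), big.mark = ","),
              nrow(x$genes), sum(x$genes$is_cds)))
  print(x$genes, n = 6)
  invisible(x)
}

#' Read a genome with annotation
#'
#' Reads a genome either from a FASTA file plus a GFF3 annotation, or from a
#' GenBank flat file. CDS features become gene models with `is_cds = TRUE`;
#' other annotated features are retained with `is_cds = FALSE`. Compound
#' (`join(...)`) locations are collapsed to their outer span, flagged in the
#' `joined` column and reported with a warning -- genes with introns are a
#' known hazard for antisense design against an annotated start codon.
#'
#' @param path Path to the FASTA (for `format = "fasta+gff3"`) or GenBank file.
#' @param format One of `"auto"`, `"fasta+gff3"`, `"genbank"`. `"auto"` picks
#'   by file extension (`.gb`, `.gbk`, `.gbff` -> GenBank).
#' @param annotation Path to the GFF3 file (required for `"fasta+gff3"`).
#' @return A [genome_record].
#' @examples
#' g <- synth_genome(synth_spec(n_genes = 2, seed = 1))$genome
#' fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
#' write_genome(g, fa, gff)
#' read_genome(fa, annotation = gff)
#' @export
read_genome <- function(path, format = c("auto", "fasta+gff3", "genbank"),
                        annotation = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|gbff)$", path, ignore.case = TRUE))
      "genbank" else "fasta+gff3"
  }
  if (format == "genbank") return(read_genbank(path))
  if (is.null(annotation)) {
    abort("format 'fasta+gff3' needs an `annotation` (GFF3) path")
  }
  if (!file.exists(annotation)) {
    abort(sprintf("file not found: %s", annotation))
  }
  dna <- Biostrings::readDNAStringSet(path)
  if (length(dna) == 0L) abort(sprintf("no FASTA record in %s", path))
  if (length(dna) > 1L) {
    warn(sprintf("%d FASTA records in %s; using the first", length(dna), path))
  }
  id <- sub("\\s.*$", "", names(dna)[1])
  gff <- rtracklayer::import(annotation, format = "gff3")
  keep <- as.character(GenomicRanges::seqnames(gff)) == id
  if (!any(keep)) {
    abort(sprintf("annotation %s has no features on sequence '%s'",
                  annotation, id))
  }
  gff <- gff[keep]
  md <- S4Vectors::mcols(gff)
  type <- as.character(md$type)
  consider <- type %in% c("CDS", "gene", "tRNA", "rRNA", "ncRNA")
  gff <- gff[consider]
  md <- S4Vectors::mcols(gff)
  type <- as.character(md$type)
  lt <- if ("locus_tag" %in% names(md)) as.character(md$locus_tag) else
    rep(NA_character_, length(gff))
  fallback_id <- if ("ID" %in% names(md)) as.character(md$ID) else
    rep(NA_character_, length(gff))
  lt <- ifelse(is.na(lt), fallback_id, lt)
  if (anyNA(lt)) {
    abort("GFF3 feature without locus_tag or ID attribute")
  }
  nm <- if ("Name" %in% names(md)) as.character(md$Name) else
    rep(NA_character_, length(gff))
  genes <- tibble(
    locus_tag = lt,
    name = nm,
    start = GenomicRanges::start(gff),
    end = GenomicRanges::end(gff),
    strand = as.character(GenomicRanges::strand(gff)),
    is_cds = type == "CDS"
  )
  if (any(genes$strand == "*")) abort("GFF3 feature without strand")
  ## a CDS split over several rows (same locus_tag) is a joined location
  genes <- genes |>
    group_by(.data$locus_tag, .data$is_cds) |>
    summarise(name = .data$name[1], start = min(.data$start),
              end = max(.data$end), strand = .data$strand[1],
              joined = n() > 1L, .groups = "drop") |>
    select("locus_tag", "name", "start", "end", "strand", "is_cds", "joined")
  ## keep the CDS row when a locus has both a gene and a CDS feature
  genes <- genes |>
    arrange(.data$locus_tag, dplyr::desc(.data$is_cds)) |>
    dplyr::distinct(.data$locus_tag, .keep_all = TRUE) |>
    arrange(.data$start, .data$locus_tag)
  if (any(genes$joined)) {
    warn(sprintf("joined (multi-part) location collapsed to outer span: %s",
                 paste(genes$locus_tag[genes$joined], collapse = ", ")))
  }
  genome_record(id, as.character(dna[[1]]), genes)
}

## Minimal GenBank flat-file reader: LOCUS/FEATURES/ORIGIN. Handles simple
## and complement() locations; join() locations are collapsed to their outer
## span and flagged. Enough for RefSeq phage/host records.
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) abort(sprintf("%s: no LOCUS line; not GenBank?", path))
  id <- strsplit(trimws(sub("^LOCUS", "", lines[locus_i[1]])), "\\s+")[[1]][1]
  acc_i <- grep("^VERSION", lines)
  if (length(acc_i)) {
    v <- strsplit(trimws(sub("^VERSION", "", lines[acc_i[1]])), "\\s+")[[1]][1]
    if (nzchar(v)) id <- v
  }
  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (!length(orig_i)) abort(sprintf("%s: no ORIGIN section", path))
  seq_lines <- lines[(orig_i[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- gsub("[^A-Za-z]", "", paste(seq_lines, collapse = ""))
  if (!nzchar(sequence)) abort(sprintf("%s: empty ORIGIN sequence", path))

  genes <- tibble(locus_tag = character(), name = character(),
                  start = integer(), end = integer(), strand = character(),
                  is_cds = logical(), joined = logical())
  if (length(feat_i)) {
    fl <- lines[(feat_i[1] + 1):(orig_i[1] - 1)]
    ## feature starts: exactly 5 leading spaces then a key
    starts <- grep("^     \\S", fl)
    if (length(starts)) {
      ends <- c(starts[-1] - 1L, length(fl))
      recs <- lapply(seq_along(starts), function(k) {
        block <- fl[starts[k]:ends[k]]
        key <- sub("^\\s+", "", sub("^(\\s+\\S+).*$", "\\1", block[1]))
        ## location may continue over lines until the first qualifier
        qual_start <- grep("^\\s+/", block)
        loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(block)
        loc <- gsub("\\s", "", paste(sub("^\\s+\\S+\\s*", "", block[1]),
                                     paste(block[seq_len(loc_end)[-1]] |>
                                             trimws(), collapse = ""),
                                     sep = ""))
        qual <- paste(block[-seq_len(loc_end)], collapse = " ")
        list(key = key, loc = loc, qual = qual)
      })
      keep <- vapply(recs, function(r)
        r$key %in% c("CDS", "gene", "tRNA", "rRNA", "ncRNA"), logical(1))
      recs <- recs[keep]
      if (length(recs)) {
        parsed <- lapply(seq_along(recs), function(k) {
          r <- recs[[k]]
          loc <- r$loc
          strand <- "+"
          if (grepl("^complement\\(", loc)) {
            strand <- "-"
            loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
          }
          joined <- grepl("^join\\(", loc)
          if (joined) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
          pos <- as.integer(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
          if (length(pos) < 1L) {
            abort(sprintf("%s: unparseable location '%s' (feature %d)",
                          path, r$loc, k))
          }
          grab <- function(q) {
            m <- regmatches(r$qual, regexec(sprintf('/%s="?([^"/]+)"?', q),
                                            r$qual))[[1]]
            if (length(m) == 2L) trimws(m[2]) else NA_character_
          }
          tibble(locus_tag = grab("locus_tag"), name = grab("gene"),
                 start = min(pos), end = max(pos), strand = strand,
                 is_cds = r$key == "CDS", joined = joined)
        })
        genes <- bind_rows(parsed)
        genes$locus_tag <- ifelse(is.na(genes$locus_tag),
                                  ifelse(is.na(genes$name),
                                         sprintf("feature_%04d",
                                                 seq_len(nrow(genes))),
                                         genes$name),
                                  genes$locus_tag)
        genes <- genes |>
          arrange(.data$locus_tag, dplyr::desc(.data$is_cds)) |>
          dplyr::distinct(.data$locus_tag, .keep_all = TRUE) |>
          arrange(.data$start, .data$locus_tag)
        if (any(genes$joined)) {
          warn(sprintf("joined location collapsed to outer span: %s",
                       paste(genes$locus_tag[genes$joined], collapse = ", ")))
        }
      }
    }
  }
  genome_record(id, sequence, genes)
}

#' Write a genome record to FASTA + GFF3
#'
#' The written pair round-trips through [read_genome()] to an identical
#' sequence and gene table; output is deterministic (stable feature order).
#'
#' @param genome A [genome_record].
#' @param fasta,gff Output paths.
#' @return Invisibly, `c(fasta, gff)`.
#' @export
write_genome <- function(genome, fasta, gff) {
  stopifnot(inherits(genome, "genome_record"))
  dna <- Biostrings::DNAStringSet(genome$sequence)
  names(dna) <- genome$id
  Biostrings::writeXStringSet(dna, fasta)
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = genome$id,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand
  )
  S4Vectors::mcols(gr)$type <- ifelse(g$is_cds, "CDS", "gene")
  S4Vectors::mcols(gr)$phase <- ifelse(g$is_cds, 0L, NA_integer_)
  S4Vectors::mcols(gr)$source <- "asodesignr"
  S4Vectors::mcols(gr)$ID <- g$locus_tag
  S4Vectors::mcols(gr)$locus_tag <- g$locus_tag
  S4Vectors::mcols(gr)$Name <- g$name
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(c(fasta, gff))
}

#' Extract translation-initiation-region (TIR) windows
#'
#' Returns the mRNA-sense sequence around each requested gene's start codon.
#' Offsets use the zeroless mRNA coordinate convention: `+1` is the A of the
#' start codon (AUG written ATG), `-1` the base immediately 5' of it; there
#' is no position 0, so the window `-37..+44` spans 81 nt. Minus-strand genes
#' are reverse-complemented so that `seq` always reads 5'->3' along the mRNA.
#' Windows running off a contig end are clipped and flagged `truncated`
#' (genomes are treated as linear).
#'
#' @param genome A [genome_record].
#' @param genes Character vector of locus tags (default: all CDS genes).
#' @param offset_from,offset_to Signed mRNA offsets of the window (defaults
#'   `-30..+15`, a ribosome-binding-site-centred window); neither may be 0.
#' @return Tibble with columns `gene`, `strand`, `offset_from`, `offset_to`,
#'   `seq`, `truncated`.
#' @examples
#' g <- synth_genome(synth_spec(n_genes = 3, seed = 1))$genome
#' extract_tir(g, offset_from = -21, offset_to = 6)
#' @export
extract_tir <- function(genome, genes = NULL, offset_from = -30L,
                        offset_to = 15L) {
  stopifnot(inherits(genome, "genome_record"))
  offset_from <- as.integer(offset_from); offset_to <- as.integer(offset_to)
  if (offset_from == 0L || offset_to == 0L) {
    abort("mRNA offsets have no position 0 (+1 is the A of the start codon)")
  }
  if (offset_from >= offset_to) abort("offset_from must be < offset_to")
  tab <- genome$genes
  if (is.null(genes)) {
    genes <- tab$locus_tag[tab$is_cds]
  } else {
    unknown <- setdiff(genes, tab$locus_tag)
    if (length(unknown)) {
      abort(sprintf("unknown locus_tag: %s", paste(unknown, collapse = ", ")))
    }
    not_cds <- genes[!tab$is_cds[match(genes, tab$locus_tag)]]
    if (length(not_cds)) {
      abort(sprintf("not a CDS feature: %s", paste(not_cds, collapse = ", ")))
    }
  }
  glen <- nchar(genome$sequence)
  idx <- off2idx(offset_from):off2idx(offset_to)
  rows <- lapply(genes, function(lt) {
    g <- tab[tab$locus_tag == lt, ]
    if (g$strand == "+") {
      pos <- g$start + idx - 1L
    } else {
      pos <- g$end - idx + 1L
    }
    keep <- pos >= 1L & pos <= glen
    truncated <- !all(keep)
    kidx <- idx[keep]
    if (!length(kidx)) {
      return(tibble(gene = lt, strand = g$strand,
                    offset_from = NA_integer_, offset_to = NA_integer_,
                    seq = "", truncated = TRUE))
    }
    pos <- pos[keep]
    if (g$strand == "+") {
      s <- substr(genome$sequence, min(pos), max(pos))
    } else {
      s <- revcomp(substr(genome$sequence, min(pos), max(pos)))
    }
    tibble(gene = lt, strand = g$strand,
           offset_from = idx2off(min(kidx)), offset_to = idx2off(max(kidx)),
           seq = s, truncated = truncated)
  })
  out <- bind_rows(rows)
  if (any(out$truncated)) {
    warn(sprintf("TIR window clipped at contig edge for: %s",
                 paste(out$gene[out$truncated], collapse = ", ")))
  }
  out
}

#' Write a TIR table to TSV
#'
#' @param tirs Tibble from [extract_tir()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tir_table <- function(tirs, path) {
  write.table(tirs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
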