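## Run code under a local, restorable RNG state so generators are pure
## functions of (spec, seed).
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, gc) {
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Specification for a synthetic annotated genome
#'
#' Describes a seeded synthetic genome that emulates the layout of an
#' annotated phage genome: protein-coding genes on alternating strands, each
#' led by a Shine-Dalgarno motif a fixed distance upstream of an ATG start
#' codon, embedded in random background of a given GC content.
#'
#' @param n_genes Number of genes (>= 1).
#' @param gene_len_range Range of CDS lengths in nt (rounded to codons).
#' @param sd_motif Planted Shine-Dalgarno motif (default `"AGGAGG"`).
#' @param sd_offset Signed mRNA position of the *last* motif base (default
#'   `-8`, i.e. a 7-nt spacer before the start codon -- canonical anti-SD
#'   spacing).
#' @param gc_content Background GC fraction (default 0.5).
#' @param seed Integer seed; identical specs generate identical genomes.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_genes, gene_len_range = c(150L, 900L),
                       sd_motif = "AGGAGG", sd_offset = -8L,
                       gc_content = 0.5, seed = 1L) {
  if (n_genes < 1L) abort("n_genes must be >= 1")
  stopifnot(gene_len_range[1] >= 60L, gene_len_range[1] <= gene_len_range[2],
            sd_offset < 0L, gc_content > 0, gc_content < 1)
  assert_dna(sd_motif, allow_n = FALSE, arg = "sd_motif")
  structure(list(n_genes = as.integer(n_genes),
                 gene_len_range = as.integer(gene_len_range),
                 sd_motif = toupper(sd_motif), sd_offset = as.integer(sd_offset),
                 gc_content = gc_content, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic annotated genome with known ground truth
#'
#' Each gene is built as an mRNA-sense cassette -- random upstream region
#' with the Shine-Dalgarno motif planted so that its last base sits at
#' `sd_offset`, an ATG start codon, random codons and a TAA stop -- and laid
#' onto the contig on alternating strands (minus-strand cassettes are
#' reverse-complemented), separated by random intergenic gaps. The truth
#' table records, for every gene, the planted coordinates and the exact
#' mRNA-sense sequence of the `-37..+44` window, sufficient to score every
#' downstream extraction and design call without re-deriving ground truth.
#'
#' @param spec A [synth_spec()].
#' @return List with elements `genome` (a [genome_record]), `truth` (tibble:
#'   `gene`, `strand`, `start`, `end`, `sd_seq`, `sd_from`, `sd_to`,
#'   `tir_seq` = planted `-37..+44` window) and `spec`.
#' @examples
#' synth_genome(synth_spec(n_genes = 2, seed = 1))$truth
#' @export
synth_genome <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_local_seed(spec$seed, {
    sd_len <- nchar(spec$sd_motif)
    sd_to <- spec$sd_offset                      # last motif base (mRNA offset)
    sd_from <- sd_to - sd_len + 1L
    up_len <- max(37L, abs(sd_from)) + 10L       # upstream context per cassette
    blocks <- character(2L * spec$n_genes + 1L)
    genes <- vector("list", spec$n_genes)
    truth <- vector("list", spec$n_genes)
    cur <- 0L
    for (i in seq_len(spec$n_genes)) {
      gap <- sample(60:150, 1)
      blocks[2L * i - 1L] <- random_dna(gap, spec$gc_content)
      cur <- cur + gap
      len <- sample(spec$gene_len_range[1]:spec$gene_len_range[2], 1)
      len <- 3L * (len %/% 3L)
      ncod <- len %/% 3L - 2L
      codons <- replicate(ncod, {
        repeat {
          cod <- random_dna(3L, spec$gc_content)
          if (!cod %in% c("TAA", "TAG", "TGA")) break
        }
        cod
      })
      cds <- paste0("ATG", paste(codons, collapse = ""), "TAA")
      up <- random_dna(up_len, spec$gc_content)
      ## plant the SD motif: sense position of mRNA offset o (< 0) within
      ## the cassette is up_len + o + 1
      substr(up, up_len + sd_from + 1L, up_len + sd_to + 1L) <- spec$sd_motif
      cassette <- paste0(up, cds)
      strand <- if (i %% 2L == 1L) "+" else "-"
      block <- if (strand == "+") cassette else revcomp(cassette)
      blocks[2L * i] <- block
      if (strand == "+") {
        start <- cur + up_len + 1L
        end <- start + len - 1L
      } else {
        start <- cur + 1L
        end <- cur + len
      }
      cur <- cur + nchar(block)
      lt <- sprintf("SYNG%04d", i)
      genes[[i]] <- tibble(locus_tag = lt, name = NA_character_,
                           start = start, end = end, strand = strand,
                           is_cds = TRUE)
      tir_seq <- paste0(substr(up, up_len - 37L + 1L, up_len),
                        substr(cds, 1L, 44L))
      truth[[i]] <- tibble(gene = lt, strand = strand, start = start,
                           end = end, sd_seq = spec$sd_motif,
                           sd_from = sd_from, sd_to = sd_to,
                           tir_seq = tir_seq)
    }
    blocks[2L * spec$n_genes + 1L] <- random_dna(sample(60:150, 1),
                                                 spec$gc_content)
    genome <- genome_record(sprintf("SYNGENOME_seed%d", spec$seed),
                            paste(blocks, collapse = ""), bind_rows(genes))
    list(genome = genome, truth = bind_rows(truth), spec = spec)
  })
}

#' Simulate a spot-count table with planted knockdown effects
#'
#' Generates the serial-dilution spot counts of a CFU/PFU screen with known
#' per-gene log10 titer effects. Control series are drawn around
#' `control_titer`; targeting series around `control_titer / 10^delta`.
#' Counts are Poisson around the expected number of plaque/colony forming
#' units in the spotted volume; a planted `delta = Inf` models complete
#' elimination (all targeting counts 0, i.e. below detection).
#'
#' @param true_deltas Tibble with columns `gene` and `delta_log10`
#'   (finite, or `Inf` for censored elimination).
#' @param control_titer Control titer per ml (default 1e9).
#' @param dilution_exponents Integer vector of spotted dilutions (default
#'   0:7, meaning 10^0 .. 10^-7).
#' @param assay `"PFU"` (default) or `"CFU"`.
#' @param spot_volume_ul Spotted volume (default 5).
#' @param seed Integer seed.
#' @return Spot-count tibble suitable for [titer_from_spots()] /
#'   [analyze_screen()].
#' @export
synth_screen_table <- function(true_deltas, control_titer = 1e9,
                               dilution_exponents = 0:7, assay = "PFU",
                               spot_volume_ul = 5, seed = 1L) {
  true_deltas <- as_tibble(true_deltas)
  stopifnot(all(c("gene", "delta_log10") %in% names(true_deltas)))
  if (any(is.na(true_deltas$delta_log10))) abort("delta_log10 must not be NA")
  vol_ml <- spot_volume_ul * 1e-3
  with_local_seed(seed, {
    rows <- lapply(seq_len(nrow(true_deltas)), function(i) {
      g <- true_deltas$gene[i]
      d <- true_deltas$delta_log10[i]
      titers <- c(control = control_titer,
                  targeting = if (is.infinite(d)) 0 else
                    control_titer / 10^d)
      purrr::imap(titers, function(ti, cond) {
        lambda <- ti * vol_ml / 10^dilution_exponents
        tibble(gene = g, aso_id = paste0(g, "_aso1"), condition = cond,
               assay = assay, dilution_exponent = dilution_exponents,
               count = rpois(length(lambda), lambda))
      }) |> bind_rows()
    })
    bind_rows(rows)
  })
}

#' Simulate an expression table with planted temporal classes
#'
#' Draws a late-vs-early log2 fold change per gene around a class-specific
#' mean and assigns adjusted P values below (significant classes) or above
#' (unclassified) the significance line used by [classify_temporal()].
#'
#' @param classes Tibble with columns `gene` and `class`
#'   (`early`/`middle_late`/`unclassified`), or a named character vector.
#' @param lfc_means Named class means of the log2 fold change.
#' @param noise_sd Standard deviation of the log2-fold-change noise
#'   (default 0.5).
#' @param seed Integer seed.
#' @return Tibble `gene`, `log2fc`, `padj`, `true_class`.
#' @export
synth_expression_table <- function(classes,
                                   lfc_means = c(early = -4, middle_late = 4,
                                                 unclassified = 0),
                                   noise_sd = 0.5, seed = 1L) {
  if (!is.data.frame(classes)) {
    classes <- tibble(gene = names(classes), class = unname(classes))
  }
  classes <- as_tibble(classes)
  stopifnot(all(c("gene", "class") %in% names(classes)),
            all(classes$class %in% names(lfc_means)))
  with_local_seed(seed, {
    n <- nrow(classes)
    lfc <- stats::rnorm(n, mean = lfc_means[classes$class], sd = noise_sd)
    sig <- classes$class != "unclassified"
    neglog10 <- ifelse(sig, runif(n, 11, 20), runif(n, 0, 9))
    tibble(gene = classes$gene, log2fc = lfc, padj = 10^(-neglog10),
           true_class = classes$class)
  })
}
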