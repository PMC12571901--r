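## Nearest-neighbor thermodynamic parameters for DNA/DNA duplexes
## (Allawi & SantaLucia 1997 unified set). dH kcal/mol, dS cal/(mol K).
.nn_dh <- c("AA" = -7.9, "AT" = -7.2, "TA" = -7.2, "CA" = -8.5, "GT" = -8.4,
            "CT" = -7.8, "GA" = -8.2, "CG" = -10.6, "GC" = -9.8, "GG" = -8.0,
            "TT" = -7.9, "TG" = -8.5, "AC" = -8.4, "AG" = -7.8, "TC" = -8.2,
            "CC" = -8.0)
.nn_ds <- c("AA" = -22.2, "AT" = -20.4, "TA" = -21.3, "CA" = -22.7,
            "GT" = -22.4, "CT" = -21.0, "GA" = -22.2, "CG" = -27.2,
            "GC" = -24.4, "GG" = -19.9,
            "TT" = -22.2, "TG" = -22.7, "AC" = -22.4, "AG" = -21.0,
            "TC" = -22.2, "CC" = -19.9)

#' Melting-temperature model for PNA/DNA duplexes
#'
#' Bundles every coefficient of the two-stage prediction used by
#' [melting_temperature()]: (1) a nearest-neighbor free-energy sum for the
#' corresponding DNA/DNA duplex (unified parameter set, terminal A/T and G/C
#' initiation terms, SantaLucia entropy salt correction), and (2) a linear
#' peptide-nucleic-acid correction
#' `Tm_PNA = b0 + b1 * Tm_NN + b2 * f_pyrimidine + b3 * L`
#' with the published PNA/DNA regression coefficients (Giesen et al. 1998)
#' as defaults. All values are plain list entries so alternative
#' parameterizations can be swapped in and are recorded with the results.
#'
#' @param conc_nM Per-strand concentration in nM used in the duplex
#'   transition term (default 5e5, i.e. 0.5 mM per strand -- the millimolar
#'   stock regime in which synthetic PNA oligomers are standardized).
#' @param na_mM Monovalent cation concentration in mM (default 50).
#' @param pna_coef Numeric vector `c(b0, b1, b2, b3)` of the linear PNA
#'   correction.
#' @return A list of class `tm_model`.
#' @export
tm_model <- function(conc_nM = 5e5, na_mM = 50,
                     pna_coef = c(b0 = 20.79, b1 = 0.83,
                                  b2 = -26.13, b3 = 0.44)) {
  stopifnot(conc_nM > 0, na_mM > 0, length(pna_coef) == 4L)
  structure(list(version = "nn-unified/pna-linear-1",
                 nn_dh = .nn_dh, nn_ds = .nn_ds,
                 init_at = c(dh = 2.3, ds = 4.1),
                 init_gc = c(dh = 0.1, ds = -2.8),
                 conc_nM = conc_nM, na_mM = na_mM,
                 pna_coef = setNames(as.numeric(pna_coef),
                                     c("b0", "b1", "b2", "b3"))),
            class = "tm_model")
}

## Nearest-neighbor Tm (deg C) for a DNA strand against its exact complement.
tm_nearest_neighbor <- function(seq, model) {
  n <- nchar(seq)
  bases <- strsplit(seq, "")[[1]]
  pairs <- substring(seq, 1:(n - 1), 2:n)
  dh <- sum(model$nn_dh[pairs])
  ds <- sum(model$nn_ds[pairs])
  for (b in bases[c(1, n)]) {
    term <- if (b %in% c("A", "T")) model$init_at else model$init_gc
    dh <- dh + term[["dh"]]
    ds <- ds + term[["ds"]]
  }
  ## SantaLucia (1998) entropy salt correction
  ds <- ds + 0.368 * (n - 1) * log(model$na_mM * 1e-3)
  selfcompl <- identical(seq, revcomp(seq))
  k <- if (selfcompl) model$conc_nM * 1e-9 else (model$conc_nM / 2) * 1e-9
  if (selfcompl) ds <- ds - 1.4
  (dh * 1000) / (ds + 1.987 * log(k)) - 273.15
}

#' Predicted melting temperature of a PNA/DNA duplex
#'
#' Predicts the duplex melting temperature of an antisense PNA strand bound
#' to its exactly complementary RNA/DNA target site. The model sums the
#' configured nearest-neighbor table for the duplex, then applies the linear
#' PNA correction using the pyrimidine fraction of the PNA strand (the
#' antisense oligomer). Mismatched-duplex thermodynamics are out of scope;
#' the two sequences must be exact reverse complements.
#'
#' @param aso_seq Character vector of antisense oligomer sequences, 5'->3',
#'   DNA alphabet.
#' @param target_site_seq Matching target site sequences (mRNA sense); must
#'   equal `revcomp(aso_seq)`. Defaults to exactly that.
#' @param model A [tm_model()].
#' @return Numeric vector of melting temperatures in deg C, reported to
#'   0.1 deg C.
#' @examples
#' melting_temperature("GACATAATTGT")
#' @export
melting_temperature <- function(aso_seq, target_site_seq = revcomp(aso_seq),
                                model = tm_model()) {
  stopifnot(inherits(model, "tm_model"))
  assert_dna(aso_seq, allow_n = FALSE, arg = "aso_seq")
  assert_dna(target_site_seq, allow_n = FALSE, arg = "target_site_seq")
  if (length(aso_seq) != length(target_site_seq)) {
    abort("aso_seq and target_site_seq lengths differ")
  }
  if (!all(target_site_seq == revcomp(aso_seq))) {
    abort("target_site_seq must be the exact reverse complement of aso_seq")
  }
  tm_nn <- vapply(aso_seq, tm_nearest_neighbor, numeric(1), model = model,
                  USE.NAMES = FALSE)
  f_pyr <- 1 - purine_fraction(aso_seq)
  b <- model$pna_coef
  round(b[["b0"]] + b[["b1"]] * tm_nn + b[["b2"]] * f_pyr +
          b[["b3"]] * nchar(aso_seq), 1)
}
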