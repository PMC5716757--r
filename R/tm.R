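# Nearest-neighbor melting temperature.

# Unified nearest-neighbor parameters (SantaLucia 1998, PNAS 95:1460):
# duplex formation enthalpy (kcal/mol) and entropy (cal/mol/K) per
# stacked dinucleotide, read 5'->3' on one strand. Complementary stacks
# share parameters (e.g. TT == AA).
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# Terminal (initiation) corrections per duplex end
INIT_DH <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
INIT_DS <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)

#' Hybridization conditions for melting-temperature prediction
#'
#' @param Na Monovalent cation concentration in mol/L (default 0.05,
#'   i.e. 50 mM, a standard PCR-buffer approximation).
#' @param oligo_conc Total single-strand concentration in mol/L
#'   (default 5e-7, i.e. 500 nM primer).
#' @return A named list used by [melting_temperature()].
#' @export
tm_conditions <- function(Na = 0.05, oligo_conc = 5e-7) {
  stopifnot(Na > 0, oligo_conc > 0)
  list(Na = Na, oligo_conc = oligo_conc)
}

#' Nearest-neighbor melting temperature
#'
#' Two-state nearest-neighbor model with the unified thermodynamic
#' parameter set (SantaLucia 1998): stacking terms summed over
#' dinucleotides, terminal initiation corrections, the entropic salt
#' correction `0.368 (N-1) ln[Na+]`, and the self-complementarity
#' symmetry correction. The model identity and conditions are attached
#' as attributes so design reports are reproducible.
#'
#' @param seq Primer sequence, 8-60 unambiguous bases.
#' @param conditions A [tm_conditions()] list.
#' @return Melting temperature in degrees Celsius, with attributes
#'   `model` and `conditions`.
#' @export
#' @examples
#' melting_temperature("ACGTACGTACGTACGTACGT")
melting_temperature <- function(seq, conditions = tm_conditions()) {
  assert_scalar_string(seq, "seq")
  seq <- toupper(seq)
  check_dna(seq, "seq", allow_n = FALSE)
  n <- nchar(seq)
  if (n < 8L || n > 60L)
    stop("sequence length must be 8-60 nt for the nearest-neighbor model",
         call. = FALSE)
  ch <- seq_chars(seq)
  stacks <- paste0(ch[-n], ch[-1L])
  dH <- sum(NN_DH[stacks]) + INIT_DH[[ch[1L]]] + INIT_DH[[ch[n]]]
  dS <- sum(NN_DS[stacks]) + INIT_DS[[ch[1L]]] + INIT_DS[[ch[n]]]
  self_comp <- identical(seq, revcomp(seq))
  if (self_comp) dS <- dS - 1.4
  dS <- dS + 0.368 * (n - 1L) * log(conditions$Na)
  ct_divisor <- if (self_comp) 1 else 4
  tm_k <- dH * 1000 / (dS + 1.9872 * log(conditions$oligo_conc / ct_divisor))
  structure(tm_k - 273.15,
            model = "nearest-neighbor (unified parameters, SantaLucia 1998)",
            conditions = conditions)
}
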