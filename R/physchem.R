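#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the declared pKa set (EMBOSS values),
#' termini included: each basic group contributes `1/(1 + 10^(pH - pKa))`,
#' each acidic group `-1/(1 + 10^(pKa - pH))`.
#'
#' @param sequence canonical amino-acid string.
#' @param ph pH value (may be a vector).
#' @param pka pKa set; see `PKA_SET` for the declared default.
#' @return numeric net charge, same length as `ph`.
#' @export
net_charge <- function(sequence, ph, pka = PKA_SET) {
  cc <- chars(toupper(sequence))
  pos_n <- vapply(names(pka$positive), function(a) sum(cc == a), numeric(1))
  neg_n <- vapply(names(pka$negative), function(a) sum(cc == a), numeric(1))
  vapply(ph, function(p) {
    plus <- 1 / (1 + 10^(p - pka$nterm)) +
      sum(pos_n / (1 + 10^(p - pka$positive)))
    minus <- 1 / (1 + 10^(pka$cterm - p)) +
      sum(neg_n / (1 + 10^(pka$negative - p)))
    plus - minus
  }, numeric(1))
}

#' Protein length, molecular weight and isoelectric point
#'
#' MW is the sum of average residue masses plus one water; pI is the pH at
#' which the net charge crosses zero, solved by bisection on (0, 14) well
#' past 0.01 pH resolution.
#'
#' @param sequence non-empty string over the 20 canonical amino acids.
#' @param pka pKa set used for the charge model.
#' @return list with `length` (residues), `mw` (Daltons), `pi` (pH units).
#' @examples
#' compute_physchem("GATEWAY")
#' @export
compute_physchem <- function(sequence, pka = PKA_SET) {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("empty sequence")
  cc <- chars(sequence)
  bad <- setdiff(unique(cc), AA_ALPHABET20)
  if (length(bad))
    stop("non-canonical residue(s): ", paste(bad, collapse = ", "))

  mw <- sum(AA_AVG_MASS[cc]) + WATER_MASS

  lo <- 0; hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid, pka) > 0) lo <- mid else hi <- mid
  }
  list(length = length(cc), mw = unname(mw), pi = (lo + hi) / 2)
}
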