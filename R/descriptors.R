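#' @include AllClasses.R
NULL

# Kyte-Doolittle hydropathy index
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2)

.HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W", "C", "P")

# EMBOSS pKa values
.PKA_EMBOSS <- list(
  nterm = 8.6, cterm = 3.6,
  basic = c(K = 10.8, R = 12.5, H = 6.5),
  acidic = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

#' Henderson-Hasselbalch net charge of a peptide
#'
#' `Z(pH) = sum over basic groups 1/(1 + 10^(pH - pKa)) - sum over acidic
#' groups 1/(1 + 10^(pKa - pH))`, including the free termini. Strictly
#' decreasing in pH, so the isoelectric point is unique.
#'
#' @param sequence one-letter peptide sequence.
#' @param pH numeric vector of pH values.
#' @param pKa pKa set (default: EMBOSS values).
#' @return net charge at each pH.
#' @export
peptideCharge <- function(sequence, pH, pKa = .PKA_EMBOSS) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  basicPka <- c(pKa$nterm, unname(pKa$basic[aa[aa %in% names(pKa$basic)]]))
  acidicPka <- c(pKa$cterm, unname(pKa$acidic[aa[aa %in% names(pKa$acidic)]]))
  vapply(pH, function(p)
    sum(1 / (1 + 10^(p - basicPka))) - sum(1 / (1 + 10^(acidicPka - p))),
    numeric(1))
}

#' Physicochemical descriptors of a client segment
#'
#' GRAVY (mean Kyte-Doolittle hydropathy), the percentage of hydrophobic
#' residues (A, V, L, I, M, F, W, C, P), and the isoelectric point,
#' solved by bisection on the Henderson-Hasselbalch net charge (including
#' termini) to `|Z| < 1e-4`. Used to tabulate the luminal segments of
#' different chaperone clients side by side.
#'
#' @param sequence one-letter peptide sequence (standard alphabet).
#' @param pKa pKa set (default: EMBOSS values; configurable because
#'   published peptide calculators differ in their internal sets).
#' @return list of class `SegmentDescriptors`: `sequence`, `gravy`,
#'   `pctHydrophobic`, `pI`.
#' @examples
#' segmentDescriptors("AAAA")$pI  # midpoint of the two termini: 6.10
#' @export
segmentDescriptors <- function(sequence, pKa = .PKA_EMBOSS) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (!length(aa)) stop("empty sequence", call. = FALSE)
  unknown <- setdiff(aa, names(.KD))
  if (length(unknown))
    stop("unknown residue letter(s): ", paste(unique(unknown), collapse = ", "),
         call. = FALSE)
  lo <- 0; hi <- 14
  zlo <- peptideCharge(sequence, lo, pKa)
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    z <- peptideCharge(sequence, mid, pKa)
    if (abs(z) < 1e-4) break
    if (sign(z) == sign(zlo)) lo <- mid else hi <- mid
  }
  structure(list(sequence = paste(aa, collapse = ""),
                 gravy = mean(.KD[aa]),
                 pctHydrophobic = 100 * mean(aa %in% .HYDROPHOBIC),
                 pI = mid),
            class = "SegmentDescriptors")
}

#' @export
print.SegmentDescriptors <- function(x, ...) {
  cat(sprintf("SegmentDescriptors: %s\n  GRAVY %.3f, %.1f%% hydrophobic, pI %.2f\n",
              x$sequence, x$gravy, x$pctHydrophobic, x$pI))
  invisible(x)
}
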