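## Protein physicochemistry: molecular weight, isoelectric point, GRAVY.
## Conventions follow ExPASy ProtParam: average (not monoisotopic) residue
## masses, Bjellqvist-style pKa values, Kyte-Doolittle hydropathy.

## Average residue masses in daltons (monomer minus water).
AA_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326)
WATER_MASS <- 18.01524

## Kyte-Doolittle hydropathy scale; bounds are [-4.5, 4.5].
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

## Default pKa set (Bjellqvist/ExPASy-style). `nterm`/`cterm` are the
## termini; the rest are side chains. Positive groups: nterm, K, R, H.
PKA_DEFAULT <- c(nterm = 7.5, cterm = 3.55,
                 D = 4.05, E = 4.45, C = 9.0, Y = 10.0,
                 H = 5.98, K = 10.0, R = 12.0)

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water, as in ExPASy ProtParam.
#' The ambiguous residue `X` contributes the mean of the 20 standard
#' residue masses.
#'
#' @param sequence character vector of amino-acid sequences.
#' @param kda return kilodaltons (default) instead of daltons.
#' @return numeric vector of masses.
#' @examples
#' molecular_weight("G", kda = FALSE)  # 75.07 Da
#' @export
molecular_weight <- function(sequence, kda = TRUE) {
  out <- vapply(sequence, function(s) {
    chars <- .check_protein_seq(s)
    if (length(chars) == 0L) .stopf("empty sequence has no molecular weight")
    masses <- AA_MASS[chars]
    masses[chars == "X"] <- mean(AA_MASS)
    sum(masses) + WATER_MASS
  }, numeric(1), USE.NAMES = FALSE)
  if (kda) out / 1000 else out
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the termini and the ionizable side
#' chains D, E, C, Y (acidic) and K, R, H (basic).
#'
#' @param sequence single amino-acid string.
#' @param ph pH value(s).
#' @param pka named pKa vector (see `PKA_DEFAULT` layout).
#' @return numeric vector of net charges, one per `ph`.
#' @export
net_charge <- function(sequence, ph, pka = PKA_DEFAULT) {
  chars <- .check_protein_seq(sequence)
  n <- table(factor(chars, levels = names(AA_MASS)))
  pos_counts <- c(nterm = 1, K = n[["K"]], R = n[["R"]], H = n[["H"]])
  neg_counts <- c(cterm = 1, D = n[["D"]], E = n[["E"]],
                  C = n[["C"]], Y = n[["Y"]])
  vapply(ph, function(p) {
    pos <- sum(pos_counts / (1 + 10^(p - pka[names(pos_counts)])))
    neg <- sum(neg_counts / (1 + 10^(pka[names(neg_counts)] - p)))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point by bisection on the net-charge curve
#'
#' The net charge is strictly decreasing in pH, so bisection on
#' \[0, 14\] converges to the unique pH where the charge magnitude falls
#' below `tol`.
#'
#' @param sequence character vector of amino-acid sequences.
#' @param pka named pKa vector.
#' @param tol convergence tolerance on |net charge| (default 1e-4).
#' @return numeric vector of pI values in pH units.
#' @export
isoelectric_point <- function(sequence, pka = PKA_DEFAULT, tol = 1e-4) {
  vapply(sequence, function(s) {
    lo <- 0; hi <- 14
    repeat {
      mid <- (lo + hi) / 2
      q <- net_charge(s, mid, pka)
      if (abs(q) < tol || (hi - lo) < 1e-12) return(mid)
      if (q > 0) lo <- mid else hi <- mid
    }
  }, numeric(1), USE.NAMES = FALSE)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues; negative values
#' indicate hydrophilic proteins. `X` contributes 0.
#'
#' @param sequence character vector of amino-acid sequences.
#' @return numeric vector in \[-4.5, 4.5\].
#' @examples
#' gravy("AAA")  # 1.8
#' @export
gravy <- function(sequence) {
  vapply(sequence, function(s) {
    chars <- .check_protein_seq(s)
    if (length(chars) == 0L) .stopf("empty sequence has no GRAVY")
    h <- KD_HYDROPATHY[chars]
    h[chars == "X"] <- 0
    mean(h)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Physicochemical profile of a protein set
#'
#' @param proteins named character vector (or `AAStringSet`).
#' @param pka named pKa vector for the pI computation.
#' @return data.frame with `protein_id`, `length_aa`, `mw_kda`, `pi`,
#'   `gravy` and `has_ambiguous` (TRUE when the sequence contains `X`).
#' @export
physchem_profile <- function(proteins, pka = PKA_DEFAULT) {
  if (methods::is(proteins, "XStringSet")) proteins <- as.character(proteins)
  if (is.null(names(proteins)))
    names(proteins) <- paste0("protein", seq_along(proteins))
  data.frame(
    protein_id = names(proteins),
    length_aa = nchar(proteins),
    mw_kda = molecular_weight(proteins),
    pi = isoelectric_point(proteins, pka = pka),
    gravy = gravy(proteins),
    has_ambiguous = grepl("X", proteins, fixed = TRUE),
    stringsAsFactors = FALSE, row.names = NULL)
}
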