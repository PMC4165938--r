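# Physicochemical properties of mature peptides: average molecular weight
# and Henderson-Hasselbalch net charge.

# average (isotope-abundance weighted) residue masses, Da
AA_AVG_MASS <- c(
  G =  57.0519, A =  71.0788, S =  87.0782, P =  97.1167, V =  99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
MASS_WATER <- 18.0153

#' Default pKa table for net-charge estimation
#'
#' Values in the family used by classic protein-calculator tools: basic
#' groups (N-terminus, K, R, H) contribute positive charge, acidic groups
#' (C-terminus, D, E, C, Y) negative.
#'
#' @param count_disulfide_cys If `FALSE` (default used via the
#'   `n_disulfides` argument of [net_charge()]), all cysteines titrate.
#' @return Named list with `basic` and `acidic` pKa vectors and the flag.
#' @export
default_pka_table <- function(count_disulfide_cys = FALSE) {
  tab <- list(
    basic = c(Nterm = 8.0, K = 10.0, R = 12.0, H = 6.5),
    acidic = c(Cterm = 3.1, D = 4.4, E = 4.4, C = 8.5, Y = 10.0),
    exclude_disulfide_cys = !count_disulfide_cys
  )
  stopifnot(all(unlist(tab[c("basic", "acidic")]) > 0),
            all(unlist(tab[c("basic", "acidic")]) < 14))
  tab
}

#' Average molecular weight of a peptide
#'
#' Sum of average residue masses plus one water; the reduced (free-thiol)
#' form is reported, i.e. no -2H per disulfide correction.
#'
#' @param peptide Peptide string over the 20 standard amino acids.
#' @return Mass in Da.
#' @examples
#' average_mw("G")   # 75.07
#' average_mw("GG")  # 132.12
#' @export
average_mw <- function(peptide) {
  aa <- strsplit(toupper(peptide), "", fixed = TRUE)[[1]]
  if (length(aa) == 0L) stop_fmt("empty peptide")
  bad <- setdiff(unique(aa), names(AA_AVG_MASS))
  if (length(bad)) stop_fmt("nonstandard residue '%s' in peptide", bad[1])
  sum(AA_AVG_MASS[aa]) + MASS_WATER
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable groups:
#' \deqn{NC = \sum_{basic} \frac{1}{1+10^{pH-pKa}} -
#'        \sum_{acidic} \frac{1}{1+10^{pKa-pH}}}
#' Cysteines engaged in disulfides can be excluded from titration via
#' `n_disulfides` (two cysteines per bond).
#'
#' @param peptide Peptide string.
#' @param pH pH, in (0, 14). Default 7.0, the convention used for
#'   defensin net-charge catalogs.
#' @param pka pKa table from [default_pka_table()].
#' @param n_disulfides Number of disulfide bonds whose cysteines are
#'   excluded from titration (default 0, fully reduced).
#' @return Net charge (elementary charge units).
#' @export
net_charge <- function(peptide, pH = 7.0, pka = default_pka_table(),
                       n_disulfides = 0) {
  stopifnot(pH > 0, pH < 14)
  aa <- strsplit(toupper(peptide), "", fixed = TRUE)[[1]]
  if (length(aa) == 0L) stop_fmt("empty peptide")
  n_cys <- sum(aa == "C")
  if (2L * n_disulfides > n_cys) {
    stop_fmt("%d disulfides need %d cysteines but peptide has %d",
             n_disulfides, 2L * n_disulfides, n_cys)
  }
  counts <- table(factor(aa, levels = AA_STANDARD))
  pos_term <- 1 / (1 + 10^(pH - pka$basic[["Nterm"]]))
  neg_term <- -1 / (1 + 10^(pka$acidic[["Cterm"]] - pH))
  z <- pos_term + neg_term
  for (g in c("K", "R", "H")) {
    z <- z + counts[[g]] / (1 + 10^(pH - pka$basic[[g]]))
  }
  cys_eff <- if (isTRUE(pka$exclude_disulfide_cys)) {
    n_cys - 2L * n_disulfides
  } else n_cys
  for (g in c("D", "E", "Y")) {
    z <- z - counts[[g]] / (1 + 10^(pka$acidic[[g]] - pH))
  }
  z <- z - cys_eff / (1 + 10^(pka$acidic[["C"]] - pH))
  unname(z)
}

#' Physicochemical table for a set of mature peptides
#'
#' @param peptides Named character vector of mature peptide sequences.
#' @param pH pH for net charge (default 7.0).
#' @return Data frame with `name`, `size`, `mw`, `nc`.
#' @export
physchem_table <- function(peptides, pH = 7.0) {
  data.frame(
    name = names(peptides) %||% as.character(seq_along(peptides)),
    size = nchar(peptides),
    mw = round(vapply(peptides, average_mw, numeric(1)), 0),
    nc = round(vapply(peptides, net_charge, numeric(1), pH = pH), 1),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
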