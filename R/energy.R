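#' Hydrogen-bond hybridization energy scheme
#'
#' The duplex energy model counts hydrogen bonds over the antiparallel
#' miRNA:site pairing and converts the count to a free energy with a fixed
#' per-bond constant. Watson-Crick G:C pairs contribute 3 bonds and A:U
#' pairs 2; the G:U wobble and the noncanonical A:C pair have configurable
#' weights (defaults 1 and 0). The default per-bond energy is 121/57
#' kJ/mol, calibrated so that the perfect 22-nt miR-619-5p duplex
#' (13 G:C + 9 A:U = 57 bonds) scores dG = -121 kJ/mol.
#'
#' The headline dG/dGm ratio is a quotient of bond counts and is therefore
#' invariant under rescaling `e_bond`: the 100% complete-complementarity
#' criterion does not depend on the calibration.
#'
#' @param gc,au,gu,ac Hydrogen bonds per pair class (non-negative
#'   integers; `gu` must not exceed `au`).
#' @param e_bond Energy per hydrogen bond, kJ/mol, positive magnitude.
#' @return An object of class `energy_scheme`.
#' @examples
#' energy_scheme()
#' energy_scheme(gu = 0)  # strict Watson-Crick-only scoring
#' @export
energy_scheme <- function(gc = 3L, au = 2L, gu = 1L, ac = 0L,
                          e_bond = 121 / 57) {
  bonds <- c(GC = as.integer(gc), AU = as.integer(au),
             GU = as.integer(gu), AC = as.integer(ac))
  if (any(is.na(bonds)) || any(bonds < 0L)) {
    stop("bond counts must be non-negative integers")
  }
  if (bonds[["GU"]] > bonds[["AU"]]) {
    stop("the G:U wobble cannot outscore the A:U Watson-Crick pair")
  }
  if (!is.numeric(e_bond) || e_bond <= 0) stop("e_bond must be > 0")
  structure(list(bonds = bonds, e_bond = e_bond), class = "energy_scheme")
}

#' @export
print.energy_scheme <- function(x, ...) {
  cat(sprintf("<energy_scheme> G:C=%d A:U=%d G:U=%d A:C=%d bonds; %.4f kJ/mol per bond\n",
              x$bonds[["GC"]], x$bonds[["AU"]], x$bonds[["GU"]],
              x$bonds[["AC"]], x$e_bond))
  invisible(x)
}

#' Read an energy scheme from a YAML config file
#'
#' Recognized keys: `gc`, `au`, `gu`, `ac`, `e_bond`; absent keys keep
#' their defaults.
#'
#' @param path YAML file.
#' @return An `energy_scheme`.
#' @export
read_energy_scheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(energy_scheme, cfg[names(cfg) %in% c("gc", "au", "gu", "ac", "e_bond")])
}

#' Classify one miRNA:site base pairing
#'
#' Pair classes are symmetric: (G, C) and (C, G) are both `GC`. `N` on
#' either side is a `MISMATCH`.
#'
#' @param mirna_base,site_base Single normalized RNA letters.
#' @return One of `"GC"`, `"AU"`, `"GU"`, `"AC"`, `"MISMATCH"`.
#' @export
classify_pair <- function(mirna_base, site_base) {
  key <- paste(sort(c(mirna_base, site_base)), collapse = "")
  switch(key, CG = "GC", AU = "AU", GU = "GU", AC = "AC", "MISMATCH")
}

# Integer base codes: A=1 C=2 G=3 U=4 N/other=5.
seq_codes <- function(seq) {
  m <- match(strsplit(seq, "", fixed = TRUE)[[1L]], RNA_BASES)
  m[is.na(m)] <- 5L
  m
}

# 5x5 symmetric bond-count lookup over coded bases.
bond_matrix <- function(scheme) {
  b <- matrix(0L, 5L, 5L)
  set <- function(x, y, v) {
    i <- match(x, RNA_BASES); j <- match(y, RNA_BASES)
    b[i, j] <<- v; b[j, i] <<- v
  }
  set("G", "C", scheme$bonds[["GC"]])
  set("A", "U", scheme$bonds[["AU"]])
  set("G", "U", scheme$bonds[["GU"]])
  set("A", "C", scheme$bonds[["AC"]])
  b
}

#' Count hydrogen bonds in an antiparallel miRNA:site duplex
#'
#' The miRNA (5'->3') is paired antiparallel against the site (5'->3'):
#' miRNA position i pairs site position L-i+1.
#'
#' @param mirna A `mature_mirna` or RNA string.
#' @param site Site sequence, same length as the miRNA.
#' @param scheme An [energy_scheme()].
#' @return Integer total bond count.
#' @examples
#' hydrogen_bonds(mir619(), reverse_complement(mir619()$sequence))  # 57
#' @export
hydrogen_bonds <- function(mirna, site, scheme = energy_scheme()) {
  mirna <- as_mirna(mirna)
  site <- normalize_seq(site, "RNA")
  if (nchar(site) != mirna$length) {
    stop(sprintf("site length %d != miRNA length %d",
                 nchar(site), mirna$length))
  }
  b <- bond_matrix(scheme)
  mcode <- rev(seq_codes(mirna$sequence))
  scode <- seq_codes(site)
  sum(b[cbind(mcode, scode)])
}

#' Score a miRNA:site duplex: dG, dGm and their percentage ratio
#'
#' `dg` is the hybridization free energy of the duplex, `dg_max` the
#' energy against the miRNA's perfect complement, and `ratio` the
#' percentage `100 * dg / dg_max` -- the site-acceptance statistic. The
#' ratio equals 100 exactly when the site is the miRNA's reverse
#' complement (given a wobble weight below the A:U weight).
#'
#' @inheritParams hydrogen_bonds
#' @return An object of class `duplex_score`: a list with `bonds`,
#'   `bonds_max`, `dg`, `dg_max` (kJ/mol, non-positive) and `ratio` (%).
#' @examples
#' delta_g(mir619(), "GGCUCAUGCCUGUAAUCCCAGC")  # dG = -121, ratio = 100
#' @export
delta_g <- function(mirna, site, scheme = energy_scheme()) {
  mirna <- as_mirna(mirna)
  bonds <- hydrogen_bonds(mirna, site, scheme)
  bonds_max <- hydrogen_bonds(mirna, reverse_complement(mirna$sequence), scheme)
  structure(
    list(bonds = bonds, bonds_max = bonds_max,
         dg = -scheme$e_bond * bonds, dg_max = -scheme$e_bond * bonds_max,
         ratio = 100 * bonds / bonds_max),
    class = "duplex_score"
  )
}

#' @export
print.duplex_score <- function(x, ...) {
  cat(sprintf("<duplex_score> dG = %.2f kJ/mol, dGm = %.2f kJ/mol, dG/dGm = %.2f%%\n",
              x$dg, x$dg_max, x$ratio))
  invisible(x)
}
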