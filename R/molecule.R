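# Molecular geometry handling and the smoothed nuclear attraction
# potential.  All internal coordinates are in bohr; XYZ files are read in
# Angstrom per the format convention.

element_Z <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
               F = 9, Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15,
               S = 16, Cl = 17, Ar = 18, K = 19, Ca = 20, Sc = 21, Ti = 22,
               V = 23, Cr = 24, Mn = 25, Fe = 26, Co = 27, Ni = 28, Cu = 29,
               Zn = 30, Ga = 31, Ge = 32, As = 33, Se = 34, Br = 35, Kr = 36)

ANGSTROM_TO_BOHR <- 1.8897259886

#' Build a molecule
#'
#' @param symbols character vector of element symbols.
#' @param coords 3 x n matrix of nuclear positions in bohr.
#' @param charge net charge (default 0).
#' @return an object of class \code{mw_molecule} with fields
#'   \code{symbols}, \code{Z}, \code{coords} (bohr), \code{charge},
#'   \code{nelec}.
#' @export
mw_molecule <- function(symbols, coords, charge = 0L) {
  coords <- matrix(as.numeric(coords), nrow = 3)
  stopifnot(length(symbols) == ncol(coords))
  unknown <- setdiff(symbols, names(element_Z))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  Z <- unname(element_Z[symbols])
  nelec <- sum(Z) - charge
  if (nelec < 1) stop("no electrons left at this charge")
  structure(list(symbols = symbols, Z = Z, coords = coords,
                 charge = as.integer(charge), nelec = as.integer(nelec)),
            class = "mw_molecule")
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ: an atom-count line, a comment line, then one
#' \code{symbol x y z} line per atom in Angstrom.  Coordinates are
#' converted to bohr (1 Angstrom = 1.8897259886 bohr).
#'
#' @param path file path.
#' @param charge net charge (default 0).
#' @return an \code{mw_molecule}.
#' @export
read_xyz <- function(path, charge = 0L) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty XYZ file: ", path)
  nat <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(nat))
    stop("malformed atom-count line 1 in ", path, ": '", lines[1], "'")
  if (length(lines) < nat + 2)
    stop("XYZ file ", path, " declares ", nat, " atoms but has only ",
         length(lines) - 2, " coordinate lines")
  syms <- character(nat)
  xyz <- matrix(0, 3, nat)
  for (i in seq_len(nat)) {
    tok <- strsplit(trimws(lines[i + 2]), "\\s+")[[1]]
    if (length(tok) < 4)
      stop("malformed coordinate line ", i + 2, " in ", path)
    syms[i] <- tok[1]
    xyz[, i] <- as.numeric(tok[2:4]) * ANGSTROM_TO_BOHR
  }
  mw_molecule(syms, xyz, charge)
}

#' Nuclear repulsion energy
#' @param mol an \code{mw_molecule}.
#' @return \eqn{\sum_{a<b} Z_a Z_b / |R_a - R_b|} in Hartree.
#' @export
nuclear_repulsion <- function(mol) {
  n <- length(mol$Z)
  e <- 0
  if (n >= 2) for (a in 1:(n - 1)) for (b in (a + 1):n) {
    e <- e + mol$Z[a] * mol$Z[b] / sqrt(sum((mol$coords[, a] - mol$coords[, b])^2))
  }
  e
}

# regularized Coulomb shape: u(x) -> 1/x for large x, finite at x = 0,
# constructed so that the induced energy error integrates to O(prec)
smoothed_u <- function(x) {
  small <- x < 1e-8
  x2 <- x^2
  out <- ifelse(small, 2 / sqrt(pi),
                pracma::erf(x) / ifelse(small, 1, x)) +
    (exp(-x2) + 16 * exp(-4 * x2)) / (3 * sqrt(pi))
  out
}

#' Smoothed nuclear attraction potential as a tree
#'
#' Projects \eqn{v(r) = -\sum_a Z_a\, u(|r - R_a|/c_a)/c_a}, the standard
#' regularized Coulomb form with per-nucleus smoothing length
#' \eqn{c_a = (0.00435\, p / Z_a^5)^{1/3}} so that the induced energy error
#' per nucleus is of order \eqn{p}.  The potential is negative everywhere.
#'
#' @param mol an \code{mw_molecule}.
#' @param basis an \code{mw_basis}.
#' @param prec precision \eqn{p} controlling both the smoothing length and
#'   the projection threshold (the projection runs at \code{prec/10}).
#' @param L domain half-width (bohr).
#' @param maxdepth projection depth cap.
#' @return an \code{mw_tree}.
#' @export
nuclear_potential <- function(mol, basis, prec, L = 32, maxdepth = 20L) {
  cs <- (0.00435 * prec / mol$Z^5)^(1 / 3)
  if (any(apply(abs(mol$coords), 2, max) + 10 * cs > L))
    stop("nucleus within smoothing length of the domain boundary")
  f <- function(x, y, z) {
    v <- 0
    for (a in seq_along(mol$Z)) {
      r <- sqrt((x - mol$coords[1, a])^2 + (y - mol$coords[2, a])^2 +
                (z - mol$coords[3, a])^2)
      v <- v - mol$Z[a] * smoothed_u(r / cs[a]) / cs[a]
    }
    v
  }
  suppressWarnings(
    mw_project(f, basis, prec / 10, L = L, maxdepth = maxdepth,
               guide = mol$coords, guide_scale = 8L))
}

#' @export
print.mw_molecule <- function(x, ...) {
  cat(sprintf("<mw_molecule %s charge=%d nelec=%d>\n",
              paste(x$symbols, collapse = ""), x$charge, x$nelec))
  invisible(x)
}
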