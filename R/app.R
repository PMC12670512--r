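# Run orchestration: configuration handling, output artifacts, and the
# drivers behind the command-line entry points (inst/exec).  The CLI
# commands are thin wrappers over these functions:
#   run   - full orbital optimization from an XYZ geometry
#   dmrg  - DMRG + gradients from an FCIDUMP file (orbital-agnostic half)
#   scan  - bond-length scan driver for diatomics
#   check - configuration validation only

#' Parse a flat key: value configuration file
#'
#' Lines of the form \code{key: value} (or \code{key = value}); blank
#' lines and \code{#} comments ignored.
#' @param path file path.
#' @return named list of strings.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("malformed configuration line: '", ln, "'")
    out[[m[2]]] <- trimws(m[3])
  }
  out
}

#' Validate a run configuration
#'
#' @param cfg named list (strings or numbers) with at least
#'   \code{geometry} and \code{M}; optional \code{N}, \code{p}, \code{k},
#'   \code{delta}, \code{L}, \code{maxiter}, \code{seed}, \code{mode},
#'   \code{out}.
#' @return normalized list with typed fields; stops with a message on an
#'   invalid configuration.
#' @export
validate_config <- function(cfg) {
  num <- function(name, default, lo = -Inf) {
    v <- if (is.null(cfg[[name]])) default else as.numeric(cfg[[name]])
    if (is.na(v) || v < lo) stop("invalid ", name, " in configuration")
    v
  }
  mode <- cfg$mode %||% "optimize"
  if (!mode %in% c("optimize", "dmrg-only", "integrals-only"))
    stop("mode must be optimize, dmrg-only or integrals-only")
  out <- list(
    geometry = cfg$geometry,
    M = as.integer(num("M", NA, 1)),
    p = num("p", 1e-5, 1e-12),
    k = as.integer(num("k", 9, 1)),
    delta = num("delta", 1e-5, 0),
    L = num("L", 32, 1),
    maxiter = as.integer(num("maxiter", 25, 1)),
    seed = as.integer(num("seed", 0, 0)),
    charge = as.integer(num("charge", 0)),
    mode = mode,
    out = cfg$out %||% "mwdmrg_out"
  )
  if (mode != "dmrg-only") {
    if (is.null(out$geometry)) stop("configuration lacks a geometry path")
    if (!file.exists(out$geometry)) stop("geometry file not found: ", out$geometry)
    mol <- read_xyz(out$geometry, out$charge)
    if (out$M < ceiling(mol$nelec / 2)) stop("M must be at least N/2")
  }
  out
}

#' Run a full optimization with output artifacts
#'
#' Writes the per-iteration trace CSV, a JSON run summary, orbital
#' checkpoints and an FCIDUMP of the final integrals into \code{cfg$out}.
#'
#' @param cfg validated configuration (see \code{\link{validate_config}}).
#' @return the \code{mwdmrg_fit}, invisibly; exit-style status in
#'   attribute \code{status} (0 converged, 3 non-convergence).
#' @export
run_optimization <- function(cfg) {
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  mol <- read_xyz(cfg$geometry, cfg$charge)
  if (cfg$mode == "integrals-only") {
    basis <- mw_basis(cfg$k)
    orbs <- guess_orbitals(mol, cfg$M, basis, cfg$p, cfg$L)
    ints <- mw_integrals(orbs, mol, cfg$p)
    fcidump_write(ints$h, ints$g, ints$ecore, mol$nelec,
                  file.path(cfg$out, "integrals.fcidump"))
    out <- list(integrals = ints, molecule = mol)
    attr(out, "status") <- 0L
    return(invisible(out))
  }
  fit <- mwdmrg(mol, M = cfg$M, k = cfg$k, prec = cfg$p, delta = cfg$delta,
                L = cfg$L, maxiter = cfg$maxiter,
                dmrg = list(seed = cfg$seed))
  utils::write.csv(fit$trace, file.path(cfg$out, "trace.csv"),
                   row.names = FALSE)
  summ <- list(energy = fit$energy, converged = fit$converged,
               iterations = fit$iterations,
               kernel_coefficients = fit$kernel_hist[[length(fit$kernel_hist)]],
               nuclear_repulsion = fit$nuclear_repulsion,
               M = fit$M, N = fit$N, k = fit$k, p = fit$prec,
               delta = fit$delta, L = fit$L)
  jsonlite::write_json(summ, file.path(cfg$out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  mw_save(fit$orbitals$orb, file.path(cfg$out, "orbitals.chk"))
  if (!is.null(fit$integrals$h))
    fcidump_write(fit$integrals$h, fit$integrals$g, fit$integrals$ecore,
                  fit$N, file.path(cfg$out, "integrals.fcidump"))
  attr(fit, "status") <- if (fit$converged) 0L else 3L
  invisible(fit)
}

#' DMRG + gradients from an FCIDUMP file
#'
#' The orbital-agnostic half of the method run standalone: builds the
#' Hamiltonian from the file, solves for the ground state and extracts
#' the gradient tensors.
#'
#' @param path FCIDUMP file.
#' @param Sz2 twice the spin projection (default from the file's MS2).
#' @param cfg DMRG options (see \code{\link{dmrg_ground_state}}).
#' @return list with \code{energy} (electronic + core), \code{gradients},
#'   \code{state}, \code{norb}, \code{nelec}.
#' @export
run_dmrg_file <- function(path, Sz2 = NULL, cfg = list()) {
  fd <- fcidump_read(path)
  if (is.null(Sz2)) Sz2 <- fd$ms2
  mpo <- build_mpo(fd$h, fd$g,
                   penalty = list(w = 25, N0 = fd$nelec, Sz0 = Sz2 / 2))
  st <- suppressWarnings(dmrg_ground_state(mpo, fd$norb, fd$nelec, Sz2, cfg))
  gr <- extract_gradients(st, fd$norb)
  list(energy = st$energy + fd$ecore, electronic = st$energy,
       core = fd$ecore, gradients = gr, state = st,
       norb = fd$norb, nelec = fd$nelec)
}

#' Bond-length scan for a diatomic
#'
#' Runs the optimizer at each separation and collects one summary row per
#' geometry.
#'
#' @param sym1,sym2 element symbols.
#' @param distances bond lengths in bohr.
#' @param M orbital count.
#' @param ... passed to \code{\link{mwdmrg}}.
#' @return data.frame with \code{distance}, \code{energy},
#'   \code{converged}, \code{iterations}.
#' @export
run_scan <- function(sym1, sym2, distances, M, ...) {
  rows <- lapply(distances, function(d) {
    mol <- mw_molecule(c(sym1, sym2),
                       matrix(c(0, 0, -d / 2, 0, 0, d / 2), 3, 2))
    fit <- mwdmrg(mol, M = M, ...)
    data.frame(distance = d, energy = fit$energy,
               converged = fit$converged, iterations = fit$iterations)
  })
  do.call(rbind, rows)
}
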