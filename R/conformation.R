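#' Backbone torsion-angle representation of a protein conformation
#'
#' A `torsion_chain` is the optimization variable of the refinement engine:
#' the backbone conformation of an L-residue protein expressed as per-residue
#' (phi, psi, omega) dihedrals in degrees. By convention the first residue has
#' no phi (no preceding carbonyl carbon) and the last residue has no psi or
#' omega (no following amide nitrogen); those entries are stored as `NA`,
#' never silently as 0. All defined angles lie in (-180, 180].
#'
#' The object is a tibble with one row per residue and columns `residue`,
#' `resname`, `phi`, `psi`, `omega`, so it pipes straight into dplyr/ggplot2.
#'
#' @param phi,psi,omega numeric vectors of length L (degrees). `phi[1]`,
#'   `psi[L]` and `omega[L]` must be `NA`; all other entries must be defined.
#' @param resname character vector of 3-letter residue codes, recycled if
#'   length 1. Defaults to `"ALA"`.
#' @return a `torsion_chain` tibble.
#' @examples
#' torsion_chain(phi = c(NA, -57, -57), psi = c(-47, -47, NA),
#'               omega = c(180, 180, NA))
#' @export
torsion_chain <- function(phi, psi, omega = NULL, resname = "ALA") {
  L <- length(phi)
  if (L < 2L) stop("A torsion chain needs at least 2 residues.", call. = FALSE)
  if (length(psi) != L) {
    stop("`phi` and `psi` must have the same length.", call. = FALSE)
  }
  if (is.null(omega)) omega <- c(rep(180, L - 1L), NA_real_)
  if (length(omega) != L) {
    stop("`omega` must have length L.", call. = FALSE)
  }
  resname <- toupper(rep_len(as.character(resname), L))
  out <- tibble::tibble(
    residue = seq_len(L),
    resname = resname,
    phi = wrap_angle(as.numeric(phi)),
    psi = wrap_angle(as.numeric(psi)),
    omega = wrap_angle(as.numeric(omega))
  )
  out <- tibble::new_tibble(out, class = "torsion_chain")
  validate_torsion_chain(out)
  out
}

validate_torsion_chain <- function(chain) {
  L <- nrow(chain)
  if (L < 2L) stop("A torsion chain needs at least 2 residues.", call. = FALSE)
  if (!is.na(chain$phi[1L])) {
    stop("phi of residue 1 is undefined by convention; store it as NA.",
         call. = FALSE)
  }
  if (!is.na(chain$psi[L]) || !is.na(chain$omega[L])) {
    stop("psi and omega of the last residue are undefined; store them as NA.",
         call. = FALSE)
  }
  def <- c(chain$phi[-1L], chain$psi[-L], chain$omega[-L])
  if (anyNA(def)) {
    stop("All interior torsion angles must be defined (non-NA).", call. = FALSE)
  }
  if (any(def <= -180 | def > 180)) {
    stop("Torsion angles must lie in (-180, 180].", call. = FALSE)
  }
  invisible(chain)
}

#' @export
print.torsion_chain <- function(x, ...) {
  cat(sprintf("# A torsion_chain: %d residues\n", nrow(x)))
  NextMethod()
}

chain_length <- function(chain) nrow(chain)

#' Covalent backbone geometry parameters
#'
#' Fixed bond lengths and bond angles used when rebuilding Cartesian
#' coordinates from torsion angles. Defaults are standard Engh--Huber-style
#' values for the trans peptide unit.
#'
#' @param b_n_ca,b_ca_c,b_c_n bond lengths N-CA, CA-C, C-N(next) in Angstrom.
#' @param a_n_ca_c,a_ca_c_n,a_c_n_ca bond angles N-CA-C, CA-C-N(next),
#'   C-N(next)-CA(next) in degrees.
#' @param b_c_o,a_ca_c_o carbonyl C=O length and CA-C-O angle, used only for
#'   placing the optional backbone oxygen.
#' @return a `geometry_params` list.
#' @export
geometry_params <- function(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                            a_n_ca_c = 111.2, a_ca_c_n = 116.2,
                            a_c_n_ca = 121.7,
                            b_c_o = 1.231, a_ca_c_o = 120.8) {
  lens <- c(b_n_ca = b_n_ca, b_ca_c = b_ca_c, b_c_n = b_c_n, b_c_o = b_c_o)
  angs <- c(a_n_ca_c = a_n_ca_c, a_ca_c_n = a_ca_c_n, a_c_n_ca = a_c_n_ca,
            a_ca_c_o = a_ca_c_o)
  if (any(lens <= 0.5 | lens >= 3.0)) {
    stop("Bond lengths must lie in (0.5, 3.0) Angstrom.", call. = FALSE)
  }
  if (any(angs <= 60 | angs >= 180)) {
    stop("Bond angles must lie in (60, 180) degrees.", call. = FALSE)
  }
  structure(as.list(c(lens, angs)), class = "geometry_params")
}

#' Cartesian backbone representation
#'
#' A `backbone_structure` is a tibble of backbone-atom coordinates, one row
#' per atom, with columns `residue`, `resname`, `atom` (N, CA, C, optionally
#' O), `x`, `y`, `z` (Angstrom) and `chain`.
#'
#' @param residue integer residue indices.
#' @param resname character 3-letter codes.
#' @param atom character atom names among N, CA, C, O.
#' @param x,y,z numeric coordinates in Angstrom.
#' @param chain chain identifier, recycled.
#' @return a `backbone_structure` tibble.
#' @export
backbone_structure <- function(residue, resname, atom, x, y, z, chain = "A") {
  out <- tibble::tibble(
    residue = as.integer(residue),
    resname = toupper(as.character(resname)),
    atom = toupper(as.character(atom)),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    chain = rep_len(as.character(chain), length(residue))
  )
  if (!all(out$atom %in% c("N", "CA", "C", "O"))) {
    stop("Backbone atoms must be among N, CA, C, O.", call. = FALSE)
  }
  if (any(!is.finite(c(out$x, out$y, out$z)))) {
    stop("Coordinates must be finite.", call. = FALSE)
  }
  tibble::new_tibble(out, class = "backbone_structure")
}

# internal: L x 3 matrices of coordinates for one atom type, rows = residues
atom_xyz <- function(structure, atom) {
  rows <- structure$atom == atom
  sub <- structure[rows, , drop = FALSE]
  sub <- sub[order(sub$residue), , drop = FALSE]
  m <- cbind(sub$x, sub$y, sub$z)
  rownames(m) <- sub$residue
  m
}

check_complete_backbone <- function(structure) {
  res <- sort(unique(structure$residue))
  for (at in c("N", "CA", "C")) {
    have <- unique(structure$residue[structure$atom == at])
    missing <- setdiff(res, have)
    if (length(missing) > 0L) {
      stop(sprintf("Missing backbone atom %s for residue(s) %s.",
                   at, paste(utils::head(missing, 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  invisible(res)
}

# internal NeRF-style placement: put atom D at bond length r from C, bond
# angle theta (B-C-D) and torsion chi (A-B-C-D), in the frame of A, B, C
place_atom <- function(a, b, c, r, theta, chi) {
  th <- theta * pi / 180
  ch <- chi * pi / 180
  d2 <- r * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# internal fast kernel: N/CA/C coordinate matrices (L x 3) from torsions,
# canonical frame (N1 at origin, CA1 on +x, C1 in the xy-plane)
nerf_backbone <- function(phi, psi, omega, geom) {
  L <- length(phi)
  N <- matrix(0, L, 3L)
  CA <- matrix(0, L, 3L)
  C <- matrix(0, L, 3L)
  CA[1L, 1L] <- geom$b_n_ca
  ang <- geom$a_n_ca_c * pi / 180
  C[1L, ] <- c(geom$b_n_ca - geom$b_ca_c * cos(ang), geom$b_ca_c * sin(ang), 0)
  if (L > 1L) {
    for (i in seq_len(L - 1L)) {
      N[i + 1L, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                                geom$b_c_n, geom$a_ca_c_n, psi[i])
      CA[i + 1L, ] <- place_atom(CA[i, ], C[i, ], N[i + 1L, ],
                                 geom$b_n_ca, geom$a_c_n_ca, omega[i])
      C[i + 1L, ] <- place_atom(C[i, ], N[i + 1L, ], CA[i + 1L, ],
                                geom$b_ca_c, geom$a_n_ca_c, phi[i + 1L])
    }
  }
  list(N = N, CA = CA, C = C)
}

# internal fast constructor: trusted inputs (already wrapped / validated),
# no per-call validation; carries an environment for cached Cartesian
# coordinates so the objective functions convert at most once per decode
new_torsion_chain <- function(phi, psi, omega, resname) {
  out <- tibble::new_tibble(
    list(residue = seq_along(phi), resname = resname,
         phi = phi, psi = psi, omega = omega),
    nrow = length(phi), class = "torsion_chain"
  )
  attr(out, "bb_cache") <- new.env(parent = emptyenv())
  out
}

# internal: N/CA/C matrices for a chain, cached on the chain when possible
bb_mats <- function(chain, geom = geometry_params()) {
  env <- attr(chain, "bb_cache")
  if (!is.null(env) && !is.null(env$mats) && identical(env$geom, geom)) {
    return(env$mats)
  }
  m <- nerf_backbone(chain$phi, chain$psi, chain$omega, geom)
  if (!is.null(env)) {
    env$mats <- m
    env$geom <- geom
  }
  m
}

#' Rebuild Cartesian backbone coordinates from torsion angles
#'
#' Sequential internal-to-Cartesian conversion: each atom is placed in the
#' frame of the previous three atoms from its bond length, bond angle and
#' torsion (the Denavit--Hartenberg-style chain construction). The first
#' three atoms fix the canonical frame: N1 at the origin, CA1 on the +x axis,
#' C1 in the xy-plane.
#'
#' @param chain a [torsion_chain()].
#' @param geom covalent geometry, a [geometry_params()].
#' @param include_oxygen place the backbone carbonyl oxygen as well (uses the
#'   psi torsion + 180; the terminal residue uses 180 relative to N-CA-C).
#' @return a [backbone_structure()] with 3 (or 4) atoms per residue.
#' @export
torsions_to_cartesian <- function(chain, geom = geometry_params(),
                                  include_oxygen = TRUE) {
  validate_torsion_chain(chain)
  if (!inherits(geom, "geometry_params")) {
    stop("`geom` must be a geometry_params object.", call. = FALSE)
  }
  L <- nrow(chain)
  bb <- bb_mats(chain, geom)
  N <- bb$N
  CA <- bb$CA
  C <- bb$C
  res <- rep(seq_len(L), each = if (include_oxygen) 4L else 3L)
  if (include_oxygen) {
    O <- matrix(NA_real_, L, 3L)
    for (i in seq_len(L)) {
      chi_o <- if (i < L) wrap_angle(chain$psi[i] + 180) else 180
      O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                           geom$b_c_o, geom$a_ca_c_o, chi_o)
    }
    xyz <- do.call(rbind, lapply(seq_len(L), function(i) {
      rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    }))
    atoms <- rep(c("N", "CA", "C", "O"), L)
  } else {
    xyz <- do.call(rbind, lapply(seq_len(L), function(i) {
      rbind(N[i, ], CA[i, ], C[i, ])
    }))
    atoms <- rep(c("N", "CA", "C"), L)
  }
  backbone_structure(residue = res,
                     resname = chain$resname[res],
                     atom = atoms,
                     x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L])
}

#' Measure backbone torsion angles from Cartesian coordinates
#'
#' The inverse of [torsions_to_cartesian()]: computes phi, psi and omega
#' dihedrals from N/CA/C coordinates. Angles are wrapped to (-180, 180];
#' terminal torsions without four defining atoms are `NA`.
#'
#' @param structure a [backbone_structure()] with complete N, CA, C atoms.
#' @return a [torsion_chain()].
#' @export
cartesian_to_torsions <- function(structure) {
  res <- check_complete_backbone(structure)
  L <- length(res)
  if (L < 2L) stop("Need at least 2 residues.", call. = FALSE)
  N <- atom_xyz(structure, "N")
  CA <- atom_xyz(structure, "CA")
  C <- atom_xyz(structure, "C")
  phi <- psi <- omega <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    if (i > 1L) {
      phi[i] <- dihedral_angle(C[i - 1L, ], N[i, ], CA[i, ], C[i, ])
    }
    if (i < L) {
      psi[i] <- dihedral_angle(N[i, ], CA[i, ], C[i, ], N[i + 1L, ])
      omega[i] <- dihedral_angle(CA[i, ], C[i, ], N[i + 1L, ], CA[i + 1L, ])
    }
  }
  resnames <- vapply(res, function(r) {
    structure$resname[structure$residue == r][1L]
  }, character(1L))
  torsion_chain(phi = phi, psi = psi, omega = omega, resname = resnames)
}

#' Randomly perturb the phi/psi torsions of a chain
#'
#' Adds independent zero-mean Gaussian noise of standard deviation `sigma`
#' (degrees) to every defined phi and psi, then re-wraps to (-180, 180]. The
#' peptide-bond omega is left untouched by default so the chain stays near
#' trans; set `include_omega = TRUE` to perturb it too.
#'
#' @param chain a [torsion_chain()].
#' @param sigma perturbation standard deviation in degrees, >= 0.
#' @param seed integer seed; the same seed reproduces the same perturbation.
#' @param include_omega also perturb omega (default `FALSE`).
#' @return a perturbed `torsion_chain`.
#' @export
perturb_chain <- function(chain, sigma, seed = NULL, include_omega = FALSE) {
  validate_torsion_chain(chain)
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop("`sigma` must be a single non-negative number.", call. = FALSE)
  }
  draw <- function() perturb_chain_impl(chain, sigma, include_omega)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

perturb_chain_impl <- function(chain, sigma, include_omega) {
  L <- nrow(chain)
  phi <- chain$phi
  psi <- chain$psi
  omega <- chain$omega
  if (sigma > 0) {
    phi[-1L] <- wrap_angle(phi[-1L] + stats::rnorm(L - 1L, 0, sigma))
    psi[-L] <- wrap_angle(psi[-L] + stats::rnorm(L - 1L, 0, sigma))
    if (include_omega) {
      omega[-L] <- wrap_angle(omega[-L] + stats::rnorm(L - 1L, 0, sigma))
    }
  }
  torsion_chain(phi = phi, psi = psi, omega = omega, resname = chain$resname)
}
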