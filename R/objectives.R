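#' Define an energy model
#'
#' An energy model maps a conformation (a [torsion_chain()] for the protein
#' surrogates, or a plain numeric vector for benchmark landscapes) to a
#' single real energy value; lower is better, and evaluation must be
#' deterministic. Real force-field backends plug in through this same
#' contract (see [external_scorer_model()]).
#'
#' @param name short label for the objective.
#' @param fn function of one argument returning one finite numeric value.
#' @return an `energy_model` object.
#' @export
energy_model <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  structure(list(name = name, evaluate = fn), class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("<energy_model: %s>\n", x$name))
  invisible(x)
}

#' Evaluate all objectives of a conformation
#'
#' Computes the multi-objective energy vector F(C): one value per energy
#' model, in the order the models are given.
#'
#' @param models list of >= 2 [energy_model()] objects.
#' @param x the conformation (or benchmark vector) to score.
#' @return named numeric vector of length M = `length(models)`.
#' @export
evaluate_all <- function(models, x) {
  if (!is.list(models) || length(models) < 2L) {
    stop("Need at least 2 energy models.", call. = FALSE)
  }
  vals <- vapply(models, function(m) {
    v <- m$evaluate(x)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("Energy model '%s' returned a non-finite value.", m$name),
           call. = FALSE)
    }
    as.numeric(v)
  }, numeric(1L))
  names(vals) <- vapply(models, `[[`, character(1L), "name")
  vals
}

# internal: interleaved N1,CA1,C1,N2,... coordinate matrix (3L x 3) for a
# chain or backbone_structure
chain_atom_matrix <- function(x, geom) {
  if (inherits(x, "torsion_chain")) {
    bb <- bb_mats(x, geom)
    L <- nrow(bb$N)
    m <- matrix(0, 3L * L, 3L)
    m[seq(1L, 3L * L, 3L), ] <- bb$N
    m[seq(2L, 3L * L, 3L), ] <- bb$CA
    m[seq(3L, 3L * L, 3L), ] <- bb$C
    return(m)
  }
  if (inherits(x, "backbone_structure")) {
    s <- x[x$atom %in% c("N", "CA", "C"), , drop = FALSE]
    ord <- order(s$residue, match(s$atom, c("N", "CA", "C")))
    s <- s[ord, , drop = FALSE]
    return(cbind(s$x, s$y, s$z))
  }
  stop("Expected a torsion_chain or backbone_structure.", call. = FALSE)
}

as_backbone <- function(x, geom = geometry_params()) {
  if (inherits(x, "backbone_structure")) return(x)
  if (inherits(x, "torsion_chain")) {
    return(torsions_to_cartesian(x, geom, include_oxygen = FALSE))
  }
  stop("Expected a torsion_chain or backbone_structure.", call. = FALSE)
}

# cache of upper-triangle masks for >= 4 bond separations, keyed by atom count
.mask_cache <- new.env(parent = emptyenv())

nonbonded_mask <- function(n) {
  key <- as.character(n)
  m <- .mask_cache[[key]]
  if (is.null(m)) {
    sep <- abs(outer(seq_len(n), seq_len(n), "-"))
    m <- sep >= 4L & upper.tri(sep)
    .mask_cache[[key]] <- m
  }
  m
}

#' Soft-sphere steric clash energy
#'
#' Sum of `max(0, r_min - d)^2` over all non-bonded backbone N/CA/C atom
#' pairs, where d is the interatomic distance. Pairs separated by three or
#' fewer bonds along the N-CA-C chain are excluded (their distances are fixed
#' by the covalent geometry and the torsions themselves), so a single residue
#' has no non-bonded pairs and zero clash energy. The default radius 3.1
#' Angstrom sits just below the closest non-bonded backbone approach of
#' regular secondary structure (about 3.2 Angstrom in an alpha-helix), so
#' well-formed conformations score 0 while distorted ones are penalized.
#'
#' @param chain a [torsion_chain()] (converted internally with ideal
#'   geometry), or a [backbone_structure()].
#' @param r_min clash radius in Angstrom (default 3.1).
#' @param geom geometry used for the internal conversion.
#' @return non-negative clash energy.
#' @export
clash_energy <- function(chain, r_min = 3.1, geom = geometry_params()) {
  m <- chain_atom_matrix(chain, geom)
  n <- nrow(m)
  if (n < 5L) return(0)
  d <- as.matrix(stats::dist(m))
  viol <- pmax(0, r_min - d[nonbonded_mask(n)])
  sum(viol^2)
}

#' Compactness energy: squared radius of gyration of the CA trace
#'
#' Favours collapsed conformations; deliberately in tension with
#' [clash_energy()] so the surrogate Pareto front is non-degenerate.
#'
#' @inheritParams clash_energy
#' @return squared radius of gyration in Angstrom^2.
#' @export
compactness_energy <- function(chain, geom = geometry_params()) {
  ca <- if (inherits(chain, "torsion_chain")) {
    bb_mats(chain, geom)$CA
  } else {
    atom_xyz(chain, "CA")
  }
  ctr <- colMeans(ca)
  mean(rowSums(sweep(ca, 2L, ctr)^2))
}

#' Torsion-basin preference energy
#'
#' Smooth quadratic penalty on the circular distance of each residue's
#' (phi, psi) from a target basin, summed over residues where both angles are
#' defined. Zero exactly at the basin. The default basin is the alpha-helical
#' region (-57, -47).
#'
#' @param chain a [torsion_chain()].
#' @param phi0,psi0 basin centre in degrees.
#' @param width scale of the penalty in degrees; the energy is
#'   `sum(dphi^2 + dpsi^2) / width^2` with circular differences. The default
#'   width of 5 degrees puts this term on a scale comparable to the other
#'   surrogates for typical chain lengths, so no single energy monopolizes
#'   the decomposition.
#' @return non-negative preference energy.
#' @export
torsion_preference_energy <- function(chain, phi0 = -57, psi0 = -47,
                                      width = 5) {
  if (!inherits(chain, "torsion_chain")) {
    stop("Expected a torsion_chain.", call. = FALSE)
  }
  ok <- !is.na(chain$phi) & !is.na(chain$psi)
  dphi <- angle_diff(chain$phi[ok], phi0)
  dpsi <- angle_diff(chain$psi[ok], psi0)
  sum(dphi^2 + dpsi^2) / width^2
}

#' Surrogate three-objective energy set for backbone refinement
#'
#' Stand-in energies exercising the full multi-objective machinery without
#' external force fields: steric clash, compactness (radius of gyration) and
#' torsion-basin preference. Clash and basin preference reward locally
#' regular, open structures while compactness rewards collapse, so the three
#' genuinely conflict and produce a non-degenerate Pareto front.
#'
#' The constants table (all overridable here):
#'
#' | constant | default | rationale |
#' |---|---|---|
#' | `r_min`  | 3.1 A | just below the closest non-bonded backbone approach of a regular helix, so regular natives score 0 and distorted models do not |
#' | `phi0`, `psi0` | -57, -47 deg | alpha-helical basin |
#' | `width`  | 5 deg | puts the torsion term on a scale comparable to compactness |
#'
#' With these defaults a regular synthetic native scores better than a
#' torsion-perturbed copy of itself on both clash and torsion preference,
#' making recovery toward the native detectable, while compactness pulls the
#' opposite way (a collapsed coil beats an extended helix), keeping the
#' front non-degenerate.
#'
#' @param phi0,psi0,width basin parameters passed to
#'   [torsion_preference_energy()].
#' @param r_min clash radius passed to [clash_energy()].
#' @param geom covalent geometry for internal conversions.
#' @return list of three [energy_model()] objects.
#' @export
surrogate_models <- function(phi0 = -57, psi0 = -47, width = 5,
                             r_min = 3.1, geom = geometry_params()) {
  list(
    energy_model("clash", function(x) clash_energy(x, r_min = r_min, geom = geom)),
    energy_model("compactness", function(x) compactness_energy(x, geom = geom)),
    energy_model("torsion_pref", function(x) {
      torsion_preference_energy(x, phi0 = phi0, psi0 = psi0, width = width)
    })
  )
}

#' Adapter contract for external force-field scorers
#'
#' Wraps a shell command that scores a written PDB file into the
#' [energy_model()] contract: the conformation is converted to Cartesian
#' coordinates, written to a temporary PDB, and `command` is run on it; its
#' standard output must be a single number. This documents how real scoring
#' backends (Rosetta-like, statistical potentials, molecular-mechanics
#' energies) would plug in; tests exercise it with a mock command only.
#'
#' @param name objective label.
#' @param command function taking a PDB path and returning one numeric score
#'   (e.g. a wrapper around [system2()]).
#' @param geom geometry for the internal-to-Cartesian conversion.
#' @return an [energy_model()].
#' @export
external_scorer_model <- function(name, command, geom = geometry_params()) {
  force(command)
  energy_model(name, function(x) {
    s <- as_backbone(x, geom)
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp))
    write_pdb(s, tmp)
    as.numeric(command(tmp))
  })
}

#' Benchmark objective landscapes with known Pareto fronts
#'
#' Three-objective test problems over a real vector domain `[0, 1]^dim`,
#' used to validate the optimizer against closed-form Pareto fronts:
#'
#' * `"dtlz2"`: the standard DTLZ2 problem; the true Pareto front is the
#'   positive octant of the unit sphere (`||F|| = 1`, attained when all
#'   distance variables equal 0.5).
#' * `"convex-plane"`: a DTLZ1-like linear problem without the multimodal
#'   term; the true Pareto front is the plane `f1 + f2 + f3 = 1` restricted
#'   to the non-negative octant.
#'
#' @param name `"dtlz2"` or `"convex-plane"`.
#' @param dim number of decision variables (>= 3).
#' @return list with `models` (three [energy_model()]s), `lower`, `upper`
#'   bound vectors, `dim`, and `pf_distance(F)` giving the distance of an
#'   objective vector from the true Pareto front surface.
#' @export
benchmark_problem <- function(name = c("dtlz2", "convex-plane"), dim = 7L) {
  name <- match.arg(name)
  dim <- as.integer(dim)
  if (dim < 3L) stop("`dim` must be at least 3.", call. = FALSE)
  g_fn <- function(x) sum((x[-(1:2)] - 0.5)^2)
  if (name == "dtlz2") {
    f <- list(
      function(x) (1 + g_fn(x)) * cos(x[1L] * pi / 2) * cos(x[2L] * pi / 2),
      function(x) (1 + g_fn(x)) * cos(x[1L] * pi / 2) * sin(x[2L] * pi / 2),
      function(x) (1 + g_fn(x)) * sin(x[1L] * pi / 2)
    )
    pf_distance <- function(F) abs(sqrt(sum(F^2)) - 1)
  } else {
    f <- list(
      function(x) (1 + g_fn(x)) * x[1L] * x[2L],
      function(x) (1 + g_fn(x)) * x[1L] * (1 - x[2L]),
      function(x) (1 + g_fn(x)) * (1 - x[1L])
    )
    pf_distance <- function(F) abs(sum(F) - 1) / sqrt(length(F))
  }
  models <- lapply(seq_along(f), function(k) {
    energy_model(paste0("f", k), f[[k]])
  })
  list(models = models, lower = rep(0, dim), upper = rep(1, dim),
       dim = dim, pf_distance = pf_distance)
}
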