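#' Generate a synthetic native backbone
#'
#' Builds a reference ("native") conformation from ideal secondary-structure
#' torsions plus a small deterministic jitter, emulating the known answer of
#' a refinement exercise:
#'
#' * `"helix"`: alpha-helical (phi, psi) = (-57, -47);
#' * `"extended"`: fully extended (180, 180);
#' * `"mixed"`: alternating helix/extended blocks of 8 residues.
#'
#' @param L residue count (>= 2).
#' @param motif one of `"helix"`, `"extended"`, `"mixed"`.
#' @param seed RNG seed (jitter is deterministic per seed).
#' @param jitter_sigma std-dev (degrees) of the jitter applied to the ideal
#'   torsions; default 2 keeps helices recognizably helical.
#' @return list with `chain` (the [torsion_chain()]) and `structure` (its
#'   [backbone_structure()] under ideal geometry).
#' @export
make_native <- function(L, motif = c("helix", "extended", "mixed"),
                        seed = 1L, jitter_sigma = 2) {
  motif <- match.arg(motif)
  L <- as.integer(L)
  if (L < 2L) stop("`L` must be at least 2.", call. = FALSE)
  base <- switch(motif,
    helix = list(phi = rep(-57, L), psi = rep(-47, L)),
    extended = list(phi = rep(180, L), psi = rep(180, L)),
    mixed = {
      block <- ((seq_len(L) - 1L) %/% 8L) %% 2L == 0L
      list(phi = ifelse(block, -57, 180), psi = ifelse(block, -47, 180))
    }
  )
  phi <- c(NA_real_, base$phi[-1L])
  psi <- c(base$psi[-L], NA_real_)
  chain <- torsion_chain(phi = phi, psi = psi)
  if (jitter_sigma > 0) {
    chain <- perturb_chain(chain, jitter_sigma, seed = seed)
  }
  list(chain = chain, structure = torsions_to_cartesian(chain))
}

#' Generate a complete synthetic refinement case
#'
#' Emulates a blind-refinement input: a synthetic native backbone plus an
#' initial model derived from it by Gaussian torsion perturbation at a
#' controlled deviation. Both structures are written as PDB files along with
#' a JSON manifest recording the initial model's RMSD and GDT-TS against the
#' native, so the starting quality is known.
#'
#' @param L residue count.
#' @param deviation_sigma std-dev (degrees) of the phi/psi perturbation
#'   generating the initial model from the native.
#' @param seed RNG seed; the whole case is deterministic given it.
#' @param dir output directory (created if needed); `NULL` skips writing.
#' @param motif native motif, see [make_native()].
#' @return list with `native_chain`, `native`, `initial_chain`, `initial`,
#'   `metrics` (one-row tibble: initial `rmsd`, `gdt_ts`), and (when written)
#'   `native_pdb`, `initial_pdb`, `manifest`.
#' @export
make_refinement_case <- function(L, deviation_sigma, seed = 1L, dir = NULL,
                                 motif = "helix") {
  nat <- make_native(L, motif = motif, seed = seed)
  init_chain <- perturb_chain(nat$chain, deviation_sigma, seed = seed + 1000L)
  init_struct <- torsions_to_cartesian(init_chain)
  metrics <- evaluate_model(init_struct, nat$structure)
  out <- list(native_chain = nat$chain, native = nat$structure,
              initial_chain = init_chain, initial = init_struct,
              metrics = metrics)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$native_pdb <- file.path(dir, "native.pdb")
    out$initial_pdb <- file.path(dir, "initial.pdb")
    write_pdb(nat$structure, out$native_pdb)
    write_pdb(init_struct, out$initial_pdb)
    out$manifest <- file.path(dir, "manifest.json")
    jsonlite::write_json(
      list(L = L, motif = motif, deviation_sigma = deviation_sigma,
           seed = seed, initial_rmsd = metrics$rmsd,
           initial_gdt_ts = metrics$gdt_ts),
      out$manifest, auto_unbox = TRUE, digits = NA
    )
  }
  out
}
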