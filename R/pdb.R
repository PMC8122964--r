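#' Read a backbone structure from a PDB file
#'
#' Extracts the backbone atoms (N, CA, C, O) of the first model and, by
#' default, the first chain. ATOM records only; for alternate locations the
#' blank or 'A' altloc is kept. Parsing is delegated to bio3d.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier to extract; `NULL` (default) takes the first
#'   chain present.
#' @return a [backbone_structure()] tibble.
#' @export
read_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("PDB file not found: %s", path), call. = FALSE)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) {
      stop(sprintf("Could not parse PDB file %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) stop("No ATOM records found.", call. = FALSE)
  if (is.null(chain)) chain <- a$chain[1L]
  a <- a[a$chain == chain, , drop = FALSE]
  if (nrow(a) == 0L) {
    stop(sprintf("No atoms found for chain '%s'.", chain), call. = FALSE)
  }
  a <- a[a$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
  a <- a[is.na(a$alt) | a$alt %in% c("", "A"), , drop = FALSE]
  # residue identity includes insertion codes
  key <- paste(a$resno, ifelse(is.na(a$insert), "", a$insert))
  idx <- match(key, unique(key))
  # drop duplicate atoms within a residue (first wins)
  keep <- !duplicated(paste(idx, a$elety))
  a <- a[keep, , drop = FALSE]
  idx <- idx[keep]
  out <- backbone_structure(residue = idx, resname = a$resid, atom = a$elety,
                            x = a$x, y = a$y, z = a$z, chain = chain)
  check_complete_backbone(out)
  if (nrow(out) < 2L || length(unique(out$residue)) < 2L) {
    stop("Need at least 2 residues with N, CA, C atoms.", call. = FALSE)
  }
  out
}

#' Write a backbone structure to a PDB file
#'
#' Emits standard fixed-column ATOM records (wwPDB v3.3 layout, coordinates
#' at 3 decimals) followed by TER/END, via bio3d.
#'
#' @param structure a [backbone_structure()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  if (!inherits(structure, "backbone_structure")) {
    stop("`structure` must be a backbone_structure.", call. = FALSE)
  }
  xyz <- as.vector(t(cbind(structure$x, structure$y, structure$z)))
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    type = rep("ATOM", nrow(structure)),
    resno = structure$residue,
    resid = structure$resname,
    eleno = seq_len(nrow(structure)),
    elety = structure$atom,
    chain = structure$chain,
    o = rep(1.00, nrow(structure)), b = rep(0.00, nrow(structure))
  )
  invisible(path)
}
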