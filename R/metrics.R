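# internal: optimal superposition of P onto Q (n x 3 each) by the Kabsch
# algorithm; returns the rotated+translated copy of P
kabsch_superpose <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp)
  Q0 <- sweep(Q, 2L, cq)
  H <- crossprod(P0, Q0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(P0 %*% t(R), 2L, cq, `+`)
}

# internal: extract matched coordinate matrices for an atom set
matched_xyz <- function(a, b, atom_set) {
  ra <- sort(unique(a$residue))
  rb <- sort(unique(b$residue))
  if (length(ra) != length(rb)) {
    stop(sprintf("Residue counts differ: %d vs %d.", length(ra), length(rb)),
         call. = FALSE)
  }
  pa <- do.call(rbind, lapply(atom_set, function(at) atom_xyz(a, at)))
  pb <- do.call(rbind, lapply(atom_set, function(at) atom_xyz(b, at)))
  if (nrow(pa) != nrow(pb)) {
    stop("Atom counts differ between the two structures.", call. = FALSE)
  }
  list(a = pa, b = pb)
}

#' RMSD after optimal (Kabsch) superposition
#'
#' Least-squares rigid-body superposition of `a` onto `b` followed by the
#' root-mean-square deviation over the chosen atom set. Pairing is positional
#' (same residue order), as appropriate for refinement, where model and
#' reference share a sequence.
#'
#' @param a,b [backbone_structure()]s with equal residue counts.
#' @param atom_set atoms to superpose and measure (default `"CA"`).
#' @return RMSD in Angstrom (>= 0).
#' @export
kabsch_rmsd <- function(a, b, atom_set = "CA") {
  m <- matched_xyz(a, b, atom_set)
  fit <- kabsch_superpose(m$a, m$b)
  sqrt(mean(rowSums((fit - m$b)^2)))
}

#' Approximate GDT-TS model-quality score
#'
#' Global distance test, total score: the mean over distance cutoffs 1, 2, 4
#' and 8 Angstrom of the maximal percentage of CA atoms that can be placed
#' within the cutoff of the reference by a rigid-body superposition. The
#' maximization over superpositions is approximate: seeds from all contiguous
#' windows of lengths 4, 8 and the full chain, each followed by iterations of
#' superposing on the currently-fitting subset. This heuristic tracks, but
#' does not reproduce, the official exhaustive search, so scores here are not
#' comparable to published assessment tables at decimal precision.
#'
#' @param model,reference [backbone_structure()]s with equal residue counts.
#' @param cutoffs distance cutoffs in Angstrom (default `c(1, 2, 4, 8)`).
#' @param refine_iter superposition refinement iterations per seed.
#' @return GDT-TS in `[0, 100]`.
#' @export
gdt_ts <- function(model, reference, cutoffs = c(1, 2, 4, 8),
                   refine_iter = 3L) {
  m <- matched_xyz(model, reference, "CA")
  P <- m$a
  Q <- m$b
  n <- nrow(P)
  windows <- list(seq_len(n))
  for (len in c(4L, 8L)) {
    if (n >= len) {
      for (s in seq_len(n - len + 1L)) windows <- c(windows, list(s:(s + len - 1L)))
    }
  }
  best <- stats::setNames(rep(0, length(cutoffs)), cutoffs)
  for (idx in windows) {
    sel <- idx
    for (it in seq_len(refine_iter + 1L)) {
      fit <- tryCatch(
        kabsch_superpose_on(P, Q, sel),
        error = function(e) NULL
      )
      if (is.null(fit)) break
      d <- sqrt(rowSums((fit - Q)^2))
      for (k in seq_along(cutoffs)) {
        frac <- mean(d <= cutoffs[k])
        if (frac > best[k]) best[k] <- frac
      }
      # refine on the atoms currently under the largest cutoff
      sel_new <- which(d <= max(cutoffs))
      if (length(sel_new) < 3L || identical(sel_new, sel)) break
      sel <- sel_new
    }
  }
  mean(best) * 100
}

# superpose P onto Q using only the subset `sel` to fit the transform
kabsch_superpose_on <- function(P, Q, sel) {
  Ps <- P[sel, , drop = FALSE]
  Qs <- Q[sel, , drop = FALSE]
  cp <- colMeans(Ps)
  cq <- colMeans(Qs)
  H <- crossprod(sweep(Ps, 2L, cp), sweep(Qs, 2L, cq))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(P, 2L, cp) %*% t(R), 2L, cq, `+`)
}

#' Compare a model against a reference structure
#'
#' Convenience wrapper computing both metrics as a one-row tibble.
#'
#' @param model,reference [backbone_structure()]s.
#' @return tibble with `rmsd` (Angstrom) and `gdt_ts`.
#' @export
evaluate_model <- function(model, reference) {
  tibble::tibble(
    rmsd = kabsch_rmsd(model, reference),
    gdt_ts = gdt_ts(model, reference)
  )
}
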