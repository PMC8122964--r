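#' Pareto dominance between two objective vectors
#'
#' `a` dominates `b` when `a` is no worse in every objective and the two
#' vectors differ (minimization). Equal vectors do not dominate each other.
#'
#' @param a,b numeric objective vectors of equal length.
#' @return logical scalar.
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b)) {
    stop("Objective vectors must have the same dimension.", call. = FALSE)
  }
  all(a <= b) && any(a < b)
}

#' Create an empty Pareto archive
#'
#' The archive maintains the evolving Pareto set: the mutually non-dominated
#' (conformation, objective-vector) pairs seen so far. Unbounded by default;
#' an optional capacity prunes by crowding distance.
#'
#' @param capacity maximum number of entries, or `Inf` (default) for the
#'   unbounded archive.
#' @return a `pareto_archive` object.
#' @export
new_archive <- function(capacity = Inf) {
  structure(
    list(obj = NULL, pos = list(), gen = integer(0L), capacity = capacity),
    class = "pareto_archive"
  )
}

#' Offer a candidate solution to the Pareto archive
#'
#' Implements the archive update of the optimizer's main loop: entries
#' dominated by the candidate are removed; the candidate is added if no
#' remaining entry dominates it. A candidate whose objective vector exactly
#' duplicates an existing entry is rejected (the first occurrence is kept).
#'
#' @param archive a [new_archive()].
#' @param position the conformation (any object; stored as-is).
#' @param objectives finite numeric objective vector.
#' @param generation generation index at which the candidate was found.
#' @return the updated `pareto_archive`.
#' @export
archive_offer <- function(archive, position, objectives, generation = 0L) {
  objectives <- as.numeric(objectives)
  if (any(!is.finite(objectives))) {
    stop("Archive entries must have finite objectives.", call. = FALSE)
  }
  if (is.null(archive$obj)) {
    archive$obj <- matrix(objectives, 1L)
    archive$pos <- list(position)
    archive$gen <- as.integer(generation)
    return(archive)
  }
  A <- archive$obj
  n <- nrow(A)
  fo <- matrix(objectives, n, ncol(A), byrow = TRUE)
  le <- A <= fo
  lt <- A < fo
  # does any member dominate (or equal) the candidate?
  dominated_by_member <- any(rowSums(le) == ncol(A) & rowSums(lt) > 0L)
  duplicate <- any(rowSums(A == fo) == ncol(A))
  if (dominated_by_member || duplicate) return(archive)
  # remove members the candidate dominates
  ge <- A >= fo
  gt <- A > fo
  kill <- rowSums(ge) == ncol(A) & rowSums(gt) > 0L
  keep <- !kill
  archive$obj <- rbind(A[keep, , drop = FALSE], objectives)
  archive$pos <- c(archive$pos[keep], list(position))
  archive$gen <- c(archive$gen[keep], as.integer(generation))
  if (is.finite(archive$capacity) && nrow(archive$obj) > archive$capacity) {
    archive <- prune_archive(archive)
  }
  archive
}

# internal: crowding-distance pruning to capacity
prune_archive <- function(archive) {
  while (nrow(archive$obj) > archive$capacity) {
    cd <- crowding_distance(archive$obj)
    drop <- which.min(cd)
    keep <- setdiff(seq_len(nrow(archive$obj)), drop)
    archive$obj <- archive$obj[keep, , drop = FALSE]
    archive$pos <- archive$pos[keep]
    archive$gen <- archive$gen[keep]
  }
  archive
}

crowding_distance <- function(obj) {
  n <- nrow(obj)
  cd <- rep(0, n)
  for (k in seq_len(ncol(obj))) {
    o <- order(obj[, k])
    rng <- diff(range(obj[, k]))
    if (rng < 1e-300) next
    cd[o[1L]] <- Inf
    cd[o[n]] <- Inf
    if (n > 2L) {
      cd[o[2:(n - 1L)]] <- cd[o[2:(n - 1L)]] +
        (obj[o[3:n], k] - obj[o[1:(n - 2L)], k]) / rng
    }
  }
  cd
}

#' @export
length.pareto_archive <- function(x) {
  if (is.null(x$obj)) 0L else nrow(x$obj)
}

#' @export
print.pareto_archive <- function(x, ...) {
  cat(sprintf("<pareto_archive: %d non-dominated entries>\n", length(x)))
  invisible(x)
}

#' Tidy a Pareto archive into a tibble of objective vectors
#'
#' @param x a `pareto_archive`.
#' @param ... unused.
#' @return tibble with one row per entry: `entry`, `generation_found`, and
#'   one column per objective (`f1`, `f2`, ... or the model names).
#' @export
tidy.pareto_archive <- function(x, ...) {
  n <- length(x)
  if (n == 0L) {
    return(tibble::tibble(entry = integer(0L), generation_found = integer(0L)))
  }
  obj <- x$obj
  nm <- colnames(obj)
  if (is.null(nm)) nm <- paste0("f", seq_len(ncol(obj)))
  out <- tibble::as_tibble(stats::setNames(as.data.frame(obj), nm))
  dplyr::bind_cols(
    tibble::tibble(entry = seq_len(n), generation_found = x$gen),
    out
  )
}

#' Write the archive objective table to a TSV file
#'
#' @param archive a `pareto_archive`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_archive_tsv <- function(archive, path) {
  utils::write.table(tidy.pareto_archive(archive), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
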