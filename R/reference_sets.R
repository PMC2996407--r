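#' Geometric validity parameters for reference sets
#'
#' A reference set is an `n`-tuple of target residues that can seed a match.
#' Validity requires: (1) each C-alpha lies within `d_maxmindist` of its
#' nearest other C-alpha in the tuple; (2) all pairwise C-alpha distances are
#' strictly below `d_diameter`; (3) every member's surface depth is at most
#' `d_maxdepth`; (4) at least one member's depth is at most `d_maxmindepth`.
#' The defaults are the values used for triples throughout: the first pair
#' of constraints keeps the tuple compact, the second pair keeps it near the
#' molecular surface.
#'
#' @param n tuple size (default 3).
#' @param d_maxmindist nearest-neighbor bound within the tuple, Angstrom
#'   (default 16).
#' @param d_diameter strict pairwise diameter bound, Angstrom (default 25).
#' @param d_maxdepth maximum member depth, Angstrom (default 3.1).
#' @param d_maxmindepth bound that at least one member must satisfy,
#'   Angstrom (default 1.6).
#' @param check_depth logical; set `FALSE` to disable the two depth
#'   constraints (useful for targets without computed depths).
#' @return an object of class `geometric_params`.
#' @export
geometric_params <- function(n = 3L, d_maxmindist = 16, d_diameter = 25,
                             d_maxdepth = 3.1, d_maxmindepth = 1.6,
                             check_depth = TRUE) {
  n <- as.integer(n)
  stopifnot(n >= 2L, d_maxmindist > 0, d_diameter > 0, d_maxdepth > 0,
            d_maxmindepth > 0, d_maxmindepth <= d_maxdepth)
  structure(list(n = n, d_maxmindist = d_maxmindist, d_diameter = d_diameter,
                 d_maxdepth = d_maxdepth, d_maxmindepth = d_maxmindepth,
                 check_depth = isTRUE(check_depth)),
            class = "geometric_params")
}

#' @export
print.geometric_params <- function(x, ...) {
  cat("Reference-set parameters: n =", x$n,
      "| d_maxmindist =", x$d_maxmindist,
      "| d_diameter =", x$d_diameter, "\n")
  if (x$check_depth)
    cat("depth constraints: d_maxdepth =", x$d_maxdepth,
        "| d_maxmindepth =", x$d_maxmindepth, "\n")
  else cat("depth constraints: disabled\n")
  invisible(x)
}

#' Sorted label key of an n-tuple
#'
#' Reference sets are indexed by the lexicographically sorted tuple of their
#' residue labels, which makes the lookup independent of residue order.
#'
#' @param labels character vector of one-letter residue labels.
#' @param n expected arity (optional; error when the length differs).
#' @return sorted character vector of the same length.
#' @export
label_key <- function(labels, n = NULL) {
  if (!is.null(n) && length(labels) != n)
    stop("label key arity ", length(labels), " != expected ", n)
  bad <- setdiff(labels, AA1)
  if (length(bad))
    stop("not standard amino-acid labels: ", paste(bad, collapse = ", "))
  sort(labels, method = "radix")
}

label_key_string <- function(labels) paste(sort(labels, method = "radix"),
                                           collapse = "")

#' Test the four geometric validity constraints on one residue tuple
#'
#' @param target a `target_structure` (depths computed unless
#'   `params$check_depth` is `FALSE`).
#' @param indices integer vector of `params$n` distinct residue indices.
#' @param params a [geometric_params()] object.
#' @return logical scalar.
#' @export
is_valid_reference_set <- function(target, indices, params = geometric_params()) {
  indices <- as.integer(indices)
  if (length(indices) != params$n || anyDuplicated(indices))
    stop("need ", params$n, " distinct residue indices")
  ca <- target$ca[indices, , drop = FALSE]
  D <- as.matrix(dist(ca))
  offd <- D[upper.tri(D)]
  if (any(offd >= params$d_diameter)) return(FALSE)          # (2), strict
  diag(D) <- Inf
  if (any(apply(D, 1L, min) > params$d_maxmindist)) return(FALSE)  # (1)
  if (params$check_depth) {
    dep <- target$depth[indices]
    if (anyNA(dep))
      stop("depths not computed for target '", target$target_id,
           "' (run compute_depth or set check_depth = FALSE)")
    if (any(dep > params$d_maxdepth)) return(FALSE)          # (3)
    if (min(dep) > params$d_maxmindepth) return(FALSE)       # (4)
  }
  TRUE
}

#' Enumerate all valid reference sets of a target
#'
#' Finds every unordered `n`-subset of residues satisfying the four
#' geometric constraints.  The search is pruned through the pairwise
#' adjacency induced by `d_diameter` (only mutually close residues can form
#' a tuple), but the result is exactly the set a brute-force scan over all
#' `choose(N, n)` subsets would return.  Output rows are ascending index
#' tuples in lexicographic order.
#'
#' @inheritParams is_valid_reference_set
#' @return object of class `reference_sets`: list with `indices` (integer
#'   matrix, one row per set, `n` columns) and `key` (character vector of
#'   concatenated sorted label keys, e.g. `"DHK"`).
#' @export
enumerate_reference_sets <- function(target, params = geometric_params()) {
  n <- params$n
  N <- nrow(target$residues)
  empty <- structure(list(indices = matrix(integer(), 0L, n),
                          key = character()),
                     class = "reference_sets")
  if (N < n) return(empty)
  ok_depth <- if (params$check_depth) {
    if (anyNA(target$depth))
      stop("depths not computed for target '", target$target_id,
           "' (run compute_depth or set check_depth = FALSE)")
    target$depth <= params$d_maxdepth
  } else rep(TRUE, N)
  cand <- which(ok_depth)
  if (length(cand) < n) return(empty)
  ca <- target$ca
  D <- as.matrix(dist(ca))
  # adjacency under the strict diameter bound, restricted to depth-feasible
  A <- D < params$d_diameter & outer(ok_depth, ok_depth, `&`)
  diag(A) <- FALSE
  if (n == 3L) {
    # vectorized triple enumeration over the adjacency
    pairs <- which(A & upper.tri(A), arr.ind = TRUE)
    if (!nrow(pairs)) return(empty)
    seqN <- seq_len(N)
    rows <- vector("list", nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1L]; j <- pairs[p, 2L]
      ks <- seqN[A[i, ] & A[j, ] & seqN > j]
      if (length(ks))
        rows[[p]] <- cbind(i, j, ks, deparse.level = 0L)
    }
    idx <- do.call(rbind, rows)
    if (is.null(idx) || !nrow(idx)) return(empty)
    d12 <- D[idx[, c(1L, 2L), drop = FALSE]]
    d13 <- D[idx[, c(1L, 3L), drop = FALSE]]
    d23 <- D[idx[, c(2L, 3L), drop = FALSE]]
    mm <- params$d_maxmindist
    keep <- (pmin(d12, d13) <= mm) & (pmin(d12, d23) <= mm) &
            (pmin(d13, d23) <= mm)
    if (params$check_depth) {
      dep <- matrix(target$depth[idx], nrow(idx), 3L)
      keep <- keep & (dep[, 1L] <= params$d_maxmindepth |
                        dep[, 2L] <= params$d_maxmindepth |
                        dep[, 3L] <= params$d_maxmindepth)
    }
    idx <- idx[keep, , drop = FALSE]
  } else {
    adj <- lapply(seq_len(N), function(i) { j <- which(A[i, ]); j[j > i] })
    rows <- list()
    grow <- function(tuple, common) {
      if (length(tuple) == n) {
        rows[[length(rows) + 1L]] <<- tuple
        return(invisible())
      }
      for (j in common) {
        grow(c(tuple, j), intersect(common[common > j], adj[[j]]))
      }
    }
    for (i in cand) grow(i, adj[[i]])
    if (!length(rows)) return(empty)
    idx <- do.call(rbind, rows)
    # constraints (1) and (4) are tuple-level; (2)-pair and (3) already hold
    keep <- vapply(seq_len(nrow(idx)), function(r) {
      t_ <- idx[r, ]
      Dt <- D[t_, t_, drop = FALSE]
      diag(Dt) <- Inf
      if (any(apply(Dt, 1L, min) > params$d_maxmindist)) return(FALSE)
      if (params$check_depth && min(target$depth[t_]) > params$d_maxmindepth)
        return(FALSE)
      TRUE
    }, logical(1L))
    idx <- idx[keep, , drop = FALSE]
  }
  if (!nrow(idx)) return(empty)
  ord <- do.call(order, as.data.frame(idx))
  idx <- idx[ord, , drop = FALSE]
  keys <- apply(idx, 1L, function(t_) label_key_string(target$residues$label[t_]))
  structure(list(indices = idx, key = keys), class = "reference_sets")
}

#' @export
print.reference_sets <- function(x, ...) {
  cat("Reference sets:", nrow(x$indices), "tuples,",
      length(unique(x$key)), "distinct label keys\n")
  invisible(x)
}
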