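#' Precompute per-residue neighbor lists at radius 2r
#'
#' For fixed-radius queries about *arbitrary* points, it suffices to store,
#' for each residue, all residues within `2r`: if the residue nearest to a
#' query point is `x` away (`x <= r`), every residue within `r` of the query
#' lies within `r + x <= 2r` of that nearest residue.  [range_query()]
#' exploits exactly this.  Lists are exact and sorted by ascending distance.
#'
#' @param target a `target_structure`.
#' @param r query radius the lists must support, Angstrom (default 7, the
#'   match rejection threshold); lists are built at radius `2r`.
#' @return object of class `neighbor_lists`: `radius_2r`, and parallel lists
#'   `idx`/`dist` (per residue: neighbor indices and distances), plus the
#'   uniform grid used for nearest-residue searches.
#' @export
precompute_neighbor_lists <- function(target, r = 7) {
  stopifnot(r > 0)
  ca <- target$ca
  N <- nrow(ca)
  r2 <- 2 * r
  idx <- vector("list", N)
  dst <- vector("list", N)
  if (N > 0L) {
    D <- as.matrix(dist(ca))
    for (i in seq_len(N)) {
      j <- unname(which(D[i, ] <= r2))
      j <- j[j != i]
      o <- order(D[i, j], j)
      idx[[i]] <- j[o]
      dst[[i]] <- unname(D[i, j[o]])
    }
  }
  structure(list(radius_2r = r2, idx = idx, dist = dst,
                 grid = build_point_grid(ca, cell = r2)),
            class = "neighbor_lists")
}

# Uniform spatial grid over points: cells are addressed by a linear index
# into a list, so queries need only integer arithmetic.
build_point_grid <- function(pts, cell) {
  n <- nrow(pts)
  if (n == 0L)
    return(list(cells = list(), origin = c(0, 0, 0), cell = cell, n = 0L,
                dims = c(0L, 0L, 0L)))
  origin <- c(min(pts[, 1L]), min(pts[, 2L]), min(pts[, 3L]))
  ci <- floor((pts[, 1L] - origin[1L]) / cell)
  cj <- floor((pts[, 2L] - origin[2L]) / cell)
  ck <- floor((pts[, 3L] - origin[3L]) / cell)
  dims <- c(max(ci), max(cj), max(ck)) + 1L
  lin <- ci + dims[1L] * (cj + dims[2L] * ck) + 1L
  cells <- vector("list", prod(dims))
  by_cell <- split(seq_len(n), lin)
  for (nm in names(by_cell)) cells[[as.integer(nm)]] <- by_cell[[nm]]
  list(cells = cells, origin = origin, cell = cell, n = n, dims = dims)
}

# Exact nearest point to q via expanding Chebyshev rings of grid cells.
# Any point in a cell at ring k >= 1 is at Euclidean distance >= (k-1)*cell
# from q, so the scan stops as soon as best_d <= ring * cell.
grid_nearest <- function(grid, pts, q) {
  if (grid$n == 0L) return(list(index = NA_integer_, dist = Inf))
  cq <- floor((q - grid$origin) / grid$cell)
  dims <- grid$dims
  max_ring <- max(abs(cq), abs(cq - dims + 1L)) + 1L
  best_i <- NA_integer_
  best_d <- Inf
  ring <- 0L
  repeat {
    lo <- pmax(cq - ring, 0)
    hi <- pmin(cq + ring, dims - 1L)
    if (all(lo <= hi)) {
      for (ii in lo[1L]:hi[1L]) for (jj in lo[2L]:hi[2L]) for (kk in lo[3L]:hi[3L]) {
        if (max(abs(ii - cq[1L]), abs(jj - cq[2L]), abs(kk - cq[3L])) != ring)
          next
        cand <- grid$cells[[ii + dims[1L] * (jj + dims[2L] * kk) + 1L]]
        if (is.null(cand)) next
        dx <- pts[cand, 1L] - q[1L]
        dy <- pts[cand, 2L] - q[2L]
        dz <- pts[cand, 3L] - q[3L]
        d <- sqrt(dx * dx + dy * dy + dz * dz)
        m <- which.min(d)
        if (d[m] < best_d) { best_d <- d[m]; best_i <- cand[m] }
      }
    }
    if (!is.na(best_i) && best_d <= ring * grid$cell) break
    if (ring > max_ring) break
    ring <- ring + 1L
  }
  list(index = best_i, dist = best_d)
}

#' Fixed-radius range query about an arbitrary point
#'
#' Returns all residues whose C-alpha lies within `r` of the query point
#' `q`, using one nearest-residue search plus that residue's precomputed
#' `2r` neighbor list; the accept path never scans the whole target.
#' Members of the list closer than `r - x` (with `x` the nearest-residue
#' distance) are accepted outright; those in `[r - x, r + x]` are
#' distance-checked against `q`.  Exact for every `r` up to half the
#' precomputed radius.
#'
#' @param target a `target_structure`.
#' @param lists its [precompute_neighbor_lists()] result.
#' @param q query point (length-3, Angstrom).
#' @param r query radius, Angstrom; must satisfy `r <= lists$radius_2r / 2`.
#' @return sorted integer vector of residue indices (possibly empty).
#' @export
range_query <- function(target, lists, q, r) {
  if (r > lists$radius_2r / 2 + 1e-9)
    stop("query radius ", r, " exceeds half the precomputed radius ",
         lists$radius_2r)
  if (nrow(target$ca) == 0L) return(integer())
  nn <- grid_nearest(lists$grid, target$ca, q)
  x <- nn$dist
  if (x > r) return(integer())   # nothing can be within r
  i <- nn$index
  cand_idx <- lists$idx[[i]]
  cand_d <- lists$dist[[i]]
  sure <- cand_idx[cand_d <= r - x]
  check <- cand_idx[cand_d > r - x & cand_d <= r + x]
  if (length(check)) {
    dq <- sqrt(colSums((t(target$ca[check, , drop = FALSE]) - q)^2))
    sure <- c(sure, check[dq <= r])
  }
  sort(unique(c(i, sure)))
}
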