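#' Sheather-Jones plug-in bandwidth
#'
#' Solve-the-equation plug-in bandwidth for Gaussian-kernel density
#' estimation of a motif's RMSD distribution.  Falls back to Silverman's
#' rule of thumb (with a warning) when the sample has fewer than two
#' distinct values or the plug-in equation has no solution; the returned
#' value carries the method used as attribute `method`.
#'
#' @param samples numeric vector of RMSDs (Angstrom).
#' @return positive bandwidth (Angstrom), attribute
#'   `method = "sheather-jones"` or `"silverman"`.
#' @export
sheather_jones_bandwidth <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L || length(unique(samples)) < 2L) {
    warning("fewer than 2 distinct samples; using Silverman's rule")
    h <- if (length(samples) >= 2L) stats::bw.nrd0(samples) else NA_real_
    if (!is.finite(h) || h <= 0) h <- 0.1
    return(structure(h, method = "silverman"))
  }
  # fine binning and a tight root tolerance: the defaults (1000 bins,
  # tol ~ 1% of the bandwidth scale) can move the solution by a few percent
  h <- tryCatch(stats::bw.SJ(samples, nb = max(10000L, length(samples)),
                             method = "ste",
                             tol = 1e-6 * stats::sd(samples)),
                error = function(e) NA_real_)
  if (!is.finite(h) || h <= 0) {
    warning("Sheather-Jones solver failed; using Silverman's rule")
    return(structure(stats::bw.nrd0(samples), method = "silverman"))
  }
  structure(h, method = "sheather-jones")
}

#' Can a motif possibly match a target, judged by labels alone?
#'
#' True iff the target has enough residues of the right types: formally,
#' iff there is a system of distinct representatives assigning every motif
#' point a distinct target residue whose label lies in the point's allowed
#' set.  Solved as an exact bipartite matching between motif points and
#' label classes with capacities given by the target's label counts (a
#' greedy count is not sufficient when allowed sets overlap).
#'
#' @param label_counts named integer vector of the target's residue label
#'   frequencies (as stored in the table).
#' @param allowed_labels list of allowed-label sets, one per motif point
#'   (or a `motif`).
#' @return logical scalar.
#' @export
can_possibly_match <- function(label_counts, allowed_labels) {
  if (inherits(allowed_labels, "motif"))
    allowed_labels <- allowed_labels$allowed_labels
  m <- length(allowed_labels)
  labels <- names(label_counts)
  cap <- as.integer(label_counts)
  used <- integer(length(cap))
  # assignment[p] = label class index for motif point p
  assignment <- rep(NA_integer_, m)
  augment <- function(p, visited) {
    for (li in which(labels %in% allowed_labels[[p]])) {
      if (visited[li]) next
      visited[li] <- TRUE
      if (used[li] < cap[li]) {
        used[li] <<- used[li] + 1L
        assignment[p] <<- li
        return(TRUE)
      }
      # capacity full: try to re-route one of the points using this class
      for (q in which(assignment == li)) {
        old <- assignment[q]
        assignment[q] <<- NA_integer_
        used[old] <<- used[old] - 1L
        if (augment(q, visited)) {
          assignment[p] <<- li
          used[li] <<- used[li] + 1L
          return(TRUE)
        }
        assignment[q] <<- old
        used[old] <<- used[old] + 1L
      }
    }
    FALSE
  }
  for (p in seq_len(m)) {
    if (!augment(p, logical(length(cap)))) return(FALSE)
  }
  TRUE
}

#' Build a motif profile from per-target best matches
#'
#' The motif profile is the smoothed distribution of per-target best-match
#' RMSDs, together with a point weight at infinity for *missed* matches:
#' targets where no match was returned although the label counts admit one
#' (their existence is an artifact of the `epsilon` cutoff, and ignoring
#' them would bias p-values).  The model assumes exactly one complete,
#' lowest-RMSD match per target, so result sets produced with
#' `keep_multiple_per_target` or `min_partial_size` are refused.
#'
#' @param results a `match_results` object (default best-per-target mode).
#' @param count_infeasible_targets should targets that cannot match on
#'   label counts alone enter the denominator of the point weight?
#'   (default `FALSE`: every target weighs equally among those that could
#'   have matched).
#' @return object of class `motif_profile`: `rmsds`, `n_matched`,
#'   `n_missed`, `bandwidth` (+ method), `epsilon`, `m`.
#' @export
build_profile <- function(results, count_infeasible_targets = FALSE) {
  stopifnot(inherits(results, "match_results"))
  if (isTRUE(results$options$keep_multiple_per_target) ||
      !is.null(results$options$min_partial_size))
    stop("significance unavailable: the profile model requires one ",
         "complete lowest-RMSD match per target (multiple/partial match ",
         "modes are not supported)")
  matched <- vapply(results$targets, function(ms) length(ms) > 0L, logical(1L))
  if (any(matched)) {
    incomplete <- vapply(results$targets[matched],
                         function(ms) !ms[[1L]]$complete, logical(1L))
    if (any(incomplete))
      stop("significance unavailable: partial matches present")
  }
  rmsds <- vapply(results$targets[matched], function(ms) ms[[1L]]$rmsd, 0)
  unmatched_ids <- names(results$targets)[!matched]
  feasible <- vapply(unmatched_ids, function(tid)
    can_possibly_match(results$label_counts[[tid]], results$motif),
    logical(1L))
  n_missed <- if (count_infeasible_targets) length(unmatched_ids)
              else sum(feasible)
  if (!length(rmsds)) stop("empty profile: no matched targets")
  bw <- sheather_jones_bandwidth(rmsds)
  structure(list(rmsds = unname(rmsds),
                 n_matched = length(rmsds),
                 n_missed = as.integer(n_missed),
                 bandwidth = as.numeric(bw),
                 bandwidth_method = attr(bw, "method"),
                 epsilon = results$options$epsilon,
                 m = results$motif$m),
            class = "motif_profile")
}

#' Corrected p-value of a match RMSD
#'
#' `p = W * F(rmsd)` where `F` is the CDF of the Gaussian-kernel density
#' over the profile RMSDs (bandwidth from the profile), renormalized to the
#' nonnegative half-line, and `W = n_matched / (n_matched + n_missed)` is
#' the matched share of the probability mass -- the remainder sits as a
#' point weight at infinity for the missed matches.  Equivalently
#' `A / (A + B + C)`: the density area left of the match over the total
#' area including the missed-match point mass.  `p` is nondecreasing in
#' RMSD and tends to `W` as RMSD grows.
#'
#' @param profile a `motif_profile`.
#' @param rmsd numeric vector of match RMSDs (Angstrom, nonnegative).
#' @return p-values in `[0, 1]`.
#' @export
corrected_pvalue <- function(profile, rmsd) {
  stopifnot(inherits(profile, "motif_profile"))
  if (any(rmsd < 0)) stop("rmsd must be nonnegative")
  if (!profile$n_matched) stop("empty profile")
  W <- profile$n_matched / (profile$n_matched + profile$n_missed)
  Fh <- halfline_kernel_cdf(profile$rmsds, profile$bandwidth)
  pmin(pmax(W * Fh(rmsd), 0), 1)
}

# CDF at r of the Gaussian kernel sum over x, renormalized to [0, Inf).
halfline_kernel_cdf <- function(x, h) {
  mass0 <- stats::pnorm(0, mean = x, sd = h)       # kernel mass below 0
  total <- sum(1 - mass0)
  function(r) {
    vapply(r, function(ri)
      sum(stats::pnorm(ri, mean = x, sd = h) - mass0) / total, 0)
  }
}

#' Kernel density of the motif profile on the half-line
#'
#' Two-column evaluation of the renormalized profile density, suitable for
#' plotting or export.
#'
#' @param profile a `motif_profile`.
#' @param grid evaluation points (default: 512 points spanning
#'   `[0, epsilon]`).
#' @return data frame with columns `rmsd` and `density` (the density
#'   integrates to `W`, the matched mass).
#' @export
profile_density <- function(profile, grid = NULL) {
  if (is.null(grid)) grid <- seq(0, profile$epsilon, length.out = 512L)
  x <- profile$rmsds
  h <- profile$bandwidth
  total <- sum(1 - stats::pnorm(0, mean = x, sd = h))
  W <- profile$n_matched / (profile$n_matched + profile$n_missed)
  dens <- vapply(grid, function(g)
    W * sum(stats::dnorm(g, mean = x, sd = h)) / total, 0)
  data.frame(rmsd = grid, density = dens)
}

#' RMSD bound below which p-values are unaffected by the epsilon cutoff
#'
#' Matches with RMSD below `epsilon / sqrt(m)` have exact corrected
#' p-values: no match that would alter the probability mass to their left
#' can have been rejected by the cutoff.  For a 6-residue motif at the
#' default `epsilon = 7` Angstrom the bound is 7 / sqrt(6), about 2.9
#' Angstrom.
#'
#' @param m motif size (number of residues), at least 1.
#' @param epsilon RMSD rejection threshold, Angstrom.
#' @return the bound, Angstrom.
#' @export
exactness_bound <- function(m, epsilon) {
  stopifnot(m >= 1, epsilon > 0)
  epsilon / sqrt(m)
}

#' @export
print.motif_profile <- function(x, ...) {
  W <- x$n_matched / (x$n_matched + x$n_missed)
  cat("Motif profile: ", x$n_matched, " matched target(s), ", x$n_missed,
      " missed (point weight ", round(1 - W, 4), " at infinity)\n", sep = "")
  cat("bandwidth ", format(x$bandwidth, digits = 4), " A (",
      x$bandwidth_method, "), epsilon ", x$epsilon,
      " A, exactness bound ", round(exactness_bound(x$m, x$epsilon), 2),
      " A\n", sep = "")
  invisible(x)
}

#' @export
plot.motif_profile <- function(x, ...) {
  d <- profile_density(x)
  plot(d$rmsd, d$density, type = "l", xlab = "RMSD (A)",
       ylab = "density", main = "Motif profile", ...)
  graphics::rug(x$rmsds)
  invisible(d)
}
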