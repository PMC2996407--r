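#' Construct a structural motif
#'
#' A motif is an ordered list of residue points: author-numbering residue
#' identities from a source structure, their C-alpha coordinates, a nonempty
#' set of allowed residue labels per point, and (optionally) side-chain
#' centroids for centroid-based best-match selection.
#'
#' @param motif_id identifier for the motif.
#' @param source_structure identifier of the structure the coordinates come
#'   from.
#' @param point_ids character vector of residue identities, e.g. `"A164"`
#'   (chain, author sequence number, optional insertion code).
#' @param ca numeric m x 3 matrix of C-alpha coordinates (Angstrom).
#' @param allowed_labels list of character vectors (one nonempty set of
#'   one-letter labels per point).
#' @param centroid optional m x 3 matrix of side-chain centroids.
#' @return an object of class `motif`.
#' @export
motif <- function(motif_id, source_structure, point_ids, ca, allowed_labels,
                  centroid = NULL) {
  ca <- as_coord_matrix(ca)
  m <- nrow(ca)
  stopifnot(length(point_ids) == m, length(allowed_labels) == m)
  if (anyDuplicated(point_ids))
    stop("duplicate motif point ids: ",
         paste(unique(point_ids[duplicated(point_ids)]), collapse = ", "))
  allowed_labels <- lapply(allowed_labels, function(l) {
    l <- sort(unique(as.character(l)), method = "radix")
    if (!length(l)) stop("each motif point needs a nonempty allowed-label set")
    bad <- setdiff(l, AA1)
    if (length(bad))
      stop("not standard amino-acid labels: ", paste(bad, collapse = ", "))
    l
  })
  if (!is.null(centroid)) centroid <- as_coord_matrix(centroid)
  structure(list(motif_id = motif_id, source_structure = source_structure,
                 point_ids = as.character(point_ids), ca = ca,
                 allowed_labels = allowed_labels, centroid = centroid,
                 m = m),
            class = "motif")
}

#' Extract a motif from a parsed target structure
#'
#' @param target a `target_structure`.
#' @param point_ids residue identities (`"A164"`-style author numbering).
#' @param allowed_labels optional list of allowed-label sets (defaults to
#'   each residue's own label).
#' @param motif_id motif identifier (default derived from the target).
#' @return a `motif` with coordinates and side-chain centroids pulled from
#'   the target.
#' @export
motif_from_target <- function(target, point_ids, allowed_labels = NULL,
                              motif_id = NULL) {
  ids <- vapply(seq_len(nrow(target$residues)), function(i)
    residue_id_string(target$residues, i), "")
  at <- match(point_ids, ids)
  if (anyNA(at))
    stop("residue(s) not found in '", target$target_id, "': ",
         paste(point_ids[is.na(at)], collapse = ", "))
  if (is.null(allowed_labels))
    allowed_labels <- as.list(target$residues$label[at])
  if (is.null(motif_id))
    motif_id <- paste0(target$target_id, "-motif")
  motif(motif_id, target$target_id, point_ids,
        target$ca[at, , drop = FALSE], allowed_labels,
        centroid = target$centroid[at, , drop = FALSE])
}

#' @export
print.motif <- function(x, ...) {
  cat("Motif '", x$motif_id, "' (source ", x$source_structure, "), ",
      x$m, " points:\n", sep = "")
  for (i in seq_len(x$m))
    cat("  ", x$point_ids[i], " {",
        paste(x$allowed_labels[[i]], collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Matching options
#'
#' @param epsilon RMSD rejection threshold, Angstrom (default 7): a partial
#'   match whose optimal-superposition RMSD exceeds it is pruned.
#'   Deliberately generous so no interesting match is missed; the
#'   significance model corrects for it.
#' @param candidate_radius radius for candidate residues around an aligned
#'   motif point, Angstrom (defaults to `epsilon`).
#' @param max_seed_refsets number of rarest motif reference sets tried as
#'   seeds (default 15).
#' @param keep_multiple_per_target keep all complete matches per target
#'   instead of only the best one (default `FALSE`).
#' @param min_partial_size when set, pruned branches of at least this many
#'   matched points are emitted as partial matches.
#' @param rmsd_weight weight (per Angstrom) of RMSD against match size in
#'   the partial-match ranking score `size - rmsd_weight * rmsd`.
#' @param best_match_criterion `"ca_rmsd"` (default) or
#'   `"sidechain_centroid_rmsd"` for per-target best-match selection.
#' @param augment_order `"centroid_distance"` (default: remaining motif
#'   points by ascending distance from the seed reference set's centroid)
#'   or `"motif_order"`.
#' @return an object of class `match_options`.
#' @export
match_options <- function(epsilon = 7, candidate_radius = epsilon,
                          max_seed_refsets = 15L,
                          keep_multiple_per_target = FALSE,
                          min_partial_size = NULL,
                          rmsd_weight = 1,
                          best_match_criterion = c("ca_rmsd",
                                                   "sidechain_centroid_rmsd"),
                          augment_order = c("centroid_distance",
                                            "motif_order")) {
  stopifnot(epsilon > 0, candidate_radius > 0, max_seed_refsets >= 1L)
  structure(list(epsilon = epsilon, candidate_radius = candidate_radius,
                 max_seed_refsets = as.integer(max_seed_refsets),
                 keep_multiple_per_target = isTRUE(keep_multiple_per_target),
                 min_partial_size = if (is.null(min_partial_size)) NULL
                                    else as.integer(min_partial_size),
                 rmsd_weight = rmsd_weight,
                 best_match_criterion = match.arg(best_match_criterion),
                 augment_order = match.arg(augment_order)),
            class = "match_options")
}

#' Valid reference sets of a motif
#'
#' All `n`-subsets of motif points satisfying the two distance constraints
#' (`d_maxmindist`, strict `d_diameter`).  Depth constraints never apply to
#' motif points -- a motif carries no molecular surface.  Each subset is
#' annotated with the set of sorted label keys induced by its points'
#' allowed-label combinations (deduplicated after sorting).
#'
#' @param motif a `motif`.
#' @param params [geometric_params()].
#' @return list of motif reference sets, each a list with `points` (integer
#'   motif point indices) and `keys` (character vector of key strings);
#'   error when the motif admits no valid reference set (such a motif is
#'   unmatchable).
#' @export
motif_reference_sets <- function(motif, params = geometric_params()) {
  n <- params$n
  if (motif$m < n)
    stop("unmatchable motif '", motif$motif_id, "': ", motif$m,
         " points < reference-set size ", n)
  combos <- combn(motif$m, n)
  D <- as.matrix(dist(motif$ca))
  out <- list()
  for (c_ in seq_len(ncol(combos))) {
    t_ <- combos[, c_]
    Dt <- D[t_, t_, drop = FALSE]
    offd <- Dt[upper.tri(Dt)]
    if (any(offd >= params$d_diameter)) next
    diag(Dt) <- Inf
    if (any(apply(Dt, 1L, min) > params$d_maxmindist)) next
    lab <- expand.grid(motif$allowed_labels[t_], stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
    keys <- unique(apply(as.matrix(lab), 1L, label_key_string))
    out[[length(out) + 1L]] <- list(points = t_,
                                    keys = sort(keys, method = "radix"))
  }
  if (!length(out))
    stop("unmatchable motif '", motif$motif_id,
         "': no valid reference set under the given geometric parameters")
  out
}

#' Rank motif reference sets by table rarity
#'
#' Seeds are tried rarest-first: a reference set matched by few stored
#' reference sets is more indicative of specific structure than a common
#' one.  Rarity is the total [key_frequency()] summed over the reference
#' set's induced keys; ties break lexicographically by key string, then by
#' motif point indices, making the order deterministic.
#'
#' @param motif_refsets result of [motif_reference_sets()].
#' @param table a `label_table`.
#' @param target_filter optional target restriction for the frequencies.
#' @return the input list, reordered, each element gaining a `frequency`.
#' @export
rank_seed_reference_sets <- function(motif_refsets, table,
                                     target_filter = NULL) {
  freq <- vapply(motif_refsets, function(rs)
    sum(vapply(rs$keys, function(k) key_frequency(table, k, target_filter),
               integer(1L))), integer(1L))
  keytie <- vapply(motif_refsets, function(rs)
    paste(rs$keys, collapse = "|"), "")
  ptstie <- vapply(motif_refsets, function(rs)
    paste(sprintf("%04d", rs$points), collapse = ""), "")
  ord <- order(freq, keytie, ptstie, method = "radix")
  out <- motif_refsets[ord]
  for (i in seq_along(out)) out[[i]]$frequency <- freq[ord[i]]
  out
}

# All permutations of 1..n (deterministic lexicographic order, memoized).
.perm_cache <- new.env(parent = emptyenv())
permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  gen <- function(n) {
    if (n == 1L) return(list(1L))
    out <- list()
    for (p in gen(n - 1L))
      for (pos in seq_len(n))
        out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    out
  }
  out <- gen(n)
  out <- out[order(vapply(out, paste, "", collapse = ","))]
  .perm_cache[[key]] <- out
  out
}

#' Solve the label correspondence between a motif reference set and a
#' stored reference set
#'
#' Stored reference sets are unordered; every bijection pairing each target
#' residue with a motif point whose allowed labels contain the residue's
#' label is a distinct candidate correspondence, and all of them are
#' considered.
#'
#' @param motif a `motif`.
#' @param refset_points integer motif point indices (one reference set).
#' @param target a `target_structure`.
#' @param index_tuple integer target residue indices (same arity).
#' @return list of integer vectors `corr` with `corr[j]` the target residue
#'   index assigned to motif point `refset_points[j]`; empty if labels are
#'   incompatible.
#' @export
resolve_correspondences <- function(motif, refset_points, target, index_tuple) {
  n <- length(refset_points)
  stopifnot(length(index_tuple) == n)
  labs <- target$residues$label[index_tuple]
  out <- list()
  for (p in permutations(n)) {
    ok <- all(vapply(seq_len(n), function(j)
      labs[p[j]] %in% motif$allowed_labels[[refset_points[j]]], logical(1L)))
    if (ok) out[[length(out) + 1L]] <- index_tuple[p]
  }
  out
}

# Order of the remaining (non-seed) motif points for augmentation.
augmentation_order <- function(motif, refset_points, options) {
  rest <- setdiff(seq_len(motif$m), refset_points)
  if (!length(rest)) return(integer())
  if (options$augment_order == "motif_order") return(rest)
  cen <- colMeans(motif$ca[refset_points, , drop = FALSE])
  d <- sqrt(colSums((t(motif$ca[rest, , drop = FALSE]) - cen)^2))
  rest[order(d, rest)]
}

#' Depth-first match augmentation from a seed correspondence
#'
#' Expands a seed (reference-set) correspondence one motif point at a time.
#' At each step the candidate target residues for the next motif point are
#' those within `candidate_radius` of the point's position under the
#' current optimal alignment (via [range_query()]), label-compatible and
#' not already used.  Each acceptance re-runs the optimal superposition on
#' the enlarged correspondence; branches whose RMSD exceeds `epsilon` are
#' pruned.  Residues added here are *not* subject to the reference-set
#' geometric or depth constraints.  Leaves of size `m` are complete
#' matches; when `min_partial_size` is set, dead-end branches of at least
#' that size are emitted as partial matches.
#'
#' @param motif a `motif`.
#' @param refset_points motif point indices of the seeding reference set.
#' @param seed_corr integer vector: target residue indices corresponded to
#'   `refset_points` (same order).
#' @param target a `target_structure`.
#' @param lists its `neighbor_lists` (precomputed at `2 * candidate_radius`
#'   or wider).
#' @param options [match_options()].
#' @return list of raw matches: each a list with `corr` (length-`m` integer
#'   vector, `NA` at unmatched points), `rmsd`, `size`, `complete`.
#' @export
augment_match <- function(motif, refset_points, seed_corr, target, lists,
                          options = match_options()) {
  m <- motif$m
  eps <- options$epsilon
  corr <- rep(NA_integer_, m)
  corr[refset_points] <- seed_corr
  seed_aln <- optimal_superposition(motif$ca[refset_points, , drop = FALSE],
                                    target$ca[seed_corr, , drop = FALSE])
  if (seed_aln$rmsd > eps) return(list())
  order_rest <- augmentation_order(motif, refset_points, options)
  results <- list()
  emit_partials <- !is.null(options$min_partial_size)

  recurse <- function(corr, aln, depth) {
    if (depth > length(order_rest)) {
      results[[length(results) + 1L]] <<- list(corr = corr, rmsd = aln$rmsd,
                                               size = m, complete = TRUE)
      return(invisible())
    }
    p <- order_rest[depth]
    pos <- apply_alignment(aln, motif$ca[p, ])
    cand <- range_query(target, lists, pos, options$candidate_radius)
    cand <- cand[target$residues$label[cand] %in% motif$allowed_labels[[p]]]
    cand <- setdiff(cand, corr[!is.na(corr)])
    extended <- FALSE
    for (j in cand) {
      new_corr <- corr
      new_corr[p] <- j
      sel <- which(!is.na(new_corr))
      new_aln <- optimal_superposition(motif$ca[sel, , drop = FALSE],
                                       target$ca[new_corr[sel], , drop = FALSE])
      if (new_aln$rmsd <= eps) {
        extended <- TRUE
        recurse(new_corr, new_aln, depth + 1L)
      }
    }
    if (!extended && emit_partials) {
      size <- sum(!is.na(corr))
      if (size >= options$min_partial_size)
        results[[length(results) + 1L]] <<- list(corr = corr,
                                                 rmsd = aln$rmsd,
                                                 size = size,
                                                 complete = FALSE)
    }
    invisible()
  }
  recurse(corr, seed_aln, 1L)
  results
}

#' Match a motif against the targets of a label table
#'
#' The matching stage: partial matches of size `n` are looked up instantly
#' under the motif's rarest reference-set keys, every label correspondence
#' of every hit is expanded by depth-first [augment_match()], duplicates
#' (identical correspondences reached from different seeds) are collapsed
#' onto the first, rarest seed, and by default only the best match per
#' target is kept.  Output is deterministic for fixed inputs.
#'
#' @param motif a `motif`.
#' @param table a `label_table` (its stored [geometric_params()] are used;
#'   supplying different `params` is refused unless `override_params =
#'   TRUE`, because mixed parameters silently invalidate the significance
#'   statistics).
#' @param target_filter optional character vector of target ids.
#' @param options [match_options()].
#' @param params optional [geometric_params()] override.
#' @param override_params allow `params` to differ from the table's.
#' @param seed_filter target set over which seed rarity is computed
#'   (default `target_filter`); [run_parallel()] passes the full run's
#'   filter here so that every worker ranks seeds identically regardless
#'   of how targets are partitioned.
#' @return object of class `match_results`: per-target lists of matches
#'   (each with `correspondence` in author numbering, `rmsd`,
#'   `sidechain_centroid_rmsd` when available, `size`, `complete`,
#'   `seed_key`), plus the considered target ids and per-target label
#'   counts for downstream significance.
#' @export
match_motif <- function(motif, table, target_filter = NULL,
                        options = match_options(), params = NULL,
                        override_params = FALSE, seed_filter = target_filter) {
  if (is.null(params)) params <- table$params
  else if (!identical(unclass(params), unclass(table$params)) &&
           !override_params)
    stop("supplied geometric params differ from the table's build params; ",
         "pass override_params = TRUE to force")
  if (2 * options$candidate_radius > table$meta$neighbor_radius_2r + 1e-9)
    stop("candidate_radius ", options$candidate_radius,
         " exceeds half the table's precomputed neighbor radius ",
         table$meta$neighbor_radius_2r)
  mrs <- motif_reference_sets(motif, params)
  ranked <- rank_seed_reference_sets(mrs, table, seed_filter)
  seeds <- head(ranked, options$max_seed_refsets)

  ids <- if (is.null(target_filter)) table$targets
         else intersect(table$targets, sort(target_filter))
  keymaps <- list()
  for (rs in seeds) for (k in rs$keys)
    if (is.null(keymaps[[k]])) keymaps[[k]] <- lookup(table, k, ids)

  per_target <- setNames(vector("list", length(ids)), ids)
  label_counts <- setNames(vector("list", length(ids)), ids)
  for (tid in ids) {
    tg <- read_target(table, tid)
    label_counts[[tid]] <- tg$label_counts
    lists <- attr(tg, "neighbor_lists")
    found <- list()
    seen <- character()
    for (rs in seeds) {
      for (k in rs$keys) {
        tuples <- keymaps[[k]][[tid]]
        if (is.null(tuples) || !nrow(tuples)) next
        for (row in seq_len(nrow(tuples))) {
          for (corr in resolve_correspondences(motif, rs$points, tg,
                                               tuples[row, ])) {
            for (mt in augment_match(motif, rs$points, corr, tg, lists,
                                     options)) {
              sig <- paste(which(!is.na(mt$corr)),
                           mt$corr[!is.na(mt$corr)],
                           sep = ":", collapse = ",")
              if (sig %in% seen) next
              seen <- c(seen, sig)
              mt$seed_key <- k
              found[[length(found) + 1L]] <- mt
            }
          }
        }
      }
    }
    per_target[[tid]] <- lapply(found, finalize_match, motif = motif,
                                target = tg, options = options)
  }

  res <- structure(list(motif = motif, options = options, params = params,
                        targets = per_target, target_ids = ids,
                        label_counts = label_counts),
                   class = "match_results")
  if (!options$keep_multiple_per_target)
    res <- select_best_per_target(res, options$best_match_criterion)
  res
}

finalize_match <- function(mt, motif, target, options) {
  sel <- which(!is.na(mt$corr))
  tres <- target$residues
  ids <- vapply(mt$corr[sel], function(i) residue_id_string(tres, i), "")
  cen_rmsd <- NA_real_
  if (!is.null(motif$centroid) && !is.null(target$centroid)) {
    aln <- optimal_superposition(motif$ca[sel, , drop = FALSE],
                                 target$ca[mt$corr[sel], , drop = FALSE])
    cen_rmsd <- rmsd_under_alignment(aln,
                                     motif$centroid[sel, , drop = FALSE],
                                     target$centroid[mt$corr[sel], , drop = FALSE])
  }
  list(target_id = target$target_id,
       points = motif$point_ids[sel],
       residues = ids,
       residue_labels = tres$label[mt$corr[sel]],
       indices = mt$corr,
       rmsd = mt$rmsd,
       sidechain_centroid_rmsd = cen_rmsd,
       size = mt$size,
       complete = mt$complete,
       seed_key = mt$seed_key,
       partial_score = mt$size - options$rmsd_weight * mt$rmsd)
}

#' Keep only the best match per target
#'
#' @param results a `match_results` object.
#' @param criterion `"ca_rmsd"` or `"sidechain_centroid_rmsd"` (the latter
#'   selects by deviation over side-chain centroids, which separates e.g.
#'   carboxylate-coordination sites better than backbone deviation); ties
#'   break by smaller C-alpha RMSD, then lexicographic correspondence.
#' @return the `match_results` with at most one match per target.
#' @export
select_best_per_target <- function(results,
                                   criterion = c("ca_rmsd",
                                                 "sidechain_centroid_rmsd")) {
  criterion <- match.arg(criterion)
  results$targets <- lapply(results$targets, function(ms) {
    if (!length(ms)) return(ms)
    if (criterion == "sidechain_centroid_rmsd") {
      bad <- vapply(ms, function(m) is.na(m$sidechain_centroid_rmsd),
                    logical(1L))
      if (any(bad))
        stop("sidechain_centroid_rmsd unavailable for match(es) on target '",
             ms[[1L]]$target_id, "' (residues: ",
             paste(unlist(lapply(ms[bad], `[[`, "residues")), collapse = ", "),
             ")")
      key1 <- vapply(ms, `[[`, 0, "sidechain_centroid_rmsd")
    } else key1 <- vapply(ms, `[[`, 0, "rmsd")
    key2 <- vapply(ms, `[[`, 0, "rmsd")
    key3 <- vapply(ms, function(m) paste(m$residues, collapse = ","), "")
    ms[order(key1, key2, key3)][1L]
  })
  results$options$keep_multiple_per_target <- FALSE
  results
}

#' @export
print.match_results <- function(x, ...) {
  nm <- sum(vapply(x$targets, length, integer(1L)) > 0L)
  cat("Match results for motif '", x$motif$motif_id, "': ",
      length(x$target_ids), " target(s) considered, ", nm,
      " with at least one match\n", sep = "")
  invisible(x)
}

#' @export
summary.match_results <- function(object, ...) {
  df <- matches_data_frame(object)
  print(object)
  if (nrow(df)) {
    cat("RMSD range: [", round(min(df$rmsd), 3), ", ",
        round(max(df$rmsd), 3), "] A over ", nrow(df), " match(es)\n",
        sep = "")
  }
  invisible(df)
}

#' Flatten match results to a data frame
#'
#' @param results a `match_results` object.
#' @return data frame with one row per match: target id, RMSDs, size,
#'   completeness, seed key and the correspondence collapsed to a string.
#' @export
matches_data_frame <- function(results) {
  rows <- list()
  for (tid in names(results$targets)) {
    for (m in results$targets[[tid]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        target_id = tid,
        rmsd = m$rmsd,
        sidechain_centroid_rmsd = m$sidechain_centroid_rmsd,
        size = m$size,
        complete = m$complete,
        seed_key = m$seed_key,
        correspondence = paste(m$points, m$residues, sep = "->",
                               collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(target_id = character(), rmsd = numeric(),
                      sidechain_centroid_rmsd = numeric(), size = integer(),
                      complete = logical(), seed_key = character(),
                      correspondence = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
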