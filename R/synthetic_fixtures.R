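#' Generate a protein-like synthetic target
#'
#' Self-avoiding random C-alpha walk with consecutive spacing 3.8 +/- 0.05
#' Angstrom, minimum non-consecutive separation 4 Angstrom, and a soft
#' confinement radius scaling like a globular chain, so targets are compact
#' enough to contain reference sets.  Residue labels are drawn from a
#' configurable composition; synthetic side-chain centroids sit at random
#' 1.5-3 Angstrom offsets from each C-alpha; depths come from the package's
#' surface approximation applied to the C-alpha trace.
#'
#' @param size number of residues (at least 4).
#' @param seed integer seed; the structure is a pure function of
#'   `(size, seed, composition)`.
#' @param composition optional named probability vector over the 20 labels
#'   (default uniform).
#' @param id target identifier (default `"SYN<seed>"`).
#' @param chain chain identifier (default `"A"`).
#' @return a `target_structure` with depths computed.
#' @export
generate_structure <- function(size, seed, composition = NULL,
                               id = NULL, chain = "A") {
  stopifnot(size >= 4L)
  if (is.null(id)) id <- paste0("SYN", seed)
  rng <- local_rng(seed)
  confine <- 3.8 * size^0.55
  for (attempt in 1:25) {
    pts <- try_walk(size, confine, rng)
    if (!is.null(pts)) break
    pts <- NULL
  }
  if (is.null(pts))
    stop("self-avoiding walk placement failed after bounded retries (seed ",
         seed, ", size ", size, ")")
  labels <- sample_labels(size, composition, rng)
  offs <- random_unit_vectors(size, rng) * rng$runif(size, 1.5, 3)
  centroid <- pts + offs
  residues <- data.frame(chain_id = chain, seq_number = seq_len(size),
                         insertion_code = "", label = labels,
                         stringsAsFactors = FALSE)
  atoms <- data.frame(res_index = seq_len(size), name = "CA", element = "C",
                      x = pts[, 1L], y = pts[, 2L], z = pts[, 3L],
                      stringsAsFactors = FALSE)
  tg <- new_target_structure(id, residues, pts, centroid,
                             centroid_flag = rep(FALSE, size), atoms = atoms)
  compute_depth(tg)
}

# Small counter-based RNG wrapper: isolates fixture generation from the
# global .Random.seed so callers' RNG state is untouched.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    runif = function(n, min = 0, max = 1) with_state(function() runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(function() rnorm(n, mean, sd)),
    sample = function(x, size, replace = FALSE, prob = NULL)
      with_state(function() sample(x, size, replace, prob)),
    sample_int = function(n, size) with_state(function() sample.int(n, size))
  )
}

try_walk <- function(size, confine, rng) {
  pts <- matrix(NA_real_, size, 3L)
  pts[1L, ] <- c(0, 0, 0)
  for (i in 2:size) {
    placed <- FALSE
    for (try in 1:200) {
      dir <- as.numeric(random_unit_vectors(1L, rng))
      step <- rng$runif(1L, 3.76, 3.84)
      cand <- pts[i - 1L, ] + dir * step
      if (sqrt(sum(cand^2)) > confine) next
      if (i > 2L) {
        d2 <- colSums((t(pts[seq_len(i - 2L), , drop = FALSE]) - cand)^2)
        if (any(d2 < 16)) next   # non-consecutive min separation 4 A
      }
      pts[i, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  pts
}

random_unit_vectors <- function(n, rng) {
  v <- matrix(rng$rnorm(3L * n), n, 3L)
  v / sqrt(rowSums(v^2))
}

sample_labels <- function(size, composition, rng) {
  if (is.null(composition)) {
    rng$sample(AA1, size, replace = TRUE)
  } else {
    stopifnot(all(names(composition) %in% AA1))
    rng$sample(names(composition), size, replace = TRUE,
               prob = as.numeric(composition))
  }
}

#' Plant a noise-perturbed motif instance into a target
#'
#' Selects a spatially compact subset of residues (a random anchor plus its
#' nearest residues), replaces their C-alpha coordinates with the motif
#' geometry perturbed by isotropic Gaussian noise (sd `noise_sigma` per
#' coordinate) and rigidly placed onto the host subset, and sets their
#' labels to a random choice from each point's allowed set.  Centroids keep
#' their offsets; depths are recomputed.  The true correspondence is
#' recorded and returned.
#'
#' @param target a `target_structure`.
#' @param motif a `motif`.
#' @param noise_sigma Gaussian noise standard deviation per coordinate,
#'   Angstrom (default 0.25).
#' @param seed integer seed.
#' @return list with `target` (modified) and `truth` (data frame: motif
#'   `point_id`, host `residue_id`, host `index`).
#' @export
plant_motif <- function(target, motif, noise_sigma = 0.25, seed = 1L) {
  m <- motif$m
  N <- nrow(target$residues)
  if (N < m) stop("target too small to host the motif")
  rng <- local_rng(seed + 7919L)
  motif_diam <- max(dist(motif$ca))
  anchors <- rng$sample_int(N, min(N, 20L))
  host <- NULL
  for (a in anchors) {
    d <- sqrt(colSums((t(target$ca) - target$ca[a, ])^2))
    cand <- order(d)[seq_len(m)]
    if (max(dist(target$ca[cand, , drop = FALSE])) <= motif_diam + 6) {
      host <- sort(cand)
      break
    }
  }
  if (is.null(host))
    stop("no compact host subset found in target '", target$target_id, "'")
  noisy <- motif$ca + matrix(rng$rnorm(3L * m, sd = noise_sigma), m, 3L)
  aln <- optimal_superposition(noisy, target$ca[host, , drop = FALSE])
  placed <- apply_alignment(aln, noisy)
  offs <- target$centroid[host, , drop = FALSE] - target$ca[host, , drop = FALSE]
  target$ca[host, ] <- placed
  target$centroid[host, ] <- placed + offs
  new_labels <- vapply(seq_len(m), function(j) {
    al <- motif$allowed_labels[[j]]
    if (length(al) == 1L) al else rng$sample(al, 1L)
  }, "")
  target$residues$label[host] <- new_labels
  if (!is.null(target$atoms)) {
    for (j in seq_len(m)) {
      rows <- which(target$atoms$res_index == host[j] &
                      target$atoms$name == "CA")
      target$atoms$x[rows] <- placed[j, 1L]
      target$atoms$y[rows] <- placed[j, 2L]
      target$atoms$z[rows] <- placed[j, 3L]
    }
  }
  target$label_counts <- count_labels(target$residues$label)
  target <- compute_depth(target)
  truth <- data.frame(
    point_id = motif$point_ids,
    residue_id = vapply(host, function(i)
      residue_id_string(target$residues, i), ""),
    index = host,
    stringsAsFactors = FALSE)
  list(target = target, truth = truth)
}

#' The default synthetic benchmark motif
#'
#' A five-point catalytic-site-like arrangement (compact, 5-10 Angstrom
#' spacing) with alternate labels patterned on a divalent-ion coordination
#' site: Lys/His, Asp, Glu, Glu/Asp/Asn, His/Lys.
#'
#' @return a `motif` (with synthetic side-chain centroids).
#' @export
default_benchmark_motif <- function() {
  ca <- matrix(c(
    0.0, 0.0, 0.0,
    6.1, 1.2, 0.8,
    2.3, 5.9, 2.1,
    7.0, 6.5, -1.0,
    3.5, 3.0, 6.0), ncol = 3L, byrow = TRUE)
  cen <- ca + matrix(c(
    1.8, 0.4, 0.6,
    -0.9, 1.5, 0.8,
    0.5, -1.7, 1.0,
    -1.2, -0.8, 1.3,
    1.0, 1.1, -1.4), ncol = 3L, byrow = TRUE)
  motif("synthetic-site", "SYNMOTIF",
        point_ids = paste0("A", 1:5),
        ca = ca,
        allowed_labels = list(c("K", "H"), "D", "E", c("E", "D", "N"),
                              c("H", "K")),
        centroid = cen)
}

#' Specification of a synthetic benchmark
#'
#' @param n_targets number of targets (default 200).
#' @param size_range inclusive range of target sizes in residues
#'   (default 50-80).
#' @param planted_fraction fraction of targets receiving a planted motif
#'   instance (default 0.5).
#' @param noise_sigma planting noise sd per coordinate, Angstrom
#'   (default 0.25).
#' @param decoy_mode `"label-shuffled"` (default: decoys keep their walk
#'   geometry but receive, at scattered positions, labels compatible with
#'   the motif so the missed-match bookkeeping is exercised) or `"plain"`
#'   (labels purely from the composition).
#' @param seed master seed; the whole benchmark is reproducible from the
#'   spec.
#' @return an object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_targets = 200L, size_range = c(50L, 80L),
                           planted_fraction = 0.5, noise_sigma = 0.25,
                           decoy_mode = c("label-shuffled", "plain"),
                           seed = 1L) {
  structure(list(n_targets = as.integer(n_targets),
                 size_range = as.integer(size_range),
                 planted_fraction = planted_fraction,
                 noise_sigma = noise_sigma,
                 decoy_mode = match.arg(decoy_mode),
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' Build a synthetic benchmark: table + motif + ground truth
#'
#' Generates `n_targets` synthetic targets, plants the benchmark motif into
#' a `planted_fraction` subset with Gaussian noise, gives decoys
#' label-compatible (but geometry-free) residues in label-shuffled mode,
#' builds a label table over all of them, and returns the ground truth for
#' sensitivity/specificity scoring of the matcher and significance modules.
#'
#' @param spec a [benchmark_spec()].
#' @param path table directory (default a fresh temporary directory).
#' @param motif the motif to plant (default [default_benchmark_motif()]).
#' @param params [geometric_params()] for the table build.
#' @param r neighbor-list query radius for the table, Angstrom (default 7;
#'   build wider when matching will use a larger candidate radius -- the
#'   stored lists are exact at any radius, so this does not alter results
#'   at smaller radii).
#' @return list with `table` (a `label_table`), `motif`, `truth` (data
#'   frame: `target_id`, `is_positive`, `planted_ids`), `spec`.
#' @export
make_benchmark <- function(spec = benchmark_spec(),
                           path = tempfile("labeltable_"),
                           motif = default_benchmark_motif(),
                           params = geometric_params(), r = 7) {
  rng <- local_rng(spec$seed)
  n <- spec$n_targets
  sub_seeds <- rng$sample_int(2147483646L, n)
  sizes <- rng$sample(seq(spec$size_range[1L], spec$size_range[2L]), n,
                      replace = TRUE)
  n_pos <- round(spec$planted_fraction * n)
  pos_set <- if (n_pos > 0L) rng$sample_int(n, n_pos) else integer()
  targets <- vector("list", n)
  truth <- data.frame(target_id = character(n), is_positive = logical(n),
                      planted_ids = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    tid <- sprintf("SYN%04d", i)
    tg <- generate_structure(sizes[i], seed = sub_seeds[i], id = tid)
    if (i %in% pos_set) {
      pl <- plant_motif(tg, motif, noise_sigma = spec$noise_sigma,
                        seed = sub_seeds[i])
      tg <- pl$target
      truth$planted_ids[i] <- paste(pl$truth$residue_id, collapse = ",")
      truth$is_positive[i] <- TRUE
    } else if (spec$decoy_mode == "label-shuffled") {
      tg <- scatter_compatible_labels(tg, motif, seed = sub_seeds[i])
    }
    truth$target_id[i] <- tid
    targets[[i]] <- tg
  }
  tab <- build_table(targets, params, path, r = r, overwrite = TRUE)
  list(table = tab, motif = motif, truth = truth, spec = spec)
}

# Give a decoy one residue with a compatible label per motif point, at
# scattered (random, distinct) positions: label-feasible, no geometry.
scatter_compatible_labels <- function(target, motif, seed) {
  rng <- local_rng(seed + 104729L)
  N <- nrow(target$residues)
  pick <- rng$sample_int(N, min(N, motif$m))
  for (j in seq_along(pick)) {
    al <- motif$allowed_labels[[j]]
    target$residues$label[pick[j]] <-
      if (length(al) == 1L) al else rng$sample(al, 1L)
  }
  target$label_counts <- count_labels(target$residues$label)
  target
}

#' Write a benchmark truth table to TSV
#'
#' @param truth the `truth` data frame from [make_benchmark()].
#' @param path output file.
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
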