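# Independent oracles used to cross-check the package's fast paths.
# These deliberately share no code with the implementation.

# SVD-based Kabsch superposition: minimal RMSD over proper rigid motions.
oracle_kabsch_rmsd <- function(P, Q) {
  k <- nrow(P)
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  C <- t(Qc) %*% Pc
  sv <- svd(C)
  s <- sign(det(sv$u %*% t(sv$v)))
  if (s == 0) s <- 1
  lam <- sum(sv$d * c(1, 1, s))
  sqrt(max(0, (sum(Pc^2) + sum(Qc^2) - 2 * lam) / k))
}

oracle_kabsch_rotation <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  sv <- svd(t(Qc) %*% Pc)
  s <- sign(det(sv$u %*% t(sv$v)))
  if (s == 0) s <- 1
  sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
           2*(x*y+w*z), 1 - 2*(x^2+z^2), 2*(y*z-w*x),
           2*(x*z-w*y), 2*(y*z+w*x), 1 - 2*(x^2+y^2)),
         3, 3, byrow = TRUE)
}

# Brute-force four-clause reference-set filter over all n-subsets.
oracle_reference_sets <- function(target, params) {
  N <- nrow(target$residues)
  if (N < params$n) return(matrix(integer(), 0, params$n))
  combos <- utils::combn(N, params$n)
  ok <- logical(ncol(combos))
  for (c_ in seq_len(ncol(combos))) {
    t_ <- combos[, c_]
    D <- as.matrix(dist(target$ca[t_, , drop = FALSE]))
    pass <- all(D[upper.tri(D)] < params$d_diameter)
    if (pass) {
      diag(D) <- Inf
      pass <- all(apply(D, 1, min) <= params$d_maxmindist)
    }
    if (pass && params$check_depth) {
      dep <- target$depth[t_]
      pass <- all(dep <= params$d_maxdepth) && min(dep) <= params$d_maxmindepth
    }
    ok[c_] <- pass
  }
  t(combos[, ok, drop = FALSE])
}

tuple_strings <- function(mat) {
  if (!nrow(mat)) return(character())
  apply(mat, 1, function(r) paste(sort(r), collapse = "-"))
}

# Brute-force fixed-radius scan.
oracle_range_query <- function(ca, q, r) {
  d <- sqrt(colSums((t(ca) - q)^2))
  sort(which(d <= r))
}

# Exhaustive search over all label-compatible injections motif -> target
# with optimal-superposition RMSD <= eps (uses the SVD oracle for RMSD).
oracle_all_complete_matches <- function(motif_ca, allowed_labels, target_ca,
                                        target_labels, eps) {
  m <- nrow(motif_ca)
  N <- nrow(target_ca)
  out <- list()
  assign_next <- function(corr) {
    p <- length(corr) + 1L
    if (p > m) {
      r <- oracle_kabsch_rmsd(motif_ca, target_ca[corr, , drop = FALSE])
      if (r <= eps)
        out[[length(out) + 1L]] <<- list(corr = corr, rmsd = r)
      return(invisible())
    }
    for (j in setdiff(which(target_labels %in% allowed_labels[[p]]), corr))
      assign_next(c(corr, j))
    invisible()
  }
  assign_next(integer())
  out
}

# Quadrature of the half-line-renormalized Gaussian kernel mixture.
oracle_pvalue_quadrature <- function(rmsds, h, n_matched, n_missed, r) {
  grid_cdf <- function(upper) {
    if (upper <= 0) return(0)
    g <- seq(0, upper, length.out = 20001)
    dens <- sapply(g, function(x) sum(dnorm(x, mean = rmsds, sd = h)))
    sum((dens[-1] + dens[-length(dens)]) / 2) * diff(g)[1]
  }
  total <- {
    upper <- max(rmsds) + 12 * h
    g <- seq(0, upper, length.out = 40001)
    dens <- sapply(g, function(x) sum(dnorm(x, mean = rmsds, sd = h)))
    sum((dens[-1] + dens[-length(dens)]) / 2) * diff(g)[1]
  }
  W <- n_matched / (n_matched + n_missed)
  W * grid_cdf(r) / total
}

# Exhaustive assignment search for label feasibility: can each motif point
# get a distinct residue with an allowed label?
oracle_can_match <- function(label_counts, allowed_labels) {
  pool <- rep(names(label_counts), as.integer(label_counts))
  m <- length(allowed_labels)
  recurse <- function(p, pool) {
    if (p > m) return(TRUE)
    for (l in unique(pool)) {
      if (l %in% allowed_labels[[p]]) {
        rest <- pool[-match(l, pool)]
        if (recurse(p + 1L, rest)) return(TRUE)
      }
    }
    FALSE
  }
  recurse(1L, pool)
}

# Independent Sheather-Jones solve-the-equation plug-in bandwidth.
oracle_sj_bandwidth <- function(x) {
  n <- length(x)
  phi4 <- function(u) (u^4 - 6 * u^2 + 3) * dnorm(u)
  phi6 <- function(u) (u^6 - 15 * u^4 + 45 * u^2 - 15) * dnorm(u)
  dmat <- outer(x, x, "-")
  SD <- function(a) sum(phi4(dmat / a)) / (n * (n - 1) * a^5)
  TD <- function(b) -sum(phi6(dmat / b)) / (n * (n - 1) * b^7)
  lambda <- min(sd(x), IQR(x) / 1.349)
  a <- 1.24 * lambda * n^(-1/7)
  b <- 1.23 * lambda * n^(-1/9)
  alpha2 <- function(h) 1.357 * (SD(a) / TD(b))^(1/7) * h^(5/7)
  fSD <- function(h) ((1 / (2 * sqrt(pi))) / (n * SD(alpha2(h))))^(1/5) - h
  h0 <- 1.06 * lambda * n^(-1/5)
  uniroot(fSD, lower = 0.05 * h0, upper = 20 * h0, tol = 1e-8)$root
}

# Deterministic hand-rolled generator context used across tests.
make_simple_target <- function(n = 12, seed = 1, spread = 12) {
  set.seed(seed)
  repeat {
    ca <- matrix(runif(3 * n, 0, spread), n, 3)
    if (min(dist(ca)) > 2.5) break
  }
  labels <- sample(c("A", "D", "E", "G", "H", "K", "L", "N", "S", "V"),
                   n, replace = TRUE)
  residues <- data.frame(chain_id = "A", seq_number = seq_len(n),
                         insertion_code = "", label = labels,
                         stringsAsFactors = FALSE)
  tg <- motifhash:::new_target_structure(
    paste0("T", seed), residues, ca,
    centroid = ca + 1.5,
    centroid_flag = rep(FALSE, n),
    atoms = data.frame(res_index = seq_len(n), name = "CA", element = "C",
                       x = ca[, 1], y = ca[, 2], z = ca[, 3],
                       stringsAsFactors = FALSE),
    depth = rep(0, n))
  tg
}
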