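test_that("a hand-written three-residue file parses with correct labels", {
  tg <- parse_structure(three_residue_pdb(), id = "MINI")[[1]]
  expect_s3_class(tg, "target_structure")
  expect_equal(nrow(tg$residues), 3)
  expect_equal(tg$residues$label, c("A", "G", "K"))
  expect_equal(tg$label_counts, c(A = 1L, G = 1L, K = 1L))
  expect_equal(residue_frequencies(tg), tg$label_counts)
  expect_equal(sum(tg$label_counts), nrow(tg$residues))

  expect_error(parse_structure(three_residue_pdb(), chain_selection = "B"),
               "available chains: A")
  expect_error(parse_structure("HEADER only\nEND"), "no ATOM records")
})

test_that("all-separate vs merged chain selection partitions the residues", {
  set.seed(7)
  tg1 <- generate_structure(30, seed = 21, chain = "A", id = "X")
  tg2 <- generate_structure(20, seed = 22, chain = "B", id = "Y")
  pdb <- c(head(write_minimal_pdb(tg1), -1), write_minimal_pdb(tg2))
  sep <- parse_structure(pdb, "all-separate", id = "TWO")
  mer <- parse_structure(pdb, "merged", id = "TWO")
  expect_length(sep, 2)
  expect_length(mer, 1)
  # independent line-level recount of CA records per chain
  ca_lines <- grep("^ATOM.........CA", pdb, value = TRUE)
  chains <- substr(ca_lines, 22, 22)
  expect_equal(nrow(sep[[1]]$residues), sum(chains == "A"))
  expect_equal(nrow(sep[[2]]$residues), sum(chains == "B"))
  expect_equal(nrow(mer[[1]]$residues), length(ca_lines))
  expect_equal(nrow(mer[[1]]$residues),
               nrow(sep[[1]]$residues) + nrow(sep[[2]]$residues))
})

test_that("parse -> write -> re-parse round-trips identity, labels and CAs", {
  tg <- parse_structure(three_residue_pdb(), id = "MINI")[[1]]
  tg2 <- parse_structure(write_minimal_pdb(tg), id = "MINI")[[1]]
  expect_equal(tg2$residues, tg$residues)
  expect_equal(tg2$ca, tg$ca, tolerance = 1e-3)
  expect_equal(tg2$centroid, tg$centroid, tolerance = 1e-3)
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  pdb <- c(
    "ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA ASER A   1       1.000   0.000   0.000  0.30  0.00           C",
    "ATOM      3  CA BSER A   1       2.000   0.000   0.000  0.70  0.00           C",
    "ATOM      4  OG ASER A   1       1.500   1.000   0.000  0.50  0.00           O",
    "ATOM      5  OG BSER A   1       2.500   1.000   0.000  0.50  0.00           O",
    "END")
  tg <- parse_structure(pdb)[[1]]
  expect_equal(nrow(tg$residues), 1)
  expect_equal(tg$ca[1, 1], 2.0)       # occupancy 0.70 wins
  expect_equal(tg$centroid[1, 1], 1.5) # tie broken by altloc order: A
})

test_that("MSE maps to methionine and other hetero residues are dropped", {
  pdb <- c(
    "HETATM    1  CA  MSE A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  CA  LIG A   2       5.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   3       8.000   0.000   0.000  1.00  0.00           C",
    "END")
  tg <- parse_structure(pdb)[[1]]
  expect_equal(tg$residues$label, c("M", "G"))
})

test_that("side-chain centroids follow the field conventions", {
  tg <- parse_structure(three_residue_pdb(), id = "MINI")[[1]]
  # glycine: centroid is CA
  expect_equal(sidechain_centroid(tg, 2), tg$ca[2, ],
               ignore_attr = TRUE)
  expect_false(attr(sidechain_centroid(tg, 2), "fallback"))
  # alanine: single side-chain atom CB
  expect_equal(sidechain_centroid(tg, 1), c(2.0, -0.773, -1.2),
               ignore_attr = TRUE)
  # lysine: arithmetic mean of its 5 side-chain atoms, recomputed by hand
  lys <- tg$atoms[tg$atoms$res_index == 3 &
                    !(tg$atoms$name %in% c("N", "CA", "C", "O", "OXT")), ]
  expect_equal(nrow(lys), 5)
  expect_equal(sidechain_centroid(tg, 3),
               c(mean(lys$x), mean(lys$y), mean(lys$z)),
               ignore_attr = TRUE)
})

test_that("depth: isolated residues are surface, buried lattice cores are not", {
  # a single isolated residue is all surface
  one <- parse_structure(grep(" A   3|^END", three_residue_pdb(),
                              value = TRUE), id = "ONE")[[1]]
  expect_equal(nrow(one$residues), 1)
  one <- compute_depth(one)
  expect_equal(one$depth, 0)

  # 6x6x6 CA lattice at 3.8 A spacing: corners shallower than the center
  g <- expand.grid(x = 0:5, y = 0:5, z = 0:5) * 3.8
  n <- nrow(g)
  residues <- data.frame(chain_id = "A", seq_number = seq_len(n),
                         insertion_code = "", label = "A",
                         stringsAsFactors = FALSE)
  ca <- as.matrix(g); dimnames(ca) <- NULL
  lat <- motifhash:::new_target_structure(
    "LAT", residues, ca, ca, rep(FALSE, n),
    atoms = data.frame(res_index = seq_len(n), name = "CA", element = "C",
                       x = ca[, 1], y = ca[, 2], z = ca[, 3],
                       stringsAsFactors = FALSE))
  lat <- compute_depth(lat)
  corner <- which(g$x == 0 & g$y == 0 & g$z == 0)
  center <- which(g$x == 3.8 * 2 & g$y == 3.8 * 2 & g$z == 3.8 * 2)
  expect_lt(lat$depth[corner], lat$depth[center])
  expect_equal(lat$depth[corner], 0)

  # depths equal brute-force distance-to-nearest-exposed recomputation
  set.seed(31)
  cl <- matrix(rnorm(300, sd = 6), 100, 3)
  resc <- data.frame(chain_id = "A", seq_number = 1:100,
                     insertion_code = "", label = "A",
                     stringsAsFactors = FALSE)
  tgc <- motifhash:::new_target_structure(
    "CLUST", resc, cl, cl, rep(FALSE, 100),
    atoms = data.frame(res_index = 1:100, name = "CA", element = "C",
                       x = cl[, 1], y = cl[, 2], z = cl[, 3],
                       stringsAsFactors = FALSE))
  tgc <- compute_depth(tgc)
  D <- as.matrix(dist(cl))
  ext_count <- rowSums(D <= 1.8 + 2 * 1.4) - 1  # all atoms in distinct residues
  exposed <- ext_count < 6
  brute <- apply(D[, exposed, drop = FALSE], 1, min)
  brute[exposed] <- 0
  expect_equal(tgc$depth, unname(brute), tolerance = 1e-9)

  # rigid invariance
  R <- random_rotation()
  tgr <- tgc
  tgr$ca <- tgc$ca %*% t(R) + 11
  tgr$atoms[, c("x", "y", "z")] <- as.data.frame(tgr$ca)
  tgr <- compute_depth(tgr)
  expect_equal(tgr$depth, tgc$depth, tolerance = 1e-6)

  # < 4 atoms: zero depths with a warning
  tiny <- motifhash:::new_target_structure(
    "TINY", resc[1:2, ], cl[1:2, ], cl[1:2, ], rep(FALSE, 2),
    atoms = data.frame(res_index = 1:2, name = "CA", element = "C",
                       x = cl[1:2, 1], y = cl[1:2, 2], z = cl[1:2, 3],
                       stringsAsFactors = FALSE))
  expect_warning(tiny <- compute_depth(tiny), "fewer than 4 atoms")
  expect_equal(tiny$depth, c(0, 0))
})

test_that("depth sidecar files override computed depths", {
  tg <- parse_structure(three_residue_pdb(), id = "MINI")[[1]]
  tf <- tempfile()
  writeLines(c("A 1 - 0.5", "A 3 - 2.25"), tf)
  tg <- read_depth_sidecar(tg, tf)
  expect_equal(tg$depth[c(1, 3)], c(0.5, 2.25))
  expect_true(is.na(tg$depth[2]))
  unlink(tf)
})
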