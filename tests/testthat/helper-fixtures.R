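# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# The default-condition synthetic benchmark (200 targets, 50% planted,
# sigma 0.25 A, seed 1), with its matches and profile; heavy, so shared by
# every test that scores against it.
default_benchmark <- function() {
  cached("benchmark", {
    # neighbor lists at r = 9 so the epsilon = 9 stability run can use its
    # full candidate radius; matching at radius 7 is unaffected (lists are
    # exact at every radius up to r)
    bm <- make_benchmark(benchmark_spec(seed = 1L),
                         path = file.path(tempdir(), "mh_bench_table"),
                         r = 9)
    res <- match_motif(bm$motif, bm$table)
    prof <- build_profile(res)
    list(bm = bm, res = res, prof = prof)
  })
}

# A small table of simple random-cluster targets for matcher tests.
small_table <- function() {
  cached("small_table", {
    targets <- lapply(1:8, function(s) make_simple_target(n = 10 + s, seed = s))
    params <- geometric_params(check_depth = FALSE)
    tab <- build_table(targets, params,
                       file.path(tempdir(), "mh_small_table"),
                       r = 7, overwrite = TRUE)
    list(table = tab, targets = targets, params = params)
  })
}

# Minimal hand-written three-residue PDB (ALA, GLY, LYS on chain A).
three_residue_pdb <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       2.000  -0.773  -1.200  1.00  0.00           C",
    "ATOM      6  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      7  CA  GLY A   2       3.988   2.839   0.000  1.00  0.00           C",
    "ATOM      8  C   GLY A   2       5.504   2.693   0.000  1.00  0.00           C",
    "ATOM      9  O   GLY A   2       6.028   1.581   0.000  1.00  0.00           O",
    "ATOM     10  N   LYS A   3       6.224   3.811   0.000  1.00  0.00           N",
    "ATOM     11  CA  LYS A   3       7.680   3.789   0.000  1.00  0.00           C",
    "ATOM     12  C   LYS A   3       8.231   5.209   0.000  1.00  0.00           C",
    "ATOM     13  O   LYS A   3       7.473   6.179   0.000  1.00  0.00           O",
    "ATOM     14  CB  LYS A   3       8.200   3.016  -1.210  1.00  0.00           C",
    "ATOM     15  CG  LYS A   3       9.720   2.950  -1.300  1.00  0.00           C",
    "ATOM     16  CD  LYS A   3      10.240   2.180  -2.500  1.00  0.00           C",
    "ATOM     17  CE  LYS A   3      11.760   2.120  -2.600  1.00  0.00           C",
    "ATOM     18  NZ  LYS A   3      12.280   1.350  -3.800  1.00  0.00           N",
    "END")
}
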