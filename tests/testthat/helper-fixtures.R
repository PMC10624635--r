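# Shared fixture builders for the test suite.  Everything is generated in
# code at test time; no binary data.

# internal atom accessor, convenient in assertions
.get_atom_public <- function(model, chain, resno, elety, insert = "")
  ploopkit:::.get_atom(model, chain, resno, elety, insert)

# canonical positive fixture: strand -> Walker-A loop -> helix, with the
# motif starting at a chosen author number
positive_fixture <- function(seed = 1L, start_resno = 145L,
                             chain_id = "A",
                             sequence = "GPPGAGKS") {
  make_motif_fixture(strand(6), motif(sequence = sequence),
                     helix(8), seed = seed, chain_id = chain_id,
                     start_resno = start_resno,
                     entry_id = sprintf("fx%02d", seed %% 100))
}

# panel of positives and negatives with known ground truth; negatives span
# sequence-only, torsion-only and orientation-only failures
fixture_panel <- function(n_pos = 20L, n_neg = 21L) {
  panel <- list()
  for (s in seq_len(n_pos)) {
    last <- if (s %% 2L == 0L) "GPPGAGKS" else "GAHGWGKT"
    fx <- positive_fixture(seed = s, sequence = last)
    panel[[length(panel) + 1L]] <- list(model = fx$model, positive = TRUE,
                                        start = fx$truth$motif_start_auth)
  }
  kinds <- rep(c("sequence", "torsion", "orientation"),
               length.out = n_neg)
  for (i in seq_len(n_neg)) {
    s <- 100L + i
    fx <- switch(kinds[i],
      # motif sequence never present
      sequence = make_motif_fixture(strand(6),
                                    motif(sequence = "GPPGAGRS"),
                                    helix(8), seed = s,
                                    start_resno = 145L),
      # Walker-A sequence but helical loop torsions
      torsion = make_motif_fixture(strand(6),
                                   motif(sequence = "GPPGAGKS",
                                         abego = "AAAAAAAA"),
                                   helix(8), seed = s,
                                   start_resno = 145L),
      # full motif with the pre-residue CB reflected
      orientation = make_motif_fixture(strand(6), motif(), helix(8),
                                       seed = s, start_resno = 145L,
                                       break_orientation = TRUE))
    panel[[length(panel) + 1L]] <- list(model = fx$model, positive = FALSE,
                                        kind = kinds[i])
  }
  panel
}

# donor + congruent-flank pseudo-loop acceptor pair for graft tests
graft_pair <- function(seed = 3L) {
  donor <- positive_fixture(seed = seed, start_resno = 226L,
                            chain_id = "B")$model
  acceptor <- make_pseudo_loop(donor, "B", c(232L, 239L))
  acceptor$atoms$chain <- "E"
  acceptor <- ploop_structure(acceptor$atoms, entry_id = "acceptor")
  list(donor = donor, acceptor = acceptor)
}

# standard small constraint set around a fixture's motif site
site_constraints <- function(model, chain_id = "A", start_resno = 151L,
                             tol = 2.5) {
  distance_constraints(
    chain = chain_id,
    resno = c(start_resno + 6L, start_resno + 7L, start_resno),
    atom = c("CA", "CA", "N"),
    ligand_atom = c("PB", "PG", "PA"),
    target = c(6, 6, 6), tolerance = tol, weight = 1)
}

# random rigid transform applied to a ploop_structure or an n x 3 matrix
random_rigid <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x),
                1 - 2 * (x^2 + y^2)), 3L, 3L, byrow = TRUE)
  list(R = R, t = stats::runif(3L, -10, 10))
}

transform_model <- function(model, rigid) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(rigid$R)
  xyz <- sweep(xyz, 2L, rigid$t, "+")
  model$atoms$x <- xyz[, 1L]
  model$atoms$y <- xyz[, 2L]
  model$atoms$z <- xyz[, 3L]
  model
}

# brute-force sliding-window motif scan used as the independent oracle
brute_scan <- function(sequence, pattern_chars) {
  seq1 <- strsplit(sequence, "")[[1L]]
  L <- length(pattern_chars)
  out <- integer(0)
  if (length(seq1) < L) return(out)
  for (s in seq_len(length(seq1) - L + 1L)) {
    ok <- TRUE
    for (k in seq_len(L)) {
      allowed <- pattern_chars[[k]]
      if (is.null(allowed)) next
      if (seq1[s + k - 1L] == "X" || !(seq1[s + k - 1L] %in% allowed)) {
        ok <- FALSE
        break
      }
    }
    if (ok) out <- c(out, s)
  }
  out
}

# tiny hand-written PDB text exercising altlocs, MSE, a ligand and a water
handmade_pdb <- function(path) {
  lines <- c(
    "HEADER    PROTEIN                                             9TST",
    "REMARK   2 RESOLUTION.    2.80 ANGSTROMS.",
    "ATOM      1  N   GLY A 151      11.104   6.134   2.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A 151      12.560   6.134   2.000  1.00  0.00           C",
    "ATOM      3  C   GLY A 151      13.110   7.553   2.000  1.00  0.00           C",
    "ATOM      4  O   GLY A 151      12.360   8.531   2.000  1.00  0.00           O",
    "ATOM      5  N  APRO A 152      14.440   7.662   2.000  0.40  0.00           N",
    "ATOM      6  N  BPRO A 152      14.460   7.700   2.100  0.60  0.00           N",
    "ATOM      7  CA APRO A 152      15.120   8.960   2.000  0.40  0.00           C",
    "ATOM      8  CA BPRO A 152      15.140   8.990   2.100  0.60  0.00           C",
    "ATOM      9  C   PRO A 152      16.640   8.810   2.000  1.00  0.00           C",
    "ATOM     10  O   PRO A 152      17.180   7.700   2.000  1.00  0.00           O",
    "HETATM   11  N   MSE A 153      17.350   9.940   2.000  1.00  0.00           N",
    "HETATM   12  CA  MSE A 153      18.800   9.940   2.000  1.00  0.00           C",
    "HETATM   13  C   MSE A 153      19.350  11.360   2.000  1.00  0.00           C",
    "HETATM   14  O   MSE A 153      18.600  12.340   2.000  1.00  0.00           O",
    "HETATM   15 SE   MSE A 153      20.500   9.000   2.000  1.00  0.00          SE",
    "HETATM   16  PB  ADP A 500       4.000   4.000   4.000  1.00  0.00           P",
    "HETATM   17  O   HOH A 600       8.000   8.000   8.000  1.00  0.00           O",
    "END")
  writeLines(lines, path)
  path
}
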