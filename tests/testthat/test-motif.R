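default_slots <- list("G", NULL, NULL, "G", NULL, "G", "K", c("T", "S"))
no_x3_slots <- list("G", NULL, NULL, NULL, NULL, "G", "K", c("T", "S"))

test_that("scan_walker_a matches the worked examples", {
  def_no_x3 <- motif_definition(required_fixed = character(0))
  expect_equal(scan_walker_a("MGPPGAGKSL", def_no_x3), 2L)
  expect_equal(scan_walker_a("MGPPGAGKSL", motif_definition()), 2L)
  expect_equal(scan_walker_a("AAAAAAAA", motif_definition()), integer(0))
  # second window fails the [T/S] slot
  expect_equal(scan_walker_a("GAAAAGKTGAAAAGKV", def_no_x3), 1L)
  # lysine-free variant of the motif
  def_nok <- motif_definition("GX1X2X3X4G[TS]",
                              required_fixed = character(0),
                              torsion_pattern = NULL,
                              orientation_required = FALSE)
  expect_equal(scan_walker_a("MGPPGAGSL", def_nok), 2L)
  # 'X' in the sequence never matches a fixed slot
  expect_equal(scan_walker_a("XPPGAGKS", def_no_x3), integer(0))
})

test_that("scan_walker_a equals brute-force window comparison", {
  set.seed(2024)
  def <- motif_definition()
  def_no_x3 <- motif_definition(required_fixed = character(0))
  alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], "X")
  for (i in 1:1000) {
    # biased alphabet so matches actually occur
    s <- paste(sample(c(alphabet, rep(c("G", "K", "T", "S"), 4L)),
                      sample(8:30, 1L), replace = TRUE), collapse = "")
    expect_identical(scan_walker_a(s, def), brute_scan(s, default_slots))
    expect_identical(scan_walker_a(s, def_no_x3),
                     brute_scan(s, no_x3_slots))
  }
})

test_that("orientation_feature follows the stated vector geometry", {
  # hand-placed model: pre residue at origin with CB along +x
  mk <- function(ca_lys) {
    atoms <- data.frame(
      chain = "A",
      resno = c(rep(150L, 4L), rep(151L, 3L), rep(157L, 1L)),
      insert = "", resid = c(rep("VAL", 4L), rep("GLY", 3L), "LYS"),
      elety = c("N", "CA", "C", "CB", "N", "CA", "C", "CA"),
      elesy = c("N", "C", "C", "C", "N", "C", "C", "C"), alt = "", o = 1,
      x = c(-1.4, 0, 0.5, 1.5, 1.2, 2.6, 3.2, ca_lys[1L]),
      y = c(0, 0, 1.4, 0, 2.2, 2.2, 3.5, ca_lys[2L]),
      z = c(0, 0, 0, 0, 0, 0, 0, ca_lys[3L]),
      het = FALSE, stringsAsFactors = FALSE)
    ploop_structure(atoms)
  }
  away <- orientation_feature(mk(c(-6, 0, 0)), "A", 151L, lys_slot = 2L)
  expect_equal(away$cosine, -1)
  expect_true(away$points_away)
  toward <- orientation_feature(mk(c(6, 0, 0)), "A", 151L, lys_slot = 2L)
  expect_equal(toward$cosine, 1)
  expect_false(toward$points_away)
  side <- orientation_feature(mk(c(0, 6, 0)), "A", 151L, lys_slot = 2L)
  expect_equal(side$cosine, 0, tolerance = 1e-12)
  expect_false(side$points_away)   # strict inequality at 0

  # no residue precedes the motif start
  m <- mk(c(-6, 0, 0))
  m$atoms <- m$atoms[m$atoms$resno != 150L, ]
  expect_error(orientation_feature(ploop_structure(m$atoms), "A", 151L,
                                   lys_slot = 2L), "precede")
})

test_that("orientation_feature is rigid-transform invariant and handles
           glycine pre-residues", {
  fx <- positive_fixture(seed = 31L)$model
  ref <- orientation_feature(fx, "A", 151L)$cosine
  for (s in 1:20) {
    moved <- transform_model(fx, random_rigid(s))
    expect_equal(orientation_feature(moved, "A", 151L)$cosine, ref,
                 tolerance = 1e-9)
  }
  # glycine pre-residue: virtual CB must be constructed
  gly_pre <- make_motif_fixture(strand(6, sequence = "VVVVVG"), motif(),
                                helix(8), seed = 31L, start_resno = 145L)
  expect_no_error(orientation_feature(gly_pre$model, "A", 151L))
})

test_that("detect_ploops separates the three failure modes", {
  pos <- positive_fixture(seed = 41L)
  hits <- detect_ploops(pos$model)
  expect_equal(nrow(hits), 1L)
  expect_true(hits$confirmed)
  expect_equal(hits$start_auth, 151L)
  expect_equal(hits$end_auth, 158L)
  expect_equal(hits$abego, "EBBGAGAA")

  # same sequence, helical loop: sequence_ok but torsion_ok FALSE
  tneg <- make_motif_fixture(strand(6),
                             motif(sequence = "GPPGAGKS",
                                   abego = "AAAAAAAA"),
                             helix(8), seed = 41L, start_resno = 145L)
  th <- detect_ploops(tneg$model)
  expect_equal(nrow(th), 1L)
  expect_true(th$sequence_ok)
  expect_false(th$torsion_ok)
  expect_false(th$confirmed)

  # flipped pre-residue CB: orientation_ok FALSE
  oneg <- make_motif_fixture(strand(6), motif(), helix(8), seed = 41L,
                             start_resno = 145L, break_orientation = TRUE)
  oh <- detect_ploops(oneg$model)
  expect_true(oh$torsion_ok)
  expect_false(oh$orientation_ok)
  expect_false(oh$confirmed)
})

test_that("detect_ploops has full sensitivity and specificity on the
           constructed panel", {
  panel <- fixture_panel(n_pos = 20L, n_neg = 21L)
  for (item in panel) {
    hits <- detect_ploops(item$model)
    n_conf <- sum(hits$confirmed)
    if (item$positive) {
      expect_equal(n_conf, 1L)
      expect_equal(hits$start_auth[hits$confirmed], item$start)
    } else {
      expect_equal(n_conf, 0L, info = item$kind)
    }
  }
})

test_that("tolerance-mode torsion matching accepts mildly perturbed loops", {
  pos <- positive_fixture(seed = 51L)$model
  tor <- backbone_torsions(pos, "A")
  # rebuild with the first loop residue pushed ~6 degrees outside its bin
  idx <- which(tor$resno == 151L)
  phi <- tor$phi; psi <- tor$psi; omega <- tor$omega
  phi[1] <- psi[length(psi)] <- omega[1] <- NA
  phi[idx] <- -6        # E needs phi >= 0; 6 degrees outside
  pert <- build_backbone(extract_chain_sequence(pos, "A")$sequence,
                         phi, psi, omega, start_resno = 145L)
  exact <- detect_ploops(pert)
  expect_false(exact$torsion_ok[1])
  tol <- detect_ploops(pert, torsion_mode = "tolerance", torsion_tol = 10)
  expect_true(tol$torsion_ok[1])
  tight <- detect_ploops(pert, torsion_mode = "tolerance", torsion_tol = 3)
  expect_false(tight$torsion_ok[1])
})

test_that("survey_motifs aggregates frequencies, orientation and
           phosphate distances", {
  models <- list(
    positive_fixture(seed = 61L, sequence = "GPPGAGKT")$model,
    positive_fixture(seed = 62L, sequence = "GAHGWGKT")$model,
    positive_fixture(seed = 63L, sequence = "GPPGAGKS")$model)
  sv <- survey_motifs(models)
  expect_equal(sv$n_hits, 3L)
  expect_equal(sv$residue_freq["pos8", "T"], 2 / 3)
  expect_equal(sv$residue_freq["pos8", "S"], 1 / 3)
  expect_equal(unname(rowSums(sv$residue_freq)), rep(1, 8),
               tolerance = 1e-9)
  expect_equal(unname(rowSums(sv$abego_freq)), rep(1, 8),
               tolerance = 1e-9)
  # all fixtures share the torsion pattern: modal frequency 1 per position
  expect_equal(unname(sv$abego_freq[cbind(1:8,
    match(strsplit("EBBGAGAA", "")[[1L]], colnames(sv$abego_freq)))]),
    rep(1, 8))
  expect_true(all(sv$orientation[c("min", "max")] < 0))

  # pseudo-phosphate exactly 4 A from the Lys NZ stand-in atom
  m <- models[[1L]]
  lys_ca <- .get_atom_public(m, "A", 157L, "CA")
  nz <- lys_ca + c(0, 0, 2)    # synthetic NZ above the Lys CA
  m$atoms <- rbind(m$atoms, data.frame(
    chain = "A", resno = 157L, insert = "", resid = "LYS", elety = "NZ",
    elesy = "N", alt = "", o = 1, x = nz[1L], y = nz[2L], z = nz[3L],
    het = FALSE, stringsAsFactors = FALSE))
  m$atoms <- rbind(m$atoms, data.frame(
    chain = "A", resno = 900L, insert = "", resid = "PO4", elety = "P",
    elesy = "P", alt = "", o = 1, x = nz[1L] + 4, y = nz[2L], z = nz[3L],
    het = TRUE, stringsAsFactors = FALSE))
  m <- ploop_structure(m$atoms)
  sv2 <- survey_motifs(list(m))
  d <- sv2$distances
  expect_equal(d$distance[d$protein_atom == "LYS_NZ"], 4, tolerance = 1e-6)

  # survey over one structure reproduces that structure's hit exactly
  expect_equal(sv2$n_hits, 1L)
  expect_equal(max(sv2$residue_freq), 1)

  expect_error(survey_motifs(list(
    make_motif_fixture(strand(4), helix(4), seed = 1L)$model)),
    "empty survey")
})

test_that("constraints_from_survey turns distance statistics into a usable
           constraint table", {
  m <- positive_fixture(seed = 71L)$model
  lys_ca <- .get_atom_public(m, "A", 157L, "CA")
  m$atoms <- rbind(m$atoms, data.frame(
    chain = "A", resno = 900L, insert = "", resid = "ADP",
    elety = c("PA", "PB"), elesy = "P", alt = "", o = 1,
    x = lys_ca[1L] + c(4, 6), y = lys_ca[2L], z = lys_ca[3L],
    het = TRUE, stringsAsFactors = FALSE))
  m <- ploop_structure(m$atoms)
  sv <- survey_motifs(list(m))
  cons <- constraints_from_survey(sv, m, "A", 151L)
  expect_true(all(c("chain", "resno", "atom", "ligand_atom", "target",
                    "tolerance", "weight") %in% names(cons)))
  expect_true(all(cons$target > 0))
  expect_true(all(cons$tolerance >= 0.25))
  # constraints evaluated against the very ligand they came from: satisfied
  lig <- m$atoms[m$atoms$het, ]
  pose <- ligand_pose("ADP", lig[, c("elety", "elesy", "x", "y", "z")])
  rpt <- evaluate_constraints(m, pose, cons)
  expect_true(rpt$all_satisfied)
})
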