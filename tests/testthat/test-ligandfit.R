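test_that("evaluate_constraints implements the flat-bottom quadratic", {
  m <- positive_fixture(seed = 1L)$model
  ca <- .get_atom_public(m, "A", 157L, "CA")
  pose_at <- function(d) ligand_pose("PO4", data.frame(
    elety = c("PA", "PB"), elesy = "P",
    x = ca[1L] + c(d, d + 3), y = ca[2L], z = ca[3L],
    stringsAsFactors = FALSE))
  cons <- distance_constraints("A", 157L, "CA", "PA", target = 5,
                               tolerance = 0.5, weight = 1)

  # distance exactly on target: zero penalty
  r0 <- evaluate_constraints(m, pose_at(5), cons)
  expect_equal(r0$penalty, 0)
  expect_true(r0$all_satisfied)
  # d = target + 2*tol: violation = tol, penalty = tol^2
  r1 <- evaluate_constraints(m, pose_at(6), cons)
  expect_equal(r1$table$violation, 0.5)
  expect_equal(r1$penalty, 0.25)
  expect_false(r1$all_satisfied)
  # inside the band on the short side: still zero
  expect_equal(evaluate_constraints(m, pose_at(4.6), cons)$penalty, 0)
  # weights scale the quadratic
  consw <- distance_constraints("A", 157L, "CA", "PA", 5, 0.5, weight = 2)
  expect_equal(evaluate_constraints(m, pose_at(6), consw)$penalty, 0.5)

  bad <- distance_constraints("A", 157L, "XX9", "PA", 5, 0.5, 1)
  expect_error(evaluate_constraints(m, pose_at(5), bad), "XX9")
})

test_that("constraint penalty is zero iff satisfied and grows
           monotonically outside the band", {
  m <- positive_fixture(seed = 1L)$model
  ca <- .get_atom_public(m, "A", 157L, "CA")
  cons <- distance_constraints("A", 157L, "CA", "PA", 5, 0.5, 1)
  dists <- seq(2, 9, by = 0.1)
  pens <- vapply(dists, function(d) {
    pose <- ligand_pose("PO4", data.frame(
      elety = c("PA", "PB"), elesy = "P", x = ca[1L] + c(d, d + 3),
      y = ca[2L], z = ca[3L], stringsAsFactors = FALSE))
    evaluate_constraints(m, pose, cons)$penalty
  }, numeric(1L))
  inside <- dists >= 4.5 + 1e-6 & dists <= 5.5 - 1e-6
  outside <- dists < 4.5 - 1e-6 | dists > 5.5 + 1e-6
  expect_true(all(pens[inside] == 0))
  expect_true(all(pens[outside] > 0))
  # non-decreasing as the distance moves away from the band on either side
  above <- pens[dists > 5.5]
  below <- rev(pens[dists < 4.5])
  expect_true(all(diff(above) >= -1e-12))
  expect_true(all(diff(below) >= -1e-12))
})

test_that("clash_score applies the scaled-vdW rule with a strict boundary", {
  # two isolated carbon atoms: protein CA vs ligand carbon
  mk_pair <- function(d) {
    prot <- ploop_structure(data.frame(
      chain = "A", resno = 1L, insert = "", resid = "ALA", elety = "CA",
      elesy = "C", alt = "", o = 1, x = 0, y = 0, z = 0, het = FALSE,
      stringsAsFactors = FALSE))
    pose <- ligand_pose("LIG", data.frame(
      elety = c("C1", "PA"), elesy = c("C", "P"),
      x = c(d, 50), y = 0, z = 0, stringsAsFactors = FALSE))
    clash_score(prot, pose)
  }
  # boundary 0.80 * (1.7 + 1.7) = 2.72: strict inequality, no clash
  expect_equal(mk_pair(2.72)$count, 0L)
  hit <- mk_pair(2.0)
  expect_equal(hit$count, 1L)
  expect_equal(hit$overlap, 0.72, tolerance = 1e-9)

  unknown <- ploop_structure(data.frame(
    chain = "A", resno = 1L, insert = "", resid = "ALA", elety = "QQ",
    elesy = "QQ", alt = "", o = 1, x = 0, y = 0, z = 0, het = FALSE,
    stringsAsFactors = FALSE))
  pose <- ligand_pose("LIG", data.frame(elety = "PA", elesy = "P",
                                        x = 1, y = 0, z = 0,
                                        stringsAsFactors = FALSE))
  expect_error(clash_score(unknown, pose), "radius")
})

test_that("clash_score equals brute-force pair enumeration on fixtures", {
  brute <- function(model, pose, scale = 0.80) {
    radii <- ploopkit:::.vdw_radii
    prot <- model$atoms[!model$atoms$het, ]
    count <- 0L
    overlap <- 0
    for (i in seq_len(nrow(prot))) {
      for (j in seq_len(nrow(pose$atoms))) {
        d <- sqrt(sum((as.numeric(prot[i, c("x", "y", "z")]) -
                       as.numeric(pose$atoms[j, c("x", "y", "z")]))^2))
        lim <- scale * (radii[[prot$elesy[i]]] +
                        radii[[pose$atoms$elesy[j]]])
        if (d < lim) {
          count <- count + 1L
          overlap <- overlap + (lim - d)
        }
      }
    }
    list(count = count, overlap = overlap)
  }
  set.seed(77)
  m <- positive_fixture(seed = 77L)$model
  for (trial in 1:5) {
    centre <- as.numeric(m$atoms[sample(nrow(m$atoms), 1L),
                                 c("x", "y", "z")])
    pose <- ligand_pose("ATP", data.frame(
      elety = c("PA", "PB", "PG", "C5"),
      elesy = c("P", "P", "P", "C"),
      x = centre[1L] + stats::rnorm(4L, 0, 2),
      y = centre[2L] + stats::rnorm(4L, 0, 2),
      z = centre[3L] + stats::rnorm(4L, 0, 2),
      stringsAsFactors = FALSE))
    got <- clash_score(m, pose)
    want <- brute(m, pose)
    expect_equal(got$count, want$count)
    expect_equal(got$overlap, want$overlap, tolerance = 1e-9)
  }
  # a crafted three-overlap case
  prot <- ploop_structure(data.frame(
    chain = "A", resno = 1:3, insert = "", resid = "ALA",
    elety = c("CA", "CB", "N"), elesy = c("C", "C", "N"), alt = "", o = 1,
    x = c(0, 1, 2), y = 0, z = 0, het = FALSE, stringsAsFactors = FALSE))
  pose3 <- ligand_pose("PO4", data.frame(elety = "PA", elesy = "P",
                                         x = 1, y = 0.5, z = 0,
                                         stringsAsFactors = FALSE))
  expect_equal(clash_score(prot, pose3)$count, 3L)
})

test_that("the exclusion set removes constrained contact atoms from
           clash counting", {
  m <- positive_fixture(seed = 13L)$model
  cons <- site_constraints(m, start_resno = 151L, tol = 3)
  pose <- make_ligand_fixture(m, cons, "satisfy", seed = 5L)
  with_excl <- clash_score(m, pose, exclude = cons)
  without <- clash_score(m, pose)
  expect_lte(with_excl$count, without$count)
})

test_that("sample_phosphate_poses is seeded, valid and honest about
           infeasibility", {
  m <- positive_fixture(seed = 13L)$model
  cons <- site_constraints(m, start_resno = 151L, tol = 2.5)
  poses <- sample_phosphate_poses(m, cons, n = 10L, seed = 1L)
  expect_length(poses, 10L)
  for (p in poses)
    expect_true(evaluate_constraints(m, p, cons)$all_satisfied)

  again <- sample_phosphate_poses(m, cons, n = 10L, seed = 1L)
  expect_identical(lapply(poses, function(p) p$atoms),
                   lapply(again, function(p) p$atoms))
  other <- sample_phosphate_poses(m, cons, n = 10L, seed = 2L)
  expect_false(identical(poses[[1L]]$atoms, other[[1L]]$atoms))

  # contradictory windows on the same pair: zero poses plus a warning
  contra <- distance_constraints("A", c(157L, 157L), "CA", c("PA", "PA"),
                                 target = c(2, 9), tolerance = 0.1,
                                 weight = 1)
  contra$ligand_atom <- c("PA", "PA")
  contra2 <- rbind(contra,
                   distance_constraints("A", 158L, "CA", "PB", 5, 3, 1))
  expect_warning(
    empty <- sample_phosphate_poses(m, contra2, n = 1L, seed = 1L,
                                    max_attempts = 2000L),
    "infeasible")
  expect_length(empty, 0L)

  single <- distance_constraints("A", 157L, "CA", "PA", 5, 1, 1)
  expect_error(sample_phosphate_poses(m, single, n = 1L, seed = 1L),
               "2 distinct")
})

test_that("filter_candidates applies the selection rule and preserves
           order", {
  cand <- data.frame(
    id = 1:5,
    binding_score = c(-9.0, -8.5, -7.0, -8.3, -2.0),
    pattern_retained = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    penalty = 0)
  kept <- filter_candidates(cand)
  expect_equal(kept$id, c(1L, 2L))

  expect_equal(nrow(filter_candidates(cand[0, ])), 0L)
  high <- cand
  high$binding_score <- abs(high$binding_score)
  expect_equal(nrow(filter_candidates(high)), 0L)

  # threshold is strict: a score exactly at -8.0 is rejected
  edge <- data.frame(id = 1L, binding_score = -8.0,
                     pattern_retained = TRUE, penalty = 0)
  expect_equal(nrow(filter_candidates(edge)), 0L)

  # without the pattern requirement candidate 4 comes back
  expect_equal(filter_candidates(cand, require_pattern = FALSE)$id,
               c(1L, 2L, 4L))
  # penalty gate
  pen <- cand
  pen$penalty <- c(0, 0.4, 0, 0, 0)
  expect_equal(filter_candidates(pen)$id, 1L)
  expect_equal(filter_candidates(pen, max_penalty = 0.5)$id, c(1L, 2L))
})

test_that("filter_candidates equals rule enumeration on random tables and
           is monotone in the threshold", {
  set.seed(555)
  for (i in 1:50) {
    n <- sample(1:30, 1L)
    cand <- data.frame(
      id = seq_len(n),
      binding_score = round(stats::runif(n, -12, 0), 2),
      pattern_retained = sample(c(TRUE, FALSE), n, replace = TRUE),
      penalty = sample(c(0, 0, 0.3), n, replace = TRUE))
    thr <- stats::runif(1L, -10, -6)
    kept <- filter_candidates(cand, score_threshold = thr)
    manual <- cand$id[cand$pattern_retained & cand$binding_score < thr &
                      cand$penalty <= 0]
    expect_identical(kept$id, manual)
    stricter <- filter_candidates(cand, score_threshold = thr - 1)
    expect_lte(nrow(stricter), nrow(kept))
    # permutation invariance up to order preservation
    perm <- sample(n)
    kept_perm <- filter_candidates(cand[perm, ], score_threshold = thr)
    expect_setequal(kept_perm$id, kept$id)
  }
})

test_that("constraint and candidate tables round-trip through TSV", {
  cons <- distance_constraints("A", c(157L, 158L), c("CA", "N"),
                               c("PB", "PG"), c(6.1, 5.2), c(1, 1.5), 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_constraints(cons, path)
  back <- read_constraints(path)
  expect_equal(back, cons)
  partial <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chain\tresno\tatom", partial)
  expect_error(read_constraints(partial), "missing columns")
})
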