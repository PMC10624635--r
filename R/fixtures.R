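# Seeded synthetic-structure generation with known ground truth.  Fixtures
# emulate the native P-loop context -- a beta strand running into the loop,
# the loop itself realizing a requested ABEGO string, and a following helix
# -- plus optional pseudo-ligand phosphates placed to satisfy or violate a
# constraint set by a stated margin.  They are geometric test articles, not
# physically realistic all-atom models.

#' Segment presets for fixture backbones
#'
#' `strand(n)` and `helix(n)` produce n residues of extended ('B') and
#' helical ('A') torsions; `motif(sequence, abego)` produces a segment whose
#' per-residue torsions realize the given ABEGO string (default the
#' canonical Walker-A designed loop `GPPGAGKS` / `EBBGAGAA`); `segment(...)`
#' gives full manual control.  Torsions are drawn from a seeded jitter box
#' strictly inside each bin, so panels of fixtures vary while every residue
#' keeps its intended classification.
#'
#' @param n residue count.
#' @param sequence one-letter sequence of the segment.
#' @param abego ABEGO string, one character per residue.
#' @param phi,psi,omega explicit angles for `segment()`.
#' @return A `fixture_segment` specification.
#' @name fixture_segments
NULL

#' @rdname fixture_segments
#' @export
strand <- function(n, sequence = NULL) {
  if (is.null(sequence)) sequence <- strrep("V", n)
  structure(list(sequence = sequence, abego = strrep("B", n)),
            class = "fixture_segment")
}

#' @rdname fixture_segments
#' @export
helix <- function(n, sequence = NULL) {
  if (is.null(sequence)) sequence <- strrep("A", n)
  structure(list(sequence = sequence, abego = strrep("A", n)),
            class = "fixture_segment")
}

#' @rdname fixture_segments
#' @export
motif <- function(sequence = "GPPGAGKS", abego = "EBBGAGAA") {
  if (nchar(sequence) != nchar(abego))
    stop("motif sequence and ABEGO string differ in length")
  structure(list(sequence = sequence, abego = abego, is_motif = TRUE),
            class = "fixture_segment")
}

#' @rdname fixture_segments
#' @export
segment <- function(sequence, phi, psi, omega = NULL) {
  n <- nchar(sequence)
  if (is.null(omega)) omega <- rep(180, n)
  stopifnot(length(phi) == n, length(psi) == n, length(omega) == n)
  structure(list(sequence = sequence, phi = phi, psi = psi, omega = omega),
            class = "fixture_segment")
}

# torsions realizing an ABEGO string: bin representative + seeded jitter
.abego_to_torsions <- function(abego, jitter = TRUE) {
  chars <- strsplit(abego, "")[[1L]]
  out <- t(vapply(chars, function(ch) {
    rep_t <- .abego_representative(ch)
    if (jitter) {
      box <- .abego_jitter(ch)
      rep_t[1:2] <- rep_t[1:2] + stats::runif(2L, -1, 1) * box[1:2]
    }
    rep_t
  }, numeric(3L)))
  dimnames(out) <- NULL
  out
}

#' Build a synthetic motif fixture with ground truth
#'
#' Concatenates segment specifications into one chain built by
#' [build_backbone()].  A `motif()` segment's sequence is a Walker-A
#' instance and its torsions realize the requested ABEGO string;
#' deterministic for a fixed seed (torsion jitter inside the ABEGO bins is
#' the only randomness).  When `break_orientation` is set, the Cbeta of the
#' residue preceding the first motif segment is reflected through its
#' Calpha along the strand axis, flipping the orientation cosine without
#' touching sequence or torsions -- a constructed orientation-negative.
#'
#' @param ... `fixture_segment` specifications, in chain order.
#' @param seed integer seed (0 disables jitter: pure bin representatives).
#' @param chain_id,start_resno,entry_id forwarded to [build_backbone()];
#'   `start_resno` sets the author number of the first residue, so motif
#'   segments can be placed at any author position (e.g. 151 or 232).
#' @param break_orientation logical, see above.
#' @return list with `model` (a [ploop_structure]) and `truth`: the full
#'   `sequence`, the intended `abego`, `motif_start_auth` /
#'   `motif_end_auth` (author numbers of the first motif segment, NA when
#'   none), and `seed`.
#' @export
make_motif_fixture <- function(..., seed = 1L, chain_id = "A",
                               start_resno = 1L, entry_id = "fixture",
                               break_orientation = FALSE) {
  segs <- list(...)
  if (length(segs) == 0L) stop("no segments supplied")
  if (!all(vapply(segs, inherits, TRUE, "fixture_segment")))
    stop("all arguments must be fixture segments (strand/helix/motif/segment)")
  set.seed(as.integer(seed))
  jitter <- seed != 0L
  sequence <- ""
  phi <- psi <- omega <- numeric(0)
  abego <- ""
  motif_start <- NA_integer_
  motif_len <- NA_integer_
  for (s in segs) {
    n_before <- nchar(sequence)
    if (!is.null(s$phi)) {
      tors <- cbind(s$phi, s$psi, s$omega)
      seg_abego <- strrep("?", nchar(s$sequence))
    } else {
      tors <- .abego_to_torsions(s$abego, jitter = jitter)
      seg_abego <- s$abego
    }
    if (isTRUE(s$is_motif) && is.na(motif_start)) {
      motif_start <- n_before + 1L
      motif_len <- nchar(s$sequence)
    }
    sequence <- paste0(sequence, s$sequence)
    abego <- paste0(abego, seg_abego)
    phi <- c(phi, tors[, 1L])
    psi <- c(psi, tors[, 2L])
    omega <- c(omega, tors[, 3L])
  }
  model <- build_backbone(sequence, phi, psi, omega, chain_id = chain_id,
                          start_resno = start_resno, entry_id = entry_id)
  if (break_orientation) {
    if (is.na(motif_start) || motif_start < 2L)
      stop("break_orientation needs a motif segment with a preceding residue")
    model <- .flip_pre_cb(model, chain_id, start_resno + motif_start - 2L)
  }
  truth <- list(sequence = sequence,
                abego = abego,
                motif_start_auth = if (is.na(motif_start)) NA_integer_ else
                  start_resno + motif_start - 1L,
                motif_end_auth = if (is.na(motif_start)) NA_integer_ else
                  start_resno + motif_start + motif_len - 2L,
                seed = as.integer(seed))
  list(model = model, truth = truth)
}

#' Turn a loop into a pseudo-loop
#'
#' Emulates a degenerated (pseudo) active-site loop: the backbone atoms of
#' the given range are rigidly rotated about the loop centroid and
#' displaced, and the residues renamed to `sequence`, while every atom
#' outside the range -- in particular the flanks a graft anchors on -- is
#' left bit-identical.  Grafting the original loop back into the result is
#' therefore an exact-restoration test with congruent anchors.
#'
#' @param model a [ploop_structure].
#' @param chain_id chain identifier.
#' @param range author-numbered inclusive range, length-2.
#' @param sequence one-letter sequence imposed on the range (same length).
#' @param angle rotation about the z axis through the centroid, degrees.
#' @param displacement translation magnitude, angstrom.
#' @return A [ploop_structure] with the scrambled loop.
#' @export
make_pseudo_loop <- function(model, chain_id, range,
                             sequence = "ANQDLRTG", angle = 25,
                             displacement = 1.5) {
  res <- chain_residues(model, chain_id)
  idx <- .range_indices(res, range)
  if (nchar(sequence) != length(idx))
    stop("sequence length does not match the range")
  sel <- model$atoms$chain == chain_id & !model$atoms$het &
    paste(model$atoms$resno, model$atoms$insert) %in%
      paste(res$resno[idx], res$insert[idx])
  xyz <- as.matrix(model$atoms[sel, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  th <- angle * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3L, 3L, byrow = TRUE)
  xyz <- sweep(xyz, 2L, ctr) %*% t(R) +
    matrix(ctr + c(displacement, 0, 0), nrow(xyz), 3L, byrow = TRUE)
  model$atoms$x[sel] <- xyz[, 1L]
  model$atoms$y[sel] <- xyz[, 2L]
  model$atoms$z[sel] <- xyz[, 3L]
  # rename residues; drop CB of residues that become glycine
  seq3 <- .one_to_three(strsplit(sequence, "")[[1L]])
  drop <- rep(FALSE, nrow(model$atoms))
  for (j in seq_along(idx)) {
    rsel <- model$atoms$chain == chain_id & !model$atoms$het &
      model$atoms$resno == res$resno[idx[j]] &
      model$atoms$insert == res$insert[idx[j]]
    model$atoms$resid[rsel] <- seq3[j]
    if (seq3[j] == "GLY") drop <- drop | (rsel & model$atoms$elety == "CB")
  }
  model$atoms <- model$atoms[!drop, , drop = FALSE]
  ploop_structure(model$atoms, entry_id = model$entry_id,
                  resolution = model$resolution)
}

# Reflect the CB of one residue through its CA: CB' = 2 CA - CB.  Inverts
# the CA->CB direction, hence the sign of the orientation cosine.
.flip_pre_cb <- function(model, chain_id, resno) {
  a <- model$atoms
  i <- which(a$chain == chain_id & a$resno == resno & a$elety == "CB" &
             !a$het)
  if (length(i) == 0L)
    stop("residue ", resno, " has no CB to flip (glycine pre-residue?)")
  ca <- .require_atom(model, chain_id, resno, "CA")
  a$x[i] <- 2 * ca[1L] - a$x[i]
  a$y[i] <- 2 * ca[2L] - a$y[i]
  a$z[i] <- 2 * ca[3L] - a$z[i]
  model$atoms <- a
  model
}

#' Attach a pseudo-ligand pose to a fixture
#'
#' Builds a phosphate [ligand_pose()] relative to a constraint set with
#' known ground truth: `"satisfy"` returns a pose with every violation
#' exactly zero (found by the seeded sampler); `"violate"` starts from a
#' satisfying pose and displaces the ligand atom of the *first* constraint
#' radially from its protein partner so that its violation equals `margin`
#' while all other constraints remain satisfied.
#'
#' @param model a [ploop_structure].
#' @param constraints constraint table (non-empty).
#' @param mode `"satisfy"` or `"violate"`.
#' @param margin violation beyond the tolerance band, angstrom
#'   (violate mode).
#' @param seed integer RNG seed.
#' @param resname pose residue name.
#' @return A [ligand_pose()].
#' @export
make_ligand_fixture <- function(model, constraints,
                                mode = c("satisfy", "violate"),
                                margin = 0.5, seed = 1L, resname = "ATP") {
  mode <- match.arg(mode)
  if (nrow(constraints) == 0L)
    stop("infeasible request: empty constraint set")
  poses <- withCallingHandlers(
    sample_phosphate_poses(model, constraints, n = 1L, seed = seed,
                           resname = resname),
    warning = function(w) invokeRestart("muffleWarning"))
  if (length(poses) == 0L)
    stop("infeasible constraint set: no satisfying pose found")
  pose <- poses[[1L]]
  if (mode == "satisfy") return(pose)

  target_atom <- constraints$ligand_atom[1L]
  p <- .require_atom(model, constraints$chain[1L], constraints$resno[1L],
                     constraints$atom[1L])
  i <- which(pose$atoms$elety == target_atom)[1L]
  q <- as.numeric(pose$atoms[i, c("x", "y", "z")])
  d_new <- constraints$target[1L] + constraints$tolerance[1L] + margin
  q_new <- p + .unit(q - p) * d_new
  pose$atoms[i, c("x", "y", "z")] <- as.list(q_new)
  rpt <- evaluate_constraints(model, pose, constraints)
  ok_others <- rpt$table$violation[-1L] == 0
  if (!all(ok_others))
    stop("could not violate constraint 1 in isolation: ",
         "another constraint shares its ligand atom")
  pose$provenance <- sprintf("violate(margin=%.3f, seed=%d)", margin, seed)
  pose
}
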