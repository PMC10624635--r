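# Backbone geometry: dihedral angles, phi/psi/omega extraction with
# chain-break handling, Kabsch superposition and whole-model Calpha RMSD.

# C(i)-N(i+1) distance beyond which the chain is considered broken
# (peptide bond ~1.33 A).
.chain_break_threshold <- 2.0

.vnorm <- function(v) sqrt(sum(v * v))
.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-10) stop("degenerate geometry: zero-length vector")
  v / n
}
.cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Dihedral angle of four points
#'
#' Signed torsion about the p2-p3 axis in the IUPAC convention, computed as
#' `atan2((n1 x n2) . b2_hat, n1 . n2)` with bond vectors `b1 = p2 - p1`,
#' `b2 = p3 - p2`, `b3 = p4 - p3` and normals `n1 = b1 x b2`,
#' `n2 = b2 x b3`.  Invariant under rigid transforms of all four points.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, angstrom.
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (.vnorm(b1) < 1e-10 || .vnorm(b2) < 1e-10 || .vnorm(b3) < 1e-10)
    stop("degenerate geometry: coincident consecutive points")
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  if (.vnorm(n1) < 1e-10 || .vnorm(n2) < 1e-10)
    stop("degenerate geometry: collinear points")
  ang <- atan2(sum(.cross(n1, n2) * .unit(b2)), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone torsions of a chain
#'
#' Computes phi, psi and omega for every polymer residue of a chain.  Phi is
#' undefined at the first residue and directly after a chain break; psi at
#' the last residue and directly before a break; omega (the torsion about
#' the C(i-1)-N(i) peptide bond) at the first residue and after breaks.  A
#' chain break is declared when the C(i)-N(i+1) distance exceeds 2.0
#' angstrom.  Residues missing backbone atoms get all-NA torsions plus a
#' warning.
#'
#' @param model a [ploop_structure].
#' @param chain_id chain identifier.
#' @return data.frame with columns `resno`, `insert`, `phi`, `psi`, `omega`
#'   (degrees, NA when undefined).
#' @export
backbone_torsions <- function(model, chain_id) {
  res <- chain_residues(model, chain_id)
  n <- nrow(res)
  get <- function(i, name) .get_atom(model, chain_id, res$resno[i], name,
                                     res$insert[i])
  N <- lapply(seq_len(n), get, "N")
  CA <- lapply(seq_len(n), get, "CA")
  C <- lapply(seq_len(n), get, "C")
  ok <- !vapply(N, is.null, TRUE) & !vapply(CA, is.null, TRUE) &
    !vapply(C, is.null, TRUE)
  if (any(!ok))
    warning("residues with missing backbone atoms in chain ", chain_id, ": ",
            paste(res$resno[!ok], collapse = ", "))
  # bonded(i): peptide bond between residue i and i+1 is intact
  bonded <- rep(FALSE, max(n - 1L, 0L))
  for (i in seq_len(max(n - 1L, 0L))) {
    if (ok[i] && ok[i + 1L])
      bonded[i] <- .vnorm(N[[i + 1L]] - C[[i]]) <= .chain_break_threshold
  }
  phi <- psi <- omega <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!ok[i]) next
    if (i > 1L && bonded[i - 1L]) {
      phi[i] <- dihedral_angle(C[[i - 1L]], N[[i]], CA[[i]], C[[i]])
      omega[i] <- dihedral_angle(CA[[i - 1L]], C[[i - 1L]], N[[i]], CA[[i]])
    }
    if (i < n && bonded[i])
      psi[i] <- dihedral_angle(N[[i]], CA[[i]], C[[i]], N[[i + 1L]])
  }
  data.frame(resno = res$resno, insert = res$insert,
             phi = phi, psi = psi, omega = omega,
             stringsAsFactors = FALSE)
}

# --- superposition ---------------------------------------------------------

#' Kabsch least-squares superposition
#'
#' Optimal proper rotation and translation mapping `mobile` onto
#' `reference`; reflections are excluded, so the rotation determinant is +1.
#'
#' @param mobile,reference n x 3 numeric matrices of paired coordinates,
#'   n >= 3.
#' @return list of class `superposition_result` with `rotation` (3 x 3),
#'   `translation` (length-3; transformed = coords %*% t(rotation) +
#'   translation), `rmsd` (angstrom) and `n_pairs`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)) || ncol(mobile) != 3L)
    stop("mobile and reference must be equal-size n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 paired points")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(reference, 2L, cr)
  H <- crossprod(P, Q)                       # 3x3 covariance
  s <- svd(H)
  if (s$d[2L] < 1e-10 * max(s$d[1L], 1e-30))
    stop("degenerate (rank-deficient) point sets: cannot superpose")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)   # maps mobile -> reference
  moved <- P %*% t(R)
  rmsd <- sqrt(sum((moved - Q)^2) / n)
  structure(list(rotation = R,
                 translation = as.numeric(cr - R %*% cm),
                 rmsd = rmsd,
                 n_pairs = n),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition over %d pairs: rmsd %.4f A\n", x$n_pairs,
              x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param coords n x 3 matrix (or 3-vector).
#' @param sup a `superposition_result` from [kabsch_superpose()].
#' @return Transformed coordinates, same shape as input.
#' @export
apply_superposition <- function(coords, sup) {
  v <- is.null(dim(coords))
  m <- if (v) matrix(coords, ncol = 3L) else as.matrix(coords)
  out <- m %*% t(sup$rotation) +
    matrix(sup$translation, nrow(m), 3L, byrow = TRUE)
  if (v) as.numeric(out) else out
}

# Calpha coordinate matrix for selected residues of a chain.
.ca_matrix <- function(model, chain_id, resno, insert) {
  m <- matrix(NA_real_, length(resno), 3L)
  for (i in seq_along(resno)) {
    p <- .get_atom(model, chain_id, resno[i], "CA", insert[i])
    if (!is.null(p)) m[i, ] <- p
  }
  m
}

#' Calpha RMSD between two models
#'
#' Pairs Calpha atoms of two chains either by author residue number
#' (default) or by global sequence alignment, then reports the optimal
#' superposition.
#'
#' @param model_a,model_b [ploop_structure] objects.
#' @param chain_a,chain_b chain identifiers (default first chain of each).
#' @param pairing `"auth_number"` or `"sequence_align"`.
#' @return A `superposition_result` (see [kabsch_superpose()]) with `rmsd`
#'   in angstrom and `n_pairs` the number of paired Calpha atoms.
#' @export
compare_models <- function(model_a, model_b,
                           chain_a = structure_chains(model_a)[1L],
                           chain_b = structure_chains(model_b)[1L],
                           pairing = c("auth_number", "sequence_align")) {
  pairing <- match.arg(pairing)
  ra <- chain_residues(model_a, chain_a)
  rb <- chain_residues(model_b, chain_b)
  if (pairing == "auth_number") {
    ka <- paste(ra$resno, ra$insert)
    kb <- paste(rb$resno, rb$insert)
    common <- intersect(ka, kb)
    ia <- match(common, ka)
    ib <- match(common, kb)
  } else {
    sa <- extract_chain_sequence(model_a, chain_a)$sequence
    sb <- extract_chain_sequence(model_b, chain_b)$sequence
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(sa), Biostrings::AAString(sb),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    ia <- ib <- integer(0)
    ca <- cb <- 0L
    for (k in seq_along(pa)) {
      if (pa[k] != "-") ca <- ca + 1L
      if (pb[k] != "-") cb <- cb + 1L
      if (pa[k] != "-" && pb[k] != "-") {
        ia <- c(ia, ca)
        ib <- c(ib, cb)
      }
    }
  }
  ma <- .ca_matrix(model_a, chain_a, ra$resno[ia], ra$insert[ia])
  mb <- .ca_matrix(model_b, chain_b, rb$resno[ib], rb$insert[ib])
  keep <- stats::complete.cases(ma) & stats::complete.cases(mb)
  if (sum(keep) < 3L)
    stop("fewer than 3 paired Calpha atoms between the models")
  kabsch_superpose(ma[keep, , drop = FALSE], mb[keep, , drop = FALSE])
}
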