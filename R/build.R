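# Internal-coordinate backbone construction (sequential natural-extension
# placement).  Only self-consistency matters for synthetic fixtures: the
# torsions recovered by backbone_torsions() reproduce the input spec.

# Ideal bond lengths (angstrom) and angles (degrees); single fixed table.
.ideal <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.521,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.5, a_n_ca_cb = 110.5,
  # improper torsion C-N-CA-CB fixing L-chirality of the virtual CB
  t_c_n_ca_cb = -122.6)

# Place atom D given A, B, C with bond |C-D|, angle B-C-D and torsion
# A-B-C-D (degrees); the torsion convention matches dihedral_angle().
.place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- cbind(bc, .cross(n, bc), n)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  as.numeric(c + m %*% d2)
}

.one_to_three <- function(one) {
  three <- bio3d::aa123(one)
  three[is.na(three) | one == "X"] <- "UNK"
  three
}

#' Build a backbone from a dihedral specification
#'
#' Sequential internal-coordinate construction of an N/CA/C/O backbone (plus
#' CB for non-glycine residues) from per-residue (phi, psi, omega) angles and
#' ideal bond lengths/angles.  `phi[1]` and `omega[1]` are ignored (undefined
#' at the N terminus); `psi[n]` is used only to place the terminal carbonyl
#' oxygen.  The construction round-trips: [backbone_torsions()] of the result
#' reproduces the specified angles to well below 1e-3 degrees.
#'
#' @param sequence one-letter amino-acid string.
#' @param phi,psi,omega numeric vectors of length `nchar(sequence)`, degrees
#'   in (-180, 180].
#' @param chain_id chain identifier for the built model.
#' @param start_resno author number of the first residue.
#' @param entry_id entry identifier of the built model.
#' @return A [ploop_structure] with one chain.
#' @export
build_backbone <- function(sequence, phi, psi, omega = NULL,
                           chain_id = "A", start_resno = 1L,
                           entry_id = "built") {
  seq1 <- strsplit(toupper(sequence), "")[[1L]]
  n <- length(seq1)
  if (n < 1L) stop("empty sequence")
  if (is.null(omega)) omega <- rep(180, n)
  if (length(phi) != n || length(psi) != n || length(omega) != n)
    stop("phi, psi, omega must match the sequence length")
  ang <- c(phi[-1L], psi, omega[-1L])
  if (any(!is.na(ang) & (ang <= -180 | ang > 180)))
    stop("angles must lie in (-180, 180]")
  phi[is.na(phi)] <- 180
  psi[is.na(psi)] <- 180
  omega[is.na(omega)] <- 180

  id <- .ideal
  N <- CA <- C <- vector("list", n)
  # first residue in a canonical frame
  N[[1L]] <- c(0, 0, 0)
  CA[[1L]] <- c(id$b_n_ca, 0, 0)
  th <- id$a_n_ca_c * pi / 180
  C[[1L]] <- CA[[1L]] + id$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)[-1L]) {
    N[[i]] <- .place_atom(N[[i - 1L]], CA[[i - 1L]], C[[i - 1L]],
                          id$b_c_n, id$a_ca_c_n, psi[i - 1L])
    CA[[i]] <- .place_atom(CA[[i - 1L]], C[[i - 1L]], N[[i]],
                           id$b_n_ca, id$a_c_n_ca, omega[i])
    C[[i]] <- .place_atom(C[[i - 1L]], N[[i]], CA[[i]],
                          id$b_ca_c, id$a_n_ca_c, phi[i])
  }
  rows <- list()
  for (i in seq_len(n)) {
    O <- .place_atom(N[[i]], CA[[i]], C[[i]], id$b_c_o, id$a_ca_c_o,
                     .wrap_angle(psi[i] + 180))
    res_atoms <- list(N = N[[i]], CA = CA[[i]], C = C[[i]], O = O)
    if (seq1[i] != "G")
      res_atoms$CB <- .place_atom(C[[i]], N[[i]], CA[[i]], id$b_ca_cb,
                                  id$a_n_ca_cb, id$t_c_n_ca_cb)
    for (nm in names(res_atoms)) {
      p <- res_atoms[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain_id, resno = start_resno + i - 1L, insert = "",
        resid = .one_to_three(seq1[i])[1L], elety = nm,
        elesy = substr(nm, 1L, 1L), alt = "", o = 1,
        x = p[1L], y = p[2L], z = p[3L], het = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  ploop_structure(do.call(rbind, rows), entry_id = entry_id)
}

.wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a <= -180, a + 360, a)
}

# Virtual CB from backbone N, CA, C (ideal tetrahedral geometry); used for
# glycine when the orientation feature needs a CB direction.
.virtual_cb <- function(N, CA, C) {
  .place_atom(C, N, CA, .ideal$b_ca_cb, .ideal$a_n_ca_cb, .ideal$t_c_n_ca_cb)
}
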