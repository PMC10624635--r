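# ABEGO torsion-bin classification.  The five-letter alphabet divides
# phi/psi/omega space into the alpha-helical region (A), the extended
# beta region (B), the positive-phi regions (G near-helical, E extended)
# and cis-peptides (O); '-' marks residues with undefined torsions
# (termini, chain breaks, missing atoms).

#' Classify backbone torsions into ABEGO bins
#'
#' Per residue: `'O'` when omega is defined and |omega| < 90 degrees
#' (cis peptide); otherwise `'A'` when phi < 0 and -75 <= psi < 50, `'B'`
#' when phi < 0 and (psi >= 50 or psi < -75), `'G'` when phi >= 0 and
#' -100 <= psi < 100, `'E'` when phi >= 0 and (psi >= 100 or psi < -100);
#' `'-'` when phi or psi is undefined.  The bins partition torsion space:
#' every defined (phi, psi, omega) maps to exactly one character.
#'
#' @param torsions data.frame with columns `phi`, `psi`, `omega` in degrees
#'   (as from [backbone_torsions()]); NA marks undefined angles.
#' @return Single character string, one letter per residue.
#' @export
abego_classify <- function(torsions) {
  stopifnot(is.data.frame(torsions), nrow(torsions) > 0L,
            all(c("phi", "psi", "omega") %in% names(torsions)))
  out <- vapply(seq_len(nrow(torsions)), function(i) {
    .abego_char(torsions$phi[i], torsions$psi[i], torsions$omega[i])
  }, character(1L))
  paste(out, collapse = "")
}

.abego_char <- function(phi, psi, omega) {
  if (!is.na(omega) && abs(omega) < 90) return("O")
  if (is.na(phi) || is.na(psi)) return("-")
  if (phi < 0) {
    if (psi >= -75 && psi < 50) "A" else "B"
  } else {
    if (psi >= -100 && psi < 100) "G" else "E"
  }
}

# Representative (phi, psi, omega) inside each bin; used by the fixture
# generator and by the tolerance-mode bin distance below.
.abego_representative <- function(char) {
  switch(char,
         A = c(-57, -47, 180),
         B = c(-120, 135, 180),
         G = c(61, 41, 180),
         E = c(75, 160, 180),
         O = c(-75, 160, 0),
         stop("no representative torsions for ABEGO character '", char, "'"))
}

# Half-widths of a jitter box around each representative that stays strictly
# inside the bin (used for seeded fixture variation).
.abego_jitter <- function(char) {
  switch(char,
         A = c(25, 20, 20),
         B = c(25, 20, 20),
         G = c(20, 20, 20),
         E = c(20, 15, 20),
         O = c(20, 15, 20),
         stop("no jitter box for ABEGO character '", char, "'"))
}

# Distance (degrees) from (phi, psi, omega) to the nearest point of the
# region of `char`, as the max over the per-angle interval distances
# (psi intervals wrap at +-180).  Zero inside the bin.  Used by the
# tolerance matching mode for perturbed/minimized models.
.abego_bin_distance <- function(phi, psi, omega, char) {
  if (is.na(phi) || is.na(psi)) return(Inf)
  iv_dist <- function(x, lo, hi) {
    if (x >= lo && x <= hi) 0 else min(abs(x - lo), abs(x - hi))
  }
  wrap_dist <- function(x, lo, hi) {
    # distance to [lo, hi] on the -180..180 circle
    d <- iv_dist(x, lo, hi)
    min(d, iv_dist(x + 360, lo, hi), iv_dist(x - 360, lo, hi))
  }
  if (char == "O") {
    if (is.na(omega)) return(Inf)
    return(max(0, abs(omega) - 90))
  }
  # non-O bins additionally require a trans-ish peptide
  om_pen <- if (!is.na(omega) && abs(omega) < 90) 90 - abs(omega) else 0
  d <- switch(char,
              A = max(iv_dist(phi, -180, 0), wrap_dist(psi, -75, 50)),
              B = max(iv_dist(phi, -180, 0),
                      min(wrap_dist(psi, 50, 180), wrap_dist(psi, -180, -75))),
              G = max(iv_dist(phi, 0, 180), wrap_dist(psi, -100, 100)),
              E = max(iv_dist(phi, 0, 180),
                      min(wrap_dist(psi, 100, 180),
                          wrap_dist(psi, -180, -100))),
              stop("unknown ABEGO character '", char, "'"))
  max(d, om_pen)
}

# Match an observed torsion table against a required ABEGO pattern.
# exact: character-for-character equality ('-' never matches).
# tolerance: accept residues whose torsions lie within `tol` degrees of the
# required bin.
.abego_pattern_match <- function(torsions, pattern,
                                 mode = c("exact", "tolerance"), tol = 10) {
  mode <- match.arg(mode)
  chars <- strsplit(pattern, "")[[1L]]
  if (nrow(torsions) != length(chars))
    stop("torsion table length does not match pattern length")
  if (mode == "exact") {
    obs <- strsplit(abego_classify(torsions), "")[[1L]]
    all(obs == chars & chars != "-")
  } else {
    all(vapply(seq_along(chars), function(i) {
      .abego_bin_distance(torsions$phi[i], torsions$psi[i],
                          torsions$omega[i], chars[i]) <= tol
    }, logical(1L)))
  }
}
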