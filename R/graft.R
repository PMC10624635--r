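# Loop grafting: replace an acceptor pseudo-loop's backbone with a donor
# P-loop backbone positioned by rigid superposition of anchor Calpha atoms.

# chain-order indices of an author-numbered range, validated contiguous
.range_indices <- function(res, range) {
  i1 <- which(res$resno == range[1L] & res$insert == "")
  i2 <- which(res$resno == range[2L] & res$insert == "")
  if (length(i1) == 0L || length(i2) == 0L)
    stop("residue range ", range[1L], "-", range[2L],
         " not resolvable in chain")
  if (i2[1L] < i1[1L]) stop("range end precedes range start")
  i1[1L]:i2[1L]
}

#' Graft a donor P-loop onto an acceptor loop
#'
#' Computes the donor-to-acceptor rigid transform from anchor Calpha atoms,
#' replaces the acceptor range's backbone atoms (N, CA, C, O, and CB where
#' the donor has one) with the transformed donor atoms, and renames the
#' grafted residues to the donor sequence with side chains truncated at CB
#' (glycine keeps no CB).  Grafted residues keep the acceptor's author
#' numbering; every atom outside the range is left bit-identical.
#'
#' Anchor modes: `"flank_window"` pairs `k` residues on each side of the
#' acceptor range with the corresponding donor flanks (deterministic, no
#' homology alignment needed); `"global_ca"` pairs all Calpha atoms shared
#' by author number between the two chains, reproducing a whole-subunit
#' superposition when donor and acceptor are homologous subunits.
#'
#' @param donor,acceptor [ploop_structure] objects.
#' @param donor_chain,acceptor_chain chain identifiers.
#' @param donor_range,acceptor_range author-numbered inclusive ranges,
#'   length-2 integer vectors; defaults 232-239 and 151-158, the donor
#'   P-loop and acceptor pseudo-loop positions of the V1-ATPase A and B
#'   subunits.
#' @param anchor `"flank_window"` or `"global_ca"`.
#' @param k flank window size in residues (default 4).
#' @param rename_sequence optional one-letter string imposed on the grafted
#'   residues instead of the donor sequence (e.g. a designed sequence).
#' @param definition [motif_definition()] used for the report's torsion
#'   pattern and orientation checks.
#' @return list with `model` (the grafted [ploop_structure]) and `report`
#'   (a `graft_report`, see [validate_graft()]; additionally carries
#'   `anchor_rmsd` and `anchor_mode`).
#' @export
graft_loop <- function(donor, acceptor,
                       donor_chain = structure_chains(donor)[1L],
                       acceptor_chain = structure_chains(acceptor)[1L],
                       donor_range = c(232L, 239L),
                       acceptor_range = c(151L, 158L),
                       anchor = c("flank_window", "global_ca"),
                       k = 4L,
                       rename_sequence = NULL,
                       definition = motif_definition()) {
  anchor <- match.arg(anchor)
  dres <- chain_residues(donor, donor_chain)
  ares <- chain_residues(acceptor, acceptor_chain)
  di <- .range_indices(dres, donor_range)
  ai <- .range_indices(ares, acceptor_range)
  if (length(di) != length(ai))
    stop("donor and acceptor ranges differ in length (", length(di),
         " vs ", length(ai), ")")
  L <- length(di)

  if (anchor == "flank_window") {
    if (min(ai) - k < 1L || max(ai) + k > nrow(ares) ||
        min(di) - k < 1L || max(di) + k > nrow(dres))
      stop("flank window of ", k, " residues exceeds a chain boundary")
    dsel <- c((min(di) - k):(min(di) - 1L), (max(di) + 1L):(max(di) + k))
    asel <- c((min(ai) - k):(min(ai) - 1L), (max(ai) + 1L):(max(ai) + k))
  } else {
    # whole-chain Calpha pairing by author number, excluding the graft
    # ranges themselves (the loops differ by construction)
    common <- intersect(paste(dres$resno, dres$insert)[-di],
                        paste(ares$resno, ares$insert)[-ai])
    dsel <- match(common, paste(dres$resno, dres$insert))
    asel <- match(common, paste(ares$resno, ares$insert))
  }
  dmat <- .ca_matrix(donor, donor_chain, dres$resno[dsel], dres$insert[dsel])
  amat <- .ca_matrix(acceptor, acceptor_chain, ares$resno[asel],
                     ares$insert[asel])
  keep <- stats::complete.cases(dmat) & stats::complete.cases(amat)
  if (sum(keep) < 3L) stop("fewer than 3 anchor Calpha pairs")
  sup <- kabsch_superpose(dmat[keep, , drop = FALSE],
                          amat[keep, , drop = FALSE])

  # transformed donor loop backbone
  loop_rows <- list()
  for (j in seq_len(L)) {
    dr <- dres[di[j], ]
    ar <- ares[ai[j], ]
    keep_atoms <- c("N", "CA", "C", "O", "CB")
    sel <- donor$atoms$chain == donor_chain &
      donor$atoms$resno == dr$resno & donor$atoms$insert == dr$insert &
      !donor$atoms$het & donor$atoms$elety %in% keep_atoms
    at <- donor$atoms[sel, , drop = FALSE]
    if (!all(c("N", "CA", "C") %in% at$elety))
      stop("donor residue ", dr$resno, " lacks backbone atoms")
    new_resid <- dr$resid
    if (!is.null(rename_sequence)) {
      if (nchar(rename_sequence) != L)
        stop("rename_sequence length does not match the grafted range")
      new_resid <- .one_to_three(substr(rename_sequence, j, j))
    }
    if (bio3d::aa321(new_resid) %in% "G")
      at <- at[at$elety != "CB", , drop = FALSE]
    xyz <- apply_superposition(as.matrix(at[, c("x", "y", "z")]), sup)
    at$x <- xyz[, 1L]
    at$y <- xyz[, 2L]
    at$z <- xyz[, 3L]
    at$chain <- acceptor_chain
    at$resno <- ar$resno
    at$insert <- ar$insert
    at$resid <- new_resid
    loop_rows[[j]] <- at
  }
  loop_atoms <- do.call(rbind, loop_rows)

  # splice: every atom outside the acceptor range is untouched
  in_range <- acceptor$atoms$chain == acceptor_chain &
    !acceptor$atoms$het &
    paste(acceptor$atoms$resno, acceptor$atoms$insert) %in%
      paste(ares$resno[ai], ares$insert[ai])
  out_atoms <- acceptor$atoms[!in_range, , drop = FALSE]
  grafted <- acceptor
  grafted$atoms <- rbind(out_atoms, loop_atoms)
  grafted <- ploop_structure(grafted$atoms, entry_id = acceptor$entry_id,
                             resolution = acceptor$resolution)

  report <- validate_graft(grafted, acceptor_chain, acceptor_range,
                           expected_pattern = definition$torsion_pattern,
                           definition = definition)
  report$anchor_rmsd <- sup$rmsd
  report$anchor_mode <- anchor
  list(model = grafted, report = report)
}

#' Validate a grafted loop
#'
#' Recomputes the loop's ABEGO string and compares it with the expected
#' torsion pattern, measures the splice C-N bond lengths on both sides of
#' the range (continuity requires 1.33 +/- 0.15 angstrom), counts
#' heavy-atom clashes of loop atoms against the rest of the protein (same
#' rule as [clash_score()]), and recomputes the orientation feature.
#'
#' @param model a [ploop_structure].
#' @param chain_id chain carrying the loop.
#' @param range author-numbered inclusive loop range, length-2.
#' @param expected_pattern required ABEGO string (default from
#'   `definition`).
#' @param definition a [motif_definition()].
#' @param torsion_mode,torsion_tol see [detect_ploops()].
#' @param clash_scale van-der-Waals overlap factor (default 0.80).
#' @return list of class `graft_report`: `loop_abego`, `pattern_retained`,
#'   `junction_bond_lengths` (angstrom, NA at a terminus),
#'   `continuity_ok`, `clash_count`, `orientation_value`,
#'   `orientation_ok`.
#' @export
validate_graft <- function(model, chain_id, range,
                           expected_pattern = NULL,
                           definition = motif_definition(),
                           torsion_mode = c("exact", "tolerance"),
                           torsion_tol = 10,
                           clash_scale = 0.80) {
  torsion_mode <- match.arg(torsion_mode)
  if (is.null(expected_pattern)) expected_pattern <- definition$torsion_pattern
  res <- chain_residues(model, chain_id)
  idx <- .range_indices(res, range)
  tor <- backbone_torsions(model, chain_id)
  tor_span <- tor[idx, , drop = FALSE]
  loop_abego <- abego_classify(tor_span)
  pattern_retained <- if (is.null(expected_pattern)) NA else
    .abego_pattern_match(tor_span, expected_pattern, mode = torsion_mode,
                         tol = torsion_tol)

  junction <- c(NA_real_, NA_real_)
  i0 <- min(idx)
  i1 <- max(idx)
  if (i0 > 1L) {
    cprev <- .get_atom(model, chain_id, res$resno[i0 - 1L], "C",
                       res$insert[i0 - 1L])
    nfirst <- .get_atom(model, chain_id, res$resno[i0], "N",
                        res$insert[i0])
    if (!is.null(cprev) && !is.null(nfirst))
      junction[1L] <- .vnorm(nfirst - cprev)
  }
  if (i1 < nrow(res)) {
    clast <- .get_atom(model, chain_id, res$resno[i1], "C",
                       res$insert[i1])
    nnext <- .get_atom(model, chain_id, res$resno[i1 + 1L], "N",
                       res$insert[i1 + 1L])
    if (!is.null(clast) && !is.null(nnext))
      junction[2L] <- .vnorm(nnext - clast)
  }
  continuity_ok <- all(abs(junction[!is.na(junction)] - 1.33) <= 0.15) &&
    any(!is.na(junction))

  # loop-vs-rest heavy-atom clash count under the shared vdW overlap rule.
  # Residues within 4 chain positions of the loop are excluded from the
  # environment: packing against the splice neighbourhood is governed by
  # the torsion and junction-bond criteria, while the clash count targets
  # non-local collisions (the loop plunging into the core).
  in_loop <- model$atoms$chain == chain_id & !model$atoms$het &
    paste(model$atoms$resno, model$atoms$insert) %in%
      paste(res$resno[idx], res$insert[idx])
  loop_xyz <- as.matrix(model$atoms[in_loop, c("x", "y", "z")])
  loop_el <- model$atoms$elesy[in_loop]
  near <- max(i0 - 4L, 1L):min(i1 + 4L, nrow(res))
  env_keep <- !in_loop & !model$atoms$het &
    !(model$atoms$chain == chain_id &
      paste(model$atoms$resno, model$atoms$insert) %in%
        paste(res$resno[near], res$insert[near]))
  env_xyz <- as.matrix(model$atoms[env_keep, c("x", "y", "z")])
  env_el <- model$atoms$elesy[env_keep]
  clash_count <- .count_clashes(loop_xyz, loop_el, env_xyz, env_el,
                                scale = clash_scale)$count

  ori <- tryCatch(
    orientation_feature(model, chain_id, range[1L],
                        lys_slot = definition$lys_slot),
    error = function(e) NULL)

  structure(list(loop_abego = loop_abego,
                 pattern_retained = pattern_retained,
                 junction_bond_lengths = junction,
                 continuity_ok = continuity_ok,
                 clash_count = clash_count,
                 orientation_value = if (is.null(ori)) NA_real_ else
                   ori$cosine,
                 orientation_ok = if (is.null(ori)) NA else
                   ori$points_away),
            class = "graft_report")
}

#' @export
print.graft_report <- function(x, ...) {
  cat("graft report\n")
  cat("  loop ABEGO:", x$loop_abego,
      if (isTRUE(x$pattern_retained)) "(pattern retained)" else
        "(pattern LOST)", "\n")
  cat(sprintf("  junction C-N bonds: %s A, continuity %s\n",
              paste(sprintf("%.3f", x$junction_bond_lengths),
                    collapse = " / "),
              if (isTRUE(x$continuity_ok)) "ok" else "BROKEN"))
  cat("  clashes:", x$clash_count,
      " orientation cosine:", sprintf("%.3f", x$orientation_value), "\n")
  if (!is.null(x$anchor_rmsd))
    cat(sprintf("  anchor rmsd: %.4f A (%s)\n", x$anchor_rmsd,
                x$anchor_mode))
  invisible(x)
}
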