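# Walker-A P-loop detection by the three conserved features: amino-acid
# sequence G-X1-X2-X3-X4-G-K-[T/S] (with the additionally conserved Gly at
# X3), backbone torsion pattern EBBGAGAA, and the orientation of the
# conserved Lys relative to the last strand residue before the loop.

#' Define a Walker-A motif
#'
#' The sequence pattern is written with fixed residues as plain letters,
#' numbered wildcards as `X1`, `X2`, ... (plain `X` also accepted) and
#' alternative sets as `[TS]` or `(T/S)`.  `required_fixed` pins wildcard
#' slots to a residue; the default pins `X3` to Gly, the additionally
#' conserved glycine of native P-loops.  The classic motif including the
#' conserved lysine is the default; the lysine-free variant
#' `"GX1X2X3X4G[TS]"` is also accepted (the orientation feature then needs
#' an explicit `lys_slot`).
#'
#' @param sequence_pattern motif expression (default `"GX1X2X3X4GK[TS]"`).
#' @param required_fixed named character vector pinning wildcard slots,
#'   e.g. `c(X3 = "G")`; use `character(0)` for none.
#' @param torsion_pattern required ABEGO string over the motif residues
#'   (default `"EBBGAGAA"`); `NULL` disables the torsion criterion.
#' @param orientation_required logical; require the conserved-Lys
#'   orientation feature for a confirmed hit.
#' @param lys_slot 1-based motif position of the conserved lysine; default
#'   locates the fixed `K` in the pattern.
#' @return An object of class `motif_definition`.
#' @export
motif_definition <- function(sequence_pattern = "GX1X2X3X4GK[TS]",
                             required_fixed = c(X3 = "G"),
                             torsion_pattern = "EBBGAGAA",
                             orientation_required = TRUE,
                             lys_slot = NULL) {
  slots <- .parse_motif_pattern(sequence_pattern)
  if (length(required_fixed) > 0L) {
    nm <- vapply(slots, function(s) s$name %||% "", character(1L))
    for (slot in names(required_fixed)) {
      i <- match(slot, nm)
      if (is.na(i)) stop("required_fixed slot '", slot,
                         "' not present in pattern")
      slots[[i]] <- list(type = "fixed",
                         allowed = toupper(required_fixed[[slot]]),
                         name = slot)
    }
  }
  if (!is.null(torsion_pattern) &&
      nchar(torsion_pattern) != length(slots))
    stop("torsion pattern length (", nchar(torsion_pattern),
         ") does not match sequence pattern length (", length(slots), ")")
  if (is.null(lys_slot)) {
    k <- which(vapply(slots, function(s)
      s$type == "fixed" && identical(s$allowed, "K"), logical(1L)))
    lys_slot <- if (length(k) > 0L) k[1L] else NA_integer_
  }
  structure(list(slots = slots,
                 pattern = sequence_pattern,
                 torsion_pattern = torsion_pattern,
                 orientation_required = orientation_required,
                 lys_slot = as.integer(lys_slot)),
            class = "motif_definition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_motif_pattern <- function(pattern) {
  chars <- strsplit(gsub("-", "", pattern), "")[[1L]]
  slots <- list()
  i <- 1L
  n_wild <- 0L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "X") {
      j <- i + 1L
      digits <- ""
      while (j <= length(chars) && grepl("[0-9]", chars[j])) {
        digits <- paste0(digits, chars[j])
        j <- j + 1L
      }
      n_wild <- n_wild + 1L
      name <- if (nzchar(digits)) paste0("X", digits) else paste0("X", n_wild)
      slots[[length(slots) + 1L]] <- list(type = "wild", allowed = NULL,
                                          name = name)
      i <- j
    } else if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1L]
      if (is.na(j)) stop("unclosed '[' in motif pattern")
      slots[[length(slots) + 1L]] <- list(
        type = "alt", allowed = toupper(chars[(i + 1L):(j - 1L)]),
        name = NULL)
      i <- j + 1L
    } else if (ch == "(") {
      j <- which(chars == ")" & seq_along(chars) > i)[1L]
      if (is.na(j)) stop("unclosed '(' in motif pattern")
      inner <- chars[(i + 1L):(j - 1L)]
      slots[[length(slots) + 1L]] <- list(
        type = "alt", allowed = toupper(inner[inner != "/"]), name = NULL)
      i <- j + 1L
    } else if (grepl("[A-WYZ]", toupper(ch))) {
      slots[[length(slots) + 1L]] <- list(type = "fixed",
                                          allowed = toupper(ch), name = NULL)
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in motif pattern")
    }
  }
  slots
}

#' @export
print.motif_definition <- function(x, ...) {
  cat("Walker-A motif:", x$pattern, "\n")
  if (!is.null(x$torsion_pattern))
    cat("  torsion pattern:", x$torsion_pattern, "\n")
  cat("  orientation required:", x$orientation_required,
      " conserved-Lys slot:", x$lys_slot, "\n")
  invisible(x)
}

#' Scan a sequence for Walker-A matches
#'
#' Slides the motif over the sequence and reports every (possibly
#' overlapping) window whose fixed and alternative slots match; wildcard
#' slots are free except those pinned by `required_fixed`.  An `'X'` in the
#' sequence (non-standard residue) never matches a fixed slot.
#'
#' @param sequence one-letter amino-acid string.
#' @param definition a [motif_definition()].
#' @return Integer vector of 1-based match start indices, left to right.
#' @export
scan_walker_a <- function(sequence, definition = motif_definition()) {
  seq1 <- strsplit(toupper(sequence), "")[[1L]]
  L <- length(definition$slots)
  n <- length(seq1)
  if (n < L) return(integer(0))
  hits <- integer(0)
  for (start in seq_len(n - L + 1L)) {
    ok <- TRUE
    for (k in seq_len(L)) {
      s <- definition$slots[[k]]
      if (s$type == "wild") next
      ch <- seq1[start + k - 1L]
      if (ch == "X" || !(ch %in% s$allowed)) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, start)
  }
  hits
}

#' Orientation of the conserved lysine
#'
#' The orientation feature of native P-loops: the vector from the Calpha of
#' the last strand residue immediately before the loop to the Calpha of the
#' conserved Lys points away from that residue's Calpha-to-Cbeta vector.
#' Operationally the "last strand residue" is the residue preceding the
#' motif start in chain order; a virtual Cbeta is constructed from N/CA/C
#' for glycine.  Returns the cosine between the two unit vectors and the
#' points-away flag (`cosine < 0`, strict).
#'
#' @param model a [ploop_structure].
#' @param chain_id chain identifier.
#' @param start_resno author number of the first motif residue.
#' @param lys_slot 1-based motif position of the conserved lysine
#'   (default 7).
#' @param start_insert insertion code of the first motif residue.
#' @return list with `cosine` (in `[-1, 1]`) and `points_away` (logical).
#' @export
orientation_feature <- function(model, chain_id, start_resno, lys_slot = 7L,
                                start_insert = "") {
  res <- chain_residues(model, chain_id)
  idx <- which(res$resno == start_resno & res$insert == start_insert)
  if (length(idx) == 0L)
    stop("motif start residue ", start_resno, " not found in chain ",
         chain_id)
  idx <- idx[1L]
  if (idx < 2L)
    stop("no residue precedes the motif start: orientation undefined")
  if (is.na(lys_slot))
    stop("conserved-Lys slot is undefined for this motif definition")
  lys_idx <- idx + lys_slot - 1L
  if (lys_idx > nrow(res))
    stop("conserved-Lys position falls outside the chain")
  pre <- idx - 1L
  ca_pre <- .require_atom(model, chain_id, res$resno[pre], "CA",
                          res$insert[pre])
  cb_pre <- .get_atom(model, chain_id, res$resno[pre], "CB",
                      res$insert[pre])
  if (is.null(cb_pre)) {
    n_pre <- .require_atom(model, chain_id, res$resno[pre], "N",
                           res$insert[pre])
    c_pre <- .require_atom(model, chain_id, res$resno[pre], "C",
                           res$insert[pre])
    cb_pre <- .virtual_cb(n_pre, ca_pre, c_pre)
  }
  ca_lys <- .require_atom(model, chain_id, res$resno[lys_idx], "CA",
                          res$insert[lys_idx])
  cosine <- sum(.unit(ca_lys - ca_pre) * .unit(cb_pre - ca_pre))
  list(cosine = cosine, points_away = cosine < 0)
}

#' Detect P-loops in a structure
#'
#' Applies the three conserved Walker-A features chain by chain: every
#' sequence match of the motif is checked for the required backbone torsion
#' pattern (exact ABEGO comparison by default, or a per-residue angular
#' tolerance for perturbed/minimized models) and for the conserved-Lys
#' orientation feature.  A hit is confirmed when all enabled criteria pass.
#'
#' @param model a [ploop_structure].
#' @param definition a [motif_definition()].
#' @param torsion_mode `"exact"` (character-for-character, `'-'` never
#'   matches) or `"tolerance"`.
#' @param torsion_tol degrees of slack in tolerance mode (default 10).
#' @return data.frame of class `ploop_hits` with one row per sequence
#'   match: `chain`, `start_auth`, `end_auth`, `matched_sequence`, `abego`,
#'   `orientation_value`, `sequence_ok`, `torsion_ok`, `orientation_ok`,
#'   `confirmed`, `reason`.
#' @export
detect_ploops <- function(model, definition = motif_definition(),
                          torsion_mode = c("exact", "tolerance"),
                          torsion_tol = 10) {
  torsion_mode <- match.arg(torsion_mode)
  L <- length(definition$slots)
  rows <- list()
  for (ch in structure_chains(model)) {
    sq <- extract_chain_sequence(model, ch)
    if (nchar(sq$sequence) < L) next
    starts <- scan_walker_a(sq$sequence, definition)
    if (length(starts) == 0L) next
    tor <- backbone_torsions(model, ch)
    for (st in starts) {
      span <- st:(st + L - 1L)
      tor_span <- tor[span, , drop = FALSE]
      abego <- abego_classify(tor_span)
      torsion_ok <- if (is.null(definition$torsion_pattern)) TRUE else
        .abego_pattern_match(tor_span, definition$torsion_pattern,
                             mode = torsion_mode, tol = torsion_tol)
      reason <- ""
      ovalue <- NA_real_
      orientation_ok <- NA
      ori <- tryCatch(
        orientation_feature(model, ch, sq$resno[st],
                            lys_slot = definition$lys_slot,
                            start_insert = sq$insert[st]),
        error = function(e) e)
      if (inherits(ori, "error")) {
        orientation_ok <- FALSE
        reason <- conditionMessage(ori)
      } else {
        ovalue <- ori$cosine
        orientation_ok <- ori$points_away
      }
      confirmed <- torsion_ok &&
        (orientation_ok || !definition$orientation_required)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch,
        start_auth = sq$resno[st],
        end_auth = sq$resno[st + L - 1L],
        matched_sequence = substr(sq$sequence, st, st + L - 1L),
        abego = abego,
        orientation_value = ovalue,
        sequence_ok = TRUE,
        torsion_ok = torsion_ok,
        orientation_ok = orientation_ok,
        confirmed = confirmed,
        reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(0), start_auth = integer(0),
               end_auth = integer(0), matched_sequence = character(0),
               abego = character(0), orientation_value = numeric(0),
               sequence_ok = logical(0), torsion_ok = logical(0),
               orientation_ok = logical(0), confirmed = logical(0),
               reason = character(0), stringsAsFactors = FALSE)
  class(out) <- c("ploop_hits", "data.frame")
  out
}
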