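# Survey of confirmed P-loop hits over a structure set: position-wise
# residue and ABEGO torsion-bin frequencies, orientation statistics, and
# distances from designated motif atoms to ligand phosphorus atoms.  The
# distance summaries feed default distance constraints for ligand fitting.

# Default nucleotide/phosphate residue names recognised as survey ligands.
.default_ligand_resnames <- c("ATP", "ADP", "AMP", "ANP", "AGS", "GTP",
                              "GDP", "GNP", "PO4", "SO4", "P3S")

#' Survey P-loop statistics over a structure set
#'
#' Runs [detect_ploops()] on each model and aggregates the confirmed hits:
#' per-position residue frequencies, per-position ABEGO frequencies, and
#' summary statistics of the orientation cosine.  For models carrying a
#' selected ligand whose phosphorus atoms come within `proximity` angstrom
#' of the conserved-Lys Calpha, distances are recorded from designated
#' motif atoms (the backbone N of every motif residue, the Lys NZ when
#' present, and the last-position Thr/Ser OG1/OG when present) to each
#' ligand phosphorus atom.
#'
#' @param models list of [ploop_structure] objects.
#' @param definition a [motif_definition()].
#' @param ligand_resnames residue names treated as phosphate-bearing
#'   ligands.
#' @param proximity angstrom cut-off from the Lys Calpha for counting a
#'   ligand as bound at the motif (default 10).
#' @param ... passed to [detect_ploops()] (e.g. `torsion_mode`).
#' @return list of class `motif_survey`: `n_structures`, `n_hits`,
#'   `residue_freq` and `abego_freq` (position x symbol matrices whose
#'   columns of observed symbols each sum to 1), `orientation` (mean, sd,
#'   min, max), `distances` (raw records) and `distance_stats` (per
#'   atom-pair mean/sd/n).
#' @export
survey_motifs <- function(models, definition = motif_definition(),
                          ligand_resnames = .default_ligand_resnames,
                          proximity = 10, ...) {
  if (inherits(models, "ploop_structure")) models <- list(models)
  L <- length(definition$slots)
  seq_rows <- list()
  abego_rows <- list()
  ovals <- numeric(0)
  dist_rows <- list()
  n_hits <- 0L
  for (model in models) {
    hits <- detect_ploops(model, definition, ...)
    hits <- hits[hits$confirmed, , drop = FALSE]
    for (h in seq_len(nrow(hits))) {
      n_hits <- n_hits + 1L
      seq_rows[[n_hits]] <- strsplit(hits$matched_sequence[h], "")[[1L]]
      abego_rows[[n_hits]] <- strsplit(hits$abego[h], "")[[1L]]
      ovals <- c(ovals, hits$orientation_value[h])
      d <- .hit_phosphate_distances(model, hits$chain[h],
                                    hits$start_auth[h], definition,
                                    ligand_resnames, proximity)
      if (!is.null(d)) dist_rows[[length(dist_rows) + 1L]] <- d
    }
  }
  if (n_hits == 0L)
    stop("empty survey: no confirmed P-loop hits across ",
         length(models), " structure(s)")
  freq_table <- function(rows) {
    mat <- do.call(rbind, rows)
    syms <- sort(unique(as.vector(mat)))
    f <- matrix(0, L, length(syms), dimnames = list(
      paste0("pos", seq_len(L)), syms))
    for (p in seq_len(L)) {
      tb <- table(mat[, p])
      f[p, names(tb)] <- as.numeric(tb) / nrow(mat)
    }
    f
  }
  distances <- if (length(dist_rows)) do.call(rbind, dist_rows) else
    data.frame(protein_atom = character(0), ligand_atom = character(0),
               distance = numeric(0), stringsAsFactors = FALSE)
  dstats <- NULL
  if (nrow(distances) > 0L) {
    key <- paste(distances$protein_atom, distances$ligand_atom, sep = "\r")
    dstats <- do.call(rbind, lapply(split(distances, key), function(g) {
      data.frame(protein_atom = g$protein_atom[1L],
                 ligand_atom = g$ligand_atom[1L],
                 n = nrow(g), mean = mean(g$distance),
                 sd = if (nrow(g) > 1L) stats::sd(g$distance) else 0,
                 min = min(g$distance), max = max(g$distance),
                 stringsAsFactors = FALSE)
    }))
    rownames(dstats) <- NULL
  }
  structure(list(n_structures = length(models),
                 n_hits = n_hits,
                 residue_freq = freq_table(seq_rows),
                 abego_freq = freq_table(abego_rows),
                 orientation = c(mean = mean(ovals), sd = stats::sd(ovals),
                                 min = min(ovals), max = max(ovals)),
                 distances = distances,
                 distance_stats = dstats),
            class = "motif_survey")
}

#' @export
print.motif_survey <- function(x, ...) {
  cat(sprintf("P-loop survey: %d hit(s) over %d structure(s)\n",
              x$n_hits, x$n_structures))
  modal <- apply(x$abego_freq, 1L, function(r) colnames(x$abego_freq)[
    which.max(r)])
  cat("  modal ABEGO:", paste(modal, collapse = ""), "\n")
  cat(sprintf("  orientation cosine: mean %.3f (sd %.3f)\n",
              x$orientation["mean"], x$orientation["sd"]))
  if (!is.null(x$distance_stats))
    cat("  phosphate distances recorded for",
        nrow(x$distance_stats), "atom pair(s)\n")
  invisible(x)
}

# Distances from designated motif atoms to ligand phosphorus atoms for one
# confirmed hit; NULL when no selected ligand is near the Lys Calpha.
.hit_phosphate_distances <- function(model, chain_id, start_auth,
                                     definition, ligand_resnames,
                                     proximity) {
  L <- length(definition$slots)
  res <- chain_residues(model, chain_id)
  idx <- which(res$resno == start_auth)[1L]
  span <- idx:(idx + L - 1L)
  lys_idx <- if (!is.na(definition$lys_slot))
    idx + definition$lys_slot - 1L else NA_integer_
  anchor <- if (!is.na(lys_idx))
    .get_atom(model, chain_id, res$resno[lys_idx], "CA",
              res$insert[lys_idx])
  else .get_atom(model, chain_id, res$resno[idx], "CA", res$insert[idx])
  if (is.null(anchor)) return(NULL)

  probes <- list()
  for (k in seq_len(L)) {
    p <- .get_atom(model, chain_id, res$resno[span[k]], "N",
                   res$insert[span[k]])
    if (!is.null(p)) probes[[paste0("N_pos", k)]] <- p
  }
  if (!is.na(lys_idx)) {
    p <- .get_atom(model, chain_id, res$resno[lys_idx], "NZ",
                   res$insert[lys_idx])
    if (!is.null(p)) probes[["LYS_NZ"]] <- p
  }
  last_i <- span[L]
  for (og in c("OG1", "OG")) {
    p <- .get_atom(model, chain_id, res$resno[last_i], og,
                   res$insert[last_i])
    if (!is.null(p)) {
      probes[["TS_OG"]] <- p
      break
    }
  }

  lig_atoms <- model$atoms[model$atoms$het &
                           model$atoms$resid %in% ligand_resnames &
                           model$atoms$elesy == "P", , drop = FALSE]
  if (nrow(lig_atoms) == 0L) return(NULL)
  d_anchor <- sqrt((lig_atoms$x - anchor[1L])^2 +
                   (lig_atoms$y - anchor[2L])^2 +
                   (lig_atoms$z - anchor[3L])^2)
  lig_atoms <- lig_atoms[d_anchor <= proximity, , drop = FALSE]
  if (nrow(lig_atoms) == 0L) return(NULL)

  rows <- list()
  for (nm in names(probes)) {
    p <- probes[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      protein_atom = nm,
      ligand_atom = lig_atoms$elety,
      distance = sqrt((lig_atoms$x - p[1L])^2 + (lig_atoms$y - p[2L])^2 +
                      (lig_atoms$z - p[3L])^2),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Derive distance constraints from a survey
#'
#' Converts the survey's phosphate-distance statistics into concrete
#' flat-bottom [distance constraints][evaluate_constraints] for one motif
#' site: target = survey mean, tolerance = `tol_mult` standard deviations
#' (floored at `min_tol`).
#'
#' @param survey a `motif_survey` with distance statistics.
#' @param model the target [ploop_structure] (used to resolve slot-labelled
#'   atoms to author numbering).
#' @param chain_id chain of the motif site.
#' @param start_resno author number of the first motif residue.
#' @param definition the [motif_definition()] the survey used.
#' @param tol_mult tolerance width in survey standard deviations
#'   (default 1).
#' @param min_tol floor on the tolerance, angstrom (default 0.25).
#' @param weight constraint weight (default 1).
#' @return data.frame of constraints (see [evaluate_constraints()]).
#' @export
constraints_from_survey <- function(survey, model, chain_id, start_resno,
                                    definition = motif_definition(),
                                    tol_mult = 1, min_tol = 0.25,
                                    weight = 1) {
  if (is.null(survey$distance_stats))
    stop("survey carries no phosphate-distance statistics")
  res <- chain_residues(model, chain_id)
  idx <- which(res$resno == start_resno)[1L]
  if (is.na(idx)) stop("motif start ", start_resno, " not found in chain ",
                       chain_id)
  L <- length(definition$slots)
  resolve <- function(label) {
    if (grepl("^N_pos", label)) {
      k <- as.integer(sub("^N_pos", "", label))
      c(resno = res$resno[idx + k - 1L], atom = "N")
    } else if (label == "LYS_NZ") {
      c(resno = res$resno[idx + definition$lys_slot - 1L], atom = "NZ")
    } else if (label == "TS_OG") {
      last_i <- idx + L - 1L
      atom <- if (!is.null(.get_atom(model, chain_id, res$resno[last_i],
                                     "OG1", res$insert[last_i])))
        "OG1" else "OG"
      c(resno = res$resno[last_i], atom = atom)
    } else {
      stop("unknown survey atom label '", label, "'")
    }
  }
  st <- survey$distance_stats
  out <- lapply(seq_len(nrow(st)), function(i) {
    r <- resolve(st$protein_atom[i])
    data.frame(chain = chain_id, resno = as.integer(r[["resno"]]),
               atom = r[["atom"]], ligand_atom = st$ligand_atom[i],
               target = st$mean[i],
               tolerance = max(tol_mult * st$sd[i], min_tol),
               weight = weight, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
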