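# Nucleotide placement evaluation: flat-bottom distance constraints between
# P-loop atoms and ligand phosphorus atoms, van-der-Waals clash scoring, a
# seeded constraint-satisfying phosphate-pose sampler, and the final design
# filters (torsion-pattern retention + binding score < -8.0).

# Bondi van-der-Waals radii, angstrom (heavy atoms common in protein/ligand)
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                MG = 1.73, ZN = 1.39, MN = 1.73, FE = 1.63, `NA` = 2.27,
                K = 2.75, CA = 2.31)

#' Construct a ligand pose
#'
#' @param resname ligand residue name (e.g. `"ATP"`, `"ADP"`, `"PO4"`).
#' @param atoms data.frame with `elety`, `elesy`, `x`, `y`, `z`.
#' @param pose_id identifier.
#' @param provenance `"supplied"` or `"sampled(seed)"`.
#' @return Object of class `ligand_pose`.
#' @export
ligand_pose <- function(resname, atoms, pose_id = 1L,
                        provenance = "supplied") {
  stopifnot(is.data.frame(atoms),
            all(c("elety", "elesy", "x", "y", "z") %in% names(atoms)))
  if (!any(atoms$elesy == "P"))
    stop("a ligand pose needs at least one phosphorus atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("pose coordinates must be finite")
  structure(list(resname = resname, atoms = atoms, pose_id = pose_id,
                 provenance = provenance),
            class = "ligand_pose")
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat(sprintf("ligand pose %s (%s, %d atoms, %s)\n", x$pose_id, x$resname,
              nrow(x$atoms), x$provenance))
  invisible(x)
}

.pose_atom <- function(pose, elety) {
  i <- which(pose$atoms$elety == elety)
  if (length(i) == 0L)
    stop("ligand atom '", elety, "' not found in pose ", pose$pose_id)
  as.numeric(pose$atoms[i[1L], c("x", "y", "z")])
}

#' Build a distance-constraint table
#'
#' Flat-bottom distance windows between named protein atoms and ligand
#' phosphate atoms.  The penalty of a measured distance d is
#' `weight * max(0, |d - target| - tolerance)^2`.
#'
#' @param chain,resno,atom protein atom selectors (recycled).
#' @param ligand_atom ligand atom labels (e.g. `"PA"`, `"PB"`, `"PG"`).
#' @param target target distances, angstrom (> 0).
#' @param tolerance half-width of the zero-penalty band, angstrom (>= 0).
#' @param weight non-negative weights (default 1).
#' @return data.frame of constraints.
#' @export
distance_constraints <- function(chain, resno, atom, ligand_atom, target,
                                 tolerance, weight = 1) {
  out <- data.frame(chain = chain, resno = as.integer(resno), atom = atom,
                    ligand_atom = ligand_atom, target = target,
                    tolerance = tolerance, weight = weight,
                    stringsAsFactors = FALSE)
  if (any(out$target <= 0)) stop("constraint targets must be positive")
  if (any(out$tolerance < 0)) stop("constraint tolerances must be >= 0")
  if (any(out$weight < 0)) stop("constraint weights must be >= 0")
  out
}

#' Read / write constraint tables
#'
#' TSV with columns `chain`, `resno`, `atom`, `ligand_atom`, `target`,
#' `tolerance`, `weight`.
#'
#' @param path file path.
#' @return `read_constraints`: a constraint data.frame.
#' @export
read_constraints <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chain", "resno", "atom", "ligand_atom", "target", "tolerance",
            "weight")
  miss <- setdiff(need, names(tb))
  if (length(miss)) stop("constraint file missing columns: ",
                         paste(miss, collapse = ", "))
  distance_constraints(tb$chain, tb$resno, tb$atom, tb$ligand_atom,
                       tb$target, tb$tolerance, tb$weight)
}

#' @rdname read_constraints
#' @param constraints a constraint data.frame.
#' @export
write_constraints <- function(constraints, path) {
  utils::write.table(constraints, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Evaluate a ligand pose against distance constraints
#'
#' Measures the Euclidean distance of every constrained atom pair and
#' applies the flat-bottom quadratic penalty: violation
#' `= max(0, |d - target| - tolerance)`, penalty
#' `= sum(weight * violation^2)`.
#'
#' @param model a [ploop_structure].
#' @param pose a [ligand_pose()].
#' @param constraints constraint data.frame (see
#'   [distance_constraints()]).
#' @return list of class `constraint_report`: `table` (per-constraint
#'   `distance`, `violation`, `satisfied`), `penalty`, `all_satisfied`.
#' @export
evaluate_constraints <- function(model, pose, constraints) {
  n <- nrow(constraints)
  if (n == 0L) stop("empty constraint set")
  dist <- viol <- numeric(n)
  for (i in seq_len(n)) {
    p <- .require_atom(model, constraints$chain[i], constraints$resno[i],
                       constraints$atom[i])
    q <- .pose_atom(pose, constraints$ligand_atom[i])
    dist[i] <- .vnorm(q - p)
    viol[i] <- max(0, abs(dist[i] - constraints$target[i]) -
                     constraints$tolerance[i])
  }
  tab <- cbind(constraints,
               data.frame(distance = dist, violation = viol,
                          satisfied = viol == 0))
  structure(list(table = tab,
                 penalty = sum(constraints$weight * viol^2),
                 all_satisfied = all(viol == 0)),
            class = "constraint_report")
}

#' @export
print.constraint_report <- function(x, ...) {
  cat(sprintf("constraint report: %d/%d satisfied, penalty %.4f\n",
              sum(x$table$satisfied), nrow(x$table), x$penalty))
  invisible(x)
}

# Pairwise clash counting under the scaled vdW overlap rule; strict
# inequality at the boundary.  Plain O(n*m) distance evaluation.
.count_clashes <- function(xyz_a, el_a, xyz_b, el_b, scale = 0.80) {
  ra <- .vdw_radii[el_a]
  rb <- .vdw_radii[el_b]
  if (any(is.na(ra))) stop("no van-der-Waals radius for element(s): ",
                           paste(unique(el_a[is.na(ra)]), collapse = ", "))
  if (any(is.na(rb))) stop("no van-der-Waals radius for element(s): ",
                           paste(unique(el_b[is.na(rb)]), collapse = ", "))
  if (nrow(xyz_a) == 0L || nrow(xyz_b) == 0L)
    return(list(count = 0L, overlap = 0))
  count <- 0L
  overlap <- 0
  for (i in seq_len(nrow(xyz_a))) {
    d <- sqrt((xyz_b[, 1L] - xyz_a[i, 1L])^2 +
              (xyz_b[, 2L] - xyz_a[i, 2L])^2 +
              (xyz_b[, 3L] - xyz_a[i, 3L])^2)
    lim <- scale * (ra[i] + rb)
    hit <- d < lim
    count <- count + sum(hit)
    overlap <- overlap + sum((lim - d)[hit])
  }
  list(count = as.integer(count), overlap = overlap)
}

#' Count protein-ligand steric clashes
#'
#' A clash is a protein-ligand heavy-atom pair closer than
#' `scale * (r_i + r_j)` (strict inequality), with Bondi van-der-Waals
#' radii.  Atoms named in `exclude` (e.g. the constrained Lys/Ser contact
#' set) are left out of the protein side.
#'
#' @param model a [ploop_structure].
#' @param pose a [ligand_pose()].
#' @param scale overlap factor (default 0.80, tolerant of unminimized
#'   geometry).
#' @param exclude optional data.frame with `chain`, `resno`, `atom` naming
#'   protein atoms to skip (a constraint table works directly).
#' @return list with `count` and `overlap` (sum of distance deficits,
#'   angstrom).
#' @export
clash_score <- function(model, pose, scale = 0.80, exclude = NULL) {
  prot <- model$atoms[!model$atoms$het, , drop = FALSE]
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    key <- paste(prot$chain, prot$resno, prot$elety)
    drop <- key %in% paste(exclude$chain, exclude$resno, exclude$atom)
    prot <- prot[!drop, , drop = FALSE]
  }
  .count_clashes(as.matrix(prot[, c("x", "y", "z")]), prot$elesy,
                 as.matrix(pose$atoms[, c("x", "y", "z")]),
                 pose$atoms$elesy, scale = scale)
}

# Rigid phosphate template: bridging-oxygen geometry with P-P ~2.95 A.
# Returned as a data.frame centred on PB.
.phosphate_template <- function(labels = c("PA", "PB", "PG")) {
  coords <- list(PA = c(-2.95, 0, 0),
                 PB = c(0, 0, 0),
                 PG = c(1.60, 2.48, 0))
  missing <- setdiff(labels, names(coords))
  if (length(missing)) stop("no template coordinates for ligand atom(s): ",
                            paste(missing, collapse = ", "))
  do.call(rbind, lapply(labels, function(l) {
    data.frame(elety = l, elesy = "P", x = coords[[l]][1L],
               y = coords[[l]][2L], z = coords[[l]][3L],
               stringsAsFactors = FALSE)
  }))
}

# uniform random rotation matrix from a normalized quaternion
.random_rotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

#' Sample constraint-satisfying phosphate poses
#'
#' Places a rigid di-/tri-phosphate template by seeded random rotation and
#' translation around the constrained site, accepting poses for which every
#' constraint is satisfied, until `n` poses are accepted or the attempt
#' budget is exhausted.  Randomness comes from R's default Mersenne-Twister
#' generator seeded once with `seed`, so results are reproducible across
#' runs and platforms.
#'
#' @param model a [ploop_structure].
#' @param constraints constraint table referencing at least two distinct
#'   ligand phosphorus labels.
#' @param n number of poses requested.
#' @param seed integer RNG seed.
#' @param resname residue name attached to sampled poses (default
#'   `"ATP"`).
#' @param max_attempts attempt budget (default `5000 * n`).
#' @return list of [ligand_pose()] objects (possibly shorter than `n`); a
#'   feasibility warning is raised when no pose could be placed.
#' @export
sample_phosphate_poses <- function(model, constraints, n, seed,
                                   resname = "ATP",
                                   max_attempts = 5000L * n) {
  labels <- unique(constraints$ligand_atom)
  if (length(labels) < 2L)
    stop("constraints must reference at least 2 distinct phosphorus labels")
  template <- .phosphate_template(labels)
  txyz <- as.matrix(template[, c("x", "y", "z")])
  txyz <- sweep(txyz, 2L, colMeans(txyz))
  span <- max(sqrt(rowSums(txyz^2)))

  # protein anchor coordinates resolved once; distances vectorized below
  anchors <- t(vapply(seq_len(nrow(constraints)), function(i)
    .require_atom(model, constraints$chain[i], constraints$resno[i],
                  constraints$atom[i]), numeric(3L)))
  lig_idx <- match(constraints$ligand_atom, template$elety)
  lo <- constraints$target - constraints$tolerance
  hi <- constraints$target + constraints$tolerance

  # proposal: orient the template at random, then translate it so the
  # first constraint's ligand atom lands inside that constraint's distance
  # band around its protein partner (uniform direction, uniform radius in
  # the band); remaining constraints are tested by rejection
  p1 <- anchors[1L, ]
  t1 <- txyz[lig_idx[1L], ]

  set.seed(as.integer(seed))
  poses <- list()
  attempts <- 0L
  while (length(poses) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    R <- .random_rotation()
    rot <- txyz %*% t(R)
    dirv <- stats::rnorm(3L)
    dirv <- dirv / sqrt(sum(dirv^2))
    r1 <- stats::runif(1L, max(lo[1L], 0), hi[1L])
    shift <- p1 + r1 * dirv - rot[lig_idx[1L], ]
    xyz <- rot + matrix(shift, nrow(rot), 3L, byrow = TRUE)
    d <- sqrt(rowSums((xyz[lig_idx, , drop = FALSE] - anchors)^2))
    if (all(d >= lo & d <= hi)) {
      cand <- template
      cand$x <- xyz[, 1L]
      cand$y <- xyz[, 2L]
      cand$z <- xyz[, 3L]
      pose <- ligand_pose(resname, cand,
                          pose_id = length(poses) + 1L,
                          provenance = sprintf("sampled(seed=%d)", seed))
      # contract: every returned pose passes the reference evaluator
      if (evaluate_constraints(model, pose, constraints)$all_satisfied)
        poses[[length(poses) + 1L]] <- pose
    }
  }
  if (length(poses) == 0L)
    warning("constraint set appears infeasible: 0 poses accepted in ",
            attempts, " attempts")
  poses
}

#' Filter design candidates
#'
#' The final selection rule applied to designed structures: discard
#' candidates that lost the conserved P-loop torsion pattern, then keep
#' those whose externally supplied binding score is strictly below the
#' threshold (default -8.0) and whose constraint penalty does not exceed
#' `max_penalty`.  Input order is preserved.
#'
#' @param candidates data.frame with columns `id`, `binding_score`,
#'   `pattern_retained` (logical), and optionally `penalty` (missing
#'   treated as 0).
#' @param score_threshold retain `binding_score < score_threshold`
#'   (strict; default -8.0).
#' @param require_pattern require `pattern_retained` (default TRUE).
#' @param max_penalty maximum allowed constraint penalty (default 0).
#' @return The retained subset of `candidates`, original order.
#' @export
filter_candidates <- function(candidates, score_threshold = -8.0,
                              require_pattern = TRUE, max_penalty = 0) {
  if (nrow(candidates) == 0L) return(candidates)
  if (!all(c("id", "binding_score") %in% names(candidates)))
    stop("candidate table needs 'id' and 'binding_score' columns")
  pen <- if ("penalty" %in% names(candidates)) candidates$penalty else
    rep(0, nrow(candidates))
  pat <- if ("pattern_retained" %in% names(candidates))
    candidates$pattern_retained else rep(TRUE, nrow(candidates))
  keep <- candidates$binding_score < score_threshold & pen <= max_penalty
  if (require_pattern) keep <- keep & pat
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a candidate table
#'
#' TSV with columns `id`, `binding_score` and optionally
#' `pattern_retained`, `penalty`, `model_path`, `pose_path`.  Binding
#' scores are opaque external numbers (e.g. Rosetta ddG values); the
#' package only applies the selection rule to them.
#'
#' @param path file path.
#' @return data.frame of candidates.
#' @export
read_candidates <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "binding_score") %in% names(tb)))
    stop("candidate file needs 'id' and 'binding_score' columns")
  if ("pattern_retained" %in% names(tb))
    tb$pattern_retained <- as.logical(tb$pattern_retained)
  tb
}
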