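## Post-hoc trajectory metrics: Kabsch RMSD, per-atom RMSF, Shrake-Rupley
## SASA with a hydrophobic/hydrophilic split, and geometric hydrogen-bond
## counting.

## Optimal proper rotation (Kabsch) aligning mobile onto ref, both already
## centred. Reflections are removed by flipping the smallest singular
## direction so det(R) = +1.
kabsch_rotation <- function(ref_c, mob_c) {
  H <- t(mob_c) %*% ref_c   # cross-covariance for row-vector coordinates
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

## Superpose mobile coords onto ref coords using the subset for the fit;
## returns the transformed full coordinate set.
superpose_coords <- function(ref, mob, subset = NULL) {
  if (is.null(subset)) subset <- seq_len(nrow(ref))
  cr <- colMeans(ref[subset, , drop = FALSE])
  cm <- colMeans(mob[subset, , drop = FALSE])
  R <- kabsch_rotation(sweep(ref[subset, , drop = FALSE], 2, cr),
                       sweep(mob[subset, , drop = FALSE], 2, cm))
  sweep(sweep(mob, 2, cm) %*% R, 2, cr, `+`)
}

#' Minimal RMSD after optimal superposition (Kabsch)
#'
#' Root-mean-square deviation between two frames minimized over all rigid
#' rotations and translations: centroids are removed and the optimal proper
#' rotation is taken from the SVD of the coordinate cross-covariance, with
#' the reflection case removed by sign-flipping the smallest singular
#' direction.
#'
#' @param ref,mobile [traj_frame()] objects with the same atom count.
#' @param subset Optional atom indices; superposition and RMSD both use the
#'   subset (default all atoms).
#' @return RMSD in nm.
#' @export
kabsch_rmsd <- function(ref, mobile, subset = NULL) {
  stopifnot(inherits(ref, "traj_frame"), inherits(mobile, "traj_frame"))
  if (nrow(ref$coords) != nrow(mobile$coords))
    stop_invalid("frames must have the same atom count")
  if (is.null(subset)) subset <- seq_len(nrow(ref$coords))
  if (length(subset) < 3L)
    stop_invalid("superposition needs at least 3 atoms")
  r <- ref$coords[subset, , drop = FALSE]
  m <- mobile$coords[subset, , drop = FALSE]
  fitted <- superpose_coords(r, m)
  sqrt(mean(rowSums((fitted - r)^2)))
}

#' Per-atom root-mean-square fluctuation
#'
#' Each frame is superposed onto a reference, the time-mean position of each
#' atom is formed, and the RMS deviation of each atom from its mean position
#' is returned. By default the reference is the time-mean structure obtained
#' by two alignment passes (align to the first frame, average, re-align to
#' the average). Set `align = FALSE` for trajectories that are already in a
#' common frame.
#'
#' @param traj A [trajectory()] with at least 2 frames.
#' @param align_to Optional [traj_frame()] reference for the superposition.
#' @param align Superpose frames before averaging (default TRUE).
#' @return Numeric vector of per-atom RMSF in nm.
#' @export
rmsf <- function(traj, align_to = NULL, align = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$frames) < 2L)
    stop_invalid("RMSF needs at least 2 frames")
  coords <- lapply(traj$frames, `[[`, "coords")
  if (align) {
    ref <- if (!is.null(align_to)) align_to$coords else {
      aligned1 <- lapply(coords, superpose_coords, ref = coords[[1]])
      Reduce(`+`, aligned1) / length(aligned1)
    }
    coords <- lapply(coords, superpose_coords, ref = ref)
  }
  mean_pos <- Reduce(`+`, coords) / length(coords)
  dev2 <- lapply(coords, function(co) rowSums((co - mean_pos)^2))
  sqrt(Reduce(`+`, dev2) / length(dev2))
}

## Quasi-uniform unit-sphere points by the golden-section spiral.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Places quasi-uniform test points on each atom's solvent-inflated sphere
#' (radius r_i + probe); a point is accessible when it lies outside every
#' other atom's inflated sphere. Per-atom area is the accessible fraction
#' times 4 pi (r_i + probe)^2; totals are split into hydrophobic and
#' hydrophilic sums using the frame's per-atom flags.
#'
#' @param frame A [traj_frame()] with radii.
#' @param probe_radius Solvent probe radius in nm (default 0.14, water).
#' @param n_points Test points per atom (default 960).
#' @return List with `total`, `hydrophobic`, `hydrophilic` (nm^2) and
#'   `per_atom` (numeric vector, nm^2).
#' @export
sasa <- function(frame, probe_radius = 0.14, n_points = 960) {
  stopifnot(inherits(frame, "traj_frame"))
  if (is.null(frame$radii) || any(!is.finite(frame$radii)))
    stop_invalid("frame must carry finite van der Waals radii")
  co <- frame$coords
  n <- nrow(co)
  rad <- frame$radii + probe_radius
  sph <- fibonacci_sphere(n_points)
  per_atom <- numeric(n)
  ## pairwise distances once, for the neighbour lists
  d2 <- as.matrix(stats::dist(co))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    pts <- sweep(sph * rad[i], 2, co[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (pts[, 1] - co[j, 1])^2 + (pts[, 2] - co[j, 2])^2 +
        (pts[, 3] - co[j, 3])^2
      eps <- 1e-9 * rad[j]^2
      ## strictly inside the neighbour's inflated sphere is buried; points
      ## exactly on the shared boundary are assigned to the lower-indexed
      ## atom so coincident surface is not double-counted
      buried <- dj2 < rad[j]^2 - eps |
        (abs(dj2 - rad[j]^2) <= eps & j < i)
      acc <- acc & !buried
      if (!any(acc)) break
    }
    per_atom[i] <- mean(acc) * 4 * pi * rad[i]^2
  }
  list(total = sum(per_atom),
       hydrophobic = sum(per_atom[frame$is_hydrophobic]),
       hydrophilic = sum(per_atom[!frame$is_hydrophobic]),
       per_atom = per_atom)
}

#' Geometric hydrogen-bond count
#'
#' Counts donor-acceptor pairs satisfying the conventional geometric
#' criterion: donor-acceptor distance at most `dist_cutoff` and
#' hydrogen-donor-acceptor angle at most `angle_cutoff_deg`, for some
#' hydrogen covalently attached to the donor (attachment taken as an H atom
#' within `h_bond_dist` of the donor heavy atom).
#'
#' @param frame A [traj_frame()]; donors/acceptors from its flags, hydrogens
#'   recognized by element "H".
#' @param dist_cutoff Donor-acceptor distance cutoff in nm (default 0.35).
#' @param angle_cutoff_deg H-donor-acceptor angle cutoff in degrees
#'   (default 30).
#' @param h_bond_dist Covalent H-donor attachment distance in nm
#'   (default 0.12).
#' @return Integer count of hydrogen bonds.
#' @export
count_hbonds <- function(frame, dist_cutoff = 0.35, angle_cutoff_deg = 30,
                         h_bond_dist = 0.12) {
  stopifnot(inherits(frame, "traj_frame"))
  co <- frame$coords
  donors <- which(frame$is_donor & frame$elements != "H")
  acceptors <- which(frame$is_acceptor & frame$elements != "H")
  hydrogens <- which(frame$elements == "H")
  if (!length(donors) || !length(acceptors)) {
    warning("no flagged donor/acceptor atoms; returning 0")
    return(0L)
  }
  count <- 0L
  for (d in donors) {
    hs <- hydrogens[sqrt(rowSums((co[hydrogens, , drop = FALSE] -
      matrix(co[d, ], length(hydrogens), 3, byrow = TRUE))^2)) <= h_bond_dist]
    if (!length(hs)) next
    for (a in acceptors) {
      if (a == d) next
      da <- co[a, ] - co[d, ]
      dist_da <- sqrt(sum(da^2))
      if (dist_da > dist_cutoff || dist_da == 0) next
      for (h in hs) {
        dh <- co[h, ] - co[d, ]
        cosang <- sum(dh * da) / (sqrt(sum(dh^2)) * dist_da)
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        if (ang <= angle_cutoff_deg) {
          count <- count + 1L
          break  # one H is enough to count the pair
        }
      }
    }
  }
  count
}
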