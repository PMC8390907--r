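# Protein solvation-shell structure: proximal number densities normalised by
# the distance-r isosurface area (a union-of-spheres SASA at uniform radius,
# not a rolling-probe SASA), a geometric strong-hydrogen-bond census, and
# surface-composition metrics for correlation analyses.

#' Proximal distance to the nearest protein heavy atom
#'
#' Minimum-image distance from each point to the nearest non-hydrogen
#' protein atom.
#'
#' @param points numeric matrix `[n x 3]` (A).
#' @param protein_xyz numeric matrix `[m x 3]` of heavy-atom coordinates.
#' @param box a [box_spec()].
#' @return numeric vector of n distances (A).
#' @export
proximal_distance <- function(points, protein_xyz, box) {
  points <- matrix(points, ncol = 3)
  protein_xyz <- matrix(protein_xyz, ncol = 3)
  if (nrow(protein_xyz) < 1) stop("empty protein selection")
  nearest_atom_distance(points, protein_xyz, box$edge_length)
}

# heavy (non-hydrogen) protein atom indices of a trajectory
.protein_heavy_idx <- function(traj) {
  idx <- which(traj$atoms$role == "protein_heavy" &
                 toupper(trimws(traj$atoms$element)) != "H" &
                 substr(trimws(traj$atoms$name), 1, 1) != "H")
  if (length(idx) == 0) stop("no protein heavy atoms in trajectory")
  idx
}

#' Area of the distance-r isosurface around a set of atoms
#'
#' The surface of points lying exactly `r` from the nearest atom center,
#' i.e. the exposed area of the union of spheres of radius `r` centred on
#' the atoms. Estimated by deterministic sphere-point sampling (Fibonacci
#' spiral; no random seed needed): a sample point on atom i's sphere is
#' exposed when no other atom center lies within `r` of it, and each atom
#' contributes `4 pi r^2` times its exposed fraction.
#'
#' @param protein_xyz numeric matrix `[m x 3]` of atom centers (A).
#' @param r isosurface distance (A), > 0.
#' @param n_sphere_points sample points per atom (default 960).
#' @return area (A^2).
#' @export
sasa_at_distance <- function(protein_xyz, r, n_sphere_points = 960) {
  if (r <= 0) stop("r must be positive")
  protein_xyz <- matrix(protein_xyz, ncol = 3)
  m <- nrow(protein_xyz)
  sphere <- r * .fibonacci_sphere(n_sphere_points)
  if (m == 1) return(4 * pi * r^2)
  total <- 0
  r2 <- r^2 * (1 - 1e-9)  # guard against ties at exactly r
  for (i in seq_len(m)) {
    pts <- sweep(sphere, 2, protein_xyz[i, ], `+`)
    others <- protein_xyz[-i, , drop = FALSE]
    covered <- rep(FALSE, n_sphere_points)
    for (j in seq_len(nrow(others))) {
      d2 <- (pts[, 1] - others[j, 1])^2 + (pts[, 2] - others[j, 2])^2 +
        (pts[, 3] - others[j, 3])^2
      covered <- covered | d2 < r2
      if (all(covered)) break
    }
    total <- total + 4 * pi * r^2 * mean(!covered)
  }
  total
}

#' Proximal number density profile of a solvent species
#'
#' Time-averaged counts of species X in shells `[r, r + dr)` of proximal
#' distance from the protein surface, normalised by `dr` times the
#' time-averaged isosurface area: `rho_X(r) = n_X(r) / (dr * SASA(r))`.
#' Water is measured at its oxygen. Densities are reported in
#' particles/nm^3. For a rigid protein the SASA curve is computed once.
#'
#' @param traj a [sim_trajectory()] containing protein and solvent.
#' @param species solvent species label or role.
#' @param dr shell thickness (A), default 0.05.
#' @param r_max profile range (A); must not exceed half the box edge.
#' @param n_sphere_points SASA sampling density (default 960).
#' @param frames frames to average (default all).
#' @return list of class `proximal_profile`: `r` (shell left edges), `r_mid`,
#'   `n_mean` (mean shell counts), `sasa_A2` (mean SASA at shell midpoints),
#'   `rho_per_nm3`, `dr`, plus per-frame count matrix `counts`.
#' @export
proximal_density <- function(traj, species, dr = 0.05,
                             r_max = traj$box$edge_length / 4,
                             n_sphere_points = 960,
                             frames = seq_len(n_frames(traj))) {
  if (r_max > traj$box$edge_length / 2)
    stop("r_max must not exceed half the box edge")
  prot <- .protein_heavy_idx(traj)
  sel <- select_atoms(traj, species)
  sel <- setdiff(sel, prot)
  nbin <- ceiling(r_max / dr)
  edges <- dr * (0:nbin)
  counts <- matrix(0, length(frames), nbin)
  rigid <- TRUE
  p0 <- traj$coords[prot, , frames[1], drop = FALSE][, , 1, drop = TRUE]
  p0 <- matrix(p0, ncol = 3)
  for (k in seq_along(frames)) {
    f <- frames[k]
    px <- matrix(traj$coords[prot, , f, drop = FALSE][, , 1, drop = TRUE],
                 ncol = 3)
    if (rigid && max(abs(px - p0)) > 1e-9) rigid <- FALSE
    d <- proximal_distance(
      matrix(traj$coords[sel, , f, drop = FALSE][, , 1, drop = TRUE],
             ncol = 3), px, traj$box)
    h <- d[d < r_max]
    counts[k, ] <- tabulate(pmin(floor(h / dr) + 1L, nbin), nbins = nbin)
  }
  mids <- edges[-(nbin + 1)] + dr / 2
  if (rigid) {
    sasa <- vapply(mids, function(rr) sasa_at_distance(p0, rr,
                                                       n_sphere_points),
                   numeric(1))
  } else {
    sasa <- rowMeans(vapply(seq_along(frames), function(k) {
      px <- matrix(traj$coords[prot, , frames[k], drop = FALSE][, , 1,
                                                                drop = TRUE],
                   ncol = 3)
      vapply(mids, function(rr) sasa_at_distance(px, rr, n_sphere_points),
             numeric(1))
    }, numeric(nbin)))
  }
  n_mean <- colMeans(counts)
  structure(list(r = edges[-(nbin + 1)], r_mid = mids, n_mean = n_mean,
                 sasa_A2 = sasa,
                 rho_per_nm3 = per_A3_to_per_nm3(n_mean / (dr * sasa)),
                 dr = dr, species = species, counts = counts,
                 n_frames = length(frames)),
            class = "proximal_profile")
}

#' @export
print.proximal_profile <- function(x, ...) {
  cat(sprintf(
    "proximal density of %s: %d shells of %.3g A, peak %.2f /nm^3 at %.2f A\n",
    x$species, length(x$r), x$dr, max(x$rho_per_nm3),
    x$r_mid[which.max(x$rho_per_nm3)]))
  invisible(x)
}

#' Write a proximal profile as CSV
#' @param profile a `proximal_profile`.
#' @param file path.
#' @export
write_profile_csv <- function(profile, file) {
  utils::write.csv(data.frame(r_A = profile$r_mid, n_mean = profile$n_mean,
                              sasa_A2 = profile$sasa_A2,
                              rho_per_nm3 = profile$rho_per_nm3),
                   file, row.names = FALSE)
  invisible(file)
}

#' Cumulative number of a species within a proximal cutoff
#'
#' Sum of mean shell counts up to `r_cut` (equivalently the integral of
#' `rho * SASA` over distance).
#'
#' @param profile a `proximal_profile`.
#' @param r_cut cutoff (A), within the profile range.
#' @return mean cumulative count.
#' @export
cumulative_number <- function(profile, r_cut) {
  r_maxp <- profile$r[length(profile$r)] + profile$dr
  if (r_cut < 0 || r_cut > r_maxp + 1e-9)
    stop("r_cut outside the profile range")
  sum(profile$n_mean[profile$r + profile$dr <= r_cut + 1e-9])
}

#' Geometric strong-hydrogen-bond criterion
#'
#' A water-donated hydrogen bond is counted when the water-oxygen to
#' acceptor distance is below `max_distance` and the O-H...acceptor angle
#' exceeds `min_angle` (strict inequalities, maximised over the two
#' hydrogens). The angle is measured at the hydrogen by default
#' (`angle_at = "hydrogen"`); `angle_at = "oxygen"` instead requires the
#' angle between the O-H bond vector and the O...A vector to be below
#' `180 - min_angle`.
#'
#' @param max_distance donor-oxygen...acceptor cutoff (A), default 3.0.
#' @param min_angle minimal angle (degrees), default 135.
#' @param acceptor_elements protein acceptor elements (default N and O).
#' @param angle_at `"hydrogen"` (default) or `"oxygen"`.
#' @return list of class `hbond_criterion`.
#' @export
hbond_criterion <- function(max_distance = 3.0, min_angle = 135,
                            acceptor_elements = c("N", "O"),
                            angle_at = c("hydrogen", "oxygen")) {
  if (max_distance <= 0) stop("max_distance must be positive")
  if (min_angle <= 0 || min_angle > 180) stop("min_angle must be in (0, 180]")
  structure(list(max_distance = max_distance, min_angle = min_angle,
                 acceptor_elements = acceptor_elements,
                 angle_at = match.arg(angle_at)), class = "hbond_criterion")
}

#' Count water -> protein strong hydrogen bonds in one frame
#'
#' Every (water, acceptor) pair satisfying the geometric criterion counts
#' once. Acceptors are protein heavy atoms whose element is in the
#' criterion's acceptor set. Distances are minimum-image.
#'
#' @param traj a [sim_trajectory()] with 3-site waters and a protein.
#' @param frame frame index.
#' @param criterion an [hbond_criterion()].
#' @return integer bond count.
#' @export
hbond_census <- function(traj, frame = 1, criterion = hbond_criterion()) {
  at <- traj$atoms
  L <- traj$box$edge_length
  ow <- which(at$role == "water" & at$name == "O")
  if (length(ow) == 0) return(0L)
  h1 <- ow + 1L; h2 <- ow + 2L
  if (any(at$role[c(h1, h2)] != "water"))
    stop("malformed water: O sites must be followed by two H sites")
  acc <- which(at$role == "protein_heavy" &
                 toupper(trimws(at$element)) %in% criterion$acceptor_elements)
  if (length(acc) == 0) return(0L)
  x <- traj$coords[, , frame]
  mi <- function(d) d - L * round(d / L)
  count <- 0L
  cosmin <- cos(criterion$min_angle * pi / 180)
  for (w in seq_along(ow)) {
    o <- x[ow[w], ]
    for (a in acc) {
      dv <- mi(x[a, ] - o)
      dOA <- sqrt(sum(dv^2))
      if (dOA >= criterion$max_distance) next
      ok <- FALSE
      for (hidx in c(h1[w], h2[w])) {
        hpos <- x[hidx, ]
        if (criterion$angle_at == "hydrogen") {
          v1 <- mi(o - hpos); v2 <- mi((o + dv) - hpos)
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          # angle at H > min_angle  <=>  cos(angle) < cos(min_angle)
          if (cosang < cosmin) ok <- TRUE
        } else {
          v1 <- mi(hpos - o); v2 <- dv
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          # O-H vs O..A angle < 180 - min_angle
          if (cosang > cos((180 - criterion$min_angle) * pi / 180)) ok <- TRUE
        }
        if (ok) break
      }
      if (ok) count <- count + 1L
    }
  }
  count
}

#' Surface density of water-protein hydrogen bonds
#'
#' `sigma_HB = mean bond count / mean SASA`, with the SASA evaluated at the
#' first maximum of the hydration layer. Returned in bonds/A^2 with a
#' bonds/nm^2 companion.
#'
#' @param mean_count time-averaged hydrogen-bond count.
#' @param mean_sasa_A2 time-averaged SASA (A^2), > 0.
#' @return list with `per_A2` and `per_nm2`.
#' @export
hbond_surface_density <- function(mean_count, mean_sasa_A2) {
  if (mean_sasa_A2 <= 0) stop("SASA must be positive")
  s <- mean_count / mean_sasa_A2
  list(per_A2 = s, per_nm2 = s * 100)
}

.default_residue_classes <- function() {
  list(acidic = c("ASP", "GLU"),
       basic = c("LYS", "ARG"),
       polar = c("SER", "THR", "ASN", "GLN", "TYR", "CYS", "HIS"),
       apolar = c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP",
                  "GLY"))
}

#' Surface composition metrics of a protein
#'
#' Residue-type counts (acidic / basic / polar / apolar), net charge
#' (acidic -1 e, basic +1 e; histidine counts as basic only when
#' `his_charged`), and per-area densities against the mean SASA.
#'
#' @param residues data.frame with columns `resid` and `resname` (one row
#'   per atom is fine; residues are de-duplicated by `resid`).
#' @param mean_sasa_A2 mean solvent-accessible surface area (A^2), > 0.
#' @param his_charged treat histidine as protonated/basic (default FALSE).
#' @param classes optional classification override, a list like
#'   `.default_residue_classes()`.
#' @return list of class `surface_composition`: counts, `net_charge_e`,
#'   `mean_sasa_A2`, `acidic_per_A2`, `charge_per_A2`.
#' @export
composition_metrics <- function(residues, mean_sasa_A2, his_charged = FALSE,
                                classes = NULL) {
  if (mean_sasa_A2 <= 0) stop("mean SASA must be positive")
  if (is.null(classes)) classes <- .default_residue_classes()
  if (his_charged) {
    classes$basic <- union(classes$basic, "HIS")
    classes$polar <- setdiff(classes$polar, "HIS")
  }
  res <- unique(residues[residues$resid != 0, c("resid", "resname")])
  rn <- toupper(res$resname)
  known <- unlist(classes, use.names = FALSE)
  if (length(rn) && any(!rn %in% known))
    stop("unknown residue name(s): ", toString(unique(rn[!rn %in% known])),
         " (supply a classification override)")
  counts <- vapply(classes, function(cl) sum(rn %in% cl), numeric(1))
  net <- counts[["basic"]] - counts[["acidic"]]
  structure(list(counts = counts, net_charge_e = net,
                 mean_sasa_A2 = mean_sasa_A2,
                 acidic_per_A2 = counts[["acidic"]] / mean_sasa_A2,
                 charge_per_A2 = net / mean_sasa_A2),
            class = "surface_composition")
}

#' Ordinary least-squares correlation between two observables
#'
#' Slope, intercept and Pearson correlation coefficient for, e.g., peak
#' hydration density versus acidic-residue surface density.
#'
#' @param x,y numeric vectors (>= 3 points).
#' @return list with `slope`, `intercept`, `pearson_r`.
#' @export
linear_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 points are required")
  if (stats::sd(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       pearson_r = stats::cor(x, y))
}
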