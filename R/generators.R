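# Synthetic generators. These emulate the inputs of the analysis pipeline --
# electrolyte boxes with known correlation structure, Brownian walks with
# known diffusion coefficients, and scripted toy protein systems -- so every
# estimator can be validated against generator parameters. No energetics:
# the generators test statistics, not physics.

.WATER_OH <- 0.9572          # O-H bond length, A (rigid 3-site geometry)
.WATER_HOH <- 104.52 * pi / 180  # H-O-H angle, rad

# expand a roster into a per-atom table (water -> O, H1, H2)
.atoms_from_roster <- function(roster) {
  rows <- lapply(seq_len(nrow(roster)), function(i) {
    lab <- roster$label[i]; role <- roster$role[i]; n <- roster$count[i]
    if (n == 0L) return(NULL)
    if (role == "water") {
      data.frame(species = lab, role = role,
                 name = rep(c("O", "H1", "H2"), n),
                 element = rep(c("O", "H", "H"), n),
                 resid = rep(seq_len(n), each = 3L),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(species = lab, role = role, name = lab,
                 element = substr(lab, 1, 2), resid = seq_len(n),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

# random unit vectors, n x 3
.unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

# a unit vector orthogonal to each row of u (n x 3)
.orthogonal_unit <- function(u) {
  r <- .unit_vectors(nrow(u))
  w <- r - u * rowSums(r * u)
  n2 <- sqrt(rowSums(w^2))
  bad <- n2 < 1e-8
  if (any(bad)) {  # unlucky parallel draw: fall back to a fixed axis
    r2 <- matrix(rep(c(1, 0, 0), each = sum(bad)), ncol = 3)
    w[bad, ] <- r2 - u[bad, , drop = FALSE] * rowSums(r2 * u[bad, , drop = FALSE])
    n2[bad] <- sqrt(rowSums(w[bad, , drop = FALSE]^2))
  }
  w / n2
}

# rigid-water hydrogen positions for oxygen positions `o` (n x 3), random
# orientation; returns list(h1, h2)
.water_hydrogens <- function(o) {
  n <- nrow(o)
  v1 <- .unit_vectors(n)
  v2 <- .orthogonal_unit(v1)
  h1 <- o + .WATER_OH * v1
  h2 <- o + .WATER_OH * (cos(.WATER_HOH) * v1 + sin(.WATER_HOH) * v2)
  list(h1 = h1, h2 = h2)
}

# fill one frame for a roster: uniform positions for every species, rigid
# randomly oriented waters; returns matrix [n_atoms_expanded x 3]
.uniform_frame <- function(atoms, box) {
  L <- box$edge_length
  x <- matrix(NA_real_, nrow(atoms), 3)
  is_o <- atoms$role == "water" & atoms$name == "O"
  non_w <- atoms$role != "water"
  x[non_w, ] <- matrix(stats::runif(3 * sum(non_w), 0, L), ncol = 3)
  if (any(is_o)) {
    o <- matrix(stats::runif(3 * sum(is_o), 0, L), ncol = 3)
    h <- .water_hydrogens(o)
    x[is_o, ] <- o
    x[which(is_o) + 1L, ] <- h$h1
    x[which(is_o) + 2L, ] <- h$h2
  }
  x
}

#' Ideal (uncorrelated) electrolyte solution generator
#'
#' Places every particle independently and uniformly in the box, frame by
#' frame. All pair radial distribution functions are 1 in expectation, making
#' this the uncorrelated-limit oracle for the Kirkwood-Buff pipeline
#' (activity derivative 1). Waters are rigid 3-site molecules with random
#' orientation.
#'
#' @param roster a [species_roster()].
#' @param box a [box_spec()].
#' @param n_frames number of frames (>= 1).
#' @param seed integer root seed; regeneration is bit-identical.
#' @return a [sim_trajectory()].
#' @export
gen_ideal_solution <- function(roster, box, n_frames, seed) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (box_volume(box) <= 0) stop("box volume must be positive")
  atoms <- .atoms_from_roster(roster)
  if (is.null(atoms)) stop("roster has no particles")
  set.seed(derive_seed(seed, 1L))
  coords <- array(NA_real_, c(nrow(atoms), 3, n_frames))
  for (f in seq_len(n_frames)) coords[, , f] <- .uniform_frame(atoms, box)
  sim_trajectory(coords, atoms, box, timestep = 1, seed = seed, wrapped = TRUE)
}

#' Ion-paired electrolyte solution generator
#'
#' Like [gen_ideal_solution()] but a fraction of cation-anion pairs is placed
#' in contact: the anion sits at a Gaussian-distributed separation
#' (mean `cip_distance`, sd `peak_width`) from its cation, in a random
#' direction. This engineers a contact-ion-pair peak of known position into
#' the cation-anion RDF for validating the Gaussian peak fitter.
#'
#' @inheritParams gen_ideal_solution
#' @param cip_distance mean contact-pair separation (A); must be < L/4.
#' @param paired_fraction fraction of ion pairs placed in contact, between
#'   0 and 1.
#' @param peak_width Gaussian sd of the separation (A).
#' @return a [sim_trajectory()].
#' @export
gen_paired_solution <- function(roster, box, cip_distance, paired_fraction,
                                peak_width, seed, n_frames = 1) {
  if (paired_fraction < 0 || paired_fraction > 1)
    stop("paired_fraction must be in [0, 1]")
  if (cip_distance >= box$edge_length / 4)
    stop("cip_distance must be smaller than a quarter box")
  if (n_frames < 1) stop("n_frames must be >= 1")
  atoms <- .atoms_from_roster(roster)
  set.seed(derive_seed(seed, 1L))
  L <- box$edge_length
  cat_idx <- which(atoms$role == "cation")
  ani_idx <- which(atoms$role == "anion")
  n_pair <- round(paired_fraction * min(length(cat_idx), length(ani_idx)))
  coords <- array(NA_real_, c(nrow(atoms), 3, n_frames))
  for (f in seq_len(n_frames)) {
    x <- .uniform_frame(atoms, box)
    if (n_pair > 0) {
      d <- stats::rnorm(n_pair, cip_distance, peak_width)
      d <- pmax(d, 0.5)  # minimum placement separation
      u <- .unit_vectors(n_pair)
      x[ani_idx[seq_len(n_pair)], ] <-
        wrap_coords(x[cat_idx[seq_len(n_pair)], , drop = FALSE] + d * u, L)
    }
    coords[, , f] <- x
  }
  sim_trajectory(coords, atoms, box, timestep = 1, seed = seed, wrapped = TRUE)
}

#' Brownian (random-walk) trajectory generator
#'
#' Every particle performs an independent Gaussian random walk: each
#' coordinate increment has variance `2 * D * timestep`, so the ensemble MSD
#' at lag tau is exactly `6 * D * tau`. Species-specific (or per-atom)
#' diffusion coefficients are supported; particles are point sites. The
#' continuous (unwrapped) coordinates are stored; wrapped coordinates are
#' available through [get_coords()].
#'
#' @inheritParams gen_ideal_solution
#' @param D_per_species named numeric vector of diffusion coefficients
#'   (A^2/ps) keyed by roster label, or a single value for all species.
#' @param timestep time between frames (ps, > 0).
#' @param n_steps number of steps; the trajectory has `n_steps + 1` frames.
#' @param wrapped logical: default coordinate view of the returned
#'   trajectory. Storage is always the continuous (unwrapped) walk, so both
#'   conventions remain retrievable through [get_coords()]; this flag only
#'   sets the default.
#' @param init optional initial coordinates matrix `[n_atoms x 3]`; default
#'   uniform in the box.
#' @param D_per_atom optional per-atom override (numeric vector, A^2/ps).
#' @return a [sim_trajectory()] storing unwrapped coordinates.
#' @export
gen_brownian <- function(roster, box, D_per_species, timestep, n_steps, seed,
                         wrapped = FALSE, init = NULL, D_per_atom = NULL) {
  if (any(D_per_species < 0)) stop("diffusion coefficients must be >= 0")
  if (timestep <= 0) stop("timestep must be > 0")
  if (n_steps < 1) stop("n_steps must be >= 1")
  roster_pts <- roster
  roster_pts$role[roster_pts$role == "water"] <- "water"
  atoms <- do.call(rbind, lapply(seq_len(nrow(roster_pts)), function(i) {
    n <- roster_pts$count[i]
    if (n == 0L) return(NULL)
    data.frame(species = roster_pts$label[i], role = roster_pts$role[i],
               name = if (roster_pts$role[i] == "water") "O" else
                 roster_pts$label[i],
               element = "X", resid = seq_len(n), stringsAsFactors = FALSE)
  }))
  n <- nrow(atoms)
  if (is.null(D_per_atom)) {
    if (length(D_per_species) == 1L && is.null(names(D_per_species)))
      D_per_atom <- rep(as.numeric(D_per_species), n)
    else {
      miss <- setdiff(unique(atoms$species), names(D_per_species))
      if (length(miss)) stop("no diffusion coefficient for: ", toString(miss))
      D_per_atom <- as.numeric(D_per_species[atoms$species])
    }
  }
  if (any(D_per_atom < 0)) stop("diffusion coefficients must be >= 0")
  set.seed(derive_seed(seed, 1L))
  L <- box$edge_length
  if (is.null(init)) init <- matrix(stats::runif(3 * n, 0, L), n, 3)
  sdev <- sqrt(2 * D_per_atom * timestep)
  coords <- array(NA_real_, c(n, 3, n_steps + 1L))
  coords[, , 1] <- init
  x <- init
  for (s in seq_len(n_steps)) {
    x <- x + matrix(stats::rnorm(3 * n, 0, sdev), n, 3)  # sd recycled per atom
    coords[, , s + 1L] <- x
  }
  tr <- sim_trajectory(coords, atoms, box, timestep = timestep, seed = seed,
                       wrapped = FALSE)
  # storage is always the continuous walk; `wrapped` only selects the default
  # view handed out by get_coords()/msd()
  tr$view_wrapped <- wrapped
  tr
}

# evenly spaced unit directions (Fibonacci sphere), n x 3, deterministic
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# place one water so that its O sits `dist` from acceptor `a` along `u`, with
# the O-H...A angle at the hydrogen equal to `angle_deg`
.scripted_water <- function(a, u, dist, angle_deg) {
  o <- a + dist * u
  v <- -u                               # unit vector O -> A
  w <- .orthogonal_unit(matrix(v, 1, 3))[1, ]
  th <- angle_deg * pi / 180
  sb <- .WATER_OH * sin(th) / dist      # law of sines: angle at acceptor
  if (abs(sb) > 1) stop("unreachable H-bond geometry (angle/distance)")
  beta <- asin(sb)
  gamma <- pi - th - beta               # angle at O between O->A and O->H
  h1 <- o + .WATER_OH * (cos(gamma) * v + sin(gamma) * w)
  h2 <- o + .WATER_OH * (cos(gamma + .WATER_HOH) * v +
                           sin(gamma + .WATER_HOH) * w)
  rbind(o, h1, h2)
}

#' Toy protein system with scripted solvation geometry
#'
#' Builds a rigid pseudo-protein -- a central carbon plus `n_sites`
#' carboxylate-like residues (C, two O, one N acceptor each) on radial arms
#' -- and places waters and ions at exactly the scripted distances and
#' angles from the site anchor oxygens. Scripted cations define the contact
#' table (`r_cryst` = scripted distance). Over multiple frames scripted ions
#' are re-oriented within a cone about the outward site normal (optionally
#' with Gaussian distance noise) while waters stay fixed, so site-resolved
#' RDFs concentrate at the scripted distances.
#'
#' @param geometry_spec data.frame with columns `species` ("water", "cation"
#'   or "anion"), `site` (site index, 1-based), `distance` (A, from the site
#'   anchor oxygen) and `angle` (degrees; O-H...acceptor angle for water,
#'   ignored for ions). May have zero rows (bare protein).
#' @param seed integer root seed.
#' @param n_sites number of carboxylate sites (default 5).
#' @param site_resnames residue names for the sites (default all "ASP").
#' @param n_frames frames in the returned trajectory (default 1).
#' @param box a [box_spec()] (default 60 A).
#' @param placement_noise Gaussian sd (A) added to scripted ion distances per
#'   frame (default 0: zero placement noise).
#' @param cone_deg half-angle (degrees) of the re-orientation cone for
#'   scripted ions across frames (default 25).
#' @return list with `structure` (single-frame [sim_trajectory()] of the bare
#'   protein), `trajectory` (protein + scripted solvent over `n_frames`) and
#'   `contact_table` (a [contact_site_table()], one row per scripted cation).
#' @export
gen_toy_protein_system <- function(geometry_spec, seed, n_sites = 5,
                                   site_resnames = rep("ASP", n_sites),
                                   n_frames = 1, box = box_spec(60),
                                   placement_noise = 0, cone_deg = 25) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  set.seed(derive_seed(seed, 1L))
  ctr <- rep(box$edge_length / 2, 3)
  u <- .fibonacci_sphere(n_sites)
  prot_xyz <- rbind(ctr)                 # central CA
  prot_tab <- data.frame(species = "protein", role = "protein_heavy",
                         name = "CA", element = "C", resid = 0L,
                         resname = "GLY", stringsAsFactors = FALSE)
  anchor_idx <- integer(n_sites)
  for (k in seq_len(n_sites)) {
    cpos <- ctr + 4.0 * u[k, ]
    w <- .orthogonal_unit(u[k, , drop = FALSE])[1, ]
    o1 <- cpos + 1.25 * u[k, ]
    o2 <- cpos + 1.25 * (cos(2) * u[k, ] + sin(2) * w)
    npos <- ctr + 2.5 * u[k, ]
    prot_xyz <- rbind(prot_xyz, cpos, o1, o2, npos)
    prot_tab <- rbind(prot_tab, data.frame(
      species = "protein", role = "protein_heavy",
      name = c("CG", "OD1", "OD2", "N"), element = c("C", "O", "O", "N"),
      resid = k, resname = site_resnames[k], stringsAsFactors = FALSE))
    anchor_idx[k] <- nrow(prot_xyz) - 2L  # OD1
  }
  gs <- geometry_spec
  if (is.null(gs) || nrow(gs) == 0L)
    gs <- data.frame(species = character(), site = integer(),
                     distance = numeric(), angle = numeric())
  if (any(gs$site < 1 | gs$site > n_sites))
    stop("geometry entries reference undefined sites")

  solv_tab <- NULL; solv_static <- NULL
  ion_rows <- which(gs$species %in% c("cation", "anion"))
  wat_rows <- which(gs$species == "water")
  resc <- 0L
  for (i in wat_rows) {
    resc <- resc + 1L
    xyz <- .scripted_water(prot_xyz[anchor_idx[gs$site[i]], ],
                           u[gs$site[i], ], gs$distance[i], gs$angle[i])
    solv_static <- rbind(solv_static, xyz)
    solv_tab <- rbind(solv_tab, data.frame(
      species = "water", role = "water", name = c("O", "H1", "H2"),
      element = c("O", "H", "H"), resid = resc, resname = "WAT",
      stringsAsFactors = FALSE))
  }
  for (i in ion_rows) {
    resc <- resc + 1L
    solv_static <- rbind(solv_static,
                         prot_xyz[anchor_idx[gs$site[i]], ] +
                           gs$distance[i] * u[gs$site[i], ])
    lab <- if (gs$species[i] == "cation") "K" else "CL"
    solv_tab <- rbind(solv_tab, data.frame(
      species = lab, role = gs$species[i], name = lab,
      element = lab, resid = resc, resname = lab, stringsAsFactors = FALSE))
  }
  atoms <- rbind(prot_tab, solv_tab)
  n_at <- nrow(atoms)
  np <- nrow(prot_xyz)
  coords <- array(NA_real_, c(n_at, 3, n_frames))
  cone <- cone_deg * pi / 180
  # map solvent-table row -> geometry row for per-frame ion redirection
  ion_atom_idx <- np + length(wat_rows) * 3L + seq_along(ion_rows)
  for (f in seq_len(n_frames)) {
    x <- rbind(prot_xyz, solv_static)
    for (j in seq_along(ion_rows)) {
      i <- ion_rows[j]
      d <- gs$distance[i] +
        if (placement_noise > 0) stats::rnorm(1, 0, placement_noise) else 0
      # direction in a cone around the outward normal of the site
      ax <- u[gs$site[i], ]
      w <- .orthogonal_unit(matrix(ax, 1, 3))[1, ]
      w2 <- c(ax[2] * w[3] - ax[3] * w[2], ax[3] * w[1] - ax[1] * w[3],
              ax[1] * w[2] - ax[2] * w[1])
      a_ang <- stats::runif(1, 0, cone); b_ang <- stats::runif(1, 0, 2 * pi)
      dir <- cos(a_ang) * ax + sin(a_ang) * (cos(b_ang) * w + sin(b_ang) * w2)
      x[ion_atom_idx[j], ] <- prot_xyz[anchor_idx[gs$site[i]], ] + d * dir
    }
    # clash guard on placed solvent
    if (n_at > np) {
      dmin <- min_pair_distance(x, box$edge_length)
      if (dmin < 0.5)
        stop(sprintf("clashing placements: minimum separation %.3f A", dmin))
    }
    coords[, , f] <- x
  }
  traj <- sim_trajectory(coords, atoms, box, timestep = 1, seed = seed,
                         wrapped = TRUE)
  structure_traj <- sim_trajectory(array(prot_xyz, c(np, 3, 1)), prot_tab,
                                   box, timestep = 1, seed = seed,
                                   wrapped = TRUE)
  cat_rows <- ion_rows[gs$species[ion_rows] == "cation"]
  ct <- if (length(cat_rows))
    contact_site_table(site_id = gs$site[cat_rows],
                       resnum = gs$site[cat_rows],
                       resname = site_resnames[gs$site[cat_rows]],
                       atom = "OD1", r_cryst_A = gs$distance[cat_rows])
  else contact_site_table(integer(), integer(), character(), character(),
                          numeric())
  list(structure = structure_traj, trajectory = traj, contact_table = ct)
}
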