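# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles are deliberately naive (plain R loops, direct formulas)
# so they share no code path with the implementation they check.

# O(N^2) minimum-image pair-distance histogram
brute_pair_histogram <- function(xa, xb, L, bw, rmax, same) {
  nbin <- ceiling(rmax / bw)
  h <- numeric(nbin)
  for (i in seq_len(nrow(xa))) {
    jseq <- if (same) seq_len(nrow(xb))[-seq_len(i)] else seq_len(nrow(xb))
    for (j in jseq) {
      d <- xa[i, ] - xb[j, ]
      d <- d - L * round(d / L)
      r <- sqrt(sum(d^2))
      if (r < rmax) h[floor(r / bw) + 1] <- h[floor(r / bw) + 1] + 1
    }
  }
  h
}

# direct geometric hydrogen-bond check for one water (o, h1, h2) and one
# acceptor a; strict inequalities, angle at the hydrogen
brute_hbond <- function(o, h1, h2, a, max_dist = 3.0, min_angle = 135) {
  if (sqrt(sum((o - a)^2)) >= max_dist) return(FALSE)
  ang <- function(h) {
    v1 <- o - h; v2 <- a - h
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  }
  max(ang(h1), ang(h2)) > min_angle
}

# hand-built single-frame trajectory from explicit coordinates
make_traj <- function(xyz, atoms, L = 60, n_frames = 1) {
  coords <- array(rep(as.numeric(t(xyz)), n_frames) * 0, c(nrow(xyz), 3, n_frames))
  for (f in seq_len(n_frames)) coords[, , f] <- xyz
  sim_trajectory(coords, atoms, box_spec(L))
}

ion_roster <- function(n = 100) {
  species_roster(c("K", "ACE"), c(n, n), c("cation", "anion"))
}

# protein + uniform-solvent merged trajectory (for proximal-density tests)
merge_protein_solvent <- function(protein_traj, solvent_traj) {
  np <- n_atoms(protein_traj)
  nf <- n_frames(solvent_traj)
  pc <- protein_traj$coords[, , 1]
  coords <- array(NA_real_, c(np + n_atoms(solvent_traj), 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- rbind(pc, solvent_traj$coords[, , f])
  at_s <- solvent_traj$atoms
  if (is.null(at_s$resname)) at_s$resname <- toupper(substr(at_s$species, 1, 3))
  at_p <- protein_traj$atoms
  if (is.null(at_p$resname)) at_p$resname <- "GLY"
  sim_trajectory(coords, rbind(at_p, at_s), solvent_traj$box)
}
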