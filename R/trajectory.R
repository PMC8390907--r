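#' Synthetic trajectory container
#'
#' Ordered frames of particle coordinates in a cubic periodic box. Coordinates
#' are stored as generated (unwrapped for Brownian walks, in-box for i.i.d.
#' placements); [get_coords()] wraps on demand so both conventions are always
#' retrievable.
#'
#' @param coords numeric array `[n_atoms, 3, n_frames]` in Angstrom.
#' @param atoms data.frame with one row per atom: columns `species` (roster
#'   label), `role`, `name` (atom name, e.g. "O", "H1"), `element`, `resid`.
#' @param box a [box_spec()].
#' @param timestep frame spacing in ps.
#' @param seed integer root seed used to generate the trajectory (metadata).
#' @param wrapped logical; whether the *stored* coordinates are guaranteed
#'   in-box.
#' @return an object of class `sim_trajectory`.
#' @export
sim_trajectory <- function(coords, atoms, box, timestep = 1, seed = NA_integer_,
                           wrapped = TRUE) {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[3] < 1L) stop("a trajectory needs at least one frame")
  if (nrow(atoms) != dim(coords)[1]) stop("atoms table does not match coords")
  structure(list(coords = coords, atoms = atoms, box = box,
                 timestep = timestep, seed = seed, wrapped = wrapped),
            class = "sim_trajectory")
}

#' @rdname sim_trajectory
#' @param traj a `sim_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname sim_trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Wrap coordinates into the primary cell [0, L)
#'
#' @param x numeric vector/matrix/array of coordinates (Angstrom).
#' @param edge_length box edge (Angstrom).
#' @return wrapped coordinates, same shape as `x`.
#' @export
wrap_coords <- function(x, edge_length) x - edge_length * floor(x / edge_length)

#' Extract coordinates from a trajectory
#'
#' @param traj a [sim_trajectory()].
#' @param frames frame indices (default all).
#' @param atoms atom indices (default all).
#' @param wrapped return in-box coordinates (`TRUE`) or the stored, possibly
#'   unwrapped, coordinates (`FALSE`). Requesting unwrapped coordinates from
#'   a trajectory stored wrapped returns the stored coordinates (they are the
#'   only record).
#' @return array `[length(atoms), 3, length(frames)]`.
#' @export
get_coords <- function(traj, frames = seq_len(n_frames(traj)),
                       atoms = seq_len(n_atoms(traj)),
                       wrapped = isTRUE(traj$view_wrapped) || traj$wrapped) {
  x <- traj$coords[atoms, , frames, drop = FALSE]
  if (wrapped && !traj$wrapped) x <- wrap_coords(x, traj$box$edge_length)
  x
}

#' Select atom indices by species label
#'
#' Water molecules are represented by three sites (O, H1, H2); analyses that
#' measure water positions use the oxygen, which `site = "position"` returns.
#'
#' @param traj a [sim_trajectory()].
#' @param species species label (roster label) or role name.
#' @param site `"position"` (default; oxygen site for water, all sites
#'   otherwise) or `"all"`.
#' @return integer atom indices.
#' @export
select_atoms <- function(traj, species, site = c("position", "all")) {
  site <- match.arg(site)
  a <- traj$atoms
  idx <- which(a$species == species | a$role == species)
  if (length(idx) == 0L) stop("no atoms match species '", species, "'")
  if (site == "position")
    idx <- idx[a$role[idx] != "water" | a$name[idx] == "O"]
  idx
}

#' @export
print.sim_trajectory <- function(x, ...) {
  cat(sprintf(
    "sim_trajectory: %d atoms x %d frames, dt = %g ps, L = %.2f A, %s\n",
    n_atoms(x), n_frames(x), x$timestep, x$box$edge_length,
    if (x$wrapped) "wrapped" else "unwrapped"))
  tab <- table(x$atoms$species)
  cat("  species:", paste(sprintf("%s(%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Derive a deterministic child seed from a root seed
#'
#' All generators consume one root seed and derive an independent child seed
#' per random stream (e.g. per replica) through a fixed affine map, so
#' replicated runs mirror independent production simulations while remaining
#' bit-reproducible.
#'
#' @param seed integer root seed.
#' @param stream integer stream index (>= 1).
#' @return integer child seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stream = 1L) {
  as.integer((abs(as.numeric(seed)) * 48271 + 7919 * as.numeric(stream)) %%
               2147483629)
}
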