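# Solvation-shell translational dynamics: first-shell tagging at t = 0,
# mean-square displacements with sliding time origins, and diffusion
# coefficients from the MSD(tau) = 6 D tau + C fit over a 20-30 ps window.

#' Tag the first-shell subpopulation at the first frame
#'
#' Members of `species` whose proximal distance to the protein surface at
#' the first analysed frame is at most `cutoff` are tagged; membership is
#' fixed thereafter (no re-tagging, no survival filter), so later excursions
#' out of the shell do not change the population.
#'
#' @param traj a [sim_trajectory()] containing the protein and the species.
#' @param species species label or role.
#' @param cutoff first-shell cutoff (A), > 0; 4.5 A is the default first
#'   hydration shell.
#' @param frame the tagging frame (default 1).
#' @return integer atom indices of the tagged members (possibly empty).
#' @export
tag_first_shell <- function(traj, species, cutoff = 4.5, frame = 1) {
  if (cutoff <= 0) stop("cutoff must be positive")
  prot <- .protein_heavy_idx(traj)
  sel <- setdiff(select_atoms(traj, species), prot)
  x <- matrix(traj$coords[sel, , frame, drop = FALSE][, , 1, drop = TRUE],
              ncol = 3)
  px <- matrix(traj$coords[prot, , frame, drop = FALSE][, , 1, drop = TRUE],
               ncol = 3)
  d <- proximal_distance(x, px, traj$box)
  sel[d <= cutoff]
}

#' Mean-square displacement of a tagged subpopulation
#'
#' `MSD(tau) = < (x(t + tau) - x(t))^2 >`, averaged over every sliding time
#' origin and over the tagged atoms. `use_wrapped = TRUE` uses in-cell
#' coordinates verbatim (the short-time convention for shell populations;
#' curves then saturate near `3 (L/2)^2` at long lags because of
#' confinement to the cell). `use_wrapped = FALSE` uses the continuous
#' coordinates.
#'
#' @param traj a [sim_trajectory()].
#' @param tagged integer atom indices (non-empty).
#' @param max_lag largest lag time (ps); must be below the trajectory span.
#' @param use_wrapped wrapped-coordinate convention (default the
#'   trajectory's own flag).
#' @param lag_stride compute every `lag_stride`-th frame lag (default 1).
#' @return list of class `msd_curve`: `tau` (ps), `msd` (A^2), `n_tagged`,
#'   `wrapped`, `timestep`.
#' @export
msd <- function(traj, tagged, max_lag,
                use_wrapped = isTRUE(traj$view_wrapped) || traj$wrapped,
                lag_stride = 1L) {
  if (length(tagged) == 0) stop("empty tagged set")
  nf <- n_frames(traj)
  if (nf < 2) stop("at least two frames are required")
  max_lag_frames <- floor(max_lag / traj$timestep + 1e-9)
  if (max_lag_frames >= nf)
    stop("max_lag exceeds the trajectory span")
  x <- get_coords(traj, atoms = tagged, wrapped = use_wrapped)
  lags <- unique(c(0L, seq.int(lag_stride, max_lag_frames, by = lag_stride)))
  vals <- msd_at_lags(as.numeric(x), length(tagged), nf, as.integer(lags))
  structure(list(tau = lags * traj$timestep, msd = vals,
                 n_tagged = length(tagged), wrapped = use_wrapped,
                 timestep = traj$timestep), class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve: %d lags to %.2f ps, %d atoms, %s coordinates\n",
              length(x$tau), max(x$tau), x$n_tagged,
              if (x$wrapped) "wrapped" else "unwrapped"))
  invisible(x)
}

#' Write an MSD curve as CSV
#' @param curve an `msd_curve`.
#' @param file path.
#' @export
write_msd_csv <- function(curve, file) {
  utils::write.csv(data.frame(tau_ps = curve$tau, msd_A2 = curve$msd), file,
                   row.names = FALSE)
  invisible(file)
}

#' Diffusion coefficient from the linear MSD window
#'
#' Ordinary least squares of `MSD` on `tau` restricted to `window`
#' (default 20-30 ps, where the dynamics is diffusive but confinement is
#' still marginal): `D = slope / 6`, `C = intercept` (the constant absorbs
#' non-diffusive short-time motion).
#'
#' @param curve an `msd_curve`.
#' @param window fit window `c(lo, hi)` in ps.
#' @return list of class `diffusion_fit`: `D` (A^2/ps), `D_1e5cm2s`, `C`
#'   (A^2), `window`, `residual_norm`, `n_points`.
#' @export
fit_diffusion <- function(curve, window = c(20, 30)) {
  sel <- curve$tau >= window[1] - 1e-9 & curve$tau <= window[2] + 1e-9
  if (sum(sel) < 3) stop("fewer than 3 MSD points in the fit window")
  fit <- stats::lm(msd ~ tau, data = data.frame(tau = curve$tau[sel],
                                                msd = curve$msd[sel]))
  D <- unname(coef(fit)[2]) / 6
  structure(list(D = D, D_1e5cm2s = A2ps_to_1e5cm2s(D),
                 C = unname(coef(fit)[1]), window = window,
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 n_points = sum(sel)), class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("D = %.4g A^2/ps (%.4g x 1e-5 cm^2/s), C = %.3g A^2, window %g-%g ps\n",
              x$D, x$D_1e5cm2s, x$C, x$window[1], x$window[2]))
  invisible(x)
}

#' First-shell versus bulk diffusion report
#'
#' For each requested species and each replica trajectory: the diffusion
#' coefficient of the subpopulation tagged in the first shell at t = 0
#' (unwrapped fit, with the wrapped-convention value reported alongside) and
#' of the full population (unwrapped), with the shell/bulk ratio. Replica
#' means and standard errors are attached when two or more replicas are
#' supplied.
#'
#' @param replicas list of [sim_trajectory()] objects.
#' @param species character vector of species labels.
#' @param cutoff first-shell cutoff (A), default 4.5.
#' @param window fit window (ps), default c(20, 30).
#' @param max_lag largest MSD lag (ps), default `window[2]`.
#' @param lag_stride lag stride in frames (default 1).
#' @return data.frame with one row per species x replica plus attribute
#'   `summary` (replica means and SEMs per species).
#' @export
shell_vs_bulk_report <- function(replicas, species, cutoff = 4.5,
                                 window = c(20, 30), max_lag = window[2],
                                 lag_stride = 1L) {
  rows <- list()
  for (k in seq_along(replicas)) {
    tr <- replicas[[k]]
    for (sp in species) {
      tagged <- tag_first_shell(tr, sp, cutoff)
      if (length(tagged) == 0) stop("no ", sp, " in the first shell")
      all_idx <- setdiff(select_atoms(tr, sp), .protein_heavy_idx(tr))
      d_shell <- fit_diffusion(msd(tr, tagged, max_lag, use_wrapped = FALSE,
                                   lag_stride = lag_stride), window)$D
      d_shell_w <- fit_diffusion(msd(tr, tagged, max_lag, use_wrapped = TRUE,
                                     lag_stride = lag_stride), window)$D
      d_bulk <- fit_diffusion(msd(tr, all_idx, max_lag, use_wrapped = FALSE,
                                  lag_stride = lag_stride), window)$D
      rows[[length(rows) + 1L]] <- data.frame(
        replica = k, species = sp, n_shell = length(tagged),
        D_shell = d_shell, D_shell_wrapped = d_shell_w, D_bulk = d_bulk,
        ratio = d_shell / d_bulk, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(out, out$species), function(d) {
    nrep <- nrow(d)
    data.frame(species = d$species[1],
               D_shell = mean(d$D_shell), D_bulk = mean(d$D_bulk),
               ratio = mean(d$ratio),
               sem_D_shell = if (nrep >= 2) sd(d$D_shell) / sqrt(nrep) else
                 NA_real_,
               sem_ratio = if (nrep >= 2) sd(d$ratio) / sqrt(nrep) else
                 NA_real_, stringsAsFactors = FALSE)
  }))
  attr(out, "summary") <- summ
  out
}
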