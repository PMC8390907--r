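# Kirkwood-Buff analysis for closed (canonical) simulation boxes. The
# integral uses the finite-size kernel
#   G_ij(R) = int_0^{2R} [f_ij g_ij(r) - 1] 4 pi r^2 (1 - 3x/2 + x^3/2) dr,
# x = r/(2R), with R a quarter of the box edge by default, and a
# multiplicative tail factor f_ij that repairs the closed-system RDF tail
# (which does not converge to 1; the deviation is of order 1/N).

#' Tail correction factor for a closed-system RDF
#'
#' `f = 1 / mean(g)` over the final `window` fraction of the range `[0, 2R]`.
#' In a closed box the RDF tail sits at `1 +- O(1/N)` rather than 1; a
#' multiplicative factor restores the open-system normalisation.
#'
#' @param rdf an `rdf` object extending to at least `2R`.
#' @param R truncation radius (A); default a quarter of the box edge.
#' @param window fraction of `[0, 2R]` averaged for the tail (default 0.2).
#' @return scalar tail factor `f_ij`.
#' @export
tail_correction <- function(rdf, R = rdf$box_edge / 4, window = 0.2) {
  if (!is.finite(R) || R <= 0) stop("R must be positive")
  if (window <= 0 || window > 1) stop("window must be in (0, 1]")
  sel <- rdf$r >= 2 * R * (1 - window) & rdf$r <= 2 * R
  if (!any(sel)) stop("tail window is empty")
  m <- mean(rdf$g[sel])
  if (m <= 0) stop("tail of g is non-positive; cannot form a tail factor")
  1 / m
}

#' Finite-size-corrected Kirkwood-Buff integral
#'
#' Trapezoidal quadrature of `[f g(r) - 1] 4 pi r^2 (1 - 3x/2 + x^3/2)` on
#' the RDF bin grid over `[0, 2R]`, `x = r/(2R)`. The kernel weight equals 1
#' at r = 0 and 0 at r = 2R. Reported in A^3 per particle and cm^3/mol.
#'
#' @param rdf an `rdf` object extending to at least `2R`.
#' @param R truncation radius (A); default a quarter of the box edge.
#' @param f tail factor (default computed by [tail_correction()]).
#' @return list of class `kb_integral`: `G_A3`, `G_cm3mol`, `R`, `f`, `pair`.
#' @export
kb_integral <- function(rdf, R = rdf$box_edge / 4, f = tail_correction(rdf, R)) {
  if (!is.finite(R) || R <= 0) stop("R must be positive")
  if (max(rdf$r) + rdf$bin_width / 2 < 2 * R - 1e-9)
    stop("rdf does not extend to 2R")
  sel <- rdf$r <= 2 * R
  r <- rdf$r[sel]
  x <- r / (2 * R)
  integrand <- (f * rdf$g[sel] - 1) * 4 * pi * r^2 * (1 - 1.5 * x + 0.5 * x^3)
  # include the exact endpoints, where the integrand is known to vanish
  # (r = 0: r^2 factor; r = 2R: kernel weight)
  rr <- c(0, r, 2 * R)
  yy <- c(0, integrand, 0)
  G <- sum(diff(rr) * (head(yy, -1) + tail(yy, -1)) / 2)
  structure(list(G_A3 = G, G_cm3mol = A3_to_cm3mol(G), R = R, f = f,
                 pair = rdf$pair), class = "kb_integral")
}

#' @export
print.kb_integral <- function(x, ...) {
  cat(sprintf("G(%s-%s) = %.2f A^3 (%.2f cm^3/mol), R = %.2f A, f = %.5f\n",
              x$pair[1], x$pair[2], x$G_A3, x$G_cm3mol, x$R, x$f))
  invisible(x)
}

#' Cosolvent Kirkwood-Buff integrals of a 1:1 electrolyte
#'
#' Electroneutrality forces the indistinguishable-ion (cosolvent) treatment:
#' `G_cc = (2 G_+- + G_++ + G_--) / 4` and `G_cw = G_+w + G_-w`.
#'
#' @param G_pp,G_mm,G_pm cation-cation, anion-anion and cation-anion
#'   integrals (A^3).
#' @param G_pw,G_mw cation-water and anion-water integrals (A^3).
#' @return list with `G_cc` and `G_cw` (A^3).
#' @export
cosolvent_kb <- function(G_pp, G_mm, G_pm, G_pw, G_mw) {
  list(G_cc = (2 * G_pm + G_pp + G_mm) / 4, G_cw = G_pw + G_mw)
}

#' Cosolvent activity derivative from Kirkwood-Buff integrals
#'
#' `a'_c = 1 / (1 + rho_c (G_cc - G_cw))`. A non-positive denominator has no
#' thermodynamic meaning (it would imply an unstable solution) and raises an
#' error.
#'
#' @param rho_c cosolvent number density (ions per A^3).
#' @param G_cc,G_cw cosolvent integrals (A^3).
#' @return scalar molar activity derivative `a'_c`.
#' @export
activity_derivative_from_kb <- function(rho_c, G_cc, G_cw) {
  den <- 1 + rho_c * (G_cc - G_cw)
  if (den <= 0)
    stop("non-positive denominator in a'_c: thermodynamically invalid input")
  1 / den
}

#' Replica-averaged activity derivative pipeline
#'
#' Runs the full closed-system route on each replica trajectory: RDFs for
#' the +-, ++, -- pairs (and +w, -w when water is present), tail factors,
#' Kirkwood-Buff integrals at `R` (a quarter box by default), the cosolvent
#' combinations and the activity derivative; reports the replica mean and
#' standard error. Without water `G_cw` is 0 (a two-species ionic system).
#'
#' @param replicas list of [sim_trajectory()] replicas (>= 2 for a SEM).
#' @param bin_width RDF bin width (A).
#' @param R truncation radius (A); default box/4.
#' @param tail_window tail-averaging window fraction (default 0.2).
#' @return list of class `activity_result`: `a_prime_c` (mean), `sem`
#'   (NA for a single replica), `per_replica`, `rho_c` and the per-replica
#'   KB integrals.
#' @export
activity_pipeline <- function(replicas, bin_width = 0.05, R = NULL,
                              tail_window = 0.2) {
  if (!is.list(replicas) || length(replicas) < 1)
    stop("replicas must be a non-empty list of trajectories")
  vals <- numeric(length(replicas))
  details <- vector("list", length(replicas))
  for (k in seq_along(replicas)) {
    tr <- replicas[[k]]
    Rk <- if (is.null(R)) tr$box$edge_length / 4 else R
    roles <- tr$atoms$role
    cat_lab <- unique(tr$atoms$species[roles == "cation"])
    ani_lab <- unique(tr$atoms$species[roles == "anion"])
    has_w <- any(roles == "water")
    if (length(cat_lab) != 1 || length(ani_lab) != 1)
      stop("expected exactly one cation and one anion species")
    r_max <- min(2 * Rk, tr$box$edge_length / 2)
    kbi <- function(a, b) {
      rdf <- compute_rdf(tr, a, b, bin_width = bin_width, r_max = r_max)
      kb_integral(rdf, R = Rk, f = tail_correction(rdf, Rk, tail_window))
    }
    g_pm <- kbi(cat_lab, ani_lab)
    g_pp <- kbi(cat_lab, cat_lab)
    g_mm <- kbi(ani_lab, ani_lab)
    if (has_w) {
      w_lab <- unique(tr$atoms$species[roles == "water"])[1]
      g_pw <- kbi(cat_lab, w_lab); g_mw <- kbi(ani_lab, w_lab)
      Gpw <- g_pw$G_A3; Gmw <- g_mw$G_A3
    } else Gpw <- Gmw <- 0
    cs <- cosolvent_kb(g_pp$G_A3, g_mm$G_A3, g_pm$G_A3, Gpw, Gmw)
    n_ions <- sum(tr$atoms$role %in% c("cation", "anion"))
    rho_c <- n_ions / box_volume(tr$box)
    vals[k] <- activity_derivative_from_kb(rho_c, cs$G_cc, cs$G_cw)
    details[[k]] <- list(G_cc = cs$G_cc, G_cw = cs$G_cw, rho_c = rho_c,
                         G_pm = g_pm, G_pp = g_pp, G_mm = g_mm)
  }
  structure(list(
    a_prime_c = mean(vals),
    sem = if (length(vals) >= 2) stats::sd(vals) / sqrt(length(vals)) else
      NA_real_,
    per_replica = vals, rho_c = details[[1]]$rho_c, details = details),
    class = "activity_result")
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf("a'_c = %.4f %s (%d replicas, rho_c = %.4g ions/A^3)\n",
              x$a_prime_c,
              if (is.na(x$sem)) "(SEM not defined)" else
                sprintf("+- %.4f (SEM)", x$sem),
              length(x$per_replica), x$rho_c))
  invisible(x)
}
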