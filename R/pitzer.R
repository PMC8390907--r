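# Pitzer ion-interaction model for a 1:1 electrolyte at 298 K: the
# experimental reference route. Mean molal activity coefficient, its
# analytic molality derivative, and the molal -> molar conversion through a
# solution-density curve.

#' Pitzer ion-interaction parameters for a 1:1 electrolyte
#'
#' @param beta0,beta1 second-virial ion-interaction constants (kg/mol).
#' @param Cphi third-virial constant (kg^2/mol^2).
#' @param Aphi Debye-Hueckel slope (osmotic convention), dimensionless;
#'   0.392 at 298 K.
#' @param alpha exponential range parameter ((kg/mol)^(1/2)), default 2.0.
#' @param b Debye-Hueckel denominator constant ((kg/mol)^(1/2)), default 1.2.
#' @return list of class `pitzer_parameters`.
#' @export
pitzer_parameters <- function(beta0, beta1, Cphi, Aphi, alpha = 2.0, b = 1.2) {
  if (alpha <= 0 || b <= 0) stop("alpha and b must be positive")
  structure(list(beta0 = beta0, beta1 = beta1, Cphi = Cphi, Aphi = Aphi,
                 alpha = alpha, b = b), class = "pitzer_parameters")
}

#' Named Pitzer presets
#'
#' `"KOAc"`: potassium acetate at 298 K, with the standard ion-interaction
#' constants beta0 = 0.1587, beta1 = 0.3251, Cphi = -0.00660 (kg/mol units)
#' and Aphi = 0.392. `"ideal"`: all interaction constants zero (gamma = 1).
#'
#' @param name preset name.
#' @return a [pitzer_parameters()] object.
#' @export
pitzer_preset <- function(name = c("KOAc", "ideal")) {
  name <- match.arg(name)
  switch(name,
    KOAc = pitzer_parameters(beta0 = 0.1587, beta1 = 0.3251,
                             Cphi = -0.00660, Aphi = 0.392),
    ideal = pitzer_parameters(0, 0, 0, 0))
}

#' Mean molal activity coefficient (log) of a 1:1 electrolyte
#'
#' `ln gamma_+- = f_gamma(I) + B_gamma(I) m + (3/2) Cphi m^2` with ionic
#' strength I = m for a 1:1 salt,
#' `f_gamma = -Aphi (sqrt(I)/(1 + b sqrt(I)) + (2/b) ln(1 + b sqrt(I)))` and
#' `B_gamma = 2 beta0 + (2 beta1/(alpha^2 I)) (1 - (1 + alpha sqrt(I) -
#' alpha^2 I / 2) exp(-alpha sqrt(I)))`.
#'
#' @param b_s molality (mol/kg), > 0; vectorised.
#' @param p a [pitzer_parameters()] object.
#' @return `ln gamma_+-` (dimensionless), same length as `b_s`.
#' @export
pitzer_ln_gamma <- function(b_s, p) {
  if (any(b_s <= 0)) stop("molality must be positive")
  m <- b_s; s <- sqrt(m)
  fg <- -p$Aphi * (s / (1 + p$b * s) + (2 / p$b) * log(1 + p$b * s))
  u <- p$alpha * s
  Bg <- 2 * p$beta0 +
    (2 * p$beta1 / (p$alpha^2 * m)) * (1 - (1 + u - u^2 / 2) * exp(-u))
  fg + Bg * m + 1.5 * p$Cphi * m^2
}

# analytic d ln(gamma) / d m for the expression above
.pitzer_dlng_dm <- function(m, p) {
  s <- sqrt(m)
  dfg_ds <- -p$Aphi * (1 / (1 + p$b * s)^2 + 2 / (1 + p$b * s))
  u <- p$alpha * s
  # B_gamma * m = 2 beta0 m + (2 beta1/alpha^2) P(u), P = 1-(1+u-u^2/2)e^-u
  dP_du <- exp(-u) * (2 * u - u^2 / 2)
  dfg_ds / (2 * s) + 2 * p$beta0 +
    (2 * p$beta1 / p$alpha^2) * dP_du * p$alpha / (2 * s) +
    3 * p$Cphi * m
}

#' Molal activity derivative of the salt
#'
#' `a'_s^(b) = d ln a_s^(b) / d ln b_s = 1 + b_s d ln gamma_+-^(b) / d b_s`,
#' equal to 1 for an ideal solution. Differentiation is analytic by default;
#' `method = "fd"` uses central differences on ln b (step `h`), retained as a
#' cross-check (both routes agree to well below 1e-6).
#'
#' @inheritParams pitzer_ln_gamma
#' @param method `"analytic"` (default) or `"fd"`.
#' @param h finite-difference step in ln b (default 1e-4).
#' @return `a'_s^(b)`, same length as `b_s`.
#' @export
molal_activity_derivative <- function(b_s, p, method = c("analytic", "fd"),
                                      h = 1e-4) {
  if (any(b_s <= 0)) stop("molality must be positive")
  method <- match.arg(method)
  if (method == "analytic")
    1 + b_s * .pitzer_dlng_dm(b_s, p)
  else
    1 + (pitzer_ln_gamma(b_s * exp(h), p) -
           pitzer_ln_gamma(b_s * exp(-h), p)) / (2 * h)
}

#' Solution-density curve of an electrolyte
#'
#' Tabulated mass density of the solution versus molality, with the salt
#' molar mass; provides the interpolated salt number density
#' `rho_s(b) = b * rho(b) / (1 + b M / 1000)` (per kg-of-water bookkeeping)
#' needed by the molal -> molar conversion. Interpolation is monotone
#' piecewise-cubic; extrapolation outside the tabulated range is an error.
#'
#' @param b_molkg strictly increasing molality grid (mol/kg).
#' @param density_gcm3 solution mass densities (g/cm^3), > 0.
#' @param molar_mass salt molar mass (g/mol).
#' @return list of class `density_curve` with interpolators `rho(b)`
#'   (solution mass density) and `rho_s(b)` (salt number density, mol/L).
#' @export
density_curve <- function(b_molkg, density_gcm3, molar_mass) {
  if (any(diff(b_molkg) <= 0)) stop("molality grid must be strictly increasing")
  if (any(density_gcm3 <= 0)) stop("densities must be positive")
  rho_fun <- stats::splinefun(b_molkg, density_gcm3, method = "monoH.FC")
  rho_s_tab <- 1000 * b_molkg * density_gcm3 / (1000 + b_molkg * molar_mass)
  if (any(diff(rho_s_tab) <= 0)) stop("salt number density must be monotone")
  rho_s_fun <- stats::splinefun(b_molkg, rho_s_tab, method = "monoH.FC")
  structure(list(b = b_molkg, density = density_gcm3,
                 molar_mass = molar_mass, rho = rho_fun, rho_s = rho_s_fun,
                 range = range(b_molkg)), class = "density_curve")
}

#' @rdname density_curve
#' @param file CSV with columns `b_molkg`, `density_gcm3`.
#' @export
read_density_curve <- function(file, molar_mass) {
  d <- utils::read.csv(file)
  density_curve(d$b_molkg, d$density_gcm3, molar_mass)
}

#' Packaged density curve for aqueous potassium acetate at 25 C
#'
#' Solution mass densities on a molality grid, compiled from standard
#' handbook data via an apparent-molar-volume representation (see the file
#' `koac_density_25C_synthetic.csv` shipped with the package); molar mass
#' 98.142 g/mol. Intended for the molal -> molar conversion of activity
#' derivatives.
#'
#' @return a [density_curve()].
#' @export
koac_density_curve <- function() {
  read_density_curve(system.file("extdata", "koac_density_25C_synthetic.csv",
                                 package = "halosolv", mustWork = TRUE),
                     molar_mass = 98.142)
}

#' Convert a molal activity derivative to the molar scale
#'
#' `a'_s = a'_s^(b) * (d ln b_s / d ln rho_s)` with the log-slope evaluated
#' by central differences on the interpolated salt-number-density curve.
#'
#' @param a_prime_molal molal derivative `a'_s^(b)`.
#' @param b_s molality (mol/kg), inside the density-curve range.
#' @param curve a [density_curve()].
#' @param h relative central-difference step on ln b (default 1e-4).
#' @return molar derivative `a'_s`.
#' @export
molal_to_molar_derivative <- function(a_prime_molal, b_s, curve, h = 1e-4) {
  lo <- b_s * exp(-h); hi <- b_s * exp(h)
  if (any(lo < curve$range[1] - 1e-12) || any(hi > curve$range[2] + 1e-12))
    stop("molality outside the density-curve range (extrapolation forbidden)")
  dlnrho_dlnb <- (log(curve$rho_s(hi)) - log(curve$rho_s(lo))) / (2 * h)
  a_prime_molal / dlnrho_dlnb
}

#' Salt-scale / cosolvent-scale conversions for a 1:1 electrolyte
#'
#' For a 1:1 electrolyte `a_s = 0.5 a_c`; activity *derivatives* and
#' activity *coefficients* are identical on the two scales
#' (`a'_s = a'_c`, `gamma_s,+- = gamma_c`).
#'
#' @param a_prime_salt salt-scale activity derivative.
#' @return the identical cosolvent-scale derivative.
#' @export
salt_to_cosolvent <- function(a_prime_salt) a_prime_salt

#' @rdname salt_to_cosolvent
#' @param a_c cosolvent-scale molar activity.
#' @export
cosolvent_to_salt_activity <- function(a_c) 0.5 * a_c

#' Pitzer reference table for a set of molalities
#'
#' Convenience wrapper producing the experimental-reference quantities at
#' each molality: `gamma_molal`, `a_prime_molal` and (when a density curve is
#' supplied) `a_prime_molar`.
#'
#' @param b_s molalities (mol/kg).
#' @param p a [pitzer_parameters()] (default the potassium acetate preset).
#' @param curve optional [density_curve()] for the molar column.
#' @return data.frame with one row per molality.
#' @export
pitzer_reference_table <- function(b_s, p = pitzer_preset("KOAc"),
                                   curve = NULL) {
  apb <- molal_activity_derivative(b_s, p)
  out <- data.frame(b_s = b_s, gamma_molal = exp(pitzer_ln_gamma(b_s, p)),
                    a_prime_molal = apb)
  out$a_prime_molar <- if (is.null(curve)) NA_real_ else
    molal_to_molar_derivative(apb, b_s, curve)
  out
}
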