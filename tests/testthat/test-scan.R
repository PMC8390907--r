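# LJ pair-parameter machinery: combination rules, scaling, potential,
# peak fitting, site scoring and the selection rule.

test_that("Lorentz-Berthelot rules: identity, arithmetic/geometric means,
           zero eps", {
  same <- lorentz_berthelot(3.0, 3.0, 0.2, 0.2)
  expect_equal(same$Rmin, 3.0); expect_equal(same$eps, 0.2)
  pair <- lorentz_berthelot(3.0, 4.0, 0.1, 0.4)
  expect_equal(pair$Rmin, 3.5); expect_equal(pair$eps, 0.2)
  expect_equal(lorentz_berthelot(3, 4, 0, 0.3)$eps, 0)
})

test_that("Rmin scaling is exact multiplication and reproduces the
           recommended pair value", {
  expect_equal(round(apply_scaling(1.08, 3.3662), 4), 3.6355)
  expect_equal(apply_scaling(1, 3.3662), 3.3662)
  expect_equal(apply_scaling(2, 1.7), 3.4)
  f <- 1.3; r <- 2.9; a <- 2.0
  expect_equal(apply_scaling(a * f, r), a * apply_scaling(f, r))
  expect_equal(apply_scaling(f, a * r), a * apply_scaling(f, r))
})

test_that("pair potential has its minimum -eps at Rmin and vanishes at
           long range", {
  pair <- lj_pair(Rmin = 3.6355, eps = 0.19)
  expect_equal(lj_potential(3.6355, pair), -0.19)
  expect_lt(abs(lj_potential(1e4, pair)), 1e-12)
  # numerical minimum by grid + refine agrees with the closed form
  gr <- seq(2, 6, by = 1e-3)
  v <- lj_potential(gr, pair)
  r0 <- optimize(function(r) lj_potential(r, pair),
                 interval = gr[which.min(v)] + c(-2e-3, 2e-3),
                 tol = 1e-10)$minimum
  expect_equal(r0, 3.6355, tolerance = 1e-6 / 3.6355)
  # Coulomb term adds the expected monovalent attraction
  pc <- lj_pair(3.6355, 0.19, q_i = 1, q_j = -1)
  expect_equal(lj_potential(5, pc, include_coulomb = TRUE) -
                 lj_potential(5, pc), -332.06371 / 5)
  expect_error(lj_potential(0, pair), "positive")
})

test_that("Gaussian peak fit recovers a synthetic peak and is invariant to
           vertical scaling and baseline offsets", {
  r <- seq(0.01, 8, by = 0.02)
  g <- 1 + 5 * exp(-(r - 2.8)^2 / (2 * 0.12^2))
  pf <- fit_first_peak(rdf_from_values(r, g))
  expect_equal(pf$r_sim, 2.8, tolerance = 0.01 / 2.8)
  pf_scaled <- fit_first_peak(rdf_from_values(r, 3.7 * g))
  pf_shift <- fit_first_peak(rdf_from_values(r, g + 0.9))
  expect_equal(pf_scaled$r_sim, pf$r_sim, tolerance = 1e-6)
  expect_equal(pf_shift$r_sim, pf$r_sim, tolerance = 1e-4)
})

test_that("a symmetric triangular peak is fitted at its apex and a flat
           curve has no peak", {
  r <- seq(0.05, 6, by = 0.1)
  apex <- r[25]
  g <- 1 + pmax(0, 1 - abs(r - apex) / 0.5)
  pf <- fit_first_peak(rdf_from_values(r, g))
  expect_equal(pf$r_sim, apex, tolerance = 0.05 / apex)
  expect_error(fit_first_peak(rdf_from_values(r, rep(1, length(r)))),
               "no peak")
})

test_that("site deviation is the unsigned relative error", {
  expect_equal(site_deviation(3.0, 3.0), 0)
  expect_equal(site_deviation(2.7, 3.0), 0.1)
  expect_equal(site_deviation(3.3, 3.0), 0.1)
  expect_error(site_deviation(3.0, -1), "positive")
})

make_candidates <- function() {
  # candidate A: inside the 7% band everywhere, mean deviation 0.04
  # candidate B: smaller deviation but violates the band at c = 2
  # candidate C: inside the band, larger deviation than A
  ref <- c("0.5" = 1.0, "1" = 1.1, "2" = 1.3)
  rows <- list(
    data.frame(f = 1.08, concentration = c(0.5, 1, 2),
               a_prime = c(1.05, 1.14, 1.25),
               r_sim_1 = 2.8 * 1.04, r_sim_2 = 3.0 * 1.04),
    data.frame(f = 1.02, concentration = c(0.5, 1, 2),
               a_prime = c(1.02, 1.12, 1.45),
               r_sim_1 = 2.8 * 1.01, r_sim_2 = 3.0 * 1.01),
    data.frame(f = 1.20, concentration = c(0.5, 1, 2),
               a_prime = c(0.97, 1.07, 1.33),
               r_sim_1 = 2.8 * 1.06, r_sim_2 = 3.0 * 1.06))
  list(cand = do.call(rbind, rows), ref = ref,
       sites = contact_site_table(1:2, 1:2, c("ASP", "GLU"),
                                  c("OD1", "OE1"), c(2.8, 3.0)))
}

test_that("selection enforces the band at every concentration before
           minimising the site deviation (hand-enumerated case)", {
  mc <- make_candidates()
  # hand enumeration: B violates |1.45-1.3|/1.3 = 11.5% > 7% at c = 2;
  # survivors A (dev 0.04) and C (dev 0.06) -> A
  sel <- select_optimal(mc$cand, mc$ref, mc$sites, band = 0.07)
  expect_equal(sel$f, 1.08)
  expect_setequal(sel$survivors, c(1.08, 1.20))
})

test_that("selection is invariant to candidate ordering and breaks ties
           toward the smaller scaling factor", {
  mc <- make_candidates()
  shuffled <- mc$cand[sample(nrow(mc$cand)), ]
  expect_equal(select_optimal(shuffled, mc$ref, mc$sites)$f, 1.08)
  # exact tie: two survivors with identical deviations
  tie <- rbind(
    data.frame(f = 1.05, concentration = 1, a_prime = 1.1,
               r_sim_1 = 2.9, r_sim_2 = 3.1),
    data.frame(f = 1.10, concentration = 1, a_prime = 1.1,
               r_sim_1 = 2.9, r_sim_2 = 3.1))
  sel <- select_optimal(tie, c("1" = 1.1),
                        contact_site_table(1:2, 1:2, c("ASP", "ASP"),
                                           c("OD1", "OD1"), c(2.8, 3.0)))
  expect_equal(sel$f, 1.05)
  # single candidate inside the band is returned; none inside errors
  one <- data.frame(f = 1.08, concentration = 1, a_prime = 1.1,
                    r_sim_1 = 2.9, r_sim_2 = 3.1)
  expect_equal(select_optimal(one, c("1" = 1.1), mc$sites)$f, 1.08)
  bad <- transform(one, a_prime = 2.0)
  expect_error(select_optimal(bad, c("1" = 1.1), mc$sites), "band")
})

test_that("pair override export: sigma and kJ conversions, exact round
           trip in both dialects", {
  f <- withr::local_tempfile()
  export_pair_override(3.6355, 0.2, f, "sigma_eps_kj")
  txt <- readLines(f)
  sigma <- as.numeric(sub("sigma_A ", "", grep("sigma_A", txt, value = TRUE)))
  epskj <- as.numeric(sub("epsilon_kJmol ", "",
                          grep("epsilon_kJmol", txt, value = TRUE)))
  expect_equal(signif(sigma, 5), 3.2389)   # Rmin / 2^(1/6)
  expect_equal(epskj, 0.8368)              # 0.2 kcal * 4.184
  for (dialect in c("rmin_eps", "sigma_eps_kj")) {
    f2 <- withr::local_tempfile()
    export_pair_override(3.6355, 0.1936, f2, dialect)
    back <- read_pair_override(f2)
    expect_equal(back$Rmin, 3.6355, tolerance = 1e-9)
    expect_equal(back$eps, 0.1936, tolerance = 1e-9)
  }
  expect_error(export_pair_override(3.6, 0.2, tempfile(), "weird"))
})

test_that("the full scan loop recovers scripted contact distances at every
           site (zero placement noise)", {
  gs <- data.frame(species = "cation", site = 1:5,
                   distance = c(2.7, 2.8, 2.9, 3.0, 3.1), angle = NA)
  toy <- gen_toy_protein_system(gs, seed = 9, n_frames = 200)
  r_sim <- fit_site_distances(toy$trajectory, toy$contact_table)
  expect_true(all(site_deviation(r_sim, toy$contact_table$r_cryst_A) < 1e-3))
})
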