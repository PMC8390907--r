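# Solvation-shell structure: proximal distances, isosurface areas, shell
# densities, hydrogen bonds and composition metrics.

test_that("proximal distance: single atom, brute-force oracle and the
           periodic image", {
  box <- box_spec(30)
  expect_equal(proximal_distance(matrix(c(15, 10, 10), 1, 3),
                                 matrix(c(10, 10, 10), 1, 3), box), 5)
  # brute force over 200 atoms
  set.seed(4)
  prot <- matrix(runif(200 * 3, 0, 30), 200, 3)
  pts <- matrix(runif(50 * 3, 0, 30), 50, 3)
  got <- proximal_distance(pts, prot, box)
  want <- apply(pts, 1, function(p) {
    min(apply(prot, 1, function(q) {
      d <- p - q; d <- d - 30 * round(d / 30); sqrt(sum(d^2))
    }))
  })
  expect_equal(got, want, tolerance = 1e-12)
  # across the boundary: 1 and 29 are 2 apart through the image
  expect_equal(proximal_distance(matrix(c(29, 0, 0), 1, 3),
                                 matrix(c(1, 0, 0), 1, 3), box), 2)
})

test_that("isosurface area reproduces the sphere closed forms within 0.5%
           at 960 points and converges with sampling density", {
  expect_equal(sasa_at_distance(matrix(0, 1, 3), 2), 4 * pi * 4,
               tolerance = 1e-9)
  two <- rbind(c(0, 0, 0), c(3, 0, 0))
  a_overlap <- sasa_at_distance(two, 2, 960)
  expect_equal(a_overlap, 4 * pi * 2 * (2 + 1.5), tolerance = 0.005)
  a_disjoint <- sasa_at_distance(two, 1.2, 960)
  expect_equal(a_disjoint, 8 * pi * 1.2^2, tolerance = 1e-9)
  # doubling the point count moves the two-sphere area by < 0.5%
  a_fine <- sasa_at_distance(two, 2, 1920)
  expect_lt(abs(a_fine - a_overlap) / a_fine, 0.005)
})

test_that("single scripted water gives the closed-form shell density", {
  atoms <- data.frame(species = c("protein", "W"),
                      role = c("protein_heavy", "water"),
                      name = c("CA", "O"), element = c("C", "O"),
                      resid = c(0L, 1L))
  r0 <- 3.025  # a bin centre for dr = 0.05
  tr <- make_traj(rbind(c(20, 20, 20), c(20 + r0, 20, 20)), atoms, L = 40)
  prof <- proximal_density(tr, "W", dr = 0.05, r_max = 5)
  hit <- which(prof$n_mean > 0)
  expect_length(hit, 1)
  expect_equal(prof$r_mid[hit], r0)
  expect_equal(prof$rho_per_nm3[hit], 1000 / (0.05 * 4 * pi * r0^2),
               tolerance = 1e-6)
  expect_equal(cumulative_number(prof, 4.5), 1)
  expect_equal(cumulative_number(prof, 0), 0)
  expect_error(cumulative_number(prof, 99), "range")
})

test_that("uniform solvent has a flat proximal density equal to N/V and
           shell counts conserve the population (normalisation cancels
           geometry)", {
  ros <- species_roster("W", 1200, "water", electroneutral = FALSE)
  profs <- lapply(1:3, function(k) {
    toy <- gen_toy_protein_system(data.frame(), seed = k)
    solv <- gen_ideal_solution(ros, box_spec(60), 12, seed = 100 + k)
    tr <- merge_protein_solvent(toy$structure, solv)
    proximal_density(tr, "W", dr = 0.3, r_max = 12)
  })
  rho <- sapply(profs, function(p) p$rho_per_nm3)
  sel <- profs[[1]]$r_mid > 1.5
  grand_mean <- mean(colMeans(rho[sel, ]))
  sem <- sd(colMeans(rho[sel, ])) / sqrt(3)
  bulk <- 1200 / 6^3  # particles per nm^3
  expect_lt(abs(grand_mean - bulk), 3 * sem + 1e-9)
  # conservation against brute-force counting on one replica
  toy <- gen_toy_protein_system(data.frame(), seed = 1)
  solv <- gen_ideal_solution(ros, box_spec(60), 5, seed = 101)
  tr <- merge_protein_solvent(toy$structure, solv)
  prof <- proximal_density(tr, "W", dr = 0.3, r_max = 12)
  prot_idx <- which(tr$atoms$role == "protein_heavy")
  w_idx <- which(tr$atoms$species == "W" & tr$atoms$name == "O")
  counts <- sapply(seq_len(n_frames(tr)), function(f) {
    d <- proximal_distance(tr$coords[w_idx, , f],
                           tr$coords[prot_idx, , f], tr$box)
    sum(d < 12)
  })
  expect_equal(sum(prof$n_mean), mean(counts), tolerance = 1e-12)
})

test_that("first-peak height of a scripted shell ignores far-field ions", {
  gs <- data.frame(species = "water", site = 1:3, distance = 2.8,
                   angle = 170)
  toy1 <- gen_toy_protein_system(gs, seed = 2)
  gs2 <- rbind(gs, data.frame(species = "cation", site = 1:3, distance = 9,
                              angle = NA))
  toy2 <- gen_toy_protein_system(gs2, seed = 2)
  p1 <- proximal_density(toy1$trajectory, "water", dr = 0.1, r_max = 5)
  p2 <- proximal_density(toy2$trajectory, "water", dr = 0.1, r_max = 5)
  expect_equal(max(p1$rho_per_nm3), max(p2$rho_per_nm3), tolerance = 1e-9)
})

test_that("hydrogen-bond census matches the ideal-geometry expectations
           and both cutoffs act strictly", {
  place <- function(distance, angle) {
    gs <- data.frame(species = "water", site = 1, distance = distance,
                     angle = angle)
    hbond_census(gen_toy_protein_system(gs, seed = 1)$trajectory)
  }
  expect_identical(place(2.8, 180), 1L)
  expect_identical(place(3.2, 180), 0L)   # distance cut
  expect_identical(place(2.8, 100), 0L)   # angle cut
})

test_that("hydrogen-bond census equals the exhaustive geometric checker on
           random geometries straddling both cutoffs", {
  set.seed(7)
  n_geo <- 200
  L <- 60
  mism <- 0
  for (i in seq_len(n_geo)) {
    d <- runif(1, 2.4, 3.4)        # straddles the 3 A cutoff
    ang <- runif(1, 110, 180)      # straddles the 135 degree cutoff
    gs <- data.frame(species = "water", site = sample(5, 1), distance = d,
                     angle = ang)
    tr <- gen_toy_protein_system(gs, seed = i)$trajectory
    got <- hbond_census(tr)
    at <- tr$atoms
    ow <- which(at$role == "water" & at$name == "O")
    acc <- which(at$role == "protein_heavy" & at$element %in% c("N", "O"))
    x <- tr$coords[, , 1]
    want <- 0L
    for (a in acc)
      if (brute_hbond(x[ow, ], x[ow + 1, ], x[ow + 2, ], x[a, ]))
        want <- want + 1L
    if (got != want) mism <- mism + 1
  }
  expect_equal(mism, 0)
})

test_that("census is invariant under rigid rotation and translation of the
           whole frame", {
  gs <- data.frame(species = "water", site = c(1, 2, 4),
                   distance = c(2.8, 2.95, 3.05), angle = c(180, 150, 170))
  toy <- gen_toy_protein_system(gs, seed = 3)
  n0 <- hbond_census(toy$trajectory)
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr2 <- toy$trajectory
  tr2$coords[, , 1] <- tr2$coords[, , 1] %*% t(Rz) + 5
  expect_identical(hbond_census(tr2), n0)
})

test_that("hydrogen-bond surface density is a homogeneous ratio", {
  s <- hbond_surface_density(100, 1000)
  expect_equal(s$per_A2, 0.1)
  expect_equal(s$per_nm2, 10)
  expect_equal(hbond_surface_density(0, 500)$per_A2, 0)
  expect_equal(hbond_surface_density(200, 2000)$per_A2, s$per_A2)
  expect_error(hbond_surface_density(5, 0), "positive")
})

test_that("composition metrics: counts, charge and densities", {
  res <- data.frame(resid = 1:5,
                    resname = c("ASP", "GLU", "ASP", "GLU", "LYS"))
  cm <- composition_metrics(res, mean_sasa_A2 = 100)
  expect_equal(unname(cm$counts[c("acidic", "basic")]), c(4, 1))
  expect_equal(cm$net_charge_e, -3)
  expect_equal(cm$acidic_per_A2, 0.04)
  expect_equal(cm$charge_per_A2, -0.03)
  # invariant to residue order
  cm2 <- composition_metrics(res[5:1, ], mean_sasa_A2 = 100)
  expect_equal(cm2$counts, cm$counts)
  # unknown names need an override; histidine flips class when titrated
  expect_error(composition_metrics(
    data.frame(resid = 1, resname = "XYZ"), 100), "unknown residue")
  his <- data.frame(resid = 1, resname = "HIS")
  expect_equal(composition_metrics(his, 100)$net_charge_e, 0)
  expect_equal(composition_metrics(his, 100, his_charged = TRUE)$net_charge_e,
               1)
})

test_that("least-squares correlation matches exact lines and the direct
           textbook formula", {
  x <- 1:10
  out <- linear_correlation(x, 2 * x + 1)
  expect_equal(out$slope, 2); expect_equal(out$intercept, 1)
  expect_equal(out$pearson_r, 1)
  expect_equal(linear_correlation(x, -3 * x + 4)$pearson_r, -1)
  set.seed(11)
  xx <- rnorm(100); yy <- 0.3 * xx + rnorm(100)
  out <- linear_correlation(xx, yy)
  sxy <- sum((xx - mean(xx)) * (yy - mean(yy)))
  expect_equal(out$slope, sxy / sum((xx - mean(xx))^2), tolerance = 1e-12)
  expect_equal(out$pearson_r,
               sxy / sqrt(sum((xx - mean(xx))^2) * sum((yy - mean(yy))^2)),
               tolerance = 1e-12)
  expect_error(linear_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
})
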