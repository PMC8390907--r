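# Shell-resolved dynamics: tagging, MSD conventions, diffusion fits.

test_that("first-shell tagging selects exactly the scripted members at the
           first frame and never re-tags", {
  gs <- rbind(
    data.frame(species = "water", site = 1:3, distance = 3.0, angle = 170),
    data.frame(species = "water", site = 1:3, distance = 7.5, angle = 170),
    data.frame(species = "water", site = 4, distance = 8.5, angle = 170))
  toy <- gen_toy_protein_system(gs, seed = 8)
  tagged <- tag_first_shell(toy$trajectory, "water", cutoff = 4.5)
  expect_length(tagged, 3)
  expect_length(tag_first_shell(toy$trajectory, "water", cutoff = 1e-6), 0)
  # tagging reads only the tagging frame: perturbing later frames changes
  # nothing
  tr2 <- toy$trajectory
  tr2$coords <- array(tr2$coords[, , c(1, 1)], c(n_atoms(tr2), 3, 2))
  tr2$coords[, , 2] <- tr2$coords[, , 2] + 50
  expect_identical(tag_first_shell(tr2, "water", cutoff = 4.5), tagged)
})

test_that("MSD closed forms: static particles, ballistic motion, global
           translation invariance", {
  n <- 20
  atoms <- data.frame(species = "W", role = "water", name = "O",
                      element = "O", resid = seq_len(n))
  x0 <- matrix(runif(n * 3, 0, 50), n, 3)
  static <- array(rep(x0, 40), c(n, 3, 40))
  tr <- sim_trajectory(static, atoms, box_spec(60), timestep = 0.5,
                       wrapped = FALSE)
  curve <- msd(tr, seq_len(n), max_lag = 10, use_wrapped = FALSE)
  expect_true(all(curve$msd == 0))
  expect_equal(curve$msd[1], 0)  # MSD(0) = 0
  fit0 <- fit_diffusion(curve, window = c(2, 10))
  expect_equal(fit0$D, 0); expect_equal(fit0$C, 0)

  v <- c(0.3, -0.1, 0.2)
  ball <- array(NA_real_, c(n, 3, 40))
  for (f in 1:40) ball[, , f] <- x0 + (f - 1) * 0.5 * rep(v, each = n)
  trb <- sim_trajectory(ball, atoms, box_spec(60), timestep = 0.5,
                        wrapped = FALSE)
  cb <- msd(trb, seq_len(n), max_lag = 8, use_wrapped = FALSE)
  expect_equal(cb$msd, sum(v^2) * cb$tau^2, tolerance = 1e-12)
  # rigid translation of every frame leaves the unwrapped MSD unchanged
  trt <- trb; trt$coords <- trb$coords + 123.4
  expect_equal(msd(trt, seq_len(n), 8, use_wrapped = FALSE)$msd, cb$msd)
})

test_that("an exact line 6 D tau + C is recovered by the window fit", {
  curve <- structure(list(tau = seq(0, 40, by = 0.5),
                          msd = 6 * 0.2 * seq(0, 40, by = 0.5) + 1.5,
                          n_tagged = 1, wrapped = FALSE, timestep = 0.5),
                     class = "msd_curve")
  fit <- fit_diffusion(curve, window = c(20, 30))
  expect_equal(fit$D, 0.2, tolerance = 1e-12)
  expect_equal(fit$C, 1.5, tolerance = 1e-10)
  expect_equal(fit$D_1e5cm2s, 2, tolerance = 1e-12)
  expect_error(fit_diffusion(curve, window = c(100, 110)), "3 MSD points")
})

test_that("wrapped-coordinate MSD is bounded by the confinement ceiling
           while the unwrapped one keeps growing", {
  ros <- species_roster("W", 150, "water", electroneutral = FALSE)
  L <- 20
  tr <- gen_brownian(ros, box_spec(L), 1.0, 0.5, 800, seed = 13)
  ids <- select_atoms(tr, "W")
  mw <- msd(tr, ids, max_lag = 350, use_wrapped = TRUE, lag_stride = 25)
  mu <- msd(tr, ids, max_lag = 350, use_wrapped = FALSE, lag_stride = 25)
  expect_lt(max(mw$msd), 3 * (L / 2)^2)
  expect_gt(max(mu$msd), 3 * (L / 2)^2)
  # saturation: the last two wrapped points differ by little
  n <- length(mw$msd)
  expect_lt(abs(mw$msd[n] - mw$msd[n - 1]) / mw$msd[n], 0.1)
})

test_that("Brownian diffusion coefficients are recovered within 5% across
           a decade of D", {
  ros <- species_roster("W", 400, "water", electroneutral = FALSE)
  for (D in c(0.05, 0.5)) {
    tr <- gen_brownian(ros, box_spec(60), D, 0.1, 4000, seed = 17)
    curve <- msd(tr, select_atoms(tr, "W"), max_lag = 30,
                 use_wrapped = FALSE, lag_stride = 20)
    fit <- fit_diffusion(curve, window = c(20, 30))
    expect_equal(fit$D, D, tolerance = 0.05)
  }
})

test_that("shell and bulk populations with different generator D give the
           engineered ratio; a homogeneous system gives ratio 1", {
  make_two_pop <- function(seed, D_shell = 0.1, D_bulk = 0.2) {
    toy <- gen_toy_protein_system(data.frame(), seed = seed)
    np <- n_atoms(toy$structure)
    n_shell <- 30; n_bulk <- 170
    # shell members start within the cutoff, bulk members far away
    ctr <- rep(30, 3)
    u <- halosolv:::.fibonacci_sphere(n_shell)
    init_shell <- sweep(8.5 * u, 2, ctr, `+`)  # ~3 A from arm tips
    set.seed(seed)
    init_bulk <- matrix(runif(n_bulk * 3, 0, 60), n_bulk, 3)
    d0 <- proximal_distance(init_bulk, toy$structure$coords[, , 1],
                            box_spec(60))
    init_bulk[d0 < 6, ] <- 55  # push accidental shell members out
    ros <- species_roster("W", n_shell + n_bulk, "water",
                          electroneutral = FALSE)
    solv <- gen_brownian(ros, box_spec(60), 1, timestep = 0.5, n_steps = 260,
                         seed = seed, init = rbind(init_shell, init_bulk),
                         D_per_atom = c(rep(D_shell, n_shell),
                                        rep(D_bulk, n_bulk)))
    np_tab <- toy$structure$atoms
    nf <- n_frames(solv)
    coords <- array(NA_real_, c(np + n_atoms(solv), 3, nf))
    for (f in seq_len(nf))
      coords[, , f] <- rbind(toy$structure$coords[, , 1], solv$coords[, , f])
    tr <- sim_trajectory(coords, rbind(np_tab, cbind(solv$atoms,
                                                     resname = "WAT")),
                         box_spec(60), timestep = 0.5, wrapped = FALSE)
    tr$wrapped <- FALSE
    tr
  }
  reps <- lapply(1:2, make_two_pop)
  rep_out <- shell_vs_bulk_report(reps, "W", cutoff = 4.5,
                                  window = c(20, 30), lag_stride = 5)
  summ <- attr(rep_out, "summary")
  # bulk is dominated by D = 0.2 particles; shell members have D = 0.1
  expect_equal(summ$D_shell, 0.1, tolerance = 0.15)
  expect_equal(summ$D_bulk, 0.2, tolerance = 0.15)
  expect_equal(summ$ratio, 0.5, tolerance = 0.3)
  expect_false(is.na(summ$sem_ratio))
  # homogeneous generator: shell and bulk dynamics coincide
  homo <- lapply(3:4, function(s) make_two_pop(s, 0.2, 0.2))
  summ_h <- attr(shell_vs_bulk_report(homo, "W", cutoff = 4.5,
                                      window = c(20, 30), lag_stride = 5),
                 "summary")
  expect_equal(summ_h$ratio, 1, tolerance = 0.25)
})
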