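test_that("initial optimiser weights follow the priority constants", {
  p <- chhip_protocol("instA")
  states <- init_states(p)
  for (s in states) {
    expected <- switch(s$goal$priority, P1 = 1000, P2 = 250,
                       P3 = s$goal$weighting_factor)
    expect_equal(s$optimiser_weight, expected)
  }
  i <- which(protocol_goal_ids(p) == "Rectum|mean_dose|")
  expect_equal(states[[i]]$optimiser_weight, 5.84)
})

test_that("dynamic positioning sets targets a constant delta below achieved", {
  p <- chhip_protocol("instA")
  # single-ROI dose field: 90 of 1000 voxels at 25 Gy -> V23.4Gy = 9.0%
  masks <- list(ROI = array(TRUE, c(10, 10, 10)))
  geom <- toy_geometry(masks)
  dose <- array(10, c(10, 10, 10)); dose[1:90] <- 25
  gdv <- planning_goal("ROI", "P3", "dv_max", 10.0, "%Vol",
                       weighting_factor = 1, dose_level = 23.4)
  st <- list(objective_state(gdv, 1))
  # delta = 0 reproduces the achieved value exactly
  up0 <- update_positions(st, dose, geom, p, pbaio_config(delta_volume = 0))
  expect_identical(up0[[1]]$dynamic_target, 9.0)
  # default delta = 2 percentage points
  up2 <- update_positions(st, dose, geom, p, pbaio_config())
  expect_identical(up2[[1]]$dynamic_target, 7.0)
  # floor at zero
  dose_low <- array(10, c(10, 10, 10)); dose_low[1:5] <- 25  # 0.5%
  upf <- update_positions(st, dose_low, geom, p, pbaio_config(delta_volume = 2))
  expect_identical(upf[[1]]$dynamic_target, 0)
  # mean-dose goal: dose-type delta of 1 Gy
  gmean <- planning_goal("ROI", "P3", "mean_dose", 5, "Gy",
                         weighting_factor = 1)
  stm <- list(objective_state(gmean, 1))
  dose_m <- array(25.3, c(10, 10, 10))
  upm <- update_positions(stm, dose_m, geom, p, pbaio_config(delta_dose = 1))
  expect_equal(upm[[1]]$dynamic_target, 24.3)
  # P2 targets are never moved
  gmin <- planning_goal("ROI", "P2", "min_dose", 59, "Gy")
  stp2 <- list(objective_state(gmin, 250))
  expect_identical(update_positions(stp2, dose, geom, p,
                                    pbaio_config())[[1]]$dynamic_target, 59)
})

test_that("positioning leaves achieved - target == delta for unfloored goals", {
  g <- small_patient()
  p <- chhip_protocol("instA")
  plan <- small_plan()
  cfg <- pbaio_config()
  states <- update_positions(init_states(p, cfg), plan$dose, g, p, cfg)
  for (s in states) {
    ach <- pgap:::positioning_achieved(s, plan$dose, g)
    if (is.null(ach)) next
    delta <- if (ach$kind == "volume") cfg$delta_volume else cfg$delta_dose
    if (s$dynamic_target > 0) {
      expect_equal(ach$value - s$dynamic_target, delta, tolerance = 1e-12)
    } else {
      expect_lte(ach$value, delta)
    }
  }
})

test_that("dynamic weighting has the stated fixed point, floor and monotonicity", {
  p <- chhip_protocol("instA")
  cfg <- pbaio_config(penalty_target = 1, weight_clip = 4, weight_span = 16)
  gmean <- planning_goal("ROI", "P3", "mean_dose", 5, "Gy",
                         weighting_factor = 2)
  mk <- function(pen) {
    s <- objective_state(gmean, 2)
    s$last_penalty <- pen
    s
  }
  # penalty at tau / WF: weight unchanged
  w1 <- update_weights(list(mk(1 / 2)), cfg)[[1]]$optimiser_weight
  expect_equal(w1, 2)
  # zero penalty: multiplied by exactly 1/rho
  w0 <- update_weights(list(mk(0)), cfg)[[1]]$optimiser_weight
  expect_equal(w0, 2 / 4)
  # monotone in the penalty
  wa <- update_weights(list(mk(3)), cfg)[[1]]$optimiser_weight
  wb <- update_weights(list(mk(0.9)), cfg)[[1]]$optimiser_weight
  expect_gt(wa, wb)
  # per-loop change clipped to rho
  whot <- update_weights(list(mk(1e9)), cfg)[[1]]$optimiser_weight
  expect_equal(whot, 2 * 4)
  # P1/P2 weights untouched
  s2 <- objective_state(planning_goal("ROI", "P2", "min_dose", 59, "Gy"), 250)
  s2$last_penalty <- 10
  expect_equal(update_weights(list(s2), cfg)[[1]]$optimiser_weight, 250)
})

test_that("weight trajectories stay within the span bound around the WF", {
  g <- small_patient()
  p <- chhip_protocol("instA")
  plan <- small_plan()
  lg <- plan$log
  for (id in unique(lg$goal[lg$priority == "P3"])) {
    wf <- p$goals[[which(protocol_goal_ids(p) == id)]]$weighting_factor
    w <- lg$weight[lg$goal == id]
    span <- plan$pbaio_config$weight_span
    expect_true(all(w >= wf / span - 1e-12 & w <= wf * span + 1e-12))
  }
})

test_that("the inner optimiser honours its contracts", {
  infl <- small_influence()
  g <- small_patient()
  p <- chhip_protocol("instA")
  cfg <- fast_pbaio()
  states <- init_states(p, cfg)
  x0 <- rep(0.5, ncol(infl$matrix))
  # n_iter = 0 returns the initial fluence untouched
  r0 <- inner_optimise(infl, states, x0, 0L, g, p, cfg)
  expect_identical(r0$fluence, x0)
  # objective sequence non-increasing
  r <- inner_optimise(infl, states, x0, 25L, g, p, cfg)
  expect_true(all(diff(r$objective) <= 0))
  expect_true(all(r$fluence >= 0))
  # deterministic
  r2 <- inner_optimise(infl, states, x0, 25L, g, p, cfg)
  expect_identical(r$fluence, r2$fluence)
})

test_that("a convex single-goal problem reaches its analytic minimum", {
  # 10-voxel toy with a mean-dose goal: the objective is
  # w * max(0, mean(D x) - T)^2, minimised to exactly zero on the
  # nonnegative orthant whenever some fluence attains mean <= T
  set.seed(2)
  M <- matrix(stats::runif(10 * 4, 0.2, 1), 10, 4)
  infl <- influence_matrix(M, voxel_index = 1:10, grid_shape = c(10, 1, 1))
  geom <- toy_geometry(list(ROI = array(TRUE, c(10, 1, 1))))
  p <- chhip_protocol("instA")
  gmean <- planning_goal("ROI", "P3", "mean_dose", 3, "Gy",
                         weighting_factor = 1)
  states <- list(objective_state(gmean, 1))
  r <- inner_optimise(infl, states, rep(5, 4), 200L, geom, p, pbaio_config())
  expect_lt(utils::tail(r$objective, 1), 1e-6)
  # and with an additional floor the analytic optimum is a uniform dose at
  # the unique balance point of the two quadratics (computed on 1 beamlet)
  M1 <- matrix(1, 1, 1)
  infl1 <- influence_matrix(M1, 1L, c(1, 1, 1))
  geom1 <- toy_geometry(list(ROI = array(TRUE, c(1, 1, 1))))
  gmin <- planning_goal("ROI", "P2", "min_dose", 10, "Gy")
  gmax <- planning_goal("ROI", "P2", "max_dose", 6, "Gy")
  states2 <- list(objective_state(gmin, 1), objective_state(gmax, 3))
  # f(d) = (10 - d)^2 + 3 (d - 6)^2 for 6 < d < 10; minimum at d = 7
  r2 <- inner_optimise(infl1, states2, 8, 300L, geom1, p,
                       pbaio_config(convergence_tol = 1e-14))
  expect_equal(r2$fluence, 7, tolerance = 1e-4)
})

test_that("autoplan is bit-reproducible and records a full state log", {
  plan1 <- small_plan()
  plan2 <- autoplan(small_patient(), chhip_protocol("instA"),
                    small_beam_config(), fast_pbaio(),
                    influence = small_influence())
  expect_identical(plan1$fluence, plan2$fluence)
  expect_identical(plan1$dose, plan2$dose)
  expect_identical(plan1$log, plan2$log)
  cfg <- fast_pbaio()
  p <- chhip_protocol("instA")
  expect_equal(nrow(plan1$log),
               (cfg$outer_loops + 1) * length(p$goals))
  expect_equal(dose_at_volume(plan1$dose, small_patient()$masks$PTV60, 50),
               60, tolerance = 1e-9)
})

test_that("raising the rectum weighting factors never worsens rectum dose", {
  g <- small_patient()
  p <- chhip_protocol("instA")
  p10 <- p
  for (i in seq_along(p10$goals)) {
    gl <- p10$goals[[i]]
    if (gl$priority == "P3" && gl$roi == "Rectum")
      p10$goals[[i]]$weighting_factor <- gl$weighting_factor * 10
  }
  cfg <- fast_pbaio()
  base <- autoplan(g, p, small_beam_config(), cfg,
                   influence = small_influence())
  hot <- autoplan(g, p10, small_beam_config(), cfg,
                  influence = small_influence())
  expect_lte(mean(hot$dose[g$masks$Rectum]),
             mean(base$dose[g$masks$Rectum]) + 0.1)
})
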