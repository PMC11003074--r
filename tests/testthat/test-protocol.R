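test_that("the packaged institution fixtures reproduce the published goal set", {
  pa <- load_protocol(system.file("extdata", "protocol_instA.json",
                                  package = "pgap"))
  pb <- load_protocol(system.file("extdata", "protocol_instB.json",
                                  package = "pgap"))
  ids_a <- protocol_goal_ids(pa)
  # rectum mean-dose goal carries WF 5.84 in both institutions
  for (p in list(pa, pb)) {
    i <- which(protocol_goal_ids(p) == "Rectum|mean_dose|")
    expect_equal(p$goals[[i]]$weighting_factor, 5.84)
  }
  # instB adds bowel V36/V45.6 at WF 0.413 and drops rectum V39.6
  ids_b <- protocol_goal_ids(pb)
  expect_true(all(c("Bowel|dv_max|36", "Bowel|dv_max|45.6") %in% ids_b))
  for (id in c("Bowel|dv_max|36", "Bowel|dv_max|45.6")) {
    expect_equal(pb$goals[[which(ids_b == id)]]$weighting_factor, 0.413)
  }
  expect_false("Rectum|dv_max|39.6" %in% ids_b)
  expect_true("Rectum|dv_max|39.6" %in% ids_a)
  # P1/P2 structure: one conformality goal, seven target goals
  expect_equal(sum(vapply(pa$goals, function(g) g$priority, "") == "P1"), 1)
  expect_equal(sum(vapply(pa$goals, function(g) g$priority, "") == "P2"), 7)
  # intra-PTV falloff high dose level differs between institutions
  i48a <- which(ids_a == "PTV48|dose_falloff_intra|")
  i48b <- which(ids_b == "PTV48|dose_falloff_intra|")
  expect_equal(pa$goals[[i48a]]$falloff$high_dose, 54.6)
  expect_equal(pb$goals[[i48b]]$falloff$high_dose, 54.0)
  # fixtures equal the in-code constructors
  expect_equal(pa, chhip_protocol("instA"))
  expect_equal(pb, chhip_protocol("instB"))
})

test_that("protocol JSON round trip preserves the protocol", {
  p <- chhip_protocol("instB")
  path <- tempfile(fileext = ".json")
  save_protocol(p, path)
  expect_equal(load_protocol(path), p)
})

test_that("schema validation rejects malformed protocols", {
  p <- chhip_protocol("instA")
  path <- tempfile(fileext = ".json")
  save_protocol(p, path)
  obj <- jsonlite::read_json(path)
  obj$unexpected <- 1
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  expect_error(load_protocol(path), "unknown protocol field")
  obj$unexpected <- NULL
  obj$goals[[10]]$weighting_factor <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  expect_error(load_protocol(path), "weighting_factor")
  expect_error(load_protocol(tempfile()), "not found")
  expect_error(planning_goal("Rectum", "P3", "dv_max", 0, "%Vol",
                             weighting_factor = 1), "dose_level")
  expect_error(planning_goal("PTV48", "P1", "conformality_max", 46.8, "Gy"),
               "distance")
})

test_that("target resolution converts each unit family", {
  p <- chhip_protocol("instA")
  g_min60 <- p$goals[[which(protocol_goal_ids(p) == "PTV60|min_dose|")]]
  expect_equal(resolve_target_dose(g_min60, p), 0.987 * 60)
  expect_equal(resolve_target_dose(g_min60, p, 100), 60)
  g575 <- p$goals[[which(protocol_goal_ids(p) == "PTV57.5|min_dose|")]]
  expect_equal(resolve_target_dose(g575, p, 100), 57.5)
  fo <- p$goals[[which(protocol_goal_ids(p) ==
                         "External|dose_falloff_external|")]]
  expect_equal(pgap:::falloff_gradient_gy_cm(fo, p), 30)  # 50 %Presc/cm
  bad <- planning_goal("Rectum", "P2", "min_dose", 98, "%Presc,PTV")
  expect_error(resolve_target_dose(bad, p), "non-PTV")
})

test_that("falloff threshold maps follow max(low, high - g d)", {
  g <- small_patient()
  p <- chhip_protocol("instA")
  ids <- protocol_goal_ids(p)
  fo <- p$goals[[which(ids == "External|dose_falloff_external|")]]
  thr <- falloff_threshold_map(fo, g, p)
  region <- !is.na(thr)
  ptvs <- g$masks$PTV60 | g$masks$`PTV57.5` | g$masks$PTV48
  expect_identical(region, g$masks$External & !ptvs)
  d_cm <- sqrt(pgap:::sq_edt(ptvs, g$spacing)) / 10
  expect_equal(thr[region], pmax(30, 60 - 30 * d_cm[region]),
               tolerance = 1e-12)
  # the 60 -> 30 Gy ramp at 30 Gy/cm bottoms out at exactly 1 cm
  expect_true(all(thr[region][d_cm[region] >= 1] == 30))
  expect_true(all(thr[region][d_cm[region] < 1 - 1e-9] > 30))
  # intra-PTV falloff on PTV48 (instA): 54.6 -> 45.6 at 45 Gy/cm,
  # plateau beyond (54.6 - 45.6)/45 = 0.2 cm
  fi <- p$goals[[which(ids == "PTV48|dose_falloff_intra|")]]
  thr2 <- falloff_threshold_map(fi, g, p)
  reg2 <- !is.na(thr2)
  expect_identical(reg2, g$masks$PTV48 & !(g$masks$`PTV57.5` | g$masks$PTV60))
  d2 <- sqrt(pgap:::sq_edt(g$masks$`PTV57.5`, g$spacing)) / 10
  expect_equal(thr2[reg2], pmax(45.6, 54.6 - 45 * d2[reg2]),
               tolerance = 1e-12)
  expect_true(all(thr2[reg2][d2[reg2] >= 0.2] == 45.6))
  # PTV57.5 intra falloff with high = low = 54 is a uniform ceiling
  f575 <- p$goals[[which(ids == "PTV57.5|dose_falloff_intra|")]]
  thr3 <- falloff_threshold_map(f575, g, p)
  expect_true(all(thr3[!is.na(thr3)] == 54))
  expect_error(falloff_threshold_map(g_min <- p$goals[[2]], g, p),
               "not a falloff")
})

test_that("penalties reproduce hand arithmetic and vanish when satisfied", {
  p <- chhip_protocol("instA")
  geom <- toy_geometry(list(ROI = array(c(TRUE, TRUE, FALSE, FALSE),
                                        c(4, 1, 1))))
  # min_dose 59 Gy on doses {58, 60}: (59-58)^2 / 2
  gmin <- planning_goal("ROI", "P2", "min_dose", 59, "Gy")
  st <- objective_state(gmin, 250)
  dose <- array(c(58, 60, 0, 0), c(4, 1, 1))
  expect_equal(as.numeric(goal_penalty(st, dose, geom, p)), 0.5)
  # fully satisfied dose: zero penalty
  expect_equal(as.numeric(goal_penalty(st, array(60, c(4, 1, 1)), geom, p)), 0)
  # dv_max V23.4Gy target 50% on {30,30,30,10}: only the single lowest
  # violating voxel of the three above the level is penalised
  geom4 <- toy_geometry(list(ROI = array(TRUE, c(4, 1, 1))))
  gdv <- planning_goal("ROI", "P3", "dv_max", 50, "%Vol",
                       weighting_factor = 1, dose_level = 23.4)
  stdv <- objective_state(gdv, 1)
  dose4 <- array(c(30, 30, 30, 10), c(4, 1, 1))
  expect_equal(as.numeric(goal_penalty(stdv, dose4, geom4, p)),
               (30 - 23.4)^2 / 4)
  # mean_dose: (mean - T)^2 above target only
  gmean <- planning_goal("ROI", "P3", "mean_dose", 20, "Gy",
                         weighting_factor = 1)
  stm <- objective_state(gmean, 1)
  expect_equal(as.numeric(goal_penalty(stm, dose4, geom4, p)),
               (mean(c(30, 30, 30, 10)) - 20)^2)
  expect_equal(as.numeric(goal_penalty(stm, array(5, c(4, 1, 1)), geom4, p)), 0)
})

test_that("dv_max tail selection matches a brute-force oracle", {
  p <- chhip_protocol("instA")
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(5:40, 1)
    doses <- round(stats::runif(n, 0, 60), 1)
    level <- stats::runif(1, 10, 50)
    vt <- stats::runif(1, 0, 60)
    geom <- toy_geometry(list(ROI = array(TRUE, c(n, 1, 1))))
    gdv <- planning_goal("ROI", "P3", "dv_max", vt, "%Vol",
                         weighting_factor = 1, dose_level = level)
    val <- as.numeric(goal_penalty(objective_state(gdv, 1),
                                   array(doses, c(n, 1, 1)), geom, p))
    above <- sort(doses[doses > level], decreasing = TRUE)
    k <- floor(vt / 100 * n)
    ref <- if (length(above) > k) sum((above[(k + 1):length(above)] - level)^2) / n
           else 0
    expect_equal(val, ref, tolerance = 1e-12)
  }
})

test_that("penalty gradients match central finite differences", {
  p <- chhip_protocol("instA")
  set.seed(31)
  n <- 24
  geom <- toy_geometry(list(ROI = array(TRUE, c(n, 1, 1))))
  goals <- list(
    planning_goal("ROI", "P2", "min_dose", 30, "Gy"),
    planning_goal("ROI", "P2", "max_dose", 25, "Gy"),
    planning_goal("ROI", "P3", "mean_dose", 10, "Gy", weighting_factor = 1),
    planning_goal("ROI", "P3", "dv_max", 20, "%Vol", weighting_factor = 1,
                  dose_level = 22),
    planning_goal("ROI", "P2", "median_max", 28, "Gy")
  )
  dose_v <- stats::runif(n, 5, 55)
  # keep clear of the dv_max tail-membership tie boundary
  dose_v[abs(dose_v - 22) < 0.5] <- 25
  for (gl in goals) {
    st <- objective_state(gl, 1)
    f <- function(v) as.numeric(goal_penalty(st, array(v, c(n, 1, 1)), geom, p))
    pen <- goal_penalty(st, array(dose_v, c(n, 1, 1)), geom, p)
    grad_full <- numeric(n)
    grad_full[attr(pen, "grad_index")] <- attr(pen, "grad")
    h <- 1e-5
    for (i in sample(n, 6)) {
      vp <- dose_v; vp[i] <- vp[i] + h
      vm <- dose_v; vm[i] <- vm[i] - h
      fd <- (f(vp) - f(vm)) / (2 * h)
      expect_equal(grad_full[i], fd, tolerance = 1e-5,
                   label = sprintf("%s grad[%d]", gl$goal_type, i))
    }
  }
})

test_that("falloff and conformality penalties respect their regions", {
  g <- small_patient()
  p <- chhip_protocol("instA")
  ids <- protocol_goal_ids(p)
  fo <- p$goals[[which(ids == "External|dose_falloff_external|")]]
  st <- objective_state(fo, fo$weighting_factor)
  # dose below every threshold: no penalty
  expect_equal(as.numeric(goal_penalty(st, array(0, g$grid_shape), g, p)), 0)
  thr <- falloff_threshold_map(fo, g, p)
  dose <- array(0, g$grid_shape)
  dose[!is.na(thr)] <- thr[!is.na(thr)] + 2
  pen <- goal_penalty(st, dose, g, p)
  expect_equal(as.numeric(pen), sum(rep(4, sum(!is.na(thr)))) / sum(!is.na(thr)))
  p1 <- p$goals[[which(ids == "PTV48|conformality_max|")]]
  stc <- objective_state(p1, 1000)
  shell <- conformality_shell(g$masks$PTV48, 1.5, g$masks$External, g$spacing)
  hot <- array(0, g$grid_shape); hot[shell] <- 50
  expect_equal(as.numeric(goal_penalty(stc, hot, g, p)),
               (50 - 46.8)^2)
})

test_that("composite objective is the weighted penalty sum", {
  p <- chhip_protocol("instA")
  geom <- toy_geometry(list(ROI = array(TRUE, c(4, 1, 1))))
  dose <- array(c(30, 30, 30, 10), c(4, 1, 1))
  gmean <- planning_goal("ROI", "P3", "mean_dose", 20, "Gy",
                         weighting_factor = 2)
  gmax <- planning_goal("ROI", "P3", "max_dose", 25, "Gy",
                        weighting_factor = 3)
  s1 <- objective_state(gmean, 2); s2 <- objective_state(gmax, 3)
  v1 <- as.numeric(goal_penalty(s1, dose, geom, p))
  v2 <- as.numeric(goal_penalty(s2, dose, geom, p))
  tot <- composite_objective(list(s1, s2), dose, geom, p)
  expect_equal(as.numeric(tot), 2 * v1 + 3 * v2)
  # doubling one weight changes the sum by exactly that goal's penalty
  s2b <- objective_state(gmax, 6)
  tot2 <- composite_objective(list(s1, s2b), dose, geom, p)
  expect_equal(as.numeric(tot2) - as.numeric(tot), 3 * v2)
  # all goals satisfied: zero
  expect_equal(as.numeric(composite_objective(list(s1, s2),
                                              array(1, c(4, 1, 1)), geom, p)), 0)
  expect_equal(names(attr(tot, "penalties")),
               c("ROI|mean_dose|", "ROI|max_dose|"))
})
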