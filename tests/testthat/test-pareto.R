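dims23 <- function() list(
  navigation_dimension("Rectum|mean_dose|", "weighting_factor",
                       c(2, 6, 18), label = "a"),
  navigation_dimension("Bladder|mean_dose|", "weighting_factor",
                       c(1, 3, 9), label = "b")
)

test_that("the combination grid is the cartesian product in documented order", {
  g <- build_grid(dims23())
  expect_equal(nrow(g), 9)
  # first dimension varies fastest
  expect_equal(g$a[1:3], c(2, 6, 18))
  expect_equal(g$b[1:3], rep(1, 3))
  one <- build_grid(list(navigation_dimension("Rectum|mean_dose|",
                                              "weighting_factor",
                                              c(1, 2, 4, 8, 16), label = "w")))
  expect_equal(one$w, c(1, 2, 4, 8, 16))
  big <- lapply(1:4, function(i)
    navigation_dimension("Rectum|mean_dose|", "weighting_factor",
                         c(1, 2, 3, 4, 5), label = paste0("d", i)))
  expect_warning(gb <- build_grid(big), "625")
  expect_equal(nrow(gb), 625)
  five <- c(big, list(navigation_dimension("Bladder|mean_dose|",
                                           "weighting_factor", c(1, 2),
                                           label = "d5")))
  w5 <- capture_warnings(gb5 <- build_grid(five))
  expect_match(w5, "dimensions", all = FALSE)
  expect_match(w5, "cardinality", all = FALSE)
  expect_equal(nrow(gb5), 1250)
  expect_error(build_grid(list()), "at least one")
  expect_error(navigation_dimension("x", "weighting_factor", c(3, 2)),
               "increasing")
  expect_error(navigation_dimension("x", "weighting_factor", 5), "2-7")
})

test_that("dataset generation covers the grid with shared configuration", {
  ds <- small_dataset()
  expect_equal(length(ds$plans), nrow(ds$grid))
  expect_equal(length(ds$plans), 4)
  # a vertex plan equals a plain autoplan under the committed protocol
  proto_v <- commit_calibration(ds, c(rwf = 58.4, fwf = 51))
  direct <- autoplan(small_patient(), proto_v, small_beam_config(),
                     fast_pbaio(), influence = small_influence())
  vert_row <- which(ds$grid$rwf == 58.4 & ds$grid$fwf == 51)
  expect_identical(ds$plans[[vert_row]]$dose, direct$dose)
})

test_that("single-value navigation of the protocol's own WF reproduces autoplan", {
  p <- chhip_protocol("instA")
  dims <- list(navigation_dimension("Rectum|mean_dose|", "weighting_factor",
                                    c(5.84, 58.4), label = "rwf"))
  ds <- generate_dataset(small_patient(), p, dims, small_beam_config(),
                         fast_pbaio(), influence = small_influence())
  expect_identical(ds$plans[[1]]$dose, small_plan()$dose)
})

test_that("multilinear interpolation satisfies its identities", {
  ds <- small_dataset()
  # vertex reproduction
  for (r in 1:4) {
    pos <- c(rwf = ds$grid$rwf[r], fwf = ds$grid$fwf[r])
    expect_lt(max(abs(interpolate(ds, pos) - ds$plans[[r]]$dose)), 1e-12)
  }
  # midpoint of a 1-D edge is the voxel-wise mean of the two corners
  mid <- interpolate(ds, c(rwf = (5.84 + 58.4) / 2, fwf = 51))
  expect_equal(mid, 0.5 * (ds$plans[[1]]$dose + ds$plans[[2]]$dose),
               tolerance = 1e-12)
  # interpolation commutes with linear functionals (mean over any mask)
  g <- small_patient()
  msk <- g$masks$Rectum
  pos <- c(rwf = 20, fwf = 130)
  cc <- pgap:::cell_coords(ds$dimensions, pgap:::resolve_position(ds, pos))
  manual <- 0
  for (b1 in 0:1) for (b2 in 0:1) {
    w <- (if (b1) cc$t[1] else 1 - cc$t[1]) * (if (b2) cc$t[2] else 1 - cc$t[2])
    row <- pgap:::grid_row_index(ds$dimensions, cc$lo + c(b1, b2))
    manual <- manual + w * mean(ds$plans[[row]]$dose[msk])
  }
  expect_equal(mean(interpolate(ds, pos)[msk]), manual, tolerance = 1e-12)
  # corner weights sum to one: interpolating a constant-dose dataset
  ds2 <- ds
  for (r in 1:4) ds2$plans[[r]]$dose <- array(7, g$grid_shape)
  expect_equal(interpolate(ds2, pos), array(7, g$grid_shape),
               tolerance = 1e-12)
  expect_true(all(interpolate(ds, pos) >= 0))
  expect_error(interpolate(ds, c(rwf = 1, fwf = 51)), "outside")
})

test_that("metric navigation reads the interpolated plan without re-optimising", {
  ds <- small_dataset()
  specs <- list(list(kind = "Dmean", roi = "Rectum"),
                list(kind = "HI", roi = "PTV60", subtract = TRUE),
                list(kind = "CI", roi = "PTV48", param = 45.6))
  vert <- navigate_metrics(ds, c(rwf = 5.84, fwf = 51), specs)
  g <- small_patient()
  expect_equal(vert$value[1], mean(ds$plans[[1]]$dose[g$masks$Rectum]),
               tolerance = 1e-12)
  # interpolated DVH remains a valid monotone non-increasing curve
  mid <- interpolate(ds, c(rwf = 20, fwf = 120))
  dvh <- cumulative_dvh(mid, g$masks$PTV60, bin_width = 0.25)
  expect_true(all(diff(dvh$volume) <= 0))
  expect_equal(dvh$volume[1], 1)
  # a reference position is evaluated alongside
  both <- navigate_metrics(ds, c(rwf = 20, fwf = 120), specs,
                           reference = c(rwf = 5.84, fwf = 51))
  expect_equal(both$reference, vert$value, tolerance = 1e-12)
  # evaluation at many positions is fast (no plan generation)
  t0 <- Sys.time()
  for (i in 1:100) {
    pos <- c(rwf = 5.84 + (i %% 10) * 5, fwf = 51 + i)
    invisible(navigate_metrics(ds, pos, specs[1]))
  }
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 2)
})

test_that("committing a calibration writes only the navigated parameters", {
  ds <- small_dataset()
  p0 <- chhip_protocol("instA")
  pc <- commit_calibration(ds, c(rwf = 30, fwf = 100))
  ids <- protocol_goal_ids(p0)
  for (i in seq_along(p0$goals)) {
    if (ids[i] == "Rectum|mean_dose|") {
      expect_equal(pc$goals[[i]]$weighting_factor, 30)
    } else if (ids[i] == "External|dose_falloff_external|") {
      expect_equal(pc$goals[[i]]$weighting_factor, 100)
    } else {
      expect_equal(pc$goals[[i]], p0$goals[[i]])
    }
  }
  # target-kind dimensions overwrite the target instead
  dims_t <- list(navigation_dimension("PTV60|min_dose|", "target",
                                      c(94, 98.7), label = "dmin"))
  ds_t <- list(dimensions = dims_t, grid = build_grid(dims_t),
               plans = list(NULL, NULL), protocol = p0,
               geometry = small_patient())
  class(ds_t) <- "pareto_dataset"
  pt <- commit_calibration(ds_t, c(dmin = 96))
  expect_equal(pt$goals[[which(ids == "PTV60|min_dose|")]]$target, 96)
})

test_that("calibration merging averages weighting factors", {
  p1 <- chhip_protocol("instA")
  p2 <- chhip_protocol("instA")
  ids <- protocol_goal_ids(p1)
  i <- which(ids == "Rectum|mean_dose|")
  p1$goals[[i]]$weighting_factor <- 2
  p2$goals[[i]]$weighting_factor <- 4
  m <- merge_calibrations(list(p1, p2))
  expect_equal(m$goals[[i]]$weighting_factor, 3)
  mg <- merge_calibrations(list(p1, p2), method = "geometric")
  expect_equal(mg$goals[[i]]$weighting_factor, sqrt(8))
  # permutation invariant; identical inputs unchanged
  expect_equal(merge_calibrations(list(p2, p1)), m)
  expect_equal(merge_calibrations(list(p1, p1)), p1)
  # structural mismatch rejected
  expect_error(merge_calibrations(list(p1, chhip_protocol("instB"))),
               "structure")
  p3 <- chhip_protocol("instA"); p3$goals[[2]]$target <- 97
  expect_error(merge_calibrations(list(p1, p3)), "targets disagree")
})
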