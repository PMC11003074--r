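# Shared small fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

small_anat <- function() list(grid_shape = c(32L, 32L, 32L), spacing = c(5, 5, 5))

small_patient <- function() cached("small_patient", function() {
  build_ptvs(generate_patient(1L, small_anat()))
})

small_beam_config <- function() beam_config(n_beams = 16L)

small_influence <- function() cached("small_influence", function() {
  build_influence_matrix(small_patient(), small_beam_config())
})

fast_pbaio <- function(...) pbaio_config(inner_iterations = 15L,
                                         outer_loops = 2L, ...)

small_plan <- function() cached("small_plan", function() {
  autoplan(small_patient(), chhip_protocol("instA"), small_beam_config(),
           fast_pbaio(), influence = small_influence())
})

# A tiny geometry wrapper around explicit masks (all voxels external).
toy_geometry <- function(masks, spacing = c(1, 1, 1)) {
  gs <- dim(masks[[1]])
  if (is.null(masks$External)) masks$External <- array(TRUE, gs)
  if (is.null(masks$Prostate)) masks$Prostate <- array(FALSE, gs)
  if (is.null(masks$Rectum)) masks$Rectum <- array(FALSE, gs)
  structure(list(grid_shape = as.integer(gs), spacing = spacing,
                 masks = masks, seed = 0L, anatomy_params = list()),
            class = "patient_geometry")
}

# Brute-force oracle for Dx%: midpoint order-statistic interpolation,
# written directly from the convention (independent of stats::quantile).
oracle_dose_at_volume <- function(doses, x) {
  d <- sort(doses, decreasing = TRUE)
  n <- length(d)
  f <- (seq_len(n) - 0.5) / n
  p <- x / 100
  if (p <= f[1]) return(d[1])
  if (p >= f[n]) return(d[n])
  i <- max(which(f <= p))
  d[i] + (d[i + 1] - d[i]) * (p - f[i]) / (f[i + 1] - f[i])
}

# Brute-force two-sided exact signed-rank p value by full enumeration.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  Wdist <- apply(combos, 1, function(s) sum(r[as.logical(s)]))
  min(1, 2 * min(mean(Wdist <= W + 1e-9), mean(Wdist >= W - 1e-9)))
}

small_dataset <- function() cached("small_dataset", function() {
  dims <- list(
    navigation_dimension("Rectum|mean_dose|", "weighting_factor",
                         c(5.84, 58.4), label = "rwf"),
    navigation_dimension("External|dose_falloff_external|",
                         "weighting_factor", c(51, 204), label = "fwf")
  )
  generate_dataset(small_patient(), chhip_protocol("instA"), dims,
                   small_beam_config(), fast_pbaio(),
                   influence = small_influence())
})
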