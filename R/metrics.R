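# DVH computation and plan-quality metrics.
#
# Dx% convention (documented, oracle-tested): voxel doses are sorted
# descending and assigned cumulative-volume positions (k - 0.5)/N; Dx% is
# linear interpolation between these order statistics, clamped to the max /
# min dose at the ends.  This equals stats::quantile(dose, 1 - x/100,
# type = 5), and gives e.g. D50% = 25 Gy for doses {10, 20, 30, 40}.

roi_doses <- function(dose, mask) {
  stopifnot(identical(dim(dose), dim(mask)))
  if (!any(mask)) stop("empty ROI mask")
  dose[mask]
}

#' Cumulative dose-volume histogram
#'
#' @param dose 3-D dose array (Gy).
#' @param mask logical ROI mask (nonempty, same shape).
#' @param bin_width histogram bin width in Gy.
#' @param roi optional ROI name stored on the curve.
#' @param spacing voxel spacing (mm) used for the absolute volume.
#' @return object of class `dvh_curve`: list with `dose` (bin edges, Gy),
#'   `volume` (fraction of ROI receiving at least that dose), `roi`,
#'   `volume_cc`.
#' @export
cumulative_dvh <- function(dose, mask, bin_width = 0.1, roi = "ROI",
                           spacing = c(1, 1, 1)) {
  d <- roi_doses(dose, mask)
  edges <- seq(0, max(d) + bin_width, by = bin_width)
  vol <- vapply(edges, function(b) mean(d >= b - 1e-12), numeric(1))
  structure(
    list(dose = edges, volume = vol, roi = roi,
         volume_cc = sum(mask) * voxel_volume_cc(spacing)),
    class = "dvh_curve"
  )
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("dvh_curve: %s (%.1f cc), %d bins to %.1f Gy\n",
              x$roi, x$volume_cc, length(x$dose), max(x$dose)))
  invisible(x)
}

#' Dose to the hottest x% of a structure (Dx%)
#'
#' @param dose,mask dose array and ROI mask.
#' @param x percentage volume, in (0, 100].
#' @return dose in Gy under the midpoint order-statistic interpolation
#'   convention described above.
#' @export
dose_at_volume <- function(dose, mask, x) {
  if (x <= 0 || x > 100) stop("x must be in (0, 100]")
  d <- roi_doses(dose, mask)
  as.numeric(stats::quantile(d, probs = 1 - x / 100, type = 5, names = FALSE))
}

#' Dose to the hottest v cm3 of a structure
#' @param dose,mask dose array and ROI mask.
#' @param v absolute volume in cm^3, in (0, ROI volume].
#' @param spacing spacing triple, mm.
#' @export
dose_at_abs_volume <- function(dose, mask, v, spacing) {
  vol <- sum(mask) * voxel_volume_cc(spacing)
  if (v <= 0 || v > vol) stop("v must be in (0, ROI volume]")
  dose_at_volume(dose, mask, 100 * v / vol)
}

#' Volume of a structure receiving at least a dose (Vd)
#' @param dose,mask dose array and ROI mask.
#' @param d dose level in Gy.
#' @param absolute if `TRUE` return cm^3, else percent of the ROI.
#' @param spacing spacing triple, mm (used for absolute volumes).
#' @export
volume_at_dose <- function(dose, mask, d, absolute = FALSE,
                           spacing = c(1, 1, 1)) {
  dd <- roi_doses(dose, mask)
  frac <- mean(dd >= d - 1e-12)
  if (absolute) frac * sum(mask) * voxel_volume_cc(spacing) else 100 * frac
}

#' Homogeneity index (D2% - D98%) / D50%
#'
#' The HI definition used throughout the package: 0 for a perfectly uniform
#' dose; computed on whatever mask is supplied (pass a subtraction-convention
#' reporting mask for nested PTVs, see [reporting_mask()]).
#' @param dose,mask dose array and ROI mask.
#' @export
homogeneity_index <- function(dose, mask) {
  d2 <- dose_at_volume(dose, mask, 2)
  d98 <- dose_at_volume(dose, mask, 98)
  d50 <- dose_at_volume(dose, mask, 50)
  (d2 - d98) / d50
}

#' Paddick conformity index
#'
#' CI = (TV_PIV)^2 / (TV * PIV), where TV is the target volume, PIV the
#' volume of the external contour receiving at least `reference_dose`, and
#' TV_PIV their intersection.  By default the reference isodose is 95% of the
#' PTV's nominal prescription (pass it explicitly).
#'
#' @param dose dose array.
#' @param ptv_mask target mask.
#' @param reference_dose reference isodose in Gy.
#' @param external_mask body mask over which the PIV is counted.
#' @return CI in `[0, 1]`; 0 (with a warning) when the PIV is empty.
#' @export
paddick_ci <- function(dose, ptv_mask, reference_dose, external_mask) {
  hot <- dose >= reference_dose - 1e-12
  piv <- sum(hot & external_mask)
  tv <- sum(ptv_mask)
  tv_piv <- sum(hot & ptv_mask)
  if (piv == 0) {
    warning("prescription isodose volume is empty; CI defined as 0")
    return(0)
  }
  tv_piv^2 / (tv * piv)
}

#' PTV reporting mask under the subtraction convention
#'
#' Higher-prescription PTVs are subtracted from lower-prescription PTVs when
#' reporting D98%, D2% and HI: `PTV57.5` maps to PTV57.5 minus PTV60, `PTV48`
#' to PTV48 minus (PTV57.5 and PTV60); `PTV60` is unchanged.
#' @param geometry a `patient_geometry` with PTVs built.
#' @param ptv_name one of `"PTV60"`, `"PTV57.5"`, `"PTV48"`.
#' @export
reporting_mask <- function(geometry, ptv_name) {
  m <- geometry$masks
  switch(ptv_name,
    "PTV60" = m$PTV60,
    "PTV57.5" = m$`PTV57.5` & !m$PTV60,
    "PTV48" = m$PTV48 & !(m$`PTV57.5` | m$PTV60),
    stop(sprintf("unknown PTV '%s'", ptv_name))
  )
}

# Resolve an ROI name against a geometry.  Supports the aliases
# "External"/"Patient Outline" and difference names such as
# "PTV57.5-PTV60" (set subtraction).
resolve_roi <- function(geometry, name) {
  masks <- geometry$masks
  alias <- function(nm) {
    if (nm %in% c("Patient Outline", "External", "Body")) return(masks$External)
    masks[[nm]]
  }
  m <- alias(name)
  if (!is.null(m)) return(m)
  if (grepl("-", name, fixed = TRUE)) {
    parts <- trimws(strsplit(name, "-", fixed = TRUE)[[1]])
    base <- alias(parts[1])
    if (is.null(base)) stop(sprintf("unknown ROI '%s'", parts[1]))
    for (p in parts[-1]) {
      sub <- alias(p)
      if (is.null(sub)) stop(sprintf("unknown ROI '%s'", p))
      base <- base & !sub
    }
    if (!any(base)) stop(sprintf("ROI '%s' resolves to an empty mask", name))
    return(base)
  }
  stop(sprintf("unknown ROI '%s'", name))
}

#' Clinical planning goal table (CHHIP-style)
#'
#' The prostate-only clinical goal panel used for plan evaluation: target
#' coverage and max-dose rules plus the rectum / bladder (and, for the
#' institution-B profile, femoral head and bowel) dose-volume limits.
#'
#' @param profile `"instA"` or `"instB"`.
#' @return data.frame with columns `roi`, `metric` (one of `D%`, `Dcc`,
#'   `V%`, `Vcc`), `param` (the x% / cm3 / Gy parameter), `limit`,
#'   `direction` (`">="` or `"<="`), `label`.
#' @export
chhip_clinical_goals <- function(profile = c("instA", "instB")) {
  profile <- match.arg(profile)
  g <- list(
    list("PTV60", "D%", 99, 0.95 * 60, ">="),
    list("PTV57.5", "D%", 99, 0.95 * 57.5, ">="),
    list("PTV48", "D%", 99, 0.95 * 48, ">="),
    list("PTV57.5-PTV60", "D%", 50, 57.5, ">="),
    list("PTV48-PTV57.5", "D%", 50, 48, ">="),
    list("PTV60", "D%", 1, 63.0, "<="),
    list("External", "Dcc", 1.8, 63.0, "<="),
    list("Rectum", "V%", 24.3, 80, "<="),
    list("Rectum", "V%", 32.4, 70, "<="),
    list("Rectum", "V%", 40.5, 60, "<="),
    list("Rectum", "V%", 48.6, 50, "<="),
    list("Rectum", "V%", 52.7, 30, "<="),
    list("Rectum", "V%", 56.8, 15, "<="),
    list("Rectum", "V%", 60.0, 3, "<="),
    list("Bladder", "V%", 40.5, 50, "<="),
    list("Bladder", "V%", 48.6, 25, "<="),
    list("Bladder", "V%", 60.0, 5, "<=")
  )
  if (profile == "instB") {
    g <- c(g, list(
      list("FemoralHead_L", "V%", 40.5, 50, "<="),
      list("FemoralHead_R", "V%", 40.5, 50, "<="),
      list("Bowel", "Vcc", 40.5, 17, "<=")
    ))
  }
  df <- do.call(rbind, lapply(g, function(r) {
    data.frame(roi = r[[1]], metric = r[[2]], param = r[[3]],
               limit = r[[4]], direction = r[[5]], stringsAsFactors = FALSE)
  }))
  df$label <- sprintf("%s %s%s", df$roi,
                      c("D%" = "D", "Dcc" = "D", "V%" = "V", "Vcc" = "V")[df$metric],
                      ifelse(df$metric == "D%", paste0(df$param, "%"),
                      ifelse(df$metric == "Dcc", paste0(df$param, "cc"),
                             paste0(df$param, "Gy"))))
  df
}

#' Evaluate a clinical goal table against a dose distribution
#'
#' @param dose dose array (Gy).
#' @param geometry a `patient_geometry` (PTVs built).
#' @param goals a goal data.frame as from [chhip_clinical_goals()].
#' @return the goal table with added `value` and `pass` columns.
#' @export
evaluate_goal_table <- function(dose, geometry, goals) {
  sp <- geometry$spacing
  vals <- vapply(seq_len(nrow(goals)), function(i) {
    mask <- resolve_roi(geometry, goals$roi[i])
    switch(goals$metric[i],
      "D%" = dose_at_volume(dose, mask, goals$param[i]),
      "Dcc" = dose_at_abs_volume(dose, mask, goals$param[i], sp),
      "V%" = volume_at_dose(dose, mask, goals$param[i]),
      "Vcc" = volume_at_dose(dose, mask, goals$param[i], absolute = TRUE,
                             spacing = sp),
      stop("unknown metric kind")
    )
  }, numeric(1))
  goals$value <- vals
  goals$pass <- ifelse(goals$direction == "<=", vals <= goals$limit + 1e-9,
                       vals >= goals$limit - 1e-9)
  goals
}

# Evaluate one metric spec (used by navigation and the study module).
# spec: list(kind, roi, param = NULL, subtract = FALSE)
#   kind in {D_percent, D_abs_volume, V_dose_percent, V_dose_abs,
#            Dmean, Dmax, D1_percent, HI, CI}
evaluate_metric <- function(dose, geometry, spec) {
  mask <- if (isTRUE(spec$subtract)) reporting_mask(geometry, spec$roi)
          else resolve_roi(geometry, spec$roi)
  sp <- geometry$spacing
  switch(spec$kind,
    D_percent = dose_at_volume(dose, mask, spec$param),
    D_abs_volume = dose_at_abs_volume(dose, mask, spec$param, sp),
    V_dose_percent = volume_at_dose(dose, mask, spec$param),
    V_dose_abs = volume_at_dose(dose, mask, spec$param, absolute = TRUE,
                                spacing = sp),
    Dmean = mean(dose[mask]),
    Dmax = max(dose[mask]),
    D1_percent = dose_at_volume(dose, mask, 1),
    HI = homogeneity_index(dose, mask),
    CI = paddick_ci(dose, resolve_roi(geometry, spec$roi), spec$param,
                    geometry$masks$External),
    stop(sprintf("unknown metric kind '%s'", spec$kind))
  )
}

metric_label <- function(spec) {
  suffix <- switch(spec$kind,
    D_percent = sprintf("D%g%%", spec$param),
    D_abs_volume = sprintf("D%gcc", spec$param),
    V_dose_percent = sprintf("V%gGy(%%)", spec$param),
    V_dose_abs = sprintf("V%gGy(cc)", spec$param),
    Dmean = "Dmean", Dmax = "Dmax", D1_percent = "D1%",
    HI = "HI", CI = "CI", spec$kind)
  paste0(spec$roi, " ", suffix)
}
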