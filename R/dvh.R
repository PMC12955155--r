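#' Cumulative dose-volume histogram
#'
#' Exact (sorting-based, unbinned) cumulative DVH: the volume fraction at
#' dose d is `|{i : d_i >= d}| / |mask|`. The curve starts at 1.0 and is
#' non-increasing in dose.
#'
#' @param dose 3D dose array (Gy) or numeric vector.
#' @param mask logical mask of the structure (same shape), nonempty.
#' @param name optional structure name carried in the result.
#' @return An object of class `dvh_curve`: list with `name`, `doses`
#'   (sorted decreasing), `volume` (fraction receiving at least that
#'   dose), `n`.
#' @export
compute_dvh <- function(dose, mask, name = "structure") {
  dv <- dose[mask]
  if (length(dv) == 0L) stop("compute_dvh: empty mask")
  ds <- sort(dv, decreasing = TRUE)
  n <- length(ds)
  structure(list(name = name, doses = ds, volume = seq_len(n) / n, n = n),
            class = "dvh_curve")
}

#' Dose at volume: Dx%
#'
#' The minimum dose received by the hottest x% of the structure, with
#' linear interpolation between adjacent sorted doses. `dose_at_volume`
#' is positively homogeneous in dose, which makes prescription
#' normalization by a global scale exact.
#'
#' @param dvh a `dvh_curve`.
#' @param x volume percentage in (0, 100].
#' @return Dx (Gy).
#' @export
dose_at_volume <- function(dvh, x) {
  if (x <= 0 || x > 100) stop("dose_at_volume: x must be in (0, 100]")
  q <- x / 100
  n <- dvh$n
  if (q <= 1 / n) return(dvh$doses[1])
  stats::approx(dvh$volume, dvh$doses, xout = q, rule = 2)$y
}

#' Volume at dose: Vd
#'
#' Fraction of the structure receiving at least `d` Gy, by exact counting
#' (reported in percent).
#'
#' @param dvh a `dvh_curve`.
#' @param d dose threshold (Gy), >= 0.
#' @return Vd in percent of the structure volume.
#' @export
volume_at_dose <- function(dvh, d) {
  if (d < 0) stop("volume_at_dose: d must be >= 0")
  100 * sum(dvh$doses >= d) / dvh$n
}

#' Mean structure dose
#' @param dvh a `dvh_curve`.
#' @export
mean_dose <- function(dvh) mean(dvh$doses)

#' Homogeneity index
#'
#' ICRU-83 form: `HI = (D2% - D98%) / D50%`; 0 for a perfectly uniform
#' target dose.
#'
#' @param dvh the PTV `dvh_curve`.
#' @return HI, or `NaN` with a warning when D50% is zero.
#' @export
homogeneity_index <- function(dvh) {
  d50 <- dose_at_volume(dvh, 50)
  if (d50 <= 0) {
    warning("homogeneity_index: D50% is zero; HI undefined")
    return(NaN)
  }
  (dose_at_volume(dvh, 2) - dose_at_volume(dvh, 98)) / d50
}

#' Paddick conformity index
#'
#' `CI = |TV intersect PIV|^2 / (|TV| * |PIV|)` where PIV is the set of
#' voxels at or above the isodose level; CI is in [0, 1] with 1 for
#' perfect conformity.
#'
#' @param dose 3D dose array (Gy).
#' @param ptv_mask logical target mask (TV).
#' @param level isodose level (Gy) defining the prescription isodose
#'   volume, > 0. Conventionally 100% (default here) or 95% of the
#'   prescription dose.
#' @return CI in [0, 1]; 0 with a warning when the PIV is empty.
#' @export
paddick_ci <- function(dose, ptv_mask, level) {
  if (level <= 0) stop("paddick_ci: level must be > 0")
  piv <- dose >= level
  n_piv <- sum(piv)
  if (n_piv == 0L) {
    warning("paddick_ci: empty prescription isodose volume; CI = 0")
    return(0)
  }
  n_tv <- sum(ptv_mask)
  n_ov <- sum(piv & ptv_mask)
  n_ov^2 / (n_tv * n_piv)
}

#' Full metric set for one plan
#'
#' Per-structure D2%, D50%, D98%, Dmean, V95% (volume at 95% of the
#' prescription) plus PTV HI and Paddick CI.
#'
#' @param dose 3D dose array (Gy).
#' @param structures a [structure_set()].
#' @param d_pres prescription dose (Gy).
#' @param ci_level_frac CI isodose level as a fraction of `d_pres`,
#'   default 1 (100%).
#' @return An object of class `plan_metrics`: nested list, one element
#'   per structure, plus `HI` and `CI`.
#' @export
plan_metrics <- function(dose, structures, d_pres, ci_level_frac = 1) {
  out <- list(structures = list())
  for (nm in names(structures$masks)) {
    msk <- structures$masks[[nm]]
    if (!any(msk)) next
    dvh <- compute_dvh(dose, msk, nm)
    out$structures[[nm]] <- list(
      D2 = dose_at_volume(dvh, 2),
      D50 = dose_at_volume(dvh, 50),
      D98 = dose_at_volume(dvh, 98),
      Dmean = mean_dose(dvh),
      V95 = volume_at_dose(dvh, 0.95 * d_pres)
    )
  }
  ptv_dvh <- compute_dvh(dose, structures$masks$PTV, "PTV")
  out$HI <- homogeneity_index(ptv_dvh)
  out$CI <- paddick_ci(dose, structures$masks$PTV, ci_level_frac * d_pres)
  out$d_pres <- d_pres
  structure(out, class = "plan_metrics")
}
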