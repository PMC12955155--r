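#' Optimization configuration
#'
#' @param max_iter iteration cap, default 500.
#' @param tol relative objective-decrease tolerance, default 1e-5.
#' @param initializer "uniform" (scaled so the mean PTV dose matches the
#'   first PTV objective's reference dose) or "zero".
#' @param seed optional RNG seed (recorded; the solver itself is
#'   deterministic).
#' @return An object of class `optimization_config`.
#' @export
optimization_config <- function(max_iter = 500, tol = 1e-5,
                                initializer = c("uniform", "zero"),
                                seed = NULL) {
  initializer <- match.arg(initializer)
  if (max_iter < 1 || tol <= 0) stop("optimization_config: invalid limits")
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 initializer = initializer, seed = seed),
            class = "optimization_config")
}

#' Fluence-map optimization by projected gradient descent
#'
#' Minimizes the composite dose objective over nonnegative beamlet
#' weights with projected gradient descent (projection `w <- max(w, 0)`)
#' and Armijo backtracking line search. Accepted objective values are
#' monotone non-increasing; the run is deterministic for a fixed
#' configuration.
#'
#' @param A dose-influence operator (nvox x nb).
#' @param objectives list of [objective_spec()]; must contain at least one
#'   `uniform` or `min_dose` objective on the PTV.
#' @param structures a [structure_set()].
#' @param cfg an [optimization_config()].
#' @return An object of class `plan`: list with `weights`, `dose`
#'   (3D array if `structures` carries a grid, else vector), `objective`
#'   (final value), `trace` (objective per accepted iterate),
#'   `iterations`, `converged`, and `scale` (1 until normalization).
#' @export
optimize_plan <- function(A, objectives, structures,
                          cfg = optimization_config()) {
  check_objectives(objectives, structures)
  ptv_obj <- Filter(function(o) o$structure == "PTV" &&
                      o$type %in% c("uniform", "min_dose"), objectives)
  if (length(ptv_obj) == 0L)
    stop("optimize_plan: need a uniform or min_dose objective on the PTV")

  nb <- ncol(A)
  if (nb < 1L) stop("optimize_plan: influence matrix has no beamlets")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  w <- rep(0, nb)
  if (cfg$initializer == "uniform") {
    ptv <- which(structures$masks$PTV)
    d1 <- as.numeric(A %*% rep(1, nb))
    mpd <- mean(d1[ptv])
    if (mpd > 0) w <- rep(ptv_obj[[1]]$d_ref / mpd, nb)
  }

  ob <- objective_value(A, w, objectives, structures)
  fw <- ob$value
  trace <- fw
  alpha <- 1 / max(sum(ob$gradient^2), .Machine$double.eps) # initial scale
  # a second calibration: unit step relative to gradient magnitude
  gn <- sqrt(sum(ob$gradient^2))
  if (gn > 0) alpha <- max(alpha, mean(abs(w)) / gn, 1e-8 / gn)
  converged <- FALSE
  it <- 0L
  c_armijo <- 1e-4

  while (it < cfg$max_iter) {
    it <- it + 1L
    g <- ob$gradient
    accepted <- FALSE
    for (ls in 1:60) {
      w_new <- pmax(0, w - alpha * g)
      step <- w_new - w
      ob_new <- objective_value(A, w_new, objectives, structures)
      if (!is.finite(ob_new$value))
        stop("optimize_plan: non-finite objective encountered")
      if (ob_new$value <= fw + c_armijo * sum(g * step)) {
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted || sum(step^2) == 0) { # stationary (projected) point
      converged <- TRUE
      break
    }
    rel_drop <- (fw - ob_new$value) / max(fw, .Machine$double.eps)
    w <- w_new
    fw <- ob_new$value
    ob <- ob_new
    trace <- c(trace, fw)
    alpha <- alpha * 1.5 # tentative growth, backtracking shrinks as needed
    if (rel_drop < cfg$tol) {
      converged <- TRUE
      break
    }
  }

  dose <- array(as.numeric(A %*% w), dim = structures$grid$dims)
  structure(list(weights = w, dose = dose, objective = fw, trace = trace,
                 iterations = it, converged = converged, scale = 1),
            class = "plan")
}

#' @export
print.plan <- function(x, ...) {
  cat(sprintf(
    "plan: %d beamlets, objective %.6g after %d iterations%s, scale %.4g\n",
    length(x$weights), x$objective, x$iterations,
    if (x$converged) " (converged)" else "", x$scale))
  invisible(x)
}

#' Normalize a plan to the prescription
#'
#' Rescales dose (and weights, if a plan is supplied) by
#' `s = D_pres / D_mode(PTV)` so that after scaling the selected PTV
#' percentile dose equals the prescription exactly — exact because the
#' dose operator is linear.
#'
#' @param plan_or_dose a `plan` or a 3D dose array.
#' @param ptv_mask logical PTV mask.
#' @param mode "D95" or "D50".
#' @param d_pres prescription dose (Gy) > 0.
#' @return Same shape as the input: a rescaled `plan` (with `scale`
#'   updated) or a list with `dose` and `scale`.
#' @export
normalize_plan <- function(plan_or_dose, ptv_mask,
                           mode = c("D95", "D50"), d_pres) {
  mode <- match.arg(mode)
  stopifnot(d_pres > 0)
  dose <- if (inherits(plan_or_dose, "plan")) plan_or_dose$dose
          else plan_or_dose
  dv <- dose[ptv_mask]
  if (length(dv) == 0L || max(dv) <= 0)
    stop("normalize_plan: zero PTV dose")
  x <- if (mode == "D95") 95 else 50
  dmode <- dose_at_volume(compute_dvh(dose, ptv_mask), x)
  if (dmode <= 0) stop("normalize_plan: D", x, "% of the PTV is zero")
  s <- d_pres / dmode
  if (inherits(plan_or_dose, "plan")) {
    plan_or_dose$weights <- plan_or_dose$weights * s
    plan_or_dose$dose <- plan_or_dose$dose * s
    plan_or_dose$scale <- plan_or_dose$scale * s
    plan_or_dose
  } else {
    list(dose = dose * s, scale = s)
  }
}
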