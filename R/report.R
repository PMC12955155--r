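#' Plan comparison report
#'
#' Tabulates DVH metrics for one or more plans sharing a grid, flags the
#' best plan per metric, and (for >= 2 plans) adds pairwise differences
#' to the first plan. Missing structures in a plan are recorded as `NA`,
#' not an error.
#'
#' @param doses named list of 3D dose arrays (one per plan).
#' @param structures a [structure_set()].
#' @param d_pres prescription dose (Gy) for V95%/CI levels.
#' @param metrics character subset of `c("D2","D50","D98","Dmean","V95")`.
#' @param ci_level_frac CI isodose fraction, default 1.
#' @param out_prefix optional path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @return data.frame with columns structure, metric, one column per
#'   plan, `best` (name of the best plan for that row; lower is better
#'   for OAR rows, target rows use distance to the ideal), and
#'   `diff_<plan>` columns versus the first plan when applicable.
#' @export
plan_report <- function(doses, structures, d_pres,
                        metrics = c("D2", "D50", "D98", "Dmean", "V95"),
                        ci_level_frac = 1, out_prefix = NULL) {
  stopifnot(is.list(doses), length(doses) >= 1)
  if (is.null(names(doses)) || any(names(doses) == ""))
    stop("plan_report: doses must be a named list")
  pm <- lapply(doses, plan_metrics, structures = structures,
               d_pres = d_pres, ci_level_frac = ci_level_frac)

  rows <- list()
  for (nm in names(structures$masks)) {
    for (met in metrics) {
      vals <- vapply(pm, function(m) {
        s <- m$structures[[nm]]
        if (is.null(s)) NA_real_ else s[[met]]
      }, numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(structure = nm, metric = met, t(vals))
    }
  }
  for (met in c("HI", "CI")) {
    vals <- vapply(pm, function(m) m[[met]], numeric(1))
    rows[[length(rows) + 1L]] <-
      data.frame(structure = "PTV", metric = met, t(vals))
  }
  tab <- do.call(rbind, rows)
  names(tab)[-(1:2)] <- names(doses)

  higher_better <- function(structure, metric) {
    structure == "PTV" && metric %in% c("V95", "CI")
  }
  tab$best <- vapply(seq_len(nrow(tab)), function(i) {
    v <- as.numeric(tab[i, names(doses)])
    if (all(is.na(v))) return(NA_character_)
    pick <- if (higher_better(tab$structure[i], tab$metric[i]))
      which.max(v) else which.min(v)
    names(doses)[pick]
  }, character(1))

  if (length(doses) >= 2) {
    ref <- names(doses)[1]
    for (other in names(doses)[-1]) {
      tab[[paste0("diff_", other)]] <- tab[[other]] - tab[[ref]]
    }
  }
  rownames(tab) <- NULL

  if (!is.null(out_prefix)) {
    utils::write.csv(tab, paste0(out_prefix, ".csv"), row.names = FALSE)
    jsonlite::write_json(tab, paste0(out_prefix, ".json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = I(17),
                         na = "null")
  }
  tab
}
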