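#' Load a run configuration
#'
#' Reads a pipeline configuration from JSON (always available) or YAML
#' (when the `yaml` package is installed), or passes a list through.
#' See [run_pipeline()] for the schema.
#'
#' @param config list, or path to a `.json` / `.yaml` / `.yml` file.
#' @return configuration list.
#' @export
load_run_config <- function(config) {
  if (is.list(config)) return(config)
  stopifnot(is.character(config), length(config) == 1L)
  if (!file.exists(config)) stop("config file not found: ", config)
  if (grepl("\\.ya?ml$", config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the 'yaml' package; use JSON instead")
    yaml::read_yaml(config)
  } else {
    jsonlite::fromJSON(config, simplifyDataFrame = FALSE)
  }
}

cfg_get <- function(cfg, key, default) {
  v <- cfg[[key]]
  if (is.null(v)) default else v
}

parse_objectives <- function(objs) {
  lapply(objs, function(o)
    objective_spec(o$structure, o$type, o$d_ref,
                   weight = if (is.null(o$weight)) 1 else o$weight,
                   v_ref = o$v_ref))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "': ", conditionMessage(e),
         call. = FALSE))
}

#' Run the two-stage planning pipeline
#'
#' Executes the full workflow — synthetic phantom, spot lattice, beamlet
#' catalog, per-beamlet Monte Carlo dose (stage 1), fluence-map
#' optimization, normalization and DVH evaluation (stage 2) — from a
#' single configuration, writing every artifact with provenance (seed,
#' config hash, package version). Reruns with the same configuration and
#' seed reproduce the dose deterministically.
#'
#' Configuration keys (all optional except `case`):
#' \describe{
#'   \item{case}{template name ("B","H","L1","L2","P1","P2","F") or an
#'     inline template list.}
#'   \item{scenario}{"lateral" (default), "central" or "bilateral".}
#'   \item{phantom}{body_radius, body_length, ptv_radius, voxel_size.}
#'   \item{beams}{lens_radius, lens_to_iso, optional `angles` override.}
#'   \item{lattice}{`m`, `k` overrides of the template.}
#'   \item{transport}{step, e_cut, n_histories, n_batches.}
#'   \item{tau}{influence-matrix pruning threshold, default 1e-3.}
#'   \item{objectives}{list of objective dicts; default: uniform PTV
#'     objective at the prescription plus max_dose 0 on every OAR.}
#'   \item{optimization}{max_iter, tol.}
#'   \item{seed}{global seed (default 1), fanned out per beamlet.}
#'   \item{out_dir}{output directory; omit to skip writing.}
#' }
#'
#' @param config list or config file path (see [load_run_config()]).
#' @return list with `phantom`, `structures`, `lattice`, `catalog`,
#'   `influence`, `plan` (normalized), `metrics`, `report`, `template`,
#'   and `provenance`.
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)

  tpl <- stage("validate", {
    if (is.null(cfg$case)) stop("missing 'case'")
    if (is.character(cfg$case)) case_templates(cfg$case)
    else case_template(cfg_get(cfg$case, "name", "custom"),
                       cfg$case$beam_angles,
                       energy = cfg_get(cfg$case, "energy", 250),
                       margin = cfg_get(cfg$case, "margin", 0.5),
                       spacing_factor = cfg_get(cfg$case, "spacing_factor", 0.36),
                       d_pres = cfg$case$d_pres,
                       n_fractions = cfg_get(cfg$case, "n_fractions", 1),
                       normalization = cfg_get(cfg$case, "normalization", "D95"))
  })
  seed <- cfg_get(cfg, "seed", 1L)
  objectives <- stage("validate", {
    if (is.null(cfg$objectives)) NULL
    else {
      objs <- parse_objectives(cfg$objectives)
      ok <- any(vapply(objs, function(o)
        o$structure == "PTV" && o$type %in% c("uniform", "min_dose"),
        logical(1)))
      if (!ok) stop("configuration has no uniform/min_dose PTV objective")
      objs
    }
  })

  out_dir <- cfg$out_dir
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(seed = seed, config_hash = config_hash(cfg),
               package_version = as.character(utils::packageVersion("fvheeplan")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  emit <- function(name, writer) if (!is.null(out_dir)) writer(file.path(out_dir, name))
  emit("config.json", function(p)
    jsonlite::write_json(c(cfg, list(provenance = prov)), p,
                         auto_unbox = TRUE, digits = I(17), null = "null"))

  pc <- cfg_get(cfg, "phantom", list())
  case <- stage("phantom", make_planning_case(
    tpl, scenario = cfg_get(cfg, "scenario", "lateral"),
    body_radius = cfg_get(pc, "body_radius", 8),
    body_length = cfg_get(pc, "body_length", 16),
    ptv_radius = cfg_get(pc, "ptv_radius", 1.5),
    voxel_size = cfg_get(pc, "voxel_size", 0.25)))

  lat_cfg <- cfg_get(cfg, "lattice", list())
  lattice <- stage("spots", generate_diamond_grid(
    case$structures$masks$PTV, case$phantom$grid,
    m = cfg_get(lat_cfg, "m", tpl$margin),
    k = cfg_get(lat_cfg, "k", tpl$spacing_factor)))
  emit("spots.csv", function(p)
    utils::write.csv(as.data.frame(lattice$positions), p, row.names = FALSE))
  emit("spots.json", function(p)
    jsonlite::write_json(list(k = lattice$k, m = lattice$m,
                              anchor = lattice$anchor,
                              positions = lattice$positions,
                              provenance = prov),
                         p, auto_unbox = TRUE, digits = I(17)))

  bc <- cfg_get(cfg, "beams", list())
  angles <- cfg_get(bc, "angles", tpl$beam_angles)
  beams <- lapply(angles, function(a)
    beam_config(a, lens_radius = cfg_get(bc, "lens_radius", 5),
                lens_to_iso = cfg_get(bc, "lens_to_iso", 50),
                energy = tpl$energy))
  catalog <- stage("beamlets", build_catalog(lattice, beams))

  tc <- cfg_get(cfg, "transport", list())
  tcfg <- transport_config(step = cfg_get(tc, "step", 0.1),
                           e_cut = cfg_get(tc, "e_cut", 2),
                           n_histories = cfg_get(tc, "n_histories", 1e4),
                           n_batches = cfg_get(tc, "n_batches", 20),
                           seed = seed)
  infl <- stage("influence", compute_influence_matrix(
    case$phantom, catalog, tcfg, tau = cfg_get(cfg, "tau", 1e-3)))
  emit("influence.txt", function(p) write_influence_matrix(infl, p))

  if (is.null(objectives)) {
    objectives <- c(
      list(objective_spec("PTV", "uniform", tpl$d_pres, weight = 100)),
      lapply(setdiff(names(case$structures$masks), c("PTV", "BODY")),
             function(nm) objective_spec(nm, "max_dose", 0, weight = 1)))
  }
  oc <- cfg_get(cfg, "optimization", list())
  ocfg <- optimization_config(max_iter = cfg_get(oc, "max_iter", 200),
                              tol = cfg_get(oc, "tol", 1e-5), seed = seed)
  plan <- stage("optimize", optimize_plan(infl$A, objectives,
                                          case$structures, ocfg))
  plan <- stage("normalize", normalize_plan(
    plan, case$structures$masks$PTV, mode = tpl$normalization,
    d_pres = tpl$d_pres))
  emit("plan.json", function(p)
    jsonlite::write_json(list(weights = plan$weights, scale = plan$scale,
                              objective = plan$objective,
                              trace = plan$trace, provenance = prov),
                         p, auto_unbox = TRUE, digits = I(17)))
  emit("dose.nrrd", function(p) {
    dp <- phantom(case$phantom$grid, plan$dose)
    write_volume(dp, p)
  })

  metrics <- stage("evaluate", plan_metrics(plan$dose, case$structures,
                                            d_pres = tpl$d_pres))
  emit("metrics.json", function(p)
    jsonlite::write_json(c(unclass(metrics), list(provenance = prov)), p,
                         auto_unbox = TRUE, digits = I(17)))
  report <- stage("evaluate", plan_report(
    stats::setNames(list(plan$dose), "fVHEE"), case$structures,
    d_pres = tpl$d_pres,
    out_prefix = if (is.null(out_dir)) NULL else file.path(out_dir, "report")))

  list(phantom = case$phantom, structures = case$structures,
       lattice = lattice, catalog = catalog, influence = infl,
       plan = plan, metrics = metrics, report = report, template = tpl,
       provenance = prov)
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = I(17),
                              null = "null"), tf)
  unname(tools::md5sum(tf))
}

#' Water-box characterization bundle
#'
#' Runs the characterization grid — energies 50/150/250 MeV crossed with
#' focal lengths 10/15/20 cm, magnetic lens of radius 5 cm placed 7 cm
#' before a water box — and writes one depth-dose CSV (and lateral
#' profile CSV) per combination. With `n_histories = 0` only file
#' skeletons (headers) are written.
#'
#' @param out_dir output directory.
#' @param energies energies in MeV, default `c(50, 150, 250)`.
#' @param focal_lengths focal lengths in cm (from the lens plane),
#'   default `c(10, 15, 20)`.
#' @param lens_gap lens-to-surface distance (cm), default 7.
#' @param box_size water box side lengths (cm).
#' @param voxel_size scoring voxel size (cm), default 0.25.
#' @param n_histories histories per combination, default 2e4 (fast);
#'   characterization-grade runs use 1e6.
#' @param seed RNG seed.
#' @return invisible list of `beam_characterization` results (NULL
#'   entries for a dry run), named `E<energy>_f<focal length>`.
#' @export
characterize_water <- function(out_dir, energies = c(50, 150, 250),
                               focal_lengths = c(10, 15, 20),
                               lens_gap = 7, box_size = c(20, 25, 20),
                               voxel_size = 0.25, n_histories = 2e4,
                               seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # box front face at the isocenter plane y = 0; lens at y = lens_gap
  box <- make_water_box(box_size, voxel_size,
                        center = c(0, -box_size[2] / 2, 0))
  res <- list()
  for (E in energies) for (f in focal_lengths) {
    tag <- sprintf("E%g_f%g", E, f)
    sub <- file.path(out_dir, tag)
    dir.create(sub, showWarnings = FALSE)
    if (n_histories < 1) { # dry run: skeletons only
      utils::write.csv(data.frame(depth = numeric(0), dose = numeric(0),
                                  rel_unc = numeric(0)),
                       file.path(sub, "depth_dose.csv"), row.names = FALSE)
      utils::write.csv(data.frame(offset_cm = numeric(0), dose = numeric(0),
                                  depth_cm = numeric(0),
                                  depth_label = character(0)),
                       file.path(sub, "lateral_profiles.csv"),
                       row.names = FALSE)
      res[[tag]] <- NULL
      next
    }
    beam <- beam_config(0, lens_radius = 5, lens_to_iso = lens_gap,
                        energy = E)
    bl <- beamlet_spec(beam, c(0, lens_gap - f, 0)) # focus f from the lens
    cfg <- transport_config(n_histories = n_histories, seed = seed)
    res[[tag]] <- characterize(bl, box, cfg, out_dir = sub)
  }
  invisible(res)
}
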