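# Two-stage pipeline orchestration: backbone NOE/J population fit, then
# the side-chain RDC tensor/population fit, classification, energetics
# and a consolidated machine-readable report.

#' Read a run configuration from YAML
#'
#' @param path YAML file. Recognised blocks: `pool` (path), `noe`
#'   (buildup CSV), `j` (CSV), `rdc` (CSV), `seed`, `output_dir`,
#'   `karplus` (A/B/C/phase), `fit` (lambda_sum/max_iter/tol),
#'   `energetics` (T/convention/reference_folded_fraction), `enrich`
#'   (n), `generator` (fields of [generator_config()], used to derive
#'   classification criteria and, for a pure demo run, to simulate the
#'   inputs).
#' @return A validated run-config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' Validate a run configuration list
#'
#' @param cfg List as read from YAML (or built in code).
#' @return The list, with defaults filled in; errors name the offending
#'   key.
#' @export
validate_run_config <- function(cfg) {
  known <- c("pool", "noe", "j", "rdc", "seed", "output_dir", "karplus",
             "fit", "energetics", "enrich", "generator")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("validation error: unknown config key(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (key in c("pool", "noe", "j", "rdc")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("validation error: ", key, " file not found: ", cfg[[key]],
           call. = FALSE)
    }
  }
  kp <- cfg$karplus
  cfg$karplus_obj <- if (is.null(kp)) karplus_coefficients() else
    karplus_coefficients(A = kp$A %||% 6.51, B = kp$B %||% -1.76,
                         C = kp$C %||% 1.60, phase = kp$phase %||% -60)
  g <- cfg$generator
  cfg$generator_obj <- generator_config(
    n_residues = g$n_residues %||% 12L,
    turn_position = g$turn_position %||% 6L,
    n_folded = g$n_folded %||% 10L,
    n_unfolded = g$n_unfolded %||% 10L,
    folded_fraction = g$folded_fraction %||% 0.5,
    dihedral_jitter = g$dihedral_jitter %||% 5,
    seed = cfg$seed %||% g$seed,
    donor_element = g$donor_element %||% "Br",
    acceptor_element = g$acceptor_element %||% "O")
  cfg$fit <- cfg$fit %||% list()
  cfg$energetics <- cfg$energetics %||% list()
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the backbone stage: classification and NOE/J population fit
#'
#' Loads the conformer pool, classifies every conformer against the
#' hairpin criteria, reduces NOE buildups to calibrated distances, fits
#' the populations by NNLS and reports the folded fraction. Backbone
#' conformations are determined first; side-chain geometry is a
#' separate, subsequent stage.
#'
#' @param cfg A run config from [read_run_config()] /
#'   [validate_run_config()].
#' @param pool Optional in-memory [conformer_pool] overriding
#'   `cfg$pool`.
#' @param noe,j Optional in-memory tables overriding the file paths.
#' @return Stage report list: `populations`, `folded_percent`,
#'   `folded_labels`, `rmsd_by_kind`, `condition_flag`, `warnings`,
#'   `classification` (per-conformer table), `pool`.
#' @export
run_backbone_stage <- function(cfg, pool = NULL, noe = NULL, j = NULL) {
  cfg <- validate_run_config(cfg[setdiff(names(cfg),
                                         c("karplus_obj", "generator_obj"))])
  warns <- character()
  if (is.null(pool)) {
    if (is.null(cfg$pool)) {
      stop("backbone stage: no pool given", call. = FALSE)
    }
    pool <- read_conformer_pool(cfg$pool)
  }
  crit <- criteria_for_config(cfg$generator_obj)
  cls <- classify_pool(pool, crit)
  if (is.null(noe) && !is.null(cfg$noe)) noe <- read_restraint_table(cfg$noe)
  if (is.null(j) && !is.null(cfg$j)) j <- read_restraint_table(cfg$j)
  if (is.null(j)) {
    warns <- c(warns, "no J table given; running NOE-only backbone fit")
    message("backbone stage: no J table given, fitting NOEs only")
  }
  if (is.null(noe)) {
    stop("backbone stage: no NOE table given", call. = FALSE)
  }
  noe_dist <- if (any(grepl("^I_\\d+$", names(noe))))
    noe_distances_from_buildups(noe) else noe
  m <- build_design_matrix(pool, noe = noe_dist, j = j,
                           k = cfg$karplus_obj)
  fit <- fit_populations(m, lambda_sum = cfg$fit$lambda_sum)
  folded <- cls$folded
  list(populations = fit$populations,
       folded_percent = folded_fraction(fit, folded),
       folded_labels = folded,
       rmsd_by_kind = as.list(fit$rmsd_by_kind),
       condition_flag = fit$condition_flag,
       warnings = warns,
       classification = cls,
       design = m,
       pool = pool)
}

#' Run the side-chain stage: RDC tensor and population fit
#'
#' Optionally enriches the pool with halogen-bond-constrained
#' conformers, then fits the alignment tensor and conformer populations
#' to the RDC table and reports the halogen-bonded population with Q/CN
#' diagnostics (CN >= 30 and Q >= 0.4 are flagged).
#'
#' @param cfg A run config.
#' @param backbone Report from [run_backbone_stage()].
#' @param rdc Optional in-memory RDC table overriding `cfg$rdc`.
#' @return Stage report list: `populations`, `xb_percent`, `q`, `cn`,
#'   `q_class`, `cn_unreliable`, `flags`, `tensor`, `pool`.
#' @export
run_sidechain_stage <- function(cfg, backbone, rdc = NULL) {
  cfg <- validate_run_config(cfg[setdiff(names(cfg),
                                         c("karplus_obj", "generator_obj"))])
  pool <- backbone$pool
  gen <- cfg$generator_obj
  if (!is.null(cfg$enrich) && (cfg$enrich$n %||% 0) > 0) {
    pool <- enrich_with_xb_conformers(pool, gen, n = cfg$enrich$n,
                                      seed = cfg$seed %||% gen$seed)
  }
  if (is.null(rdc)) {
    if (is.null(cfg$rdc)) {
      stop("side-chain stage: no RDC table given", call. = FALSE)
    }
    rdc <- read_restraint_table(cfg$rdc)
  }
  if (!"d_obs" %in% names(rdc)) {
    if (!all(c("t_strong", "t_weak") %in% names(rdc))) {
      stop("side-chain stage: RDC table needs d_obs or t_strong/t_weak",
           call. = FALSE)
    }
    rdc$d_obs <- rdc_from_couplings(rdc$t_strong, rdc$t_weak)
  }
  fit <- fit_tensor_and_populations(
    pool, rdc,
    max_iter = cfg$fit$max_iter %||% 200,
    tol = cfg$fit$tol %||% 1e-6,
    lambda_sum = cfg$fit$lambda_sum)
  sel <- xb_selectors(pool)
  xcrit <- xb_criteria(strict = FALSE)
  xb_labels <- vapply(pool$conformers, function(cf)
    classify_xb(cf, sel$donor, sel$acceptor, crit = xcrit), logical(1))
  flags <- character()
  if (fit$cn_unreliable) flags <- c(flags, "CN >= 30: tensor unreliable")
  if (fit$q >= 0.4) flags <- c(flags, "Q >= 0.4: poor fit")
  list(populations = fit$populations,
       xb_percent = xb_population(fit, xb_labels),
       xb_labels = xb_labels,
       q = fit$q, cn = fit$cn, q_class = fit$q_class,
       cn_unreliable = fit$cn_unreliable,
       flags = flags,
       tensor = fit$tensor$s,
       pool = pool)
}

#' Run the full two-stage analysis
#'
#' Backbone fit, side-chain RDC fit, energetics and the consolidated
#' report. With file inputs in the config the stages read them; a
#' `generator` block plus `seed` and no file inputs runs the packaged
#' synthetic end-to-end demo (simulate, then fit).
#'
#' @param cfg A run config (list or path to YAML).
#' @param write_report Write `report.json` into `cfg$output_dir`
#'   (default `TRUE` when `output_dir` is set).
#' @return A run report list: `folded_percent`, `xb_percent`,
#'   `populations` (both stages), `q`, `cn`, `flags`, `energetics`,
#'   `provenance`.
#' @export
run_full <- function(cfg, write_report = !is.null(cfg$output_dir)) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_run_config(cfg[setdiff(names(cfg),
                                         c("karplus_obj", "generator_obj"))])
  pool <- NULL; noe <- NULL; j <- NULL; rdc <- NULL
  simulated <- FALSE
  if (is.null(cfg$pool)) {
    # synthetic demo: simulate inputs from the generator block
    simulated <- TRUE
    gen <- cfg$generator_obj
    if (is.null(gen$seed)) {
      stop("validation error: seed required for a synthetic run",
           call. = FALSE)
    }
    sim <- sample_pool(gen)
    pool <- sim$pool
    obs <- simulate_observables(pool, sim$truth, seed = gen$seed + 1,
                                k = cfg$karplus_obj)
    noe <- obs$noe; j <- obs$j; rdc <- obs$rdc
  }
  backbone <- run_backbone_stage(cfg, pool = pool, noe = noe, j = j)
  sidechain <- run_sidechain_stage(cfg, backbone, rdc = rdc)
  ecfg <- energetics_config(
    T = cfg$energetics$T %||% 298.15,
    convention = cfg$energetics$convention %||% "population_ratio")
  p_ref <- cfg$energetics$reference_folded_fraction %||% NULL
  p <- backbone$folded_percent / 100
  energ <- list(convention = ecfg$convention, T = ecfg$T)
  if (!is.null(p_ref) && p > 0 && p < 1 && p_ref > 0 && p_ref < 1) {
    energ$ddg_vs_reference_kj_mol <- boltzmann_ddg(p, p_ref, ecfg)
    energ$fold_ratio <- fold_ratio(p, p_ref)$ratio
  }
  report <- list(
    schema_version = "1.0",
    folded_percent = round(backbone$folded_percent, 1),
    folded_percent_raw = backbone$folded_percent,
    xb_percent = round(sidechain$xb_percent, 1),
    xb_percent_raw = sidechain$xb_percent,
    backbone = list(populations = backbone$populations,
                    rmsd_by_kind = backbone$rmsd_by_kind,
                    condition_flag = backbone$condition_flag,
                    warnings = backbone$warnings),
    sidechain = list(populations = sidechain$populations,
                     q = sidechain$q, cn = sidechain$cn,
                     q_class = sidechain$q_class,
                     flags = sidechain$flags,
                     tensor = sidechain$tensor),
    energetics = energ,
    provenance = list(
      seed = cfg$seed %||% cfg$generator_obj$seed,
      simulated_inputs = simulated,
      config_hash = .config_hash(cfg),
      package_version = as.character(utils::packageVersion("hairpinxb"))))
  if (isTRUE(write_report)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report,
                         file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# stable hash of the user-facing config (not the derived objects)
.config_hash <- function(cfg) {
  cfg <- cfg[setdiff(names(cfg), c("karplus_obj", "generator_obj"))]
  txt <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  # polynomial rolling hash; avoids an external digest dependency
  h <- 0
  for (b in utf8ToInt(as.character(txt))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Write synthetic demo inputs to disk
#'
#' Generates a pool and observables from a [generator_config()] and
#' writes the multi-model PDB plus the three CSV restraint tables,
#' returning a run-config list pointing at them. Used by the `simulate`
#' CLI subcommand and the end-to-end tests.
#'
#' @param gen A [generator_config()] with a seed.
#' @param dir Output directory (created if needed).
#' @param noise A [noise_levels()] list.
#' @return Run-config list with `pool`, `noe`, `j`, `rdc`, `seed`,
#'   `generator` fields, plus `truth` attached as an attribute.
#' @export
write_demo_inputs <- function(gen, dir, noise = noise_levels()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- sample_pool(gen)
  obs <- simulate_observables(sim$pool, sim$truth, noise = noise,
                              seed = gen$seed + 1)
  paths <- list(pool = file.path(dir, "pool.pdb"),
                noe = file.path(dir, "noe_buildups.csv"),
                j = file.path(dir, "j_couplings.csv"),
                rdc = file.path(dir, "rdcs.csv"))
  write_conformer_pool(sim$pool, paths$pool)
  write_restraint_table(obs$noe, paths$noe)
  write_restraint_table(obs$j, paths$j)
  write_restraint_table(obs$rdc, paths$rdc)
  cfg <- list(pool = paths$pool, noe = paths$noe, j = paths$j,
              rdc = paths$rdc, seed = gen$seed,
              generator = list(
                n_residues = gen$n_residues,
                turn_position = gen$turn_position,
                donor_element = gen$donor_element,
                acceptor_element = gen$acceptor_element))
  attr(cfg, "truth") <- sim$truth
  cfg
}
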