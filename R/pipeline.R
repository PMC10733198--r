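# End-to-end orchestration: physiology -> plasma forcing -> Kp,uu /
# asymmetry factors -> CNS simulation -> (optional) evaluation against
# observations.  Exposed both as run_pipeline() and as a small
# subcommand CLI (cli_main; see inst/cli/cnspbpk.R).

#' Run the CNS PK prediction pipeline for one drug
#'
#' @param config list (or path to a JSON file) with fields:
#'   `drug` (name in the packaged fixtures), `physiology_file` (optional
#'   JSON path; default packaged mouse registry), `plasma_source`
#'   (`"fixture"` or a list `list(fit = TRUE, observations = <csv>)`),
#'   `kpuu_source` (`"fixture"`, `"estimate:auc_ratio"` or
#'   `"estimate:clearance_ratio"`, the latter two requiring
#'   `observations`), `observations` (optional CSV of in vivo data for
#'   evaluation), `t_end` (min; default 6 half-lives of the terminal
#'   slope, capped at 1440), `n_grid`, `body_weight_kg`, `out_dir`,
#'   `seed`.
#' @return invisible list with the assembled objects, written file
#'   paths, and (when observations were supplied) the metric report.
#' @export
run_pipeline <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(
    list(physiology_file = NULL, plasma_source = "fixture",
         kpuu_source = "fixture", observations = NULL, t_end = NULL,
         n_grid = 241L, body_weight_kg = 0.025, out_dir = "cnspbpk_run",
         seed = 1L),
    config)
  if (is.null(cfg$drug)) stop("config$drug is required")
  stage <- function(nm, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s (check the config %s)",
                   nm, conditionMessage(e), nm), call. = FALSE))
  }
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  phys <- stage("physiology", {
    if (is.null(cfg$physiology_file)) mouse_physiology()
    else read_physiology(cfg$physiology_file)
  })
  drug <- stage("drug", cns_drugs(cfg$drug)[[1]])
  obs <- NULL
  if (!is.null(cfg$observations))
    obs <- stage("observations", read_study_csv(cfg$observations))

  pm <- stage("plasma", {
    if (identical(cfg$plasma_source, "fixture")) plasma_models(cfg$drug)[[1]]
    else {
      if (is.null(obs)) stop("fitting requires observations")
      st <- cfg$plasma_source
      fit_plasma_model(obs,
                       dose_event(dose_from_mg_kg(st$dose_mg_kg,
                                                  cfg$body_weight_kg)),
                       structure = st$structure, fu_plasma = drug$fu_plasma,
                       seed = cfg$seed)$model
    }
  })
  dose <- dose_event(dose_from_mg_kg(pm$dose_mg_kg %||% 10,
                                     cfg$body_weight_kg))
  forcing <- plasma_forcing(pm, dose)

  kpuu <- stage("kpuu", {
    src <- cfg$kpuu_source
    if (identical(src, "fixture")) drug$kpuu_bbb
    else if (identical(src, "estimate:auc_ratio")) {
      pl <- obs[obs$matrix == "plasma" & obs$bql == 0, ]
      ec <- obs[obs$matrix == "brain_ecf" & obs$bql == 0, ]
      pl <- stats::aggregate(conc_ng_ml ~ time_min, pl, mean)
      ec <- stats::aggregate(conc_ng_ml ~ time_min, ec, mean)
      pl$conc_ng_ml <- pl$conc_ng_ml * pm$fu_plasma
      kpuu_from_auc(pl, ec)$kpuu
    } else if (identical(src, "estimate:clearance_ratio")) {
      estimate_bbb_clearances(pm, dose, obs, seed = cfg$seed)$kpuu
    } else stop("unknown kpuu_source: ", src)
  })
  af <- asymmetry_factors(kpuu)
  model <- stage("cns_model", cns_model(phys, drug, af = af))

  t_end <- cfg$t_end
  if (is.null(t_end)) {
    lam <- min(Mod(Re(eigen(.plasma_system(pm)$A, only.values = TRUE)$values)))
    t_end <- min(1440, max(60, 6 * log(2) / max(lam, 1e-4)))
  }
  sim <- stage("simulate", simulate_cns(model, forcing, t_end = t_end,
                                        n_grid = cfg$n_grid))

  profile_csv <- file.path(cfg$out_dir, paste0(cfg$drug, "_profiles.csv"))
  utils::write.csv(as.data.frame(sim), profile_csv, row.names = FALSE)

  report <- list(drug = cfg$drug, kpuu = kpuu,
                 af = list(AF_in = af$AF_in, AF_out = af$AF_out),
                 t_end = t_end,
                 ecf_cmax = max(sim$conc["ECF", ]),
                 mass_balance_max = max(abs(sim$mass_balance_rel)))
  if (!is.null(obs)) {
    report$metrics <- stage("evaluate", {
      grid_fun <- function(m) stats::approxfun(sim$times, sim$conc[m, ],
                                               rule = 2)
      ev <- obs[obs$bql == 0 & obs$conc_ng_ml > 0, ]
      ev$predicted <- ifelse(
        ev$matrix == "plasma",
        forcing(ev$time_min) / pm$fu_plasma,
        grid_fun("ECF")(ev$time_min))
      by_mat <- lapply(split(ev, ev$matrix), function(d)
        list(n = nrow(d),
             afe_percent = afe_percent(d$predicted, d$conc_ng_ml),
             aafe_percent = aafe_percent(d$predicted, d$conc_ng_ml)))
      by_mat
    })
  }
  meta <- list(package_version = as.character(utils::packageVersion("cnspbpk")),
               r_version = R.version.string,
               seed = cfg$seed, config = cfg)
  cfg_file <- file.path(cfg$out_dir, "run_config.json")
  jsonlite::write_json(meta, cfg_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  meta$config_hash <- unname(tools::md5sum(cfg_file))
  metrics_file <- file.path(cfg$out_dir, paste0(cfg$drug, "_metrics.json"))
  jsonlite::write_json(c(report, list(run = meta)), metrics_file,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(list(physiology = phys, drug = drug, plasma_model = pm,
                 kpuu = kpuu, af = af, model = model, sim = sim,
                 report = report,
                 files = c(profiles = profile_csv, metrics = metrics_file,
                           config = cfg_file)))
}

#' Command-line entry point
#'
#' Subcommands: `generate` (synthetic study), `fit-plasma`,
#' `estimate-kpuu`, `simulate`, `evaluate`, `run` (full pipeline).
#' Invoked by the `inst/cli/cnspbpk.R` wrapper script; callable directly
#' with a character vector of arguments for testing.
#'
#' @param args character vector, e.g. `c("run", "--config", "cfg.json")`.
#' @return exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cnspbpk <command> [options]",
    "commands:",
    "  run           --config <json>            full pipeline",
    "  simulate      --drug <name> [--t-end <min>] [--out <dir>]",
    "  fit-plasma    --obs <csv> --dose-mg-kg <x> [--route IV] [--ncpt 1]",
    "  estimate-kpuu --drug <name> --obs <csv>   clearance-ratio estimate",
    "  generate      --drug <name> --out <dir> [--seed <int>]",
    "  evaluate      --obs <csv> --pred <csv>    %AFE / %AAFE report",
    sep = "\n")
  if (length(args) == 0) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  status <- 0L
  switch(cmd,
    run = {
      cfgf <- opt("--config")
      if (is.null(cfgf)) stop("run requires --config <json>")
      res <- run_pipeline(cfgf)
      cat("wrote:", paste(res$files, collapse = ", "), "\n")
    },
    simulate = {
      cfg <- list(drug = opt("--drug"),
                  out_dir = opt("--out", "cnspbpk_run"),
                  seed = as.integer(opt("--seed", "1")))
      te <- opt("--t-end"); if (!is.null(te)) cfg$t_end <- as.numeric(te)
      res <- run_pipeline(cfg)
      cat(sprintf("ECF Cmax %.4g ng/ml; wrote %s\n",
                  res$report$ecf_cmax, res$files[["profiles"]]))
    },
    `fit-plasma` = {
      obs <- read_study_csv(opt("--obs"))
      fit <- fit_plasma_model(
        obs, dose_event(dose_from_mg_kg(as.numeric(opt("--dose-mg-kg")))),
        structure = list(n_compartments = as.integer(opt("--ncpt", "1")),
                         route = opt("--route", "IV"),
                         error_model = opt("--error", "proportional"),
                         ka = !is.null(opt("--ka"))))
      print(fit)
    },
    `estimate-kpuu` = {
      drug <- opt("--drug")
      obs <- read_study_csv(opt("--obs"))
      pm <- plasma_models(drug)[[1]]
      est <- estimate_bbb_clearances(
        pm, dose_event(dose_from_mg_kg(pm$dose_mg_kg)), obs)
      cat(sprintf("CL_in %.4g ml/min, CL_out %.4g ml/min, Kp,uu %.4g\n",
                  est$CL_in, est$CL_out, est$kpuu))
    },
    generate = {
      drug <- opt("--drug"); outd <- opt("--out", "cnspbpk_run")
      seed <- as.integer(opt("--seed", "1"))
      dir.create(outd, showWarnings = FALSE, recursive = TRUE)
      pm <- plasma_models(drug)[[1]]
      truth <- ground_truth(pm, mouse_physiology(), cns_drugs(drug)[[1]])
      std <- generate_study(truth, study_design(dose_mg_kg = pm$dose_mg_kg,
                                                route = pm$route),
                            seed = seed)
      write_study_csv(std$observations, file.path(outd, "observations.csv"))
      write_dosing_csv(std$doses, file.path(outd, "dosing.csv"))
      cat("wrote synthetic study to", outd, "\n")
    },
    evaluate = {
      obs <- read_study_csv(opt("--obs"))
      pred <- utils::read.csv(opt("--pred"))
      m <- merge(obs[obs$bql == 0, ], pred, by = c("time_min"))
      cat(sprintf("%%AFE %.1f, %%AAFE %.1f (n = %d)\n",
                  afe_percent(m$conc_ng_ml.y, m$conc_ng_ml.x),
                  aafe_percent(m$conc_ng_ml.y, m$conc_ng_ml.x), nrow(m)))
    },
    { cat(usage, "\n"); status <- 1L }
  )
  invisible(status)
}
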