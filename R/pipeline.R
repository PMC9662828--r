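#' @include AllClasses.R synthetic.R connectome-io.R graph-metrics.R
#' @include neural-sim.R dynamic-range.R hemodynamics.R timescale.R
#' @include decision-model.R
NULL

#' Run the analysis pipeline from a configuration
#'
#' Config-driven orchestration of the package: each subcommand runs one
#' analysis stage on the configured connectome (a file path or a synthetic
#' specification). Every run writes its tidy outputs plus a
#' manifest (config, seed, package version, file hash) to the output
#' directory, and identical config + seed gives byte-identical outputs.
#'
#' Config keys (YAML): \code{connectome} (either \code{path}/\code{format}
#' (+ optional \code{labels}) or \code{synthetic:} with arguments of
#' [syntheticConnectome()]), \code{w_grid} (\code{from}, \code{to},
#' \code{by}), \code{duration}, \code{dt}, \code{transient_frac},
#' \code{ww}/\code{bw}/\code{ddm} parameter overrides, \code{seed}.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#' @param subcommand one of \code{"graph"} (graph metrics), \code{"sweep"}
#'   (response functions), \code{"dynrange"} (sweep + dynamic-range
#'   profile), \code{"networks"} (within-network FC vs w),
#'   \code{"timescale"} (regional timescales), \code{"ddm"} (accuracy
#'   curves), \code{"all"}.
#' @param outDir output directory (created if needed).
#' @param seed integer seed overriding the config's.
#' @return \code{outDir}, invisibly.
#' @export
runPipeline <- function(config, subcommand = c("all", "graph", "sweep",
                                               "dynrange", "networks",
                                               "timescale", "ddm"),
                        outDir = "conndyn-out", seed = NULL) {
  subcommand <- match.arg(subcommand)
  cfgPath <- NA_character_
  if (is.character(config)) {
    cfgPath <- config
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML path or a list")
  known <- c("connectome", "w_grid", "duration", "dt", "transient_frac",
             "ww", "bw", "ddm", "seed")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("invalid config key(s): ", paste(bad, collapse = ", "))
  if (is.null(seed)) seed <- config$seed %||% 1L
  seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  C <- pipelineConnectome(config)
  wGrid <- pipelineGrid(config)
  duration <- config$duration %||% 720
  dt <- config$dt %||% 0.01
  ww <- do.call(wwParams, config$ww %||% list())
  bw <- do.call(bwParams, config$bw %||% list())
  ddm <- do.call(ddmParams, config$ddm %||% list())
  msg <- function(...) message("[conndyn] ", sprintf(...))

  writeTable <- function(df, name) {
    utils::write.csv(df, file.path(outDir, name), row.names = FALSE,
                     quote = FALSE)
  }

  if (subcommand %in% c("all", "graph")) {
    msg("graph metrics (n = %d)", nRegions(C))
    cc <- clusteringCoefficients(C)
    pl <- pathLengths(C)
    mod <- modularityQ(C, nRestarts = 20, seed = seed)
    swp <- smallWorldPropensity(C, nNull = 10, seed = seed)
    writeTable(data.frame(
      region = rep(regionLabels(C), 2),
      metric = rep(c("clustering", "path_length"), each = nRegions(C)),
      value = c(cc@values, pl@values)), "graph_regional.csv")
    writeTable(data.frame(metric = c("modularity_Q", "small_world_propensity"),
                          value = c(mod$Q, swp)), "graph_global.csv")
    writeTable(data.frame(region = regionLabels(C),
                          module = mod$partition), "graph_partition.csv")
  }

  rf <- NULL
  if (subcommand %in% c("all", "sweep", "dynrange")) {
    msg("response-function sweep (%d grid points)", length(wGrid))
    rf <- responseFunction(C, ww, wGrid = wGrid, duration = duration,
                           dt = dt, seed = seed)
    writeTable(asTidy(rf), "response_functions.csv")
  }
  if (subcommand %in% c("all", "dynrange")) {
    prof <- drProfile(rf)
    writeTable(asTidy(prof), "dynamic_range.csv")
    jsonlite::write_json(
      list(sigma = prof@sigma, n_defined = prof@nDefined),
      file.path(outDir, "dynamic_range_summary.json"), auto_unbox = TRUE,
      digits = NA)
  }

  if (subcommand %in% c("all", "networks")) {
    part <- networkPartition(C)
    if (is.null(part)) {
      msg("networks: no partition on connectome; skipping")
    } else {
      msg("within-network FC vs w")
      netGrid <- if (length(wGrid) > 9) {
        wGrid[seq(1, length(wGrid), length.out = 9)]
      } else wGrid
      writeTable(fcVsW(C, netGrid, part, ww, bw, duration = duration,
                       dt = dt, seed = seed), "fc_vs_w.csv")
    }
  }

  if (subcommand %in% c("all", "timescale")) {
    msg("regional timescales at w = %.2f", ww@w)
    ts <- regionalTimescales(C, ww, duration = duration, dt = dt,
                             seed = seed)
    writeTable(data.frame(region = ts@labels, tau = ts@values),
               "timescales.csv")
  }

  if (subcommand %in% c("all", "ddm")) {
    msg("drift-diffusion ensemble (%d trials)", ddm@nTrials)
    ac <- accuracyCurves(C, ddm, seed = seed)
    writeTable(asTidy(ac), "ddm_accuracy.csv")
    writeTable(data.frame(t = ac@t, accuracy = ac@wholeBrain),
               "ddm_whole_brain.csv")
  }

  manifest <- list(
    subcommand = subcommand,
    seed = seed,
    config = config,
    config_path = cfgPath,
    config_md5 = if (!is.na(cfgPath)) unname(tools::md5sum(cfgPath))
                 else NA_character_,
    package_version = as.character(utils::packageVersion("conndyn")),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       na = "null")
  invisible(outDir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipelineConnectome <- function(config) {
  cc <- config$connectome
  if (is.null(cc)) stop("config must name a 'connectome'")
  if (!is.null(cc$synthetic)) {
    do.call(syntheticConnectome, cc$synthetic)
  } else if (!is.null(cc$path)) {
    readConnectome(cc$path, format = cc$format %||% "dense_csv",
                   labelsPath = cc$labels)
  } else {
    stop("connectome config needs either 'synthetic' or 'path'")
  }
}

pipelineGrid <- function(config) {
  g <- config$w_grid
  if (is.null(g)) return(seq(0, 1, by = 0.01))
  seq(g$from %||% 0, g$to %||% 1, by = g$by %||% 0.01)
}
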