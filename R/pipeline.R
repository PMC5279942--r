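# Orchestration: validate a run configuration, fan the global seed out
# to per-stage child seeds, run synthetic-cohort generation plus every
# analysis stage, and emit the summary tables.

defaultRunConfig <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    calibration = list(E_MPa = 2.1, r_um = 1.79, L_um = 5.87),
    binning = list(edges = c(0, 10, 50, 100, 250, 500, 1000)),
    detector = list(k_sd = 5, sustain_ms = 0.3, baseline_window_ms = 20,
                    latency_max_ms = 5, tau1_max_ms = 1),
    imaging = list(pixel_size_nm = 161, spot_sigma_nm = 600,
                   grid_pitch_nm = 4160, peak_counts = 2000,
                   background_counts = 200, read_noise_sd = 15,
                   n_scenes = 3),
    cohorts = list(
      chondrocyte = list(phenotype = "chondrocyte-WT", n_cells = 24,
                         n_traces = 8),
      dedifferentiated = list(phenotype = "dedifferentiated", n_cells = 15,
                              n_traces = 8)),
    hspc = list(p50 = 87.1, slope = 10, imax = 45.2, noise_sd = 2,
                n_patches = 12),
    calcium = list(n_cells = 30, baseline = 100, noise_sd = 2))
}

# deterministic seed fan-out: every stage gets an independent,
# reproducible child seed derived from the global seed and its index
childSeed <- function(seed, stageIndex) {
  (as.numeric(seed) * 1009 + stageIndex * 9973) %% 2147483647
}

validateLeaf <- function(cfg, path, check, msg, errs) {
  v <- cfg
  for (k in path) {
    v <- v[[k]]
    if (is.null(v)) return(errs)   # default was injected already
  }
  if (!check(v)) errs <- c(errs, sprintf("%s: %s", paste(path, collapse = "$"), msg))
  errs
}

#' Validate a pipeline run configuration
#'
#' Accepts a config list or a YAML/JSON file path. Unknown top-level
#' keys are rejected; missing keys receive documented defaults (pillar
#' calibration defaults to the published array: E 2.1 MPa, r 1.79 um,
#' L 5.87 um). All violations are collected and reported together, not
#' first-failure.
#'
#' @param config list, or path to a YAML or JSON file.
#' @return the completed config (class \code{RunConfig}); errors carry
#'   the full violation list.
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config)) {
    stopifnot(file.exists(config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  def <- defaultRunConfig()
  unknown <- setdiff(names(config), names(def))
  errs <- character(0)
  if (length(unknown))
    errs <- c(errs, paste("unknown config keys:",
                          paste(unknown, collapse = ", ")))
  merged <- utils::modifyList(def, config[setdiff(names(config), unknown)])
  # the cohort set is a definition, not a patch: a config that names
  # cohorts replaces the default groups wholesale
  if (!is.null(config$cohorts)) merged$cohorts <- config$cohorts

  pos <- function(v) is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0
  errs <- validateLeaf(merged, c("calibration", "E_MPa"), pos,
                       "must be a positive number (MPa)", errs)
  errs <- validateLeaf(merged, c("calibration", "r_um"), pos,
                       "must be a positive number (um)", errs)
  errs <- validateLeaf(merged, c("calibration", "L_um"), pos,
                       "must be a positive number (um)", errs)
  errs <- validateLeaf(merged, c("binning", "edges"),
                       function(v) is.numeric(v) && all(diff(v) > 0),
                       "must be strictly increasing", errs)
  errs <- validateLeaf(merged, c("detector", "k_sd"), pos,
                       "must be a positive number", errs)
  errs <- validateLeaf(merged, c("imaging", "pixel_size_nm"), pos,
                       "must be a positive number (nm)", errs)
  errs <- validateLeaf(merged, c("hspc", "slope"), pos,
                       "must be > 0 (mmHg)", errs)
  errs <- validateLeaf(merged, "seed",
                       function(v) is.numeric(v) && length(v) == 1,
                       "must be a single number", errs)
  for (g in names(merged$cohorts)) {
    co <- merged$cohorts[[g]]
    if (!is.null(co$n_cells) &&
        (!is.numeric(co$n_cells) || co$n_cells < 0))
      errs <- c(errs, sprintf("cohorts$%s$n_cells: must be >= 0", g))
  }
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  structure(merged, class = c("RunConfig", "list"))
}

cohortPhenotype <- function(co) {
  if (is(co$phenotype, "ChannelPhenotype")) co$phenotype
  else presetPhenotype(co$phenotype)
}

#' Run the full synthetic pipeline end to end
#'
#' Generates synthetic cohorts per the configuration and runs every
#' analysis stage: pillar tracking on rendered scenes with force
#' conversion, per-trace current kinetics, binned stimulus-response with
#' group comparisons, pressure-clamp Boltzmann fits, and calcium-epoch
#' scoring. Deterministic given the config seed (each stage draws from
#' its own child seed). When \code{config$output_dir} is set, tables are
#' written there as CSV plus a \code{report.json}.
#'
#' @param config a [validateConfig()] result, config list, or file path.
#' @return invisibly, a list of stage results: \code{calibration},
#'   \code{deflections}, \code{kinetics}, \code{kinetics_summary},
#'   \code{stimulus_response}, \code{comparison}, \code{hspc},
#'   \code{calcium}.
#' @export
runPipeline <- function(config = list()) {
  cfg <- if (inherits(config, "RunConfig")) config else validateConfig(config)
  seed <- cfg$seed

  geom <- PillarGeometry(E = cfg$calibration$E_MPa,
                         r = cfg$calibration$r_um, L = cfg$calibration$L_um)
  k <- springConstant(geom)

  # --- pillar tracking on rendered scenes -------------------------------
  img <- cfg$imaging
  defl <- NULL
  if (img$n_scenes > 0) {
    defl <- do.call(rbind, lapply(seq_len(img$n_scenes), function(i) {
      sc <- generatePillarScene(
        gridPitch = img$grid_pitch_nm, spotSigma = img$spot_sigma_nm,
        pixelSize = img$pixel_size_nm, peakAmplitude = img$peak_counts,
        background = img$background_counts, readNoiseSd = img$read_noise_sd,
        trueDeflection = c(50 + 150 * i, 0), nGrid = 3,
        seed = childSeed(seed, 100 + i))
      tr <- trackPillarScene(sc)
      tr$scene <- i
      tr
    }))
    if (!is.null(defl) && nrow(defl))
      defl$force_nN <- deflectionToForce(defl$d_nm, k)
  }

  # --- cohorts: population + stimulus-response --------------------------
  phens <- lapply(cfg$cohorts, cohortPhenotype)
  names(phens) <- names(cfg$cohorts)
  nCells <- vapply(cfg$cohorts, function(co) as.integer(co$n_cells),
                   integer(1))
  groups <- list(); srTables <- list()
  if (any(nCells > 0)) {
    pop <- generatePopulation(phens[nCells > 0], nCells[nCells > 0],
                              seed = childSeed(seed, 200))
    scheme <- binningScheme(cfg$binning$edges)
    for (g in names(phens)[nCells > 0]) {
      m <- pop$measurements[pop$measurements$group == g, ]
      groups[[g]] <- list(binned = binResponses(m, scheme),
                          cells = summarizeCells(m))
      srTables[[g]] <- groups[[g]]$binned$summary
    }
  } else {
    warning("no cells configured; emitting empty tables")
  }
  comparison <- if (length(groups) >= 2)
    compareGroups(groups[[1]], groups[[2]]) else NULL

  # --- kinetics ---------------------------------------------------------
  det <- cfg$detector
  kin <- NULL
  gi <- 0
  for (g in names(phens)) {
    gi <- gi + 1
    nT <- cfg$cohorts[[g]]$n_traces
    if (is.null(nT) || nT < 1) next
    rows <- lapply(seq_len(nT), function(i) {
      tr <- generateCurrentTrace(phens[[g]], deflection = 1000,
                                 forceResponder = TRUE,
                                 seed = childSeed(seed, 300 + 50 * gi + i))
      cbind(group = g, extractKinetics(
        tr, baselineWindow = det$baseline_window_ms, kSd = det$k_sd,
        sustainMs = det$sustain_ms, latencyMax = det$latency_max_ms,
        tau1Max = det$tau1_max_ms))
    })
    kin <- rbind(kin, do.call(rbind, rows))
  }
  kinSummary <- NULL
  if (!is.null(kin)) {
    kinSummary <- do.call(rbind, lapply(split(kin, kin$group), function(d) {
      sm <- function(v) {
        v <- v[!is.na(v)]
        c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
          median = stats::median(v))
      }
      data.frame(group = d$group[1], n = nrow(d),
                 t(c(latency = sm(d$latency), tau1 = sm(d$tau1),
                     tau2 = sm(d$tau2), amplitude = sm(d$amplitude))),
                 rapid_fraction = mean(d$rapid_gating, na.rm = TRUE))
    }))
    rownames(kinSummary) <- NULL
  }

  # --- pressure clamp ---------------------------------------------------
  hs <- cfg$hspc
  hspc <- NULL
  if (hs$n_patches > 0) {
    fams <- lapply(seq_len(hs$n_patches), function(i)
      generatePressureFamily(hs$p50, hs$slope, hs$imax,
                             noiseSd = hs$noise_sd,
                             patchId = sprintf("patch%02d", i),
                             seed = childSeed(seed, 400 + i)))
    hspc <- fitPressureFamilies(fams)
    hspc$peaks <- peakCurrentSummary(list(all = fams))$summary
  }

  # --- calcium ----------------------------------------------------------
  ca <- cfg$calcium
  calcium <- NULL
  if (ca$n_cells > 0) {
    eps <- defaultCalciumEpochs()
    traces <- lapply(seq_len(ca$n_cells), function(i)
      generateFluorescenceTrace(ca$baseline, eps, noiseSd = ca$noise_sd,
                                cellId = sprintf("cell%03d", i),
                                seed = childSeed(seed, 500 + i)))
    calcium <- scoreCalciumCohort(traces)
  }

  out <- list(
    calibration = data.frame(E_MPa = geom@E, r_um = geom@r, L_um = geom@L,
                             k_pN_per_nm = k,
                             threshold_force_nN = if (length(groups))
                               deflectionToForce(mean(
                                 groups[[1]]$cells$threshold, na.rm = TRUE), k)
                             else NA_real_),
    deflections = defl, kinetics = kin, kinetics_summary = kinSummary,
    stimulus_response = srTables, comparison = comparison,
    hspc = hspc, calcium = calcium, config = cfg)

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(d, f) if (!is.null(d))
      utils::write.csv(d, file.path(cfg$output_dir, f), row.names = FALSE)
    wr(out$calibration, "calibration.csv")
    wr(out$deflections, "deflections.csv")
    wr(out$kinetics, "kinetics.csv")
    wr(out$kinetics_summary, "kinetics_summary.csv")
    for (g in names(srTables))
      wr(srTables[[g]], sprintf("stimulus_response_%s.csv", g))
    if (!is.null(hspc)) wr(hspc$fits, "hspc_fits.csv")
    if (!is.null(calcium)) wr(calcium$scores, "calcium_scores.csv")
    jsonlite::write_json(
      list(seed = seed,
           k_pN_per_nm = k,
           threshold_force_nN = out$calibration$threshold_force_nN,
           comparison = if (!is.null(comparison)) list(
             fisher_p = comparison$responder$fisher_p,
             threshold_p = comparison$threshold$p),
           hspc_p50 = if (!is.null(hspc)) hspc$p50_mean),
      file.path(cfg$output_dir, "report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
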