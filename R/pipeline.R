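#' @include AllClasses.R oxdna-io.R sites.R modes.R fes.R accessibility.R fixtures.R
NULL

#' Write a TSV with a commented metadata header
#'
#' @param df data.frame.
#' @param path output path.
#' @param meta named list written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
writeTsvReport <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [writeTsvReport()]
#' @param path file path.
#' @return data.frame (header comments skipped).
#' @export
readTsvReport <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

.defaultConfig <- list(
  lengthUnit = OXDNA_LENGTH_UNIT, motif = "GCGC", flankLeft = 3,
  thetaBins = 72, marginBp = 2, nBins = 100, sides = c("scaffold", "staple"),
  selection = "scaffold", probe = list(extent = 3, nParticles = 2000,
                                       offset = 0, seed = 0))

#' Load and normalize a run configuration
#'
#' @param config named list or path to a YAML file.
#' @return list with defaults filled in.
#' @export
loadRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.defaultConfig, config)
  if (is.null(cfg$topology) || is.null(cfg$trajectory))
    stop("run config: 'topology' and 'trajectory' paths are required")
  for (f in c("topology", "trajectory", "design", "pdb", "experiment"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop(sprintf("run config: %s file not found: %s", f, cfg[[f]]))
  cfg
}

#' Run the full site-accessibility pipeline
#'
#' Executes sites -> modes -> accessibility (-> correlation) as configured and
#' writes TSV reports (with the config echoed verbatim and its md5 in every
#' header) into the output directory. Identical configs reproduce identical
#' result files.
#'
#' @param config named list or YAML path; see `loadRunConfig()`. Required:
#'   `topology`, `trajectory`, `outDir`. Optional: `design` +
#'   `scaffoldSequence`, `pdb` or `probe` (extent/nParticles/offset/seed),
#'   `experiment` (TSV with columns site, fraction), plus the analysis knobs
#'   `motif`, `flankLeft`, `thetaBins`, `marginBp`, `nBins`, `sides`,
#'   `selection`, `lengthUnit`.
#' @return invisible list with the main in-memory results (`sites`, `spectrum`,
#'   `rmsf`, `projection`, `profile`, `twoState`, `accessibility`,
#'   `correlation`).
#' @export
runPipeline <- function(config) {
  cfg <- loadRunConfig(config)
  outDir <- cfg$outDir
  if (is.null(outDir)) stop("run config: 'outDir' is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cfgPath <- file.path(outDir, "config.yaml")
  yaml::write_yaml(cfg, cfgPath)
  hash <- unname(tools::md5sum(cfgPath))
  meta0 <- list(config_md5 = hash)
  logCon <- file(file.path(outDir, "run.log"), "w")
  on.exit(close(logCon))
  logmsg <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, logCon)
    message(msg)
  }

  stage <- "input"
  result <- withCallingHandlers(tryCatch({
    top <- readOxTopology(cfg$topology)
    traj <- readOxTrajectory(cfg$trajectory, top, lengthUnit = cfg$lengthUnit)
    logmsg("input: %d nucleotides, %d frames", nNucleotides(traj), nFrames(traj))
    if (!length(top@pairing)) {
      top <- inferPairing(top, getFrame(traj, 1))
      traj@topology <- top
      logmsg("input: pairing inferred geometrically (%d paired nt)",
             sum(!is.na(top@pairing)))
    }

    stage <- "sites"
    sites <- NULL
    if (!is.null(cfg$design)) {
      seqArg <- cfg$scaffoldSequence
      if (is.null(seqArg)) stop("design given but no scaffoldSequence")
      if (file.exists(seqArg)) seqArg <- paste(readLines(seqArg), collapse = "")
      design <- readCadnanoDesign(cfg$design, seqArg,
                                  omitStaples = cfg$omitStaples %||% integer(0))
      sites <- scanRecognitionSites(design, top, motif = cfg$motif,
                                    flankLeft = cfg$flankLeft)
      logmsg("sites: %d %s occurrences (%d crossover-flagged, %d truncated)",
             length(sites), cfg$motif,
             sum(vapply(sites, function(s) s@crossoverOverlap, logical(1))),
             sum(vapply(sites, function(s) s@truncated, logical(1))))
      writeTsvReport(siteTable(sites), file.path(outDir, "sites.tsv"),
                     c(meta0, motif = cfg$motif))
    }

    stage <- "modes"
    selection <- if (identical(cfg$selection, "scaffold")) scaffoldOrder(top)
                 else as.integer(cfg$selection)
    aa <- alignAndAverage(traj, selection)
    spec <- covarianceModes(aa$aligned, selection)
    proj <- projectOntoMode(aa$aligned, spec, mode = 1)
    ## a rigid selection projects to a constant; skip the profile then
    prof <- tryCatch(freeEnergyProfile(proj, nBins = cfg$nBins),
                     error = function(e) NULL)
    ts <- if (!is.null(prof)) twoStateStats(proj, prof)
    logmsg("modes: total MSF %.4g nm^2; lambda1 %.4g nm^2; %s",
           totalMsf(spec), eigenvalues(spec)[1],
           if (is.null(ts)) "degenerate projection, profile skipped"
           else if (ts@singleState) "single state"
           else sprintf("two states, barriers %.2f/%.2f kBT",
                        ts@barriers[1], ts@barriers[2]))
    writeTsvReport(data.frame(nucleotide = selection, rmsf = aa$rmsf),
                   file.path(outDir, "rmsf.tsv"),
                   c(meta0, selection_size = length(selection)))
    writeTsvReport(data.frame(mode = seq_along(eigenvalues(spec)),
                              eigenvalue = eigenvalues(spec)),
                   file.path(outDir, "eigenvalues.tsv"),
                   c(meta0, total_msf = sprintf("%.8g", totalMsf(spec))))
    writeTsvReport(data.frame(time = frameTimes(proj), s = values(proj)),
                   file.path(outDir, "projection.tsv"), c(meta0, mode = "1"))
    if (!is.null(prof))
      writeTsvReport(data.frame(center = prof@centers, free = prof@free,
                                count = prof@counts),
                     file.path(outDir, "fes.tsv"),
                     c(meta0, bins = cfg$nBins,
                       bin_width = sprintf("%.6g", diff(prof@centers[1:2]))))

    stage <- "accessibility"
    access <- NULL
    if (!is.null(sites)) {
      helix <- buildIdealHelix(10)
      template <- if (!is.null(cfg$pdb)) {
        clouds <- readPdbParticles(cfg$pdb)
        buildDockingTemplate(clouds$protein, clouds$dna, helix)
      } else {
        probeTemplate(makeProbeCloud(cfg$probe$extent, cfg$probe$nParticles,
                                     cfg$probe$offset, cfg$probe$seed),
                      helix)
      }
      usable <- Filter(function(s) !s@truncated, sites)
      access <- lapply(usable, function(s) {
        r <- siteAccessibility(traj, s, template, sides = cfg$sides,
                               nTheta = cfg$thetaBins, marginBp = cfg$marginBp)
        logmsg("accessibility site %d: %s (used %d, skipped %d)", s@id,
               paste(sprintf("%s=%.3f", names(fractions(r)), fractions(r)),
                     collapse = " "), r@framesUsed, r@framesSkipped)
        r
      })
      atab <- do.call(rbind, lapply(access, function(r) {
        data.frame(site = r@siteId, side = names(fractions(r)),
                   fraction = unname(fractions(r)), framesUsed = r@framesUsed,
                   framesSkipped = r@framesSkipped)
      }))
      writeTsvReport(atab, file.path(outDir, "accessibility.tsv"),
                     c(meta0, theta_bins = cfg$thetaBins))
    }

    stage <- "correlation"
    corr <- NULL
    if (!is.null(access) && !is.null(cfg$experiment)) {
      exp <- readTsvReport(cfg$experiment)
      keep <- !vapply(sites, function(s) s@crossoverOverlap, logical(1))[
        vapply(access, function(r) r@siteId, 0L)]
      th <- vapply(access, function(r) fractions(r)[["scaffold"]], 0)
      names(th) <- vapply(access, function(r) as.character(r@siteId), "")
      th <- th[keep]
      ex <- stats::setNames(exp$fraction, as.character(exp$site))
      corr <- correlateWithExperiment(th, ex)
      logmsg("correlation: Pearson %.3f on %d sites (%d dropped)",
             corr$correlation, corr$nUsed, length(corr$dropped))
      writeTsvReport(data.frame(pearson = corr$correlation, n = corr$nUsed),
                     file.path(outDir, "correlation.tsv"), meta0)
    }

    list(sites = sites, spectrum = spec, rmsf = aa$rmsf, projection = proj,
         profile = prof, twoState = ts, accessibility = access,
         correlation = corr)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }), warning = function(w) {
    writeLines(paste("warning:", conditionMessage(w)), logCon)
    invokeRestart("muffleWarning")
  })
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
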