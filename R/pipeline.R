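## Orchestration: configuration, the end-to-end run, and the run manifest.

#' Default pipeline configuration
#'
#' Nested list of every stage parameter with the package defaults: -80 dB
#' minimum Sv; 5 / 10 dB fish / macrozooplankton dB-difference limits;
#' 150 m multifrequency split; 45-55 m subsurface-front band at 0.01 deg
#' resolution; 5 x 5 smoothing; 1.5 m bottom offset; 2 m near-field
#' buffer; gamma = 2; 10 dB SNR threshold. Unknown keys in a user config
#' are rejected.
#'
#' @return nested named list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    simulate = list(enabled = TRUE),
    paths = list(echograms = NULL, ctd = NULL, sst = NULL, trawl = NULL),
    preprocess = list(
      resampleTolerance = 2, transducerRadius = 0.2, surfaceBuffer = 2,
      bottomThreshold = -35, bottomMinDepth = 20, bottomOffset = 1.5,
      noiseCell = c(40L, 10L), snrThreshold = 10, maxNoise = -100,
      impulseContext = 2L, impulseSmooth = 5L, impulseThreshold = 10,
      smoothWindow = c(5L, 5L), svThreshold = -80),
    grid = list(statsCellDepth = 3, statsCellDist = 0.25,
                rgbCellDepth = 1, rgbCellDist = 0.1, minFraction = 0.3),
    classify = list(splitDepth = 150, fishMax = 5, zooMin = 10,
                    nascBinWidth = 0.1),
    fronts = list(band = c(45, 55), resolution = 0.01, minGradient = 0.5),
    covariates = list(bands = list(surface = c(0, 10), middle = c(45, 55),
                                   bottom = c(150, 250))),
    composite = list(gamma = 2, brighten = 1),
    stats = list(anosimPermutations = 999L, alpha = 0.05,
                 excludeTaxa = "MMZ"))
}

.checkKeys <- function(user, defaults, path = "") {
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    stop(sprintf("unknown config key(s): %s",
                 paste0(path, extra, collapse = ", ")))
  for (nm in names(user))
    if (is.list(user[[nm]]) && is.list(defaults[[nm]]) &&
        !is.null(names(defaults[[nm]])) && nm != "bands")
      .checkKeys(user[[nm]], defaults[[nm]], paste0(path, nm, "$"))
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' Merges a YAML file over \code{\link{defaultPipelineConfig}}; unknown
#' keys are rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return resolved configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  def <- defaultPipelineConfig()
  .checkKeys(user, def)
  utils::modifyList(def, user)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the end-to-end frontal analysis
#'
#' Executes simulate (or load) -> preprocess -> classify -> integrate ->
#' fronts / water mass / stability -> composite -> statistics, writing
#' NASC and front-fix CSVs, the water-mass and stability sections, PNG
#' composites, correlation / diversity / ANOSIM tables and a
#' machine-readable run manifest (resolved config, seed, output
#' checksums) into \code{outDir}. A stage failure aborts with the failing
#' stage named; outputs of completed stages are retained.
#'
#' @param config configuration list (see
#'   \code{\link{defaultPipelineConfig}}) or path to a YAML file.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the principal in-memory results.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)

  ## ---- inputs ----
  if (isTRUE(config$simulate$enabled)) {
    sim <- .stage("simulate", {
      sc <- simulationConfig(seed = seed)
      list(ech = simulateEchograms(sc),
           ctd = simulateCtdTransect(sc),
           sst = simulateSstSeries(sc),
           trawl = simulateTrawlCatches(sc),
           sc = sc)
    })
    grids <- sim$ech$grids
    section <- sim$ctd$section
    sst <- sim$sst
    catch <- sim$trawl$catch
    iceOpen <- sim$sc@front$openIce; iceClosed <- sim$sc@front$closedIce
    date <- sim$sc@transect$date
  } else {
    p <- config$paths
    for (nm in c("echograms", "ctd", "sst", "trawl")) {
      if (is.null(p[[nm]])) stop(sprintf("missing input path: %s", nm))
      for (f in p[[nm]]) if (!file.exists(f))
        stop(sprintf("input not found: %s", f))
    }
    grids <- .stage("load", lapply(p$echograms, readEchogramCsv))
    names(grids) <- paste0("f", vapply(grids, function(g) g@frequency,
                                       numeric(1)))
    section <- .stage("load", readSectionCsv(p$ctd))
    sst <- .stage("load", data.table::fread(p$sst, data.table = FALSE))
    catch <- .stage("load", data.table::fread(p$trawl, data.table = FALSE))
    iceOpen <- iceClosed <- NA_real_
    date <- sst$date[1]
  }

  ## ---- preprocess ----
  pp <- .stage("preprocess",
               preprocessEchograms(grids, params = config$preprocess))
  gr <- config$grid
  mvFine <- .stage("grid", lapply(pp$grids, computeMvbs,
                                  cellDepth = gr$rgbCellDepth,
                                  cellDist = gr$rgbCellDist,
                                  minFraction = gr$minFraction, date = date))
  mvStats <- .stage("grid", lapply(pp$grids, computeMvbs,
                                   cellDepth = gr$statsCellDepth,
                                   cellDist = gr$statsCellDist,
                                   minFraction = gr$minFraction, date = date))

  ## ---- classify + integrate ----
  cl <- config$classify
  classified <- .stage("classify",
                       classifyCells(mvStats$f38, mvStats$f120,
                                     splitDepth = cl$splitDepth,
                                     fishMax = cl$fishMax, zooMin = cl$zooMin))
  nasc <- .stage("integrate", rbind(
    integrateNasc(classified, "FISH", "SHALLOW", cl$nascBinWidth),
    integrateNasc(classified, "FISH", "DEEP", cl$nascBinWidth),
    integrateNasc(classified, "MACROZOOPLANKTON", "SHALLOW", cl$nascBinWidth)))

  ## ---- fronts / water mass / stability ----
  fr <- config$fronts
  fronts <- .stage("fronts", data.frame(
    date = date,
    surface_front_lat = locateSurfaceFront(sst$lat, sst$sst,
                                           resolution = fr$resolution,
                                           minGradient = fr$minGradient),
    subsurface_front_lat = locateSubsurfaceFront(section, band = fr$band,
                                                 resolution = fr$resolution,
                                                 minGradient = fr$minGradient),
    open_ice_lat = iceOpen, closed_ice_lat = iceClosed))
  wm <- .stage("watermass", {
    ok <- !section@mask
    cls <- matrix(NA_character_, nrow(section@mask), ncol(section@mask))
    cls[ok] <- as.character(classifyWaterMass(section@SA[ok], section@CT[ok],
                                              section@sigmaTheta[ok]))
    cls
  })
  stab <- .stage("stability", {
    dz <- diff(section@depth)
    n2 <- (9.81 / 1025) * t(apply(section@sigmaTheta, 1, diff)) /
      matrix(dz, nrow(section@sigmaTheta), length(dz), byrow = TRUE)
    n2
  })

  ## ---- composite ----
  comp <- .stage("composite", buildRgb(mvFine$f18, mvFine$f38, mvFine$f120,
                                       gamma = config$composite$gamma,
                                       brighten = config$composite$brighten))

  ## ---- statistics ----
  st <- config$stats
  stats <- .stage("stats", {
    cov <- joinCovariates(nasc, fronts, section,
                          bands = config$covariates$bands)
    cov$series <- paste(cov$class, cov$stratum, sep = "_")
    wide <- Reduce(function(a, b) merge(a, b, by = "distance"),
                   lapply(split(cov, cov$series), function(d)
                     stats::setNames(d[, c("distance", "nasc")],
                                     c("distance", d$series[1]))))
    covars <- cov[cov$series == cov$series[1],
                  c("distance", "latitude", grep("^(dist_|temp_|sal_)",
                                                 names(cov), value = TRUE))]
    wide <- merge(wide, covars, by = "distance")
    resp <- setdiff(names(wide), c("distance", names(covars)))
    corr <- correlationTable(wide, resp,
                             setdiff(names(covars), "distance"),
                             alpha = st$alpha)
    taxa <- intersect(names(catch),
                      simulationConfig()@community$taxa)
    std <- standardizeCatch(catch, taxa)
    div <- diversityTable(std, taxa, exclude = st$excludeTaxa)
    an <- anosim(brayCurtis(as.matrix(std[taxa])), std$water_mass,
                 nPerm = st$anosimPermutations, seed = seed)
    list(correlation = corr, diversity = div, anosim = an, covariates = wide)
  })

  ## ---- outputs ----
  .stage("write", {
    .fwrite(nasc, file.path(outDir, "nasc.csv"))
    .fwrite(fronts, file.path(outDir, "fronts.csv"))
    writeSectionCsv(section, file.path(outDir, "ctd_section.csv"))
    .fwrite(data.frame(lat = rep(section@latitude, ncol(wm)),
                       depth_m = rep(section@depth, each = nrow(wm)),
                       water_mass = as.vector(wm)),
            file.path(outDir, "water_mass.csv"))
    .fwrite(data.frame(lat = rep(section@latitude, ncol(stab)),
                       depth_m = rep(section@depth[-1] - diff(section@depth) / 2,
                                     each = nrow(stab)),
                       n2 = as.vector(stab)),
            file.path(outDir, "stability.csv"))
    writeComposite(comp, file.path(outDir, "composite.png"))
    for (k in 1:3)
      .fwrite(as.data.frame(comp@rgb[, , k]),
              file.path(outDir, sprintf("composite_channel_%d.csv", k)))
    .fwrite(stats$correlation, file.path(outDir, "correlation.csv"))
    .fwrite(stats$diversity, file.path(outDir, "diversity.csv"))
    .fwrite(data.frame(test = "anosim_water_mass",
                       R = stats$anosim$statistic, p = stats$anosim$p,
                       n_perm = stats$anosim$nPerm),
            file.path(outDir, "anosim.csv"))
    .fwrite(stats$covariates, file.path(outDir, "covariates.csv"))
  })
  files <- setdiff(list.files(outDir), "manifest.json")
  manifest <- list(
    seed = seed, config = config,
    files = as.list(tools::md5sum(file.path(outDir, sort(files)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(grids = pp$grids, noise = pp$noise, mvbs = mvStats,
                 classified = classified, nasc = nasc, fronts = fronts,
                 composite = comp, stats = stats))
}
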