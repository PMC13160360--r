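## Generics, accessors and show() methods.

#' @name accessors
#' @title Accessors for frontscan containers
#' @description Slot access for the S4 containers goes through these
#'   accessors rather than \code{@}.
#' @param object a frontscan S4 object.
#' @param layer name of a mask layer (for \code{maskLayer}).
#' @return the requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("sv", function(object) standardGeneric("sv"))
#' @rdname accessors
#' @export
setMethod("sv", "EchogramGrid", function(object) object@Sv)

#' @rdname accessors
#' @export
setGeneric("depthEdges", function(object) standardGeneric("depthEdges"))
#' @rdname accessors
#' @export
setMethod("depthEdges", "EchogramGrid", function(object) object@depthEdges)
#' @rdname accessors
#' @export
setMethod("depthEdges", "MvbsGrid", function(object) object@depthEdges)
#' @rdname accessors
#' @export
setMethod("depthEdges", "ClassifiedGrid", function(object) object@depthEdges)

#' @rdname accessors
#' @export
setGeneric("distEdges", function(object) standardGeneric("distEdges"))
#' @rdname accessors
#' @export
setMethod("distEdges", "MvbsGrid", function(object) object@distEdges)
#' @rdname accessors
#' @export
setMethod("distEdges", "ClassifiedGrid", function(object) object@distEdges)

#' @rdname accessors
#' @export
setGeneric("frequency", function(object) standardGeneric("frequency"))
#' @rdname accessors
#' @export
setMethod("frequency", "EchogramGrid", function(object) object@frequency)
#' @rdname accessors
#' @export
setMethod("frequency", "MvbsGrid", function(object) object@frequency)

#' @rdname accessors
#' @export
setGeneric("stage", function(object) standardGeneric("stage"))
#' @rdname accessors
#' @export
setMethod("stage", "EchogramGrid", function(object) object@stage)

#' @rdname accessors
#' @export
setGeneric("mvbs", function(object) standardGeneric("mvbs"))
#' @rdname accessors
#' @export
setMethod("mvbs", "MvbsGrid", function(object) object@mvbs)

#' @rdname accessors
#' @export
setGeneric("cellClass", function(object) standardGeneric("cellClass"))
#' @rdname accessors
#' @export
setMethod("cellClass", "ClassifiedGrid", function(object) object@cellClass)

#' @rdname accessors
#' @export
setGeneric("exclusionMask", function(object) standardGeneric("exclusionMask"))

#' @describeIn accessors combined exclusion mask (TRUE = excluded) over all
#'   exclusion layers; informational layers (impulse repairs) do not count.
#' @export
setMethod("exclusionMask", "EchogramGrid", function(object) {
  m <- matrix(FALSE, nrow(object@Sv), ncol(object@Sv))
  for (nm in setdiff(names(object@masks), .infoLayers))
    m <- m | object@masks[[nm]]
  m
})

#' @rdname accessors
#' @export
setGeneric("maskLayer", function(object, layer) standardGeneric("maskLayer"))
#' @rdname accessors
#' @export
setMethod("maskLayer", "EchogramGrid", function(object, layer) {
  if (!layer %in% names(object@masks))
    return(matrix(FALSE, nrow(object@Sv), ncol(object@Sv)))
  object@masks[[layer]]
})

#' @rdname accessors
#' @export
setGeneric("bottomLine", function(object) standardGeneric("bottomLine"))
#' @rdname accessors
#' @export
setMethod("bottomLine", "EchogramGrid", function(object) object@lines$bottom)

#' @rdname accessors
#' @export
setGeneric("surfaceLine", function(object) standardGeneric("surfaceLine"))
#' @rdname accessors
#' @export
setMethod("surfaceLine", "EchogramGrid", function(object) object@lines$surface)

## ---- internal helpers ------------------------------------------------------

## depth-bin centres double as sample range r for TVG purposes
.binCenters <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

## Sv with excluded samples set to NA
.maskedSv <- function(grid) {
  s <- grid@Sv
  s[exclusionMask(grid)] <- NA_real_
  s
}

.dbToLin <- function(x) 10^(x / 10)
.linToDb <- function(x) 10 * log10(x)

## OR a new exclusion layer into the grid (monotone: never unmasks)
.addMask <- function(grid, layer, m) {
  prev <- maskLayer(grid, layer)
  grid@masks[[layer]] <- prev | m
  grid
}

## Enforce cleaning-chain order: an operation producing stage `newStage`
## refuses grids that already passed `newStage` or anything later.
.advanceStage <- function(grid, newStage) {
  if (.stageRank[grid@stage] >= .stageRank[newStage])
    stop(sprintf(paste0("pipeline order violation: cannot apply a '%s' stage ",
                        "operation to a grid already at stage '%s'"),
                 newStage, grid@stage), call. = FALSE)
  grid@stage <- newStage
  grid
}

## ---- show methods ----------------------------------------------------------

setMethod("show", "EchogramGrid", function(object) {
  cat(sprintf("EchogramGrid: %g kHz, %d pings x %d bins (%.1f-%.1f m), stage '%s'\n",
              object@frequency, nrow(object@Sv), ncol(object@Sv),
              min(object@depthEdges), max(object@depthEdges), object@stage))
  excl <- mean(exclusionMask(object))
  cat(sprintf("  mask layers: %s (%.1f%% excluded)\n",
              if (length(object@masks)) paste(names(object@masks), collapse = ", ")
              else "none", 100 * excl))
})

setMethod("show", "CtdProfile", function(object) {
  cat(sprintf("CtdProfile '%s' at %.3f N, %.3f E: %d levels, %.1f-%.1f m\n",
              object@station, object@latitude, object@longitude,
              length(object@depth), min(object@depth), max(object@depth)))
})

setMethod("show", "CtdSection", function(object) {
  cat(sprintf("CtdSection: %d latitudes (%.3f-%.3f N) x %d depths (%.1f-%.1f m), %.1f%% masked\n",
              length(object@latitude), min(object@latitude), max(object@latitude),
              length(object@depth), min(object@depth), max(object@depth),
              100 * mean(object@mask)))
})

setMethod("show", "MvbsGrid", function(object) {
  cat(sprintf("MvbsGrid: %g kHz, %d distance x %d depth cells, %.1f%% defined\n",
              object@frequency, nrow(object@mvbs), ncol(object@mvbs),
              100 * mean(!is.na(object@mvbs))))
})

setMethod("show", "ClassifiedGrid", function(object) {
  tab <- table(factor(object@cellClass,
                      c("FISH", "MACROZOOPLANKTON", "UNCLASSIFIED", "EXCLUDED")))
  cat(sprintf("ClassifiedGrid: %d x %d cells, split at %g m\n",
              nrow(object@cellClass), ncol(object@cellClass), object@splitDepth))
  print(tab)
})

setMethod("show", "NoiseEstimate", function(object) {
  cat(sprintf("NoiseEstimate: %g kHz, %d ping blocks, %.1f to %.1f dB (cap %.1f)\n",
              object@frequency, length(object@noise),
              min(object@noise, na.rm = TRUE), max(object@noise, na.rm = TRUE),
              object@maxNoise))
})

setMethod("show", "RgbComposite", function(object) {
  cat(sprintf("RgbComposite: %d x %d pixels, gamma %g\n",
              dim(object@rgb)[1], dim(object@rgb)[2], object@gamma))
})

setMethod("show", "SimulationConfig", function(object) {
  tr <- object@transect
  cat(sprintf("SimulationConfig: seed %d, %d pings x %g nmi, %g m deep, front at %.2f N, %d targets\n",
              object@seed, tr$nPings, tr$pingSpacing, tr$maxDepth,
              object@front$lat, length(object@targets)))
})
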