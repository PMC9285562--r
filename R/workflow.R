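#' Pipeline configuration
#'
#' Collects every user choice of the segmentation pipeline.  Anatomy
#' presets encode the per-anatomy defaults: `"aneurysm"` (bright fluid,
#' 0.1 mm target spacing, reference iso0 = inlet speed / 10) and
#' `"airway"` (dark fluid, 0.25 mm target spacing, iso0 = inlet speed).
#'
#' @param input a [VolumetricImage-class] or a file path for [readVolume()].
#' @param coarseRange length-2 inclusive intensity range `c(imin, imax)`.
#' @param preset `"aneurysm"` or `"airway"`.
#' @param roi optional list with 0-based half-open `lower`/`upper` bounds.
#' @param fluidBright is the fluid the bright phase? Defaults by preset.
#' @param If,Is reference intensities; default: the coarse-range bounds,
#'   oriented by `fluidBright`.
#' @param targetSpacing isotropic resample target, mm; `NA` skips
#'   resampling; default by preset.
#' @param epsMin solidification porosity cutoff.
#' @param fluid fluid preset name or a [FluidProps-class].
#' @param inletSide,outletSides box sides for inlet/outlets.
#' @param symmetrySides box sides treated as symmetry planes.
#' @param inletSpeed inlet velocity magnitude, m s^-1.
#' @param tol solver tolerance.
#' @param isoValues sweep iso-values; default [defaultIsoValues()] plus
#'   the preset iso0.
#' @param iso0 reference iso-value; default by preset.
#' @param indicator `"dR"` or `"dr"` for [selectIso()].
#' @param slopeFraction plateau threshold for [selectIso()].
#' @param userIso optional manual iso override.
#' @param outputDir optional directory for persisted outputs.
#' @return Config list for [runPipeline()].
#' @export
pipelineConfig <- function(input, coarseRange,
                           preset = c("aneurysm", "airway"),
                           roi = NULL, fluidBright = NULL,
                           If = NULL, Is = NULL, targetSpacing = NULL,
                           epsMin = 0.1, fluid = "blood",
                           inletSide = "x-", outletSides = "x+",
                           symmetrySides = character(),
                           inletSpeed = 1e-4, tol = 1e-8,
                           isoValues = NULL, iso0 = NULL,
                           indicator = c("dR", "dr"), slopeFraction = 0.05,
                           userIso = NULL, outputDir = NULL) {
  preset <- match.arg(preset)
  indicator <- match.arg(indicator)
  assertThat(length(coarseRange) == 2L && coarseRange[1] < coarseRange[2],
             "coarseRange must be c(imin, imax) with imin < imax")
  if (is.null(fluidBright)) fluidBright <- preset == "aneurysm"
  if (is.null(If)) If <- if (fluidBright) coarseRange[2] else coarseRange[1]
  if (is.null(Is)) Is <- if (fluidBright) coarseRange[1] else coarseRange[2]
  if (is.null(targetSpacing))
    targetSpacing <- if (preset == "aneurysm") 0.1 else 0.25
  if (is.null(iso0))
    iso0 <- if (preset == "aneurysm") inletSpeed / 10 else inletSpeed
  if (is.null(isoValues)) isoValues <- defaultIsoValues(iso0)
  if (is.character(fluid)) fluid <- fluidPreset(fluid)
  list(input = input, coarseRange = coarseRange, preset = preset, roi = roi,
       fluidBright = fluidBright, If = If, Is = Is,
       targetSpacing = targetSpacing, epsMin = epsMin, fluid = fluid,
       inletSide = inletSide, outletSides = outletSides,
       symmetrySides = symmetrySides, inletSpeed = inletSpeed, tol = tol,
       isoValues = isoValues, iso0 = iso0, indicator = indicator,
       slopeFraction = slopeFraction, userIso = userIso,
       outputDir = outputDir)
}

#' Run the segmentation pipeline end-to-end
#'
#' Stages: crop, coarse threshold, isotropic resample, intensity to
#' porosity, solidify, shrunken-voxel resistance, creeping-flow solve,
#' iso-value sweep, indicator curve, iso selection, surface extraction.
#' Voxel counts are logged at every reducing stage.  When `outputDir` is
#' set, the resolved config, intermediate fields (NIfTI), the sweep CSV,
#' the selection JSON and the chosen surface (STL) are persisted;
#' re-running with an identical config reproduces them byte-identically.
#'
#' @param cfg a [pipelineConfig()].
#' @param quiet suppress stage messages.
#' @return List: `report` (stage timings, voxel counts, mass balance,
#'   selection), `mesh` (chosen [SurfaceMesh-class]), `solution`
#'   ([FlowSolution-class]), `domain`, `sweep`, `curve`, `selection`.
#' @export
runPipeline <- function(cfg, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  timings <- c(); counts <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic(); out <- force(expr)
    timings[[name]] <<- tic() - t0
    out
  }

  img <- stage("read", {
    if (is(cfg$input, "VolumetricImage")) cfg$input else readVolume(cfg$input)
  })
  counts$input <- prod(dim(img@data))

  if (!is.null(cfg$roi)) {
    img <- stage("crop", cropVolume(img, cfg$roi$lower, cfg$roi$upper))
    say("cropped to ", paste(dim(img@data), collapse = "x"))
  }

  if (!is.na(cfg$targetSpacing) &&
      max(abs(img@spacing - cfg$targetSpacing)) > 1e-9) {
    img <- stage("resample", resampleIsotropic(img, cfg$targetSpacing))
    say("resampled to ", paste(dim(img@data), collapse = "x"),
        " at ", cfg$targetSpacing, " mm")
  }

  mask <- stage("coarseThreshold",
                coarseThreshold(img, cfg$coarseRange[1], cfg$coarseRange[2]))
  counts$candidate <- sum(mask)
  say("coarse threshold retains ", counts$candidate, " voxels")

  pf <- stage("porosity",
              porosityFromIntensity(img, If = cfg$If, Is = cfg$Is,
                                    candidateMask = mask))
  pf <- stage("solidify", solidify(pf, cfg$epsMin))
  counts$fluid <- sum(!pf@solidMask)
  say("solidify (eps <= ", cfg$epsMin, ") leaves ", counts$fluid,
      " fluid voxels")
  if (counts$fluid == 0L)
    stop("flow domain is empty after solidification", call. = FALSE)

  rf <- stage("resistance", shrunkenViscousResistance(pf, cfg$fluid))

  outlets <- lapply(as.list(cfg$outletSides), boundarySpec)
  dom <- stage("domain",
               buildFlowDomain(pf, rf, inlets = boundarySpec(cfg$inletSide),
                               outlets = outlets,
                               symmetrySides = cfg$symmetrySides))
  counts$solved <- sum(dom@fluidMask)

  sol <- stage("solve",
               solveCreepingFlow(dom, cfg$fluid,
                                 solverConfig(inletSpeed = cfg$inletSpeed,
                                              tol = cfg$tol)))
  mb <- massBalanceReport(sol, dom)
  say("solved: relative mass imbalance ",
      signif(mb$relativeImbalance, 3))

  speed <- speedField(sol)
  sweep <- stage("sweep", isoSweep(speed, cfg$isoValues, sol@spacing,
                                   sol@origin))
  curve <- stage("indicator", indicatorCurve(sweep, cfg$iso0))
  sel <- stage("select",
               selectIso(curve, indicator = cfg$indicator,
                         slopeFraction = cfg$slopeFraction,
                         userIso = cfg$userIso))
  say("selected iso = ", signif(sel@chosenIso, 4), " m/s (", sel@method, ")")
  mesh <- stage("extract",
                extractIsosurface(speed, sel@chosenIso, sol@spacing,
                                  sol@origin))

  report <- list(timings = timings, counts = counts,
                 chosenIso = sel@chosenIso, selectionMethod = sel@method,
                 massBalance = mb,
                 surface = list(vertices = nrow(mesh@vertices),
                                triangles = nrow(mesh@triangles),
                                watertight = mesh@watertight,
                                volume = meshVolume(mesh),
                                area = meshArea(mesh)))

  if (!is.null(cfg$outputDir)) persistOutputs(cfg, pf, rf, sol, sweep,
                                              curve, sel, mesh, report)
  list(report = report, mesh = mesh, solution = sol, domain = dom,
       sweep = sweep, curve = curve, selection = sel)
}

persistOutputs <- function(cfg, pf, rf, sol, sweep, curve, sel, mesh,
                           report) {
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$outputDir, f)
  resolved <- cfg
  resolved$input <- if (is.character(cfg$input)) cfg$input else "<in-memory>"
  resolved$fluid <- list(rho = cfg$fluid@rho, mu = cfg$fluid@mu)
  yaml::write_yaml(resolved, out("config.yaml"))
  writeVolume(VolumetricImage(pf@epsilon, pf@spacing, pf@origin),
              out("porosity.nii.gz"))
  writeVolume(VolumetricImage(rf@Pv, rf@spacing, rf@origin),
              out("resistance.nii.gz"))
  writeVolume(VolumetricImage(sol@speed, sol@spacing, sol@origin),
              out("speed.nii.gz"))
  tb <- merge(sweep@table, curve@table[, c("iso", "dR", "dr")], by = "iso")
  tb <- tb[order(-tb$iso), ]
  write.csv(format(tb, digits = 12), out("sweep.csv"), row.names = FALSE,
            quote = FALSE)
  jsonlite::write_json(list(chosenIso = sel@chosenIso, method = sel@method,
                            iso0 = curve@iso0, R0 = curve@R0, r0 = curve@r0),
                       out("selection.json"), auto_unbox = TRUE, digits = NA)
  exportSurface(mesh, out("surface.stl"))
  ## stage timings vary run to run; the persisted report stays reproducible
  persist <- report[setdiff(names(report), "timings")]
  jsonlite::write_json(persist, out("report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(NULL)
}

#' Read a pipeline config from YAML
#'
#' @param path YAML file with [pipelineConfig()] fields (`input`,
#'   `coarseRange`, `preset`, ...).
#' @return Config list for [runPipeline()].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  assertThat(!is.null(y$input) && !is.null(y$coarseRange),
             "config must provide 'input' and 'coarseRange'")
  args <- y[intersect(names(y), names(formals(pipelineConfig)))]
  args$coarseRange <- as.numeric(args$coarseRange)
  if (!is.null(args$roi))
    args$roi <- list(lower = as.integer(args$roi$lower),
                     upper = as.integer(args$roi$upper))
  do.call(pipelineConfig, args)
}
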