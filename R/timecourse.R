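## Timecourse simulation: one scan pair per culture day, with volume
## compaction and optional mineral deposition raising the scatterer
## impedance via the forward calcium model.

#' Timecourse configuration
#'
#' Per-day phantom configurations (geometry, concentration, attenuation,
#' sound speed) plus per-day total deposited calcium mass.  The per-day
#' scatterer impedance is derived from the baseline impedance and the
#' deposited mass through the forward mineralization model
#' (\code{\link{impedanceForCalcium}}); the per-day configuration's own
#' impedance slot is overridden.
#'
#' @slot days culture days, strictly increasing.
#' @slot configs list of \linkS4class{PhantomConfig}, one per day
#'   (finite \code{constructRadius} so the construct volume is defined).
#' @slot calciumMassUg per-day total deposited calcium mass, ug.
#' @slot baselineImpedance Q_0 of the unmineralized cells.
#' @slot cScatterer scatterer sound speed, m/s.
#' @name TimecourseConfig-class
#' @rdname TimecourseConfig
#' @exportClass TimecourseConfig
setClass("TimecourseConfig",
  representation(days = "numeric", configs = "list",
                 calciumMassUg = "numeric", baselineImpedance = "numeric",
                 cScatterer = "numeric"))

setValidity("TimecourseConfig", function(object) {
  msgs <- character()
  if (length(object@days) < 1L) msgs <- c(msgs, "at least one day required")
  if (any(diff(object@days) <= 0)) msgs <- c(msgs, "days must be strictly increasing")
  if (length(object@configs) != length(object@days))
    msgs <- c(msgs, "one PhantomConfig per day required")
  if (length(object@calciumMassUg) != length(object@days))
    msgs <- c(msgs, "one calcium mass per day required")
  if (any(object@calciumMassUg < 0)) msgs <- c(msgs, "calcium mass must be >= 0")
  ok <- vapply(object@configs, function(cfg)
    is(cfg, "PhantomConfig") && is.finite(cfg@constructRadius), logical(1))
  if (!all(ok))
    msgs <- c(msgs, "configs must be PhantomConfigs with finite constructRadius")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TimecourseConfig
#'
#' @param days culture days.
#' @param configs list of \linkS4class{PhantomConfig}, one per day.
#' @param calciumMassUg per-day deposited calcium mass, ug.
#' @param baselineImpedance Q_0 of the cells alone.
#' @param cScatterer scatterer sound speed, m/s.
#' @return A \linkS4class{TimecourseConfig}.
#' @export
timecourseConfig <- function(days, configs,
                             calciumMassUg = numeric(length(days)),
                             baselineImpedance = 0.6, cScatterer = 1540) {
  new("TimecourseConfig", days = days, configs = configs,
      calciumMassUg = calciumMassUg, baselineImpedance = baselineImpedance,
      cScatterer = cScatterer)
}

#' Ground-truth construct volume of a configuration
#'
#' Volume of the simulated disc-shaped construct, pi R^2 L.
#'
#' @param config a \linkS4class{PhantomConfig} with finite
#'   \code{constructRadius}.
#' @return Volume, mm^3.
#' @export
constructVolumeTruth <- function(config) {
  stopifnot(is.finite(config@constructRadius))
  pi * config@constructRadius^2 * config@thickness
}

#' Simulate a construct development timecourse
#'
#' One scan pair per day.  The day's scatterer impedance is derived from
#' the configured deposited calcium mass via the forward mineralization
#' model, and the ground-truth record carries everything the estimators
#' should recover (radius, C, Q, alpha, c_t, L, construct volume, calcium
#' mass and concentration).
#'
#' @param tc a \linkS4class{TimecourseConfig}.
#' @param transducer a \linkS4class{TransducerSpec}.
#' @param medium a \linkS4class{MediumSpec}.
#' @param nLines,nSlices grid size per scan.
#' @param seed integer seed; day d uses substream \code{seed + d}.
#' @return List of per-day entries, each with \code{day}, \code{sample},
#'   \code{reference} and \code{truth}.
#' @export
simulateTimecourse <- function(tc, transducer = transducerSpec(),
                               medium = mediumSpec(), nLines = 64L,
                               nSlices = 1L, seed = 1L) {
  validObject(tc)
  out <- vector("list", length(tc@days))
  for (d in seq_along(tc@days)) {
    cfg <- tc@configs[[d]]
    volMm3 <- constructVolumeTruth(cfg)
    nScat <- cfg@concentration * volMm3
    qDay <- impedanceForCalcium(tc@calciumMassUg[d], tc@baselineImpedance,
                                nScat, cfg@scattererDiameter / 2,
                                rhoEcm = medium@rhoEcm, cEcm = medium@cEcm,
                                cScatterer = tc@cScatterer)
    cfg@impedance <- qDay
    scan <- simulateScan(cfg, transducer, medium, nLines = nLines,
                         nSlices = nSlices, seed = seed + d)
    scan$truth$day <- tc@days[d]
    scan$truth$impedance <- qDay
    scan$truth$baselineImpedance <- tc@baselineImpedance
    scan$truth$cq2 <- cfg@concentration * qDay^2
    scan$truth$volumeMm3 <- volMm3
    scan$truth$nScatterers <- nScat
    scan$truth$calciumMassUg <- tc@calciumMassUg[d]
    scan$truth$calciumConcUgMl <- tc@calciumMassUg[d] / (volMm3 / 1000)
    out[[d]] <- c(list(day = tc@days[d]), scan)
  }
  out
}

#' Default construct-development timecourse configuration
#'
#' Encodes the study conditions used throughout the package's recovery
#' tests: a disc-shaped cell-seeded construct (1 mm radius x 1 mm thick on
#' day 1) compacting to about 27.5% of its initial volume by day 7 and
#' stable thereafter; cell concentration falling from 1000 to 100 /mm^3
#' over 21 days; attenuation rising over time in culture; and day-21
#' mineralization depositing the calcium mass that corresponds to
#' \code{calciumConcUgMl} (default 40 ug/ml of the day-21 construct
#' volume).  See the methods vignette for the rationale behind each value.
#'
#' @param calciumConcUgMl day-21 deposited calcium concentration, ug/ml.
#' @param baselineImpedance Q_0 of the unmineralized cells.
#' @param snrDb acquisition noise level.
#' @return A \linkS4class{TimecourseConfig}.
#' @export
exampleTimecourseConfig <- function(calciumConcUgMl = 40,
                                    baselineImpedance = 0.6, snrDb = 30) {
  geom <- data.frame(
    day = c(1, 7, 14, 21),
    radius = c(1.0, 0.65, 0.65, 0.65),
    thickness = c(1.0, 0.65, 0.65, 0.65),
    concentration = c(1000, 800, 300, 100),
    attenuation = c(0.3, 0.4, 0.45, 0.5))
  configs <- lapply(seq_len(nrow(geom)), function(i)
    phantomConfig(scattererDiameter = 14,
                  concentration = geom$concentration[i],
                  impedance = baselineImpedance,
                  attenuation = geom$attenuation[i],
                  thickness = geom$thickness[i],
                  constructRadius = geom$radius[i],
                  snrDb = snrDb))
  volDay21 <- pi * geom$radius[4]^2 * geom$thickness[4]    # mm^3
  mass <- c(0, 0, 0, calciumConcUgMl * volDay21 / 1000)    # ug
  timecourseConfig(geom$day, configs, calciumMassUg = mass,
                   baselineImpedance = baselineImpedance)
}
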