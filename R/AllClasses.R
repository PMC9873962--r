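#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData rowData
NULL

#' Simulation configuration for synthetic myocardial-infarction cohorts
#'
#' An S4 container holding every parameter of the synthetic-cohort
#' generator: group sizes, the table of planted differential miRNAs,
#' baseline array intensity, the multiplicative noise level, the number of
#' non-differential background miRNAs, the fraction of rows simulated to
#' straddle the intensity floor, and the RNG seed.
#'
#' @slot groupSizes Named integer vector, patients per clinical group.
#'   Defaults to 10 each for NHF (normal cardiac function, the control
#'   group), AMHF (acute myocardial infarction with heart failure), AMNHF
#'   (acute myocardial infarction without heart failure) and OMHF (heart
#'   failure after old myocardial infarction).
#' @slot deTable `data.frame` with columns `mirna`, `control`, `case`,
#'   `fold_change`: the planted differential effects, one row per
#'   (miRNA, comparison) pair. The case-group mean of a planted miRNA is
#'   `baseline * fold_change`.
#' @slot baseline Baseline fluorescence intensity of a non-differential
#'   miRNA (arbitrary units).
#' @slot noiseCV Coefficient of variation of the per-cell multiplicative
#'   log-normal noise (dimensionless). Zero gives exact, noise-free
#'   intensities.
#' @slot nBackground Number of non-differential background miRNAs.
#' @slot belowFloorFraction Fraction of background rows drawn near the
#'   intensity floor so that the floor filter has rows to remove.
#' @slot floor Intensity floor used when placing the floor-straddling rows
#'   (same units as `baseline`).
#' @slot seed Integer RNG seed; a fixed seed yields byte-identical output.
#'
#' @seealso [SimConfig()], [simulateExpression()]
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    groupSizes = "integer",
    deTable = "data.frame",
    baseline = "numeric",
    noiseCV = "numeric",
    nBackground = "integer",
    belowFloorFraction = "numeric",
    floor = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  gs <- object@groupSizes
  if (length(gs) < 2L || is.null(names(gs)) || anyDuplicated(names(gs)))
    msg <- c(msg, "groupSizes must be a named vector with unique group labels")
  if (any(gs < 2L))
    msg <- c(msg, "all group sizes must be >= 2")
  de <- object@deTable
  need <- c("mirna", "control", "case", "fold_change")
  if (!all(need %in% names(de))) {
    msg <- c(msg, sprintf("deTable must have columns %s",
                          paste(need, collapse = ", ")))
  } else {
    if (nrow(de) > 0L && any(de$fold_change <= 0))
      msg <- c(msg, "all planted fold changes must be > 0")
    if (nrow(de) > 0L && !all(c(de$control, de$case) %in% names(gs)))
      msg <- c(msg, "deTable references a group absent from groupSizes")
    if (anyDuplicated(de[, c("mirna", "case")]))
      msg <- c(msg, "deTable has duplicate (mirna, case) pairs")
  }
  if (object@noiseCV < 0) msg <- c(msg, "noiseCV must be >= 0")
  if (object@baseline <= 0) msg <- c(msg, "baseline must be > 0")
  if (object@belowFloorFraction < 0 || object@belowFloorFraction >= 1)
    msg <- c(msg, "belowFloorFraction must be in [0, 1)")
  if (object@floor < 0) msg <- c(msg, "floor must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a [SimConfig-class] object
#'
#' @param groupSizes Named integer-like vector of patients per group.
#' @param deTable Planted differential-effect table; defaults to
#'   [plantedFoldChanges()], the full set of published screening effects
#'   for the three case-vs-control comparisons.
#' @param baseline Baseline intensity in fluorescence units.
#' @param noiseCV Coefficient of variation of the multiplicative noise.
#' @param nBackground Number of non-differential background miRNAs.
#' @param belowFloorFraction Fraction of background rows placed below the
#'   intensity floor.
#' @param floor Intensity floor (fluorescence units).
#' @param seed Integer RNG seed.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- SimConfig(noiseCV = 0, seed = 7)
#' cfg
#' @export
SimConfig <- function(groupSizes = c(NHF = 10L, AMHF = 10L,
                                     AMNHF = 10L, OMHF = 10L),
                      deTable = plantedFoldChanges(),
                      baseline = 1000,
                      noiseCV = 0.15,
                      nBackground = 300L,
                      belowFloorFraction = 0.05,
                      floor = 50,
                      seed = 1L) {
  new("SimConfig",
      groupSizes = structure(as.integer(groupSizes), names = names(groupSizes)),
      deTable = as.data.frame(deTable),
      baseline = as.numeric(baseline),
      noiseCV = as.numeric(noiseCV),
      nBackground = as.integer(nBackground),
      belowFloorFraction = as.numeric(belowFloorFraction),
      floor = as.numeric(floor),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat("  groups      :",
      paste(sprintf("%s(%d)", names(object@groupSizes), object@groupSizes),
            collapse = " "), "\n")
  cat("  planted     :", nrow(object@deTable), "miRNA x comparison effects\n")
  cat("  background  :", object@nBackground, "miRNAs, baseline",
      object@baseline, "\n")
  cat("  noise CV    :", object@noiseCV, "\n")
  cat("  seed        :", object@seed, "\n")
})

#' miRNA microarray intensity container
#'
#' A thin extension of
#' [SummarizedExperiment::SummarizedExperiment-class] carrying a single
#' `"intensity"` assay (miRNAs in rows, patient samples in columns) and a
#' mandatory `group` column in `colData` giving each sample's clinical
#' group. Validity enforces finite, non-negative intensities with no
#' missing cells.
#'
#' @seealso [MirnaArraySet()], [intensities()], [groupLabels()]
#' @exportClass MirnaArraySet
setClass("MirnaArraySet", contains = "SummarizedExperiment")

setValidity("MirnaArraySet", function(object) {
  msg <- character()
  if (!"intensity" %in% assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  else {
    m <- assay(object, "intensity")
    if (anyNA(m) || any(!is.finite(m)))
      msg <- c(msg, "intensities must be finite with no missing cells")
    else if (any(m < 0))
      msg <- c(msg, "intensities must be >= 0")
  }
  if (!"group" %in% names(colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (column names) must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a [MirnaArraySet-class]
#'
#' @param intensity Numeric matrix of fluorescence intensities, miRNA ids
#'   as row names and sample ids as column names.
#' @param group Character vector (or factor) of clinical group labels,
#'   one per column of `intensity`.
#' @return A validated [MirnaArraySet-class].
#' @examples
#' m <- matrix(100, 3, 4,
#'             dimnames = list(paste0("mir", 1:3), paste0("s", 1:4)))
#' MirnaArraySet(m, group = c("NHF", "NHF", "AMHF", "AMHF"))
#' @export
MirnaArraySet <- function(intensity, group) {
  stopifnot(is.matrix(intensity), length(group) == ncol(intensity))
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    colData = S4Vectors::DataFrame(group = as.character(group),
                                   row.names = colnames(intensity)))
  new("MirnaArraySet", se)
}

#' @describeIn MirnaArraySet Extract the intensity matrix.
#' @param x A `MirnaArraySet`.
#' @export
intensities <- function(x) {
  stopifnot(is(x, "MirnaArraySet"))
  assay(x, "intensity")
}

#' @describeIn MirnaArraySet Extract the per-sample clinical group labels.
#' @export
groupLabels <- function(x) {
  stopifnot(is(x, "MirnaArraySet"))
  as.character(colData(x)$group)
}

setMethod("show", "MirnaArraySet", function(object) {
  callNextMethod()
  tab <- table(groupLabels(object))
  cat("groups:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "),
      "\n")
})

#' Kaplan-Meier product-limit curve
#'
#' Step-function estimate of the survival function. `time` holds the
#' distinct observed times (events and censorings), `surv` the estimate
#' just after each time, `nRisk`/`nEvent`/`nCensor` the risk-set
#' bookkeeping at each time. The curve starts at 1 before the first
#' event and is non-increasing.
#'
#' @slot time Increasing observed times.
#' @slot surv Survival estimate S(t) immediately after each time.
#' @slot nRisk Number at risk just before each time.
#' @slot nEvent Deaths at each time.
#' @slot nCensor Censorings at each time.
#' @slot n Total number of patients.
#' @seealso [kmEstimate()], [medianSurvival()]
#' @exportClass KMCurve
setClass("KMCurve",
  representation(time = "numeric", surv = "numeric", nRisk = "numeric",
                 nEvent = "numeric", nCensor = "numeric", n = "integer"))

setValidity("KMCurve", function(object) {
  msg <- character()
  k <- length(object@time)
  if (any(lengths(list(object@surv, object@nRisk, object@nEvent,
                       object@nCensor)) != k))
    msg <- c(msg, "all step vectors must share one length")
  if (k > 1L && any(diff(object@time) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (any(object@surv < 0 | object@surv > 1))
    msg <- c(msg, "survival values must lie in [0, 1]")
  if (k > 1L && any(diff(object@surv) > 1e-12))
    msg <- c(msg, "survival must be non-increasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "KMCurve", function(object) {
  ev <- sum(object@nEvent)
  cat(sprintf("KMCurve: %d patients, %d events, %d time points\n",
              object@n, as.integer(ev), length(object@time)))
  med <- medianSurvival(object)
  cat("  median survival:", if (is.na(med)) "not reached" else format(med),
      "\n")
})
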