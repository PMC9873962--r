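#' @importFrom stats rnorm rlnorm runif rexp median sd uniroot
NULL

## One global seed expands to independent per-stream sub-seeds so that
## adding or resizing one data stream never perturbs another.
expandSeed <- function(seed, n = 4L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

## Mean-preserving multiplicative log-normal noise: for CV c the
## log-scale sd is sqrt(log(1+c^2)) and the log-scale mean is offset so
## that E[noise] = 1 exactly.
lnormNoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Simulate a plasma miRNA intensity matrix with planted effects
#'
#' Generates a miRNA-by-sample fluorescence matrix for the configured
#' clinical groups. Every planted (miRNA, case-group) pair in the
#' configuration's `deTable` has expected case mean
#' `baseline * fold_change`; in the NHF control group and in any group a
#' miRNA is not planted for, the expected mean is `baseline`. Noise is
#' multiplicative log-normal per cell with the configured coefficient of
#' variation, centred so that the expectation of each cell equals its
#' planted mean (`noiseCV = 0` reproduces the planted fold changes to
#' machine precision). A `belowFloorFraction` share of background rows is
#' drawn at low intensity (below the floor) so the downstream intensity
#' filter has work to do.
#'
#' @param config A [SimConfig-class].
#' @return A list with elements
#'   \describe{
#'     \item{experiment}{[MirnaArraySet-class] of intensities.}
#'     \item{design}{`data.frame` mapping `sample_id` to `group`.}
#'     \item{truth}{the planted-effect table (a copy of
#'       `config@deTable`), so downstream tests never need to re-derive
#'       the ground truth.}
#'   }
#' @examples
#' sim <- simulateExpression(SimConfig(noiseCV = 0, seed = 1))
#' dim(intensities(sim$experiment))
#' @export
simulateExpression <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)

  gs <- config@groupSizes
  groups <- rep(names(gs), gs)
  sampleIds <- unlist(lapply(names(gs), function(g)
    paste0(g, "_", seq_len(gs[[g]]))), use.names = FALSE)

  de <- config@deTable
  planted <- unique(de$mirna)
  nFloor <- as.integer(round(config@belowFloorFraction *
                             (length(planted) + config@nBackground)))
  nFloor <- min(nFloor, config@nBackground)
  nBg <- config@nBackground - nFloor
  bgIds <- if (nBg > 0L) sprintf("hsa-miR-bg-%04d", seq_len(nBg)) else character()
  floorIds <- if (nFloor > 0L) sprintf("hsa-miR-low-%04d", seq_len(nFloor)) else character()
  mirnas <- c(planted, bgIds, floorIds)

  ## expected-mean matrix
  mu <- matrix(config@baseline, nrow = length(mirnas), ncol = length(groups),
               dimnames = list(mirnas, sampleIds))
  if (nrow(de) > 0L) {
    for (i in seq_len(nrow(de))) {
      cols <- groups == de$case[i]
      mu[de$mirna[i], cols] <- config@baseline * de$fold_change[i]
    }
  }
  if (nFloor > 0L) {
    lowMeans <- runif(nFloor, min = 0.4 * config@floor, max = 0.96 * config@floor)
    mu[floorIds, ] <- matrix(lowMeans, nFloor, length(groups))
  }

  m <- mu * matrix(lnormNoise(length(mu), config@noiseCV),
                   nrow(mu), ncol(mu))

  ## contract: every floor row has at least one sample below the floor.
  ## The draw all but guarantees it already; nudge the row minimum on the
  ## astronomically rare miss.
  if (nFloor > 0L) {
    for (r in floorIds) {
      if (min(m[r, ]) >= config@floor) {
        j <- which.min(m[r, ])
        m[r, j] <- 0.96 * config@floor
      }
    }
  }

  list(experiment = MirnaArraySet(m, group = groups),
       design = data.frame(sample_id = sampleIds, group = groups,
                           stringsAsFactors = FALSE),
       truth = de)
}

#' Simulate a stack of technical-replicate scans
#'
#' Microarray scanning reads each spot several times; the pipeline
#' averages the reads before filtering. This helper emits `nReplicates`
#' matrices around the same expected-mean surface, each with independent
#' per-read noise, for exercising [averageReplicates()].
#'
#' @param config A [SimConfig-class]; `noiseCV` is the per-read CV.
#' @param nReplicates Number of technical reads (default 10).
#' @return List of `nReplicates` intensity matrices with identical
#'   dimnames.
#' @export
simulateReplicateStack <- function(config, nReplicates = 10L) {
  stopifnot(nReplicates >= 1L)
  base <- simulateExpression(config)
  mu <- intensities(base$experiment)  # one realization as the mean surface
  set.seed(config@seed + 1L)
  lapply(seq_len(nReplicates), function(i)
    mu * matrix(lnormNoise(length(mu), config@noiseCV), nrow(mu), ncol(mu)))
}

## group-level echocardiographic parameter profiles (means); case groups
## have depressed contractility (lower EF and fractional shortening),
## dilation in the heart-failure groups, and the published group-mean
## anthropometrics (height in metres 1.62/1.64/1.65/1.65, weight in kg).
echoProfiles <- function() {
  list(
    NHF   = list(LVEDV = 110, EF = 0.62, FS = 0.34, LVIDd = 4.7,
                 IVS = 0.95, PWTs = 1.45, SBP = 118, LVET = 0.30,
                 HR = 72, height = 162, weight = 55.3),
    AMHF  = list(LVEDV = 160, EF = 0.35, FS = 0.18, LVIDd = 5.9,
                 IVS = 1.00, PWTs = 1.20, SBP = 105, LVET = 0.26,
                 HR = 86, height = 164, weight = 55.9),
    AMNHF = list(LVEDV = 130, EF = 0.50, FS = 0.27, LVIDd = 5.2,
                 IVS = 0.98, PWTs = 1.30, SBP = 112, LVET = 0.28,
                 HR = 78, height = 165, weight = 52.8),
    OMHF  = list(LVEDV = 165, EF = 0.33, FS = 0.17, LVIDd = 6.0,
                 IVS = 1.02, PWTs = 1.18, SBP = 104, LVET = 0.26,
                 HR = 88, height = 165, weight = 57.5)
  )
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate echocardiographic records for one clinical group
#'
#' Draws per-patient echocardiographic measurements (volumes, wall
#' thicknesses, internal diameters, systolic blood pressure, ejection
#' time, stroke volume, heart rate) plus height and weight from
#' group-specific physiological profiles. Case groups are generated with
#' lower contractility (ejection fraction and fractional shortening) than
#' the NHF control group; heart-failure groups are dilated. Construction
#' guarantees the anatomical invariants `LVESV < LVEDV` and
#' `LVIDs < LVIDd`.
#'
#' @param group One of `"NHF"`, `"AMHF"`, `"AMNHF"`, `"OMHF"`.
#' @param n Number of patients (>= 1).
#' @param seed Integer RNG seed.
#' @return `data.frame` with one row per patient and columns `patient_id`,
#'   `group`, `LVEDV`, `LVESV` (mL), `IVS`, `PWTs` (cm), `LVIDd`, `LVIDs`
#'   (cm), `SBP` (mmHg), `LVET` (s), `LVSV` (mL), `heart_rate`
#'   (beats/min), `height` (cm), `weight` (kg).
#' @examples
#' head(simulateEcho("NHF", n = 5, seed = 1))
#' @export
simulateEcho <- function(group, n, seed = 1L) {
  profiles <- echoProfiles()
  if (!group %in% names(profiles))
    stop("unknown group label: ", group)
  stopifnot(n >= 1L)
  p <- profiles[[group]]
  set.seed(as.integer(seed))

  LVEDV <- clamp(rnorm(n, p$LVEDV, 0.10 * p$LVEDV), 60, 260)
  EF    <- clamp(rnorm(n, p$EF, 0.05), 0.10, 0.80)
  LVESV <- LVEDV * (1 - EF)
  LVIDd <- clamp(rnorm(n, p$LVIDd, 0.30), 3.5, 7.5)
  FS    <- clamp(rnorm(n, p$FS, 0.03), 0.05, 0.55)
  LVIDs <- LVIDd * (1 - FS)
  IVS   <- clamp(rnorm(n, p$IVS, 0.08), 0.6, 1.6)
  PWTs  <- clamp(rnorm(n, p$PWTs, 0.12), 0.7, 2.0)
  SBP   <- clamp(rnorm(n, p$SBP, 10), 80, 180)
  LVET  <- clamp(rnorm(n, p$LVET, 0.02), 0.18, 0.40)
  HR    <- clamp(rnorm(n, p$HR, 8), 45, 130)
  height <- clamp(rnorm(n, p$height, 5), 145, 185)
  weight <- clamp(rnorm(n, p$weight, 6), 38, 90)

  data.frame(
    patient_id = sprintf("%s_%02d", group, seq_len(n)),
    group = group,
    LVEDV = LVEDV, LVESV = LVESV, IVS = IVS, PWTs = PWTs,
    LVIDd = LVIDd, LVIDs = LVIDs, SBP = SBP, LVET = LVET,
    LVSV = LVEDV - LVESV, heart_rate = HR,
    height = height, weight = weight,
    stringsAsFactors = FALSE)
}

#' Simulate a survival cohort split by target-gene expression
#'
#' Event times are exponential; patients in the high-expression stratum
#' have hazard `hazard_ratio` times the low-expression baseline hazard,
#' emulating a cohort in which high target-gene expression carries worse
#' prognosis. Expression values are drawn in two well-separated strata so
#' that a median split ([splitByExpression()]) recovers the planted
#' grouping. Censoring times are independent uniform on `(0, tau)` with
#' `tau` solved numerically so the expected censored fraction equals
#' `censor_rate`; `censor_rate = 0` observes every event.
#'
#' @param n Cohort size (>= 2).
#' @param split Fraction of patients in the high-expression stratum,
#'   strictly between 0 and 1 (default 0.5).
#' @param hazard_ratio Hazard of the high- relative to the low-expression
#'   stratum (> 0).
#' @param censor_rate Expected fraction of censored patients in `[0, 1)`.
#' @param seed Integer RNG seed.
#' @param baseline_hazard Event hazard of the low-expression stratum per
#'   unit follow-up time (default 0.1).
#' @return `data.frame` with columns `patient_id`, `time`, `event`
#'   (logical, `TRUE` = death observed), `expression` and `stratum`
#'   (planted truth, `"high"`/`"low"`).
#' @examples
#' simulateSurvival(n = 10, hazard_ratio = 3, seed = 1)
#' @export
simulateSurvival <- function(n, split = 0.5, hazard_ratio = 3,
                             censor_rate = 0.2, seed = 1L,
                             baseline_hazard = 0.1) {
  stopifnot(n >= 2L, split > 0, split < 1, hazard_ratio > 0,
            censor_rate >= 0, censor_rate < 1, baseline_hazard > 0)
  set.seed(as.integer(seed))

  nHigh <- max(1L, min(n - 1L, as.integer(round(n * split))))
  stratum <- sample(c(rep("high", nHigh), rep("low", n - nHigh)))
  hazard <- ifelse(stratum == "high",
                   baseline_hazard * hazard_ratio, baseline_hazard)
  evtime <- rexp(n, rate = hazard)

  ## expression strata separated so the cohort median falls in the gap
  expression <- ifelse(stratum == "high", runif(n, 3, 4), runif(n, 1, 2))

  if (censor_rate > 0) {
    ## For T ~ Exp(h), C ~ U(0, tau): P(C < T) = (1 - exp(-h*tau))/(h*tau).
    ## Solve for tau at the cohort-average hazard.
    h <- mean(hazard)
    f <- function(tau) (1 - exp(-h * tau)) / (h * tau) - censor_rate
    tau <- uniroot(f, lower = 1e-8, upper = 1e6 / h, tol = 1e-10)$root
    ctime <- runif(n, 0, tau)
    event <- evtime <= ctime
    time <- pmin(evtime, ctime)
  } else {
    event <- rep(TRUE, n)
    time <- evtime
  }

  data.frame(patient_id = sprintf("pt_%03d", seq_len(n)),
             time = time, event = event,
             expression = expression, stratum = stratum,
             stringsAsFactors = FALSE)
}

#' Simulate an optical-density viability trajectory
#'
#' Cell-viability assays read optical density (OD) at 490 nm daily over a
#' multi-day culture; under miRNA overexpression viability declines. The
#' generator interpolates per-day expected OD linearly from `start_od` on
#' day 1 to `end_od` on the final day and adds independent Gaussian well
#' noise; `noise_sd = 0` places every well exactly on the line, so the
#' final-day mean equals `end_od` exactly.
#'
#' @param days Number of consecutive days (>= 2).
#' @param start_od Expected OD on day 1.
#' @param end_od Expected OD on the final day.
#' @param n_wells Replicate wells per day (>= 1, default 4).
#' @param noise_sd Standard deviation of the per-well Gaussian noise.
#' @param seed Integer RNG seed.
#' @return `data.frame` with columns `day`, `well`, `od`.
#' @examples
#' od <- simulateOD(days = 5, start_od = 2.4, end_od = 1.75,
#'                  noise_sd = 0, seed = 1)
#' odSummary(od)
#' @export
simulateOD <- function(days, start_od, end_od, n_wells = 4L,
                       noise_sd = 0.05, seed = 1L) {
  stopifnot(days >= 2L, n_wells >= 1L, noise_sd >= 0,
            start_od > 0, end_od > 0)
  set.seed(as.integer(seed))
  mu <- seq(start_od, end_od, length.out = days)
  od <- rep(mu, each = n_wells) + rnorm(days * n_wells, 0, noise_sd)
  data.frame(day = rep(seq_len(days), each = n_wells),
             well = rep(seq_len(n_wells), times = days),
             od = pmax(od, .Machine$double.eps))
}
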