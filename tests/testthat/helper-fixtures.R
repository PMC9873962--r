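# small in-code fixtures shared across test files

# tiny config: few background rows so per-test screens stay fast
tinyConfig <- function(seed = 1L, noiseCV = 0.15, nBackground = 60L,
                       deTable = plantedFoldChanges(), ...) {
  SimConfig(seed = seed, noiseCV = noiseCV, nBackground = nBackground,
            deTable = deTable, ...)
}

# simulate -> preprocess -> screen, silenced
quietScreen <- function(config, case, control = "NHF",
                        params = screenParams()) {
  sim <- simulateExpression(config)
  pre <- suppressMessages(preprocess(sim$experiment))
  suppressMessages(screenMirnas(pre, control = control, case = case,
                                params = params))
}

# hand-built MirnaArraySet from a matrix
mas <- function(m, group) {
  if (is.null(rownames(m))) rownames(m) <- paste0("mir", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  MirnaArraySet(m, group = group)
}

# random valid echocardiographic records for oracle sweeps
randomEchoRecords <- function(n, seed = 1L) {
  set.seed(seed)
  lvedv <- runif(n, 70, 240)
  ef <- runif(n, 0.15, 0.75)
  lvidd <- runif(n, 3.8, 7.0)
  fs <- runif(n, 0.08, 0.50)
  data.frame(
    patient_id = sprintf("r%04d", seq_len(n)),
    LVEDV = lvedv, LVESV = lvedv * (1 - ef),
    IVS = runif(n, 0.6, 1.6), PWTs = runif(n, 0.7, 2.0),
    LVIDd = lvidd, LVIDs = lvidd * (1 - fs),
    SBP = runif(n, 85, 175), LVET = runif(n, 0.20, 0.38),
    LVSV = lvedv * ef, heart_rate = runif(n, 50, 120),
    height = runif(n, 150, 185), weight = runif(n, 42, 85))
}
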