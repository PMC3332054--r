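# Shared fixture builders. All data are generated in code under fixed seeds.

suppressPackageStartupMessages(library(SummarizedExperiment))

# Compact study-design simulation: full four-group layout, small probe count.
tinySim <- function(seed = 1, nProbes = 400,
                    signatureSpec = list(PTPN11 = list(n = 15, effectSize = 1.5)),
                    confoundSpec = list(nAge = 10, nSex = 0, nLeukocyte = 0,
                                        beta = 0.6),
                    detection = list(lowExpressionQuantile = 0.2, dropoutP = 0.9),
                    ...) {
  simulatePBMC(simulationConfig(
    nProbes = nProbes,
    groupSizes = c(control = 8, PTPN11 = 7, SOS1 = 4, SHOC2 = 4),
    signatureSpec = signatureSpec, confoundSpec = confoundSpec,
    detection = detection, seed = seed, ...))
}

# Log2-ratio container straight from a matrix, default all-control groups.
makeLR <- function(m, groups = rep("control", ncol(m))) {
  if (is.null(rownames(m))) rownames(m) <- paste0("p", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  Log2RatioExperiment(m, samples = data.frame(sample_id = colnames(m),
                                              group = groups))
}

# A Signature built directly from entries (directions derived from the sign).
makeSignature <- function(probes, log2ratios, comparison = "PTPN11",
                          t_p = rep(1e-4, length(probes)),
                          snr = log2ratios * 2) {
  new("Signature", comparison = comparison, caseGroups = comparison,
      controlGroup = "control",
      entries = data.frame(probe_id = probes, mean_log2ratio = log2ratios,
                           t_p = t_p, snr = snr,
                           direction = ifelse(log2ratios > 0, "up", "down"),
                           stringsAsFactors = FALSE),
      thresholds = unclass(signatureThresholds()))
}

# Planted-design simulation used by the calibration and power checks:
# 5000 probes, study group sizes, 200 PTPN11-planted probes of two-fold
# effect over 0.5 log2 residual noise, no confounders, no dropout.
plantedSim <- function(seed) {
  simulatePBMC(simulationConfig(
    nProbes = 5000,
    signatureSpec = list(PTPN11 = list(n = 200, effectSize = 1.0)),
    confoundSpec = list(nAge = 0, nSex = 0, nLeukocyte = 0),
    detection = list(lowExpressionQuantile = 0, dropoutP = 0),
    residualSd = 0.5, seed = seed))
}

# Same design under the global null (no planted effects).
nullSim <- function(seed, nProbes = 5000) {
  simulatePBMC(simulationConfig(
    nProbes = nProbes, signatureSpec = list(),
    confoundSpec = list(nAge = 0, nSex = 0, nLeukocyte = 0),
    detection = list(lowExpressionQuantile = 0, dropoutP = 0),
    residualSd = 0.5, seed = seed))
}
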