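# Shared fixtures: small phantoms and hand-built cases, all generated in
# code at test time.

smallSpec <- function(seed = 1L, nTZ = 0L, nPZ = 1L, nMimic = 1L,
                      noise = 0.04) {
  phantomSpec(volumeShape = c(8L, 32L, 32L), spacingMm = c(3, 2.5, 2.5),
              nLesionsTZ = nTZ, nLesionsPZ = nPZ, nMimicPairs = nMimic,
              lesionRadiusMm = c(4, 6), noiseSigma = noise, seed = seed)
}

smallCase <- function(...) generatePhantom(smallSpec(...))

tinyModelConfig <- function(outChannels = 2L) {
  modelConfig(inChannels = 5L, encoderChannels = c(4L, 6L, 8L),
              blocksPerLevel = 1L, decoderBlocksPerLevel = 1L,
              outChannels = outChannels)
}

# a hand-built rectangular case: no randomness, fully controlled geometry
boxCase <- function(D = 4L, H = 16L, W = 16L, spacing = c(3, 1, 1),
                    lesionVox = NULL, tzRows = 5:8, pzRows = 9:12) {
  z <- array(0, c(D, H, W))
  tz <- z; tz[, tzRows, 3:(W - 2)] <- 1
  pz <- z; pz[, pzRows, 3:(W - 2)] <- 1
  les <- z
  tab <- data.frame(lesionId = integer(), zone = character(),
                    cz = numeric(), cy = numeric(), cx = numeric(),
                    radiusMm = numeric())
  if (!is.null(lesionVox)) {
    les[lesionVox[1], lesionVox[2], lesionVox[3]] <- 1
    zone <- if (tz[lesionVox[1], lesionVox[2], lesionVox[3]] == 1)
      "TZ" else "PZ"
    tab <- data.frame(lesionId = 1L, zone = zone, cz = lesionVox[1],
                      cy = lesionVox[2], cx = lesionVox[3], radiusMm = 1)
  }
  new("MpMRICase", t2w = z + 0.5, adc = z + 0.5, highb = z + 0.5,
      tzMask = tz, pzMask = pz, lesionMask = les, lesionTable = tab,
      spacingMm = spacing, caseId = "box")
}
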