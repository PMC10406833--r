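# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

getFixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), .fixtures)
  get(name, envir = .fixtures)
}

# A reduced design: the full 4-location HP cycle with 2 biased blocks per
# sequence (11 blocks of 56), enough for 10-fold decoding at avg_k = 3.
smallDesign <- function(seed = 42L)
  designConfig(hp_cycle = c(2L, 6L, 4L, 0L), neutral_after = 2,
               practice = FALSE, seed = seed)

# Two-location micro design for fast structural tests (5 blocks).
microDesign <- function(seed = 42L)
  designConfig(hp_cycle = c(0L, 4L), neutral_after = 2, practice = FALSE,
               seed = seed)

smallSchedule <- function() getFixture("smallSchedule", function()
  generateSchedule(smallDesign()))

# Epochs over a trimmed window keep memory and runtime down; the decode
# window -200..600 ms is fully inside.
epochWindow <- c(-250, 650)

signalEpochs <- function() getFixture("signalEpochs", function()
  rereference(generateEEG(smallSchedule(), signalModel(), seed = 7,
                          window = epochWindow)))

nullEpochs <- function() getFixture("nullEpochs", function()
  rereference(generateEEG(smallSchedule(), signalModel(class_gain = 0),
                          seed = 7, window = epochWindow)))

# Manufactures a minimal EpochSet wrapper for tests that only need trial
# bookkeeping (flags), not EEG content.
stubEpochs <- function(trials) {
  n <- nrow(trials)
  new("EpochSet", data = array(0, c(n, 1, 2)), srate = 512,
      times = c(0, 2), channels = "Cz", trials = trials,
      flags = data.frame(keep = rep(TRUE, n), reason = rep("", n)),
      log = list())
}
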