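# Condition classes used across the package so that callers (and the CLI)
# can distinguish bad options, bad input data and numerical degeneracy.

stopUsage <- function(...) {
  stop(errorCondition(paste0(...), class = c("sludgeUsageError", "sludgeError")))
}

stopInput <- function(...) {
  stop(errorCondition(paste0(...), class = c("sludgeInputError", "sludgeError")))
}

stopDegenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("sludgeDegenerateError", "sludgeError")))
}
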