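# Structured error conditions so callers (and the command-line wrapper)
# can distinguish bad input data from bad configuration or short series.

snError <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "snError")))
}

snValidationError <- function(msg) snError(msg, "snValidationError")
snConfigError <- function(msg) snError(msg, "snConfigError")
snInsufficientDataError <- function(msg) snError(msg, "snInsufficientDataError")
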