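## Structured error conditions. Every error raised by the package carries a
## specific condition class so callers (and tests) can discriminate failure
## modes without parsing messages.

ventvolError <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "ventvolError"), call = call))
}

stopUnsupportedImage <- function(message) ventvolError(message, "UnsupportedImage")
stopInvalidGeometry  <- function(message) ventvolError(message, "InvalidGeometry")
stopDegenerateHistogram <- function(message) ventvolError(message, "DegenerateHistogram")
stopParcellationFailure <- function(message) ventvolError(message, "ParcellationFailure")
stopAlignmentError   <- function(message) ventvolError(message, "AlignmentError")
stopDegenerateLabels <- function(message) ventvolError(message, "DegenerateLabels")
stopInvalidArgument  <- function(message) ventvolError(message, "InvalidArgument")
stopDegenerateFeature <- function(message) ventvolError(message, "DegenerateFeature")
stopMissingFeature   <- function(message) ventvolError(message, "MissingFeature")
stopInvalidSplit     <- function(message) ventvolError(message, "InvalidSplit")
stopInvalidSpec      <- function(message) ventvolError(message, "InvalidSpec")
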