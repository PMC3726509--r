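# Classed conditions so callers (and the CLI) can map failures to exit codes:
# validation/parse errors -> 1, computation errors -> 2.

rs_validation_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("refstab_validation_error", "refstab_error")))
}

rs_parse_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("refstab_parse_error",
                                "refstab_validation_error", "refstab_error")))
}

rs_computation_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("refstab_computation_error", "refstab_error")))
}
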