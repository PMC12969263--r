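# Structured error conditions. Three families are distinguished so that
# callers (and the CLI) can map them to distinct exit codes:
#   * input errors   -- malformed sequences, files, unknown residue letters
#   * config errors  -- inconsistent option combinations
#   * domain errors  -- numerically out-of-range arguments
abort_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("hdxmix_input_error", "hdxmix_error")))
}

abort_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("hdxmix_config_error", "hdxmix_error")))
}

abort_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("hdxmix_domain_error", "hdxmix_error")))
}

# "no exchangeable amide" is a domain error with its own subclass so code
# iterating over residues can distinguish it from genuinely bad input
abort_no_amide <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("hdxmix_no_amide_error", "hdxmix_domain_error",
                                "hdxmix_error")))
}
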