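# Structured conditions so callers (and the CLI) can distinguish schema/validation
# failures from estimator precondition failures.

stop_validation <- function(msg, ...) {
  stop(structure(
    class = c("stmf_validation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_precondition <- function(msg, ...) {
  stop(structure(
    class = c("stmf_precondition_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
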