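## Structured condition helpers. All package errors carry class
## c("vitmech_<kind>", "vitmech_error", "error", "condition") so callers can
## catch a specific failure mode without string matching.

vm_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "vitmech_error")))
}

vm_warn <- function(message, class, ...) {
  warning(warningCondition(message, ..., class = c(class, "vitmech_warning")))
}
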