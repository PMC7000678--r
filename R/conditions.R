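# Structured condition helpers: every contract violation raises an error
# condition carrying a package-specific class so callers can dispatch on it.

ns_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "neustonet_error")))
}

ns_warn <- function(class, msg, ...) {
  warning(warningCondition(sprintf(msg, ...),
                           class = c(class, "neustonet_warning")))
}
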