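# Structured error conditions. Every user-facing failure signals a condition
# of class c(<specific>, "phenokg_error", "error"), so callers can branch on
# the failure kind without parsing messages.

stop_phenokg <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "phenokg_error")))
}

stop_lookup <- function(what) {
  stop_phenokg("phenokg_lookup_error", sprintf("unknown term or resource: '%s'", what),
               curie = what)
}

stop_syntax <- function(message, position = NA_integer_) {
  stop_phenokg("phenokg_syntax_error",
               if (is.na(position)) message else sprintf("%s (at position %d)", message, position),
               position = position)
}
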