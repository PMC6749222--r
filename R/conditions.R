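# Structured error conditions. Every error the package raises carries a
# subclass so callers (and the CLI exit-code mapping) can dispatch on it.

hv_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("hv_", class, "_error"), "hv_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

hv_warn <- function(msg, class) {
  warning(structure(
    class = c(paste0("hv_", class, "_warning"), "hv_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_odd_window <- function(w, name, min = 3L) {
  if (length(w) != 1L || !is.finite(w) || w < min || w %% 2L != 1L) {
    hv_stop(sprintf("`%s` must be an odd integer >= %d, got %s",
                    name, min, paste(w, collapse = ",")), "parameter")
  }
  as.integer(w)
}
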