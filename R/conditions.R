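# Classed conditions so callers can distinguish validation failures.

cpt_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "cpt_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

cpt_warn <- function(message, class) {
  warning(structure(
    class = c(class, "cpt_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    cpt_abort(sprintf("`%s` must be a single finite number", name),
              "cpt_type_error")
  invisible(x)
}
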