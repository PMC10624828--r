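# Classed conditions so callers can distinguish failure modes programmatically.
# Every error signalled by the package carries class c("fb_<what>", "fb_error").

fb_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "fb_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

fb_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "fb_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# shared argument checks ------------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    fb_stop("fb_domain_error", "`%s` must be a single finite number", name)
  bad_low <- if (allow_equal_lower) x < lower else x <= lower
  if (bad_low || x > upper)
    fb_stop("fb_domain_error", "`%s` = %g is outside its valid range", name, x)
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    fb_stop("fb_domain_error", "`%s` must be TRUE or FALSE", name)
  invisible(x)
}
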