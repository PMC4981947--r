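## internal helpers shared across modules

stop_bloomkit <- function(msg, class) {
  stop(structure(class = c(class, "bloomkit_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          class = "bloomkit_domain_error") {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop_bloomkit(sprintf("`%s` must be finite numeric", name), class)
  if (any(x < lower) || any(x > upper))
    stop_bloomkit(sprintf("`%s` must lie in [%s, %s]", name, lower, upper), class)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    stop_bloomkit(sprintf("`%s` must be an integer >= %d", name, min),
                  "bloomkit_config_error")
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
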