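# Classed conditions so callers can test failure modes precisely.
# Every error carries class c("fluorotrack_<what>", "fluorotrack_error").

ft_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "fluorotrack_error"),
                      call = call))
}

ft_assert_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    ft_stop(sprintf("%s must be finite numeric", what),
            "fluorotrack_invalid_input")
  invisible(x)
}
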