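Z95 <- 1.959964  # 95% normal CI multiplier

#' @keywords internal
new_causal_estimate <- function(method, beta, se, ci_low, ci_high, p_value,
                                settings = list()) {
  structure(list(method = method, beta = beta, se = se,
                 ci_low = ci_low, ci_high = ci_high,
                 p_value = p_value, settings = settings),
            class = "causal_estimate")
}

#' @export
print.causal_estimate <- function(x, digits = 4, ...) {
  cat(x$method, "\n")
  cat(sprintf("  beta = %.*g (SE %.*g)\n", digits, x$beta, digits, x$se))
  cat(sprintf("  95%% CI [%.*g, %.*g], p = %.*g\n",
              digits, x$ci_low, digits, x$ci_high, digits, x$p_value))
  invisible(x)
}

#' @export
as.data.frame.causal_estimate <- function(x, ...) {
  data.frame(method = x$method, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, p = x$p_value,
             stringsAsFactors = FALSE)
}
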