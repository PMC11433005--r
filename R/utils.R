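#' @importFrom stats rnorm runif sd var qnorm pnorm pt qt pf aov coef lm
#' @importFrom stats complete.cases median quantile setNames cor
#' @importFrom utils combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed condition so callers can test on error class, not message wording
stop_husphen <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "husphen_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

warn_husphen <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "husphen_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_husphen("validation_error", "'%s' must be a single finite number", name)
  ok <- if (strict_min) x > min else x >= min
  if (!ok)
    stop_husphen("validation_error", "'%s' must be %s %s", name,
                 if (strict_min) ">" else ">=", format(min))
  invisible(x)
}

# population (n-denominator) standard deviation
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}
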