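# Internal helpers shared across modules.

# Configuration errors always name the offending field so a bad config is
# diagnosable from the message alone.
stop_config <- function(field, msg) {
  rlang::abort(
    sprintf("invalid configuration: field `%s` %s", field, msg),
    class = "rsga_config_error"
  )
}

stop_format <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "rsga_format_error")
}

check_number <- function(x, field, min = -Inf, max = Inf,
                         strict_min = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config(field, "must be a single finite number")
  }
  if (strict_min && x <= min) {
    stop_config(field, sprintf("must be > %s", min))
  }
  if (!strict_min && x < min) {
    stop_config(field, sprintf("must be >= %s", min))
  }
  if (x > max) stop_config(field, sprintf("must be <= %s", max))
  if (integerish && x != round(x)) stop_config(field, "must be an integer")
  invisible(x)
}

check_fraction <- function(x, field) check_number(x, field, min = 0, max = 1)

# Population (n-denominator) standard deviation, used for screen Z-scores.
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}

# Two-sample p-value with an explicit guard for degenerate (zero-variance)
# inputs: identical constant samples give p = 1, constant samples with
# different means give p = 0; t.test() itself errors on constant data.
two_sample_p <- function(x, y, test = c("welch", "student", "wilcoxon")) {
  test <- match.arg(test)
  eps <- 1e-12
  if (test == "wilcoxon") {
    return(suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value))
  }
  if (var(x) < eps && var(y) < eps) {
    return(if (abs(mean(x) - mean(y)) < eps) 1 else 0)
  }
  t.test(x, y, var.equal = (test == "student"))$p.value
}
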