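#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish failure modes programmatically.
me_stop <- function(msg, class, call. = FALSE, ...) {
  stop(errorCondition(msg, ..., class = c(class, "microed_error")))
}

me_warn <- function(msg, class, ...) {
  warning(warningCondition(msg, ..., class = c(class, "microed_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Non-standard-evaluation column names used in ggplot2 calls.
utils::globalVariables(c("phi_mid", "intensity", "sigma", "value", "x", "y"))

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is_scalar_num(x))
    me_stop(sprintf("`%s` must be a single finite number", name), "invalid_argument")
  if (positive && x <= 0)
    me_stop(sprintf("`%s` must be > 0 (got %g)", name, x), "invalid_argument")
  if (nonneg && x < 0)
    me_stop(sprintf("`%s` must be >= 0 (got %g)", name, x), "invalid_argument")
  invisible(x)
}

check_frame <- function(frame, name = "frame") {
  if (!is.matrix(frame) || !is.numeric(frame))
    me_stop(sprintf("`%s` must be a numeric matrix (fast, slow)", name),
            "invalid_argument")
  invisible(frame)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
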