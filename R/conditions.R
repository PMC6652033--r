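# Classed error conditions used across the package. Every error raised by
# reflexquant carries the "reflexquant_error" class plus a specific subclass so
# callers (and tests) can discriminate failure modes without string matching.

stop_reflex <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "reflexquant_error"),
                      call = call))
}

format_error <- function(message) stop_reflex(message, "reflexquant_format_error")
io_error <- function(message) stop_reflex(message, "reflexquant_io_error")
usage_error <- function(message) stop_reflex(message, "reflexquant_usage_error")
aliasing_error <- function(message) stop_reflex(message, "reflexquant_aliasing_error")
calibration_error <- function(message) stop_reflex(message, "reflexquant_calibration_error")
no_impact_error <- function(message) stop_reflex(message, "reflexquant_no_impact_error")
insufficient_data_error <- function(message) stop_reflex(message, "reflexquant_insufficient_data_error")
filter_design_error <- function(message) stop_reflex(message, "reflexquant_filter_design_error")
degenerate_signal_error <- function(message) stop_reflex(message, "reflexquant_degenerate_signal_error")
feature_error <- function(message) stop_reflex(message, "reflexquant_feature_error")
zero_variance_error <- function(message) stop_reflex(message, "reflexquant_zero_variance_error")

# Run an expression with a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded helpers do not perturb the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% 2147483647L))
  }
  force(expr)
}
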