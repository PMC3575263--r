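# Structured conditions so callers (notably the batch workflow) can route
# failures: open errors send a slide to the failed folder, validation
# errors are programming mistakes and abort.

ss_abort <- function(message, class, call = sys.call(-1)) {
  cnd <- structure(
    class = c(class, "slidesplit_error", "error", "condition"),
    list(message = message, call = call)
  )
  stop(cnd)
}

ss_open_error <- function(message, call = sys.call(-1)) {
  ss_abort(message, "slidesplit_open_error", call)
}

ss_bounds_error <- function(message, call = sys.call(-1)) {
  ss_abort(message, "slidesplit_bounds_error", call)
}

ss_validation_error <- function(message, call = sys.call(-1)) {
  ss_abort(message, "slidesplit_validation_error", call)
}

ss_io_error <- function(message, call = sys.call(-1)) {
  ss_abort(message, "slidesplit_io_error", call)
}
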