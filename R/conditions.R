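# Classed conditions so callers can handle specific failure modes
# (e.g. tryCatch(..., pedtriage_unknown_item = ...)) instead of matching
# on message text.

ped_stop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "pedtriage_error")))
}

ped_warn <- function(class, msg, ...) {
  warning(warningCondition(msg, ..., class = c(class, "pedtriage_warning")))
}

# scalar-checking helpers used across constructors
is_count1 <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == trunc(x)
}

is_level <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x %in% 1:5
}

`%||%` <- function(a, b) if (is.null(a)) b else a
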