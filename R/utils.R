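#' @keywords internal
"_PACKAGE"

## Deterministic per-stage seed derivation from one master seed.
## Stage seeds must stay below 2^31 (R integers are 32-bit).
child_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  as.integer((abs(master) + 1000003 * stage) %% 2147483647)
}

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop_("'%s' must be a single integer >= %s", name, min)
  as.integer(x)
}
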