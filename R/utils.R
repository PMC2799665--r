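# internal validation helpers

stop_looplab <- function(class, msg, ...) {
  stop(structure(class = c(class, "looplab_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_looplab("looplab_parameter_error", "'%s' must be a finite number", name)
  if (positive && x <= 0)
    stop_looplab("looplab_parameter_error", "'%s' must be > 0", name)
  if (nonneg && x < 0)
    stop_looplab("looplab_parameter_error", "'%s' must be >= 0", name)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop_looplab("looplab_parameter_error",
                 "'%s' must be an integer >= %d", name, min)
  invisible(as.numeric(x))
}

# deterministic child seeds derived from one master seed (one per stream)
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  as.list(sample.int(.Machine$integer.max - 1L, n))
}
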