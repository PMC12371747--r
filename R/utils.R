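# Internal condition helpers: classed errors so callers (and the pipeline's
# exit-code mapping) can distinguish configuration, data and fitting problems.

abort_config <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("ntcpval_config_error", "ntcpval_error")))
}

abort_data <- function(msg) {
  stop(errorCondition(msg, class = c("ntcpval_data_error", "ntcpval_error")))
}

abort_fit <- function(msg) {
  stop(errorCondition(msg, class = c("ntcpval_fit_error", "ntcpval_error")))
}

abort_domain <- function(msg) {
  stop(errorCondition(msg, class = c("ntcpval_domain_error", "ntcpval_error")))
}

# Run `expr` under a fixed RNG state, restoring the caller's stream afterwards
# so simulation helpers do not perturb user code.
with_preserved_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  if (!is.null(seed)) set.seed(seed)
  force(expr)
}

check_prob <- function(p, name = "p", open = TRUE) {
  if (!is.numeric(p) || length(p) == 0 || anyNA(p)) {
    abort_data(sprintf("'%s' must be numeric without missing values", name))
  }
  if (open) {
    if (any(p <= 0 | p >= 1)) {
      abort_domain(sprintf("'%s' must lie strictly inside (0, 1)", name))
    }
  } else if (any(p < 0 | p > 1)) {
    abort_domain(sprintf("'%s' must lie in [0, 1]", name))
  }
  invisible(p)
}

check_binary <- function(y, name = "y") {
  if (!all(y %in% c(0, 1))) {
    abort_data(sprintf("'%s' must be binary 0/1", name))
  }
  invisible(as.integer(y))
}
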