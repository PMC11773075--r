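# internal helpers shared across the package

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream. seed = NULL leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_domain <- function(...) {
  stop(structure(class = c("gs_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_estimation <- function(...) {
  stop(structure(class = c("gs_estimation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(name, " must be a single finite number")
  invisible(x)
}

fmt_num <- function(x, digits = 6) format(signif(x, digits), big.mark = ",")
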