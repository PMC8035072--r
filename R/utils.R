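#' @importFrom stats rnbinom rbinom rbeta rgamma rpois runif rnorm sd
#' @importFrom stats prcomp kmeans predict complete.cases quantile lm coef
#' @importFrom utils head tail
#' @import data.table
NULL

# Scoped seeding: set the RNG inside a function without clobbering the
# caller's stream. Restores (or removes) .Random.seed on exit.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  restore <- function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
  withr_style_defer(restore, envir)
  set.seed(as.integer(seed))
  invisible(NULL)
}

# Minimal on.exit-in-parent helper (avoids a withr dependency).
withr_style_defer <- function(expr_fun, envir) {
  done <- FALSE
  handler <- function() {
    if (!done) expr_fun()
    done <<- TRUE
  }
  do.call(on.exit, list(substitute(handler(), list(handler = handler)),
                        add = TRUE), envir = envir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}
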