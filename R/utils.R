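#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{expr} under \code{set.seed(seed)} and restores the caller's
#' RNG state afterwards, so seeded package functions do not perturb the
#' global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single integer")
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

#' Round half away from zero
#'
#' Integerization used at the testing boundary: fractional redistributed
#' counts are rounded with ties going away from zero (0.5 -> 1), unlike
#' \code{round()}'s round-half-even.
#'
#' @param x Numeric vector.
#' @return Numeric vector of integers.
#' @keywords internal
roundHalfAway <- function(x) {
    sign(x) * floor(abs(x) + 0.5)
}

# key=value logging line used by the pipeline so tests can assert counts
logLine <- function(stage, ...) {
    kv <- list(...)
    paste0("stage=", stage,
           paste0(vapply(names(kv), function(k)
               paste0(" ", k, "=", format(kv[[k]], scientific = FALSE)),
               character(1)), collapse = ""))
}
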