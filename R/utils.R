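## Internal utilities: seeded evaluation and argument checks.

.datatable.aware <- TRUE

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
## The caller's RNG stream is restored afterwards, so seeded operations
## never perturb an enclosing simulation.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Deterministic fan-out of one master seed into named sub-seeds (< 2^31).
fanOutSeeds <- function(seed, n) {
    withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.assertFraction <- function(x, name = deparse(substitute(x))) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
        stop(sprintf("'%s' must be in [0, 1]", name), call. = FALSE)
    invisible(x)
}

.assertPositive <- function(x, name = deparse(substitute(x))) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
        stop(sprintf("'%s' must be positive", name), call. = FALSE)
    invisible(x)
}

## Clopper-Pearson interval for x successes out of n.
.clopperPearson <- function(x, n, conf.level = 0.95) {
    if (n == 0L) return(c(NA_real_, NA_real_))
    alpha <- 1 - conf.level
    lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
    hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
    c(lo, hi)
}
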