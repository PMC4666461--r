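# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL means "use the current stream" (callers embedded in a larger
# seeded simulation rely on this).
with_seed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

# Deterministic per-node seed for recursive permutation tests, kept within
# the 32-bit integer range.
node_seed <- function(base, lo, hi) {
    as.integer((base + 1000003 * lo + 7919 * hi) %% 2147483629) + 1L
}

stop_if_not_matrix <- function(x, what) {
    if (!is.matrix(x) || !is.numeric(x))
        stop(what, " must be a numeric matrix", call. = FALSE)
    if (is.null(rownames(x)) || is.null(colnames(x)))
        stop(what, " must have row and column names", call. = FALSE)
    invisible(x)
}
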