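# internal helpers

# Run expr under a local RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(force(expr))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    expr
}

.assertProb <- function(x, name) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
        stop(name, " must lie in [0, 1]")
    invisible(TRUE)
}

# chromosome order as given (names of chromLengths), used for site sorting
.seqinfoFrom <- function(chromLengths) {
    GenomeInfoDb::Seqinfo(seqnames = names(chromLengths),
                          seqlengths = unname(as.integer(chromLengths)))
}
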