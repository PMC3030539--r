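# Internal helpers shared across modules.

# Derive a per-stage child seed from the pipeline seed so each stage is
# independently reproducible. Stable across platforms: integer arithmetic
# on the UTF-8 codes of the stage name, kept below 2^31.
childSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

# All randomness in the package goes through R's default generator with a
# fixed, named algorithm so results are reproducible across platforms.
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    expr
}

# Unordered pair table (u < v lexicographically) from a square symmetric
# matrix with dimnames; used by the correlation module.
pairsFromMatrix <- function(m) {
    ids <- rownames(m)
    idx <- which(upper.tri(m), arr.ind = TRUE)
    data.frame(u = ids[idx[, 1]], v = ids[idx[, 2]],
               value = m[idx], stringsAsFactors = FALSE)
}

stopIfNot <- function(cond, msg, ...) if (!cond) stop(sprintf(msg, ...), call. = FALSE)
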