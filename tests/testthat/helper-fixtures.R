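## Shared fixtures built in code.

## a minimal map with evenly spaced SNPs, for closed-form checks
evenMap <- function(L = 1000, at = c(100, 300, 500, 700, 900)) {
    MarkerMap(data.frame(
        id = c(paste0("L", at), paste0("R", at)),
        arm = rep(c("LEFT", "RIGHT"), each = length(at)),
        distance = c(at, at),
        kind = "SNP"), L, L)
}

## hand-built clone table from a named list of call vectors
tinyTable <- function(map, cloneCalls, ...) {
    CloneTable(map, do.call(cbind, cloneCalls), ...)
}

## binomial 3-sigma half-width
binomTol <- function(p, n) 3 * sqrt(p * (1 - p) / n)

expect_within3sigma <- function(observed, p, n) {
    expect_lt(abs(observed - p), binomTol(p, n) + 1e-12)
}
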