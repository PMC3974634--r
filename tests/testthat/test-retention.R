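test_that("retention counting handles no-calls and the sectored convention", {
    map <- makeDefaultMap()
    ids <- as.data.frame(markers(map))$id
    mk <- function(x) structure(rep(x, 10), names = ids)
    ## marker-wise no-call exclusion: V in one clone, N in the other
    cl <- cbind(mk("V"), mk("C"))
    cl["NcoI", 2] <- "N"
    tab <- CloneTable(map, cl)
    prof <- retentionProfile(tab)
    expect_equal(prof$nTotal[prof$id == "NcoI"], 1)
    expect_equal(prof$freq[prof$id == "NcoI"], 1)
    expect_equal(prof$nTotal[prof$id == "SspI"], 2)

    ## all-chromosomal clone: frequency zero everywhere
    solo <- CloneTable(map, cbind(mk("C")))
    expect_true(all(retentionProfile(solo)$freq == 0))

    ## sectored markers count as retained by default, not when disabled
    sect <- CloneTable(map, cbind(mk("S")))
    expect_true(all(retentionProfile(sect)$freq == 1))
    expect_true(all(retentionProfile(sect, countSectoredAsRetained = FALSE)$freq == 0))

    expect_error(retentionProfile(tab[, 0]), "empty")
})

test_that("retention profiles are invariant to clone order", {
    tab <- simulateEndsOut(makeDefaultMap(),
                           SimParams(nClones = 100, seed = 5), mode = "COLONY")
    perm <- sample(ncol(tab))
    expect_equal(retentionProfile(tab), retentionProfile(tab[, perm]))
})

test_that("linear fits recover exact collinear and constant profiles", {
    prof <- data.frame(id = c("a", "b", "c"), arm = "LEFT",
                       distance = c(100, 500, 900),
                       signedDistance = -c(100, 500, 900),
                       nRetained = c(90, 50, 10), nTotal = 100,
                       freq = c(0.9, 0.5, 0.1))
    fit <- fitRetentionModel(prof, "LEFT", "LINEAR")
    expect_equal(unname(fit$params["slope"]), -0.001, tolerance = 1e-10)
    expect_equal(unname(fit$params["intercept"]), 1, tolerance = 1e-10)
    expect_equal(fit$rSquared, 1, tolerance = 1e-10)

    const <- transform(prof, freq = 1, nRetained = 100)
    cfit <- fitRetentionModel(const, "LEFT", "LINEAR")
    expect_equal(unname(cfit$params["slope"]), 0, tolerance = 1e-12)
    expect_equal(unname(cfit$params["intercept"]), 1, tolerance = 1e-12)
    expect_gte(cfit$rSquared, 0)
    expect_lte(cfit$rSquared, 1)

    ## exact collinear data still prefers linear, with positive RSS gap
    cmp <- compareRetentionModels(prof, "LEFT")
    expect_equal(cmp$preferred, "LINEAR")
    expect_gt(cmp$deltaRss, 0)
})

test_that("fit preconditions are enforced", {
    prof <- data.frame(id = c("a", "b"), arm = "LEFT", distance = c(1, 2),
                       signedDistance = -c(1, 2), nRetained = 1, nTotal = 2,
                       freq = 0.5)
    expect_error(fitRetentionModel(prof, "LEFT"), ">= 3 markers")
    zero <- data.frame(id = letters[1:3], arm = "RIGHT",
                       distance = c(1, 2, 3), signedDistance = c(1, 2, 3),
                       nRetained = 0, nTotal = 10, freq = 0)
    expect_error(fitRetentionModel(zero, "RIGHT", "EXPONENTIAL"),
                 "all frequencies are zero")
})

test_that("simulated ends-out panels reproduce the high per-arm linearity", {
    tab <- simulateEndsOut(makeDefaultMap(),
                           SimParams(nClones = 230, seed = 13))
    prof <- retentionProfile(tab)
    for (arm in c("LEFT", "RIGHT"))
        expect_gte(fitRetentionModel(prof, arm, "LINEAR")$rSquared, 0.945)
})

test_that("fitted slope approaches -1/L and intercept 1 for large panels", {
    tab <- simulateEndsOut(evenMap(), SimParams(nClones = 1e5, seed = 17))
    prof <- retentionProfile(tab)
    for (arm in c("LEFT", "RIGHT")) {
        fit <- fitRetentionModel(prof, arm, "LINEAR")
        expect_equal(unname(fit$params["slope"]), -1e-3, tolerance = 0.02)
        expect_equal(unname(fit$params["intercept"]), 1, tolerance = 0.02)
    }
})

test_that("model comparison identifies the generating law in >= 18/20 seeds", {
    map <- makeDefaultMap()
    d <- as.data.frame(markers(map))
    linWins <- expWins <- 0L
    for (seed in 1:20) {
        tab <- simulateEndsOut(map, SimParams(nClones = 230, seed = seed))
        prof <- retentionProfile(tab)
        pref <- c(compareRetentionModels(prof, "LEFT")$preferred,
                  compareRetentionModels(prof, "RIGHT")$preferred)
        linWins <- linWins + (sum(pref == "LINEAR") == 2L)

        ## exponential generator: binomial sampling around A exp(-3 d / L)
        set.seed(1000 + seed)
        pTrue <- exp(-3 * d$distance / 1000)
        eprof <- data.frame(id = d$id, arm = d$arm, distance = d$distance,
                            signedDistance = ifelse(d$arm == "LEFT", -1, 1) *
                                d$distance,
                            nRetained = rbinom(nrow(d), 230, pTrue),
                            nTotal = 230)
        eprof$freq <- eprof$nRetained / eprof$nTotal
        epref <- c(compareRetentionModels(eprof, "LEFT")$preferred,
                   compareRetentionModels(eprof, "RIGHT")$preferred)
        expWins <- expWins + (sum(epref == "EXPONENTIAL") == 2L)
    }
    expect_gte(linWins, 18L)
    expect_gte(expWins, 18L)
})

test_that("selection guarantees an exact plateau between cassette and DSB", {
    ti <- simulateEndsIn(makeDefaultMap(halfSite = "right"),
                         SimParams(nClones = 4000, seed = 19,
                                   dsb = list(arm = "RIGHT", position = 266)))
    prof <- retentionProfile(ti)
    inner <- prof$arm == "RIGHT" & prof$distance < 266
    expect_true(all(prof$freq[inner] == 1))
})
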