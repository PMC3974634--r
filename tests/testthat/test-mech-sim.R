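test_that("segregant ends-out retention matches the 1 - d/L closed form", {
    map <- evenMap()
    n <- 20000
    tab <- simulateEndsOut(map, SimParams(nClones = n, seed = 11))
    prof <- retentionProfile(tab)
    for (i in seq_len(nrow(prof)))
        expect_within3sigma(prof$freq[i], 1 - prof$distance[i] / 1000, n)
})

test_that("expected retention is non-increasing in distance for every mechanism", {
    map <- makeDefaultMap()
    n <- 10000
    tabs <- list(
        simulateEndsOut(map, SimParams(nClones = n, seed = 21)),
        simulateEndsOut(map, SimParams(nClones = n, seed = 22), mode = "COLONY"),
        simulateSSA(map, SimParams(nClones = n, seed = 23)),
        simulateEndsIn(makeDefaultMap(halfSite = "right"),
                       SimParams(nClones = n, seed = 24,
                                 dsb = list(arm = "RIGHT", position = 266))))
    for (tab in tabs) {
        prof <- retentionProfile(tab)
        for (arm in c("LEFT", "RIGHT")) {
            p <- prof[prof$arm == arm, ]
            p <- p[order(p$distance), ]
            jump <- diff(p$freq)
            ## allow 3-sigma noise on each adjacent difference
            tol <- 3 * sqrt(p$freq[-1] * (1 - p$freq[-1]) / n +
                            p$freq[-nrow(p)] * (1 - p$freq[-nrow(p)]) / n)
            expect_true(all(jump <= tol + 1e-12))
        }
    }
})

test_that("identical seed and parameters reproduce the clone table exactly", {
    map <- makeDefaultMap()
    p <- SimParams(nClones = 50, seed = 7, rReject = 0.1)
    a <- simulateEndsOut(map, p, mode = "COLONY")
    b <- simulateEndsOut(map, p, mode = "COLONY")
    expect_identical(calls(a), calls(b))
    expect_identical(assay(a, "subcloneA"), assay(b, "subcloneA"))
    expect_identical(attempts(a), attempts(b))
    pi2 <- SimParams(nClones = 50, seed = 7,
                     dsb = list(arm = "RIGHT", position = 266))
    mi <- makeDefaultMap(halfSite = "right")
    expect_identical(calls(simulateEndsIn(mi, pi2)),
                     calls(simulateEndsIn(mi, pi2)))
})

test_that("every emitted clone is selection-surviving and attempts cover rejections", {
    map <- makeDefaultMap()
    tab <- simulateEndsOut(map, SimParams(nClones = 200, seed = 31,
                                          rReject = 0.1, nMismatches = 15))
    expect_true(all(isSelected(tab)))
    expect_gte(attempts(tab), ncol(tab))
    ## expected acceptance (1-0.1)^15 ~ 0.206: attempts should be well above n
    expect_gt(attempts(tab), 400)

    ti <- simulateEndsIn(makeDefaultMap(halfSite = "right"),
                         SimParams(nClones = 200, seed = 32, pAlt = 0,
                                   dsb = list(arm = "RIGHT", position = 266)))
    expect_true(all(isSelected(ti)))
    expect_gte(attempts(ti), ncol(ti))
})

test_that("single-strand assimilation never sectors but shares the ends-out marginal law", {
    map <- makeDefaultMap()
    n <- 2000
    ssa <- simulateSSA(map, SimParams(nClones = n, seed = 41))
    expect_false(any(calls(ssa) == "S"))
    eo <- simulateEndsOut(map, SimParams(nClones = n, seed = 42))
    ps <- retentionProfile(ssa)
    pe <- retentionProfile(eo)
    pvals <- vapply(seq_len(nrow(ps)), function(i)
        stats::prop.test(c(ps$nRetained[i], pe$nRetained[i]),
                         c(ps$nTotal[i], pe$nTotal[i]))$p.value, 0)
    expect_true(all(pvals > 0.01))
})

test_that("ends-in clones retain every marker between cassette and DSB, and distal markers per (L-d)/(L-s)", {
    ## right-side DSB at +266: SspI (+130) and SacI (+261) always retained
    n <- 5000
    ti <- simulateEndsIn(makeDefaultMap(halfSite = "right"),
                         SimParams(nClones = n, seed = 51,
                                   dsb = list(arm = "RIGHT", position = 266)))
    prof <- retentionProfile(ti)
    expect_equal(prof$freq[prof$id %in% c("SspI", "SacI")], c(1, 1))
    ## left-side mirror at -569: AseI (-300) and NcoI (-547)
    tl <- simulateEndsIn(makeDefaultMap(halfSite = "left"),
                         SimParams(nClones = n, seed = 52,
                                   dsb = list(arm = "LEFT", position = 569)))
    profL <- retentionProfile(tl)
    expect_equal(profL$freq[profL$id %in% c("AseI", "NcoI")], c(1, 1))

    ## DSBR-only distal retention: marker at the midpoint of (s, L) -> 1/2
    map <- MarkerMap(data.frame(id = c("mid", "other"),
                                arm = c("RIGHT", "LEFT"),
                                distance = c(633, 500), kind = "SNP"),
                     1000, 1000)
    td <- simulateEndsIn(map, SimParams(nClones = n, seed = 53, pAlt = 0,
                                        dsb = list(arm = "RIGHT",
                                                   position = 266)))
    pd <- retentionProfile(td)
    expect_within3sigma(pd$freq[pd$id == "mid"], (1000 - 633) / (1000 - 266), n)
    ## far arm follows the proximal-coverage law 1 - d/L
    expect_within3sigma(pd$freq[pd$id == "other"], 1 - 500 / 1000, n)
})

test_that("pAlt = 0 yields no half-site clones; pAlt partitions mechanisms", {
    ti <- simulateEndsIn(makeDefaultMap(halfSite = "right"),
                         SimParams(nClones = 500, seed = 61, pAlt = 0,
                                   dsb = list(arm = "RIGHT", position = 266)))
    expect_false(any(halfSitePresent(ti)))
    expect_true(all(truthMechanism(ti) == "ENDS_IN_DSBR"))

    ta <- simulateEndsIn(makeDefaultMap(halfSite = "right"),
                         SimParams(nClones = 500, seed = 62, pAlt = 1,
                                   dsb = list(arm = "RIGHT", position = 266)))
    expect_true(all(halfSitePresent(ta)))
    ## ALT clones lose everything distal to the DSB and keep the plateau
    pr <- retentionProfile(ta)
    expect_equal(pr$freq[pr$id %in% c("SspI", "SacI")], c(1, 1))
    expect_equal(pr$freq[pr$id %in% c("RHP", "XbaI", "SbfI")], c(0, 0, 0))
})

test_that("random integration retains every marker in every clone", {
    tab <- simulateRandomIntegration(makeDefaultMap(),
                                     SimParams(nClones = 38, seed = 71))
    expect_true(all(calls(tab) == "V"))
    expect_true(all(truthMechanism(tab) == "RANDOM_INTEGRATION"))
    prof <- retentionProfile(tab)
    expect_true(all(prof$freq == 1))
    fit <- fitRetentionModel(prof, "LEFT", "LINEAR")
    expect_equal(unname(fit$params["slope"]), 0, tolerance = 1e-12)
    expect_equal(unname(fit$params["intercept"]), 1, tolerance = 1e-12)
})

test_that("mismatch-repair rejection changes efficiency but never tract geometry", {
    map <- makeDefaultMap()
    n <- 3000
    a <- simulateEndsOut(map, SimParams(nClones = n, seed = 81, rReject = 0))
    b <- simulateEndsOut(map, SimParams(nClones = n, seed = 82, rReject = 0.3))
    expect_gt(attempts(b), attempts(a))
    pa <- retentionProfile(a)
    pb <- retentionProfile(b)
    pvals <- vapply(seq_len(nrow(pa)), function(i)
        stats::prop.test(c(pa$nRetained[i], pb$nRetained[i]),
                         c(pa$nTotal[i], pb$nTotal[i]))$p.value, 0)
    expect_true(all(pvals > 0.01))
})

test_that("double-event mixtures interpolate the trans fraction as 1 - q/2", {
    map <- makeDefaultMap()
    n <- 3000
    ## q = 1: all colonies from two independent events, trans ~ 1/2
    d1 <- simulateDoubleEventMixture(map, SimParams(nClones = n, seed = 91), 1)
    s1 <- sectoringSummary(d1)
    expect_within3sigma(s1$pTrans, 0.5, s1$nTrans + s1$nCis)
    ## q = 0: pure single events, all informative colonies trans
    d0 <- simulateDoubleEventMixture(map, SimParams(nClones = 500, seed = 92), 0)
    s0 <- sectoringSummary(d0)
    expect_equal(s0$pTrans, 1)
    expect_error(simulateDoubleEventMixture(map, SimParams(nClones = 5), 1.2))
})
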