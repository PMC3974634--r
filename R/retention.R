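#' Per-marker retention profile
#'
#' The central statistic of the package: for each SNP/hairpin marker, the
#' fraction of clones carrying the vector-derived allele, tabulated against
#' the marker's signed distance from the central heterology.
#'
#' @param table a [CloneTable-class].
#' @param countSectoredAsRetained should \code{"S"} calls count as retained?
#'   Default \code{TRUE}: a sectored marker demonstrably carries the viral
#'   allele in part of the colony. \code{"N"} calls reduce \code{nTotal} for
#'   that marker only.
#' @return a data.frame with one row per marker: \code{id}, \code{arm},
#'   \code{distance}, \code{signedDistance}, \code{nRetained}, \code{nTotal},
#'   \code{freq}.
#' @examples
#' tab <- simulateEndsOut(makeDefaultMap(), SimParams(nClones = 230, seed = 1))
#' retentionProfile(tab)
#' @seealso [fitRetentionModel()], [compareRetentionModels()]
#' @export
retentionProfile <- function(table, countSectoredAsRetained = TRUE) {
    stopifnot(is(table, "CloneTable"))
    if (ncol(table) == 0L)
        stop("empty CloneTable")
    cl <- calls(table)
    gm <- as.data.frame(rowData(table))
    retained <- cl == "V"
    if (countSectoredAsRetained)
        retained <- retained | cl == "S"
    usable <- cl != "N"
    data.frame(id = gm$id, arm = gm$arm, distance = gm$distance,
               signedDistance = ifelse(gm$arm == "LEFT", -1, 1) * gm$distance,
               nRetained = rowSums(retained & usable),
               nTotal = rowSums(usable),
               freq = rowSums(retained & usable) / rowSums(usable),
               row.names = NULL)
}

#' Fit a retention model to one homology arm
#'
#' Fits the per-arm relationship between retention frequency and unsigned
#' marker distance. \code{"LINEAR"} is ordinary least squares with intercept
#' (uniformly distributed crossover resolution predicts frequency
#' \eqn{1 - d/L}, a straight line); \code{"EXPONENTIAL"} fits
#' \eqn{A e^{-k d}} by nonlinear least squares (the tract-length law reported
#' for yeast, fly and murine ES-cell recombination), initialized from a
#' log-linear fit on the positive frequencies. R-squared is computed as
#' \eqn{1 - RSS/TSS} about the mean for both models so they are comparable.
#'
#' @param profile a data.frame from [retentionProfile()].
#' @param arm \code{"LEFT"} or \code{"RIGHT"}.
#' @param model \code{"LINEAR"} or \code{"EXPONENTIAL"}.
#' @param weighted if \code{TRUE}, weight points by inverse binomial variance
#'   (default \code{FALSE}: plain regression).
#' @return an object of class \code{"retentionFit"}: a list with
#'   \code{model}, \code{params} (\code{slope}/\code{intercept} or
#'   \code{amplitude}/\code{decayRate}), \code{rSquared}, \code{rss},
#'   \code{nPoints}, \code{arm}.
#' @export
fitRetentionModel <- function(profile, arm = c("LEFT", "RIGHT"),
                              model = c("LINEAR", "EXPONENTIAL"),
                              weighted = FALSE) {
    arm <- match.arg(arm)
    model <- match.arg(model)
    pts <- profile[profile$arm == arm & profile$nTotal > 0, , drop = FALSE]
    if (nrow(pts) < 3L)
        stop(sprintf("need >= 3 markers with data on the %s arm, have %d",
                     arm, nrow(pts)))
    d <- pts$distance
    f <- pts$freq
    w <- if (weighted) {
        v <- pmax(f * (1 - f), 1 / (4 * pts$nTotal)) / pts$nTotal
        1 / v
    } else rep(1, length(f))
    tss <- sum(w * (f - stats::weighted.mean(f, w))^2)
    if (model == "LINEAR") {
        fit <- stats::lm(f ~ d, weights = w)
        pars <- c(slope = unname(stats::coef(fit)[2L]),
                  intercept = unname(stats::coef(fit)[1L]))
        rss <- sum(w * stats::residuals(fit)^2)
    } else {
        if (all(f <= 0))
            stop("exponential fit impossible: all frequencies are zero")
        pos <- f > 0
        ## log-linear start values; fall back to a flat guess when the
        ## positive points cannot anchor a slope
        k0 <- if (sum(pos) >= 2L) {
            sl <- stats::coef(stats::lm(log(f[pos]) ~ d[pos]))[2L]
            max(-sl, 1e-6)
        } else 1 / max(d)
        A0 <- max(f)
        fit <- minpack.lm::nlsLM(f ~ A * exp(-k * dd),
                                 data = list(f = f, dd = d),
                                 start = list(A = A0, k = unname(k0)),
                                 weights = w,
                                 control = minpack.lm::nls.lm.control(maxiter = 200))
        cf <- stats::coef(fit)
        pars <- c(amplitude = unname(cf["A"]), decayRate = unname(cf["k"]))
        rss <- sum(w * stats::residuals(fit)^2)
    }
    r2 <- if (tss > .Machine$double.eps^0.5) 1 - rss / tss
          else if (rss < .Machine$double.eps^0.5) 1 else 0
    structure(list(model = model, params = pars,
                   rSquared = max(min(r2, 1), if (model == "LINEAR") 0 else -Inf),
                   rss = rss, nPoints = nrow(pts), arm = arm),
              class = "retentionFit")
}

#' @export
print.retentionFit <- function(x, ...) {
    cat(sprintf("%s retention fit, %s arm (%d markers)\n",
                x$model, x$arm, x$nPoints))
    cat(sprintf("  %s\n", paste(sprintf("%s = %.6g", names(x$params),
                                        x$params), collapse = ", ")))
    cat(sprintf("  R^2 = %.4f, RSS = %.4g\n", x$rSquared, x$rss))
    invisible(x)
}

#' Compare linear and exponential retention models on one arm
#'
#' Fits both models and prefers the one with the lower residual sum of
#' squares (ties break to linear). A linear profile indicates evenly
#' distributed crossover resolution; an exponential profile indicates
#' resolution concentrated near the initiation site.
#'
#' @inheritParams fitRetentionModel
#' @return a list: \code{preferred} (\code{"LINEAR"}/\code{"EXPONENTIAL"}),
#'   \code{deltaRss} (exponential RSS minus linear RSS), \code{rSquared}
#'   (named vector per model) and the two \code{"retentionFit"} objects.
#' @export
compareRetentionModels <- function(profile, arm = c("LEFT", "RIGHT")) {
    arm <- match.arg(arm)
    lin <- fitRetentionModel(profile, arm, "LINEAR")
    ex <- fitRetentionModel(profile, arm, "EXPONENTIAL")
    delta <- ex$rss - lin$rss
    list(preferred = if (lin$rss <= ex$rss) "LINEAR" else "EXPONENTIAL",
         deltaRss = delta,
         rSquared = c(LINEAR = lin$rSquared, EXPONENTIAL = ex$rSquared),
         linear = lin, exponential = ex)
}

#' Plot a retention profile with fitted curves
#'
#' Retention frequency against signed marker distance, with per-arm linear
#' (and optionally exponential) fits overlaid.
#'
#' @inheritParams fitRetentionModel
#' @param exponential overlay the exponential fits as dashed curves.
#' @param ... passed to [plot()].
#' @return invisibly, the list of per-arm fits.
#' @export
plotRetentionProfile <- function(profile, exponential = FALSE, ...) {
    plot(profile$signedDistance, profile$freq, ylim = c(0, 1),
         xlab = "signed distance from central heterology (bp)",
         ylab = "retention frequency",
         pch = ifelse(profile$arm == "LEFT", 19, 17), ...)
    abline(v = 0, col = "grey40")
    fits <- list()
    for (arm in ARMS) {
        sgn <- if (arm == "LEFT") -1 else 1
        pts <- profile[profile$arm == arm & profile$nTotal > 0, ]
        if (nrow(pts) < 3L) next
        dd <- seq(0, max(pts$distance), length.out = 100)
        lin <- fitRetentionModel(profile, arm, "LINEAR")
        lines(sgn * dd, lin$params["intercept"] + lin$params["slope"] * dd,
              col = if (arm == "LEFT") "darkgreen" else "purple")
        fits[[arm]] <- list(linear = lin)
        if (exponential) {
            ex <- fitRetentionModel(profile, arm, "EXPONENTIAL")
            lines(sgn * dd, ex$params["amplitude"] *
                      exp(-ex$params["decayRate"] * dd),
                  lty = 2, col = if (arm == "LEFT") "darkgreen" else "purple")
            fits[[arm]]$exponential <- ex
        }
    }
    invisible(fits)
}
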