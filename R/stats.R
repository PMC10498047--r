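## Circular statistics for phase control, dose-response modelling, and the
## group comparisons the pipeline reports.

#' Convert between ZT hours and angles
#'
#' 24 h maps to the full circle: \code{angle = 2*pi*zt/24}. The inverse
#' wraps to \code{[0, 24)}.
#'
#' @param ztH time in ZT hours.
#' @param rad angle in radians.
#' @return radians (\code{ztToAngle}) or hours in \code{[0, 24)}
#'   (\code{angleToZt}).
#' @examples
#' ztToAngle(6) == pi / 2
#' angleToZt(ztToAngle(30.25))  # 6.25
#' @export
ztToAngle <- function(ztH) {
    stopifnot(all(is.finite(ztH)))
    (ztH %% 24) * 2 * pi / 24
}

#' @rdname ztToAngle
#' @export
angleToZt <- function(rad) {
    stopifnot(all(is.finite(rad)))
    (rad * 24 / (2 * pi)) %% 24
}

.resultant <- function(theta) {
    z <- mean(exp(1i * theta))
    list(R = Mod(z), mean = Arg(z) %% (2 * pi))
}

#' Circular mean, resultant length and circular median
#'
#' \code{circularMean} is the argument of the mean resultant vector;
#' \code{resultantLength} its modulus (0 for perfectly dispersed, 1 for
#' identical angles). \code{circularMedian} minimizes the mean circular
#' absolute deviation over the sample angles, breaking ties toward the
#' circular mean.
#'
#' @param theta angles in radians.
#' @return radians in \code{[0, 2*pi)} or a scalar in \code{[0, 1]}.
#' @export
circularMean <- function(theta) .resultant(theta)$mean

#' @rdname circularMean
#' @export
resultantLength <- function(theta) .resultant(theta)$R

#' @rdname circularMean
#' @export
circularMedian <- function(theta) {
    theta <- theta %% (2 * pi)
    cand <- unique(theta)
    dev <- vapply(cand, function(m) {
        d <- abs(theta - m) %% (2 * pi)
        mean(pmin(d, 2 * pi - d))
    }, numeric(1))
    best <- cand[abs(dev - min(dev)) < 1e-12]
    if (length(best) == 1L) return(best)
    mu <- circularMean(theta)
    d <- abs(best - mu) %% (2 * pi)
    best[which.min(pmin(d, 2 * pi - d))]
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null of a uniform circular distribution against unimodal
#' clustering. The statistic is the mean resultant length
#' \eqn{R = |\sum e^{i\theta}|/n}; the p-value uses the standard
#' approximation with finite-sample correction,
#' \eqn{p \approx e^{-Z}[1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 -
#' 9Z^4)/(288n^2)]} with \eqn{Z = nR^2}.
#'
#' @param theta angles in radians, n >= 2.
#' @return object of class \code{"htest"} with \code{statistic} (R),
#'   \code{p.value} and \code{parameter} (n).
#' @export
rayleighTest <- function(theta) {
    n <- length(theta)
    if (n < 2L) stop("need at least two angles")
    R <- resultantLength(theta)
    Z <- n * R^2
    p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
    p <- min(max(p, 0), 1)
    structure(list(statistic = c(R = R), parameter = c(n = n), p.value = p,
                   method = "Rayleigh test of circular uniformity",
                   data.name = deparse(substitute(theta))),
              class = "htest")
}

#' V-test (modified Rayleigh test) for a known mean angle
#'
#' Rayleigh-type test of uniformity against the alternative of clustering
#' around a hypothesized mean angle \code{mu0} supplied externally (never
#' estimated from the same sample). \eqn{V = R\cos(\bar\theta - \mu_0)},
#' \eqn{u = V\sqrt{2n}}, with a one-sided upper-tail normal p-value.
#'
#' @param theta angles in radians, n >= 2.
#' @param mu0 hypothesized mean angle in radians.
#' @return object of class \code{"htest"} with \code{statistic} (u),
#'   \code{estimate} (V and R) and \code{p.value}.
#' @export
vTest <- function(theta, mu0) {
    n <- length(theta)
    if (n < 2L) stop("need at least two angles")
    r <- .resultant(theta)
    V <- r$R * cos(r$mean - mu0)
    u <- V * sqrt(2 * n)
    structure(list(statistic = c(u = u),
                   estimate = c(V = V, R = r$R, mu0 = mu0),
                   parameter = c(n = n),
                   p.value = stats::pnorm(u, lower.tail = FALSE),
                   method = "V-test for a specified mean direction",
                   data.name = deparse(substitute(theta))),
              class = "htest")
}

#' Assess phase control after release into constant conditions
#'
#' An entrained oscillator must keep its phase on the first day of constant
#' conditions. The hypothesized direction is the circular median of the
#' entrained phases; the V-test is then applied to the release-day phases.
#'
#' @param entrainedZtH entrained peak phases in ZT hours.
#' @param releaseZtH first-release-day peak phases in ZT hours.
#' @return the V-test \code{"htest"} result (see [vTest()]).
#' @export
assessPhaseControl <- function(entrainedZtH, releaseZtH) {
    if (!length(entrainedZtH) || !length(releaseZtH))
        stop("both phase samples must be non-empty")
    mu0 <- circularMedian(ztToAngle(entrainedZtH))
    vTest(ztToAngle(releaseZtH), mu0)
}

#' Four-parameter logistic dose-response fit
#'
#' Least-squares fit of
#' \deqn{y = \alpha_L + \delta / (1 + \exp(-\eta (x - \phi_m)))}
#' (lower asymptote \eqn{\alpha_L}, span \eqn{\delta}, growth rate
#' \eqn{\eta}, midpoint dose \eqn{\phi_m}) by Levenberg-Marquardt from a
#' deterministic grid of starting values; the best converged fit by residual
#' sum of squares is kept.
#'
#' @param dose numeric doses (here: light intensities in uW/cm2, untransformed).
#' @param response numeric responses (here: free-running periods in hours).
#' @return list of class \code{"logistic4Fit"}: \code{coefficients}
#'   (alpha_L, delta, eta, phi_m), \code{rss}, \code{fitted},
#'   \code{converged}, \code{n}, \code{dose}, \code{response}.
#' @export
fitLogistic4 <- function(dose, response) {
    if (length(dose) != length(response)) stop("dose/response length mismatch")
    ok <- is.finite(dose) & is.finite(response)
    dose <- dose[ok]; response <- response[ok]
    n <- length(response)
    if (n < 4L) stop("need at least 4 observations")
    if (length(unique(dose)) < 3L) stop("need at least 3 distinct doses")
    f <- function(x, aL, delta, eta, phiM)
        aL + delta / (1 + exp(-eta * (x - phiM)))
    rng <- diff(range(response))
    spread <- diff(range(dose))
    starts <- expand.grid(
        delta = c(rng, -rng),
        eta = c(0.5, 2, 8, 40, 160) / max(spread, 1e-9),
        phiM = stats::quantile(dose, c(0.1, 0.3, 0.5, 0.7, 0.9),
                               names = FALSE))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
        st <- starts[i, ]
        aL0 <- if (st$delta >= 0) min(response) else max(response)
        fit <- tryCatch(
            minpack.lm::nls.lm(
                par = c(aL = aL0, delta = st$delta, eta = st$eta,
                        phiM = st$phiM),
                fn = function(p) response - f(dose, p[1], p[2], p[3], p[4]),
                control = minpack.lm::nls.lm.control(maxiter = 300)),
            error = function(e) NULL)
        if (is.null(fit) || !fit$info %in% 1:4) next
        rss <- sum(fit$fvec^2)
        if (is.null(best) || rss < best$rss)
            best <- list(fit = fit, rss = rss)
    }
    flatRss <- sum((response - mean(response))^2)
    if (is.null(best)) {
        ## non-convergence everywhere: flag, report the flat model
        out <- list(coefficients = c(alpha_L = mean(response), delta = 0,
                                     eta = 0, phi_m = mean(dose)),
                    rss = flatRss, fitted = rep(mean(response), n),
                    converged = FALSE, n = n, dose = dose,
                    response = response)
        class(out) <- "logistic4Fit"
        return(out)
    }
    cf <- best$fit$par
    ## the 4PL is invariant under (delta, eta) -> (-delta, -eta) with
    ## alpha_L -> alpha_L + delta; canonicalize to eta >= 0
    if (cf[["eta"]] < 0) {
        cf[["aL"]] <- cf[["aL"]] + cf[["delta"]]
        cf[["delta"]] <- -cf[["delta"]]
        cf[["eta"]] <- -cf[["eta"]]
    }
    out <- list(coefficients = c(alpha_L = unname(cf["aL"]),
                                 delta = unname(cf["delta"]),
                                 eta = unname(cf["eta"]),
                                 phi_m = unname(cf["phiM"])),
                rss = best$rss,
                fitted = as.numeric(f(dose, cf["aL"], cf["delta"],
                                      cf["eta"], cf["phiM"])),
                converged = TRUE, n = n, dose = dose, response = response)
    class(out) <- "logistic4Fit"
    out
}

#' @export
print.logistic4Fit <- function(x, ...) {
    cat("4-parameter logistic dose-response fit\n")
    print(round(x$coefficients, 4))
    cat(sprintf("RSS = %.4g on n = %d%s\n", x$rss, x$n,
                if (x$converged) "" else " (NOT converged)"))
    invisible(x)
}

#' F-test of a dose-response fit against a flat line
#'
#' Tests the fitted four-parameter logistic model against the null of a
#' flat line (no intensity-dependent change):
#' \eqn{F = ((RSS_0 - RSS_1)/(p_1 - p_0)) / (RSS_1/(n - p_1))} with
#' \eqn{p_0 = 1}, \eqn{p_1 = 4}; p-value from \eqn{F_{3, n-4}}.
#'
#' @param fit a \code{"logistic4Fit"} from [fitLogistic4()].
#' @return object of class \code{"htest"} with \code{statistic} (F),
#'   \code{parameter} (df) and \code{p.value}.
#' @export
anovaVsFlat <- function(fit) {
    stopifnot(inherits(fit, "logistic4Fit"))
    n <- fit$n
    p1 <- 4L
    if (n <= p1) stop("need more observations than model parameters")
    rss0 <- sum((fit$response - mean(fit$response))^2)
    rss1 <- fit$rss
    Fstat <- max(0, ((rss0 - rss1) / 3) / (rss1 / (n - p1)))
    p <- stats::pf(Fstat, 3, n - p1, lower.tail = FALSE)
    structure(list(statistic = c(F = Fstat),
                   parameter = c(df1 = 3, df2 = n - p1),
                   p.value = p,
                   method = "F-test: logistic dose-response vs flat line",
                   data.name = "logistic4Fit"),
              class = "htest")
}

#' Kruskal-Wallis test with Bonferroni pairwise letters
#'
#' Rank-based comparison of phase (or period) distributions across light
#' regimes: the Kruskal-Wallis H test with tie correction, followed by
#' pairwise Wilcoxon rank-sum comparisons at Bonferroni-corrected alpha and
#' a compact letter display in which groups sharing a letter are not
#' significantly different.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param alpha family-wise significance level.
#' @return list with \code{H}, \code{p}, \code{pairwise} (matrix of
#'   Bonferroni-adjusted p-values) and \code{letters} (named character
#'   vector).
#' @export
kruskalWithLetters <- function(groups, alpha = 0.05) {
    if (length(groups) < 2L) stop("need at least two groups")
    if (any(lengths(groups) < 2L)) stop("each group needs n >= 2")
    if (is.null(names(groups)))
        names(groups) <- paste0("g", seq_along(groups))
    kw <- stats::kruskal.test(groups)
    k <- length(groups)
    nm <- names(groups)
    pmat <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
    m <- k * (k - 1) / 2
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        p <- suppressWarnings(
            stats::wilcox.test(groups[[i]], groups[[j]])$p.value)
        pmat[i, j] <- pmat[j, i] <- min(1, p * m)
    }
    letters <- .compactLetters(pmat < alpha, nm)
    list(H = unname(kw$statistic), p = kw$p.value, pairwise = pmat,
         letters = letters)
}

## insert-and-absorb compact letter display; sigMat[i,j] TRUE when groups
## i and j differ significantly
.compactLetters <- function(sigMat, nm) {
    k <- length(nm)
    sets <- list(seq_len(k))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        if (!isTRUE(sigMat[i, j])) next
        for (s in seq_along(sets)) {
            if (all(c(i, j) %in% sets[[s]])) {
                a <- setdiff(sets[[s]], i)
                b <- setdiff(sets[[s]], j)
                sets[[s]] <- a
                sets[[length(sets) + 1L]] <- b
            }
        }
        ## absorb subsets
        keep <- rep(TRUE, length(sets))
        for (s in seq_along(sets)) for (t in seq_along(sets))
            if (s != t && keep[s] && keep[t] &&
                all(sets[[s]] %in% sets[[t]])) keep[s] <- FALSE
        sets <- sets[keep]
    }
    out <- setNames(rep("", k), nm)
    for (s in seq_along(sets))
        out[sets[[s]]] <- paste0(out[sets[[s]]], letters[s])
    out
}

#' Wilcoxon rank-sum test for two independent samples
#'
#' Exact p-value when the smaller sample has at most \code{exactMax}
#' observations and there are no ties; otherwise the normal approximation
#' with continuity and tie correction.
#'
#' @param a,b numeric samples (each n >= 1).
#' @param exactMax largest min-sample size for which the exact distribution
#'   is used.
#' @param ... further arguments passed to [stats::wilcox.test()] (e.g.
#'   \code{alternative}).
#' @return object of class \code{"htest"} (statistic W).
#' @export
wilcoxonRankSum <- function(a, b, exactMax = 25L, ...) {
    if (!length(a) || !length(b)) stop("both samples must be non-empty")
    suppressWarnings(
        stats::wilcox.test(a, b, exact = min(length(a), length(b)) <=
                               exactMax, correct = TRUE, ...))
}
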