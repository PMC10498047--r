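## Orchestration of the three experiment analyses (skeleton photoperiod,
## constant-light period, ramp entrainment) with reproducible CSV/JSON
## report bundles, and actogram rendering.

.writeReport <- function(report, outDir, profileList = NULL) {
    if (is.null(outDir)) return(invisible(report))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report$config,
                         file.path(outDir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    for (nm in names(report$csv))
        utils::write.csv(report$csv[[nm]],
                         file.path(outDir, paste0(nm, ".csv")),
                         row.names = FALSE)
    stats <- report$stats
    if (!is.null(stats))
        jsonlite::write_json(stats, file.path(outDir, "stats.json"),
                             auto_unbox = TRUE, digits = NA, null = "null",
                             force = TRUE)
    invisible(report)
}

.profileDF <- function(profile) {
    data.frame(zt_min = (seq_along(profile@mean) - 1L) * profile@binMinutes,
               mean = profile@mean, sem = profile@sem)
}

#' Skeleton-photoperiod entrainment analysis
#'
#' Per-regime cohort analysis: each fly is gated with [classifySkeleton()];
#' average activity profiles are built from entrained flies only; evening
#' peak phases of entrained flies are extracted; when more than one regime
#' is supplied, phases are compared across regimes by Kruskal-Wallis with
#' Bonferroni pairwise letters.
#'
#' @param cohorts named list: regime name -> list with elements
#'   \code{tables} (list of single-fly 1-min tables) and \code{regime}
#'   (the [LightRegime-class]).
#' @param profileBinMinutes profile bin width.
#' @param outDir optional report bundle directory (CSV + JSON).
#' @param seed seed recorded into the report config.
#' @return report list: \code{per_fly} (verdicts and phases),
#'   \code{percent_entrained}, \code{profiles} (entrained-only
#'   [ActivityProfile-class] per regime, NULL with a warning when a regime
#'   has no entrained flies), \code{phase_test} (Kruskal-Wallis +
#'   letters, when >= 2 regimes), \code{csv}, \code{config}.
#' @export
runSkeletonAnalysis <- function(cohorts, profileBinMinutes = 30,
                                outDir = NULL, seed = NA_integer_) {
    stopifnot(length(cohorts) >= 1L)
    perFly <- list()
    profiles <- list()
    phaseGroups <- list()
    pct <- list()
    for (rg in names(cohorts)) {
        co <- cohorts[[rg]]
        calls <- lapply(co$tables, classifySkeleton)
        entrained <- vapply(calls, function(c) verdict(c) == "entrained",
                            logical(1))
        phases <- rep(NA_real_, length(calls))
        for (i in which(entrained))
            phases[i] <- eveningPeakPhase(co$tables[[i]],
                                          co$regime)$zt_h
        perFly[[rg]] <- data.frame(
            regime = rg,
            fly = if (is.null(names(co$tables)))
                      paste0("fly", seq_along(co$tables))
                  else names(co$tables),
            verdict = vapply(calls, verdict, character(1)),
            peak_period_h = vapply(calls, function(c)
                evidence(c)$peak_period_h, numeric(1)),
            rhythmic_power = vapply(calls, function(c)
                evidence(c)$rhythmic_power, numeric(1)),
            evening_phase_zt_h = phases)
        pct[[rg]] <- cbind(regime = rg, cohortSummary(calls))
        if (any(entrained)) {
            profiles[[rg]] <- averageProfile(co$tables[entrained],
                                             profileBinMinutes)
            phaseGroups[[rg]] <- phases[entrained & !is.na(phases)]
        } else {
            warning("no entrained flies under regime ", rg,
                    "; profile omitted")
            profiles[rg] <- list(NULL)
        }
    }
    phaseTest <- NULL
    grps <- phaseGroups[lengths(phaseGroups) >= 2L]
    if (length(grps) >= 2L)
        phaseTest <- kruskalWithLetters(grps)
    perFlyDF <- do.call(rbind, c(perFly, list(make.row.names = FALSE)))
    pctDF <- do.call(rbind, c(pct, list(make.row.names = FALSE)))
    csv <- list(per_fly = perFlyDF, percent_entrained = pctDF)
    for (rg in names(profiles))
        if (!is.null(profiles[[rg]]))
            csv[[paste0("profile_", rg)]] <- .profileDF(profiles[[rg]])
    report <- list(
        per_fly = perFlyDF, percent_entrained = pctDF,
        profiles = profiles, phase_test = phaseTest, csv = csv,
        stats = if (is.null(phaseTest)) NULL else
            list(kruskal_H = phaseTest$H, kruskal_p = phaseTest$p,
                 letters = as.list(phaseTest$letters)),
        config = list(analysis = "skeleton", seed = seed,
                      profile_bin_minutes = profileBinMinutes,
                      regimes = names(cohorts),
                      n_flies = vapply(cohorts, function(co)
                          length(co$tables), numeric(1))))
    .writeReport(report, outDir)
}

## per-fly period and power under constant conditions (20-min bins,
## SG-smoothed like the entrainment gate)
.constantPeriods <- function(tables) {
    t(vapply(tables, function(tb) {
        call <- classifySkeleton(tb)
        c(period_h = evidence(call)$peak_period_h,
          power = evidence(call)$rhythmic_power)
    }, numeric(2)))
}

#' Constant-light free-running period analysis
#'
#' Per-fly free-running period and rhythmic power under DD and under LL at
#' one or more intensities; DD vs pooled-LL Wilcoxon comparison of periods;
#' per-intensity medians; and, when at least three intensities are present,
#' the four-parameter logistic dose-response fit of period on intensity
#' with its flat-line ANOVA.
#'
#' @param ddTables list of single-fly 1-min tables recorded under DD
#'   (>= 10 days each).
#' @param llTables named list: intensity (coercible to numeric, uW/cm2) ->
#'   list of single-fly tables under LL at that intensity.
#' @param outDir optional report bundle directory.
#' @param seed seed recorded into the report config.
#' @return report list: \code{per_fly}, \code{medians},
#'   \code{wilcoxon} (DD vs pooled LL), \code{dose_response} (fit + ANOVA,
#'   NULL with a notice when < 3 intensities), \code{csv}, \code{config}.
#' @export
runLLPeriodAnalysis <- function(ddTables, llTables, outDir = NULL,
                                seed = NA_integer_) {
    dd <- .constantPeriods(ddTables)
    ll <- lapply(llTables, .constantPeriods)
    perFly <- rbind(
        data.frame(condition = "DD", intensity = 0,
                   period_h = dd[, "period_h"], power = dd[, "power"]),
        do.call(rbind, lapply(names(ll), function(nm)
            data.frame(condition = "LL", intensity = as.numeric(nm),
                       period_h = ll[[nm]][, "period_h"],
                       power = ll[[nm]][, "power"]))))
    rownames(perFly) <- NULL
    rhythmic <- !is.na(perFly$period_h)
    medians <- do.call(rbind, lapply(
        split(perFly[rhythmic, ], interaction(perFly$condition[rhythmic],
                                              perFly$intensity[rhythmic],
                                              drop = TRUE)),
        function(d) data.frame(condition = d$condition[1L],
                               intensity = d$intensity[1L],
                               n = nrow(d),
                               median_period_h = stats::median(d$period_h),
                               median_power = stats::median(d$power))))
    rownames(medians) <- NULL
    ddPer <- dd[!is.na(dd[, "period_h"]), "period_h"]
    llPer <- perFly$period_h[perFly$condition == "LL" & rhythmic]
    wx <- if (length(ddPer) && length(llPer))
        wilcoxonRankSum(ddPer, llPer) else NULL
    doseResponse <- NULL
    if (length(ll) >= 3L) {
        dose <- rep(as.numeric(names(ll)),
                    vapply(ll, nrow, integer(1)))
        resp <- unlist(lapply(ll, function(m) m[, "period_h"]),
                       use.names = FALSE)
        ok <- !is.na(resp)
        fit <- fitLogistic4(dose[ok], resp[ok])
        doseResponse <- list(fit = fit, anova = anovaVsFlat(fit))
    } else if (length(ll) < 3L)
        message("fewer than 3 intensities: dose-response section skipped")
    report <- list(
        per_fly = perFly, medians = medians, wilcoxon = wx,
        dose_response = doseResponse,
        csv = list(per_fly = perFly, medians = medians),
        stats = c(
            if (!is.null(wx)) list(wilcoxon_W = unname(wx$statistic),
                                   wilcoxon_p = wx$p.value),
            if (!is.null(doseResponse)) list(
                dose_params = as.list(doseResponse$fit$coefficients),
                anova_F = unname(doseResponse$anova$statistic),
                anova_p = doseResponse$anova$p.value)),
        config = list(analysis = "ll_period", seed = seed,
                      intensities = as.numeric(names(llTables)),
                      n_dd = length(ddTables),
                      n_ll = vapply(llTables, length, numeric(1))))
    .writeReport(report, outDir)
}

#' Ramped-light entrainment analysis
#'
#' Per-fly four-way classification under ramped cycles, the verdict
#' percentage table, entrained-only average profiles and dominant-peak
#' phases, and - when release data are present - the phase-control V-test
#' comparing first-release-day phases against the entrained phase
#' direction.
#'
#' @param tables list of single-fly 1-min tables (>= 9 ramp cycles,
#'   optionally followed by release days).
#' @param regime the ramped [LightRegime-class].
#' @param releaseAfter cycle index after which flies run under constant
#'   nadir light, or NULL when no release data exist.
#' @param nCycles ramp cycles analysed per fly.
#' @param outDir optional report bundle directory.
#' @param seed seed recorded into the report config.
#' @return report list: \code{per_fly}, \code{percentages},
#'   \code{profile} (entrained flies), \code{entrained_phases_zt_h},
#'   \code{release_phases_zt_h}, \code{phase_control} (V-test or NULL),
#'   \code{csv}, \code{config}.
#' @export
runRampAnalysis <- function(tables, regime, releaseAfter = NULL,
                            nCycles = 9L, outDir = NULL,
                            seed = NA_integer_) {
    calls <- lapply(tables, classifyRamp, nCycles = nCycles)
    verdicts <- vapply(calls, verdict, character(1))
    entr <- which(verdicts == "entrained")
    perFly <- data.frame(
        fly = if (is.null(names(tables))) paste0("fly", seq_along(tables))
              else names(tables),
        verdict = verdicts,
        peak_period_h = vapply(calls, function(c)
            evidence(c)$peak_period_h, numeric(1)),
        rhythmic_power = vapply(calls, function(c)
            evidence(c)$rhythmic_power, numeric(1)),
        drift_min_per_cycle = vapply(calls, function(c)
            evidence(c)$drift_min_per_cycle, numeric(1)))
    pct <- cohortSummary(calls)
    profile <- NULL
    entrainedPhases <- releasePhases <- numeric(0)
    phaseControl <- NULL
    if (length(entr)) {
        rampOnly <- lapply(tables[entr], function(tb)
            ActivityTable(tb@counts[seq_len(nCycles * 1440L), ,
                                    drop = FALSE],
                          binMinutes = 1, zt0Offset = tb@zt0Offset))
        profile <- averageProfile(rampOnly, 15)
        ## phases from the full recording: post-release data keep the
        ## smoothing filter's boundary away from the entrained cycles
        entrainedPhases <- vapply(tables[entr], function(tb) {
            ph <- .cyclePeakPhases(tb, cycles = 6:nCycles)
            ph <- ph[!is.na(ph)]
            if (length(ph)) circularMeanHours(ph) else NA_real_
        }, numeric(1))
        if (!is.null(releaseAfter)) {
            haveRelease <- vapply(tables[entr], function(tb)
                nBins(tb) >= (releaseAfter + 1) * 1440L, logical(1))
            releasePhases <- vapply(tables[entr][haveRelease], function(tb)
                releaseDayPhase(tb, releaseAfter * 1440L)$zt_h,
                numeric(1))
            releasePhases <- releasePhases[!is.na(releasePhases)]
            ok <- entrainedPhases[!is.na(entrainedPhases)]
            if (length(ok) && length(releasePhases) >= 2L)
                phaseControl <- assessPhaseControl(ok, releasePhases)
        }
    }
    report <- list(
        per_fly = perFly, percentages = pct, profile = profile,
        entrained_phases_zt_h = entrainedPhases,
        release_phases_zt_h = releasePhases,
        phase_control = phaseControl,
        csv = c(list(per_fly = perFly, percentages = pct),
                if (!is.null(profile))
                    list(profile_entrained = .profileDF(profile))),
        stats = if (is.null(phaseControl)) NULL else list(
            v_test_u = unname(phaseControl$statistic),
            v_test_p = phaseControl$p.value,
            mu0_zt_h = angleToZt(unname(phaseControl$estimate["mu0"]))),
        config = list(analysis = "ramp", seed = seed, n_cycles = nCycles,
                      release_after = if (is.null(releaseAfter))
                          NA_integer_ else releaseAfter,
                      n_flies = length(tables)))
    .writeReport(report, outDir)
}

#' Render an actogram
#'
#' Day-by-row raster of a fly's activity, optionally double-plotted (each
#' row spans 48 h: day d beside day d+1), with the light regime's
#' intensity overlaid as shading. Always returns the underlying matrix;
#' draws to a PNG when \code{file} is given.
#'
#' @param table single-fly [ActivityTable-class] with >= 2 complete days.
#' @param regime optional [LightRegime-class] for shading.
#' @param doublePlot logical; 48 h rows.
#' @param binMinutes plotting bin width.
#' @param file optional PNG path.
#' @param channel channel index.
#' @return the plotted matrix (days x bins), invisibly when drawing.
#' @export
renderActogram <- function(table, regime = NULL, doublePlot = FALSE,
                           binMinutes = 15, file = NULL, channel = 1L) {
    dm <- splitDays(binActivity(table, binMinutes), channel = channel)
    if (nrow(dm) < 2L) stop("need at least 2 complete days")
    mat <- if (doublePlot)
        cbind(dm[-nrow(dm), , drop = FALSE], dm[-1L, , drop = FALSE])
    else dm
    if (!is.null(file)) {
        grDevices::png(file, width = 900, height = 120 + 60 * nrow(mat))
        on.exit(grDevices::dev.off())
        .drawActogram(mat, regime, doublePlot, binMinutes)
    }
    invisible(mat)
}

.drawActogram <- function(mat, regime, doublePlot, binMinutes) {
    nd <- nrow(mat)
    nb <- ncol(mat)
    hoursPerRow <- nb * binMinutes / 60
    graphics::par(mar = c(3, 3, 1, 1))
    graphics::plot(NULL, xlim = c(0, hoursPerRow), ylim = c(0, nd),
                   xlab = "ZT (h)", ylab = "day", xaxs = "i", yaxs = "i",
                   yaxt = "n")
    graphics::axis(2, at = seq_len(nd) - 0.5, labels = rev(seq_len(nd)),
                   las = 1)
    if (!is.null(regime)) {
        zt <- seq(0, hoursPerRow * 60 - 1, by = binMinutes)
        iv <- intensityAt(regime, zt)
        if (max(iv) > 0) {
            shade <- grDevices::gray(1 - 0.35 * iv / max(iv))
            for (b in seq_along(zt))
                graphics::rect((b - 1) * binMinutes / 60, 0,
                               b * binMinutes / 60, nd,
                               col = shade[b], border = NA)
        }
    }
    mx <- max(mat, 1)
    for (d in seq_len(nd)) {
        y0 <- nd - d
        h <- 0.9 * mat[d, ] / mx
        graphics::rect((seq_len(nb) - 1) * binMinutes / 60, y0,
                       seq_len(nb) * binMinutes / 60, y0 + h,
                       col = "black", border = NA)
    }
    invisible(NULL)
}
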