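## Ground-truth generator: phase-oscillator fly model with parametric
## (continuous velocity modulation) and non-parametric (transition jump)
## light action, masking, startle, and Poisson count emission.

.defaultWaveform <- function(bimodal = TRUE) {
    if (bimodal)
        list(centers = c(0.5, 11.5), kappas = c(8, 6),
             weights = c(0.35, 0.65), baseline = 0.1)
    else
        list(centers = 12, kappas = 1, weights = 0, baseline = 1)
}

## evaluate the two-bump von Mises mixture waveform, normalized to mean 1
.waveformFun <- function(wf) {
    raw <- function(phi) {
        v <- rep(wf$baseline, length(phi))
        for (j in seq_along(wf$weights))
            v <- v + wf$weights[j] *
                exp(wf$kappas[j] * (cos(2 * pi * (phi - wf$centers[j]) / 24) -
                                    1))
        v
    }
    grid <- seq(0, 24, length.out = 1441L)[-1441L]
    m <- mean(raw(grid))
    if (m <= 0) function(phi) rep(1, length(phi))
    else function(phi) raw(phi) / m
}

#' Construct a FlySpec
#'
#' Fills mode-appropriate defaults for the phase-oscillator fly model. The
#' modes emulate the behavioural categories the analysis chain must
#' classify: \code{entrained_locked} (phase rigidly locked to the
#' zeitgeber, 24.0 h), \code{oscillator} (free oscillator entrained
#' parametrically and/or by transition jumps), \code{free_running} (pure
#' clock at \code{tauH}, light-blind), \code{relative_coordination}
#' (oscillator whose parametric gain is too weak to lock its
#' \code{tauH != 24} clock, producing period wobble), \code{arrhythmic}
#' (flat waveform, pure Poisson noise) and \code{masker} (flat waveform
#' with light-driven suppression, so activity tracks the light cycle, not a
#' clock).
#'
#' @param mode one of the six modes above.
#' @param tauH intrinsic period in hours.
#' @param psi0H initial phase in hours.
#' @param epsP parametric velocity-modulation gain.
#' @param prcAmpH transition-jump amplitude in hours.
#' @param waveform list(centers, kappas, weights, baseline); default is a
#'   bimodal (morning + dominant evening) von Mises mixture.
#' @param startleAmp,startleDecayMin startle transient amplitude (counts/min)
#'   and exponential decay (min).
#' @param maskCoeff masking coefficient (exp(-maskCoeff * I_norm) rate
#'   suppression).
#' @param baseRate baseline Poisson rate, counts/min.
#' @param seed integer RNG seed, recorded in simulated outputs.
#' @return a [FlySpec-class].
#' @examples
#' flySpec("free_running", tauH = 25)
#' @export
flySpec <- function(mode = "oscillator", tauH = 24, psi0H = 0,
                    epsP = NULL, prcAmpH = NULL, waveform = NULL,
                    startleAmp = 6, startleDecayMin = 12, maskCoeff = 0,
                    baseRate = 1.5, seed = 1L) {
    mode <- match.arg(mode, .FLY_MODES)
    if (is.null(epsP))
        epsP <- switch(mode, oscillator = 0.4,
                       relative_coordination = 0.3, 0)
    if (is.null(prcAmpH))
        prcAmpH <- switch(mode, oscillator = 0.8, 0)
    if (is.null(waveform))
        waveform <- .defaultWaveform(!(mode %in% c("arrhythmic", "masker")))
    if (mode == "masker" && maskCoeff == 0) maskCoeff <- 1.5
    if (mode == "relative_coordination" && tauH == 24) tauH <- 24.45
    new("FlySpec", mode = mode, tauH = tauH, psi0H = psi0H, epsP = epsP,
        prcAmpH = prcAmpH, waveform = waveform, startleAmp = startleAmp,
        startleDecayMin = startleDecayMin, maskCoeff = maskCoeff,
        baseRate = baseRate, seed = as.integer(seed))
}

#' Advance the oscillator phase by one step
#'
#' Continuous (parametric) light action: the phase advances as
#' \deqn{d\phi = dt \cdot (24/\tau)(1 + \epsilon_p\, g(\phi)\, I_{norm})}
#' with velocity-response curve \eqn{g(\phi) = \sin(2\pi(\phi - 12)/24)},
#' which decelerates the clock through the subjective evening (light late
#' in the day delays) and accelerates it through the subjective morning
#' (light early in the day advances). In darkness the phase advances at
#' exactly \code{24/tauH} hours per hour.
#'
#' @param phi current phase in hours.
#' @param iNorm normalized light intensity in [0, 1].
#' @param dtMin step in minutes (> 0).
#' @param spec a [FlySpec-class].
#' @return new phase in [0, 24).
#' @export
advancePhase <- function(phi, iNorm, dtMin, spec) {
    stopifnot(dtMin > 0)
    g <- sin(2 * pi * (phi - 12) / 24)
    (phi + (dtMin / 60) * (24 / spec@tauH) *
         (1 + spec@epsP * g * iNorm)) %% 24
}

## delay-advance phase-response kernel with a subjective-day dead zone
## (phi in [1, 11]): delays through the early subjective night
## (phi ~ 11-18), advances through the late subjective night into dawn.
## Without the dead zone, dawn and dusk pulses of a skeleton photoperiod
## cancel and discrete entrainment cannot lock.
.prcKernel <- function(phi) {
    phi <- phi %% 24
    phiN <- ifelse(phi <= 1, phi + 24, phi)  # subjective night on [11, 25]
    ifelse(phiN >= 11, sin(2 * pi * (phiN - 18) / 14), 0)
}

#' Instantaneous phase jump at a discrete light transition
#'
#' Non-parametric light action: at a discontinuity of intensity the phase
#' resets by \code{prcAmpH * prc(phi)}, with a standard delay-advance
#' kernel: zero through the subjective day (dead zone, phase hours 1-11),
#' a half-sine over the subjective night giving delays early in the night
#' and advances late in the night and around subjective dawn.
#' Lights-off transitions act with half the amplitude of
#' lights-on transitions; amplitude scales with the normalized jump size.
#' A no-op when \code{prcAmpH = 0}.
#'
#' @param phi phase in hours.
#' @param dINorm signed normalized intensity jump (non-zero).
#' @param spec a [FlySpec-class].
#' @return new phase in [0, 24).
#' @export
transitionJump <- function(phi, dINorm, spec) {
    stopifnot(dINorm != 0)
    if (spec@prcAmpH == 0) return(phi %% 24)
    gain <- min(1, abs(dINorm)) * if (dINorm > 0) 1 else 0.5
    (phi + spec@prcAmpH * gain * .prcKernel(phi)) %% 24
}

#' Expected emission rate of a simulated fly
#'
#' \deqn{rate = base \cdot w(\phi)\, e^{-\kappa I_{norm}} +
#'   A\, e^{-t/\tau_s} \,[t \le 60]}
#' where \eqn{w} is the circadian activity waveform (identically 1 in
#' masker/arrhythmic modes, so activity tracks light alone), \eqn{\kappa}
#' the masking coefficient, and the startle term decays from amplitude
#' \eqn{A} with constant \eqn{\tau_s} minutes and acts only within 60 min
#' of a discrete light transition.
#'
#' @param phi phase in hours (vectorized).
#' @param iNorm normalized intensity in [0, 1].
#' @param tSinceTransition minutes since the last discrete transition
#'   (\code{Inf} when none).
#' @param spec a [FlySpec-class].
#' @return expected counts per minute.
#' @export
emissionRate <- function(phi, iNorm, tSinceTransition, spec) {
    wf <- .waveformFun(spec@waveform)
    rate <- spec@baseRate * wf(phi %% 24) * exp(-spec@maskCoeff * iNorm)
    startle <- ifelse(tSinceTransition <= 60,
                      spec@startleAmp *
                          exp(-tSinceTransition / spec@startleDecayMin), 0)
    rate + startle
}

## per-minute intensity vector over the experiment, plus discrete
## transition minutes (0-based); release switches to constant light at the
## cycle nadir
.lightSchedule <- function(regime, days, releaseAfter = NULL, iRef = NULL) {
    cyc <- intensityAt(regime, 0:1439)
    minutes <- days * 1440L
    I <- rep(cyc, length.out = minutes)
    tr <- transitions(regime)
    trMin <- integer(0)
    cyclicDays <- if (is.null(releaseAfter)) days else min(releaseAfter, days)
    if (nrow(tr))
        trMin <- as.integer(outer(tr$zt_min, (seq_len(cyclicDays) - 1L) *
                                      1440L, "+"))
    if (!is.null(releaseAfter) && releaseAfter < days) {
        nadir <- min(cyc)
        from <- releaseAfter * 1440L
        pre <- I[from]  # last cyclic minute's intensity
        I[(from + 1L):minutes] <- nadir
        if (abs(pre - nadir) > 1e-9) trMin <- c(trMin, from)
    }
    list(I = I, trMin = sort(unique(trMin)),
         iMax = if (is.null(iRef)) max(cyc) else iRef, nadir = min(cyc))
}

#' Simulate one fly
#'
#' Integrates the phase oscillator at 1-min steps under the given light
#' regime (Euler step of [advancePhase()], with [transitionJump()] applied
#' at every discrete light transition), evaluates the emission rate, and
#' draws per-minute Poisson counts. Fully reproducible from \code{seed}.
#'
#' @param spec a [FlySpec-class].
#' @param regime a [LightRegime-class].
#' @param days number of 24 h cycles to simulate.
#' @param releaseAfter optional cycle count after which the regime switches
#'   to constant light at the cycle's nadir intensity (release protocol).
#' @param iRef reference intensity for normalization (\code{I_norm =
#'   I/iRef}, capped at 1). Defaults to the regime's cycle maximum; supply
#'   a common reference (e.g. the highest intensity of a dose series) when
#'   comparing regimes of different absolute intensity.
#' @param seed RNG seed; defaults to the spec's.
#' @return list with \code{table} (single-channel 1-min
#'   [ActivityTable-class]) and \code{truth} (list: mode, tau_h, seed,
#'   psi0_h, phase_by_cycle at each cycle start, release_after).
#' @export
simulateFly <- function(spec, regime, days, releaseAfter = NULL,
                        iRef = NULL, seed = NULL) {
    stopifnot(is(spec, "FlySpec"), is(regime, "LightRegime"), days >= 1)
    if (is.null(seed)) seed <- spec@seed
    sched <- .lightSchedule(regime, days, releaseAfter, iRef)
    minutes <- days * 1440L
    iNorm <- if (sched$iMax > 0) pmin(1, sched$I / sched$iMax)
             else rep(0, minutes)
    tMin <- seq_len(minutes) - 1L

    locked <- spec@mode %in% c("entrained_locked", "arrhythmic", "masker")
    parametric <- spec@epsP != 0 && any(iNorm > 0)
    jumps <- spec@prcAmpH != 0 && length(sched$trMin) > 0
    if (locked) {
        phi <- (spec@psi0H + tMin / 60) %% 24
    } else if (!parametric && !jumps) {
        phi <- (spec@psi0H + (tMin / 60) * (24 / spec@tauH)) %% 24
    } else {
        phi <- numeric(minutes)
        p <- spec@psi0H %% 24
        isTr <- rep(FALSE, minutes)
        isTr[sched$trMin[sched$trMin > 0] + 1L] <- TRUE
        dNorm <- c(0, diff(sched$I)) / max(sched$iMax, 1e-12)
        for (i in seq_len(minutes)) {
            if (isTr[i] && dNorm[i] != 0)
                p <- transitionJump(p, dNorm[i], spec)
            phi[i] <- p
            p <- advancePhase(p, iNorm[i], 1, spec)
        }
    }

    tSince <- rep(Inf, minutes)
    if (length(sched$trMin)) {
        ev <- sched$trMin + 1L
        idx <- findInterval(seq_len(minutes), ev)
        has <- idx > 0
        tSince[has] <- (seq_len(minutes)[has]) - ev[idx[has]]
    }
    rate <- emissionRate(phi, iNorm, tSince, spec)
    set.seed(seed)
    countsVec <- stats::rpois(minutes, rate)
    tab <- ActivityTable(matrix(countsVec, ncol = 1L,
                                dimnames = list(NULL, "ch1")),
                         binMinutes = 1, zt0Offset = 0)
    truth <- list(mode = spec@mode, tau_h = spec@tauH, seed = seed,
                  psi0_h = spec@psi0H,
                  phase_by_cycle = phi[(seq_len(days) - 1L) * 1440L + 1L],
                  release_after = if (is.null(releaseAfter)) NA_integer_
                                  else releaseAfter)
    list(table = tab, truth = truth)
}

#' Simulate a cohort of flies
#'
#' Runs [simulateFly()] for every spec, optionally serializes the cohort to
#' Trikinetics-dialect monitor files (32 flies per file) with a ground-truth
#' CSV alongside.
#'
#' @param flies list of [FlySpec-class] objects.
#' @param regime a [LightRegime-class].
#' @param days cycles to simulate.
#' @param releaseAfter optional release cycle (see [simulateFly()]).
#' @param iRef optional common reference intensity (see [simulateFly()]).
#' @param dir optional output directory for monitor + truth files.
#' @return list with \code{tables} (list of single-fly tables),
#'   \code{truth} (data.frame: fly, mode, tau_h, seed, psi0_h,
#'   release_after) and \code{files} (written paths, if any).
#' @export
simulateCohort <- function(flies, regime, days, releaseAfter = NULL,
                           iRef = NULL, dir = NULL) {
    stopifnot(length(flies) >= 1L)
    sims <- lapply(flies, simulateFly, regime = regime, days = days,
                   releaseAfter = releaseAfter, iRef = iRef)
    tables <- lapply(sims, `[[`, "table")
    names(tables) <- paste0("fly", seq_along(tables))
    truth <- data.frame(
        fly = names(tables),
        mode = vapply(sims, function(s) s$truth$mode, character(1)),
        tau_h = vapply(sims, function(s) s$truth$tau_h, numeric(1)),
        seed = vapply(sims, function(s) s$truth$seed, numeric(1)),
        psi0_h = vapply(sims, function(s) s$truth$psi0_h, numeric(1)),
        release_after = vapply(sims, function(s)
            as.numeric(s$truth$release_after), numeric(1)))
    files <- character(0)
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        grp <- split(seq_along(tables), (seq_along(tables) - 1L) %/% 32L)
        for (g in seq_along(grp)) {
            idx <- grp[[g]]
            cts <- do.call(cbind, lapply(tables[idx], activityCounts))
            f <- file.path(dir, sprintf("Monitor%d.txt", g))
            writeMonitorFile(ActivityTable(cts), f)
            files <- c(files, f)
        }
        tf <- file.path(dir, "truth.csv")
        utils::write.csv(truth, tf, row.names = FALSE)
        files <- c(files, tf)
    }
    list(tables = tables, truth = truth, files = files)
}
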