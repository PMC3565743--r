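#' Normalized sup-norm discrepancy between two responses
#'
#' sup_t |y1(t) - y2(t)| divided by the peak-to-peak range of y1.  If
#' y1 is (numerically) flat the absolute sup-norm is returned instead,
#' so that identical flat responses still score 0.
#'
#' @param y1,y2 numeric vectors on a common time grid.
#' @return non-negative scalar.
#' @export
fcdDiscrepancy <- function(y1, y2) {
  stopifnot(length(y1) == length(y2), length(y1) > 0)
  supd <- max(abs(y1 - y2))
  rng <- diff(range(y1))
  if (rng <= 1e-9 * max(abs(y1), 1)) supd else supd / rng
}

.defaultTol <- function(model) if (model@activity == "log") 1e-6 else 0.05

.pairGrid <- function(pair, by = 0.5) seq(0, pair@horizon, by = by)

.armProgram <- function(pair, arm) {
  if (arm == 1L) ligandProgram(c(0, pair@stepTime), c(pair@LPre1, pair@LPost1))
  else ligandProgram(c(0, pair@stepTime), c(pair@LPre2, pair@LPost2))
}

#' Run a scaled step pair and judge fold-change detection
#'
#' Simulates the two arms of a \code{\link{ScaledStepPair}}, each arm
#' started from its own adapted steady state at the pre-step level, and
#' compares the responses on the named observable.  Under the
#' log-regime activity the two responses are algebraically identical
#' (exact FCD) whenever the integral-feedback structure is intact.
#'
#' @param model a \code{\link{ChemotaxisModel}}.
#' @param pair a \code{\link{ScaledStepPair}}.
#' @param observable channel name (default "f"; for model III the
#'   natural readout is "Y6p").
#' @param tol verdict threshold; defaults to 1e-6 for log-regime
#'   models (exact FCD) and 0.05 for exact-activity models
#'   (regime-limited FCD).
#' @param by output grid spacing (s).
#' @return list(traj1, traj2, verdict) with both \code{Trajectory}
#'   objects on the common grid and the \code{\link{FCDVerdict}}.
#' @export
runScaledPair <- function(model, pair = scaledStepPair(), observable = "f",
                          tol = .defaultTol(model), by = 0.5) {
  stopifnot(is(model, "ChemotaxisModel"), is(pair, "ScaledStepPair"))
  tt <- .pairGrid(pair, by)
  tr1 <- simulateTrajectory(model, .armProgram(pair, 1L), tt)
  tr2 <- simulateTrajectory(model, .armProgram(pair, 2L), tt)
  d <- fcdDiscrepancy(trajChannel(tr1, observable), trajChannel(tr2, observable))
  list(traj1 = tr1, traj2 = tr2, verdict = .verdict(observable, d, tol))
}

#' Equivariance check of the fold-change symmetry
#'
#' Direct numerical verification of the symmetry underlying FCD: the
#' response to the scaled input p L(t), started from the adapted state
#' with the methylation coordinates shifted by ln(p)/alpha (and, for
#' model II, the internal-ligand state scaled by p), must reproduce the
#' unscaled activity, phospho and flagellar trajectories exactly.  The
#' symmetry is exact only under the log-regime activity, so models
#' configured with the exact Boltzmann activity are rejected.
#'
#' @param model a log-regime \code{\link{ChemotaxisModel}}.
#' @param program a \code{\link{LigandProgram}} with positive levels.
#' @param p input scale factor > 0.
#' @param times output grid (s); default seq over the program span.
#' @return absolute sup-norm discrepancy over the channels a, at, all
#'   phospho species and f (expected at solver accuracy, ~1e-10).
#' @export
equivarianceCheck <- function(model, program, p, times = NULL) {
  stopifnot(is(model, "ChemotaxisModel"))
  if (model@activity != "log")
    stop("equivariance is exact only under the log-regime activity; ",
         "use setActivityForm(model, \"log\")", call. = FALSE)
  if (!is.finite(p) || p <= 0) stop("'p' must be > 0", call. = FALSE)
  if (is.null(times))
    times <- seq(program@times[1L], max(program@times) + 200, by = 0.5)
  s0 <- steadyState(model, ligandAt(program, times[1L]))
  tr1 <- simulateTrajectory(model, program, times, init = s0)
  s0p <- s0
  s0p[["m"]] <- s0[["m"]] + fcdMethylationShift(p, model@membrane@alpha)
  s0p[["mt"]] <- s0[["mt"]] + fcdMethylationShift(p, model@cytoplasmic@alpha)
  if (model@variant == "II") s0p[["Lt"]] <- p * s0[["Lt"]]
  tr2 <- simulateTrajectory(model, scaleProgram(program, p), times, init = s0p)
  ch <- c("a", "at", "A2p", "A34p", "Y3p", "Y4p", "Y6p", "B1p", "B2p", "f")
  max(vapply(ch, function(x)
    max(abs(trajChannel(tr1, x) - trajChannel(tr2, x))), numeric(1)))
}

#' Scan ligand backgrounds for fold-change detection
#'
#' For each background L the pair of step programs (L -> L/fold) and
#' (L/s -> L/(s fold)) is run with the exact MWC activity and judged on
#' the observable.  Backgrounds deep in the regime
#' K_I << L << K_A (after allowing for the variant's internal-ligand
#' attenuation, see \code{\link{fcdBoundFactor}}) pass; backgrounds at
#' or outside the dissociation constants fail.
#'
#' @param model a \code{\link{ChemotaxisModel}} (run with exact
#'   activity regardless of its configured form).
#' @param fold step fold-change > 1.
#' @param backgrounds pre-step ligand levels (uM).
#' @param tol verdict threshold (default 0.05).
#' @param s scale factor between the two arms (default 2).
#' @param observable channel name.
#' @return data.frame(background_uM, discrepancy, is_fcd).
#' @export
fcdRangeScan <- function(model, fold = 5, backgrounds, tol = 0.05, s = 2,
                         observable = "f") {
  stopifnot(fold > 1, s > 0)
  model <- setActivityForm(model, "exact")
  rows <- lapply(backgrounds, function(L) {
    pair <- scaledStepPair(L, L / fold, L / s, L / (s * fold))
    res <- runScaledPair(model, pair, observable = observable, tol = tol)
    data.frame(background_uM = L, discrepancy = res$verdict@discrepancy,
               is_fcd = res$verdict@isFCD)
  })
  do.call(rbind, rows)
}

# Resolve "block.param" or "block.param.entry" paths into a model copy.
.setModelParam <- function(model, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  if (length(parts) < 2L)
    stop("unresolvable parameter path '", path, "'", call. = FALSE)
  block <- parts[1L]
  obj <- switch(block,
                membrane = model@membrane, cytoplasmic = model@cytoplasmic,
                phospho = model@phospho, methylation = model@methylation,
                flagellar = model@flagellar,
                stop("unresolvable parameter path '", path, "'", call. = FALSE))
  if (!parts[2L] %in% slotNames(obj))
    stop("unresolvable parameter path '", path, "'", call. = FALSE)
  cur <- slot(obj, parts[2L])
  if (length(parts) == 3L) {
    if (!parts[3L] %in% names(cur))
      stop("unresolvable parameter path '", path, "'", call. = FALSE)
    cur[[parts[3L]]] <- value
  } else cur <- value
  slot(obj, parts[2L]) <- cur
  validObject(obj)
  slot(model, block) <- obj
  model
}

#' Parametric robustness sweep of the FCD verdict
#'
#' Re-runs a scaled step pair at each value of one swept parameter
#' (e.g. the CheY6 auto-dephosphorylation rate "phospho.kDephos.Y6",
#' the total CheB1 concentration "phospho.totals.B1", or the
#' demethylation rate "methylation.kB1").  Under the log-regime
#' activity the FCD verdict is structurally guaranteed and should be
#' unchanged across the sweep.
#'
#' @param model a \code{\link{ChemotaxisModel}}.
#' @param paramPath dotted path into the parameter blocks, e.g.
#'   "methylation.kB1".
#' @param values numeric values to sweep.
#' @param pair a \code{\link{ScaledStepPair}}.
#' @param observable channel name.
#' @param tol verdict threshold (defaults per activity form).
#' @return data.frame(value, discrepancy, is_fcd).
#' @export
robustnessSweep <- function(model, paramPath, values, pair = scaledStepPair(),
                            observable = "f", tol = .defaultTol(model)) {
  rows <- lapply(values, function(v) {
    m2 <- .setModelParam(model, paramPath, v)
    res <- runScaledPair(m2, pair, observable = observable, tol = tol)
    data.frame(value = v, discrepancy = res$verdict@discrepancy,
               is_fcd = res$verdict@isFCD)
  })
  out <- do.call(rbind, rows)
  out$param <- paramPath
  out[, c("param", "value", "discrepancy", "is_fcd")]
}

#' Regime-violation experiment
#'
#' Overrides the dissociation constants of both clusters (default
#' K_I = 1800, K_A = 3000 uM so that the canonical stimuli no longer
#' satisfy K_I << L << K_A), switches to the exact MWC activity and
#' runs the pair.  Outside the log regime the two scaled responses
#' visibly differ and the FCD test fails.
#'
#' @param model a \code{\link{ChemotaxisModel}}.
#' @param pair a \code{\link{ScaledStepPair}}.
#' @param K_I,K_A overriding dissociation constants (uM), applied to
#'   both clusters.
#' @param observable channel name.
#' @param tol verdict threshold (default 0.05).
#' @return the \code{\link{FCDVerdict}}.
#' @export
regimeViolationRun <- function(model, pair = scaledStepPair(), K_I = 1800,
                               K_A = 3000, observable = "f", tol = 0.05) {
  model <- setActivityForm(model, "exact")
  for (cl in c("membrane", "cytoplasmic")) {
    rp <- slot(model, cl)
    rp@K_I <- K_I; rp@K_A <- K_A
    validObject(rp)
    slot(model, cl) <- rp
  }
  runScaledPair(model, pair, observable = observable, tol = tol)$verdict
}

#' In-silico mutant fold-change-detection suite
#'
#' Runs the scaled-pair protocol for the gene-deletion and
#' overexpression mutants, each on the observables that remain
#' informative: Y6p for cheA2_del (CheY6 is then phosphorylated only by
#' the cytoplasmic cluster), Y3p/Y4p/Y6p for cheA3_del (all driven by
#' the membrane cluster), the membrane-driven Y3p/Y4p for cheB2_del
#' (the cytoplasmic cluster loses its only demethylase, so its
#' adaptation is structurally lost and the flagellar frequency
#' collapses towards zero), and f for cheY4_5x.
#'
#' Arms of a mutant that has lost adaptation in one cluster are
#' initialized from quasi-equilibrated states (long pre-integration)
#' instead of true steady states, and judged at the exact-activity
#' tolerance.
#'
#' @param model a \code{\link{ChemotaxisModel}} (variant I or II;
#'   model III is accepted but its cheA2_del mutant loses membrane
#'   adaptation since CheB1 is then the only membrane demethylase).
#' @param pair a \code{\link{ScaledStepPair}}.
#' @param mutants character subset of the four supported mutations.
#' @param tol verdict threshold for fully adapting mutants.
#' @return data.frame(mutant, observable, discrepancy, is_fcd,
#'   adaptation_lost_membrane, adaptation_lost_cytoplasmic).
#' @export
mutantFcdSuite <- function(model, pair = scaledStepPair(),
                           mutants = c("cheA2_del", "cheA3_del", "cheB2_del",
                                       "cheY4_5x"),
                           tol = .defaultTol(model)) {
  mutants <- match.arg(mutants, .MUTATIONS, several.ok = TRUE)
  obsFor <- list(cheA2_del = "Y6p", cheA3_del = c("Y3p", "Y4p", "Y6p"),
                 cheB2_del = c("Y3p", "Y4p"), cheY4_5x = "f")
  rows <- list()
  for (mut in mutants) {
    m2 <- addMutation(model, mut)
    drift <- lostAdaptation(m2)
    tolm <- if (any(drift)) max(tol, 0.05) else tol
    tt <- .pairGrid(pair)
    run_arm <- function(arm) {
      prog <- .armProgram(pair, arm)
      init <- if (any(drift))
        steadyState(m2, prog@levels[1L], allowDrift = TRUE)
      else steadyState(m2, prog@levels[1L])
      simulateTrajectory(m2, prog, tt, init = init)
    }
    tr1 <- run_arm(1L); tr2 <- run_arm(2L)
    for (obs in obsFor[[mut]]) {
      d <- fcdDiscrepancy(trajChannel(tr1, obs), trajChannel(tr2, obs))
      rows[[length(rows) + 1L]] <- data.frame(
        mutant = mut, observable = obs, discrepancy = d, is_fcd = d <= tolm,
        adaptation_lost_membrane = unname(drift[["membrane"]]),
        adaptation_lost_cytoplasmic = unname(drift[["cytoplasmic"]]))
    }
  }
  do.call(rbind, rows)
}
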