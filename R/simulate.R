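#' Steady state of the closed loop at constant ligand
#'
#' Finds the adapted state at a constant external ligand level by long
#' integration followed by a damped Newton polish on the full
#' right-hand side (finite-difference Jacobian).  Because the
#' methylation feedback is integral, the activities and flagellar
#' frequency at the returned state are independent of \code{L} under
#' the log-regime activity (exact adaptation).
#'
#' For a model in which a cluster has lost all of its demethylases (see
#' \code{\link{lostAdaptation}}) no steady state exists -- the
#' methylation level drifts -- and an error is raised unless
#' \code{allowDrift = TRUE}, in which case the state after
#' \code{preEquilibrate} seconds of integration is returned.
#'
#' @param model a \code{\link{ChemotaxisModel}}.
#' @param L constant external ligand (uM, >= 0; > 0 for log-regime
#'   models).
#' @param tol convergence tolerance on the max-norm of the RHS (1/s).
#' @param preEquilibrate length of the initial relaxation integration (s).
#' @param allowDrift return the quasi-equilibrated state even when a
#'   cluster cannot adapt.
#' @param init optional initial state for the relaxation (named as the
#'   model's state vector); defaults to an unphosphorylated state at
#'   m = mtilde = m0.
#' @return named state vector with attributes \code{"a"}, \code{"at"},
#'   \code{"f"} (activities and flagellar frequency at the fixed point)
#'   and \code{"residual"} (max-norm of the RHS).
#' @export
steadyState <- function(model, L, tol = 1e-11, preEquilibrate = 4000,
                        allowDrift = FALSE, init = NULL) {
  stopifnot(is(model, "ChemotaxisModel"), length(L) == 1L, L >= 0)
  pc <- .compileModel(model)
  if (pc$logAct && L <= 0)
    stop("log-regime activity requires L > 0", call. = FALSE)
  pc$L <- L
  nm <- .stateNames(model@variant)
  if (is.null(init)) {
    init <- c(m = model@membrane@m0, mt = model@cytoplasmic@m0,
              if (model@variant == "II") c(Lt = L),
              A2p = 0, A34p = 0, Y3p = 0, Y4p = 0, Y6p = 0, B1p = 0, B2p = 0)
  }
  y <- unname(init[nm])
  drift <- lostAdaptation(model)
  # a truncated relaxation (hostile parameter draws during fitting) still
  # provides a usable Newton start, so integrator warnings are not fatal
  sol <- suppressWarnings(.integrateSegment(y, c(0, preEquilibrate), pc,
                                            rtol = 1e-10, atol = 1e-10))
  y <- as.numeric(sol[nrow(sol), -1L])
  if (any(!is.finite(y)))
    stop("relaxation integration diverged", call. = FALSE)
  if (!any(drift)) {
    n <- length(y)
    for (iter in seq_len(60L)) {
      r <- .rhsCore(y, pc)
      if (max(abs(r)) < tol) break
      J <- matrix(0, n, n)
      h <- 1e-7 * pmax(abs(y), 1)
      for (j in seq_len(n)) {
        yp <- y; ym <- y
        yp[j] <- yp[j] + h[j]; ym[j] <- ym[j] - h[j]
        J[, j] <- (.rhsCore(yp, pc) - .rhsCore(ym, pc)) / (2 * h[j])
      }
      step <- tryCatch(solve(J, -r), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      r0 <- max(abs(r))
      repeat {
        yn <- y + lam * step
        rn <- tryCatch(max(abs(.rhsCore(yn, pc))), error = function(e) Inf)
        if (rn < r0 || lam < 1e-4) break
        lam <- lam / 2
      }
      if (rn >= r0) break
      y <- yn
    }
    res <- max(abs(.rhsCore(y, pc)))
    if (res > 1e3 * tol)
      stop(sprintf(paste0("steady-state solve did not converge at L = %g uM ",
                          "(residual %.3e)"), L, res), call. = FALSE)
  } else {
    if (!allowDrift)
      stop("no steady state: cluster(s) without demethylation feedback (",
           paste(names(drift)[drift], collapse = ", "),
           "); use allowDrift = TRUE for a quasi-equilibrated state",
           call. = FALSE)
    res <- max(abs(.rhsCore(y, pc)))
  }
  names(y) <- nm
  off <- if (model@variant == "II") 3L else 2L
  Lt <- switch(model@variant,
               I = 10 * L / (10 + y[[off + 3L]] + y[[off + 4L]]),
               II = y[["Lt"]], III = L)
  actFun <- if (pc$logAct) activityLogRegime else activityExact
  attr(y, "a") <- actFun(y[["m"]], L, model@membrane)
  attr(y, "at") <- actFun(y[["mt"]], Lt, model@cytoplasmic)
  attr(y, "f") <- flagellarFrequency(y[["Y3p"]], y[["Y4p"]], y[["Y6p"]],
                                     model@flagellar)
  attr(y, "residual") <- res
  y
}

#' Simulate a model under a ligand program
#'
#' Integrates the closed-loop ODE system over a piecewise-constant
#' ligand program, restarting the integrator exactly at every ligand
#' breakpoint (steps are not smoothed).  Derived channels (activities,
#' internal ligand, flagellar frequency, external ligand) are appended
#' to the state channels.
#'
#' @param model a \code{\link{ChemotaxisModel}}.
#' @param program a \code{\link{LigandProgram}}.
#' @param times output time grid (s), increasing, starting at or after
#'   \code{program@times[1]}.
#' @param init initial state; defaults to the adapted state at the
#'   program's initial ligand level.
#' @return a \code{\link{Trajectory}}.
#' @examples
#' \donttest{
#' mod <- chemotaxisModel("I")
#' tr <- simulateTrajectory(mod, ligandProgram(), times = seq(0, 600, 2))
#' range(trajChannel(tr, "f"))
#' }
#' @export
simulateTrajectory <- function(model, program, times, init = NULL) {
  stopifnot(is(model, "ChemotaxisModel"), is(program, "LigandProgram"))
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("'times' must be increasing", call. = FALSE)
  pc <- .compileModel(model)
  if (pc$logAct && any(program@levels <= 0))
    stop("log-regime activity requires strictly positive ligand levels",
         call. = FALSE)
  nm <- .stateNames(model@variant)
  if (is.null(init)) init <- steadyState(model, ligandAt(program, times[1L]))
  y <- unname(init[nm])
  if (any(!is.finite(y))) stop("initial state must be finite", call. = FALSE)

  brk <- program@times[program@times > times[1L] & program@times < times[length(times)]]
  seg_bounds <- c(times[1L], brk, times[length(times)])
  out <- matrix(NA_real_, length(times), length(nm))
  if (times[1L] >= seg_bounds[1L]) out[1L, ] <- y
  filled <- 1L
  for (s in seq_len(length(seg_bounds) - 1L)) {
    t0 <- seg_bounds[s]; t1 <- seg_bounds[s + 1L]
    pc$L <- ligandAt(program, t0)
    inner <- times[times > t0 & times <= t1]
    tt <- unique(c(t0, inner, t1))
    sol <- tryCatch(
      .integrateSegment(y, tt, pc, rtol = model@solver$rtol,
                        atol = model@solver$atol,
                        hmax = model@solver$maxStep),
      warning = function(w)
        stop(sprintf("integration failed in segment starting t = %g s: %s",
                     t0, conditionMessage(w)), call. = FALSE))
    if (length(inner)) {
      rows <- match(inner, sol[, 1L])
      out[filled + seq_along(inner), ] <- as.matrix(sol[rows, -1L, drop = FALSE])
      filled <- filled + length(inner)
    }
    y <- as.numeric(sol[nrow(sol), -1L])
  }
  colnames(out) <- nm
  L <- ligandAt(program, times)
  Lt <- switch(model@variant,
               I = 10 * L / (10 + out[, "Y3p"] + out[, "Y4p"]),
               II = out[, "Lt"],
               III = L)
  actFun <- if (pc$logAct) activityLogRegime else activityExact
  a <- actFun(out[, "m"], L, model@membrane)
  at <- actFun(out[, "mt"], Lt, model@cytoplasmic)
  f <- flagellarFrequency(out[, "Y3p"], out[, "Y4p"], out[, "Y6p"],
                          model@flagellar)
  series <- cbind(out[, c("m", "mt"), drop = FALSE], Lt = unname(Lt),
                  out[, c("A2p", "A34p", "Y3p", "Y4p", "Y6p", "B1p", "B2p"),
                      drop = FALSE],
                  a = unname(a), at = unname(at), f = unname(f), L = L)
  new("Trajectory", time = times, series = series)
}

#' @describeIn Trajectory Time grid (s).
#' @param traj a \code{Trajectory}.
#' @export
trajTimes <- function(traj) traj@time

#' @describeIn Trajectory Channel names.
#' @export
trajChannels <- function(traj) colnames(traj@series)

#' @describeIn Trajectory Extract one channel as a numeric vector.
#' @param channel channel name.
#' @export
trajChannel <- function(traj, channel) {
  if (!channel %in% colnames(traj@series))
    stop("unknown channel '", channel, "'", call. = FALSE)
  traj@series[, channel]
}

#' Convert a trajectory to a data.frame
#'
#' @param x a \code{\link{Trajectory}}.
#' @param row.names,optional unused, for S3 compatibility.
#' @param format "wide" (one column per channel) or "long" (tidy:
#'   t_s, channel, value).
#' @param ... ignored.
#' @return a data.frame.
#' @export
as.data.frame.Trajectory <- function(x, row.names = NULL, optional = FALSE,
                                     format = c("wide", "long"), ...) {
  format <- match.arg(format)
  wide <- data.frame(t_s = x@time, x@series, check.names = FALSE)
  if (format == "wide") return(wide)
  ch <- colnames(x@series)
  data.frame(t_s = rep(x@time, times = length(ch)),
             channel = rep(ch, each = length(x@time)),
             value = as.vector(x@series))
}

#' Write a trajectory to CSV
#'
#' @param traj a \code{\link{Trajectory}}.
#' @param path output file.
#' @param format "wide" or "long" (tidy).
#' @return \code{path}, invisibly.
#' @export
writeTrajectory <- function(traj, path, format = c("wide", "long")) {
  utils::write.csv(as.data.frame(traj, format = match.arg(format)), path,
                   row.names = FALSE)
  invisible(path)
}

setMethod("show", "ReceptorClusterParams", function(object) {
  cat(sprintf(
    "MWC receptor cluster: N = %g, alpha = %g kT, m0 = %g, K_I = %g uM, K_A = %g uM\n",
    object@N, object@alpha, object@m0, object@K_I, object@K_A))
})

setMethod("show", "ChemotaxisModel", function(object) {
  cat(sprintf("ChemotaxisModel variant %s (%s activity)\n", object@variant,
              if (object@activity == "log") "log-regime" else "exact MWC"))
  cat(sprintf("  membrane:    N = %g, K_I = %g, K_A = %g uM\n",
              object@membrane@N, object@membrane@K_I, object@membrane@K_A))
  cat(sprintf("  cytoplasmic: N = %g, K_I = %g, K_A = %g uM\n",
              object@cytoplasmic@N, object@cytoplasmic@K_I,
              object@cytoplasmic@K_A))
  if (object@variant == "II")
    cat(sprintf("  internal-ligand lag: tau = %g s\n", object@tauLt))
  cat(sprintf("  mutations:   %s\n",
              if (length(object@mutations)) paste(object@mutations, collapse = ", ")
              else "none"))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d time points over [%g, %g] s, channels: %s\n",
              length(object@time), min(object@time), max(object@time),
              paste(colnames(object@series), collapse = ", ")))
})

setMethod("show", "FCDVerdict", function(object) {
  cat(sprintf("FCD verdict on '%s': discrepancy %.3e (tol %.1e) -> %s\n",
              object@observable, object@discrepancy, object@tol,
              if (object@isFCD) "FCD" else "no FCD"))
})
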