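.FIT_PARAMS <- c("methylation.kR", "methylation.kRt", "methylation.kB1",
                 "methylation.kB2", "methylation.kB2t", "flagellar.q")

#' Root-mean-squared error between model output and a trace
#'
#' @param pred model flagellar frequency evaluated at the trace sample
#'   times (Hz).
#' @param obs observed frequencies (Hz).
#' @return RMSE (Hz).
#' @export
rmseTrace <- function(pred, obs) {
  if (!length(obs)) stop("empty trace", call. = FALSE)
  stopifnot(length(pred) == length(obs))
  sqrt(mean((pred - obs)^2))
}

#' Parameter-fitting problem
#'
#' Fits the six free kinetic parameters of the pathway -- the
#' methylation rates kR, kRt, the demethylation rates kB1, kB2, kB2t
#' and the flagellar half-effect scale q -- to a tethered-cell trace.
#' The free-energy sensitivities alpha and the offsets m0 are fixed (a
#' scaling of alpha is exactly compensated by rescaling the k sets, so
#' it is not identifiable from output data; see
#' \code{\link{alphaScalingCheck}}).
#'
#' @slot trace data.frame(t_s, f_hz).
#' @slot schedule the \code{\link{LigandProgram}} under which the trace
#'   was recorded.
#' @slot model template \code{\link{ChemotaxisModel}} carrying the
#'   variant and all fixed parameters.
#' @slot lower,upper named numeric box bounds for the six free
#'   parameters.
#' @slot seed integer(1) RNG seed.
#' @slot nSA integer(1), simulated-annealing iterations.
#' @slot T0,TEnd numeric(1), initial and final annealing temperatures
#'   (in RMSE units, Hz).
#' @slot stepScale numeric(1), proposal standard deviation as a
#'   fraction of each log-bound width.
#' @slot polish logical(1), run the Levenberg-Marquardt basin-hopping
#'   refinement from the annealing optimum.
#' @slot nHops integer(1), number of perturb-and-repolish restarts
#'   (the fitting surface is multimodal: compensating methylation /
#'   demethylation rate combinations create secondary minima).
#' @slot hopSd numeric(1), hop standard deviation as a fraction of each
#'   log-bound width.
#' @exportClass FitProblem
setClass("FitProblem",
  representation(trace = "data.frame", schedule = "LigandProgram",
                 model = "ChemotaxisModel", lower = "numeric",
                 upper = "numeric", seed = "integer", nSA = "integer",
                 T0 = "numeric", TEnd = "numeric", stepScale = "numeric",
                 polish = "logical", nHops = "integer", hopSd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(c("t_s", "f_hz") %in% names(object@trace)) ||
        !nrow(object@trace))
      msg <- c(msg, "'trace' must be a non-empty data.frame(t_s, f_hz)")
    if (!identical(names(object@lower), .FIT_PARAMS) ||
        !identical(names(object@upper), .FIT_PARAMS))
      msg <- c(msg, "bounds must be named after the six free parameters")
    else if (any(!is.finite(c(object@lower, object@upper))) ||
             any(object@lower <= 0) || any(object@upper <= object@lower))
      msg <- c(msg, "bounds must satisfy 0 < lower < upper (finite)")
    if (length(msg)) msg else TRUE
  })

#' @describeIn FitProblem Constructor.
#' @param trace,schedule,model,seed,nSA,T0,TEnd,stepScale,polish,nHops,hopSd
#'   see slots.
#' @param lower,upper named (partial) overrides of the default bounds
#'   (rates in [1e-3, 1] 1/s or 1/(uM s); q in [1, 500]).
#' @export
fitProblem <- function(trace, schedule = ligandProgram(),
                       model = chemotaxisModel("I"),
                       lower = NULL, upper = NULL, seed = 1L, nSA = 500L,
                       T0 = 0.5, TEnd = 1e-3, stepScale = 0.08,
                       polish = TRUE, nHops = 10L, hopSd = 0.1) {
  lo <- c(1e-3, 1e-3, 1e-3, 1e-3, 1e-3, 1)
  hi <- c(1, 1, 1, 1, 1, 500)
  names(lo) <- names(hi) <- .FIT_PARAMS
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  # tight integrator tolerances keep finite-difference Jacobians of the
  # objective above the solver-noise floor during the polish
  model@solver$rtol <- min(model@solver$rtol, 1e-10)
  model@solver$atol <- min(model@solver$atol, 1e-12)
  new("FitProblem", trace = trace, schedule = schedule,
      model = setActivityForm(model, "exact"), lower = lo, upper = hi,
      seed = as.integer(seed), nSA = as.integer(nSA), T0 = as.numeric(T0),
      TEnd = as.numeric(TEnd), stepScale = as.numeric(stepScale),
      polish = polish, nHops = as.integer(nHops), hopSd = as.numeric(hopSd))
}

#' Fit result
#'
#' @slot estimates named numeric, fitted values of the six free
#'   parameters.
#' @slot rmse numeric(1), RMSE (Hz) at the optimum.
#' @slot objectiveTrace numeric, best-so-far objective per annealing
#'   iteration (non-increasing).
#' @slot seed integer(1).
#' @slot nEval integer(1), total number of objective evaluations.
#' @exportClass FitResult
setClass("FitResult",
  representation(estimates = "numeric", rmse = "numeric",
                 objectiveTrace = "numeric", seed = "integer",
                 nEval = "integer"),
  validity = function(object) {
    if (object@rmse < 0) "'rmse' must be >= 0"
    else if (is.unsorted(-object@objectiveTrace))
      "'objectiveTrace' must be non-increasing (best-so-far)"
    else TRUE
  })

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: RMSE %.4g Hz after %d evaluations (seed %d)\n",
              object@rmse, object@nEval, object@seed))
  print(signif(object@estimates, 4))
})

# Apply a named parameter vector (on the natural scale) to the template.
.applyFitParams <- function(model, theta) {
  for (p in names(theta)) model <- .setModelParam(model, p, theta[[p]])
  model
}

# Residual vector (pred - obs) in log-parameter space, for the
# Levenberg-Marquardt polish; failures yield a large constant residual.
.makeResiduals <- function(problem) {
  cache <- new.env(parent = emptyenv())
  cache$ss <- NULL
  L0 <- problem@schedule@levels[1L]
  tt <- problem@trace$t_s
  obs <- problem@trace$f_hz
  function(z) {
    th <- exp(z); names(th) <- .FIT_PARAMS
    m <- .applyFitParams(problem@model, th)
    .quietly(tryCatch({
      ss <- tryCatch(
        if (!is.null(cache$ss))
          steadyState(m, L0, preEquilibrate = 300, init = cache$ss)
        else stop("cold"),
        error = function(e) steadyState(m, L0))
      cache$ss <- ss
      tr <- simulateTrajectory(m, problem@schedule, tt, init = ss)
      trajChannel(tr, "f") - obs
    }, error = function(e) rep(1e3, length(obs))))
  }
}

# Swallow the integrator's console diagnostics for hostile candidate
# parameter sets explored by the global search.
.quietly <- function(expr) {
  tc <- textConnection(NULL, "w", local = TRUE)
  sink(tc)
  on.exit({ sink(); close(tc) })
  expr
}

# Objective closure with a warm-started steady-state cache.
.makeObjective <- function(problem) {
  cache <- new.env(parent = emptyenv())
  cache$ss <- NULL
  cache$n <- 0L
  L0 <- problem@schedule@levels[1L]
  tt <- problem@trace$t_s
  obs <- problem@trace$f_hz
  function(theta) {
    cache$n <- cache$n + 1L
    m <- .applyFitParams(problem@model, theta)
    val <- .quietly(tryCatch({
      ss <- tryCatch(
        if (!is.null(cache$ss))
          steadyState(m, L0, preEquilibrate = 300, init = cache$ss)
        else stop("cold"),
        error = function(e) steadyState(m, L0))
      cache$ss <- ss
      tr <- simulateTrajectory(m, problem@schedule, tt, init = ss)
      rmseTrace(trajChannel(tr, "f"), obs)
    }, error = function(e) NA_real_))
    if (!is.finite(val)) 1e6 else val
  }
}

#' Fit the six free parameters to a trace
#'
#' Seeded simulated annealing in log-parameter space within the box
#' bounds (Gaussian proposals with temperature-scaled width, reflected
#' at the bounds, Metropolis acceptance, geometric cooling), followed
#' by an optional L-BFGS-B polish from the annealing optimum.  The
#' objective is the RMSE between the simulated and observed flagellar
#' frequency; each candidate is simulated from its own adapted state.
#' Deterministic for a fixed seed.
#'
#' @param problem a \code{\link{FitProblem}}.
#' @return a \code{\link{FitResult}}.
#' @export
fitTrace <- function(problem) {
  stopifnot(is(problem, "FitProblem"))
  obj <- .makeObjective(problem)
  lo <- log(problem@lower); hi <- log(problem@upper)
  width <- hi - lo
  reflect <- function(z) {
    # reflect into [lo, hi] coordinate-wise
    for (j in seq_along(z)) {
      while (z[j] < lo[j] || z[j] > hi[j]) {
        if (z[j] < lo[j]) z[j] <- 2 * lo[j] - z[j]
        if (z[j] > hi[j]) z[j] <- 2 * hi[j] - z[j]
      }
    }
    z
  }
  evalz <- function(z) {
    th <- exp(z); names(th) <- .FIT_PARAMS
    obj(th)
  }
  oldseed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv))
  set.seed(problem@seed)
  z <- (lo + hi) / 2
  fz <- evalz(z)
  best <- z; fbest <- fz
  btrace <- numeric(problem@nSA)
  cool <- (problem@TEnd / problem@T0)^(1 / max(1L, problem@nSA - 1L))
  Temp <- problem@T0
  for (i in seq_len(problem@nSA)) {
    sdv <- problem@stepScale * width * sqrt(Temp / problem@T0)
    zn <- reflect(z + stats::rnorm(length(z), sd = sdv))
    fn <- evalz(zn)
    if (fn < fz || stats::runif(1) < exp(-(fn - fz) / Temp)) {
      z <- zn; fz <- fn
      if (fn < fbest) { best <- zn; fbest <- fn }
    }
    btrace[i] <- fbest
    Temp <- Temp * cool
  }
  nEvalSA <- problem@nSA + 1L
  if (problem@polish) {
    # Levenberg-Marquardt on the residual vector: far better conditioned
    # than generic quasi-Newton along the shallow kB1/kB2 trade-off ridge.
    # The surface is multimodal (compensating rate combinations), so the
    # polish is restarted from seeded perturbations of the incumbent.
    residFun <- .makeResiduals(problem)
    nres <- new.env(parent = emptyenv()); nres$n <- 0L
    rf <- function(z) { nres$n <- nres$n + 1L; residFun(z) }
    lmFrom <- function(z) tryCatch(
      minpack.lm::nls.lm(par = z, lower = lo, upper = hi, fn = rf,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 150, ftol = 1e-14, ptol = 1e-12,
                           epsfcn = 1e-8)),
      error = function(e) NULL)
    takeIfBetter <- function(lm) {
      if (!is.null(lm)) {
        flm <- sqrt(mean(lm$fvec^2))
        if (flm < fbest) { best <<- lm$par; fbest <<- flm }
      }
    }
    takeIfBetter(lmFrom(best))
    for (k in seq_len(problem@nHops)) {
      z0 <- reflect(best + stats::rnorm(length(best),
                                        sd = problem@hopSd * width))
      takeIfBetter(lmFrom(z0))
    }
    nEvalSA <- nEvalSA + nres$n
  }
  est <- exp(best); names(est) <- .FIT_PARAMS
  new("FitResult", estimates = est, rmse = fbest,
      objectiveTrace = btrace, seed = problem@seed,
      nEval = as.integer(nEvalSA))
}

#' Per-parameter identifiability profiles
#'
#' Profiles the objective along each fitted parameter (the others held
#' at their estimates) over a multiplicative span around the estimate,
#' and flags parameters whose objective varies less than \code{flatTol}
#' across the inner +/-10 percent window as practically degenerate.
#'
#' @param problem the \code{\link{FitProblem}} that was fitted.
#' @param result the corresponding \code{\link{FitResult}}.
#' @param span half-width of the profiled multiplicative range
#'   (default 0.15, i.e. 85--115 percent of the estimate).
#' @param nGrid grid points per parameter.
#' @param flatTol objective-variation threshold (Hz) under which a
#'   parameter is flagged degenerate.
#' @return data.frame(param, estimate, obj_min, obj_range_10pct,
#'   degenerate) with attribute \code{"profiles"} (a list of
#'   data.frames value/objective).
#' @export
degeneracyReport <- function(problem, result, span = 0.15, nGrid = 7L,
                             flatTol = 1e-4) {
  stopifnot(is(problem, "FitProblem"), is(result, "FitResult"))
  obj <- .makeObjective(problem)
  est <- result@estimates
  profiles <- list()
  rows <- lapply(.FIT_PARAMS, function(p) {
    fac <- seq(1 - span, 1 + span, length.out = nGrid)
    vals <- est[[p]] * fac
    o <- vapply(vals, function(v) {
      th <- est; th[[p]] <- v
      obj(th)
    }, numeric(1))
    profiles[[p]] <<- data.frame(value = vals, objective = o)
    inner <- abs(fac - 1) <= 0.10 + 1e-12
    data.frame(param = p, estimate = est[[p]], obj_min = min(o),
               obj_range_10pct = diff(range(o[inner])),
               degenerate = diff(range(o[inner])) < flatTol)
  })
  out <- do.call(rbind, rows)
  attr(out, "profiles") <- profiles
  out
}

#' Verify the alpha-scaling degeneracy
#'
#' The methylation sensitivity alpha is not identifiable from output
#' data: scaling alpha (and alphatilde) by a factor eps while dividing
#' the methylation/demethylation rate sets (kR, kB1, kB2) and
#' (kRt, kB2t) by eps leaves the simulated flagellar output unchanged
#' (the methylation coordinate absorbs the change of variables).  This
#' function simulates both parameterizations and returns the sup-norm
#' difference of f(t), expected at solver accuracy.
#'
#' @param model a \code{\link{ChemotaxisModel}}.
#' @param eps positive scale factor for alpha.
#' @param program a \code{\link{LigandProgram}}.
#' @param times output grid (s).
#' @return sup-norm difference of the two flagellar outputs (Hz).
#' @export
alphaScalingCheck <- function(model, eps = 2,
                              program = ligandProgram(),
                              times = seq(0, 600, by = 1)) {
  stopifnot(eps > 0)
  tr1 <- simulateTrajectory(model, program, times)
  m2 <- model
  for (cl in c("membrane", "cytoplasmic")) {
    rp <- slot(m2, cl); rp@alpha <- rp@alpha * eps; slot(m2, cl) <- rp
  }
  me <- m2@methylation
  me@kR <- me@kR / eps; me@kB1 <- me@kB1 / eps; me@kB2 <- me@kB2 / eps
  me@kRt <- me@kRt / eps; me@kB2t <- me@kB2t / eps
  m2@methylation <- me
  tr2 <- simulateTrajectory(m2, program, times)
  max(abs(trajChannel(tr1, "f") - trajChannel(tr2, "f")))
}
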