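#' Ligand-induced free-energy difference
#'
#' Change in the free-energy difference between the inactive and active
#' receptor conformations caused by ligand binding,
#' gL(L) = ln((1 + L/K_I) / (1 + L/K_A)), in kT.  Because ligand binds
#' inactive receptors more tightly (K_A > K_I), gL is strictly
#' increasing in L, with gL(0) = 0 and gL -> ln(K_A/K_I) as L -> Inf.
#'
#' @param L ligand concentration(s), uM, >= 0.
#' @param params a \code{\link{ReceptorClusterParams}}.
#' @return dimensionless energy (kT), same length as \code{L}.
#' @examples
#' ligandFreeEnergy(100, receptorParams())
#' @export
ligandFreeEnergy <- function(L, params) {
  stopifnot(is(params, "ReceptorClusterParams"))
  if (any(!is.finite(L)) || any(L < 0))
    stop("'L' must be finite and >= 0", call. = FALSE)
  log1p(L / params@K_I) - log1p(L / params@K_A)
}

#' MWC receptor activity, exact Boltzmann form
#'
#' Probability that a receptor cluster is active: the ratio of the
#' Boltzmann factor of the active state to the sum over both states,
#' a = 1 / (1 + exp(N * (gL(L) - alpha * (m - m0)))).  Methylation
#' lowers the active-state free energy, so activity increases with m
#' and decreases with L.
#'
#' @param m average methylation level (methylation units; unbounded).
#' @param L ligand concentration, uM, >= 0.
#' @param params a \code{\link{ReceptorClusterParams}}.
#' @return activity in (0, 1); vectorized over \code{m} and \code{L}.
#' @examples
#' activityExact(m = 5, L = 0, receptorParams())   # 0.5 at the bias point
#' @export
activityExact <- function(m, L, params) {
  gL <- ligandFreeEnergy(L, params)
  plogis(-params@N * (gL - params@alpha * (m - params@m0)))
}

#' MWC receptor activity, log-regime approximation
#'
#' In the ligand range K_I << L << K_A the free-energy term gL(L) is
#' approximated by ln(L / K_I), giving
#' a = 1 / (1 + exp(N * (ln(L/K_I) - alpha * (m - m0)))).  Under this
#' approximation the activity is exactly invariant under the joint
#' scaling (L, m) -> (p L, m + ln(p)/alpha), the algebraic root of
#' fold-change detection.
#'
#' @inheritParams activityExact
#' @return activity in (0, 1).
#' @seealso \code{\link{fcdMethylationShift}}
#' @export
activityLogRegime <- function(m, L, params) {
  stopifnot(is(params, "ReceptorClusterParams"))
  if (any(!is.finite(L)) || any(L <= 0))
    stop("'L' must be > 0 in the log-regime approximation ",
         "(use activityExact for stimuli that include L = 0)", call. = FALSE)
  plogis(-params@N * (log(L / params@K_I) - params@alpha * (m - params@m0)))
}

#' Methylation shift absorbing an input scaling
#'
#' The translation Delta m = ln(p)/alpha of the methylation coordinate
#' that exactly absorbs a scaling of the ligand input by p > 0 under the
#' log-regime activity.  Shifts compose additively:
#' shift(p1) + shift(p2) = shift(p1 * p2).
#'
#' @param p input scale factor, > 0.
#' @param alpha free-energy sensitivity (kT per methylation unit), > 0.
#' @return methylation offset (methylation units).
#' @examples
#' fcdMethylationShift(5, 2)   # log(5)/2
#' @export
fcdMethylationShift <- function(p, alpha) {
  if (any(!is.finite(p)) || any(p <= 0))
    stop("'p' must be finite and > 0", call. = FALSE)
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("'alpha' must be finite and > 0", call. = FALSE)
  log(p) / alpha
}
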