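#' Model I internal-ligand map
#'
#' Static map conveying external ligand to the cytoplasmic cluster with
#' attenuation by the phosphorylated CheY3/CheY4 feedback:
#' Ltilde = 10 L / (10 + Y3p + Y4p).  It reduces to the identity when
#' Y3p = Y4p = 0 and is bounded below by 10 L / (10 + Y3tot + Y4tot),
#' which sets the worst-case attenuation factor of the fold-change
#' detection range (2.64 at the measured totals 3.2 and 13.2 uM).
#'
#' @param L external ligand (uM, >= 0).
#' @param Y3p,Y4p phosphorylated CheY3/CheY4 (uM, >= 0).
#' @return internal ligand concentration (uM).
#' @export
internalLigandModelI <- function(L, Y3p, Y4p) {
  if (any(c(L, Y3p, Y4p) < 0)) stop("inputs must be >= 0", call. = FALSE)
  10 * L / (10 + Y3p + Y4p)
}

#' Model II internal-ligand filter right-hand side
#'
#' First-order lag dLtilde/dt = (L - Ltilde) / tauLt, the minimal stable
#' positive linear time-invariant filter.  For a step L_a -> L_b started
#' at Ltilde = L_a the trajectory stays in [min(L_a, L_b), max(L_a, L_b))
#' and converges to L exponentially; scaling both L and Ltilde(0) by p
#' scales the whole trajectory by p (linearity).
#'
#' @param Lt current internal ligand (uM).
#' @param L external ligand (uM).
#' @param tauLt filter time constant (s), > 0.
#' @return dLtilde/dt (uM/s).
#' @export
internalLigandLagRHS <- function(Lt, L, tauLt) {
  if (!is.finite(tauLt) || tauLt <= 0)
    stop("'tauLt' must be finite and > 0", call. = FALSE)
  (L - Lt) / tauLt
}

#' CheB demethylation wiring of a model variant
#'
#' Models I and II use the asymmetric wiring in which CheB2-P
#' demethylates both clusters and CheB1-P only the membrane cluster;
#' model III assigns CheB1-P to the membrane and CheB2-P to the
#' cytoplasmic cluster only.
#'
#' @param variant "I", "II" or "III".
#' @return list with logical entries \code{memB1}, \code{memB2},
#'   \code{cytB2}: which CheB-P species demethylate which cluster.
#' @export
demethConnectivity <- function(variant) {
  variant <- match.arg(variant, c("I", "II", "III"))
  list(memB1 = TRUE, memB2 = variant != "III", cytB2 = TRUE)
}

#' Methylation right-hand side
#'
#' Integral-feedback methylation kinetics: CheR methylates only
#' inactive receptors at saturation, phosphorylated CheB demethylates
#' only active receptors,
#' dm/dt = kR (1 - a) - (demethylation rate) a, and analogously for the
#' cytoplasmic cluster.  Crucially, neither expression depends
#' explicitly on m or mtilde; this is the structural requirement for
#' exact adaptation and fold-change detection.
#'
#' @param a,at membrane/cytoplasmic activities in (0, 1).
#' @param B1p,B2p phosphorylated CheB concentrations (uM, >= 0).
#' @param params a \code{\link{MethylationParams}}.
#' @param connectivity a wiring list as returned by
#'   \code{\link{demethConnectivity}}.
#' @return numeric c(dm, dmt) (methylation units / s).
#' @export
methylationRHS <- function(a, at, B1p, B2p, params,
                           connectivity = demethConnectivity("I")) {
  stopifnot(is(params, "MethylationParams"))
  demMem <- (if (connectivity$memB1) params@kB1 * B1p else 0) +
            (if (connectivity$memB2) params@kB2 * B2p else 0)
  demCyt <- if (connectivity$cytB2) params@kB2t * B2p else 0
  c(dm = params@kR * (1 - a) - demMem * a,
    dmt = params@kRt * (1 - at) - demCyt * at)
}

#' Phosphotransfer-network right-hand side
#'
#' Mass-action kinetics of the CheA autophosphorylation (gated by the
#' receptor activities) and the competing phosphotransfer to the CheY
#' and CheB proteins, with first-order auto-dephosphorylation.  Every
#' phosphoryl group leaving a donor arrives at exactly one acceptor, so
#' the total phospho pool changes only through autophosphorylation and
#' dephosphorylation.
#'
#' @param x named numeric state c(A2p, A34p, Y3p, Y4p, Y6p, B1p, B2p)
#'   (uM), each within [0, total].
#' @param a,at membrane/cytoplasmic activities in (0, 1).
#' @param params a \code{\link{PhosphoNetworkParams}}.
#' @param totals optional named totals overriding \code{params@totals}
#'   (used to apply gene deletions).
#' @return named derivative vector (uM/s) with attribute
#'   \code{"fluxes"} = c(auto, dephos): total autophosphorylation inflow
#'   and dephosphorylation outflow, for bookkeeping checks.
#' @export
phosphoRHS <- function(x, a, at, params, totals = params@totals) {
  stopifnot(is(params, "PhosphoNetworkParams"))
  if (any(x < -1e-9) || any(x > totals[.PHOSPHO_SPECIES] + 1e-9))
    stop("phospho state outside [0, total]", call. = FALSE)
  A2p <- x[["A2p"]]; A34p <- x[["A34p"]]
  pfree <- totals[.A2_ACCEPTORS] -
    c(x[["Y3p"]], x[["Y4p"]], x[["Y6p"]], x[["B1p"]], x[["B2p"]])
  t2 <- params@kTransA2 * pfree                      # per-uM-donor fluxes
  t34 <- params@kTransA34 * pfree[.A34_ACCEPTORS]
  autoA2 <- params@kAutoA2 * a * (totals[["A2"]] - A2p)
  autoA34 <- params@kAutoA34 * at * (totals[["A34"]] - A34p)
  inflow <- A2p * t2
  inflow[.A34_ACCEPTORS] <- inflow[.A34_ACCEPTORS] + A34p * t34
  deph <- params@kDephos *
    c(x[["Y3p"]], x[["Y4p"]], x[["Y6p"]], x[["B1p"]], x[["B2p"]])
  d <- c(A2p = autoA2 - sum(A2p * t2),
         A34p = autoA34 - sum(A34p * t34),
         Y3p = inflow[["Y3"]] - deph[["Y3"]],
         Y4p = inflow[["Y4"]] - deph[["Y4"]],
         Y6p = inflow[["Y6"]] - deph[["Y6"]],
         B1p = inflow[["B1"]] - deph[["B1"]],
         B2p = inflow[["B2"]] - deph[["B2"]])
  attr(d, "fluxes") <- c(auto = autoA2 + autoA34, dephos = sum(deph))
  d
}

#' Flagellar rotation frequency
#'
#' Hill-type output of the tethered flagellum,
#' f = fMax / (1 + (V/q)^hillN) with V = Y6p (Y3p + Y4p).  The product
#' form realizes the AND gate observed experimentally: rotation is
#' inhibited only when CheY6-P and at least one of CheY3-P/CheY4-P are
#' present, and f = fMax whenever either factor vanishes.
#'
#' @param Y3p,Y4p,Y6p phosphorylated CheY concentrations (uM, >= 0).
#' @param params a \code{\link{FlagellarParams}}.
#' @return rotation frequency (Hz) in (0, fMax].
#' @examples
#' flagellarFrequency(0, 0, 0, flagellarParams())   # fMax = 8 Hz
#' @export
flagellarFrequency <- function(Y3p, Y4p, Y6p, params = flagellarParams()) {
  stopifnot(is(params, "FlagellarParams"))
  if (any(c(Y3p, Y4p, Y6p) < 0)) stop("inputs must be >= 0", call. = FALSE)
  V <- abs(Y6p * (Y3p + Y4p))
  params@fMax / (1 + (V / params@q)^params@hillN)
}

#' Totals after applying the model's mutations
#'
#' Gene deletions zero the corresponding protein total (cheA2_del,
#' cheA3_del, cheB2_del); cheY4_5x multiplies the CheY4 total by five.
#'
#' @param model a \code{\link{ChemotaxisModel}}.
#' @return named numeric vector of effective totals (uM).
#' @export
effectiveTotals <- function(model) {
  stopifnot(is(model, "ChemotaxisModel"))
  tot <- model@phospho@totals
  if ("cheA2_del" %in% model@mutations) tot[["A2"]] <- 0
  if ("cheA3_del" %in% model@mutations) tot[["A34"]] <- 0
  if ("cheB2_del" %in% model@mutations) tot[["B2"]] <- 0
  if ("cheY4_5x" %in% model@mutations) tot[["Y4"]] <- 5 * tot[["Y4"]]
  tot
}

#' Add a mutation to a model
#'
#' @param model a \code{\link{ChemotaxisModel}}.
#' @param mutation one of "cheA2_del", "cheA3_del", "cheB2_del",
#'   "cheY4_5x".
#' @return the modified model.
#' @export
addMutation <- function(model, mutation) {
  mutation <- match.arg(mutation, .MUTATIONS, several.ok = TRUE)
  model@mutations <- unique(c(model@mutations, mutation))
  validObject(model)
  model
}

#' Switch the receptor-activity form used in the closed loop
#'
#' @param model a \code{\link{ChemotaxisModel}}.
#' @param activity "exact" or "log".
#' @return the modified model.
#' @export
setActivityForm <- function(model, activity = c("exact", "log")) {
  model@activity <- match.arg(activity)
  model
}

#' Which clusters have lost all demethylation feedback
#'
#' A cluster whose every demethylase has been deleted can no longer
#' adapt: its methylation level drifts (logarithmically) instead of
#' settling, as for the cytoplasmic cluster under cheB2_del.
#'
#' @param model a \code{\link{ChemotaxisModel}}.
#' @return logical c(membrane, cytoplasmic): TRUE where adaptation is
#'   structurally lost.
#' @export
lostAdaptation <- function(model) {
  conn <- demethConnectivity(model@variant)
  tot <- effectiveTotals(model)
  me <- model@methylation
  # a demethylase contributes only if present (total > 0), active
  # (rate > 0) and phosphorylatable: CheB1 receives phosphoryl groups
  # from CheA2 only, CheB2 from both kinases
  b1Alive <- tot[["B1"]] > 0 && tot[["A2"]] > 0 &&
    model@phospho@kTransA2[["B1"]] > 0
  b2Alive <- tot[["B2"]] > 0 &&
    ((tot[["A2"]] > 0 && model@phospho@kTransA2[["B2"]] > 0) ||
     (tot[["A34"]] > 0 && model@phospho@kTransA34[["B2"]] > 0))
  mem <- (if (conn$memB1 && b1Alive) me@kB1 else 0) +
         (if (conn$memB2 && b2Alive) me@kB2 else 0)
  cyt <- if (conn$cytB2 && b2Alive) me@kB2t else 0
  c(membrane = mem <= 0, cytoplasmic = cyt <= 0)
}

#' Lower-bound factor of the fold-change-detection ligand range
#'
#' The FCD range of the cytoplasmic cluster is
#' Ktilde_I << Ltilde << Ktilde_A.  Expressed in terms of the external
#' ligand L, the lower bound is multiplied by the worst-case attenuation
#' max(L / Ltilde) of the variant's internal-ligand map: for model I
#' this is (10 + Y3tot + Y4tot)/10 (2.64 at the wild-type totals,
#' 7.92 under fivefold CheY4 overexpression); models II and III convey
#' L undiminished, so the factor is 1.
#'
#' @param model a \code{\link{ChemotaxisModel}}.
#' @return dimensionless factor >= 1.
#' @export
fcdBoundFactor <- function(model) {
  stopifnot(is(model, "ChemotaxisModel"))
  if (model@variant != "I") return(1)
  tot <- effectiveTotals(model)
  (10 + tot[["Y3"]] + tot[["Y4"]]) / 10
}

# Flatten a model into plain numerics for the integrator hot path.
.compileModel <- function(model) {
  stopifnot(is(model, "ChemotaxisModel"))
  conn <- demethConnectivity(model@variant)
  tot <- effectiveTotals(model)
  mem <- model@membrane; cyt <- model@cytoplasmic
  me <- model@methylation
  list(variant = model@variant,
       logAct = model@activity == "log",
       Nm = mem@N, am = mem@alpha, m0m = mem@m0, KIm = mem@K_I, KAm = mem@K_A,
       Nc = cyt@N, ac = cyt@alpha, m0c = cyt@m0, KIc = cyt@K_I, KAc = cyt@K_A,
       tot = unname(tot),                        # A2 A34 Y3 Y4 Y6 B1 B2
       kAutoA2 = model@phospho@kAutoA2, kAutoA34 = model@phospho@kAutoA34,
       kt2 = unname(model@phospho@kTransA2),     # Y3 Y4 Y6 B1 B2
       kt34 = unname(model@phospho@kTransA34),   # Y6 B2
       kd = unname(model@phospho@kDephos),       # Y3 Y4 Y6 B1 B2
       kR = me@kR * model@phospho@R2, kRt = me@kRt * model@phospho@R3,
       kB1 = me@kB1, kB2 = me@kB2, kB2t = me@kB2t,
       memB1 = conn$memB1, memB2 = conn$memB2, cytB2 = conn$cytB2,
       tauLt = model@tauLt, mLeak = model@mLeak,
       fMax = model@flagellar@fMax, q = model@flagellar@q,
       hillN = model@flagellar@hillN,
       nState = if (model@variant == "II") 10L else 9L)
}

# State layout: y = (m, mt, [Lt], A2p, A34p, Y3p, Y4p, Y6p, B1p, B2p)
.stateNames <- function(variant) {
  c("m", "mt", if (variant == "II") "Lt",
    "A2p", "A34p", "Y3p", "Y4p", "Y6p", "B1p", "B2p")
}

# Activity from compiled scalars (log-regime or exact Boltzmann form).
.actC <- function(m, L, N, alpha, m0, KI, KA, logAct) {
  g <- if (logAct) log(L / KI) else log1p(L / KI) - log1p(L / KA)
  1 / (1 + exp(N * (g - alpha * (m - m0))))
}

# Closed-loop RHS; L is the (segment-constant) external ligand in pc$L.
.rhsCore <- function(y, pc) {
  m <- y[1L]; mt <- y[2L]
  off <- if (pc$nState == 10L) 3L else 2L
  A2p <- y[off + 1L]; A34p <- y[off + 2L]
  Y3p <- y[off + 3L]; Y4p <- y[off + 4L]; Y6p <- y[off + 5L]
  B1p <- y[off + 6L]; B2p <- y[off + 7L]
  L <- pc$L
  Lt <- switch(pc$variant,
               I = 10 * L / (10 + Y3p + Y4p),
               II = y[3L],
               III = L)
  a <- .actC(m, L, pc$Nm, pc$am, pc$m0m, pc$KIm, pc$KAm, pc$logAct)
  at <- .actC(mt, Lt, pc$Nc, pc$ac, pc$m0c, pc$KIc, pc$KAc, pc$logAct)
  tot <- pc$tot
  pY3 <- tot[3L] - Y3p; pY4 <- tot[4L] - Y4p; pY6 <- tot[5L] - Y6p
  pB1 <- tot[6L] - B1p; pB2 <- tot[7L] - B2p
  kt2 <- pc$kt2; kt34 <- pc$kt34; kd <- pc$kd
  out2 <- kt2[1L] * pY3 + kt2[2L] * pY4 + kt2[3L] * pY6 +
          kt2[4L] * pB1 + kt2[5L] * pB2
  out34 <- kt34[1L] * pY6 + kt34[2L] * pB2
  dA2p <- pc$kAutoA2 * a * (tot[1L] - A2p) - A2p * out2
  dA34p <- pc$kAutoA34 * at * (tot[2L] - A34p) - A34p * out34
  dY3p <- kt2[1L] * A2p * pY3 - kd[1L] * Y3p
  dY4p <- kt2[2L] * A2p * pY4 - kd[2L] * Y4p
  dY6p <- (kt2[3L] * A2p + kt34[1L] * A34p) * pY6 - kd[3L] * Y6p
  dB1p <- kt2[4L] * A2p * pB1 - kd[4L] * B1p
  dB2p <- (kt2[5L] * A2p + kt34[2L] * A34p) * pB2 - kd[5L] * B2p
  demMem <- (if (pc$memB1) pc$kB1 * B1p else 0) +
            (if (pc$memB2) pc$kB2 * B2p else 0)
  dm <- pc$kR * (1 - a) - demMem * a - pc$mLeak * m
  dmt <- pc$kRt * (1 - at) - (if (pc$cytB2) pc$kB2t * B2p else 0) * at
  if (pc$nState == 10L)
    c(dm, dmt, (L - y[3L]) / pc$tauLt, dA2p, dA34p, dY3p, dY4p, dY6p,
      dB1p, dB2p)
  else
    c(dm, dmt, dA2p, dA34p, dY3p, dY4p, dY6p, dB1p, dB2p)
}

.rhsDeSolve <- function(t, y, pc) list(.rhsCore(y, pc))

# Parameter vector for the compiled RHS (see src/rsfcd_rhs.c for layout).
.packParms <- function(pc) {
  c(switch(pc$variant, I = 1, II = 2, III = 3), as.numeric(pc$logAct),
    pc$Nm, pc$am, pc$m0m, pc$KIm, pc$KAm,
    pc$Nc, pc$ac, pc$m0c, pc$KIc, pc$KAc,
    pc$tot, pc$kAutoA2, pc$kAutoA34, pc$kt2, pc$kt34, pc$kd,
    pc$kR, pc$kRt, pc$kB1, pc$kB2, pc$kB2t,
    as.numeric(pc$memB1), as.numeric(pc$memB2), as.numeric(pc$cytB2),
    pc$tauLt, pc$mLeak, pc$L)
}

# lsoda over one constant-ligand segment using the compiled RHS.
.integrateSegment <- function(y, times, pc, rtol, atol, hmax = Inf) {
  deSolve::lsoda(y, times = times, func = "rsfcd_derivs", parms = .packParms(pc),
                 dllname = "rsfcd", initfunc = "rsfcd_initmod",
                 rtol = rtol, atol = atol, hmax = hmax, maxsteps = 10000)
}
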