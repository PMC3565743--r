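#' @import methods
NULL

.PHOSPHO_SPECIES <- c("A2", "A34", "Y3", "Y4", "Y6", "B1", "B2")
.A2_ACCEPTORS <- c("Y3", "Y4", "Y6", "B1", "B2")
.A34_ACCEPTORS <- c("Y6", "B2")
.MUTATIONS <- c("cheA2_del", "cheA3_del", "cheB2_del", "cheY4_5x")

#' MWC receptor-cluster energetics
#'
#' Parameters of one two-state (active/inactive) allosteric receptor
#' cluster: the cooperativity \code{N}, the free-energy sensitivity
#' \code{alpha} (kT per methylation unit), the methylation bias \code{m0}
#' and the ligand dissociation constants of the active (\code{K_A}) and
#' inactive (\code{K_I}) conformations, in micromolar.  Ligand binds the
#' inactive conformation more tightly, so \code{K_A > K_I} is enforced.
#'
#' @slot N numeric(1), receptor cooperativity, > 0.
#' @slot alpha numeric(1), kT per methylation unit, > 0.
#' @slot m0 numeric(1), methylation offset at which the cluster is
#'   half-active in the absence of ligand.
#' @slot K_A,K_I numeric(1), dissociation constants (uM), K_A > K_I > 0.
#' @exportClass ReceptorClusterParams
setClass("ReceptorClusterParams",
  representation(N = "numeric", alpha = "numeric", m0 = "numeric",
                 K_A = "numeric", K_I = "numeric"),
  validity = function(object) {
    msg <- character()
    for (s in c("N", "alpha", "m0", "K_A", "K_I")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v))
        msg <- c(msg, sprintf("'%s' must be a single finite number", s))
    }
    if (!length(msg)) {
      if (object@N <= 0) msg <- c(msg, "'N' must be > 0")
      if (object@alpha <= 0) msg <- c(msg, "'alpha' must be > 0")
      if (!(object@K_A > object@K_I && object@K_I > 0))
        msg <- c(msg, "need K_A > K_I > 0 (ligand binds inactive receptors more tightly)")
    }
    if (length(msg)) msg else TRUE
  })

#' @describeIn ReceptorClusterParams Constructor. Defaults are the
#'   dissociation constants adopted from the E. coli chemotaxis
#'   literature (K_I = 18 uM, K_A = 3 mM) with alpha = 2 kT and m0 = 5.
#' @param N,alpha,m0,K_A,K_I see slots.
#' @export
receptorParams <- function(N = 1, alpha = 2, m0 = 5, K_A = 3000, K_I = 18) {
  new("ReceptorClusterParams", N = as.numeric(N), alpha = as.numeric(alpha),
      m0 = as.numeric(m0), K_A = as.numeric(K_A), K_I = as.numeric(K_I))
}

#' Phosphotransfer-network parameters
#'
#' Totals and mass-action rate constants of the CheA/CheB/CheY
#' phosphotransfer network.  CheY3, CheY4, CheY6, CheB1 and CheB2 compete
#' for phosphoryl groups from CheA2 (gated by membrane-cluster activity),
#' while CheY6 and CheB2 also receive phosphoryl groups from the CheA3A4
#' complex (gated by cytoplasmic-cluster activity).
#'
#' @slot totals named numeric, total concentrations (uM) of
#'   A2, A34, Y3, Y4, Y6, B1, B2.
#' @slot kAutoA2,kAutoA34 numeric(1), activity-gated autophosphorylation
#'   rate constants (1/s).
#' @slot kTransA2 named numeric, phosphotransfer rate constants
#'   (1/(uM s)) for the edges A2 -> {Y3, Y4, Y6, B1, B2}.
#' @slot kTransA34 named numeric, edges A34 -> {Y6, B2}.
#' @slot kDephos named numeric, auto-dephosphorylation rates (1/s) of
#'   Y3, Y4, Y6, B1, B2; the Y6 entry is the rate conventionally
#'   called k10.
#' @slot R2,R3 numeric(1), CheR2/CheR3 concentrations (uM); the
#'   methyltransferases operate at saturation so these act as constant
#'   multipliers of the methylation rates.
#' @exportClass PhosphoNetworkParams
setClass("PhosphoNetworkParams",
  representation(totals = "numeric", kAutoA2 = "numeric", kAutoA34 = "numeric",
                 kTransA2 = "numeric", kTransA34 = "numeric",
                 kDephos = "numeric", R2 = "numeric", R3 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(names(object@totals), .PHOSPHO_SPECIES))
      msg <- c(msg, "'totals' must be named A2, A34, Y3, Y4, Y6, B1, B2")
    if (!identical(names(object@kTransA2), .A2_ACCEPTORS))
      msg <- c(msg, "'kTransA2' must be named Y3, Y4, Y6, B1, B2")
    if (!identical(names(object@kTransA34), .A34_ACCEPTORS))
      msg <- c(msg, "'kTransA34' must be named Y6, B2")
    if (!identical(names(object@kDephos), .A2_ACCEPTORS))
      msg <- c(msg, "'kDephos' must be named Y3, Y4, Y6, B1, B2")
    vals <- c(object@totals, object@kAutoA2, object@kAutoA34, object@kTransA2,
              object@kTransA34, object@kDephos, object@R2, object@R3)
    if (any(!is.finite(vals)) || any(vals < 0))
      msg <- c(msg, "all totals and rate constants must be finite and >= 0")
    if (length(msg)) msg else TRUE
  })

#' @describeIn PhosphoNetworkParams Constructor.  The CheY3 and CheY4
#'   totals default to the measured 3.2 and 13.2 uM; the remaining
#'   totals and rates are package defaults chosen for sub-second
#'   phosphotransfer equilibration (see the methods vignette) and are
#'   fully overridable.
#' @param totals,kAutoA2,kAutoA34,kTransA2,kTransA34,kDephos,R2,R3 see slots;
#'   partial named vectors override the defaults entry-wise.
#' @export
phosphoParams <- function(totals = NULL, kAutoA2 = 10, kAutoA34 = 10,
                          kTransA2 = NULL, kTransA34 = NULL, kDephos = NULL,
                          R2 = 1, R3 = 1) {
  def_tot <- c(A2 = 5, A34 = 5, Y3 = 3.2, Y4 = 13.2, Y6 = 10, B1 = 2, B2 = 2)
  def_t2 <- c(Y3 = 2, Y4 = 2, Y6 = 2, B1 = 2, B2 = 2)
  def_t34 <- c(Y6 = 2, B2 = 2)
  def_kd <- c(Y3 = 5, Y4 = 5, Y6 = 5, B1 = 2, B2 = 2)
  merge_named <- function(def, user, what) {
    if (is.null(user)) return(def)
    user <- unlist(user)
    bad <- setdiff(names(user), names(def))
    if (length(bad))
      stop("unknown ", what, " entr", if (length(bad) > 1) "ies: " else "y: ",
           paste(bad, collapse = ", "), call. = FALSE)
    def[names(user)] <- as.numeric(user)
    def
  }
  new("PhosphoNetworkParams",
      totals = merge_named(def_tot, totals, "totals"),
      kAutoA2 = as.numeric(kAutoA2), kAutoA34 = as.numeric(kAutoA34),
      kTransA2 = merge_named(def_t2, kTransA2, "kTransA2"),
      kTransA34 = merge_named(def_t34, kTransA34, "kTransA34"),
      kDephos = merge_named(def_kd, kDephos, "kDephos"),
      R2 = as.numeric(R2), R3 = as.numeric(R3))
}

#' Methylation/demethylation kinetics
#'
#' Rate constants of the integral-feedback methylation system.  CheR
#' methylates only inactive receptors (at saturation), phosphorylated
#' CheB demethylates only active receptors; which CheB-P species acts on
#' which cluster is decided by the model variant.
#'
#' @slot kR,kRt numeric(1), methylation rate constants (1/s) of the
#'   membrane and cytoplasmic clusters, > 0.
#' @slot kB1,kB2,kB2t numeric(1), demethylation rate constants
#'   (1/(uM s)): CheB1-P and CheB2-P on the membrane cluster, CheB2-P on
#'   the cytoplasmic cluster, > 0.
#' @exportClass MethylationParams
setClass("MethylationParams",
  representation(kR = "numeric", kRt = "numeric", kB1 = "numeric",
                 kB2 = "numeric", kB2t = "numeric"),
  validity = function(object) {
    v <- c(kR = object@kR, kRt = object@kRt, kB1 = object@kB1,
           kB2 = object@kB2, kB2t = object@kB2t)
    if (any(!is.finite(v)) || any(v < 0))
      "all methylation/demethylation rate constants must be finite and >= 0"
    else if (object@kR <= 0 || object@kRt <= 0)
      "methylation rates kR and kRt must be > 0"
    else TRUE
  })

#' @describeIn MethylationParams Constructor (rates in 1/s and 1/(uM s)).
#' @param kR,kRt,kB1,kB2,kB2t see slots.
#' @export
methylationParams <- function(kR = 0.02, kRt = 0.02, kB1 = 0.01,
                              kB2 = 0.01, kB2t = 0.02) {
  new("MethylationParams", kR = as.numeric(kR), kRt = as.numeric(kRt),
      kB1 = as.numeric(kB1), kB2 = as.numeric(kB2), kB2t = as.numeric(kB2t))
}

#' Flagellar Hill output
#'
#' The tethered-flagellum rotation frequency is a decreasing Hill
#' function of the phosphorylated CheY proteins,
#' f = fMax / (1 + (V/q)^hillN) with V = Y6p (Y3p + Y4p): an AND gate
#' that only engages when CheY6-P and at least one of CheY3-P/CheY4-P
#' are present.
#'
#' @slot fMax numeric(1), maximal rotation frequency (Hz); the tethered
#'   flagellum is physically limited to about 8 Hz.
#' @slot q numeric(1), half-effect scale of V (uM^2 since V is a
#'   product of concentrations), > 0.
#' @slot hillN numeric(1), Hill coefficient (default 4).
#' @exportClass FlagellarParams
setClass("FlagellarParams",
  representation(fMax = "numeric", q = "numeric", hillN = "numeric"),
  validity = function(object) {
    v <- c(object@fMax, object@q, object@hillN)
    if (any(!is.finite(v)) || any(v <= 0))
      "'fMax', 'q' and 'hillN' must be finite and > 0"
    else TRUE
  })

#' @describeIn FlagellarParams Constructor.
#' @param fMax,q,hillN see slots.
#' @export
flagellarParams <- function(fMax = 8, q = 12, hillN = 4) {
  new("FlagellarParams", fMax = as.numeric(fMax), q = as.numeric(q),
      hillN = as.numeric(hillN))
}

#' Piecewise-constant ligand stimulus program
#'
#' External ligand concentration L(t) held constant on intervals:
#' level \code{levels[i]} applies on [\code{times[i]}, \code{times[i+1]}),
#' and \code{levels[length(levels)]} from the last breakpoint onward.
#'
#' @slot times numeric, strictly increasing interval start times (s);
#'   times[1] is the start of the program.
#' @slot levels numeric, ligand concentrations (uM, >= 0), same length
#'   as \code{times}.
#' @exportClass LigandProgram
setClass("LigandProgram",
  representation(times = "numeric", levels = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@times) != length(object@levels) || !length(object@times))
      msg <- c(msg, "'times' and 'levels' must have equal positive length")
    if (any(diff(object@times) <= 0))
      msg <- c(msg, "'times' must be strictly increasing")
    if (any(!is.finite(object@levels)) || any(object@levels < 0))
      msg <- c(msg, "'levels' must be finite and >= 0")
    if (length(msg)) msg else TRUE
  })

#' @describeIn LigandProgram Constructor.  The default is the reference
#'   tethered-cell schedule: L = 0 until a step to 100 uM at 245 s and
#'   back to 0 at 375 s.
#' @param times,levels see slots.
#' @export
ligandProgram <- function(times = c(0, 245, 375), levels = c(0, 100, 0)) {
  new("LigandProgram", times = as.numeric(times), levels = as.numeric(levels))
}

#' @describeIn LigandProgram Evaluate L(t) at times \code{t}.
#' @param program a \code{LigandProgram}.
#' @param t numeric vector of times (s).
#' @export
ligandAt <- function(program, t) {
  idx <- findInterval(t, program@times, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  program@levels[idx]
}

#' @describeIn LigandProgram Scale all levels by a factor p > 0
#'   (fold-change-preserving input scaling).
#' @param p positive scale factor.
#' @export
scaleProgram <- function(program, p) {
  stopifnot(is.numeric(p), length(p) == 1L, is.finite(p), p > 0)
  new("LigandProgram", times = program@times, levels = p * program@levels)
}

#' Assembled chemotaxis pathway model
#'
#' Closed-loop model combining the two MWC receptor clusters, the
#' phosphotransfer network, the methylation feedback and the flagellar
#' output.  The \code{variant} selects how external ligand reaches the
#' cytoplasmic cluster and the CheB demethylation wiring:
#' \describe{
#'   \item{I}{static internal-ligand map with CheY3-P/CheY4-P feedback,
#'     Ltilde = 10 L / (10 + Y3p + Y4p); CheB1-P demethylates the
#'     membrane cluster, CheB2-P demethylates both.}
#'   \item{II}{first-order lag dLtilde/dt = (L - Ltilde)/tauLt; same
#'     demethylation wiring as model I.}
#'   \item{III}{static identity map Ltilde = L, no CheY feedback;
#'     CheB1-P demethylates the membrane cluster only, CheB2-P the
#'     cytoplasmic cluster only.}
#' }
#'
#' @slot variant character(1), "I", "II" or "III".
#' @slot membrane,cytoplasmic \code{ReceptorClusterParams}.
#' @slot phospho \code{PhosphoNetworkParams}.
#' @slot methylation \code{MethylationParams}.
#' @slot flagellar \code{FlagellarParams}.
#' @slot tauLt numeric(1), time constant (s) of the model II filter.
#' @slot mutations character, subset of cheA2_del, cheA3_del, cheB2_del,
#'   cheY4_5x.
#' @slot activity character(1), "exact" (full Boltzmann form, valid at
#'   L = 0) or "log" (log-regime approximation, valid for
#'   K_I << L << K_A; gives exact fold-change detection).
#' @slot mLeak numeric(1), strength of an optional explicitly
#'   methylation-dependent leak term -mLeak * m added to dm/dt.  The
#'   default 0 preserves the integral-feedback structure; a positive
#'   value deliberately violates it and serves as the non-FCD negative
#'   control.
#' @slot solver list(rtol, atol, maxStep) passed to the integrator.
#' @exportClass ChemotaxisModel
setClass("ChemotaxisModel",
  representation(variant = "character",
                 membrane = "ReceptorClusterParams",
                 cytoplasmic = "ReceptorClusterParams",
                 phospho = "PhosphoNetworkParams",
                 methylation = "MethylationParams",
                 flagellar = "FlagellarParams",
                 tauLt = "numeric",
                 mutations = "character",
                 activity = "character",
                 mLeak = "numeric",
                 solver = "list"),
  validity = function(object) {
    msg <- character()
    if (!(length(object@variant) == 1L && object@variant %in% c("I", "II", "III")))
      msg <- c(msg, "'variant' must be one of \"I\", \"II\", \"III\"")
    if (!(length(object@activity) == 1L && object@activity %in% c("exact", "log")))
      msg <- c(msg, "'activity' must be \"exact\" or \"log\"")
    bad <- setdiff(object@mutations, .MUTATIONS)
    if (length(bad))
      msg <- c(msg, paste0("unknown mutation(s): ", paste(bad, collapse = ", ")))
    if (!(length(object@tauLt) == 1L && is.finite(object@tauLt) && object@tauLt > 0))
      msg <- c(msg, "'tauLt' must be a single finite number > 0")
    if (!(length(object@mLeak) == 1L && is.finite(object@mLeak) && object@mLeak >= 0))
      msg <- c(msg, "'mLeak' must be a single finite number >= 0")
    need <- c("rtol", "atol", "maxStep")
    if (!all(need %in% names(object@solver)))
      msg <- c(msg, "'solver' must contain rtol, atol, maxStep")
    if (length(msg)) msg else TRUE
  })

#' @describeIn ChemotaxisModel Constructor.  Model III defaults its
#'   receptor cooperativities to N = Ntilde = 17.5; models I and II use
#'   N = Ntilde = 1.
#' @param variant,membrane,cytoplasmic,phospho,methylation,flagellar,tauLt,mutations,activity,mLeak,solver
#'   see slots; \code{NULL} entries take variant-appropriate defaults.
#' @export
chemotaxisModel <- function(variant = c("I", "II", "III"),
                            membrane = NULL, cytoplasmic = NULL,
                            phospho = phosphoParams(),
                            methylation = methylationParams(),
                            flagellar = flagellarParams(),
                            tauLt = 10, mutations = character(),
                            activity = c("exact", "log"), mLeak = 0,
                            solver = list(rtol = 1e-10, atol = 1e-10,
                                          maxStep = Inf)) {
  variant <- match.arg(variant)
  activity <- match.arg(activity)
  defN <- if (variant == "III") 17.5 else 1
  if (is.null(membrane)) membrane <- receptorParams(N = defN)
  if (is.null(cytoplasmic)) cytoplasmic <- receptorParams(N = defN)
  def_solver <- list(rtol = 1e-10, atol = 1e-10, maxStep = Inf)
  def_solver[names(solver)] <- solver
  new("ChemotaxisModel", variant = variant, membrane = membrane,
      cytoplasmic = cytoplasmic, phospho = phospho,
      methylation = methylation, flagellar = flagellar,
      tauLt = as.numeric(tauLt), mutations = unique(as.character(mutations)),
      activity = activity, mLeak = as.numeric(mLeak), solver = def_solver)
}

#' Simulated pathway trajectory
#'
#' Time grid plus named channels: methylation levels (m, mt), internal
#' ligand (Lt, uM), activities (a, at, probabilities), phosphorylated
#' protein concentrations (A2p ... B2p, uM), external ligand (L, uM)
#' and flagellar frequency (f, Hz).
#'
#' @slot time numeric, time grid (s).
#' @slot series matrix, one column per channel.
#' @exportClass Trajectory
setClass("Trajectory",
  representation(time = "numeric", series = "matrix"),
  validity = function(object) {
    if (nrow(object@series) != length(object@time))
      "nrow(series) must equal length(time)"
    else if (is.null(colnames(object@series)))
      "series must have column names"
    else TRUE
  })

#' Fold-change-detection verdict
#'
#' Result of comparing the responses to two scaled stimuli on one
#' observable: the normalized sup-norm discrepancy, the threshold and
#' the boolean verdict (is_fcd iff discrepancy <= tol).
#'
#' @slot observable character(1), channel name compared.
#' @slot discrepancy numeric(1), sup-norm difference divided by the
#'   peak-to-peak range of the first response (absolute sup-norm if the
#'   first response is flat).
#' @slot tol numeric(1), threshold.
#' @slot isFCD logical(1).
#' @exportClass FCDVerdict
setClass("FCDVerdict",
  representation(observable = "character", discrepancy = "numeric",
                 tol = "numeric", isFCD = "logical"),
  validity = function(object) {
    if (!identical(object@isFCD, object@discrepancy <= object@tol))
      "isFCD must equal (discrepancy <= tol)"
    else TRUE
  })

.verdict <- function(observable, discrepancy, tol) {
  new("FCDVerdict", observable = observable,
      discrepancy = as.numeric(discrepancy), tol = as.numeric(tol),
      isFCD = as.numeric(discrepancy) <= as.numeric(tol))
}

#' Scaled step-stimulus pair
#'
#' Two ligand step programs that are positive linear scalings of each
#' other: pre- and post-step levels of arm 2 equal those of arm 1
#' divided by the common fold p.  The canonical instance compares steps
#' 1000 -> 200 uM and 500 -> 100 uM.
#'
#' @slot LPre1,LPost1,LPre2,LPost2 numeric(1), uM.
#' @slot stepTime numeric(1), time of the step (s) after the start of
#'   each arm.
#' @slot horizon numeric(1), duration simulated per arm (s).
#' @exportClass ScaledStepPair
setClass("ScaledStepPair",
  representation(LPre1 = "numeric", LPost1 = "numeric", LPre2 = "numeric",
                 LPost2 = "numeric", stepTime = "numeric", horizon = "numeric"),
  validity = function(object) {
    msg <- character()
    lv <- c(object@LPre1, object@LPost1, object@LPre2, object@LPost2)
    if (any(!is.finite(lv)) || any(lv <= 0))
      msg <- c(msg, "all four levels must be finite and > 0")
    else {
      p1 <- object@LPre1 / object@LPre2
      p2 <- object@LPost1 / object@LPost2
      if (abs(p1 - p2) > 1e-9 * max(p1, p2))
        msg <- c(msg, "pre and post levels must share a common scale factor")
    }
    if (object@stepTime <= 0 || object@horizon <= object@stepTime)
      msg <- c(msg, "need 0 < stepTime < horizon")
    if (length(msg)) msg else TRUE
  })

#' @describeIn ScaledStepPair Constructor; defaults to the canonical
#'   1000 -> 200 vs 500 -> 100 uM pair.
#' @param LPre1,LPost1,LPre2,LPost2,stepTime,horizon see slots.
#' @export
scaledStepPair <- function(LPre1 = 1000, LPost1 = 200, LPre2 = 500,
                           LPost2 = 100, stepTime = 100, horizon = 500) {
  new("ScaledStepPair", LPre1 = as.numeric(LPre1), LPost1 = as.numeric(LPost1),
      LPre2 = as.numeric(LPre2), LPost2 = as.numeric(LPost2),
      stepTime = as.numeric(stepTime), horizon = as.numeric(horizon))
}

#' @describeIn ScaledStepPair The common scale factor p between the arms.
#' @param pair a \code{ScaledStepPair}.
#' @export
pairScaleFactor <- function(pair) pair@LPre1 / pair@LPre2
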