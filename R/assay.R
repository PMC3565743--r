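#' Synthetic tethered-cell assay configuration
#'
#' Describes the in-silico analogue of a tethered-cell
#' flagellar-rotation experiment: the ligand schedule (default: a step
#' from 0 to 100 uM at 245 s and back to 0 at 375 s over a 600 s
#' horizon), the sampling rate, additive Gaussian measurement noise and
#' the generating ("truth") model.
#'
#' @slot schedule a \code{\link{LigandProgram}}.
#' @slot horizon numeric(1), recording length (s).
#' @slot sampleRate numeric(1), samples per second (> 0).
#' @slot noiseSd numeric(1), measurement-noise standard deviation
#'   (Hz, >= 0).
#' @slot seed integer(1), RNG seed.
#' @slot truth a \code{\link{ChemotaxisModel}} used as the generator.
#' @exportClass AssayConfig
setClass("AssayConfig",
  representation(schedule = "LigandProgram", horizon = "numeric",
                 sampleRate = "numeric", noiseSd = "numeric",
                 seed = "integer", truth = "ChemotaxisModel"),
  validity = function(object) {
    msg <- character()
    if (!(object@sampleRate > 0)) msg <- c(msg, "'sampleRate' must be > 0")
    if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
    if (object@horizon <= max(object@schedule@times))
      msg <- c(msg, "'horizon' must exceed the last schedule breakpoint")
    if (length(msg)) msg else TRUE
  })

#' @describeIn AssayConfig Constructor.  The schedule includes L = 0
#'   segments, so the truth model must use (and is forced to) the exact
#'   MWC activity.
#' @param schedule,horizon,sampleRate,noiseSd,seed,truth see slots.
#' @export
assayConfig <- function(schedule = ligandProgram(), horizon = 600,
                        sampleRate = 1, noiseSd = 0.5, seed = 1L,
                        truth = chemotaxisModel("I")) {
  new("AssayConfig", schedule = schedule, horizon = as.numeric(horizon),
      sampleRate = as.numeric(sampleRate), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed), truth = setActivityForm(truth, "exact"))
}

#' Generate a synthetic tethered-cell trace
#'
#' Simulates the truth model from its adapted state at the schedule's
#' initial ligand level, samples the flagellar frequency at the
#' configured rate, adds i.i.d. Gaussian noise and clips to
#' [0, fMax] Hz (the physical limit of the tethered flagellum).
#' Reproducible for a fixed seed.
#'
#' @param cfg an \code{\link{AssayConfig}}.
#' @return data.frame(t_s, f_hz) with attributes \code{"noiseless"}
#'   (the noise-free frequency samples) and \code{"seed"}.
#' @export
generateTrace <- function(cfg) {
  stopifnot(is(cfg, "AssayConfig"))
  tt <- seq(cfg@schedule@times[1L], cfg@horizon, by = 1 / cfg@sampleRate)
  tr <- simulateTrajectory(cfg@truth, cfg@schedule, tt)
  f0 <- trajChannel(tr, "f")
  fmax <- cfg@truth@flagellar@fMax
  if (cfg@noiseSd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(cfg@seed)
    f <- f0 + stats::rnorm(length(f0), sd = cfg@noiseSd)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  } else f <- f0
  out <- data.frame(t_s = tt, f_hz = pmin(fmax, pmax(0, f)))
  attr(out, "noiseless") <- f0
  attr(out, "seed") <- cfg@seed
  out
}

#' Write / read a tethered-cell trace as CSV
#'
#' The on-disk format is a two-column CSV with header \code{t_s, f_hz}.
#' \code{readTrace} validates the header, numeric content and strict
#' monotonicity of the time column.
#'
#' @param trace data.frame(t_s, f_hz).
#' @param path file path.
#' @return \code{writeTrace}: \code{path}, invisibly.
#'   \code{readTrace}: the validated data.frame.
#' @export
writeTrace <- function(trace, path) {
  stopifnot(all(c("t_s", "f_hz") %in% names(trace)))
  utils::write.csv(trace[, c("t_s", "f_hz")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop("cannot parse trace CSV '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  missing <- setdiff(c("t_s", "f_hz"), names(df))
  if (length(missing))
    stop("trace CSV '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in c("t_s", "f_hz")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop(sprintf("trace CSV '%s': non-numeric value in column '%s' at data line %d",
                   path, col, bad[1L]), call. = FALSE)
  }
  if (any(diff(df$t_s) <= 0)) {
    i <- which(diff(df$t_s) <= 0)[1L] + 1L
    stop(sprintf("trace CSV '%s': time not strictly increasing at data line %d",
                 path, i), call. = FALSE)
  }
  df[, c("t_s", "f_hz")]
}
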