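.CONFIG_BLOCKS <- c("variant", "mutations", "activity", "tau_Lt", "m_leak",
                    "receptor", "phospho", "methylation", "flagellar",
                    "solver")

.receptorToList <- function(rp)
  list(N = rp@N, alpha = rp@alpha, m0 = rp@m0, K_A_uM = rp@K_A,
       K_I_uM = rp@K_I)

.receptorFromList <- function(x, where) {
  known <- c("N", "alpha", "m0", "K_A_uM", "K_I_uM")
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("config: unknown key '", where, ".", bad[1L], "'", call. = FALSE)
  def <- list(N = 1, alpha = 2, m0 = 5, K_A_uM = 3000, K_I_uM = 18)
  def[names(x)] <- x
  tryCatch(
    receptorParams(N = def$N, alpha = def$alpha, m0 = def$m0,
                   K_A = def$K_A_uM, K_I = def$K_I_uM),
    error = function(e) stop("config: invalid '", where, "': ",
                             conditionMessage(e), call. = FALSE))
}

#' Serialize a model to a plain list
#'
#' The list mirrors the on-disk config layout (blocks
#' \code{receptor.membrane}, \code{receptor.cytoplasmic},
#' \code{phospho}, \code{methylation}, \code{flagellar}, \code{variant},
#' \code{mutations}, \code{solver}) and round-trips through
#' \code{\link{modelFromList}}.
#'
#' @param model a \code{\link{ChemotaxisModel}}.
#' @return nested list.
#' @export
modelToList <- function(model) {
  ph <- model@phospho
  list(variant = model@variant,
       mutations = as.list(model@mutations),
       activity = model@activity,
       tau_Lt = model@tauLt,
       m_leak = model@mLeak,
       receptor = list(membrane = .receptorToList(model@membrane),
                       cytoplasmic = .receptorToList(model@cytoplasmic)),
       phospho = list(totals = as.list(ph@totals),
                      k_auto = list(A2 = ph@kAutoA2, A34 = ph@kAutoA34),
                      k_transfer = list(A2 = as.list(ph@kTransA2),
                                        A34 = as.list(ph@kTransA34)),
                      k_dephos = as.list(ph@kDephos),
                      R2 = ph@R2, R3 = ph@R3),
       methylation = list(k_R = model@methylation@kR,
                          k_Rt = model@methylation@kRt,
                          k_B1 = model@methylation@kB1,
                          k_B2 = model@methylation@kB2,
                          k_B2t = model@methylation@kB2t),
       flagellar = list(f_max = model@flagellar@fMax, q = model@flagellar@q,
                        hill_n = model@flagellar@hillN),
       solver = model@solver)
}

#' Build a model from a configuration list
#'
#' Unknown keys raise an error naming the offending key; omitted blocks
#' take the package defaults; all parameter-type invariants
#' (K_A > K_I, positive rates, non-negative totals) are enforced by the
#' class validity methods.
#'
#' @param cfg nested list as produced by \code{\link{modelToList}} or
#'   parsed from a YAML/JSON config file.
#' @return a \code{\link{ChemotaxisModel}}.
#' @export
modelFromList <- function(cfg) {
  stopifnot(is.list(cfg))
  bad <- setdiff(names(cfg), .CONFIG_BLOCKS)
  if (length(bad))
    stop("config: unknown key '", bad[1L], "'", call. = FALSE)
  variant <- if (is.null(cfg$variant)) "I" else as.character(cfg$variant)
  rec <- cfg$receptor
  if (!is.null(rec)) {
    bad <- setdiff(names(rec), c("membrane", "cytoplasmic"))
    if (length(bad))
      stop("config: unknown key 'receptor.", bad[1L], "'", call. = FALSE)
  }
  defN <- if (identical(variant, "III")) 17.5 else 1
  mem <- if (is.null(rec$membrane)) receptorParams(N = defN)
         else .receptorFromList(rec$membrane, "receptor.membrane")
  cyt <- if (is.null(rec$cytoplasmic)) receptorParams(N = defN)
         else .receptorFromList(rec$cytoplasmic, "receptor.cytoplasmic")
  ph <- cfg$phospho
  phospho <- if (is.null(ph)) phosphoParams() else {
    bad <- setdiff(names(ph),
                   c("totals", "k_auto", "k_transfer", "k_dephos", "R2", "R3"))
    if (length(bad))
      stop("config: unknown key 'phospho.", bad[1L], "'", call. = FALSE)
    tryCatch(
      phosphoParams(totals = ph$totals,
                    kAutoA2 = if (is.null(ph$k_auto$A2)) 10 else ph$k_auto$A2,
                    kAutoA34 = if (is.null(ph$k_auto$A34)) 10 else ph$k_auto$A34,
                    kTransA2 = ph$k_transfer$A2,
                    kTransA34 = ph$k_transfer$A34,
                    kDephos = ph$k_dephos,
                    R2 = if (is.null(ph$R2)) 1 else ph$R2,
                    R3 = if (is.null(ph$R3)) 1 else ph$R3),
      error = function(e) stop("config: invalid 'phospho': ",
                               conditionMessage(e), call. = FALSE))
  }
  me <- cfg$methylation
  meth <- if (is.null(me)) methylationParams() else {
    bad <- setdiff(names(me), c("k_R", "k_Rt", "k_B1", "k_B2", "k_B2t"))
    if (length(bad))
      stop("config: unknown key 'methylation.", bad[1L], "'", call. = FALSE)
    def <- list(k_R = 0.02, k_Rt = 0.02, k_B1 = 0.01, k_B2 = 0.01,
                k_B2t = 0.02)
    def[names(me)] <- me
    tryCatch(
      methylationParams(def$k_R, def$k_Rt, def$k_B1, def$k_B2, def$k_B2t),
      error = function(e) stop("config: invalid 'methylation': ",
                               conditionMessage(e), call. = FALSE))
  }
  fl <- cfg$flagellar
  flag <- if (is.null(fl)) flagellarParams() else {
    bad <- setdiff(names(fl), c("f_max", "q", "hill_n"))
    if (length(bad))
      stop("config: unknown key 'flagellar.", bad[1L], "'", call. = FALSE)
    def <- list(f_max = 8, q = 12, hill_n = 4)
    def[names(fl)] <- fl
    tryCatch(flagellarParams(def$f_max, def$q, def$hill_n),
             error = function(e) stop("config: invalid 'flagellar': ",
                                      conditionMessage(e), call. = FALSE))
  }
  solver <- list(rtol = 1e-10, atol = 1e-10, maxStep = Inf)
  if (!is.null(cfg$solver)) {
    bad <- setdiff(names(cfg$solver), names(solver))
    if (length(bad))
      stop("config: unknown key 'solver.", bad[1L], "'", call. = FALSE)
    solver[names(cfg$solver)] <- cfg$solver
    for (k in names(solver)) {
      solver[[k]] <- suppressWarnings(as.numeric(solver[[k]]))
      if (is.na(solver[[k]]))
        stop("config: non-numeric value for 'solver.", k, "'", call. = FALSE)
    }
  }
  tryCatch(
    chemotaxisModel(variant = variant, membrane = mem, cytoplasmic = cyt,
                    phospho = phospho, methylation = meth, flagellar = flag,
                    tauLt = if (is.null(cfg$tau_Lt)) 10 else cfg$tau_Lt,
                    mutations = unlist(cfg$mutations),
                    activity = if (is.null(cfg$activity)) "exact"
                               else cfg$activity,
                    mLeak = if (is.null(cfg$m_leak)) 0 else cfg$m_leak,
                    solver = solver),
    error = function(e) stop("config: ", conditionMessage(e), call. = FALSE))
}

#' Load / write a model configuration file
#'
#' YAML or JSON by file extension.  \code{loadConfig} validates every
#' block and injects defaults for omitted ones; \code{writeConfig}
#' emits a file that loads back to a semantically identical model.
#'
#' @param path config file (.yaml/.yml or .json).
#' @param model a \code{\link{ChemotaxisModel}}.
#' @return \code{loadConfig}: a \code{ChemotaxisModel};
#'   \code{writeConfig}: \code{path}, invisibly.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  modelFromList(cfg)
}

#' @rdname loadConfig
#' @export
writeConfig <- function(model, path) {
  cfg <- modelToList(model)
  # an infinite step cap is the default; YAML/JSON lack a portable Inf
  if (!is.finite(cfg$solver$maxStep)) cfg$solver$maxStep <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read / write a ligand stimulus program as JSON
#'
#' On-disk format: a JSON array of segments
#' \code{[{"t_start_s": ..., "L_uM": ...}, ...]} with strictly
#' increasing start times.
#'
#' @param program a \code{\link{LigandProgram}}.
#' @param path JSON file path.
#' @return \code{writeLigandProgram}: \code{path}, invisibly;
#'   \code{readLigandProgram}: a \code{LigandProgram}.
#' @export
writeLigandProgram <- function(program, path) {
  df <- data.frame(t_start_s = program@times, L_uM = program@levels)
  jsonlite::write_json(df, path, digits = NA)
  invisible(path)
}

#' @rdname writeLigandProgram
#' @export
readLigandProgram <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("t_start_s", "L_uM") %in% names(df)))
    stop("stimulus JSON '", path,
         "' must contain fields t_start_s and L_uM", call. = FALSE)
  ligandProgram(times = df$t_start_s, levels = df$L_uM)
}

#' Model-discrimination report
#'
#' Assembles, for each supplied model, the in-silico evidence that
#' discriminates MWC-based pathway models from alternatives: the
#' canonical scaled-pair FCD verdict (exact under the log-regime
#' activity), the predicted lower-bound factors of the FCD ligand range
#' for the wild type, the fivefold-CheY4 overexpression and the CheB2
#' deletion, and the gene-deletion FCD suite.
#'
#' @param models named list of \code{\link{ChemotaxisModel}} objects
#'   (e.g. list(I = ..., II = ..., III = ...)).
#' @param pair a \code{\link{ScaledStepPair}}.
#' @param outDir optional directory; when given, the report tables are
#'   written as CSV files and the manifest as JSON.
#' @param seed integer recorded in the manifest (the protocols
#'   themselves are deterministic).
#' @return list with elements \code{pairs}, \code{rangeFactors},
#'   \code{mutants} (data.frames) and \code{manifest}; failures of
#'   individual sub-runs are recorded in the tables rather than
#'   aborting the report.
#' @export
discriminationReport <- function(models, pair = scaledStepPair(),
                                 outDir = NULL, seed = 1L) {
  stopifnot(is.list(models), length(models) > 0)
  if (is.null(names(models)) || any(!nzchar(names(models))))
    names(models) <- as.character(seq_along(models))
  pairs <- list(); factors <- list(); muts <- list()
  for (nm in names(models)) {
    mod <- models[[nm]]
    obs <- if (mod@variant == "III") "Y6p" else "f"
    v <- tryCatch({
      res <- runScaledPair(setActivityForm(mod, "log"), pair, observable = obs)
      data.frame(model = nm, observable = obs,
                 discrepancy = res$verdict@discrepancy,
                 is_fcd = res$verdict@isFCD, error = NA_character_)
    }, error = function(e)
      data.frame(model = nm, observable = obs, discrepancy = NA_real_,
                 is_fcd = NA, error = conditionMessage(e)))
    pairs[[nm]] <- v
    factors[[nm]] <- data.frame(
      model = nm,
      wild_type = fcdBoundFactor(mod),
      cheY4_5x = fcdBoundFactor(addMutation(mod, "cheY4_5x")),
      cheB2_del = fcdBoundFactor(addMutation(mod, "cheB2_del")))
    muts[[nm]] <- tryCatch({
      mm <- mutantFcdSuite(setActivityForm(mod, "log"), pair)
      cbind(model = nm, mm, error = NA_character_)
    }, error = function(e)
      data.frame(model = nm, mutant = NA, observable = NA,
                 discrepancy = NA_real_, is_fcd = NA,
                 adaptation_lost_membrane = NA,
                 adaptation_lost_cytoplasmic = NA,
                 error = conditionMessage(e)))
  }
  report <- list(pairs = do.call(rbind, pairs),
                 rangeFactors = do.call(rbind, factors),
                 mutants = do.call(rbind, muts))
  manifest <- list(
    package_version = as.character(utils::packageVersion("rsfcd")),
    seed = as.integer(seed),
    pair = list(LPre1 = pair@LPre1, LPost1 = pair@LPost1,
                LPre2 = pair@LPre2, LPost2 = pair@LPost2,
                stepTime = pair@stepTime, horizon = pair@horizon),
    configs = lapply(models, modelToList),
    config_md5 = vapply(models, function(m) {
      tf <- tempfile(fileext = ".yaml")
      on.exit(unlink(tf), add = TRUE)
      writeConfig(m, tf)
      unname(tools::md5sum(tf))
    }, character(1)))
  report$manifest <- manifest
  rownames(report$pairs) <- rownames(report$rangeFactors) <-
    rownames(report$mutants) <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report$pairs, file.path(outDir, "pair_verdicts.csv"),
                     row.names = FALSE)
    utils::write.csv(report$rangeFactors,
                     file.path(outDir, "fcd_range_factors.csv"),
                     row.names = FALSE)
    utils::write.csv(report$mutants, file.path(outDir, "mutant_suite.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
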