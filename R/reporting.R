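#' Pipeline runners and report writers
#'
#' \code{runDematel}, \code{runDanp}, \code{runScore} and
#' \code{runSimulate} tie the pipeline together for scripted use: they
#' accept file paths (the CSV/JSON dialects of the load/write functions)
#' or in-memory objects, write report files into \code{outDir}, log every
#' defaulted parameter (normalization divisor, INRM threshold, panel
#' consensus) to \code{message()}, and return the computed objects
#' invisibly. Report tables carry full-precision columns next to
#' 2-decimal round-half-up presentation columns, so published tables can
#' be reproduced while numbers remain auditable.
#'
#' @param model a \linkS4class{DecisionModel} or model JSON path.
#' @param panel an \linkS4class{ExpertPanel}, or character vector of
#'   questionnaire CSVs (exclusive with \code{aggregate}).
#' @param aggregate an \linkS4class{AggregateMatrix} or CSV path.
#' @param method panel aggregation method ("median" or "mean").
#' @param threshold optional INRM threshold (default: mean off-diagonal).
#' @param outDir output directory, created if needed.
#' @param digits presentation precision (default 2).
#' @return invisibly, a list of the computed pipeline objects and the
#'   written file paths.
#' @name pipeline-runners
NULL

resolveModel <- function(model)
  if (is.character(model)) loadModel(model) else model

resolveAggregate <- function(model, panel, aggregate, method) {
  if (is.null(panel) == is.null(aggregate))
    stopf("supply exactly one of 'panel' and 'aggregate'")
  if (!is.null(aggregate)) {
    ai <- if (is.character(aggregate)) loadAggregate(aggregate, model)
          else aggregate
    return(list(ai = ai, panel = NULL))
  }
  p <- if (is.character(panel)) loadPanel(panel, model) else panel
  if (length(p@responses) >= 2) {
    cl <- consensusConfidence(p)
    message(sprintf("panel consensus confidence: %.2f%%", cl))
    if (cl < 95)
      warning(sprintf("consensus confidence %.2f%% is below 95%%", cl),
              call. = FALSE)
  } else {
    message("single-expert panel: consensus check skipped")
  }
  list(ai = aggregatePanel(p, method), panel = p)
}

writeProminenceCSV <- function(tab, path, digits = 2) {
  for (col in c("r", "d", "r_plus_d", "r_minus_d"))
    tab[[paste0(col, "_2dp")]] <- roundHalfUp(tab[[col]], digits)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline-runners
#' @export
runDematel <- function(model, panel = NULL, aggregate = NULL,
                       method = "median", threshold = NULL,
                       outDir = ".", digits = 2) {
  model <- resolveModel(model)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  agg <- resolveAggregate(model, panel, aggregate, method)
  ai <- agg$ai
  norm <- normalizeInfluence(ai)
  message(sprintf("normalization divisor s = %g", norm@scaleDivisor))
  t <- totalInfluence(norm)
  td <- dimensionMatrix(t, model)
  critTab <- prominenceRelation(t)
  dimTab <- dimensionProminence(td)
  edgesC <- inrmEdges(t, threshold)
  edgesD <- inrmEdges(td, threshold)
  message(sprintf("INRM thresholds: criterion %.4f, dimension %.4f",
                  attr(edgesC, "threshold"), attr(edgesD, "threshold")))
  files <- c(
    AI = writeMatrixCSV(as.matrix(ai), file.path(outDir, "AI.csv")),
    N = writeMatrixCSV(as.matrix(norm), file.path(outDir, "N.csv")),
    T = writeMatrixCSV(as.matrix(t), file.path(outDir, "T.csv")),
    TD = writeMatrixCSV(as.matrix(td), file.path(outDir, "TD.csv")),
    criterion_prominence = writeProminenceCSV(
      critTab, file.path(outDir, "criterion_prominence.csv"), digits),
    dimension_prominence = writeProminenceCSV(
      dimTab, file.path(outDir, "dimension_prominence.csv"), digits),
    inrm_criteria_dot = writeInrmDot(
      edgesC, file.path(outDir, "inrm_criteria.dot")),
    inrm_criteria_graphml = writeInrmGraphML(
      edgesC, file.path(outDir, "inrm_criteria.graphml")),
    inrm_dimensions_dot = writeInrmDot(
      edgesD, file.path(outDir, "inrm_dimensions.dot")),
    inrm_dimensions_graphml = writeInrmGraphML(
      edgesD, file.path(outDir, "inrm_dimensions.graphml")))
  invisible(list(model = model, ai = ai, norm = norm, t = t, td = td,
                 criterionProminence = critTab, dimensionProminence = dimTab,
                 inrmCriteria = edgesC, inrmDimensions = edgesD,
                 files = files))
}

weightsTable <- function(wv, digits = 2) {
  w <- criterionWeights(wv)
  roll <- dimensionRollup(wv)
  member <- wv@membership[names(w)]
  data.frame(id = names(w),
             dimension = unname(member),
             weight = unname(w),
             weight_percent_2dp = roundHalfUp(100 * unname(w), digits),
             rank = rank(-w, ties.method = "min"),
             dimension_rollup = unname(roll[member]),
             dimension_rollup_percent_2dp =
               roundHalfUp(100 * unname(roll[member]), digits),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname pipeline-runners
#' @param policy optional \linkS4class{GroupPolicy} or policy JSON path;
#'   when given together with a panel, experience-weighted re-calculated
#'   weights are reported side-by-side with the plain ones.
#' @export
runDanp <- function(model, panel = NULL, aggregate = NULL,
                    method = "median", threshold = NULL, policy = NULL,
                    outDir = ".", digits = 2) {
  base <- runDematel(model, panel, aggregate, method, threshold,
                     outDir, digits)
  model <- base$model
  tdn <- normalizeDimensionMatrix(base$td)
  wv <- {
    w <- unweightedSupermatrix(base$t, model)
    limitSupermatrix(weightedSupermatrix(tdn, w, model))
  }
  tab <- weightsTable(wv, digits)
  files <- c(base$files,
    TDN = writeMatrixCSV(as.matrix(tdn), file.path(outDir, "TDN.csv")),
    weights_csv = {
      utils::write.csv(tab, file.path(outDir, "weights.csv"),
                       row.names = FALSE, quote = FALSE)
      file.path(outDir, "weights.csv")
    },
    weights_json = {
      jsonlite::write_json(tab, file.path(outDir, "weights.json"),
                           dataframe = "rows", digits = NA)
      file.path(outDir, "weights.json")
    })
  comparison <- NULL
  if (!is.null(policy)) {
    if (is.character(policy)) policy <- loadPolicy(policy)
    agg <- resolveAggregate(model, panel, NULL, method)
    if (is.null(agg$panel))
      stopf("experience weighting requires a panel, not an aggregate")
    wv2 <- danpWeights(experienceWeightedPanel(agg$panel, policy), model)
    t2 <- weightsTable(wv2, digits)
    comparison <- data.frame(
      id = tab$id,
      weight = tab$weight, rank = tab$rank,
      weight_percent_2dp = tab$weight_percent_2dp,
      recalculated_weight = t2$weight[match(tab$id, t2$id)],
      recalculated_rank = t2$rank[match(tab$id, t2$id)],
      recalculated_weight_percent_2dp =
        t2$weight_percent_2dp[match(tab$id, t2$id)],
      stringsAsFactors = FALSE)
    utils::write.csv(comparison, file.path(outDir, "weights_comparison.csv"),
                     row.names = FALSE, quote = FALSE)
    files <- c(files,
               weights_comparison = file.path(outDir,
                                              "weights_comparison.csv"))
  }
  invisible(c(base[setdiff(names(base), "files")],
              list(tdn = tdn, weights = wv, weightsTable = tab,
                   comparison = comparison, files = files)))
}

#' @rdname pipeline-runners
#' @param weights a \linkS4class{WeightVector}, named numeric, or a
#'   weights CSV written by \code{runDanp}.
#' @param patients patient grade data.frame or CSV path.
#' @param store optional path of a JSON-lines risk-record file; scored
#'   patients labelled via \code{labels} are appended to it.
#' @param labels optional named character vector patient_id -> label.
#' @export
runScore <- function(model, weights, patients, outDir = ".",
                     store = NULL, labels = NULL, digits = 2) {
  model <- resolveModel(model)
  if (is.character(weights)) {
    df <- utils::read.csv(weights, stringsAsFactors = FALSE)
    weights <- stats::setNames(df$weight, df$id)
  }
  if (is.character(patients)) patients <- loadPatients(patients, model)
  else patients <- validatePatients(patients, model)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  outPath <- file.path(outDir, "scores.csv")
  if (!nrow(patients)) {
    empty <- data.frame(patient_id = character(), score = numeric(),
                        rank = integer(), tie = logical())
    utils::write.csv(empty, outPath, row.names = FALSE, quote = FALSE)
    return(invisible(list(scores = list(), ranking = empty,
                          files = c(scores = outPath))))
  }
  scores <- sawScores(weights, patients)
  ranking <- rankPatients(scores)
  ranking$score_2dp <- roundHalfUp(ranking$score, digits)
  utils::write.csv(ranking, outPath, row.names = FALSE, quote = FALSE)
  st <- NULL
  if (!is.null(store)) {
    st <- riskRecordStore(store)
    for (s in scores) {
      lab <- if (!is.null(labels) && s@patientId %in% names(labels))
        labels[[s@patientId]] else "unlabelled"
      st <- recordCase(st, s, lab)
    }
  }
  invisible(list(scores = scores, ranking = ranking, store = st,
                 files = c(scores = outPath)))
}

#' @rdname pipeline-runners
#' @param config a \code{\link{panelConfig}} for the synthetic panel.
#' @param nPatients number of synthetic patients to score.
#' @export
runSimulate <- function(model, config = panelConfig(), nPatients = 3,
                        threshold = NULL, outDir = ".", digits = 2) {
  model <- resolveModel(model)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  truth <- generateTrueMatrix(model, seed = config$seed)
  panel <- generatePanel(truth, config, model = model)
  writeAggregate(truth, file.path(outDir, "truth.csv"))
  writePanel(panel, file.path(outDir, "panel"))
  patients <- generatePatients(model, nPatients, seed = config$seed)
  writePatients(patients, file.path(outDir, "patients.csv"))
  res <- runDanp(model, panel = panel, threshold = threshold,
                 outDir = outDir, digits = digits)
  truthW <- danpWeights(truth, model)
  recovered <- names(which.max(criterionWeights(res$weights)))
  planted <- names(which.max(criterionWeights(truthW)))
  summary <- data.frame(
    seed = config$seed,
    consensus = consensusConfidence(panel),
    top_truth = planted,
    top_recovered = recovered,
    top_recovered_ok = identical(planted, recovered),
    max_weight_error = max(abs(criterionWeights(res$weights) -
                                 criterionWeights(truthW))),
    stringsAsFactors = FALSE)
  utils::write.csv(summary, file.path(outDir, "recovery_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  scoreRes <- runScore(model, res$weights, patients, outDir = outDir,
                       digits = digits)
  invisible(list(truth = truth, panel = panel, patients = patients,
                 danp = res, truthWeights = truthW, summary = summary,
                 ranking = scoreRes$ranking))
}
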