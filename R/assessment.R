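#' Simple additive weighting (SAW) risk score
#'
#' Aggregates a patient's per-criterion grades (1 = low risk ... 10 = high
#' risk) with the DANP influential weights: score = sum over criteria of
#' weight x grade. With weights summing to 1 the score stays between the
#' smallest and largest grade. Besides a full-precision
#' \linkS4class{WeightVector}, a plain named numeric is accepted so that
#' published two-decimal weight tables (divided by 100) can be reproduced
#' verbatim; such printed weights may sum to slightly less than 1 and are
#' used exactly as given.
#'
#' @param weights a \linkS4class{WeightVector} or named numeric summing to
#'   1 within 0.01.
#' @param grades named numeric grades in [1, 10], one per criterion (or a
#'   one-row patient data.frame with a \code{patient_id} column).
#' @param patientId identifier; default taken from \code{grades}.
#' @return a \linkS4class{RiskScore}.
#' @examples
#' w <- akiPrintedWeights()
#' pts <- akiPatients()
#' sawScore(w, pts[pts$patient_id == "A", ])
#' @export
sawScore <- function(weights, grades, patientId = NULL) {
  w <- if (is(weights, "WeightVector")) criterionWeights(weights) else weights
  if (is.null(names(w))) stopf("weights must be named by criterion id")
  if (abs(sum(w) - 1) > 0.01)
    stopf("weights must sum to 1 (got %.4f)", sum(w))
  if (is.data.frame(grades)) {
    if (nrow(grades) != 1L) stopf("expected a single patient row")
    if (is.null(patientId) && "patient_id" %in% names(grades))
      patientId <- as.character(grades$patient_id)
    grades <- unlist(grades[setdiff(names(grades), "patient_id")])
  }
  if (is.null(patientId)) patientId <- NA_character_
  miss <- setdiff(names(w), names(grades))
  if (length(miss))
    stopf("grades missing for criterion %s", paste(miss, collapse = ", "))
  extra <- setdiff(names(grades), names(w))
  if (length(extra))
    stopf("grade for unknown criterion %s", paste(extra, collapse = ", "))
  g <- grades[names(w)]
  if (any(g < 1 | g > 10)) {
    bad <- names(w)[which(g < 1 | g > 10)[1]]
    stopf("grade out of [1, 10] for patient '%s', criterion %s",
          patientId, bad)
  }
  contrib <- w * g
  new("RiskScore", patientId = patientId, score = sum(contrib),
      contributions = contrib)
}

#' Score a whole patient table
#'
#' @param weights as in \code{\link{sawScore}}.
#' @param patients data.frame with \code{patient_id} plus criterion columns.
#' @return list of \linkS4class{RiskScore}, one per row.
#' @export
sawScores <- function(weights, patients) {
  lapply(seq_len(nrow(patients)),
         function(i) sawScore(weights, patients[i, , drop = FALSE]))
}

#' Rank patients by descending risk
#'
#' Stable descending sort on the score; exact ties are broken by
#' lexicographic patient id and flagged.
#'
#' @param scores list of \linkS4class{RiskScore} (or data.frame with
#'   \code{patient_id} and \code{score}).
#' @return data.frame (patient_id, score, rank, tie), highest risk first.
#' @export
rankPatients <- function(scores) {
  if (is.data.frame(scores)) {
    df <- scores[, c("patient_id", "score")]
  } else {
    if (!length(scores)) stopf("no scores to rank")
    df <- data.frame(
      patient_id = vapply(scores, function(s) s@patientId, character(1)),
      score = vapply(scores, function(s) s@score, numeric(1)),
      stringsAsFactors = FALSE)
  }
  df <- df[order(-df$score, df$patient_id), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$tie <- duplicated(df$score) | duplicated(df$score, fromLast = TRUE)
  rownames(df) <- NULL
  df
}

#' Experience-weighted panel aggregation
#'
#' Groups the panel's experts by experience (per the policy's membership,
#' falling back to each response's own group tag), takes the elementwise
#' median within each group — the same outlier-resistant aggregate used for
#' the plain panel — and combines the group medians by the policy's
#' weighted arithmetic mean. Weights of empty groups are dropped with a
#' warning and the remaining weights renormalized.
#'
#' @param panel an \linkS4class{ExpertPanel}.
#' @param policy a \linkS4class{GroupPolicy}.
#' @return an \linkS4class{AggregateMatrix} (method
#'   "experience-weighted"), ready for \code{\link{danpWeights}}.
#' @export
experienceWeightedPanel <- function(panel, policy) {
  groups <- vapply(panel@responses, function(r) {
    g <- policy@membership[r@expertId]
    if (is.na(g)) g <- r@group
    g
  }, character(1))
  if (anyNA(groups)) {
    bad <- vapply(panel@responses, function(r) r@expertId,
                  character(1))[is.na(groups)]
    stopf("expert(s) with no experience group: %s",
          paste(bad, collapse = ", "))
  }
  unknown <- setdiff(unique(groups), names(policy@groupWeights))
  if (length(unknown))
    stopf("expert assigned to group without a policy weight: %s",
          paste(unknown, collapse = ", "))
  gw <- policy@groupWeights
  empty <- setdiff(names(gw)[gw > 0], unique(groups))
  if (length(empty)) {
    warning(sprintf("empty group(s) with positive weight dropped: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  }
  gw <- gw[intersect(names(gw), unique(groups))]
  if (sum(gw) <= 0) stopf("no represented group has positive weight")
  gw <- gw / sum(gw)
  acc <- 0
  for (g in names(gw)) {
    sub <- panel@responses[groups == g]
    arr <- array(unlist(lapply(sub, as.matrix)),
                 dim = c(dim(as.matrix(sub[[1]])), length(sub)))
    med <- apply(arr, c(1, 2), stats::median)
    acc <- acc + gw[[g]] * med
  }
  dimnames(acc) <- dimnames(as.matrix(panel@responses[[1]]))
  new("AggregateMatrix", matrix = acc, method = "experience-weighted",
      nExperts = length(panel@responses))
}

#' Append-only risk record store
#'
#' Accumulates clinician-labelled risk scores (e.g. "dangerous" /
#' "not dangerous") so that empirical score ranges per label emerge as
#' cases accrue; the package deliberately hard-codes no danger threshold.
#' When a path is given the store mirrors every record to a JSON-lines
#' file and reloads existing records from it.
#'
#' @param path optional JSON-lines file backing the store.
#' @return an empty (or reloaded) \linkS4class{RiskRecordStore}.
#' @export
riskRecordStore <- function(path = character()) {
  records <- data.frame(patient_id = character(), score = numeric(),
                        label = character(), timestamp = character(),
                        stringsAsFactors = FALSE)
  if (length(path) && file.exists(path)) {
    lines <- readLines(path)
    if (length(lines)) {
      rows <- lapply(lines, jsonlite::fromJSON)
      records <- do.call(rbind, lapply(rows, as.data.frame,
                                       stringsAsFactors = FALSE))
    }
  }
  new("RiskRecordStore", records = records, path = path)
}

#' @rdname riskRecordStore
#' @param store a \linkS4class{RiskRecordStore}.
#' @param score a \linkS4class{RiskScore}.
#' @param label clinician's categorization of the case.
#' @param timestamp record time (default now, UTC).
#' @return \code{recordCase}: the updated store (also appended to the
#'   backing file when one is configured).
#' @export
recordCase <- function(store, score, label,
                       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                          tz = "UTC")) {
  rec <- data.frame(patient_id = score@patientId, score = score@score,
                    label = label, timestamp = timestamp,
                    stringsAsFactors = FALSE)
  if (length(store@path)) {
    con <- file(store@path, open = "a")
    on.exit(close(con))
    writeLines(jsonlite::toJSON(as.list(rec), auto_unbox = TRUE,
                                digits = NA), con)
  }
  new("RiskRecordStore", records = rbind(store@records, rec),
      path = store@path)
}

#' @rdname riskRecordStore
#' @return \code{labelRanges}: data.frame (label, n, min, max) of the
#'   empirical score range observed per clinician label.
#' @export
labelRanges <- function(store) {
  r <- store@records
  if (!nrow(r))
    return(data.frame(label = character(), n = integer(),
                      min = numeric(), max = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(split(r, r$label), function(x)
    data.frame(label = x$label[1], n = nrow(x),
               min = min(x$score), max = max(x$score),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
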