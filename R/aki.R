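#' The packaged AKI risk-assessment example
#'
#' A worked decision model for assessing acute-kidney-injury (AKI) risk in
#' elderly patients, elicited from a panel of ten nephrologists: three
#' dimensions — Comorbidity (D1), Laboratory Values (D2) and Comprehensive
#' Geriatric Assessments (D3) — over 14 criteria (diabetes through
#' nutritional assessment), with the panel's published median influence
#' matrix, three illustrative patients' grade rows, the published
#' two-decimal DANP weight table, and the experience-group weighting
#' policy (senior 50%, mid-career 30%, junior 20% over groups of 1, 5 and
#' 4 doctors).
#'
#' \code{akiAggregate} is the panel's elementwise-median initial average
#' matrix (half-steps such as 2.50 arise from the even split of ten
#' integer responses). \code{akiPrintedWeights} returns the published
#' per-criterion percentages divided by 100, for reproducing the published
#' patient risk levels verbatim; full-precision weights come from
#' \code{danpWeights(akiAggregate(), akiModel())}.
#'
#' @return \code{akiModel}: a \linkS4class{DecisionModel};
#'   \code{akiAggregate}: an \linkS4class{AggregateMatrix};
#'   \code{akiPatients}: a patient grade data.frame;
#'   \code{akiPrintedWeights}: named numeric weights summing to ~1;
#'   \code{akiPolicy}: a \linkS4class{GroupPolicy} with a synthetic
#'   expert-to-group assignment (the real assignment was never published;
#'   only the group sizes and weights were).
#' @name aki-example
NULL

akiFile <- function(name) system.file("extdata", name, package = "danprisk")

#' @rdname aki-example
#' @export
akiModel <- function() loadModel(akiFile("aki_model.json"))

#' @rdname aki-example
#' @export
akiAggregate <- function(model = akiModel()) {
  ai <- loadAggregate(akiFile("aki_initial_average.csv"), model)
  ai@method <- "median"
  ai@nExperts <- 10
  ai
}

#' @rdname aki-example
#' @param model the AKI \linkS4class{DecisionModel} (loaded by default).
#' @export
akiPatients <- function(model = akiModel()) {
  loadPatients(akiFile("aki_patients.csv"), model)
}

#' @rdname aki-example
#' @export
akiPrintedWeights <- function() {
  df <- utils::read.csv(akiFile("aki_printed_weights.csv"),
                        stringsAsFactors = FALSE)
  stats::setNames(df$weight_percent / 100, df$id)
}

#' @rdname aki-example
#' @export
akiPolicy <- function() loadPolicy(akiFile("aki_group_policy.json"))

#' Synthetic stand-in for the ten unpublished questionnaires
#'
#' The individual expert questionnaires behind the published median
#' matrix were never published; this function constructs a deterministic
#' synthetic panel of ten integer questionnaires consistent with it. On
#' integer cells all experts agree with the median. Each half-step cell
#' (an even split of the real panel) is resolved so that (a) exactly five
#' experts take the floor and five the ceiling, making the panel's
#' elementwise median reproduce the published matrix cell-for-cell, and
#' (b) the forced group-median deviations (a 1-expert or 5-expert group
#' cannot produce a half-step) alternate in sign down each column, so the
#' experience-weighted aggregate stays as close to the published matrix
#' as integer parity permits. This is the packaged worked panel for the
#' group re-weighting mechanism; it is synthetic, not the study's data.
#'
#' @param model the AKI \linkS4class{DecisionModel}.
#' @return an \linkS4class{ExpertPanel} of ten experts in groups
#'   G1 (1), G2 (5), G3 (4).
#' @export
akiSyntheticPanel <- function(model = akiModel()) {
  tm <- as.matrix(akiAggregate(model))
  ids <- criterionIds(model)
  half <- which(abs(tm - floor(tm) - 0.5) < 1e-9, arr.ind = TRUE)
  sgn <- integer(nrow(half))
  for (cc in unique(half[, 2])) {
    idx <- which(half[, 2] == cc)
    idx <- idx[order(half[idx, 1])]
    sgn[idx] <- rep(c(1L, -1L), length.out = length(idx))
  }
  groups <- rep(c("G1", "G2", "G3"), c(1, 5, 4))
  mats <- lapply(1:10, function(e) {
    mm <- roundHalfUp(tm, 0)
    for (q in seq_len(nrow(half))) {
      f <- floor(tm[half[q, 1], half[q, 2]])
      up <- sgn[q] == 1L
      v <- if (e == 1) {
        if (up) f + 1 else f               # G1 takes the cell's sign
      } else if (e <= 6) {                 # G2 median lands opposite G1
        if (e - 1 <= (if (up) 2 else 3)) f + 1 else f
      } else {                             # G3 splits 2/2: median exact
        if (e - 6 <= 2) f + 1 else f
      }
      mm[half[q, 1], half[q, 2]] <- v
    }
    dimnames(mm) <- list(ids, ids)
    mm
  })
  expertPanel(mats, model, groups = groups)
}
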