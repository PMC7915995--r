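#' Configuration for synthetic expert panels
#'
#' Defaults emulate the packaged study conditions: a panel of ten experts
#' in three experience groups of sizes 1, 5 and 4, each expert reproducing
#' the ground-truth influence matrix except that any given cell deviates
#' with probability \code{noiseProb} by a uniform integer step of at most
#' \code{maxDev} (clipped to the 0--4 scale). The perturbation is a
#' bounded integer shift, not Gaussian noise, because the questionnaire
#' scale is ordinal. The default \code{noiseProb} of 0.05 is calibrated so
#' that generated panels match the published panel's reported stability
#' (running-mean consensus confidence above 95\%) across seeds.
#'
#' @param nExperts number of experts.
#' @param noiseProb probability a cell deviates from truth.
#' @param maxDev maximum absolute deviation in integer steps (1..4).
#' @param groupSizes named integer vector of experience-group sizes,
#'   summing to \code{nExperts}.
#' @param seed integer seed; all generation is reproducible from it.
#' @return a validated config list (class "PanelConfig").
#' @export
panelConfig <- function(nExperts = 10, noiseProb = 0.05, maxDev = 1,
                        groupSizes = c(G1 = 1, G2 = 5, G3 = 4), seed = 1) {
  if (noiseProb < 0 || noiseProb > 1) stopf("noiseProb must be in [0, 1]")
  if (!maxDev %in% 1:4) stopf("maxDev must be an integer in 1..4")
  if (sum(groupSizes) != nExperts)
    stopf("group sizes (%d) must sum to nExperts (%d)",
          sum(groupSizes), nExperts)
  structure(list(nExperts = nExperts, noiseProb = noiseProb,
                 maxDev = maxDev, groupSizes = groupSizes, seed = seed),
            class = "PanelConfig")
}

#' Generate a ground-truth influence matrix
#'
#' Draws an integer 0--4 influence matrix with zero diagonal. The
#' "structured" profile plants a designated high-influence criterion whose
#' column sum is strictly maximal (its column is drawn from {3, 4} while
#' all other columns are capped at 3), emulating a dominant risk factor;
#' the "uniform" profile draws every off-diagonal cell uniformly from
#' 0..4.
#'
#' @param model a \linkS4class{DecisionModel}.
#' @param seed integer seed.
#' @param profile "structured" (default) or "uniform".
#' @param target criterion id to plant as dominant (structured profile;
#'   default: the last criterion of the last dimension).
#' @return an \linkS4class{AggregateMatrix} (method "truth").
#' @export
generateTrueMatrix <- function(model, seed = 1,
                               profile = c("structured", "uniform"),
                               target = NULL) {
  profile <- match.arg(profile)
  ids <- criterionIds(model)
  n <- length(ids)
  withSeed(seed, {
    if (profile == "uniform") {
      m <- matrix(sample(0:4, n * n, replace = TRUE), n, n)
    } else {
      if (is.null(target)) target <- ids[n]
      if (!target %in% ids) stopf("unknown target criterion '%s'", target)
      m <- matrix(sample(0:3, n * n, replace = TRUE), n, n)
      tc <- match(target, ids)
      m[, tc] <- sample(3:4, n, replace = TRUE)
      if (all(m[-tc, tc] == 3)) m[sample(setdiff(1:n, tc), 1), tc] <- 4
    }
    diag(m) <- 0
    dimnames(m) <- list(ids, ids)
    new("AggregateMatrix", matrix = m, method = "truth",
        nExperts = NA_real_)
  })
}

#' Generate a synthetic expert panel around a ground truth
#'
#' Each expert starts from the truth rounded to the nearest integer; a
#' half-step cell (e.g. 2.50, which in a median matrix records an even
#' split of the panel) is resolved by giving the floor to half of the
#' experts and the ceiling to the other half, so the noise-free panel
#' median reproduces the truth exactly. Every off-diagonal cell then
#' deviates with probability \code{noiseProb} by a uniform integer in
#' [-maxDev, maxDev], clipped to [0, 4]. The diagonal stays zero. Experts
#' are assigned to experience groups in order of \code{groupSizes}. Fully
#' reproducible from the config's seed.
#'
#' @param truth an \linkS4class{AggregateMatrix} (or plain matrix).
#' @param config a \code{\link{panelConfig}}.
#' @param model optional \linkS4class{DecisionModel} used to validate the
#'   responses (inferred dimnames are kept either way).
#' @return an \linkS4class{ExpertPanel}.
#' @export
generatePanel <- function(truth, config = panelConfig(), model = NULL) {
  tm <- if (is(truth, "AggregateMatrix")) as.matrix(truth) else truth
  n <- nrow(tm)
  k <- config$nExperts
  half <- abs(tm - floor(tm) - 0.5) < 1e-9   # even-split cells of a median
  groups <- rep(names(config$groupSizes), config$groupSizes)
  withSeed(config$seed, {
    responses <- lapply(seq_len(k), function(e) {
      m <- roundHalfUp(tm, 0)
      m[half] <- floor(tm[half]) + e %% 2
      flip <- matrix(stats::runif(n * n) < config$noiseProb, n, n)
      dev <- matrix(sample(-config$maxDev:config$maxDev, n * n,
                           replace = TRUE), n, n)
      m[flip] <- m[flip] + dev[flip]
      m <- pmin(pmax(m, 0), 4)
      diag(m) <- 0
      new("RawResponse", matrix = m, expertId = sprintf("E%02d", e),
          group = groups[e])
    })
    mod <- if (!is.null(model)) model else
      decisionModel(
        dimensions = data.frame(id = "D1", label = "All"),
        criteria = data.frame(id = rownames(base), label = rownames(base),
                              dimension = "D1"))
    new("ExpertPanel", model = mod, responses = responses)
  })
}

#' Generate synthetic patient grade tables
#'
#' Grades are drawn uniformly from the integers 1..10 per criterion,
#' emulating clinician-assigned risk grades.
#'
#' @param model a \linkS4class{DecisionModel}.
#' @param n number of patients (>= 1).
#' @param seed integer seed.
#' @return data.frame with \code{patient_id} ("P01", ...) plus one column
#'   per criterion, valid under \code{\link{validatePatients}}.
#' @export
generatePatients <- function(model, n = 3, seed = 1) {
  if (n < 1) stopf("n must be at least 1")
  ids <- criterionIds(model)
  withSeed(seed, {
    g <- matrix(sample(1:10, n * length(ids), replace = TRUE), n,
                dimnames = list(NULL, ids))
    df <- data.frame(patient_id = sprintf("P%02d", seq_len(n)), g,
                     check.names = FALSE, stringsAsFactors = FALSE)
    validatePatients(df, model)
  })
}
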