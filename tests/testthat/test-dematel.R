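test_that("panel aggregation: median (even split) and weighted mean", {
  m <- oneDimModel(2)
  mk <- function(v) matrix(c(0, v, 1, 0), 2, 2, byrow = TRUE,
                           dimnames = list(criterionIds(m),
                                           criterionIds(m)))
  # constant panel is a fixed point of both methods
  p <- expertPanel(list(mk(3), mk(3)), m)
  expect_equal(as.matrix(aggregatePanel(p, "median")), mk(3))
  expect_equal(as.matrix(aggregatePanel(p, "mean")), mk(3))

  # four experts {2,2,3,4}: even count averages the two middle values
  p4 <- expertPanel(lapply(c(2, 2, 3, 4), mk), m)
  expect_equal(as.matrix(aggregatePanel(p4, "median"))[1, 2], 2.5)

  # weighted mean {0,2,4} with weights (1,1,2): (0 + 2 + 8) / 4
  p3 <- expertPanel(lapply(c(0, 2, 4), mk), m)
  expect_equal(
    as.matrix(aggregatePanel(p3, "mean", expertWeights = c(1, 1, 2)))[1, 2],
    2.5)
  expect_error(aggregatePanel(p3, "mean", expertWeights = c(1, 1)),
               "expected 3")
  expect_error(aggregatePanel(p3, "mean", expertWeights = c(0, 0, 0)),
               "not all zero")
})

test_that("aggregation is order-invariant and the median resists one outlier", {
  m <- oneDimModel(3)
  withr::with_seed(11, {
    mats <- replicate(5, {
      mm <- matrix(sample(0:4, 9, replace = TRUE), 3, 3)
      diag(mm) <- 0
      dimnames(mm) <- list(criterionIds(m), criterionIds(m))
      mm
    }, simplify = FALSE)
  })
  p <- expertPanel(mats, m)
  perm <- expertPanel(mats[c(3, 1, 5, 2, 4)], m)
  for (method in c("median", "mean"))
    expect_equal(as.matrix(aggregatePanel(p, method)),
                 as.matrix(aggregatePanel(perm, method)))

  # an expert that is the unique maximum everywhere can be replaced by any
  # legal matrix without moving the median
  base <- constMatrix(m, 1)
  top <- constMatrix(m, 4)
  p5 <- expertPanel(list(base, base, constMatrix(m, 2), base, top), m)
  p5b <- expertPanel(list(base, base, constMatrix(m, 2), base,
                          constMatrix(m, 3)), m)
  expect_equal(as.matrix(aggregatePanel(p5)), as.matrix(aggregatePanel(p5b)))
})

test_that("consensus confidence matches the hand-computed running-mean gap", {
  m <- oneDimModel(2)
  mk <- function(a, b) matrix(c(0, a, b, 0), 2, 2, byrow = TRUE,
                              dimnames = list(criterionIds(m),
                                              criterionIds(m)))
  # identical responses: the running mean does not move
  p <- expertPanel(list(mk(2, 3), mk(2, 3)), m)
  expect_equal(consensusConfidence(p), 100)

  # off-diagonal cells (4,4) then (2,4): A(1) = (4,4), A(2) = (3,4);
  # gap = (|3-4|/3 + 0)/2 * 100 = 16.67 -> confidence 83.33
  p2 <- expertPanel(list(mk(4, 4), mk(2, 4)), m)
  expect_equal(consensusConfidence(p2), 100 - 100 / 6, tolerance = 1e-12)
  # reversing the expert order changes the running mean's last step
  expect_equal(consensusConfidence(p2, order = c(2, 1)),
               100 - 50 * (abs(3 - 2) / 3), tolerance = 1e-12)

  expect_error(consensusConfidence(expertPanel(list(mk(1, 1)), m)),
               "two experts")

  # cells with zero running mean are skipped, divisor reduced
  p0 <- expertPanel(list(mk(0, 4), mk(0, 4)), m)
  expect_equal(consensusConfidence(p0), 100)
})

test_that("normalization divides by the dominant row/column sum", {
  # published 14 x 14 example: the Frailty column dominates every row sum
  norm <- normalizeInfluence(akiAggregate())
  expect_equal(norm@scaleDivisor, 44.5)
  expect_equal(max(max(rowSums(as.matrix(norm))),
                   max(colSums(as.matrix(norm)))), 1)

  # row-dominant case: divisor is that row's sum
  m <- matrix(0, 3, 3); m[1, 2] <- 4; m[1, 3] <- 4
  expect_equal(normalizeInfluence(m)@scaleDivisor, 8)

  # a symmetric 2 x 2 normalizes to spectral radius 1: no convergence
  expect_error(normalizeInfluence(matrix(c(0, 2, 2, 0), 2, 2)),
               "spectral radius")
  expect_error(normalizeInfluence(matrix(0, 3, 3)), "all-zero")
})

test_that("closed-form T matches the truncated influence series", {
  # hand case: N with 0.5 off-diagonal
  n2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  norm <- new("NormalizedMatrix", matrix = n2, scaleDivisor = 2)
  tm <- as.matrix(totalInfluence(norm))
  expect_equal(tm, matrix(c(1, 2, 2, 1) / 3, 2, 2), tolerance = 1e-12)

  # property: random small matrices, series truncated at w = 200
  withr::with_seed(42, {
    for (rep in 1:20) {
      n <- sample(2:8, 1)
      a <- matrix(stats::runif(n * n, 0, 4), n, n)
      diag(a) <- 0
      norm <- normalizeInfluence(a)
      tm <- as.matrix(totalInfluence(norm))
      expect_equal(tm, seriesTotalInfluence(as.matrix(norm)),
                   tolerance = 1e-9)
      # conservation: total given equals total received
      t <- totalInfluence(norm)
      expect_equal(sum(t@r), sum(t@d), tolerance = 1e-9)
      expect_equal(sum(t@r - t@d), 0, tolerance = 1e-9)
    }
  })
})

test_that("rescaling the questionnaire scale leaves N and T unchanged", {
  withr::with_seed(5, {
    a <- matrix(stats::runif(25, 0, 4), 5, 5)
    diag(a) <- 0
  })
  n1 <- normalizeInfluence(a)
  n2 <- normalizeInfluence(a * 0.5)
  expect_equal(as.matrix(n1), as.matrix(n2), tolerance = 1e-12)
  expect_equal(as.matrix(totalInfluence(n1)), as.matrix(totalInfluence(n2)),
               tolerance = 1e-12)
})

test_that("prominence tables carry r, d, r+d, r-d per item", {
  t <- totalInfluence(new("NormalizedMatrix",
                          matrix = matrix(c(0, 0.5, 0.5, 0), 2, 2),
                          scaleDivisor = 2))
  tab <- prominenceRelation(t)
  expect_equal(tab$r_plus_d, c(2, 2), tolerance = 1e-12)
  expect_equal(tab$r_minus_d, c(0, 0), tolerance = 1e-12)
  # symmetric T: every net relation vanishes
  expect_true(all(abs(tab$r_minus_d) < 1e-12))
  # prominence bounds net relation in magnitude
  expect_true(all(tab$r_plus_d >= abs(tab$r_minus_d)))
})

test_that("published criterion analytics reproduce at two decimals", {
  t <- totalInfluence(normalizeInfluence(akiAggregate()))
  tab <- prominenceRelation(t, digits = 2)
  expect_equal(tab$r_plus_d[tab$id == "C34"], 8.14)
  expect_equal(tab$r_plus_d[tab$id == "C22"], 7.06)
  # C22 has the largest prominence within its dimension block
  d2 <- tab[tab$id %in% c("C21", "C22", "C23", "C24", "C25"), ]
  expect_equal(d2$id[which.max(d2$r_plus_d)], "C22")
})

test_that("dimension matrix averages the partition blocks", {
  # degenerate partition: single dimension reduces to the mean of T
  m1 <- oneDimModel(3)
  a <- pertMatrix(m1, 2)
  t <- totalInfluence(normalizeInfluence(a))
  td <- dimensionMatrix(t, m1)
  expect_equal(as.vector(as.matrix(td)), mean(as.matrix(t)))

  # constant matrix: every block mean is that constant
  m2 <- twoDimModel()
  tOnes <- new("TotalInfluence", matrix = matrix(1, 4, 4),
               r = rep(4, 4), d = rep(4, 4))
  expect_equal(as.matrix(dimensionMatrix(tOnes, m2)),
               matrix(1, 2, 2, dimnames = list(c("D1", "D2"),
                                               c("D1", "D2"))))
  expect_error(dimensionMatrix(tOnes, oneDimModel(3)), "does not match")
})

test_that("dimension prominence: hand sums and published values", {
  td <- new("DimensionMatrix",
            matrix = matrix(c(1, 3, 2, 4), 2, 2,
                            dimnames = list(c("D1", "D2"), c("D1", "D2"))))
  tab <- dimensionProminence(td)
  expect_equal(tab$r, c(3, 7))
  expect_equal(tab$d, c(4, 6))
  expect_equal(tab$r_minus_d, c(-1, 1))

  t <- totalInfluence(normalizeInfluence(akiAggregate()))
  dtab <- dimensionProminence(dimensionMatrix(t, akiModel()), digits = 2)
  expect_equal(dtab$r_plus_d[dtab$id == "D1"], 1.33)
  expect_equal(dtab$r_minus_d[dtab$id == "D1"], 0.16)
  # D1 is the only net cause at dimension level
  expect_equal(dtab$id[dtab$r_minus_d > 0], "D1")
})

test_that("INRM edge extraction thresholds and sorts directed edges", {
  t <- totalInfluence(normalizeInfluence(akiAggregate()))
  all14 <- inrmEdges(t, threshold = 0)
  expect_equal(nrow(all14), 14 * 13)
  expect_true(all(diff(all14$strength) <= 0))
  expect_equal(nrow(inrmEdges(t, threshold = max(as.matrix(t)) + 1)), 0)
  expect_error(inrmEdges(t, threshold = -1), "nonnegative")

  # default threshold is the mean off-diagonal entry, recorded on output
  tm <- as.matrix(t)
  e <- inrmEdges(t)
  expect_equal(attr(e, "threshold"), mean(tm[row(tm) != col(tm)]))

  # at dimension level, the net-cause dimension D1 influences D3
  ed <- inrmEdges(dimensionMatrix(t, akiModel()))
  expect_true(any(ed$source == "D1" & ed$target == "D3"))

  dir <- withr::local_tempdir()
  writeInrmDot(ed, file.path(dir, "inrm.dot"))
  expect_true(any(grepl("D1.*->.*D3", readLines(file.path(dir, "inrm.dot")))))
  writeInrmGraphML(ed, file.path(dir, "inrm.graphml"))
  expect_true(file.size(file.path(dir, "inrm.graphml")) > 0)
})
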