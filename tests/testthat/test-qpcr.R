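# Brute-force geNorm oracle: all pairwise log2-ratio SDs, averaged per gene.
bruteM <- function(q) {
  n <- nrow(q)
  sapply(seq_len(n), function(j) {
    mean(sapply(setdiff(seq_len(n), j), function(k) {
      sd(log2(q[j, ] / q[k, ]))
    }))
  })
}

toyCq <- function() {
  cq <- rbind(ACT7 = c(20, 21, 22, 20.5),
              CDC27B = c(22, 23, 24, 22.4),
              PUB33 = c(25, 27, 25.5, 28),
              NCED3 = c(30, 28, 33, 29))
  colnames(cq) <- paste0("s", 1:4)
  CqExperiment(cq, efficiency = c(ACT7 = 0.95, CDC27B = 0.9,
                                  PUB33 = 1, NCED3 = 0.85))
}

test_that("relative quantities are efficiency-corrected with max 1 per gene", {
  q1 <- relativeQuantity(matrix(c(20, 21), 1, 2, dimnames = list("g", NULL)),
                         efficiency = 1)
  expect_equal(unname(q1), matrix(c(1, 0.5), 1, 2))  # perfect doubling
  q2 <- relativeQuantity(matrix(c(18, 20), 1, 2, dimnames = list("g", NULL)),
                         efficiency = 0.9)
  expect_equal(unname(q2[1, 2]), 1.9^-2)                     # 0.27700...
  q <- relativeQuantity(toyCq())
  expect_equal(unname(apply(q, 1, max)), rep(1, 4))  # per-gene minimum Cq -> 1
  # factor-form efficiencies are accepted
  cq <- matrix(c(20, 21), 1, 2, dimnames = list("g", NULL))
  a <- CqExperiment(cq, efficiency = c(g = 0.9))
  b <- CqExperiment(cq, efficiency = c(g = 1.9), efficiencyForm = "factor")
  expect_equal(relativeQuantity(a), relativeQuantity(b))
  expect_error(CqExperiment(cq, efficiency = c(other = 1)), "missing efficiency")
})

test_that("geNorm M agrees with the brute-force all-pairs oracle", {
  q <- relativeQuantity(toyCq())
  expect_equal(unname(geNormM(q)), bruteM(q), tolerance = 1e-12)
  # random matrices up to 6x6
  set.seed(11)
  for (n in c(3, 5, 6)) {
    qr <- matrix(2^runif(n * 6, -4, 0), n, 6,
                 dimnames = list(paste0("g", 1:n), NULL))
    expect_equal(unname(geNormM(qr)), bruteM(qr), tolerance = 1e-12)
  }
})

test_that("geNorm M is zero for constant-ratio pairs and symmetric under duplication", {
  s <- c(1, 0.5, 0.25, 0.8)
  q <- rbind(a = s, b = 0.3 * s)
  expect_equal(unname(geNormM(q)), c(0, 0))
  q3 <- relativeQuantity(toyCq())
  qDup <- rbind(q3, dup = q3["ACT7", ])
  m <- geNormM(qDup)
  expect_equal(unname(m["dup"]), unname(m["ACT7"]))
  expect_error(geNormM(rbind(a = c(1, 0), b = c(1, 1))), "log-ratio")
})

test_that("M values are invariant to per-sample global scaling", {
  q <- relativeQuantity(toyCq())
  scaled <- sweep(q, 2, c(1, 10, 0.2, 5), `*`)
  expect_equal(geNormM(scaled), geNormM(q), tolerance = 1e-12)
})

test_that("reference selection takes the lowest-M pair with lexicographic ties", {
  q <- relativeQuantity(toyCq())
  m <- geNormM(q)
  expect_equal(selectReferences(m, 2), names(sort(m))[1:2])
  tied <- c(zeta = 0.2, alpha = 0.2, beta = 0.5)
  expect_equal(selectReferences(tied, 2), c("alpha", "zeta"))
  expect_equal(sort(selectReferences(tied, 3)), sort(names(tied)))
  expect_error(selectReferences(tied, 4), "exceeds")
  rep <- genormReport(q)
  expect_s4_class(rep, "StabilityReport")
  expect_length(rep@references, 2)
  expect_equal(length(rep@pairwiseVariation), nrow(q) - 2)
})

test_that("normalization divides by the geometric mean of the references", {
  q <- rbind(ref1 = c(0.25, 1), ref2 = c(1, 1), target = c(0.5, 2))
  n <- normalizeTargets(q, c("ref1", "ref2"))
  expect_equal(unname(n["target", 1]), 0.5 / sqrt(0.25))     # geomean 0.5 -> 1
  expect_equal(unname(n["target", ]), c(1, 2))
  # a target identical to the single reference normalizes to 1
  n1 <- normalizeTargets(rbind(ref = c(2, 3), t = c(2, 3)), "ref")
  expect_equal(unname(n1["t", ]), c(1, 1))
  # per-sample global scaling cancels
  q2 <- sweep(q, 2, c(7, 0.3), `*`)
  expect_equal(normalizeTargets(q2, c("ref1", "ref2"))["target", ],
               n["target", ])
  # sample-independent rescaling of one reference rescales all samples equally
  q3 <- q; q3["ref1", ] <- q3["ref1", ] * 4
  expect_equal(normalizeTargets(q3, c("ref1", "ref2"))["target", ] * 2,
               n["target", ])
  expect_error(normalizeTargets(q, c("ref1", "nope")), "not in the matrix")
  q0 <- q; q0["ref1", 1] <- 0
  expect_error(normalizeTargets(q0, c("ref1", "ref2")), "reference quantity")
})

test_that("CqExperiment validity enforces the Cq and efficiency contracts", {
  cq <- matrix(c(20, 21, 22, 23), 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_s4_class(CqExperiment(cq, c(a = 0.9, b = 1)), "CqExperiment")
  expect_error(CqExperiment(-cq, c(a = 0.9, b = 1)), "> 0")
  expect_error(CqExperiment(cq, c(a = 1.5, b = 1)), "fractions in")
  cqNA <- cq; cqNA["a", ] <- NA
  expect_error(CqExperiment(cqNA, c(a = 0.9, b = 1)), "entirely missing")
})
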