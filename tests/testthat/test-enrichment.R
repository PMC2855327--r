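toy_universe <- sprintf("g%02d", 1:20)

test_that("hypergeometric tails match closed form and enumeration oracle", {
  sets <- geneSetCollection(list(S = toy_universe[1:5]), "toy")
  # perfect overlap of a 5-gene cluster with a 5-gene set in a 20-universe
  e <- hypergeomEnrich(toy_universe[1:5], sets, toy_universe)
  expect_equal(e$p_raw, 1 / choose(20, 5))
  expect_equal(e$overlap, 5L)

  # cluster = universe and zero overlap both give p = 1
  expect_equal(hypergeomEnrich(toy_universe, sets, toy_universe)$p_raw, 1)
  e0 <- hypergeomEnrich(toy_universe[6:10],
                        geneSetCollection(list(S = toy_universe[11:15]), "t"),
                        toy_universe)
  expect_equal(e0$p_raw, 1)

  # exhaustive subset enumeration on universes <= 15
  for (cse in list(c(12, 4, 5, 2), c(10, 3, 3, 1), c(15, 6, 7, 4),
                   c(8, 4, 4, 4))) {
    U <- cse[1]; K <- cse[2]; n <- cse[3]; ov <- cse[4]
    uni <- sprintf("u%02d", seq_len(U))
    set <- geneSetCollection(list(S = uni[seq_len(K)]), "o")
    cluster <- c(uni[seq_len(ov)], uni[K + seq_len(n - ov)])
    e <- hypergeomEnrich(cluster, set, uni)
    expect_equal(e$overlap, ov)
    expect_equal(e$p_raw, oracle_hyper_tail(U, K, n, ov), tolerance = 1e-12)
  }
})

test_that("Bonferroni correction uses the class size and is monotone", {
  uni <- toy_universe
  s1 <- list(A = uni[1:5])
  s3 <- list(A = uni[1:5], B = uni[6:10], C = uni[11:15])
  cl <- uni[1:5]
  e1 <- hypergeomEnrich(cl, geneSetCollection(s1, "one"), uni)
  e3 <- hypergeomEnrich(cl, geneSetCollection(s3, "three"), uni)
  expect_equal(e3$p_bonferroni[1], min(1, e1$p_raw[1] * 3))
  # adding sets never rescues an insignificant record
  insig1 <- e1$set_name[!e1$significant]
  insig3 <- e3$set_name[!e3$significant & e3$set_name %in% insig1]
  expect_setequal(insig3, insig1)
  expect_error(hypergeomEnrich(cl, geneSetCollection(s1, "x"), character()),
               "empty universe")
})

test_that("sensitivity and specificity are perfect on a matched toy", {
  cl <- list(toy_universe[1:10], toy_universe[11:20])
  p <- new("Partition", clusters = cl,
           perGraphModularity = matrix(numeric(0), 0, 0),
           minModularity = numeric(0))
  classes <- geneSetCollection(list(A = toy_universe[1:10],
                                    B = toy_universe[11:20]), "ref")
  ss <- sensitivitySpecificity(p, classes, toy_universe)
  expect_equal(ss$sensitivity, 100)
  expect_equal(ss$specificity, 100)
  expect_equal(ss$coverage, 20)
  expect_true(all(ss$sensitivity >= 0 & ss$sensitivity <= 100))
})

test_that("random clusters are not called significant under the null", {
  set.seed(12)
  uni <- sprintf("u%03d", 1:200)
  cl <- list(sample(uni, 15))
  p <- new("Partition", clusters = cl,
           perGraphModularity = matrix(numeric(0), 0, 0),
           minModularity = numeric(0))
  sets <- geneSetCollection(
    stats::setNames(lapply(1:10, function(i) sample(uni, 12)),
                    sprintf("S%02d", 1:10)), "null")
  ss <- sensitivitySpecificity(p, sets, uni)
  expect_equal(ss$specificity, 0)
  expect_equal(ss$sensitivity, 0)
})

test_that("cluster recovery follows the enrichment rule and is monotone", {
  ref <- toy_universe[1:10]
  p <- new("Partition", clusters = list(toy_universe[1:10], toy_universe[11:20]),
           perGraphModularity = matrix(numeric(0), 0, 0),
           minModularity = numeric(0))
  expect_true(recovered(ref, p, toy_universe))

  set.seed(9)
  uni <- sprintf("u%03d", 1:300)
  refr <- sample(uni, 12)
  prand <- new("Partition",
               clusters = split(sample(uni), rep(1:10, each = 30)),
               perGraphModularity = matrix(numeric(0), 0, 0),
               minModularity = numeric(0))
  expect_false(recovered(refr, prand, uni))
  # adding the reference cluster itself can only help
  pplus <- new("Partition",
               clusters = c(list(refr), lapply(prand@clusters, setdiff, refr)),
               perGraphModularity = matrix(numeric(0), 0, 0),
               minModularity = numeric(0))
  expect_true(recovered(refr, pplus, uni))
})

test_that("guilt-by-association predicts the most enriched set", {
  uni <- toy_universe
  p <- new("Partition", clusters = list(uni[1:10], uni[11:20]),
           perGraphModularity = matrix(numeric(0), 0, 0),
           minModularity = numeric(0))
  go <- geneSetCollection(list(proc_a = uni[1:9], proc_b = uni[11:19]), "GO")
  pred <- predictFunction(p, go, uncharacterized = c("g10", "g20"), uni)
  expect_equal(pred[["g10"]], "proc_a")
  expect_equal(pred[["g20"]], "proc_b")

  # tie in p-values resolves to the lexicographically smallest set name
  go2 <- geneSetCollection(list(zz = uni[1:9], aa = uni[1:9]), "GO")
  pred2 <- predictFunction(p, go2, uncharacterized = "g10", uni)
  expect_equal(unname(pred2), "aa")

  # genes outside every reported cluster receive no prediction
  expect_false("g99" %in% names(pred))
  p2 <- new("Partition", clusters = list(uni[1:10], uni[11:20]),
            perGraphModularity = matrix(numeric(0), 0, 0),
            minModularity = numeric(0))
  predNone <- predictFunction(p2, geneSetCollection(list(x = uni[1:2]), "GO"),
                              uncharacterized = "g10", uni)
  expect_equal(length(predNone), 0)
})

test_that("correlation support counts Bonferroni-significant co-members", {
  set.seed(21)
  base <- rnorm(30)
  expr <- rbind(target = base,
                m1 = base + rnorm(30, sd = 0.01),
                m2 = base + rnorm(30, sd = 0.01),
                m3 = rnorm(30))
  cl <- c("target", "m1", "m2", "m3")
  cs <- correlationSupport("target", cl, expr)
  expect_equal(cs$count, 2)
  expect_equal(cs$threshold, 0.05 / 4)
  expect_lte(cs$count, length(cl) - 1)
  expect_error(correlationSupport("nope", cl, expr), "no expression")

  # under independent noise the support fraction stays near the corrected
  # per-test level
  set.seed(22)
  n <- 100
  exprN <- matrix(rnorm(41 * n), 41,
                  dimnames = list(c("g0", sprintf("m%02d", 1:40)), NULL))
  csN <- correlationSupport("g0", rownames(exprN), exprN)
  expect_lte(csN$fraction, 0.05)  # expected approx 0.05/41, generous bound
})
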