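test_that("shannon index matches closed forms and vegan", {
  expect_equal(shannonIndex(1), 0)
  expect_equal(shannonIndex(rep(1 / 8, 8)), log(8))
  p <- c(0.5, 0.25, 0.25)
  expect_equal(shannonIndex(p), -sum(p * log(p)))
  for (s in 1:5) {
    set.seed(900 + s)
    v <- rgamma(12, 1); v <- v / sum(v)
    expect_equal(shannonIndex(v), unname(vegan::diversity(v)))
    # uniform maximizes shannon among perturbations
    expect_lte(shannonIndex(v), log(12))
  }
})

test_that("bray-curtis matches its formula and vegan", {
  a <- c(0.2, 0.3, 0.5); b <- a
  expect_equal(brayCurtis(a, b), 0)
  expect_equal(brayCurtis(c(1, 0, 0), c(0, 0.4, 0.6)), 1)
  for (s in 1:5) {
    set.seed(950 + s)
    a <- runif(10); b <- runif(10)
    expect_equal(brayCurtis(a, b), 1 - 2 * sum(pmin(a, b)) / sum(a + b))
    expect_equal(brayCurtis(a, b),
                 unname(as.matrix(vegan::vegdist(rbind(a, b), "bray"))[1, 2]))
  }
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "all-zero")
})

test_that("pcoa recovers configurations from euclidean distances", {
  # two points at distance d sit at +/- d/2 on the first axis
  d <- matrix(c(0, 3, 3, 0), 2)
  co <- pcoa(d)$coordinates
  expect_equal(sort(co[, 1]), c(-1.5, 1.5))

  # known 2-D configuration: recovered up to rotation/reflection
  set.seed(1001)
  X <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(X))
  fit <- pcoa(D)
  expect_true(all(fit$eigenvalues[-(1:2)] < 1e-8))
  Y <- fit$coordinates[, 1:2]
  # compare via inter-point distances (rotation-invariant)
  expect_equal(as.matrix(dist(Y)), D, tolerance = 1e-8,
               ignore_attr = TRUE)
  # and against classical scaling in stats
  ref <- cmdscale(D, k = 2)
  expect_equal(abs(cor(Y[, 1], ref[, 1])), 1, tolerance = 1e-8)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("permanova is calibrated under the null and detects separation", {
  set.seed(1100)
  rejections <- replicate(40, {
    m <- matrix(runif(20 * 8), 20, 8)
    d <- as.matrix(dist(m))
    dimnames(d) <- list(paste0("s", 1:20), paste0("s", 1:20))
    lab <- rep(c("a", "b"), each = 10)
    permanova(d, lab, nPerm = 199L, seed = sample.int(1e6, 1))$p < 0.05
  })
  expect_lt(mean(rejections), 0.2)  # ~0.05 nominal, wide band at 40 reps
  # strong separation is detected
  m <- rbind(matrix(rnorm(40, 0), 10), matrix(rnorm(40, 3), 10))
  d <- as.matrix(dist(m))
  expect_lt(permanova(d, rep(c("a", "b"), each = 10), 199L, seed = 4)$p,
            0.05)
})

test_that("wilcoxon differential abundance: exact cases and BH q-values", {
  # constant column totals so relative abundances keep the planted order:
  # group a gets 10..50, group b 60..100 of a 200-count total
  sep <- c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100)
  m <- rbind(g__Sep = sep, g__Null = 200 - sep)
  colnames(m) <- paste0("s", 1:10)
  rel <- toRelative(AbundanceTable(m))
  g <- rep(c("a", "b"), each = 5)
  res <- wilcoxonFdr(rel, g)
  # completely separated 5 vs 5 without ties: exact p = 2/choose(10,5)
  expect_equal(res$p[res$taxon_id == "g__Sep"], 2 / 252)

  # q-values equal an independent BH oracle
  for (s in 1:3) {
    tab <- toRelative(randomCountTable(15, 12, seed = 1200 + s))
    g2 <- rep(c("a", "b"), each = 6)
    res2 <- wilcoxonFdr(tab, g2)
    expect_equal(res2$q, bhOracle(res2$p))
  }
  expect_error(wilcoxonFdr(rel, c(rep("a", 2), rep("b", 8))), ">= 3")
})

test_that("wilcoxon exact p equals enumeration for combined n <= 12", {
  for (s in 1:6) {
    set.seed(1300 + s)
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    v <- pmin(abs(c(rnorm(n1), rnorm(n2, 0.5))) * 0.3 + 0.01, 0.95)
    rel <- RelativeAbundanceTable(
      rbind(g__T = v, g__U = 1 - v,
            deparse.level = 0) |>
        `dimnames<-`(list(c("g__T", "g__U"), paste0("s", seq_along(v)))))
    res <- wilcoxonFdr(rel, rep(c("a", "b"), c(n1, n2)))
    expect_equal(res$p[res$taxon_id == "g__T"],
                 wilcoxEnumOracle(v[1:n1], v[(n1 + 1):(n1 + n2)]),
                 tolerance = 1e-9)
  }
})

test_that("two-stage step-up matches a reference implementation", {
  # degenerate ends
  expect_false(any(bkyAdjust(rep(1, 10))$discoveries))
  expect_true(all(bkyAdjust(rep(1e-10, 10))$discoveries))
  # random p mixtures against the procedure coded independently
  for (s in 1:10) {
    set.seed(1400 + s)
    p <- c(runif(12), rbeta(8, 0.1, 10))
    for (q in c(0.05, 0.1, 0.2)) {
      expect_identical(bkyAdjust(p, q)$discoveries, bkyOracle(p, q))
    }
    # discovery sets are monotone in the nominal level
    d1 <- bkyAdjust(p, 0.05)$discoveries
    d2 <- bkyAdjust(p, 0.10)$discoveries
    expect_true(all(d2[d1]))
    # and BH itself is monotone
    bh <- bhOracle(p)
    expect_true(all((bh <= 0.10)[bh <= 0.05]))
  }
})

test_that("multiTBky runs per-feature t-tests with BKY control", {
  set.seed(1500)
  m <- rbind(matrix(rnorm(60, 0), 6), matrix(rnorm(40, 0), 4))
  m[1:6, 6:10] <- m[1:6, 6:10] + 4  # strong effects in 6 features
  rownames(m) <- sprintf("f%02d", 1:10); colnames(m) <- paste0("s", 1:10)
  res <- multiTBky(m, rep(c("a", "b"), each = 5))
  expect_true(all(res$discovery[1:6]))
  expect_identical(res$discovery, bkyOracle(res$p, 0.05))
  # zero-variance feature flagged with p = 1
  m2 <- rbind(m, fconst = rep(3, 10))
  res2 <- multiTBky(m2, rep(c("a", "b"), each = 5))
  expect_equal(res2$p[res2$taxon_id == "fconst"], 1)
  expect_identical(res2$flag[res2$taxon_id == "fconst"], "zero_variance")
})

test_that("group summaries use Student-t intervals", {
  # SD 0 collapses the interval onto the mean
  s0 <- summarizeGroup(rep(2.5, 5))
  expect_equal(c(s0$ci_low, s0$ci_high), c(2.5, 2.5))
  # raw-vector and summary paths agree
  set.seed(1600); v <- rnorm(20, 5, 2)
  a <- summarizeGroup(v)
  b <- groupSummaryFromStats(mean(v), sd(v), 20)
  expect_equal(a$ci_low, b$ci_low)
  expect_equal(a$ci_high, b$ci_high)
  # against t.test's interval
  ci <- t.test(v)$conf.int
  expect_equal(c(a$ci_low, a$ci_high), as.numeric(ci))
  expect_error(summarizeGroup(3), "n >= 2")
})

test_that("pooled t from summaries equals t.test on raw data", {
  set.seed(1700)
  x <- rnorm(12, 1); y <- rnorm(15, 2)
  ours <- twoSampleTFromStats(mean(x), sd(x), 12, mean(y), sd(y), 15)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
  expect_equal(twoSampleTFromStats(1, 0.5, 10, 1, 0.5, 10)$p, 1)
})

test_that("chao1 richness follows the closed form", {
  expect_equal(chao1(c(5, 1, 2, 0)), 3 + 1^2 / (2 * 1))
  expect_equal(chao1(c(1, 1, 3)), 3 + 2 * 1 / 2)  # F2 = 0, bias-corrected
})
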