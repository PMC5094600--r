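test_that("terminal bias is 1 under the null and obeys the conservation law", {
  comp <- list(counts = c(A = 300L, K = 100L, R = 100L, G = 500L),
               total = 1000L)
  # detections drawn exactly at genome frequencies
  det <- c(A = 30L, K = 10L, R = 10L, G = 50L)
  tb <- terminalBias(det, comp)
  expect_true(all(tb$bias == 1))
  # conservation: genome-frequency-weighted mean of biases is exactly 1
  set.seed(43)
  for (i in 1:10) {
    det <- stats::setNames(rpois(4, c(5, 20, 1, 8)), names(comp$counts))
    det[det == 0] <- 1L
    tb <- terminalBias(det, comp)
    expect_equal(sum(tb$bias * tb$genome / tb$genome_total), 1)
  }
  # zero detections give bias 0 but stay in the table
  tb0 <- terminalBias(c(A = 5L), comp)
  expect_equal(nrow(tb0), 4L)
  expect_equal(tb0$bias[tb0$residue == "K"], 0)
  expect_error(terminalBias(c(Z = 1L), comp), "absent")
})

test_that("K/R enrichment chi-square matches the standard goodness-of-fit test", {
  # oracle: stats::chisq.test on the two-cell table
  grid <- expand.grid(O = c(5, 12, 25, 40), n = c(50, 148),
                      g = c(0.08, 0.2, 0.4))
  for (i in seq_len(nrow(grid))) {
    O <- grid$O[i]; n <- grid$n[i]; p0 <- grid$g[i]
    ours <- trypticEnrichmentTest(O, n, round(p0 * 1e6), 1e6)
    ref <- suppressWarnings(
      stats::chisq.test(c(O, n - O), p = c(p0, 1 - p0)))
    expect_equal(unname(ours$statistic), unname(ref$statistic))
    expect_equal(ours$p.value, ref$p.value)
  }
  # O = E exactly gives statistic 0, p = 1
  h <- trypticEnrichmentTest(20, 100, 200, 1000)
  expect_equal(unname(h$statistic), 0)
  expect_equal(h$p.value, 1)
  # p decreases monotonically as O moves away from E
  ps <- vapply(20:40, function(O)
    trypticEnrichmentTest(O, 100, 200, 1000)$p.value, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("one-cell mapping enrichment matches the chi-square survival function", {
  # closed-form oracle: upper tail of chi2_1 is 2 * (1 - Phi(sqrt(x)))
  for (O in c(5, 14, 29, 33))
    for (E in c(2.64, 13.01, 15.65, 30)) {
      h <- mappingEnrichment(O, E)
      stat <- (O - E)^2 / E
      expect_equal(unname(h$statistic), stat)
      expect_equal(h$p.value, 2 * (1 - pnorm(sqrt(stat))))
    }
  expect_equal(mappingEnrichment(10, 10)$p.value, 1)
  expect_error(mappingEnrichment(5, 0), "positive")
})

test_that("Fisher combination follows -2 sum log p with 2k df", {
  h1 <- fisherCombine(0.2)
  expect_equal(h1$p.value, 0.2)          # k = 1 identity
  expect_equal(fisherCombine(c(1, 1, 1))$p.value, 1)
  expect_error(fisherCombine(c(0.5, 0)), "0, 1")
  expect_error(fisherCombine(numeric(0)))
  # monotone: decreasing any p decreases the combined p
  base <- fisherCombine(c(0.2, 0.3, 0.4))$p.value
  expect_lt(fisherCombine(c(0.1, 0.3, 0.4))$p.value, base)
  expect_lt(fisherCombine(c(0.2, 0.3, 0.2))$p.value, base)
})

test_that("one-tailed Pearson p agrees with cor.test and a permutation oracle", {
  set.seed(47)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- 0.3 * x + rnorm(n)
    ours <- pearsonOneTailed(x, y)
    ref <- stats::cor.test(x, y, alternative = "greater")
    expect_equal(unname(ours$estimate), unname(ref$estimate))
    expect_equal(ours$p.value, ref$p.value)
  }
  expect_equal(unname(pearsonOneTailed(1:5, 1:5)$estimate), 1)
  expect_error(pearsonOneTailed(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearsonOneTailed(1:3, 1:4), "equal length")
  # exact permutation p on n = 9 synthetic data
  set.seed(53)
  x <- rnorm(9); y <- 0.5 * x + rnorm(9)
  r_obs <- cor(x, y)
  perm <- replicate(20000, cor(x, sample(y)))
  p_perm <- mean(perm >= r_obs)
  expect_lt(abs(pFromR(r_obs, 9) - p_perm), 0.03)
})

test_that("the correlation suite pairs transforms and combines across analyses", {
  counts <- list(a = c(t1 = 3, t2 = 9, t3 = 1, t4 = 7),
                 b = c(u1 = 2, u2 = 5, u3 = 11))
  coverage <- list(a = c(t2 = 0.4, t1 = 0.1, t3 = 0.05, t4 = 0.3),
                   b = c(u1 = 0.1, u2 = 0.2, u3 = 0.5))
  res <- correlationSuite(counts, coverage)
  expect_equal(res$table$analysis, c("a", "b"))
  expect_equal(res$table$n, c(4L, 3L))
  # keys are matched by name, not position
  expect_equal(res$table$r[1], cor(counts$a, coverage$a[names(counts$a)]))
  expect_equal(res$combined$p.value, fisherCombine(res$table$p)$p.value)
  expect_error(correlationSuite(counts, coverage["a"]), "differ")
  bad <- coverage; names(bad$b) <- c("x1", "x2", "x3")
  expect_error(correlationSuite(counts, bad), "keys differ")
  flat <- coverage; flat$a[] <- 0.2
  expect_error(correlationSuite(counts, flat), "constant")
})

test_that("peptide-on-RNA mapping uses full containment, matching a set oracle", {
  expect_true(peptideMapsOnRna(cbind(10, 40), cbind(0, 100)))
  expect_false(peptideMapsOnRna(cbind(90, 120), cbind(0, 100)))
  expect_false(peptideMapsOnRna(cbind(10, 40), NULL))
  # split peptide intervals must each be covered
  expect_true(peptideMapsOnRna(rbind(c(5, 10), c(20, 30)),
                               rbind(c(0, 12), c(18, 40))))
  expect_false(peptideMapsOnRna(rbind(c(5, 10), c(20, 30)),
                                rbind(c(0, 12))))
  set.seed(59)
  for (i in 1:30) {
    pep <- cbind(start = s <- sample(0:80, 2), end = s + sample(3:15, 2))
    rna <- cbind(start = r <- sample(0:80, 3), end = r + sample(5:30, 3))
    pep_pos <- unlist(apply(pep, 1, function(x) x[1]:(x[2] - 1)))
    rna_pos <- unlist(apply(rna, 1, function(x) x[1]:(x[2] - 1)))
    expect_equal(peptideMapsOnRna(pep, rna),
                 all(pep_pos %in% rna_pos))
  }
})

test_that("expected mapping sums per-transform coverage fractions", {
  expect_equal(expectedMapping(rep("t1", 10), c(t1 = 0.1)), 1)
  expect_equal(expectedMapping(c("a", "b"), c(a = 0, b = 0)), 0)
  expect_error(expectedMapping("z", c(a = 0.5)), "no coverage")
  expect_error(expectedMapping("a", c(a = 1.2)), "\\[0, 1\\]")
  # Bernoulli simulation oracle on a mixed-coverage toy set
  set.seed(61)
  cov <- c(a = 0.15, b = 0.6, c = 0.02)
  tr <- sample(names(cov), 40, replace = TRUE)
  E <- expectedMapping(tr, cov)
  sims <- replicate(4000, sum(runif(40) < cov[tr]))
  expect_lt(abs(mean(sims) - E), 3 * sd(sims) / sqrt(4000))
})

test_that("single-alternative tryptic fraction averages T/(T + n_r)", {
  toy <- data.frame(analysis = "a",
                    residue = c("K", "R", "A", "G"),
                    detected = c(6L, 4L, 10L, 0L))
  res <- trypticFractionSingleAlternative(toy)
  expect_equal(res$n_cells, 2L)
  expect_equal(res$fraction, mean(c(10 / 20, 1)))   # n_r = T -> 0.5; 0 -> 1
  allzero <- data.frame(analysis = "a", residue = c("K", "A", "C"),
                        detected = c(5L, 0L, 0L))
  expect_equal(trypticFractionSingleAlternative(allzero)$fraction, 1)
  noT <- data.frame(analysis = "a", residue = c("A", "G"),
                    detected = c(1L, 2L))
  expect_error(trypticFractionSingleAlternative(noT), "tryptic")
})

test_that("stop-insertion bias ratios and chi-squares match hand arithmetic", {
  mito <- c(A = 50L, B = 30L, C = 20L)
  obs <- c(A = 10L, B = 3L, C = 7L)
  res <- stopInsertionBias(obs, mito)
  expect_equal(res$bias[res$residue == "A"], (10 / 20) / (50 / 100))
  expect_equal(res$bias[res$residue == "C"], (7 / 20) / (20 / 100))
  e_c <- 20 * 20 / 100
  expect_equal(res$statistic[res$residue == "C"], (7 - e_c)^2 / e_c)
  expect_equal(res$p[res$residue == "C"],
               pchisq((7 - e_c)^2 / e_c, 1, lower.tail = FALSE))
  # proportional counts give bias 1 everywhere
  prop <- stopInsertionBias(c(A = 5L, B = 3L, C = 2L), mito)
  expect_true(all(prop$bias == 1))
  expect_error(stopInsertionBias(obs, c(A = 0L, B = 1L, C = 1L)), "> 0")
})

test_that("xcorr is the lagged dot product with zero padding", {
  expect_equal(xcorr(c(1, 1, 1), c(1, 1, 1), 0), 3)
  expect_equal(xcorr(rnorm(5), rep(0, 5)), 0)
  naive <- function(x, y, tau) {
    s <- 0
    for (i in seq_along(x)) {
      j <- i + tau
      if (j >= 1 && j <= length(y)) s <- s + x[i] * y[j]
    }
    s
  }
  set.seed(67)
  for (tau in c(-3, 0, 2, 9, 12)) {
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(xcorr(x, y, tau), naive(x, y, tau))
  }
  expect_error(xcorr(1:3, 1:4), "equal length")
})

test_that("detection filtering applies the q and Xcorr thresholds when present", {
  d <- data.frame(sequence = letters[1:4], analysis = "a",
                  cterm = "K", q = c(0.01, 0.2, NA, 0.04),
                  xcorr = c(2.5, 2.5, 2.5, 1.5))
  expect_equal(filterDetections(d)$sequence, c("a", "c"))
  d2 <- data.frame(sequence = letters[1:3], analysis = "a", cterm = "K")
  expect_equal(nrow(filterDetections(d2)), 3L)   # scores absent: pass-through
})
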