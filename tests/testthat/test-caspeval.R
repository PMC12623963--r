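test_that("two-pass domain Z-scores match hand arithmetic", {
  x <- c(p1 = 0.9, p2 = 0.8, p3 = 0.7, p4 = 0.2)
  z <- domain_zscores(x)
  # pass 1: mean 0.65, population sd sqrt(0.0725); min z > -2 so pass 2 equals
  s <- sqrt(sum((x - 0.65)^2) / 4)
  expect_equal(unname(z), unname((x - 0.65) / s), tolerance = 1e-12)
  expect_equal(z[["p1"]], 0.25 / s, tolerance = 1e-12)
  expect_gt(min(z), -2)

  # all-equal scores: degenerate sd gives all-zero Z
  expect_equal(unname(domain_zscores(c(a = 0.5, b = 0.5, c = 0.5))),
               rep(0, 3))

  # absent entries stay absent; fewer than 2 present warns and returns absent
  z2 <- domain_zscores(c(a = 0.9, b = NA, c = 0.7))
  expect_true(is.na(z2[["b"]]) && !is.na(z2[["a"]]))
  expect_warning(z3 <- domain_zscores(c(a = 0.9, b = NA)), "fewer than 2")
  expect_true(all(is.na(z3)))
})

test_that("outlier exclusion recentres the survivors", {
  set.seed(2)
  x <- c(rnorm(20, 0.8, 0.02), 0.05)
  names(x) <- paste0("p", 1:21)
  z <- domain_zscores(x)
  # the low outlier is dropped in pass 1, so survivor Z has mean ~0
  expect_lt(z[["p21"]], -2)
  expect_equal(mean(z[1:20]), 0, tolerance = 1e-12)
  expect_equal(sd(z[1:20]) * sqrt(19 / 20), 1, tolerance = 1e-9)
})

test_that("sample-sd mode is supported", {
  x <- c(a = 0.9, b = 0.8, c = 0.7, d = 0.2)
  z <- domain_zscores(x, zscore_config(sd_mode = "sample"))
  expect_equal(z[["a"]], (0.9 - 0.65) / sd(x), tolerance = 1e-12)
})

test_that("cumulative Z accumulates positive parts and merges alternative pairs", {
  tab <- rbind(P = c(d1 = 0.3, d2 = 0.2), Q = c(0.6, 0.4), R = c(0.9, 0.5))
  rep0 <- cumulative_zscore(tab)
  # clip at zero: a predictor below average everywhere accumulates 0
  expect_equal(rep0$cumulative[["P"]], 0)
  expect_equal(rep0$unique_domain_count, 2L)

  # pair averaging happens on raw z before clipping: (+1, -0.5) -> 0.25
  tab2 <- rbind(A = c(u = 1, v = 1), B = c(2, 2), C = c(3, 3))
  z <- cumulative_zscore(tab2)$per_domain_z
  cfgp <- zscore_config(alt_pairs = list(c("u", "v")))
  repp <- cumulative_zscore(tab2, cfgp)
  expect_equal(repp$unique_domain_count, 1L)
  expect_equal(unname(repp$cumulative),
               unname(pmax(0, (z[, "u"] + z[, "v"]) / 2)))

  # a pair member with no submission takes the other member's value
  tab3 <- rbind(A = c(u = 0.9, v = NA), B = c(0.5, 0.2), C = c(0.1, 0.8))
  rp <- cumulative_zscore(tab3, zscore_config(alt_pairs = list(c("u", "v"))))
  zz <- cumulative_zscore(tab3)$per_domain_z
  expect_equal(rp$unit_z["A", "u"], zz["A", "u"])

  expect_error(cumulative_zscore(tab, zscore_config(
    alt_pairs = list(c("d1", "nope")))), "unknown")
})

test_that("cumulative Z is monotone whenever the outlier-exclusion set is stable", {
  # which entries of one domain column get excluded in pass 1
  excl_set <- function(x) {
    v <- x[!is.na(x)]
    s <- sqrt(mean((v - mean(v))^2))
    if (s == 0) character(0) else names(v)[(v - mean(v)) / s < -2]
  }
  set.seed(6)
  checked <- 0
  for (trial in 1:300) {
    np <- sample(4:8, 1); nd <- sample(2:5, 1)
    tab <- matrix(runif(np * nd), np, nd,
                  dimnames = list(paste0("p", 1:np), paste0("d", 1:nd)))
    tab[sample(length(tab), round(length(tab) * 0.1))] <- NA
    i <- sample(np, 1); j <- sample(nd, 1)
    tab2 <- tab
    tab2[i, j] <- min(1, (if (is.na(tab[i, j])) 0 else tab[i, j]) +
                        runif(1, 0.05, 0.3))
    if (!identical(excl_set(tab[, j]), excl_set(tab2[, j]))) next
    checked <- checked + 1
    before <- cumulative_zscore(tab)$cumulative[i]
    after <- cumulative_zscore(tab2)$cumulative[i]
    expect_gte(after, before - 1e-9)
  }
  expect_gt(checked, 200)
})

test_that("rescuing an outlier by raising the top score can deflate its Z", {
  # the exclusion threshold makes the protocol discontinuous: widening the
  # score spread pulls a borderline outlier back above -2, and the larger
  # re-standardization pool lowers the top predictor's recalculated Z
  x <- c(p1 = 0.6684, p2 = 0.7803, p3 = 0.8382, p4 = 0.5659, p5 = 0.8487,
         p6 = 0.2734, p7 = 0.9755, p8 = 0.0007)
  x2 <- x
  x2["p7"] <- 1.0
  z <- domain_zscores(x)
  z2 <- domain_zscores(x2)
  expect_lt(z2[["p8"]], -1.9)       # outlier re-included after the raise
  expect_gt(z[["p8"]], -3.3)        # ... was excluded and re-standardized
  expect_lt(z2[["p7"]], z[["p7"]])  # raiser's own Z drops
})

test_that("TM summaries count threshold fractions two independent ways", {
  s <- summarize_tm(c(a = 1, b = 1, c = 1))
  expect_equal(s$frac_above_9, 1)
  expect_equal(s$frac_above_5, 1)

  s <- summarize_tm(c(a = 0.95, b = 0.6, c = 0.4))
  expect_equal(s$frac_above_9, 1 / 3)
  expect_equal(s$frac_above_5, 2 / 3)
  expect_equal(s$below_5, "c")
  expect_equal(s$mean, mean(c(0.95, 0.6, 0.4)))

  set.seed(8)
  for (trial in 1:20) {
    x <- setNames(runif(30), paste0("d", 1:30))
    s <- summarize_tm(x)
    # sorting-based recount
    xs <- sort(x)
    expect_equal(s$n_above_9, 30 - findInterval(0.9, xs))
    expect_equal(s$n_above_5, 30 - findInterval(0.5, xs))
  }
})

test_that("head-to-head comparisons list clear wins per side", {
  a <- c(d1 = 0.9, d2 = 0.5, d3 = 0.7)
  expect_equal(head_to_head(a, a)$a_better, character(0))

  b <- a; b["d2"] <- 0.35
  h <- head_to_head(a, b)
  expect_equal(h$a_better, "d2")
  expect_equal(h$b_better, character(0))

  set.seed(12)
  for (trial in 1:20) {
    x <- setNames(runif(15), paste0("d", 1:15))
    y <- setNames(runif(15), paste0("d", 1:15))
    h <- head_to_head(x, y)
    expect_equal(sort(h$a_better), sort(names(x)[x - y > 0.1]))
    expect_equal(sort(h$b_better), sort(names(x)[y - x > 0.1]))
  }
  expect_error(head_to_head(c(a = 1), c(b = 1)), "no shared")
})

test_that("one-sided signed-rank test matches exact enumeration", {
  a <- 1:10 + 0.5
  b <- as.numeric(1:10)
  # constant positive shift: the most extreme of 2^10 sign patterns
  expect_equal(paired_onesided_test(a, b), 1 / 2^10)

  # pairing invariance
  set.seed(14)
  x <- runif(12); y <- runif(12)
  perm <- sample(12)
  expect_equal(paired_onesided_test(x, y),
               paired_onesided_test(x[perm], y[perm]))

  expect_error(paired_onesided_test(x, x), "zero")
})
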