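test_that("normality gating picks Pearson only when both vectors pass", {
  set.seed(51)
  x <- rnorm(50); y <- rnorm(50)
  m <- choose_method(x, y)
  # oracle: the gate is exactly the two Shapiro-Wilk tests
  expect_identical(as.character(m),
                   if (shapiro.test(x)$p.value > 0.05 &&
                       shapiro.test(y)$p.value > 0.05) "pearson" else "spearman")
  expect_identical(as.character(m), "pearson")

  xo <- c(rnorm(29), 40)  # one extreme heavy-tail outlier
  expect_lt(shapiro.test(xo)$p.value, 0.05)
  expect_identical(as.character(choose_method(xo, rnorm(30))), "spearman")
})

test_that("the gate needs at least four observations and warns on constants", {
  expect_error(choose_method(1:3, 1:3), "at least 4")
  expect_warning(m <- choose_method(rep(1, 10), rnorm(10)), "constant")
  expect_identical(as.character(m), "spearman")
})

test_that("perfectly correlated pairs give unit coefficients with labels", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 9.3)
  up <- correlate_pair(x, x, "pearson")
  expect_equal(up$coefficient, 1)
  expect_identical(up$strength, "strong")
  expect_identical(up$sign, "+")
  dn <- correlate_pair(x, -x, "pearson")
  expect_equal(dn$coefficient, -1)
  expect_identical(dn$sign, "-")
})

test_that("coefficients match direct formula evaluation on a fixed table", {
  x <- c(2.1, 3.5, 1.2, 4.8, 3.3, 2.9, 5.1, 0.7, 4.2, 3.8)
  y <- c(1.0, 2.2, 1.5, 3.9, 2.0, 3.1, 4.0, 1.1, 2.8, 3.5)
  # brute-force product-moment formula
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate_pair(x, y, "pearson")$coefficient, r_oracle,
               tolerance = 1e-12)
  # Spearman as Pearson on mid-ranks
  rs_oracle <- sum((rank(x) - 5.5) * (rank(y) - 5.5)) /
    sqrt(sum((rank(x) - 5.5)^2) * sum((rank(y) - 5.5)^2))
  expect_equal(correlate_pair(x, y, "spearman")$coefficient, rs_oracle,
               tolerance = 1e-12)
})

test_that("degenerate variance is an error for Pearson, NA for Spearman", {
  expect_error(correlate_pair(rep(1, 5), 1:5, "pearson"), "zero variance")
  expect_warning(res <- correlate_pair(rep(1, 5), 1:5, "spearman"),
                 "zero variance")
  expect_true(is.na(res$coefficient))
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(52)
  x <- rnorm(40); y <- 0.6 * x + rnorm(40, sd = 0.5)
  base <- correlate_pair(x, y, "spearman")$coefficient
  expect_equal(correlate_pair(exp(x), y, "spearman")$coefficient, base)
  expect_equal(correlate_pair(x, y^3 + 5 * y, "spearman")$coefficient, base)
})

test_that("strength bands reproduce the printed table labels", {
  expect_identical(classify_strength(0.448), "moderate")
  expect_identical(classify_strength(-0.836), "strong")
  expect_identical(classify_strength(0.06), "small")
  # band edges: [0, .3) small, [.3, .5) moderate, [.5, 1] strong
  expect_identical(classify_strength(c(0, 0.299, 0.3, 0.499, 0.5, 1)),
                   c("small", "small", "moderate", "moderate",
                     "strong", "strong"))
  expect_error(classify_strength(1.2), "at most 1")
})

test_that("complete separation gives U = 0 with the published mean ranks", {
  a <- c(4.0, 4.2, 4.5)           # every intermediate above every novice
  b <- c(1.5, 1.8, 2.0, 2.2, 2.4, 2.6, 2.8, 3.0)
  m <- mann_whitney(a, b)
  expect_equal(m$U, 0)
  expect_equal(m$mean_rank_1, 10.0)
  expect_equal(m$mean_rank_2, 4.5)
  expect_lt(m$p, 0.05)
})

test_that("full ties give the symmetric U and equal mean ranks", {
  m <- mann_whitney(1, 1)
  expect_equal(m$U, 0.5)
  expect_equal(m$mean_rank_1, m$mean_rank_2)
  expect_equal(m$p, 1)
})

test_that("small-sample p matches the exact distribution", {
  set.seed(53)
  for (i in 1:10) {
    a <- sample(1:20, 3, replace = TRUE)
    b <- sample(1:20, 4, replace = TRUE)
    got <- mann_whitney(a, b, exact = "always")
    if (!anyDuplicated(c(a, b))) {
      # independent cross-check for tie-free data
      expect_equal(got$p, wilcox.test(a, b, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
    # exhaustive permutation oracle over all C(7,3) assignments
    pooled <- c(a, b)
    rk <- rank(pooled)
    us <- apply(combn(7, 3), 2, function(idx) {
      u1 <- sum(rk[idx]) - 6
      min(u1, 12 - u1)
    })
    expect_equal(got$p, mean(us <= got$U + 1e-9), tolerance = 1e-12)
  }
})

test_that("the U statistic respects its invariances", {
  set.seed(54)
  a <- rnorm(6); b <- rnorm(9)
  m <- mann_whitney(a, b)
  swapped <- mann_whitney(b, a)
  expect_equal(m$U, swapped$U)
  expect_equal(m$p, swapped$p)
  expect_equal(m$mean_rank_1, swapped$mean_rank_2)
  mono <- mann_whitney(exp(a), exp(b))
  expect_equal(m$U, mono$U)
  expect_equal(m$p, mono$p)
  expect_true(m$U >= 0 && m$U <= length(a) * length(b))
})

test_that("the battery mirrors the table structure and its labels recompute", {
  set.seed(55)
  spec <- fast_spec(seed = 55)
  spec$n_intermediate <- 4; spec$n_novice <- 4
  cohort <- simulate_cohort(spec)
  tab <- run_correlation_battery(cohort$planted, unit = "task")
  expect_equal(nrow(tab), 6L)
  expect_setequal(unique(tab$pair), c("FD-SSD", "FN-SSN", "SN-SSM"))
  ok <- !is.na(tab$coefficient)
  expect_identical(tab$strength[ok], classify_strength(tab$coefficient[ok]))
  expect_identical(tab$sign[ok], ifelse(tab$coefficient[ok] < 0, "-", "+"))

  # two identical groups give identical rows
  recs <- cohort$planted
  recs$group <- "g1"
  recs2 <- recs
  recs2$group <- "g2"
  both <- run_correlation_battery(rbind(recs, recs2), unit = "task")
  expect_equal(both$coefficient[both$group == "g1"],
               both$coefficient[both$group == "g2"])
})

test_that("a group with a constant metric is reported via spearman with warning", {
  recs <- data.frame(participant = rep(c("a", "b"), each = 5),
                     scenario = "S1", task = rep(0:4, 2),
                     FD = rnorm(10, 400, 30), FN = 5L, SN = rnorm(10, 4),
                     SSD = rnorm(10, 400, 30), SSN = rnorm(10, 10),
                     SSM = rnorm(10, 4), group = "novice")
  w <- capture_warnings(tab <- run_correlation_battery(recs, unit = "task"))
  expect_match(w, "constant", all = FALSE)
  expect_match(w, "zero variance", all = FALSE)
  row <- tab[tab$pair == "FN-SSN", ]
  expect_identical(row$method, "spearman")
  expect_true(is.na(row$coefficient))
})

test_that("outlier flagging reports extreme z-scores without removal", {
  x <- c(rnorm(30), 25)
  expect_identical(flag_outliers(x), 31L)
  expect_identical(flag_outliers(rep(3, 10)), integer())
})
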