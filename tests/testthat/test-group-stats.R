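mk_table <- function(cells, minute = 5) {
  ## cells: named list "genotype|mosm" -> numeric vector
  do.call(rbind, lapply(names(cells), function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    v <- cells[[k]]
    tibble::tibble(animal_id = paste0(k, "_", seq_along(v)),
                   genotype = parts[1],
                   osmolarity_mosm = as.numeric(parts[2]),
                   minute = minute, turns_per_min = v)
  }))
}

test_that("per-cell summaries report mean, SEM = SD/sqrt(n), and n", {
  tab <- mk_table(list("WT|150" = c(10, 12, 14), "WT|400" = c(30, 30, 30),
                       "mut|150" = 7))
  s <- suppressWarnings(summarize_rates(tab)) # mut x 400 cell is empty
  wt150 <- s[s$genotype == "WT" & s$osmolarity_mosm == "150", ]
  expect_equal(wt150$mean, 12)
  expect_equal(wt150$sem, 2 / sqrt(3)) # 1.1547
  expect_equal(wt150$n, 3L)
  ## constant cell: SEM = 0; singleton cell: SEM undefined
  expect_equal(s$sem[s$genotype == "WT" & s$osmolarity_mosm == "400"], 0)
  expect_true(is.na(s$sem[s$genotype == "mut"]))
  expect_error(summarize_rates(tab, minute = 3), "minute 3")
})

test_that("empty design cells are omitted with a warning", {
  tab <- mk_table(list("WT|150" = c(1, 2), "WT|400" = c(3, 4),
                       "mut|150" = c(5, 6)))
  expect_warning(s <- summarize_rates(tab), "omitted")
  expect_equal(nrow(s), 3)
})

test_that("pooled t test matches its own summary-statistic form exactly", {
  set.seed(7)
  x <- rnorm(12, 20, 4); y <- rnorm(9, 16, 4)
  raw <- two_group_t(x, y)
  summ <- two_group_t_summary(mean(x), sd(x) / sqrt(12), 12,
                              mean(y), sd(y) / sqrt(9), 9)
  expect_identical(raw$t, summ$t)
  expect_identical(raw$p_value, summ$p_value)
  ## and agrees with the independent base implementation
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(raw$t, unname(ref$statistic))
  expect_equal(raw$p_value, ref$p.value)
  ## Welch flag
  expect_equal(two_group_t(x, y, welch = TRUE)$p_value,
               t.test(x, y)$p.value)
})

test_that("degenerate t-test inputs error or behave trivially", {
  expect_error(two_group_t(1, c(2, 3)), "n >= 2")
  expect_error(two_group_t(c(1, 1), c(1, 1)), "pooled variance")
  same <- c(4, 5, 6)
  res <- two_group_t(same, same)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
})

test_that("the droplet-volume check statistic reproduces from summaries", {
  ## 23.6 +/- 0.31 vs 23.2 +/- 0.35 ul at n = 8: p ~ 0.4 (the published
  ## 0.38 used unrounded raw data)
  res <- two_group_t_summary(23.6, 0.31, 8, 23.2, 0.35, 8)
  expect_equal(res$df, 14)
  expect_equal(res$p_value, 0.38, tolerance = 0.05 / 0.38)
  expect_equal(res$p_value, 0.4065, tolerance = 1e-3)
})

test_that("t test holds its nominal type-I error under the null", {
  ## 10,000 null replicates at n = 16 per group, vectorized
  set.seed(101)
  n <- 16; reps <- 10000
  x <- matrix(rnorm(n * reps), n)
  y <- matrix(rnorm(n * reps), n)
  mx <- colMeans(x); my <- colMeans(y)
  vx <- colSums((x - rep(mx, each = n))^2) / (n - 1)
  vy <- colSums((y - rep(my, each = n))^2) / (n - 1)
  tstat <- (mx - my) / sqrt((vx + vy) / n)
  p <- 2 * pt(-abs(tstat), 2 * n - 2)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
  ## spot-check the vectorized oracle against the package on one column
  expect_equal(two_group_t(x[, 1], y[, 1])$p_value, p[1])
})

test_that("interaction ANOVA matches a brute-force balanced computation", {
  set.seed(8)
  k <- 6
  tab <- mk_table(list("WT|150" = rnorm(k, 10), "WT|400" = rnorm(k, 30),
                       "mut|150" = rnorm(k, 10), "mut|400" = rnorm(k, 18)))
  res <- interaction_anova(tab)
  ## brute force from cell means (balanced two-way layout)
  y <- tab$turns_per_min
  A <- factor(tab$genotype); B <- factor(tab$osmolarity_mosm)
  cell <- tapply(y, list(A, B), mean)
  gm <- mean(y)
  ssA <- 2 * k * sum((rowMeans(cell) - gm)^2)
  ssB <- 2 * k * sum((colMeans(cell) - gm)^2)
  ssAB <- k * sum((cell - outer(rowMeans(cell) - gm, colMeans(cell) - gm,
                                "+") - gm)^2)
  sse <- sum((y - cell[cbind(A, B)])^2)
  int <- res[res$term == "genotype:osmolarity_mosm", ]
  expect_equal(int$sumsq, ssAB, tolerance = 1e-10)
  expect_equal(res$sumsq[res$term == "genotype"], ssA, tolerance = 1e-10)
  expect_equal(res$sumsq[res$term == "osmolarity_mosm"], ssB,
               tolerance = 1e-10)
  f_ref <- (ssAB / 1) / (sse / (4 * k - 4))
  expect_equal(int$statistic, f_ref, tolerance = 1e-10)
  expect_equal(int$p_value, pf(f_ref, 1, 4 * k - 4, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("a constructed interaction dominates as noise vanishes", {
  f_at <- function(eps) {
    set.seed(9)
    tab <- mk_table(list(
      "WT|150" = rnorm(4, 0, eps), "WT|400" = rnorm(4, 0, eps),
      "mut|150" = rnorm(4, 0, eps), "mut|400" = rnorm(4, 5, eps)))
    res <- interaction_anova(tab)
    res$statistic[res$term == "genotype:osmolarity_mosm"]
  }
  fs <- vapply(c(1, 0.1, 0.01), f_at, numeric(1))
  expect_true(all(diff(fs) > 0))
  expect_gt(fs[3], 1e4)
})

test_that("interaction ANOVA rejects incomplete designs", {
  tab <- mk_table(list("WT|150" = c(1, 2), "WT|400" = c(3, 4),
                       "mut|150" = c(5, 6)))
  expect_error(interaction_anova(tab), "missing design cell")
  tab2 <- mk_table(list("WT|150" = c(1, 2), "WT|400" = c(3, 4),
                        "mut|150" = c(5, 6), "mut|400" = 7))
  expect_error(interaction_anova(tab2), "n >= 2")
})

test_that("Type II and sequential sums of squares agree when balanced", {
  set.seed(10)
  tab <- mk_table(list("WT|150" = rnorm(8, 10), "WT|400" = rnorm(8, 25),
                       "mut|150" = rnorm(8, 12), "mut|400" = rnorm(8, 20)))
  res <- interaction_anova(tab)
  fit <- lm(turns_per_min ~ factor(genotype) * factor(osmolarity_mosm),
            data = tab)
  seq_ss <- anova(fit)
  expect_equal(res$sumsq[1:3], seq_ss$`Sum Sq`[1:3], tolerance = 1e-10)
})

test_that("interaction test holds its nominal size on additive data", {
  ## additive effects only (no interaction); unbalanced cells like the
  ## published designs
  set.seed(11)
  reps <- 400
  rej <- vapply(seq_len(reps), function(r) {
    ns <- c(16, 14, 15, 16)
    g <- rep(c("WT", "WT", "mut", "mut"), ns)
    o <- rep(c(150, 400, 150, 400), ns)
    mu <- 10 + 15 * (o == 400) + 2 * (g == "mut")
    tab <- tibble::tibble(genotype = g, osmolarity_mosm = o, minute = 5,
                          turns_per_min = mu + rnorm(sum(ns), 0, 4))
    res <- interaction_anova(tab)
    res$p_value[res$term == "genotype:osmolarity_mosm"] < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.025)
})
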