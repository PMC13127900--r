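# Mann-Whitney U with exact small-sample route, Bonferroni bookkeeping and
# cohort summaries.

# independent oracle: U by pairwise counting, p by enumerating all group
# assignments of the pooled values
mw_oracle <- function(x, y) {
  u_pair <- function(a, b)
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(pooled), nx)
  us <- apply(idx, 2, function(ii) u_pair(pooled[ii], pooled[-ii]))
  u <- u_pair(x, y)
  mu <- nx * (length(pooled) - nx) / 2
  list(U = u, p = mean(abs(us - mu) >= abs(u - mu) - 1e-12))
}

test_that("frozen example: {1,2,3} vs {4,5,6} gives U = 0, exact p = 0.1", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)
})

test_that("identical groups give p = 1", {
  mw <- mann_whitney_u(c(2, 2, 2), c(2, 2, 2))
  expect_equal(mw$p_value, 1)
  expect_equal(mw$U, 4.5)   # midranks: nx*ny/2
})

test_that("exact route agrees with enumeration oracle (ties included)", {
  uterodyn:::with_seed(99, {
    for (rep in 1:60) {
      nx <- sample(1:6, 1); ny <- sample(1:6, 1)
      x <- sample(1:8, nx, replace = TRUE)
      y <- sample(1:8, ny, replace = TRUE)
      got <- mann_whitney_u(x, y)
      ora <- mw_oracle(x, y)
      expect_equal(got$U, ora$U)
      expect_equal(got$p_value, ora$p)
    }
  })
})

test_that("U(x,y) + U(y,x) = nx * ny under the midrank convention", {
  uterodyn:::with_seed(5, {
    for (rep in 1:20) {
      x <- sample(1:5, sample(2:7, 1), replace = TRUE)
      y <- sample(1:5, sample(2:7, 1), replace = TRUE)
      expect_equal(mann_whitney_u(x, y, exact = FALSE)$U +
                     mann_whitney_u(y, x, exact = FALSE)$U,
                   length(x) * length(y))
    }
  })
})

test_that("approximate route tracks stats::wilcox.test", {
  uterodyn:::with_seed(21, {
    x <- rnorm(25); y <- rnorm(30, 0.5)
    got <- mann_whitney_u(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                               exact = FALSE))
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  })
})

test_that("five comparisons at alpha 0.01 give the 0.002 threshold", {
  ev <- data.frame(
    label = rep(c("placental", "uterine"), each = 6),
    halfmax_duration_min = c(2:7, 1:6) / 2,
    max_volume_drop_pct = c(15:20, 11:16),
    dr2s_change_per_ms = rnorm(12, 0.003, 0.001),
    max_wall_area_change_pct = c(rnorm(6, 4), rnorm(6, -1)),
    max_sphericity_change = c(rnorm(6, 0.01, 0.002), rnorm(6, -0.005, 0.002)))
  cmp <- compare_groups(ev)
  expect_equal(nrow(cmp), 5)
  expect_true(all(cmp$alpha_bonferroni == 0.01 / 5))
  expect_true(all(cmp$alpha_bonferroni == 0.002))
  expect_identical(cmp$significant, cmp$p_value < 0.002)
  expect_true(all(cmp$n_placental == 6 & cmp$n_uterine == 6))
})

test_that("empty groups are skipped with a notice", {
  ev <- data.frame(label = rep("placental", 4),
                   max_volume_drop_pct = 11:14,
                   max_sphericity_change = rep(0.01, 4))
  expect_message(cmp <- compare_groups(ev, features = "max_volume_drop_pct"),
                 "empty group")
  expect_null(cmp)
})

test_that("cohort summary: single session and quartile convention", {
  one <- list(list(events = data.frame(max_volume_drop_pct = c(12, 15, 20),
                                       halfmax_duration_min = c(1, 2, 3)),
                   duration_s = 1800))
  sm <- summarize_cohort(one, features = c("halfmax_duration_min",
                                           "max_volume_drop_pct"))
  expect_equal(unname(sm$rates$all), c(6, 6, 6))
  # rates {2,4,6,8}: type-7 quartiles 3.5 / 6.5, median 5
  four <- lapply(c(1, 2, 3, 4), function(k)
    list(events = data.frame(max_volume_drop_pct = rep(12, k),
                             halfmax_duration_min = rep(1, k)),
         duration_s = 1800))
  sm4 <- summarize_cohort(four, features = "max_volume_drop_pct")
  expect_equal(unname(sm4$rates$all), c(5, 3.5, 6.5),
               tolerance = 1e-12)
  # empty gated subset produces an NA row with a notice
  expect_message(
    sm0 <- summarize_cohort(list(list(
      events = data.frame(max_volume_drop_pct = c(3, 4),
                          halfmax_duration_min = c(1, 1)),
      duration_s = 1800)), features = "halfmax_duration_min"),
    "no events")
  expect_true(is.na(sm0$features$median_gated))
})

test_that("Bonferroni significance flag is monotone in p", {
  ps <- c(0.0001, 0.001, 0.0019, 0.0021, 0.5)
  flags <- ps < 0.002
  expect_true(all(diff(as.integer(flags)) <= 0))
})
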