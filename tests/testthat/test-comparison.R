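# brute-force average ranks, written out from the counting definition so
# the oracle shares no code with stats::rank
brute_ranks <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

brute_pearson <- function(a, b) {
  am <- a - mean(a)
  bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

test_that("Bland-Altman on differences {-2, 0, 2} gives bias 0 and LOA +/- 3.92", {
  res <- bland_altman(c(-2, 0, 2), c(0, 0, 0))
  expect_equal(res$bias, 0)
  expect_equal(res$sd_diff, 2)
  expect_equal(res$loa_low, -3.92)
  expect_equal(res$loa_high, 3.92)
  # normal-theory CIs: bias +/- t * sd/sqrt(n), LOA +/- t * sd * sqrt(3/n)
  tq <- stats::qt(0.975, 2)
  expect_equal(res$bias_ci, c(-tq * 2 / sqrt(3), tq * 2 / sqrt(3)))
  expect_equal(res$loa_high_ci, 3.92 + c(-1, 1) * tq * 2 * 1)
})

test_that("identical and constant-offset score vectors behave trivially", {
  a <- c(50, 60, 70, 80)
  res0 <- bland_altman(a, a)
  expect_equal(res0$bias, 0)
  expect_equal(c(res0$loa_low, res0$loa_high), c(0, 0))
  res1 <- bland_altman(a, a - 1)
  expect_equal(res1$bias, 1)
  expect_equal(c(res1$loa_low, res1$loa_high), c(1, 1))
})

test_that("agreement is antisymmetric and shift-invariant", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    a <- stats::rnorm(n, 50, 10)
    b <- a + stats::rnorm(n, -1, 2)
    ab <- bland_altman(a, b)
    ba <- bland_altman(b, a)
    expect_equal(ba$bias, -ab$bias)
    expect_equal(ba$loa_low, -ab$loa_high)
    expect_equal(ba$loa_high, -ab$loa_low)
    k <- stats::runif(1, -20, 20)
    shifted <- bland_altman(a + k, b + k)
    expect_equal(shifted$bias, ab$bias)
    expect_equal(shifted$loa_low, ab$loa_low)
    expect_equal(shifted$loa_high, ab$loa_high)
  }
})

test_that("too few pairs raise an insufficient-data error", {
  expect_error(bland_altman(1, 1), class = "mhei_insufficient_data_error")
})

test_that("Spearman equals Pearson on brute-force average ranks", {
  vectors <- list(
    list(a = c(5, 5, 0, 10, 5), b = c(10, 5, 0, 10, 0)),
    list(a = c(0, 0, 0, 5, 5, 10, 10, 10), b = c(1, 2, 2, 2, 3, 3, 9, 9)),
    list(a = c(3, 1, 4, 1, 5), b = c(2, 7, 1, 8, 2)),
    list(a = c(2, 2, 2, 3), b = c(1, 1, 4, 4))
  )
  for (v in vectors) {
    expected <- brute_pearson(brute_ranks(v$a), brute_ranks(v$b))
    sa <- data.frame(subject_id = seq_along(v$a), total_fruits = v$a,
                     total = v$a)
    sb <- data.frame(subject_id = seq_along(v$b), total_fruits = v$b,
                     total = v$b)
    cors <- score_correlations(paired_scores(sa, sb))
    expect_equal(cors$spearman[["total_fruits"]], expected, tolerance = 1e-12)
  }
})

test_that("Pearson on totals detects exact linear relations", {
  a <- data.frame(subject_id = 1:5, total = c(40, 50, 55, 70, 90))
  up <- a
  up$total <- 2 * a$total + 3
  down <- a
  down$total <- -a$total
  expect_equal(score_correlations(paired_scores(a, up))$pearson_total, 1)
  expect_equal(score_correlations(paired_scores(a, down))$pearson_total, -1)
})

test_that("zero variance yields NA correlations with a flag, not an error", {
  a <- data.frame(subject_id = 1:4, total = rep(50, 4),
                  sodium = c(1, 2, 3, 4))
  b <- data.frame(subject_id = 1:4, total = c(48, 51, 50, 52),
                  sodium = rep(10, 4))
  cors <- score_correlations(paired_scores(a, b))
  expect_true(is.na(cors$pearson_total))
  expect_true(is.na(cors$spearman[["sodium"]]))
  expect_setequal(attr(cors, "zero_variance"), c("total", "sodium"))
})

test_that("subject mismatch in pairing names the unmatched ids", {
  a <- data.frame(subject_id = c("s1", "s2"), total = c(1, 2))
  b <- data.frame(subject_id = c("s2", "s3"), total = c(1, 2))
  err <- expect_error(paired_scores(a, b), class = "mhei_pairing_error")
  expect_match(conditionMessage(err), "s1")
  expect_match(conditionMessage(err), "s3")
})

test_that("summaries use sample SD and type-7 IQR", {
  constant <- data.frame(subject_id = 1:5, total = rep(42, 5))
  s <- summarize_scores(constant)
  expect_equal(s$sd, 0)
  expect_equal(s$iqr, 0)
  three <- data.frame(subject_id = 1:3, total = c(40, 50, 60))
  s3 <- summarize_scores(three)
  expect_equal(s3$mean, 50)
  expect_equal(s3$median, 50)
  expect_equal(s3$sd, 10)
  expect_equal(s3$iqr, 10)  # type-7 quartiles 45 and 55
})

test_that("cohort summaries match the generating distribution", {
  set.seed(77)
  n <- 4000
  x <- stats::rnorm(n, mean = 52, sd = 13)
  s <- summarize_scores(data.frame(subject_id = seq_len(n), total = x))
  expect_equal(s$mean, 52, tolerance = 0.03)
  expect_equal(s$sd, 13, tolerance = 0.03)
  expect_equal(s$median, 52, tolerance = 0.03)
  expect_equal(s$iqr, 2 * stats::qnorm(0.75) * 13, tolerance = 0.05)
})

test_that("the Bland-Altman plot writes an image and a CSV of plotted values", {
  set.seed(5)
  a <- data.frame(subject_id = 1:30, total = stats::rnorm(30, 50, 10))
  b <- a
  b$total <- a$total + stats::rnorm(30, 0, 1)
  paired <- paired_scores(a, b)
  path <- file.path(withr::local_tempdir(), "ba.png")
  bland_altman_plot(paired, path = path)
  expect_true(file.exists(path))
  csv <- utils::read.csv(sub("png$", "csv", path))
  expect_identical(nrow(csv), 30L)
  expect_equal(csv$difference, a$total - b$total, tolerance = 1e-9)
})
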