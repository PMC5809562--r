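test_that("chi-square statistic matches hand-computed tables", {
  # maximally heterogeneous 2x2: pooled proportions (.5,.5), each cell 5
  res <- chisq_participant_heterogeneity(matrix(c(10, 0, 0, 10), 2,
                                                byrow = TRUE),
                                         tree = c("t", "t"))
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1L)
  # identical rows: no heterogeneity at all
  res0 <- chisq_participant_heterogeneity(matrix(5, 2, 2),
                                          tree = c("t", "t"))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
})

test_that("degrees of freedom follow (P-1) * sum(K_t - 1)", {
  m <- htsm_restricted()
  sim <- gen_trait_mpt(24, c(E = 16, U = 16, N = 32),
                       trait_pop_spec(c(a = 0.3, b = -0.1, d1 = 0.6,
                                        D1 = 0.5), 0.5),
                       m, seed = 8)
  res <- chisq_participant_heterogeneity(sim$data)
  expect_equal(res$df, 138L)   # 23 participants x 3 trees x 2 free categories
})

test_that("chi-square statistic is invariant to row and tree order", {
  set.seed(2)
  counts <- matrix(rpois(8 * 6, 20), 8, 6)
  tree <- c("a", "a", "a", "b", "b", "b")
  r1 <- chisq_participant_heterogeneity(counts, tree)
  r2 <- chisq_participant_heterogeneity(counts[sample(8), ], tree)
  ord <- c(4:6, 1:3)
  r3 <- chisq_participant_heterogeneity(counts[, ord], tree[ord])
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$statistic, r3$statistic)
})

test_that("zero pooled categories are dropped with a warning", {
  counts <- matrix(c(5, 0, 5, 5, 0, 5), 2, byrow = TRUE)
  expect_warning(res <- chisq_participant_heterogeneity(counts,
                                                        tree = rep("t", 3)),
                 "zero-count")
  expect_equal(res$df, 1L)
})

test_that("permutation test reproduces the observed statistic and seed", {
  set.seed(5)
  rec <- expand.grid(participant = 1:6, item = 1:10)
  rec$response <- sample(c("h", "m"), nrow(rec), replace = TRUE)
  long <- as_mpt_long(rec, list(t1 = c("h", "m")))
  r1 <- permutation_participant_heterogeneity(long, n_perm = 50, seed = 9)
  r2 <- permutation_participant_heterogeneity(long, n_perm = 50, seed = 9)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$null_statistics, r2$null_statistics)
  # observed statistic equals the chi-square statistic on the table
  tab <- table(rec$participant, rec$response)
  chq <- chisq_participant_heterogeneity(matrix(tab, nrow(tab)),
                                         tree = rep("t1", ncol(tab)))
  expect_equal(r1$statistic, chq$statistic)
  # p in (0, 1] with the add-one estimator
  expect_gt(r1$p_value, 0)
  expect_lte(r1$p_value, 1)
})

test_that("permutation test holds its size under homogeneity", {
  m <- toy_model()
  n_sim <- 60
  rejections <- 0L
  for (i in seq_len(n_sim)) {
    theta <- matrix(c(0.6, 0.4), 1, dimnames = list(NULL, c("D", "g")))
    # all participants share one theta: homogeneous null is true
    probs <- category_probabilities(theta, m)[1, ]
    rec <- with_seed(1000 + i, {
      g <- expand.grid(participant = 1:20, item = 1:30)
      g$response <- sample(c("h", "m"), nrow(g), replace = TRUE,
                           prob = probs)
      g
    })
    long <- as_mpt_long(rec, list(t1 = c("h", "m")))
    r <- permutation_participant_heterogeneity(long, n_perm = 60,
                                               seed = 2000 + i)
    if (r$p_value <= 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_sim
  expect_gte(rate, 0.0)
  expect_lte(rate, 0.12)
})

test_that("permutation test detects strong participant heterogeneity", {
  # two participant types with opposite response tendencies
  rec <- expand.grid(participant = 1:10, item = 1:40)
  rec$response <- with_seed(77, ifelse(
    rec$participant <= 5,
    sample(c("h", "m"), nrow(rec), TRUE, prob = c(0.9, 0.1)),
    sample(c("h", "m"), nrow(rec), TRUE, prob = c(0.2, 0.8))))
  long <- as_mpt_long(rec, list(t1 = c("h", "m")))
  r <- permutation_participant_heterogeneity(long, n_perm = 200, seed = 3)
  expect_lt(r$p_value, 0.01)
})

test_that("long-format data validates categories and duplicates", {
  rec <- data.frame(participant = c(1, 1), item = c(1, 1),
                    response = c("h", "m"))
  long <- as_mpt_long(rec, list(t1 = c("h", "m")))
  expect_error(permutation_participant_heterogeneity(long, 10, 1),
               "at most once")
  expect_error(as_mpt_long(data.frame(p = 1, i = 1, r = "x"),
                           list(t1 = c("h", "m"))),
               "not covered")
})

test_that("frequency summaries return boxplot data and means", {
  counts <- matrix(c(2, 8, 2, 8, 2, 8), 3, byrow = TRUE,
                   dimnames = list(NULL, c("h", "m")))
  m <- toy_model()
  d <- as_mpt_data(counts, m)
  fs <- frequency_summary(d)
  expect_equal(fs$mean, c(2, 8))
  expect_equal(fs$q1, fs$q3)  # identical rows: zero IQR
  rel <- frequency_summary(d, relative = TRUE)
  expect_equal(sum(rel$mean), 1)  # relative means per tree sum to one
  # means equal column averages on a 3-participant table
  counts2 <- matrix(c(1, 9, 4, 6, 7, 3), 3, byrow = TRUE,
                    dimnames = list(NULL, c("h", "m")))
  fs2 <- frequency_summary(as_mpt_data(counts2, m))
  expect_equal(fs2$mean, c(4, 6))
})
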