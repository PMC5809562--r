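test_that("EQN parsing reads trees, categories, branches and parameters", {
  m <- toy_model()
  expect_s3_class(m, "mpt_model")
  expect_equal(m$trees, "t1")
  expect_equal(m$categories$category, c("h", "m"))
  expect_equal(length(m$branches), 3L)
  expect_equal(m$params, c("D", "g"))

  full <- htsm_model()
  expect_equal(length(full$trees), 3L)
  expect_equal(nrow(full$categories), 9L)
  expect_equal(length(full$params), 8L)
  expect_setequal(full$params, c("D1", "D2", "D3", "d1", "d2", "a", "b", "g"))
})

test_that("numeric constants and repeated factors accumulate correctly", {
  m <- parse_eqn(c("#", "t1 h 0.5*D*D", "t1 m 0.5", "t1 m (1-D)*D*(1-D)"))
  br <- m$branches[[1]]
  expect_equal(br$c, 0.5)
  expect_equal(br$a[["D"]], 2L)
  br3 <- m$branches[[3]]
  expect_equal(br3$b[["D"]], 2L)
  expect_equal(br3$a[["D"]], 1L)
  # evaluates like the polynomial written by hand
  th <- c(D = 0.3)
  expect_equal(branch_probability(th, br), 0.5 * 0.3^2)
  expect_equal(branch_probability(th, br3), 0.7^2 * 0.3)
})

test_that("malformed equations and duplicate categories are rejected", {
  expect_error(parse_eqn(c("#", "t1 h D+g")), "malformed")
  expect_error(parse_eqn(c("#", "t1 h")), "expected")
  expect_error(parse_eqn(c("#", "t1 h D", "t2 h g")), "appears in trees")
})

test_that("first line and #-comments are skipped, * optional at parens", {
  m <- parse_eqn(c("this is ignored even without #",
                   "# a comment", "",
                   "t1 h D", "t1 m (1-D)"))
  expect_equal(m$params, "D")
  m2 <- parse_eqn(c("#", "t1 h (1-D)(1-g)", "t1 m (1-D)"))
  # "(1-D)(1-g)" multiplies without explicit *
  expect_equal(m2$branches[[1]]$b, c(D = 1L, g = 1L))
})

test_that("restriction chains produce classes and constants", {
  r <- parse_restrictions(c("D1 = D2 = D3", "d1 = d2", "a = g"))
  expect_equal(length(r$equality_classes), 3L)
  expect_equal(length(r$constants), 0L)

  r2 <- parse_restrictions("g = 0.5")
  expect_equal(r2$constants, c(g = 0.5))

  # chain ending in a constant fixes every member
  r3 <- parse_restrictions("a = g = 0.5")
  expect_equal(sort(names(r3$constants)), c("a", "g"))
  expect_true(all(r3$constants == 0.5))

  expect_error(parse_restrictions("a = 0.5 = g"), "last element")
  expect_error(parse_restrictions(c("x = y"), model = toy_model()),
               "unknown parameter")
})

test_that("applying restrictions collapses the 2HTSM to 4 parameters", {
  r <- htsm_restricted()
  expect_equal(length(r$params), 4L)
  expect_setequal(r$params, c("D1", "d1", "a", "b"))
  # identity restriction changes nothing
  m <- toy_model()
  same <- apply_restrictions(m, parse_restrictions(character(0)))
  th <- theta_at(m, 0.37)
  expect_equal(category_probabilities(th, same),
               category_probabilities(th, m))
})

test_that("restricted model equals unrestricted model at mapped parameters", {
  full <- htsm_model()
  r <- htsm_restricted()
  set.seed(11)
  for (i in 1:20) {
    th_r <- setNames(runif(4, 0.05, 0.95), r$params)
    th_full <- c(D1 = th_r[["D1"]], D2 = th_r[["D1"]], D3 = th_r[["D1"]],
                 d1 = th_r[["d1"]], d2 = th_r[["d1"]],
                 a = th_r[["a"]], g = th_r[["a"]], b = th_r[["b"]])
    expect_equal(category_probabilities(th_r, r)[1, ],
                 category_probabilities(th_full, full)[1, ],
                 tolerance = 1e-12)
  }
})

test_that("constants fold into branch probabilities", {
  m <- toy_model()
  r <- apply_restrictions(m, "g = 0.5")
  expect_equal(r$params, "D")
  # h probability becomes D + 0.5 (1 - D)
  for (D in c(0.2, 0.7)) {
    p <- category_probabilities(c(D = D), r)
    expect_equal(unname(p[1, "h"]), D + 0.5 * (1 - D))
  }
  expect_error(apply_restrictions(m, c("D = 0.5", "g = 0.5")),
               "nothing left")
})

test_that("within-subjects replication suffixes labels per condition", {
  r <- htsm_restricted()
  ws <- within_subject_eqn(r, c("high", "low"), constant_params = c("a", "b"))
  expect_setequal(ws$params, c("D1_high", "D1_low", "d1_high", "d1_low",
                               "a", "b"))
  expect_equal(length(ws$trees), 6L)
  expect_equal(nrow(ws$categories), 18L)

  m <- toy_model()
  one <- within_subject_eqn(m, "x")
  expect_equal(one$params, c("D_x", "g_x"))
  th <- setNames(c(0.4, 0.6), one$params)
  expect_equal(unname(category_probabilities(th, one)[1, ]),
               unname(category_probabilities(c(D = 0.4, g = 0.6), m)[1, ]))

  t2 <- within_subject_eqn(m, c("1", "2"), constant_params = "g")
  expect_equal(length(t2$params), 3L)
  expect_error(within_subject_eqn(m, c("a", "a")), "distinct")
})

test_that("serialization round-trips to an equivalent model", {
  for (model in list(toy_model(), htsm_restricted(), htsm_model())) {
    m2 <- parse_eqn(write_eqn(model))
    set.seed(5)
    for (i in 1:100) {
      th <- setNames(runif(length(model$params)), model$params)
      expect_lt(max(abs(category_probabilities(th, model)[1, ] -
                        category_probabilities(th[m2$params], m2)[1, colnames(category_probabilities(th, model))])),
                1e-12)
    }
  }
})

test_that("category probabilities sum to one per tree at random theta", {
  set.seed(99)
  for (model in list(toy_model(), htsm_model(), htsm_restricted())) {
    th <- matrix(runif(30 * length(model$params)), 30,
                 dimnames = list(NULL, model$params))
    p <- category_probabilities(th, model)
    for (t in model$trees) {
      sums <- rowSums(p[, model$categories$tree == t, drop = FALSE])
      expect_lt(max(abs(sums - 1)), 1e-10)
    }
  }
})

test_that("validation reports simplex deviation and identifiability rank", {
  v <- validate_model(htsm_model(), n_random_theta = 8, seed = 3)
  expect_lt(max(v$max_sum_deviation), 1e-12)
  expect_lt(v$jacobian_rank, 8)    # saturated model is not identifiable
  expect_false(v$identifiable)

  v2 <- validate_model(htsm_restricted(), n_random_theta = 10, seed = 3)
  expect_equal(v2$jacobian_rank, 4)
  expect_true(v2$identifiable)
})
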