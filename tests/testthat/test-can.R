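test_that("CAN formulas evaluate exactly on the canonical cases", {
  # cells generated by the CNI forward equations at (0.3, 0.5, 0.4)
  expect_equal(can_parameters(c(0.51, 0.21, 0.86, 0.56)),
               c(C = 0.30, N = 0.35, A = 0.535))
  # pure consequentialist, pure deontologist, random responder
  expect_equal(can_parameters(c(1, 0, 1, 0)), c(C = 1, N = 0, A = 0.5))
  expect_equal(can_parameters(c(0, 0, 1, 1)), c(C = 0, N = 1, A = 0.5))
  expect_equal(can_parameters(c(0.5, 0.5, 0.5, 0.5)),
               c(C = 0, N = 0, A = 0.5))
  expect_error(can_parameters(c(1.2, 0, 0, 0)), "\\[0, 1\\]")
})

test_that("CAN scores are linear in the cell probabilities and in range", {
  set.seed(1)
  for (i in 1:20) {
    p <- runif(4)
    q <- runif(4)
    w <- runif(1)
    lhs <- can_parameters(w * p + (1 - w) * q)
    rhs <- w * can_parameters(p) + (1 - w) * can_parameters(q)
    expect_equal(lhs, rhs)
    x <- can_parameters(p)
    expect_lte(abs(x[["C"]]) + abs(x[["N"]]), 2)
    expect_gte(x[["A"]], 0)
    expect_lte(x[["A"]], 1)
  }
})

test_that("CAN recovers the generating structure of all three trees", {
  grid <- seq(0.1, 0.9, by = 0.2)
  for (a in grid) for (b in grid) for (ci in grid) {
    # CNI-generated cells: C comes back exactly, N is deflated by (1 - C),
    # and A - 0.5 = (1-C)(1-N)(0.5 - I)
    x <- can_parameters(cni_forward(c(a, b, ci)))
    expect_equal(x[["C"]], a)
    expect_equal(x[["N"]], (1 - a) * b)
    expect_equal(x[["A"]] - 0.5, (1 - a) * (1 - b) * (0.5 - ci))
    # DNA-generated cells: C = D(1-N), N = DN
    y <- can_parameters(dna_forward(c(a, b, ci)))
    expect_equal(y[["C"]], a * (1 - b))
    expect_equal(y[["N"]], a * b)
  }
})

test_that("group summaries report exact one-sample t statistics", {
  scores <- data.frame(C = c(0.1, 0.2, 0.3), N = c(0, 0, 0),
                       A = c(0.5, 0.5, 0.5))
  gs <- group_summary(scores)
  rC <- gs[gs$parameter == "C", ]
  expect_equal(rC$mean, 0.2)
  expect_equal(rC$sd, 0.1)
  expect_equal(rC$t, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(rC$df, 2L)
  expect_false(rC$degenerate)

  # zero-variance parameters are flagged, not reported with infinite t
  rN <- gs[gs$parameter == "N", ]
  rA <- gs[gs$parameter == "A", ]
  expect_true(rN$degenerate && rA$degenerate)
  expect_true(is.na(rN$t) && is.na(rA$t))
  expect_equal(rA$mean, 0.5)

  expect_error(group_summary(scores[1, ]), "at least 2")
})

test_that("classification follows the decision rules on the group means", {
  # consequence-sensitive, norm-insensitive, no action bias: pure morality
  set.seed(2)
  n <- 40
  scores <- data.frame(C = 0.3 + rnorm(n, 0, 0.05),
                       N = rnorm(n, 0, 0.05),
                       A = 0.5 + rnorm(n, 0, 0.05))
  cl <- classify_group(group_summary(scores))
  expect_equal(cl$consequence, "supporting")
  expect_equal(cl$norm, "insensitive")
  expect_equal(cl$overall, "neutral")
  expect_equal(cl$summary, "pure_morality")

  # nothing significant: random responding
  scores2 <- data.frame(C = rnorm(n, 0, 0.05), N = rnorm(n, 0, 0.05),
                        A = 0.5 + rnorm(n, 0, 0.05))
  cl2 <- classify_group(group_summary(scores2))
  expect_equal(cl2$summary, "random")

  # strong action preference forces a mixed profile
  scores3 <- data.frame(C = rnorm(n, 0, 0.05), N = -0.4 + rnorm(n, 0, 0.05),
                        A = 0.8 + rnorm(n, 0, 0.05))
  cl3 <- classify_group(group_summary(scores3))
  expect_equal(cl3$overall, "action_preference")
  expect_equal(cl3$norm, "opposing")
  expect_equal(cl3$summary, "mixed")
})

test_that("per-participant scores match the closed-form on each row", {
  set.seed(3)
  acts <- matrix(sample(0:6, 4 * 8, replace = TRUE), ncol = 4)
  bat <- make_battery(acts, k = 6L)
  s <- can_scores(bat)
  for (i in seq_len(nrow(s))) {
    p <- cell_probabilities(bat, s$participant[i])
    expect_equal(unlist(s[i, c("C", "N", "A")]),
                 can_parameters(p), ignore_attr = TRUE)
  }
})
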