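test_that("two-group t tests match the pooled-variance hand calculation", {
  scores <- data.frame(
    group = rep(c("g1", "g2"), each = 3),
    C = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
    N = rep(0.2, 6), A = rep(0.5, 6)
  )
  res <- compare_groups_can(scores)
  rC <- res[res$parameter == "C", ]
  expect_equal(rC$t, -3.674, tolerance = 1e-3)
  expect_equal(rC$df, 4)
  expect_equal(rC$d, -3.0, tolerance = 1e-12)

  # identical groups: no evidence of a difference anywhere
  same <- data.frame(group = rep(c("g1", "g2"), each = 3),
                     C = rep(c(0.1, 0.2, 0.3), 2),
                     N = rep(c(0.0, 0.1, 0.2), 2),
                     A = rep(c(0.4, 0.5, 0.6), 2))
  res0 <- compare_groups_can(same)
  expect_true(all(res0$t == 0 & res0$p_value == 1 & res0$d == 0))

  three <- rbind(scores, data.frame(group = "g3", C = 0.1, N = 0.1, A = 0.5))
  expect_error(compare_groups_can(three), "pairwise")
})

test_that("trait correlations behave at the exact, null and planted cases", {
  # trait an affine function of C: perfect correlation
  set.seed(4)
  scores <- data.frame(C = runif(30), N = runif(30), A = runif(30))
  scores$trait <- 2 * scores$C + 1
  res <- correlate_traits(scores)
  expect_equal(res$r[res$parameter == "C"], 1, tolerance = 1e-12)

  # independent trait: negligible correlations at n = 1000
  spec <- population_spec(1000, "cni", c(0.3, 0.5, 0.4), latent_sds = 0.5,
                          seed = 8)
  s <- can_scores(simulate_battery(spec))
  set.seed(9)
  s$trait <- rnorm(1000)
  res_null <- correlate_traits(s)
  expect_true(all(abs(res_null$r) < 0.1))

  # trait built from the latent norm sensitivity: strongly negative r for N
  spec2 <- population_spec(300, "cni", c(0.3, 0.5, 0.4), latent_sds = 0.8,
                           seed = 10)
  bat2 <- simulate_battery(spec2)
  lat <- attr(bat2, "latents")
  s2 <- can_scores(bat2)
  set.seed(11)
  s2$trait <- -lat$N[match(s2$participant, lat$participant)] +
    rnorm(300, 0, 0.2)
  res_planted <- correlate_traits(s2)
  rN <- res_planted[res_planted$parameter == "N", ]
  expect_lt(rN$r, -0.3)
  expect_lt(rN$p_value, 0.001)

  # degenerate inputs flagged, missing traits dropped listwise
  s3 <- data.frame(C = rep(0.2, 5), N = runif(5), A = runif(5),
                   trait = c(1, 2, 3, NA, 5))
  expect_message(res3 <- correlate_traits(s3), "dropping 1")
  expect_true(res3$degenerate[res3$parameter == "C"])
  expect_equal(res3$n, rep(4L, 3))
})

test_that("identity checks are exact on noise-free model-generated cells", {
  # CNI-generated battery at (0.3, 0.5, 0.4), exact counts (k = 100)
  bat <- exact_battery(cni_forward(c(0.3, 0.5, 0.4)), k = 100, n = 6)
  hc <- run_hypothesis_checks(bat, tolerance = 1e-3)
  expect_true(hc$evaluable)
  expect_true(hc$h1_pass)
  expect_true(hc$h2_pass)
  expect_false(hc$h3$boundary)
  expect_true(hc$h3$opposite_signs)  # I = 0.4 below 0.5, A = 0.535 above

  # DNA-generated battery: the identities still hold (C = D(1-N), N = DN)
  bat_dna <- exact_battery(dna_forward(c(0.8, 0.6, 0.5)), k = 50, n = 6)
  hc_dna <- run_hypothesis_checks(bat_dna, tolerance = 1e-3)
  expect_true(hc_dna$h1_pass)
  expect_true(hc_dna$h2_pass)

  # random responders sit exactly on the H3 boundary
  bat_rand <- exact_battery(c(0.5, 0.5, 0.5, 0.5), k = 6, n = 6)
  hc_rand <- run_hypothesis_checks(bat_rand, tolerance = 1e-3)
  expect_true(hc_rand$h3$boundary)
  expect_equal(hc_rand$can_means[["A"]], 0.5)
})

test_that("comparison report flags agreement between the two frameworks", {
  # groups differing only in latent norm sensitivity
  b1 <- simulate_battery(population_spec(200, "cni", c(0.3, 0.4, 0.4),
                                         seed = 14),
                         group = "low", id_prefix = "lo_")
  b2 <- simulate_battery(population_spec(200, "cni", c(0.3, 0.6, 0.4),
                                         seed = 15),
                         group = "high", id_prefix = "hi_")
  bat <- combine_batteries(b1, b2)
  rep1 <- build_comparison_report(bat)
  rN <- rep1$rows[rep1$rows$mpt_parameter == "N", ]
  expect_lt(rN$mpt_p, 0.001)
  expect_lt(rN$can_p, 0.001)
  expect_true(rN$agreement)
  expect_equal(rep1$rows$can_parameter, c("C", "N", "A"))

  # agreement flags are symmetric in the group labels
  swapped <- as.data.frame(bat)
  swapped$group <- ifelse(swapped$group == "low", "high", "low")
  rep2 <- build_comparison_report(as_battery(swapped))
  expect_equal(rep1$rows$agreement, rep2$rows$agreement)
  expect_equal(rep1$rows$delta_g2, rep2$rows$delta_g2, tolerance = 1e-6)

  expect_error(build_comparison_report(b1), "two groups")
})
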