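test_that("paired tables count frame-to-frame transitions", {
  resp <- data.frame(
    participant_id = rep(c("a", "b", "c"), each = 2),
    country = "UK",
    frame = rep(c("UNFRAMED", "FAMILY_PASSENGER"), 3),
    choice = c("MOST", "OCCUPANTS", "MOST", "OCCUPANTS", "RANDOM", "RANDOM"))
  tab <- build_paired_table(resp, "UNFRAMED", "FAMILY_PASSENGER")
  expect_equal(sum(tab), 3)
  expect_equal(tab["MOST", "OCCUPANTS"], 2)
  expect_equal(tab["RANDOM", "RANDOM"], 1)
  # unchanged respondents sit on the diagonal
  same <- resp
  same$choice <- rep(c("MOST", "PEDESTRIANS", "RANDOM"), each = 2)
  tab2 <- build_paired_table(same, "UNFRAMED", "FAMILY_PASSENGER")
  expect_equal(sum(diag(tab2)), 3)
  expect_equal(sum(tab2) - sum(diag(tab2)), 0)
  # a participant missing one frame is excluded
  expect_message(
    tab3 <- build_paired_table(resp[-2, ], "UNFRAMED", "FAMILY_PASSENGER"),
    "excluded 1")
  expect_equal(sum(tab3), 2)
})

test_that("the symmetry statistic matches its formula and McNemar at k = 2", {
  tab22 <- matrix(c(5, 2, 6, 9), 2, 2)  # n_12 = 6, n_21 = 2
  bt <- bowker_test(tab22)
  expect_equal(bt$statistic, (6 - 2)^2 / 8)
  expect_equal(bt$df, 1L)
  mc <- mcnemar.test(tab22, correct = FALSE)
  expect_equal(bt$statistic, unname(mc$statistic))
  expect_equal(bt$p_value, mc$p.value)
  # symmetric tables are a perfect null
  sym <- matrix(c(4, 3, 7, 3, 5, 2, 7, 2, 6), 3, 3)
  bs <- bowker_test(sym)
  expect_equal(bs$statistic, 0)
  expect_equal(bs$p_value, 1)
  # df counts informative pairs; a fully informative 4x4 gives 6
  full <- matrix(1:16, 4, 4)
  expect_equal(bowker_test(full)$df, 6L)
  sparse <- matrix(c(5, 0, 1, 0, 6, 0, 2, 3, 7), 3, 3)  # pair (1,2) empty
  expect_equal(bowker_test(sparse)$df, 2L)
  expect_error(bowker_test(diag(4)), "degenerate")
})

test_that("the symmetry statistic is invariant under category relabelling", {
  set.seed(11)
  for (r in 1:25) {
    tab <- matrix(rpois(16, 4), 4, 4)
    if (all(tab[upper.tri(tab)] + t(tab)[upper.tri(tab)] == 0)) next
    perm <- sample(4)
    expect_equal(bowker_test(tab[perm, perm])$statistic,
                 bowker_test(tab)$statistic)
  }
})

test_that("t statistics agree with from-the-definition computations", {
  set.seed(12)
  for (r in 1:25) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.3
    d <- x - y
    tt <- paired_t_test(x, y)
    expect_equal(tt$statistic, mean(d) / (sd(d) / sqrt(n)), tolerance = 1e-10)
    expect_equal(tt$df, n - 1L)
    m <- sample(5:30, 1)
    z <- rnorm(m, 0.5)
    t2 <- two_sample_t_test(x, z)
    sp2 <- ((n - 1) * var(x) + (m - 1) * var(z)) / (n + m - 2)
    expect_equal(t2$statistic, (mean(x) - mean(z)) / sqrt(sp2 * (1/n + 1/m)),
                 tolerance = 1e-10)
    expect_equal(t2$df, n + m - 2L)
  }
  # degenerate identical pairs: t = 0, p = 1 by convention
  same <- c(2, 5, 3)
  d0 <- paired_t_test(same, same)
  expect_equal(d0$statistic, 0)
  expect_equal(d0$p_value, 1)
})

test_that("willingness summaries use the strict greater-than-4 rule", {
  lik <- data.frame(participant_id = as.character(1:3), country = "UK",
                    condition = "BASELINE", response = c(4L, 4L, 5L))
  s <- willingness_summary(lik, "BASELINE")
  expect_equal(s$share_likely, 33.3)
  expect_equal(s$share_neither, 66.7)
  expect_equal(s$mean, mean(c(4, 4, 5)))
  expect_equal(s$se, sd(c(4, 4, 5)) / sqrt(3))
  all7 <- data.frame(participant_id = as.character(1:5), country = "UK",
                     condition = "BASELINE", response = 7L)
  expect_equal(willingness_summary(all7, "BASELINE")$share_likely, 100)
  expect_error(willingness_summary(lik, "MANDATE_PED"), "no responses")
})

test_that("the overlap partition is exhaustive and disjoint", {
  mk <- function(id, most, ped, occ) {
    data.frame(participant_id = id, country = "UK",
               condition = c("MANDATE_MOST", "MANDATE_PED", "MANDATE_OCC"),
               response = c(most, ped, occ))
  }
  lik <- rbind(mk("a", 7L, 7L, 7L), mk("b", 5L, 3L, 3L), mk("c", 2L, 2L, 2L))
  part <- overlap_partition(lik)
  expect_equal(sum(part$count), 3)
  expect_equal(sum(part$share), 100)
  expect_equal(part$count[part$most & part$ped & part$occ], 1)
  # response (5, 3, 3) lands only in the MOST-only cell
  expect_equal(part$count[part$most & !part$ped & !part$occ], 1)
  expect_equal(part$count[!part$most & !part$ped & !part$occ], 1)
  # all-enthusiast boundary
  all7 <- rbind(mk("a", 7L, 7L, 7L), mk("b", 5L, 5L, 5L))
  p7 <- overlap_partition(all7)
  expect_equal(p7$share[p7$most & p7$ped & p7$occ], 100)
  # incomplete participants are excluded, counts still sum
  expect_message(px <- overlap_partition(lik[-2, ]), "excluded 1")
  expect_equal(sum(px$count), attr(px, "n_complete"))
})

test_that("the battery reports every preplanned test with its sample size", {
  pop_n <- 40
  prefs <- simulate_preferences(categorical_spec(frame_shift = 0.5), pop_n,
                                seed = 13)
  lik <- simulate_likert(likert_spec(), prefs, seed = 14)
  out <- preference_battery(prefs, lik)
  expect_equal(nrow(out), 6)
  expect_true(all(out$n == pop_n))
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))
  # the strong framing shift must register as asymmetry
  expect_lt(out$p_value[out$test == "bowker_unframed_vs_family_passenger"], 0.01)
})
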