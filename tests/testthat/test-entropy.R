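test_that("transition counting pools sequences without crossing boundaries", {
  tm <- estimate_transition_matrix(list(c("SU", "DP2", "SU", "DP2")))
  expect_equal(tm$probs["SU", "DP2"], 1)
  expect_equal(tm$probs["DP2", "SU"], 1)
  expect_equal(tm$counts["SU", "DP2"], 2L)
  expect_equal(tm$counts["DP2", "SU"], 1L)

  solo <- estimate_transition_matrix(list(c("SU", "SU", "SU")))
  expect_equal(solo$states, "SU")
  expect_equal(unname(solo$probs[1, 1]), 1)

  # no cross-boundary DP2 -> DP2 transition
  two <- estimate_transition_matrix(list(c("SU", "DP2"), c("DP2", "SU")))
  expect_equal(two$counts["SU", "DP2"], 1L)
  expect_equal(two$counts["DP2", "SU"], 1L)
  expect_equal(two$counts["DP2", "DP2"], 0L)
  expect_equal(two$n_transitions, 2L)

  expect_error(estimate_transition_matrix(list("SU"), singer_id = "F9"),
               "F9")
})

test_that("state support and smoothing options behave", {
  tm_full <- estimate_transition_matrix(list(c("SU", "DP2", "SU")),
                                        states = "full")
  expect_equal(tm_full$states, phrase_alphabet())
  expect_equal(rowSums(tm_full$probs)[["DP3"]], 0)  # unobserved row

  tm_sm <- estimate_transition_matrix(list(c("SU", "DP2", "SU")),
                                      states = "full", alpha = 0.5)
  expect_equal(unname(rowSums(tm_sm$probs)), rep(1, 6), tolerance = 1e-12)
  expect_true(all(tm_sm$probs > 0))
})

test_that("stationary distribution solves pi P = pi", {
  P <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, 2, byrow = TRUE)
  pi <- stationary_distribution(P)
  expect_equal(unname(pi), c(5 / 6, 1 / 6), tolerance = 1e-12)
  expect_equal(unname(pi %*% P), t(unname(pi)), tolerance = 1e-12)

  k <- 5
  expect_equal(unname(stationary_distribution(matrix(1 / k, k, k))),
               rep(1 / k, k), tolerance = 1e-12)

  # two absorbing states: no unique stationary distribution
  expect_error(stationary_distribution(diag(2)), "recurrent classes")

  # transient state feeding one recurrent class is fine
  P3 <- matrix(c(0, 0.5, 0.5,
                 0, 0.3, 0.7,
                 0, 0.6, 0.4), 3, 3, byrow = TRUE)
  pi3 <- stationary_distribution(P3)
  expect_equal(pi3[1], 0)
  expect_equal(sum(pi3), 1, tolerance = 1e-12)
})

test_that("largest-class restriction resolves reducible empirical chains", {
  # two closed blocks; the SU/DP2 block carries 4x the transition mass
  seqs <- list(rep(c("SU", "DP2"), 5), c("DP3", "DP4", "DP3"))
  tm <- estimate_transition_matrix(seqs)
  expect_error(stationary_distribution(tm), "recurrent classes")
  pi <- stationary_distribution(tm, on_reducible = "largest")
  expect_equal(sum(pi[c("SU", "DP2")]), 1, tolerance = 1e-12)
  expect_equal(unname(pi[c("DP3", "DP4")]), c(0, 0))
})

test_that("entropy rate matches closed forms and unit conventions", {
  cycle <- matrix(c(0, 1, 0,
                    0, 0, 1,
                    1, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(entropy_rate(cycle), 0)

  expect_equal(entropy_rate(matrix(1 / 6, 6, 6)), log(6), tolerance = 1e-12)
  expect_equal(entropy_rate(matrix(1 / 6, 6, 6), log_base = 2), log2(6),
               tolerance = 1e-12)

  P <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, 2, byrow = TRUE)
  h_hand <- (5 / 6) * -(0.9 * log(0.9) + 0.1 * log(0.1)) +
    (1 / 6) * -(0.5 * log(0.5) + 0.5 * log(0.5))
  expect_equal(entropy_rate(P), h_hand, tolerance = 1e-12)
  expect_equal(round(entropy_rate(P), 4), 0.3864)
  expect_error(entropy_rate(P, pi = c(1, 0, 0)), "dimension")
})

test_that("entropy rate is bounded by log(k) with equality at uniform", {
  for (s in 1:20) {
    P <- make_transition_matrix(6, concentration = runif(1, 0.2, 5),
                                seed = 400 + s)
    h <- entropy_rate(P)
    expect_gte(h, 0)
    expect_lte(h, log(6) + 1e-12)
  }
})

test_that("simulation-based entropy agrees with the analytic rate", {
  P <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, 2, byrow = TRUE)
  sim <- simulate_entropy_rate(P, chain_length = 1e5, n_reps = 5, seed = 3)
  expect_lt(abs(sim$entropy_rate - entropy_rate(P)),
            max(3 * sim$se, 0.01))
  sim2 <- simulate_entropy_rate(P, chain_length = 1e5, n_reps = 5, seed = 3)
  expect_identical(sim, sim2)

  cycle <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  expect_equal(simulate_entropy_rate(cycle, chain_length = 2000,
                                     n_reps = 2, seed = 1)$entropy_rate, 0)
})

test_that("per-singer entropy table annotates and prunes correctly", {
  co <- tiny_corpus()
  et <- entropy_table(co)
  expect_equal(nrow(et), 6)
  expect_setequal(et$singer_id, co$singers$singer_id)
  expect_equal(et$category[et$singer_id == "F1"], "dominant_female")
  expect_true(all(et$entropy_rate >= 0))
  expect_true(all(et$entropy_rate <= log(6) + 1e-12))

  # a singer with only length-1 contributions is dropped with a warning
  singers <- co$singers
  contributions <- co$contributions
  contributions <- rbind(contributions,
                         data.frame(song_id = "S3", singer_id = "F1",
                                    stringsAsFactors = FALSE,
                                    tokens = I(list("SU"))))
  only1 <- data.frame(song_id = "S9", singer_id = "X1",
                      stringsAsFactors = FALSE, tokens = I(list("DP2")))
  singers <- rbind(singers,
                   data.frame(singer_id = "X1", sex = "unrecorded",
                              status = "non_dominant", group_id = "GA",
                              stringsAsFactors = FALSE))
  co2 <- indri_corpus(singers, rbind(contributions, only1))
  expect_warning(et2 <- entropy_table(co2), "length 1")
  expect_false("X1" %in% et2$singer_id)
})

test_that("plug-in entropy converges to the generating rate with length", {
  P <- make_transition_matrix(6, 0.8, seed = 17)
  h_true <- entropy_rate(P)
  errs <- vapply(c(500, 5000, 50000), function(n) {
    set.seed(99)
    s <- sample_markov_sequence(P, n)
    abs(entropy_rate(estimate_transition_matrix(list(s))) - h_true)
  }, numeric(1))
  expect_lt(errs[3], 0.02)
  expect_lt(errs[3], errs[1])
})
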