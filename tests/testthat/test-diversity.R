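test_that("normalized diversity is distinct types over length", {
  nd <- normalized_diversity(c("DP2", "DP3", "DP3", "DP5", "DP4"))
  expect_equal(nd$richness, 4L)
  expect_equal(nd$length, 5L)
  expect_equal(nd$value, 0.8)
  expect_equal(normalized_diversity("SU")$value, 1)
  expect_equal(normalized_diversity(c("DP2", "DP2", "DP2"))$value, 1 / 3)
  expect_error(normalized_diversity(character(0)), "empty")
})

test_that("normalized diversity is order-free, bounded and saturates at 6", {
  set.seed(81)
  for (i in 1:50) {
    s <- random_sequence(20)
    nd <- normalized_diversity(s)$value
    expect_equal(normalized_diversity(sample(s))$value, nd)
    expect_gt(nd, 0)
    expect_lte(nd, 1)
    if (length(s) > 6) expect_lte(nd, 6 / length(s))
    if (anyDuplicated(s) == 0) expect_equal(nd, 1)
    if (length(unique(s)) == 1) expect_equal(nd, 1 / length(s))
  }
})

test_that("diversity_table yields one annotated record per contribution", {
  co <- tiny_corpus()
  div <- diversity_table(co)
  expect_equal(nrow(div), nrow(co$contributions))
  expect_equal(div$category[div$singer_id == "N2"],
               rep("non_dominant", 2))
  # the known 0.8 contribution and its natural-log transform
  row <- div[div$singer_id == "M2" & div$song_id == "S1", ]
  expect_equal(row$nd, 0.8)
  expect_equal(row$log_nd, log(0.8), tolerance = 1e-12)
  expect_equal(round(row$log_nd, 4), -0.2231)
  div2 <- diversity_table(co, log_base = 2)
  expect_equal(div2$log_nd, div$log_nd / log(2), tolerance = 1e-12)
})

test_that("category diversity means agree under a matched generator", {
  P <- make_transition_matrix(6, 1.0, seed = 12)
  cfg <- synthetic_config(
    n_groups = 5, n_nondominants_per_group = 2, songs_per_group = 25,
    transition_matrices = list(dominant_female = P, dominant_male = P,
                               non_dominant = P),
    coupling_w_max = 0, coupling_length_sigma = 0,
    p_nondominant_sing = 1, seed = 13)
  div <- diversity_table(generate_corpus(cfg))
  means <- tapply(div$nd, div$category, mean)
  ns <- tapply(div$nd, div$category, length)
  pooled_se <- sqrt(sum(tapply(div$nd, div$category, var) / ns))
  expect_lt(max(means) - min(means), 4 * pooled_se)
})

test_that("duet pairing intersects the dominants' shared songs", {
  singers <- data.frame(
    singer_id = c("F", "M"), sex = c("female", "male"),
    status = "dominant", group_id = "G", stringsAsFactors = FALSE)
  contributions <- data.frame(
    song_id = c(paste0("s", 1:7), paste0("s", 1:5)),
    singer_id = c(rep("F", 7), rep("M", 5)),
    stringsAsFactors = FALSE)
  contributions$tokens <- replicate(12, c("SU", "DP2"), simplify = FALSE)
  co <- indri_corpus(singers, contributions)
  div <- diversity_table(co)
  pairs <- pair_duet_diversities(div, co, "G")
  expect_equal(nrow(pairs), 5)  # 5 shared songs, 2 female-only excluded
  expect_equal(pairs$song_id, paste0("s", 1:5))

  # a group missing one dominant cannot be paired
  solo <- indri_corpus(singers[1, , drop = FALSE],
                       contributions[1:7, , drop = FALSE])
  expect_error(pair_duet_diversities(diversity_table(solo), solo, "G"),
               "dominant")
})

test_that("no shared songs yields an empty pairing and an untested group", {
  singers <- data.frame(
    singer_id = c("F", "M"), sex = c("female", "male"),
    status = "dominant", group_id = "G", stringsAsFactors = FALSE)
  contributions <- data.frame(
    song_id = c("s1", "s2", "s3", "s4"),
    singer_id = c("F", "F", "M", "M"), stringsAsFactors = FALSE)
  contributions$tokens <- replicate(4, c("SU", "DP2"), simplify = FALSE)
  co <- indri_corpus(singers, contributions)
  div <- diversity_table(co)
  expect_equal(nrow(pair_duet_diversities(div, co, "G")), 0)
  cov <- group_covariation(div, co)
  expect_equal(cov$status, "untested")
  expect_true(is.na(cov$rho))
})

test_that("group covariation reproduces exact and midrank Spearman values", {
  singers <- data.frame(
    singer_id = c("F", "M"), sex = c("female", "male"),
    status = "dominant", group_id = "G", stringsAsFactors = FALSE)
  mk_corpus <- function(f_seqs, m_seqs) {
    n <- length(f_seqs)
    contributions <- data.frame(
      song_id = rep(sprintf("s%02d", 1:n), 2),
      singer_id = rep(c("F", "M"), each = n), stringsAsFactors = FALSE)
    contributions$tokens <- c(f_seqs, m_seqs)
    indri_corpus(singers, contributions)
  }
  # concordant ranks: ND rises together
  up <- list(c("SU", "SU", "SU", "SU"), c("SU", "DP2", "SU", "SU"),
             c("SU", "DP2", "DP3", "SU"), c("SU", "DP2", "DP3", "DP4"))
  down <- rev(up)
  co <- mk_corpus(up, up)
  cov <- group_covariation(diversity_table(co), co)
  expect_equal(cov$rho, 1)
  co2 <- mk_corpus(up, down)
  expect_equal(group_covariation(diversity_table(co2), co2)$rho, -1)

  # ties handled by midranks, cross-checked against a hand-rolled rank
  # computation on a 6-pair example
  f6 <- list(c("SU"), c("SU", "DP2"), c("SU", "DP2"),
             c("SU", "SU", "DP2"), c("SU", "DP2", "DP3"), c("SU", "SU"))
  m6 <- list(c("DP2", "DP2"), c("SU"), c("SU", "DP2", "DP4"),
             c("SU", "DP5"), c("DP3", "DP3", "DP3"), c("SU", "DP2"))
  co6 <- mk_corpus(f6, m6)
  div6 <- diversity_table(co6)
  pairs <- pair_duet_diversities(div6, co6, "G")
  expect_equal(group_covariation(div6, co6)$rho,
               spearman_oracle(pairs$nd_female, pairs$nd_male),
               tolerance = 1e-12)
})

test_that("coupled generators induce mostly positive duet covariation", {
  rhos <- unlist(lapply(1:10, function(r) {
    cfg <- synthetic_config(n_groups = 3, songs_per_group = 30,
                            duet_coupling = 0.8, coupling_w_max = 0.8,
                            coupling_length_sigma = 0.8,
                            p_nondominant_sing = 0, seed = 7000 + r)
    co <- generate_corpus(cfg)
    group_covariation(diversity_table(co), co)$rho
  }))
  expect_equal(length(rhos), 30)
  expect_gte(mean(rhos > 0), 0.75)
})
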