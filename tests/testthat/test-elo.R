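test_that("expected win probability is a symmetric monotone sigmoid", {
  expect_equal(expected_win_prob(0), 0.5)
  d <- c(-500, -120, -1, 0, 3, 57, 999)
  expect_equal(expected_win_prob(d) + expected_win_prob(-d), rep(1, length(d)))
  expect_true(all(diff(expected_win_prob(seq(-800, 800, by = 50))) > 0))
  expect_gt(expected_win_prob(1e6), 1 - 1e-12)
  # classic convention: 200-point gap -> p ~ 0.76
  expect_equal(expected_win_prob(200), 1 / (1 + 10^(-200 / 400)))
})

test_that("a single update transfers k(1-p) and conserves the total", {
  cfg <- elo_config()
  expect_equal(unname(elo_update(1000, 1000, cfg)), c(1050, 950))
  # higher-rated winner gains less than k/2
  up <- elo_update(1200, 1000, cfg)
  expect_lt(up[["winner"]] - 1200, 50)
  for (pair in list(c(800, 1300), c(1000, 1000), c(1534.2, 912.8))) {
    up <- elo_update(pair[1], pair[2], cfg)
    expect_equal(sum(up), sum(pair))
  }
  # fixed-transfer variant always moves k
  upf <- elo_update(1200, 1000, elo_config(update = "fixed"))
  expect_equal(unname(upf), c(1300, 900))
})

test_that("sequential trajectories match hand-applied updates", {
  cfg <- elo_config()
  ids <- c("A", "B", "C")
  one <- run_elo_sequence(make_contests("A", "B", 1), ids, cfg)
  expect_equal(one$final_scores, c(A = 1050, B = 950, C = 1000))
  # empty sequence: identity
  empty <- run_elo_sequence(make_contests("A", "B", 0), ids, cfg)
  expect_equal(empty$final_scores, c(A = 1000, B = 1000, C = 1000))
  # A beats B then B beats A, derived by direct arithmetic
  two <- run_elo_sequence(rbind(make_contests("A", "B", 1),
                                make_contests("B", "A", 1, start_index = 2)),
                          ids, cfg)
  s <- 400 / log(10)
  t2 <- 100 * (1 - 1 / (1 + exp(-(950 - 1050) / s)))
  expect_equal(two$final_scores[["B"]], 950 + t2)
  expect_equal(two$final_scores[["A"]], 1050 - t2)
  # the upset transfers more than k/2, so A ends below 1000
  expect_lt(two$final_scores[["A"]], 1000)
})

test_that("scores are zero-sum after every event and only participants move", {
  sim <- simulate_group(group_params(rng_seed = 5))
  recs <- sim$records[sim$records$session_id == "S3", ]
  present <- sim$sessions$individuals_present[[3]]
  tr <- run_elo_sequence(recs, present, elo_config())
  expect_equal(rowSums(tr$scores), rep(1000 * length(present), nrow(tr$scores)))
  moved <- abs(diff(tr$scores)) > 0
  expect_true(all(rowSums(moved) <= 2))
})

test_that("half-credit draws shift scores toward the underdog only", {
  rec <- make_contests("A", "B", n_wins = 0, n_draws = 1)
  even <- run_elo_sequence(rec, c("A", "B"), elo_config(draw_credit = TRUE))
  expect_equal(even$final_scores, c(A = 1000, B = 1000))
  uneven <- rbind(make_contests("A", "B", 1),
                  make_contests("A", "B", 0, n_draws = 1, start_index = 2))
  tr <- run_elo_sequence(uneven, c("A", "B"), elo_config(draw_credit = TRUE))
  expect_lt(tr$final_scores[["A"]], 1050)
  expect_equal(sum(tr$final_scores), 2000)
})

test_that("randomized Elo is deterministic, rank-correct and symmetric", {
  cfg <- elo_config(n_randomizations = 200, rng_seed = 21)
  ids <- c("A", "B", "C")
  rec <- rbind(make_contests("A", "B", 6), make_contests("A", "C", 5, start_index = 7),
               make_contests("B", "C", 4, start_index = 12))
  r1 <- randomized_elo(rec, ids, cfg)
  r2 <- randomized_elo(rec, ids, cfg)
  expect_identical(r1$per_randomization_finals, r2$per_randomization_finals)
  expect_equal(r1$mean_scores, colMeans(r1$per_randomization_finals))
  # all events won by A: A first under any ordering
  all_a <- rbind(make_contests("A", "B", 5), make_contests("A", "C", 5, start_index = 6))
  ra <- randomized_elo(all_a, ids, cfg)
  expect_equal(ra$ranking[1], "A")
  expect_true(all(ra$per_randomization_finals[, "A"] >
                    apply(ra$per_randomization_finals[, c("B", "C")], 1, max)))
  # symmetric dataset: A and B statistically indistinguishable
  sym <- rbind(make_contests("A", "B", 5), make_contests("B", "A", 5, start_index = 6))
  rs <- randomized_elo(sym, c("A", "B"), elo_config(n_randomizations = 1000, rng_seed = 9))
  mc_se <- sd(rs$per_randomization_finals[, "A"]) / sqrt(1000)
  expect_lt(abs(rs$mean_scores[["A"]] - rs$mean_scores[["B"]]), 6 * mc_se + 1e-9)
  expect_error(randomized_elo(make_contests("A", "B", 0, n_draws = 2), ids, cfg),
               "skip")
})

test_that("batch randomization agrees with the reference R sequence", {
  sim <- simulate_group(group_params(rng_seed = 8))
  recs <- sim$records[sim$records$session_id == "S4", ]
  present <- sim$sessions$individuals_present[[4]]
  cfg <- elo_config(n_randomizations = 25, rng_seed = 13)
  res <- randomized_elo(recs, present, cfg)
  # rebuild the same seeded permutations and replay each in pure R
  dec <- recs[recs$category == "agonistic" & recs$outcome != "draw", ]
  set.seed(13)
  for (j in 1:25) {
    ord <- sample.int(nrow(dec))
    tr <- run_elo_sequence(dec[ord, ], present, cfg)
    expect_equal(unname(res$per_randomization_finals[j, present]),
                 unname(tr$final_scores[present]), tolerance = 1e-10)
  }
})

test_that("adding a constant to the initial score shifts scores, not ranks", {
  rec <- rbind(make_contests("A", "B", 4), make_contests("B", "C", 3, start_index = 5),
               make_contests("C", "A", 1, start_index = 8))
  ids <- c("A", "B", "C")
  base <- randomized_elo(rec, ids, elo_config(n_randomizations = 50, rng_seed = 2))
  shifted <- randomized_elo(rec, ids, elo_config(init_score = 1400,
                                                 n_randomizations = 50, rng_seed = 2))
  expect_equal(shifted$mean_scores, base$mean_scores + 400)
  expect_identical(as.character(shifted$ranking), as.character(base$ranking))
})
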