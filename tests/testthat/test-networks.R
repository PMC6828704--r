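test_that("networks are rate-normalized, rank-ordered and roster-checked", {
  ses <- make_sessions(ids = c("A", "B", "C"), duration = 2)[1, ]
  rec <- rbind(make_contests("A", "B", 2),
               make_records("S1", "B", "C", "allopreen"))
  net <- build_network(rec, ses, "agonistic", ranking = c("C", "A", "B"))
  expect_equal(net$weights["A", "B"], 1.0)
  expect_equal(net$individuals, c("C", "A", "B"))
  expect_equal(net$raw_counts, net$weights * 2)
  expect_true(all(diag(net$weights) == 0))
  # draws count as interactions
  with_draw <- rbind(rec, make_contests("A", "B", 0, n_draws = 1, start_index = 5))
  netd <- build_network(with_draw, ses, "agonistic", ranking = c("C", "A", "B"))
  expect_equal(netd$raw_counts["A", "B"], 3)
  # empty category -> zero matrix of correct dimension
  aff <- build_network(make_contests("A", "B", 1), ses, "affiliative",
                       ranking = c("A", "B", "C"))
  expect_equal(dim(aff$weights), c(3, 3))
  expect_true(all(aff$weights == 0))
  # roster violations and uncovered rankings are errors
  expect_error(build_network(make_contests("A", "Z", 1), ses, "agonistic",
                             ranking = c("A", "B", "C", "Z")), "roster")
  expect_error(build_network(rec, ses, "agonistic", ranking = c("A", "B")),
               "ranking does not cover")
})

test_that("session rosters drive network dimension across the series", {
  sim <- simulate_group(group_params(rng_seed = 6))
  rk <- sim$params$individual_ids
  dims <- vapply(seq_len(5), function(s) {
    nrow(build_network(sim$records, sim$sessions[s, ], "agonistic", rk)$weights)
  }, numeric(1))
  expect_equal(dims, c(4, 4, 5, 5, 5))
})

test_that("graph correlation equals a flat off-diagonal Pearson", {
  set.seed(31)
  a <- random_network_matrix(3)
  expect_equal(graph_correlation(a, a), 1.0)
  b <- 2 * a + 3
  diag(b) <- 0
  expect_equal(graph_correlation(a, b), 1.0)
  # hand-flattened oracle on fixed 3x3 matrices
  m1 <- matrix(c(0, 1, 2, 3, 0, 4, 5, 6, 0), 3, 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m2 <- matrix(c(0, 2, 1, 5, 0, 3, 2, 8, 0), 3, 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(graph_correlation(m1, m2),
               cor(c(1, 2, 3, 4, 5, 6), c(2, 1, 5, 3, 2, 8)))
  # alignment is by identifier, not by position
  m2_shuffled <- m2[c("C", "A", "B"), c("C", "A", "B")]
  expect_equal(graph_correlation(m1, m2_shuffled), graph_correlation(m1, m2))
  expect_error(graph_correlation(m1, random_network_matrix(3, c("X", "Y", "Z"))),
               "different individuals")
  zero <- m1 * 0
  expect_warning(r <- graph_correlation(m1, zero), "zero variance")
  expect_true(is.na(r))
})

test_that("exact QAP matches brute-force enumeration over all relabelings", {
  set.seed(7)
  a4 <- random_network_matrix(4)
  q <- qap_test(a4, a4, mode = "exact")
  o <- brute_qap(a4, a4)
  expect_equal(q$r_observed, 1.0)
  expect_equal(q$n_permutations, 24)
  expect_equal(q$p_greater, o$p_greater)
  expect_equal(sort(q$null_distribution), sort(o$null))
  # distinct structure: only the identity attains r = 1
  expect_equal(q$p_greater, 1 / 24)
  # a permuted copy of a structured network sits inside the null at the
  # same quantile the enumeration assigns it
  b4 <- a4[c(2, 4, 1, 3), c(2, 4, 1, 3)]
  dimnames(b4) <- dimnames(a4)
  q2 <- qap_test(a4, b4, mode = "exact")
  o2 <- brute_qap(a4, b4)
  expect_equal(q2$r_observed, o2$r_observed)
  expect_equal(q2$p_greater, o2$p_greater)
  expect_equal(q2$p_lesser, o2$p_lesser)
  expect_error(qap_test(random_network_matrix(9), random_network_matrix(9),
                        mode = "exact"), "N <= 8")
})

test_that("relabeling both networks together changes nothing", {
  set.seed(12)
  a <- random_network_matrix(5)
  b <- random_network_matrix(5)
  q1 <- qap_test(a, b, mode = "exact")
  p <- c(3, 5, 1, 2, 4)
  ap <- a[p, p]; bp <- b[p, p]
  q2 <- qap_test(ap, bp, mode = "exact")
  expect_equal(q2$r_observed, q1$r_observed)
  expect_equal(sort(q2$null_distribution), sort(q1$null_distribution))
  expect_equal(q2$p_greater, q1$p_greater)
})

test_that("sampled QAP is seeded-deterministic and applies the +1 correction", {
  set.seed(2)
  a <- random_network_matrix(5)
  b <- random_network_matrix(5)
  q1 <- qap_test(a, b, n_permutations = 500, seed = 77)
  q2 <- qap_test(a, b, n_permutations = 500, seed = 77)
  expect_identical(q1$null_distribution, q2$null_distribution)
  expect_equal(q1$p_greater,
               (sum(q1$null_distribution >= q1$r_observed - 1e-12) + 1) / 501)
  expect_gt(q1$p_greater, 0)
  expect_gt(q1$p_lesser, 0)
})

test_that("rescaling observation time leaves correlation and QAP unchanged", {
  ses1 <- make_sessions(ids = c("A", "B", "C", "D"), duration = 2)[1, ]
  ses2 <- make_sessions(ids = c("A", "B", "C", "D"), duration = 6)[1, ]
  rec <- rbind(make_contests("A", "B", 3), make_contests("B", "C", 2, start_index = 4),
               make_contests("C", "D", 1, start_index = 6),
               make_contests("A", "D", 2, start_index = 7))
  rk <- c("A", "B", "C", "D")
  n1 <- build_network(rec, ses1, "agonistic", rk)
  n2 <- build_network(rec, ses2, "agonistic", rk)
  expect_equal(n2$weights, n1$weights / 3)
  expect_equal(graph_correlation(n1, n2), 1.0)
  q1 <- qap_test(n1, n1, mode = "exact")
  q2 <- qap_test(n2, n2, mode = "exact")
  expect_equal(q1$null_distribution, q2$null_distribution)
  expect_equal(q1$p_greater, q2$p_greater)
})

test_that("consistency report tests consecutive same-roster pairs only", {
  set.seed(9)
  ids4 <- c("A", "B", "C", "D")
  nets <- list(as_network(random_network_matrix(4, ids4), "S1"),
               as_network(random_network_matrix(4, ids4), "S2"),
               as_network(random_network_matrix(5), "S3"),
               as_network(random_network_matrix(5), "S4"),
               as_network(random_network_matrix(5), "S5"))
  rep5 <- consistency_report(nets, n_permutations = 200, seed = 4)
  expect_equal(rep5$tested, c(TRUE, FALSE, TRUE, TRUE))
  expect_match(rep5$note[2], "different individuals")
  expect_equal(rep5$session_a[rep5$tested], c("S1", "S3", "S4"))
  # degenerate and self-consistent cases
  expect_equal(nrow(consistency_report(nets[1])), 0)
  self <- consistency_report(list(nets[[1]], nets[[1]]), n_permutations = 50)
  expect_equal(self$r_observed, 1.0)
  # all-pairs mode covers every same-roster combination
  ap <- consistency_report(nets[3:5], n_permutations = 50, all_pairs = TRUE)
  expect_equal(nrow(ap), 3)
  expect_true(all(ap$tested))
})

test_that("edge lists carry exactly the non-zero directed edges", {
  ses <- make_sessions(ids = c("A", "B", "C"), duration = 2)[1, ]
  rec <- rbind(make_contests("A", "B", 2), make_contests("C", "A", 1, start_index = 3))
  net <- build_network(rec, ses, "agonistic", c("A", "B", "C"))
  el <- as.data.frame(net)
  expect_equal(nrow(el), 2)
  expect_equal(el$weight[el$from == "A"], 1.0)
  expect_equal(sum(el$count), 3)
})
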