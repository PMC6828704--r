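# In-code fixtures shared across test files.

# Minimal session table for in-memory record fixtures.
make_sessions <- function(ids = c("A", "B", "C"), n = 1, duration = 2) {
  data.frame(session_id = paste0("S", seq_len(n)),
             date = as.Date("2015-07-01") + 27 * (seq_len(n) - 1),
             duration_hours = duration,
             individuals_present = I(rep(list(ids), n)),
             stringsAsFactors = FALSE)
}

# One-row-per-interaction records; outcome defaults by category.
make_records <- function(session, from, to, code,
                         outcome = NULL, eth = default_ethogram()) {
  category <- unname(unclass(eth)[code])
  if (is.null(outcome)) {
    outcome <- ifelse(category == "agonistic", "initiator_wins", "not_applicable")
  }
  data.frame(session_id = session,
             order_index = stats::ave(seq_along(from), session, FUN = seq_along),
             initiator_id = from, recipient_id = to, behaviour_code = code,
             category = category, outcome = outcome, stringsAsFactors = FALSE)
}

# n_wins decided contests won by `winner` over `loser`, optional draws.
make_contests <- function(winner, loser, n_wins, n_draws = 0, session = "S1",
                          start_index = 1) {
  n <- n_wins + n_draws
  if (n == 0) {
    return(data.frame(session_id = character(0), order_index = integer(0),
                      initiator_id = character(0), recipient_id = character(0),
                      behaviour_code = character(0), category = character(0),
                      outcome = character(0), stringsAsFactors = FALSE))
  }
  data.frame(session_id = session,
             order_index = seq_len(n) + start_index - 1,
             initiator_id = winner, recipient_id = loser,
             behaviour_code = "peck", category = "agonistic",
             outcome = c(rep("initiator_wins", n_wins), rep("draw", n_draws)),
             stringsAsFactors = FALSE)
}

# Random directed weight matrix with zero diagonal.
random_network_matrix <- function(n, ids = LETTERS[seq_len(n)]) {
  m <- matrix(stats::rexp(n * n), n, n, dimnames = list(ids, ids))
  diag(m) <- 0
  m
}

# Independent oracle for QAP: enumerate every relabeling of b via
# expand.grid (keeping only permutation rows) and correlate flattened
# off-diagonal cells with an explicit double loop. Deliberately avoids
# the package's permutation and correlation code paths.
brute_qap <- function(a, b) {
  n <- nrow(a)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- grid[apply(grid, 1, function(r) length(unique(r)) == n), , drop = FALSE]
  offdiag <- function(m) {
    v <- c()
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) v <- c(v, m[i, j])
    v
  }
  x <- offdiag(a)
  null <- numeric(nrow(perms))
  for (k in seq_len(nrow(perms))) {
    p <- perms[k, ]
    null[k] <- stats::cor(x, offdiag(b[p, p]))
  }
  r_obs <- stats::cor(x, offdiag(b))
  list(r_observed = r_obs, null = null,
       p_greater = mean(null >= r_obs - 1e-12),
       p_lesser = mean(null <= r_obs + 1e-12))
}

# Wrap a plain matrix as an interaction_network for series-level tests.
as_network <- function(weights, session_id, type = "agonistic", duration = 1) {
  structure(list(session_id = session_id, network_type = type,
                 individuals = rownames(weights),
                 raw_counts = weights * duration, weights = weights,
                 duration_hours = duration),
            class = "interaction_network")
}

# group_params for the parameter-recovery conditions: steep hierarchy
# (adjacent win prob 0.9), fixed 132 decided events, uniform dyad
# sampling, all individuals present.
steep_recovery_params <- function() {
  group_params(n_sessions = 1, agonistic_rate_sd = 0, draw_prob = 0,
               initiation_bias = 0, absent_schedule = list(),
               ability_shift_events = list())
}
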