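#' Elo-rating configuration
#'
#' Parameters of the sequential Elo update and its order randomization.
#' Every individual starts at `init_score` (default 1000); after each
#' decided contest the winner gains and the loser loses
#' `k * (1 - p_win)` points, where `p_win` is the winner's expected win
#' probability given the pre-contest score difference (so upsets move
#' scores more than expected wins). The expectation curve is logistic with
#' scale `sigmoid_scale`; the default `400 / ln(10)` reproduces the
#' classic Elo convention in which a 200-point gap gives p ~ 0.76.
#'
#' @param init_score Starting score for every individual.
#' @param k Maximum points transferred per contest.
#' @param n_randomizations Number of random interaction orders averaged by
#'   [randomized_elo()].
#' @param sigmoid_scale Steepness scale of the expected-win curve.
#' @param rng_seed Integer seed controlling order randomization.
#' @param update `"expected"` (transfer `k * (1 - p_win)`, default) or
#'   `"fixed"` (always transfer `k`).
#' @param draw_credit If `TRUE`, draws enter the sequence as half-credit
#'   contests (the initiator gains `k * (0.5 - p_init)`); by default draws
#'   are excluded from Elo entirely.
#' @return An `elo_config` list.
#' @export
elo_config <- function(init_score = 1000, k = 100, n_randomizations = 1000,
                       sigmoid_scale = 400 / log(10), rng_seed = 1L,
                       update = c("expected", "fixed"), draw_credit = FALSE) {
  update <- match.arg(update)
  stopifnot(k > 0, n_randomizations >= 1, sigmoid_scale > 0)
  structure(list(init_score = init_score, k = k,
                 n_randomizations = as.integer(n_randomizations),
                 sigmoid_scale = sigmoid_scale,
                 rng_seed = as.integer(rng_seed),
                 update = update, draw_credit = draw_credit),
            class = "elo_config")
}

#' Expected win probability from a score difference
#'
#' Logistic curve `1 / (1 + exp(-score_diff / sigmoid_scale))`:
#' monotonically increasing, 0.5 at zero difference, and satisfying
#' `p(d) + p(-d) = 1`.
#'
#' @param score_diff Score of the focal individual minus its opponent's.
#' @param sigmoid_scale Steepness scale (default: classic Elo, 200-point
#'   gap gives p ~ 0.76).
#' @return Probability in (0, 1); vectorized.
#' @export
expected_win_prob <- function(score_diff, sigmoid_scale = 400 / log(10)) {
  stopifnot(sigmoid_scale > 0)
  stats::plogis(score_diff / sigmoid_scale)
}

#' Single Elo update
#'
#' Transfers `k * (1 - p_win)` points from loser to winner (or a fixed
#' `k` under `update = "fixed"`). The sum of the two scores is conserved
#' exactly.
#'
#' @param winner_score,loser_score Pre-contest scores.
#' @param config An [elo_config()].
#' @return Named numeric vector `c(winner = ..., loser = ...)`.
#' @export
elo_update <- function(winner_score, loser_score, config = elo_config()) {
  transfer <- if (config$update == "fixed") config$k else
    config$k * (1 - expected_win_prob(winner_score - loser_score, config$sigmoid_scale))
  c(winner = winner_score + transfer, loser = loser_score - transfer)
}

decided_contests <- function(records, draw_credit = FALSE) {
  ag <- records[records$category == "agonistic", , drop = FALSE]
  if (!draw_credit) ag <- ag[ag$outcome != "draw", , drop = FALSE]
  winner <- ifelse(ag$outcome == "recipient_wins", ag$recipient_id, ag$initiator_id)
  loser <- ifelse(ag$outcome == "recipient_wins", ag$initiator_id, ag$recipient_id)
  data.frame(winner = winner, loser = loser, draw = ag$outcome == "draw",
             stringsAsFactors = FALSE)
}

#' Run one Elo sequence in a given interaction order
#'
#' Applies [elo_update()] sequentially to the agonistic records in the
#' order given. Non-participants keep their scores; the total score is
#' `length(individuals) * init_score` after every event.
#'
#' @param records Interaction records (agonistic records are used; draws
#'   are skipped unless `config$draw_credit`).
#' @param individuals Identifiers; all contest participants must be
#'   included.
#' @param config An [elo_config()].
#' @return An `elo_trajectory`: list with `individuals`, `scores` (matrix
#'   of per-individual scores, one row per state: initial plus one per
#'   event), `final_scores`, and the `events` used.
#' @export
run_elo_sequence <- function(records, individuals, config = elo_config()) {
  ev <- decided_contests(records, config$draw_credit)
  extra <- setdiff(unique(c(ev$winner, ev$loser)), individuals)
  if (length(extra)) stop("participant(s) not in individuals: ", paste(extra, collapse = ", "))
  if (any(ev$winner == ev$loser)) stop("winner equals loser")
  n <- length(individuals)
  s <- stats::setNames(rep(config$init_score, n), individuals)
  scores <- matrix(NA_real_, nrow(ev) + 1L, n, dimnames = list(NULL, individuals))
  scores[1L, ] <- s
  for (e in seq_len(nrow(ev))) {
    w <- ev$winner[e]; l <- ev$loser[e]
    if (ev$draw[e]) {
      p <- expected_win_prob(s[[w]] - s[[l]], config$sigmoid_scale)
      transfer <- config$k * (0.5 - p)
      s[w] <- s[[w]] + transfer
      s[l] <- s[[l]] - transfer
    } else {
      upd <- elo_update(s[[w]], s[[l]], config)
      s[w] <- upd[["winner"]]
      s[l] <- upd[["loser"]]
    }
    scores[e + 1L, ] <- s
  }
  structure(list(individuals = individuals, scores = scores,
                 final_scores = s, events = ev, config = config),
            class = "elo_trajectory")
}

#' @export
print.elo_trajectory <- function(x, ...) {
  cat("Elo trajectory:", nrow(x$events), "contests,",
      length(x$individuals), "individuals\n")
  print(round(x$final_scores, 1))
  invisible(x)
}

#' Plot Elo score trajectories
#'
#' Score of each individual against the running event index, in the order
#' the sequence was applied.
#'
#' @param x An `elo_trajectory`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.elo_trajectory <- function(x, ...) {
  graphics::matplot(seq_len(nrow(x$scores)) - 1L, x$scores, type = "l", lty = 1,
                    xlab = "interaction number", ylab = "Elo score", ...)
  graphics::legend("topleft", legend = x$individuals, lty = 1,
                   col = seq_along(x$individuals), bty = "n", cex = 0.8)
  invisible(x)
}

#' Randomized Elo rating
#'
#' Because Elo scores depend on the temporal sequence of interactions and
#' individuals interact at different rates, the interaction order is
#' randomized `n_randomizations` times (default 1000) and final scores are
#' averaged over orders. Permutations are drawn sequentially from
#' `rng_seed`, so permutation j is the same for any
#' `n_randomizations >= j` (prefix-stable streams).
#'
#' @param records Interaction records for one observation day; at least
#'   one decided agonistic record is required.
#' @param individuals Identifiers (typically the session roster).
#' @param config An [elo_config()].
#' @return An `elo_result`: `mean_scores`, `per_randomization_finals`
#'   (randomizations x individuals), `ranking` (descending mean score;
#'   ties broken by total wins then identifier), `n_events`, `config`.
#' @export
randomized_elo <- function(records, individuals, config = elo_config()) {
  ev <- decided_contests(records, draw_credit = FALSE)
  if (nrow(ev) == 0) {
    stop("no decided agonistic records: skip this observation day")
  }
  extra <- setdiff(unique(c(ev$winner, ev$loser)), individuals)
  if (length(extra)) stop("participant(s) not in individuals: ", paste(extra, collapse = ", "))
  n_ev <- nrow(ev)
  n_rand <- config$n_randomizations
  orders <- matrix(0L, n_ev, n_rand)
  withr_seed <- config$rng_seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(withr_seed)
  for (j in seq_len(n_rand)) orders[, j] <- sample.int(n_ev)
  finals <- elo_batch_finals(match(ev$winner, individuals),
                             match(ev$loser, individuals),
                             orders, length(individuals),
                             config$init_score, config$k, config$sigmoid_scale,
                             config$update == "fixed")
  colnames(finals) <- individuals
  mean_scores <- colMeans(finals)
  wins <- table(factor(ev$winner, levels = individuals))
  ranking <- rank_individuals(mean_scores, as.numeric(wins), individuals)
  structure(list(individuals = individuals, mean_scores = mean_scores,
                 per_randomization_finals = finals, ranking = ranking,
                 n_events = n_ev, config = config),
            class = "elo_result")
}

#' @export
print.elo_result <- function(x, ...) {
  cat(sprintf("Randomized Elo rating: %d contests, %d order randomizations\n",
              x$n_events, nrow(x$per_randomization_finals)))
  sc <- sort(x$mean_scores, decreasing = TRUE)
  cat("Mean scores (descending):\n")
  print(round(sc, 1))
  if (isTRUE(attr(x$ranking, "ties"))) cat("note: tied mean scores present\n")
  invisible(x)
}

#' @export
summary.elo_result <- function(object, ...) {
  f <- object$per_randomization_finals
  out <- data.frame(
    individual = object$individuals,
    mean_score = object$mean_scores,
    sd_score = apply(f, 2, stats::sd),
    rank = match(object$individuals, object$ranking),
    row.names = NULL
  )
  out[order(out$rank), ]
}

#' @export
coef.elo_result <- function(object, ...) object$mean_scores

#' Plot the distribution of randomized final scores
#'
#' One box per individual (ordered by rank) over the final scores of all
#' order randomizations.
#'
#' @param x An `elo_result`.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.elo_result <- function(x, ...) {
  f <- x$per_randomization_finals[, x$ranking, drop = FALSE]
  graphics::boxplot(f, ylab = "final Elo score", xlab = "individual (by rank)", ...)
  invisible(x)
}
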