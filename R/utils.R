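# Internal helpers shared across modules.

# Deterministic substream seed derived from a master seed and a stream label.
# Keeps every derived seed in [1, 2^31 - 2] so it is a valid R integer seed.
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 1009 + h * 31) %% 2147483629 + 1)
}

# Round half away from zero (base round() is half-to-even).
round_half_up <- function(x) floor(x + 0.5)

# All permutations of 1..n as an n! x n integer matrix. Fine for n <= 8.
all_permutations <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  m <- do.call(rbind, out)
  storage.mode(m) <- "integer"
  m
}

# Rank individuals by descending score; ties broken by total wins (descending)
# then by identifier. Returns ids in rank order with a "ties" attribute.
rank_individuals <- function(scores, wins = NULL, ids = names(scores)) {
  stopifnot(!is.null(ids), length(ids) == length(scores))
  if (is.null(wins)) wins <- rep(0, length(scores))
  ord <- order(-scores, -wins, ids)
  ranking <- ids[ord]
  tied <- duplicated(scores[ord]) | duplicated(scores[ord], fromLast = TRUE)
  attr(ranking, "ties") <- any(tied)
  ranking
}

`%||%` <- function(a, b) if (is.null(a)) b else a
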