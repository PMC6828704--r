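#' Build a per-session interaction network
#'
#' Converts one session's records of one category into a directed,
#' weighted adjacency matrix: `raw_counts[i, j]` is the number of
#' interactions initiated by `i` toward `j` (draws included — a draw is
#' still an interaction), and `weights = raw_counts / duration_hours`
#' expresses interactions per hour, so sessions of different length are
#' comparable. Nodes are ordered by the supplied dominance ranking
#' (attribute-ordered network).
#'
#' @param records Interaction records (any sessions/categories; filtered
#'   internally).
#' @param session One row of the sessions data.frame, or a list with
#'   `session_id`, `duration_hours`, `individuals_present`.
#' @param network_type `"agonistic"` or `"affiliative"`.
#' @param ranking Individuals in descending dominance order; must cover
#'   the session roster (extra individuals are ignored).
#' @return An `interaction_network`: `session_id`, `network_type`,
#'   `individuals` (rank order), `raw_counts`, `weights`,
#'   `duration_hours`.
#' @export
build_network <- function(records, session, network_type = c("agonistic", "affiliative"),
                          ranking) {
  network_type <- match.arg(network_type)
  if (is.data.frame(session)) {
    stopifnot(nrow(session) == 1)
    session <- list(session_id = session$session_id,
                    duration_hours = session$duration_hours,
                    individuals_present = session$individuals_present[[1]])
  }
  present <- session$individuals_present
  missing_rank <- setdiff(present, ranking)
  if (length(missing_rank)) {
    stop("ranking does not cover present individual(s): ",
         paste(missing_rank, collapse = ", "))
  }
  nodes <- ranking[ranking %in% present]
  rec <- records[records$session_id == session$session_id &
                   records$category == network_type, , drop = FALSE]
  extra <- setdiff(unique(c(rec$initiator_id, rec$recipient_id)), present)
  if (length(extra)) {
    stop("individual(s) ", paste(extra, collapse = ", "),
         " interact but are absent from the session roster")
  }
  counts <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (nrow(rec) > 0) {
    tab <- table(factor(rec$initiator_id, levels = nodes),
                 factor(rec$recipient_id, levels = nodes))
    counts[] <- as.integer(tab)
  }
  structure(list(session_id = session$session_id, network_type = network_type,
                 individuals = nodes, raw_counts = counts,
                 weights = counts / session$duration_hours,
                 duration_hours = session$duration_hours),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("%s network, session %s: %d individuals, %d interactions (%.1f h)\n",
              x$network_type, x$session_id, length(x$individuals),
              sum(x$raw_counts), x$duration_hours))
  print(round(x$weights, 2))
  invisible(x)
}

#' @export
as.matrix.interaction_network <- function(x, ...) x$weights

#' Edge list of an interaction network
#'
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @return data.frame with `from`, `to`, `count`, `weight` (interactions
#'   per hour), non-zero edges only.
#' @export
as.data.frame.interaction_network <- function(x, ...) {
  idx <- which(x$raw_counts > 0, arr.ind = TRUE)
  data.frame(from = x$individuals[idx[, 1]], to = x$individuals[idx[, 2]],
             count = x$raw_counts[idx], weight = x$weights[idx],
             row.names = NULL)
}

#' Plot an interaction network
#'
#' Directed graph with edge width proportional to the interaction rate and
#' node order following dominance rank. Requires the igraph package.
#'
#' @param x An `interaction_network`.
#' @param ... Passed to `igraph::plot.igraph()`.
#' @export
plot.interaction_network <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("plotting networks requires the igraph package")
  }
  g <- igraph::graph_from_adjacency_matrix(x$weights, mode = "directed", weighted = TRUE)
  n <- length(x$individuals)
  lay <- cbind(0, rev(seq_len(n)))
  igraph::plot.igraph(g, layout = lay,
                      edge.width = 1 + 4 * igraph::E(g)$weight / max(igraph::E(g)$weight),
                      vertex.size = 30 * (n:1) / n + 10,
                      edge.curved = 0.4,
                      main = sprintf("%s, session %s", x$network_type, x$session_id), ...)
  invisible(x)
}

net_weights <- function(x) {
  if (inherits(x, "interaction_network")) x$weights
  else if (is.matrix(x)) {
    if (is.null(rownames(x))) {
      dimnames(x) <- list(paste0("ind", seq_len(nrow(x))), paste0("ind", seq_len(nrow(x))))
    }
    x
  } else stop("expected an interaction_network or a square matrix")
}

#' Graph correlation between two networks
#'
#' Pearson product-moment correlation over corresponding off-diagonal
#' cells of the two weight matrices (the diagonal is structurally zero and
#' excluded). Matrices are aligned by individual identifier first; the
#' individual sets must be identical.
#'
#' @param net_a,net_b `interaction_network` objects or square matrices
#'   with dimnames.
#' @return Correlation in `[-1, 1]`, or `NA` (with a warning) when one
#'   matrix has zero variance off the diagonal.
#' @export
graph_correlation <- function(net_a, net_b) {
  a <- net_weights(net_a); b <- net_weights(net_b)
  if (!setequal(rownames(a), rownames(b))) {
    stop("networks cover different individuals; only same-individual networks are comparable")
  }
  b <- b[rownames(a), rownames(a)]
  off <- row(a) != col(a)
  x <- a[off]; y <- b[off]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance off-diagonal: graph correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

# Null distribution of graph correlations under joint row/column
# relabelings of b. perms: one permutation per row. Vectorized: the
# off-diagonal cells of b[p, p] are b[cbind(p[ii], p[jj])].
qap_null <- function(a, b, perms) {
  n <- nrow(a)
  off <- which(row(a) != col(a), arr.ind = TRUE)
  ii <- off[, 1]; jj <- off[, 2]
  x <- a[cbind(ii, jj)]
  xs <- (x - mean(x)) / stats::sd(x)
  m <- length(x)
  ynull <- matrix(b[cbind(as.vector(perms[, ii]), as.vector(perms[, jj]))],
                  nrow(perms), m)
  yc <- ynull - rowMeans(ynull)
  ysd <- sqrt(rowSums(yc^2) / (m - 1))
  as.vector((yc %*% xs) / (m - 1)) / ysd
}

#' QAP permutation test of network association
#'
#' Quadratic assignment procedure: the observed graph correlation between
#' two networks on the same individuals is compared with the distribution
#' obtained by jointly permuting rows and columns of the second network
#' (relabeling its individuals) and recomputing the correlation. Joint
#' permutation preserves each network's internal structure, so the test
#' asks whether the *alignment* of the two networks is stronger than
#' chance.
#'
#' In `"sampled"` mode, `n_permutations` uniform random relabelings are
#' drawn (seeded) and `p_greater = (#\{null >= observed\} + 1) / (n + 1)`,
#' counting the identity arrangement, so p is never 0. In `"exact"` mode
#' all `N!` relabelings are enumerated (requires `N <= 8`) and p-values
#' are exact proportions.
#'
#' @param net_a,net_b `interaction_network` objects or square matrices
#'   with dimnames; identical individual sets.
#' @param n_permutations Number of sampled permutations (ignored in exact
#'   mode).
#' @param seed Integer seed for sampled mode.
#' @param mode `"sampled"` (default) or `"exact"`.
#' @return A `qap_test`: `r_observed`, `null_distribution`, `p_greater`,
#'   `p_lesser`, `n_permutations`, `exact`, `n_individuals`.
#' @export
qap_test <- function(net_a, net_b, n_permutations = 1000, seed = 1L,
                     mode = c("sampled", "exact")) {
  mode <- match.arg(mode)
  a <- net_weights(net_a); b <- net_weights(net_b)
  if (!setequal(rownames(a), rownames(b))) {
    stop("networks cover different individuals; only same-individual networks are comparable")
  }
  b <- b[rownames(a), rownames(a)]
  n <- nrow(a)
  r_obs <- graph_correlation(a, b)
  if (is.na(r_obs)) stop("graph correlation undefined (zero variance); QAP not applicable")
  if (mode == "exact") {
    if (n > 8) stop("exact mode enumerates N! relabelings; use N <= 8")
    perms <- all_permutations(n)
  } else {
    if (n_permutations < 1) stop("n_permutations must be >= 1")
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    perms <- t(replicate(n_permutations, sample.int(n)))
  }
  null <- qap_null(a, b, perms)
  eps <- 1e-12
  if (mode == "exact") {
    p_greater <- mean(null >= r_obs - eps)
    p_lesser <- mean(null <= r_obs + eps)
  } else {
    p_greater <- (sum(null >= r_obs - eps) + 1) / (length(null) + 1)
    p_lesser <- (sum(null <= r_obs + eps) + 1) / (length(null) + 1)
  }
  structure(list(r_observed = r_obs, null_distribution = null,
                 p_greater = p_greater, p_lesser = p_lesser,
                 n_permutations = nrow(perms), exact = mode == "exact",
                 n_individuals = n),
            class = "qap_test")
}

#' @export
print.qap_test <- function(x, ...) {
  cat(sprintf("QAP graph correlation test (%s, %d permutations)\n",
              if (x$exact) "exact enumeration" else "sampled", x$n_permutations))
  cat(sprintf("  r = %.3f, N = %d, p(greater) = %.4g, p(lesser) = %.4g\n",
              x$r_observed, x$n_individuals, x$p_greater, x$p_lesser))
  invisible(x)
}

#' QAP consistency of a network series through time
#'
#' Runs [qap_test()] for each consecutive pair of networks that share an
#' identical individual roster (networks with differing rosters are not
#' comparable and the pair is reported as skipped). Optionally tests all
#' pairs rather than consecutive ones.
#'
#' @param networks List of `interaction_network` objects of one type, in
#'   temporal order.
#' @param n_permutations,seed,mode Passed to [qap_test()].
#' @param all_pairs Test every pair instead of consecutive pairs only.
#' @return A `qap_consistency` data.frame: `session_a`, `session_b`,
#'   `n`, `r_observed`, `p_greater`, `p_lesser`, `tested`, `note`.
#' @export
consistency_report <- function(networks, n_permutations = 1000, seed = 1L,
                               mode = c("sampled", "exact"), all_pairs = FALSE) {
  mode <- match.arg(mode)
  stopifnot(all(vapply(networks, inherits, logical(1), "interaction_network")))
  k <- length(networks)
  pairs <- if (all_pairs && k >= 2) {
    which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  } else if (k >= 2) {
    cbind(seq_len(k - 1), seq_len(k - 1) + 1L)
  } else {
    matrix(integer(0), 0, 2)
  }
  rows <- lapply(seq_len(nrow(pairs)), function(p) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    na <- networks[[i]]; nb <- networks[[j]]
    base <- data.frame(session_a = na$session_id, session_b = nb$session_id,
                       n = NA_integer_, r_observed = NA_real_,
                       p_greater = NA_real_, p_lesser = NA_real_,
                       tested = FALSE, note = "", stringsAsFactors = FALSE)
    if (!setequal(na$individuals, nb$individuals)) {
      base$note <- "skipped: different individuals"
      return(base)
    }
    q <- tryCatch(qap_test(na, nb, n_permutations,
                           seed = substream_seed(seed, paste0(na$session_id, "-", nb$session_id)),
                           mode = mode),
                  error = function(e) e)
    if (inherits(q, "error")) {
      base$note <- paste("skipped:", conditionMessage(q))
      return(base)
    }
    base$n <- q$n_individuals
    base$r_observed <- q$r_observed
    base$p_greater <- q$p_greater
    base$p_lesser <- q$p_lesser
    base$tested <- TRUE
    base
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(session_a = character(0), session_b = character(0),
               n = integer(0), r_observed = numeric(0), p_greater = numeric(0),
               p_lesser = numeric(0), tested = logical(0), note = character(0))
  class(out) <- c("qap_consistency", "data.frame")
  out
}

#' @export
print.qap_consistency <- function(x, ...) {
  cat("QAP consistency of consecutive networks\n")
  df <- as.data.frame(x)
  df$r_observed <- round(df$r_observed, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
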