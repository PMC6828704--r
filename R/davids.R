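#' David's scores from a win-loss matrix
#'
#' An order-independent dominance index. For each dyad with `n_ij > 0`
#' interactions, the win proportion is `P_ij = wins_ij / n_ij`; the
#' chance-corrected dyadic index shrinks it toward 0.5 in proportion to
#' how little the dyad interacted:
#' `D_ij = P_ij - (P_ij - 0.5) / (n_ij + 1)`.
#' Non-interacting dyads contribute 0 to every sum. Then
#' `w_i = sum_j D_ij`, `w2_i = sum_j D_ij * w_j`, `l_i = sum_j D_ji`,
#' `l2_i = sum_j D_ji * l_j`, and `DS_i = w_i + w2_i - l_i - l2_i`,
#' normalized as `normDS_i = (DS_i + N(N-1)/2) / N` (range 0 to N-1).
#' `sum_i DS_i = 0` always. The uncorrected variant built from raw `P`
#' is reported alongside (`DS_raw`, `normDS_raw`).
#'
#' @param win_loss Square matrix with dimnames: cell `(i, j)` = wins of
#'   `i` over `j` (see [build_win_loss_matrix()]).
#' @return A `davids_scores` object: matrices `P`, `D`, vectors `w`,
#'   `w2`, `l`, `l2`, `DS`, `normDS`, `DS_raw`, `normDS_raw`, and
#'   `ranking` (descending `DS`, ties by total wins then identifier).
#' @export
davids_scores <- function(win_loss) {
  stopifnot(is.matrix(win_loss), nrow(win_loss) == ncol(win_loss))
  n <- nrow(win_loss)
  if (n < 2) stop("David's scores need at least 2 individuals")
  ids <- rownames(win_loss) %||% paste0("ind", seq_len(n))
  wl <- matrix(as.numeric(win_loss), n, n, dimnames = list(ids, ids))
  nij <- wl + t(wl)
  P <- matrix(0, n, n, dimnames = list(ids, ids))
  has <- nij > 0
  P[has] <- wl[has] / nij[has]
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  D[has] <- P[has] - (P[has] - 0.5) / (nij[has] + 1)
  diag(P) <- 0
  diag(D) <- 0

  ds_parts <- function(M) {
    w <- rowSums(M)
    l <- colSums(M)
    w2 <- as.vector(M %*% w)
    l2 <- as.vector(t(M) %*% l)
    list(w = w, w2 = w2, l = l, l2 = l2, DS = w + w2 - l - l2)
  }
  corr <- ds_parts(D)
  raw <- ds_parts(P)
  norm_ds <- function(DS) (DS + n * (n - 1) / 2) / n
  wins <- rowSums(wl)
  DS <- stats::setNames(corr$DS, ids)
  structure(list(individuals = ids, P = P, D = D,
                 w = stats::setNames(corr$w, ids),
                 w2 = stats::setNames(corr$w2, ids),
                 l = stats::setNames(corr$l, ids),
                 l2 = stats::setNames(corr$l2, ids),
                 DS = DS, normDS = stats::setNames(norm_ds(DS), ids),
                 DS_raw = stats::setNames(raw$DS, ids),
                 normDS_raw = stats::setNames(norm_ds(raw$DS), ids),
                 ranking = rank_individuals(DS, wins, ids)),
            class = "davids_scores")
}

#' @export
print.davids_scores <- function(x, ...) {
  cat("David's scores (chance-corrected),", length(x$individuals), "individuals\n")
  out <- data.frame(DS = x$DS, normDS = x$normDS)[order(-x$DS), ]
  print(round(out, 3))
  invisible(x)
}

#' @export
coef.davids_scores <- function(object, ...) object$DS

#' @export
summary.davids_scores <- function(object, ...) {
  data.frame(individual = object$individuals,
             w = object$w, w2 = object$w2, l = object$l, l2 = object$l2,
             DS = object$DS, normDS = object$normDS,
             rank = match(object$individuals, object$ranking),
             row.names = NULL)[order(match(object$individuals, object$ranking)), ]
}

#' Compare Elo and David's score rankings
#'
#' Pearson correlation (with two-sided p from the t transform) between the
#' two score vectors, plus Spearman rank agreement. With fewer than 3
#' paired individuals the correlations are reported without p-values.
#'
#' @param elo An `elo_result` or a named numeric vector of scores.
#' @param ds A `davids_scores` or a named numeric vector of scores.
#' @return A `rank_comparison`: `n`, `pearson_r`, `pearson_p`,
#'   `spearman_rho`, `spearman_p`.
#' @export
compare_rankings <- function(elo, ds) {
  a <- if (inherits(elo, "elo_result")) elo$mean_scores else elo
  b <- if (inherits(ds, "davids_scores")) ds$DS else ds
  stopifnot(is.numeric(a), is.numeric(b), !is.null(names(a)), !is.null(names(b)))
  if (!setequal(names(a), names(b))) stop("individual sets differ")
  b <- b[names(a)]
  n <- length(a)
  if (n < 3) {
    r <- if (n == 2) stats::cor(a, b) else NA_real_
    rho <- if (n == 2) stats::cor(a, b, method = "spearman") else NA_real_
    res <- list(n = n, pearson_r = r, pearson_p = NA_real_,
                spearman_rho = rho, spearman_p = NA_real_)
  } else {
    pe <- suppressWarnings(stats::cor.test(a, b, method = "pearson"))
    sp <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
    res <- list(n = n, pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
                spearman_rho = unname(sp$estimate), spearman_p = sp$p.value)
  }
  structure(res, class = "rank_comparison")
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat(sprintf("Elo vs David's scores (n = %d): Pearson r = %.3f", x$n, x$pearson_r))
  if (!is.na(x$pearson_p)) cat(sprintf(" (p = %.3g)", x$pearson_p))
  cat(sprintf("; Spearman rho = %.3f", x$spearman_rho))
  if (!is.na(x$spearman_p)) cat(sprintf(" (p = %.3g)", x$spearman_p))
  cat("\n")
  invisible(x)
}
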