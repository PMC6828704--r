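#' Read and validate dyadic interaction records
#'
#' Reads an interaction table (one row per observed dyadic interaction) and
#' a session table, annotates each record with its behavioural category from
#' the ethogram, validates the result, and returns records ordered by
#' session and within-session temporal order.
#'
#' The interaction table must have columns `session_id`, `order_index`,
#' `initiator_id`, `recipient_id`, `behaviour_code`, `outcome`. `outcome`
#' is one of `initiator_wins`, `recipient_wins`, `draw` for agonistic
#' records and `not_applicable` (or empty) otherwise. The session table
#' must have columns `session_id`, `date`, `duration_hours`,
#' `individuals_present` (identifiers separated by `;`).
#'
#' Records whose behaviour code maps to the `ambiguous` category are
#' retained and flagged in the `category` column but are excluded from
#' every downstream computation (tallies report them separately;
#' hierarchies and networks never see them).
#'
#' @param interaction_file CSV/TSV path (delimiter inferred from extension).
#' @param session_file CSV/TSV path.
#' @param ethogram An `ethogram` object, named list/vector coercible via
#'   [as_ethogram()], or a path to a YAML/JSON ethogram file.
#' @return A list with `records` (data.frame of validated
#'   interaction records) and `sessions` (data.frame with list-column
#'   `individuals_present`).
#' @export
read_interactions <- function(interaction_file, session_file, ethogram) {
  rec <- read_delim_auto(interaction_file)
  ses <- read_delim_auto(session_file)
  if (is.character(ethogram) && length(ethogram) == 1 && file.exists(ethogram)) {
    ethogram <- read_ethogram(ethogram)
  } else if (!inherits(ethogram, "ethogram")) {
    ethogram <- as_ethogram(ethogram)
  }
  sessions <- parse_sessions(ses)
  records <- validate_interactions(rec, sessions, ethogram)
  list(records = records, sessions = sessions)
}

read_delim_auto <- function(path) {
  stopifnot(file.exists(path))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8",
                    check.names = TRUE)
}

parse_sessions <- function(ses) {
  needed <- c("session_id", "date", "duration_hours", "individuals_present")
  missing_cols <- setdiff(needed, names(ses))
  if (length(missing_cols)) {
    stop("session table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(ses$session_id)) stop("duplicated session_id in session table")
  dur <- as.numeric(ses$duration_hours)
  if (any(is.na(dur)) || any(dur <= 0)) stop("duration_hours must be positive")
  present <- lapply(strsplit(ses$individuals_present, ";", fixed = TRUE),
                    function(v) trimws(v[nzchar(trimws(v))]))
  if (any(lengths(present) == 0)) stop("individuals_present must be non-empty")
  data.frame(session_id = ses$session_id,
             date = as.Date(ses$date),
             duration_hours = dur,
             individuals_present = I(present),
             stringsAsFactors = FALSE)
}

#' Validate and categorize an interaction data.frame
#'
#' Applied by [read_interactions()]; exported so in-memory tables (e.g.
#' from [simulate_group()]) can be validated the same way.
#'
#' @param rec data.frame with the interaction-table columns.
#' @param sessions data.frame as returned in `$sessions`.
#' @param ethogram An `ethogram`.
#' @return The records data.frame with a `category` column, ordered by
#'   session (in session-table order) and `order_index`.
#' @export
validate_interactions <- function(rec, sessions, ethogram) {
  needed <- c("session_id", "order_index", "initiator_id", "recipient_id",
              "behaviour_code", "outcome")
  missing_cols <- setdiff(needed, names(rec))
  if (length(missing_cols)) {
    stop("interaction table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!inherits(ethogram, "ethogram")) ethogram <- as_ethogram(ethogram)
  rec$order_index <- as.integer(rec$order_index)
  unknown <- setdiff(unique(rec$behaviour_code), names(ethogram))
  if (length(unknown)) {
    stop("unknown behaviour code(s): ", paste(unknown, collapse = ", "))
  }
  self <- rec$initiator_id == rec$recipient_id
  if (any(self)) {
    stop("initiator equals recipient in row(s): ",
         paste(utils::head(which(self), 5), collapse = ", "))
  }
  missing_ses <- setdiff(unique(rec$session_id), sessions$session_id)
  if (length(missing_ses)) {
    stop("session(s) absent from session table: ", paste(missing_ses, collapse = ", "))
  }
  rec$category <- unname(unclass(ethogram)[rec$behaviour_code])
  out <- ifelse(is.na(rec$outcome) | rec$outcome == "", "not_applicable", rec$outcome)
  bad_out <- !out %in% c("initiator_wins", "recipient_wins", "draw", "not_applicable")
  if (any(bad_out)) {
    stop("invalid outcome value(s): ", paste(unique(out[bad_out]), collapse = ", "))
  }
  ag <- rec$category == "agonistic"
  if (any(ag & out == "not_applicable")) {
    stop("agonistic record(s) without an outcome (need initiator_wins, recipient_wins or draw)")
  }
  if (any(!ag & out != "not_applicable")) {
    stop("non-agonistic record(s) carry a win/loss outcome")
  }
  rec$outcome <- out
  # roster check: every participant must be present in the session
  for (s in unique(rec$session_id)) {
    roster <- sessions$individuals_present[[match(s, sessions$session_id)]]
    inds <- unique(c(rec$initiator_id[rec$session_id == s],
                     rec$recipient_id[rec$session_id == s]))
    extra <- setdiff(inds, roster)
    if (length(extra)) {
      stop("individual(s) ", paste(extra, collapse = ", "),
           " interact in session ", s, " but are not in its roster")
    }
  }
  ord <- order(match(rec$session_id, sessions$session_id), rec$order_index)
  if (anyDuplicated(rec[ord, c("session_id", "order_index")])) {
    stop("order_index must strictly order records within a session")
  }
  rownames(rec) <- NULL
  rec[ord, c(needed[1:5], "category", "outcome")]
}

#' Write interaction records and sessions back to CSV
#'
#' Inverse of [read_interactions()]: writing then re-reading reproduces the
#' records field-for-field.
#'
#' @param records,sessions As returned by [read_interactions()] or
#'   [simulate_group()].
#' @param interaction_file,session_file Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_interactions <- function(records, sessions, interaction_file, session_file) {
  rec <- records[, c("session_id", "order_index", "initiator_id",
                     "recipient_id", "behaviour_code", "outcome")]
  utils::write.csv(rec, interaction_file, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  ses <- data.frame(session_id = sessions$session_id,
                    date = as.character(sessions$date),
                    duration_hours = sessions$duration_hours,
                    individuals_present = vapply(sessions$individuals_present,
                                                 paste, character(1), collapse = ";"))
  utils::write.csv(ses, session_file, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(c(interaction_file, session_file))
}

#' Tally interactions by category and session
#'
#' Totals and per-session counts for each behavioural category, with the
#' per-session mean and SD computed over all provided sessions (sessions
#' with no record of a category count as zero). With a single session the
#' SD is `NA`.
#'
#' @param records,sessions As returned by [read_interactions()].
#' @return An `interaction_tally`: list with `per_session` (session x
#'   category counts) and `totals` (category, total, mean, sd).
#' @export
tally_interactions <- function(records, sessions) {
  cats <- c("agonistic", "affiliative", "ambiguous")
  per <- matrix(0L, nrow = nrow(sessions), ncol = length(cats),
                dimnames = list(sessions$session_id, cats))
  if (nrow(records) > 0) {
    tab <- table(factor(records$session_id, levels = sessions$session_id),
                 factor(records$category, levels = cats))
    per[] <- as.integer(tab)
  }
  totals <- data.frame(
    category = cats,
    total = colSums(per),
    mean = colMeans(per),
    sd = apply(per, 2, stats::sd),
    row.names = NULL
  )
  structure(list(per_session = as.data.frame(per), totals = totals),
            class = "interaction_tally")
}

#' @export
print.interaction_tally <- function(x, ...) {
  cat("Interaction tally over", nrow(x$per_session), "session(s)\n\n")
  print(x$per_session)
  cat("\n")
  t <- x$totals
  for (i in seq_len(nrow(t))) {
    cat(sprintf("  %-11s total %4d  per session %.1f +/- %s\n",
                t$category[i], t$total[i], t$mean[i],
                ifelse(is.na(t$sd[i]), "NA", sprintf("%.1f", t$sd[i]))))
  }
  invisible(x)
}

#' Win-loss matrix from decided agonistic interactions
#'
#' Cell `(i, j)` counts the agonistic interactions that `i` won against
#' `j`. Draws are excluded (they carry no winner), as are affiliative and
#' ambiguous records. The matrix always spans the full `individuals` list,
#' so individuals with no interaction contribute all-zero rows/columns.
#'
#' @param records Interaction records (any mix; filtered internally to
#'   agonistic).
#' @param individuals Character vector of identifiers defining matrix
#'   order and dimension.
#' @return Integer matrix with `individuals` as dimnames and attribute
#'   `n_decided` (number of decided records counted).
#' @export
build_win_loss_matrix <- function(records, individuals) {
  stopifnot(length(individuals) >= 1, !anyDuplicated(individuals))
  ag <- records[records$category == "agonistic", , drop = FALSE]
  extra <- setdiff(unique(c(ag$initiator_id, ag$recipient_id)), individuals)
  if (length(extra)) {
    stop("record(s) involve individual(s) not in the list: ",
         paste(extra, collapse = ", "))
  }
  m <- matrix(0L, length(individuals), length(individuals),
              dimnames = list(individuals, individuals))
  dec <- ag[ag$outcome != "draw", , drop = FALSE]
  if (nrow(dec) > 0) {
    winner <- ifelse(dec$outcome == "initiator_wins", dec$initiator_id, dec$recipient_id)
    loser <- ifelse(dec$outcome == "initiator_wins", dec$recipient_id, dec$initiator_id)
    tab <- table(factor(winner, levels = individuals),
                 factor(loser, levels = individuals))
    m[] <- as.integer(tab)
  }
  attr(m, "n_decided") <- nrow(dec)
  m
}
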