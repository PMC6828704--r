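#' Configuration for the full analysis pipeline
#'
#' Bundles input locations (or in-memory data), Elo and QAP settings, and
#' a single global seed that is fanned out to named substreams (one per
#' stochastic stage and session), so any stage can be re-run in isolation
#' reproducibly.
#'
#' @param interaction_file,session_file Paths to the interaction and
#'   session tables (CSV/TSV), or `NULL` when `data` is supplied.
#' @param ethogram An ethogram object/list or path to a YAML/JSON file.
#' @param data Optional in-memory input: a `sim_group` or a
#'   `list(records =, sessions =)` as returned by [read_interactions()].
#' @param elo An [elo_config()] (its `rng_seed` is overridden by derived
#'   streams of `seed`).
#' @param qap_n_permutations,qap_mode,all_pairs QAP settings (see
#'   [consistency_report()]).
#' @param out_dir Optional directory for `report.json` and `report.txt`.
#' @param seed Global seed.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(interaction_file = NULL, session_file = NULL,
                            ethogram = default_ethogram(), data = NULL,
                            elo = elo_config(),
                            qap_n_permutations = 1000,
                            qap_mode = c("sampled", "exact"),
                            all_pairs = FALSE,
                            out_dir = NULL, seed = 1L) {
  qap_mode <- match.arg(qap_mode)
  if (is.null(data)) {
    stopifnot(!is.null(interaction_file), !is.null(session_file))
    for (f in c(interaction_file, session_file)) {
      if (!file.exists(f)) stop("input file not found: ", f)
    }
  }
  structure(list(interaction_file = interaction_file, session_file = session_file,
                 ethogram = ethogram, data = data, elo = elo,
                 qap_n_permutations = qap_n_permutations, qap_mode = qap_mode,
                 all_pairs = all_pairs, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the full dominance and network analysis
#'
#' Executes every stage in order: ingest and validate the interaction
#' records; tally by category; per observation session infer the
#' dominance hierarchy by randomized Elo-rating and by David's scores and
#' compare the two; build the agonistic and affiliative per-session
#' networks ordered by the session's Elo ranking; and test network
#' consistency through time with QAP for consecutive same-roster session
#' pairs. Sessions without a decided agonistic record are skipped from
#' hierarchy inference and listed in the report's skip list.
#'
#' @param config An [analysis_config()].
#' @return An `analysis_report`: `tally`, `hierarchies` (per-session list
#'   of `elo`, `davids`, `comparison`), `pooled_comparison` (per-day score
#'   pairs pooled across sessions), `networks` (per type, per session),
#'   `consistency` (per type), `skipped`, `provenance`. Written to
#'   `config$out_dir` as JSON and text when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  if (!is.null(config$data)) {
    sessions <- config$data$sessions
    records <- validate_interactions(config$data$records, sessions, config$ethogram)
  } else {
    inp <- read_interactions(config$interaction_file, config$session_file,
                             config$ethogram)
    records <- inp$records
    sessions <- inp$sessions
  }
  tally <- tally_interactions(records, sessions)
  skipped <- list()

  hierarchies <- list()
  pooled_elo <- numeric(0)
  pooled_ds <- numeric(0)
  rankings <- list()
  for (s in sessions$session_id) {
    present <- sessions$individuals_present[[match(s, sessions$session_id)]]
    recs <- records[records$session_id == s, , drop = FALSE]
    dec <- decided_contests(recs)
    if (nrow(dec) == 0) {
      skipped[[length(skipped) + 1L]] <- list(
        stage = "dominance", session = s,
        reason = "no decided agonistic records")
      rankings[[s]] <- sort(present)
      next
    }
    cfg <- config$elo
    cfg$rng_seed <- substream_seed(config$seed, paste0("elo-", s))
    elo <- randomized_elo(recs, present, cfg)
    ds <- davids_scores(build_win_loss_matrix(recs, present))
    hierarchies[[s]] <- list(elo = elo, davids = ds,
                             comparison = compare_rankings(elo, ds))
    rankings[[s]] <- elo$ranking
    pooled_elo <- c(pooled_elo, stats::setNames(elo$mean_scores,
                                                paste(s, names(elo$mean_scores))))
    pooled_ds <- c(pooled_ds, stats::setNames(ds$DS, paste(s, names(ds$DS))))
  }
  pooled_comparison <- if (length(pooled_elo) >= 2) {
    compare_rankings(pooled_elo, pooled_ds)
  } else NULL

  networks <- list(agonistic = list(), affiliative = list())
  for (s in sessions$session_id) {
    srow <- sessions[sessions$session_id == s, , drop = FALSE]
    for (ty in c("agonistic", "affiliative")) {
      networks[[ty]][[s]] <- build_network(records, srow, ty, rankings[[s]])
    }
  }
  consistency <- lapply(networks, function(nets) {
    consistency_report(unname(nets), n_permutations = config$qap_n_permutations,
                       seed = substream_seed(config$seed, "qap"),
                       mode = config$qap_mode, all_pairs = config$all_pairs)
  })

  report <- structure(list(
    tally = tally, hierarchies = hierarchies,
    pooled_comparison = pooled_comparison,
    networks = networks, consistency = consistency, skipped = skipped,
    provenance = list(seed = config$seed,
                      package_version = as.character(utils::packageVersion("dominet")),
                      elo = unclass(config$elo)[c("init_score", "k", "n_randomizations",
                                                  "sigmoid_scale", "update")],
                      qap = list(n_permutations = config$qap_n_permutations,
                                 mode = config$qap_mode),
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "analysis_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Serialize an analysis report
#'
#' Writes `report.json` (machine-readable; every number regenerable from
#' config + inputs + seed, the timestamp being the only run-specific
#' field) and `report.txt` (the printed report).
#'
#' @param report An `analysis_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  js <- list(
    tally = list(per_session = report$tally$per_session,
                 totals = report$tally$totals),
    hierarchies = lapply(report$hierarchies, function(h) list(
      mean_elo_scores = as.list(h$elo$mean_scores),
      elo_ranking = h$elo$ranking,
      n_contests = h$elo$n_events,
      davids_DS = as.list(h$davids$DS),
      davids_normDS = as.list(h$davids$normDS),
      davids_ranking = h$davids$ranking,
      comparison = unclass(h$comparison))),
    pooled_comparison = if (!is.null(report$pooled_comparison))
      unclass(report$pooled_comparison) else NULL,
    networks = lapply(report$networks, function(nets) lapply(nets, function(nw) list(
      session_id = nw$session_id, individuals = nw$individuals,
      duration_hours = nw$duration_hours,
      raw_counts = nw$raw_counts, weights = nw$weights))),
    consistency = lapply(report$consistency, as.data.frame),
    skipped = report$skipped,
    provenance = report$provenance)
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("==== Dominance and social-network analysis report ====\n\n")
  print(x$tally)
  cat("\n-- Per-session hierarchies --\n")
  for (s in names(x$hierarchies)) {
    h <- x$hierarchies[[s]]
    cat(sprintf("%s: Elo ranking %s (%d contests); Elo-vs-David's r = %.3f\n",
                s, paste(h$elo$ranking, collapse = " > "), h$elo$n_events,
                h$comparison$pearson_r))
  }
  if (!is.null(x$pooled_comparison)) {
    cat("\nPooled across sessions: ")
    print(x$pooled_comparison)
  }
  for (ty in names(x$consistency)) {
    cat(sprintf("\n-- %s network consistency --\n", ty))
    print(x$consistency[[ty]])
  }
  if (length(x$skipped)) {
    cat("\nSkipped stages:\n")
    for (sk in x$skipped) {
      cat(sprintf("  %s / %s: %s\n", sk$stage, sk$session, sk$reason))
    }
  }
  cat(sprintf("\nSeed %d, package version %s\n", x$provenance$seed,
              x$provenance$package_version))
  invisible(x)
}
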