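# Run report: the tabulations a swarm-acoustics run produces (per-period
# tone summaries, event counts, scenario tables) plus the contingency
# statistics block.

#' Assemble the run report
#'
#' Collects per-period frequency/amplitude summaries per sex, event
#' counts per swarm period, the mixed-sex scenario count table with its
#' equal-probability goodness-of-fit statistic and BH post-hoc
#' comparisons, and (optionally) writes everything as CSV plus a
#' human-readable text summary. Missing stages produce a partial report
#' with explicit gaps.
#'
#' @param analysis A [analyze_swarm()] result.
#' @param interactions Optional [sampled_interactions()] result; computed
#'   from `analysis` when omitted.
#' @param out_dir Optional directory for CSV/text export.
#' @return A `swarm_report` list of tables and statistics.
#' @export
build_report <- function(analysis, interactions = NULL, out_dir = NULL) {
  stopifnot(inherits(analysis, "swarm_analysis"))
  rep_tables <- list()
  rep_tables$period_summary <- do.call(rbind, lapply(
    names(analysis$period_summary), function(sx) {
      cbind(sex = sx, analysis$period_summary[[sx]])
    }))

  ev <- analysis$events
  ev_counts <- stats::setNames(integer(length(SWARM_PERIODS)),
                               SWARM_PERIODS)
  if (!is.null(ev) && nrow(ev)) {
    per <- swarm_period_of(pmin(ev$onset, 3599.99))
    tb <- table(per)
    ev_counts[names(tb)] <- as.integer(tb)
  }
  rep_tables$event_counts <- data.frame(period = names(ev_counts),
                                        n_events = as.integer(ev_counts))

  if (is.null(interactions)) {
    interactions <- tryCatch(sampled_interactions(analysis),
                             error = function(e) NULL)
  }
  stats_block <- list()
  if (!is.null(interactions) && nrow(interactions)) {
    sc <- table(interactions$scenario)
    rep_tables$scenario_counts <- data.frame(
      scenario = names(sc), n = as.integer(sc))
    if (sum(sc) > 0 && all(as.integer(sc) >= 0)) {
      gof <- chisq_gof(as.integer(sc))
      stats_block$scenario_gof <- gof
      stats_block$scenario_posthoc <- tryCatch(
        posthoc_pairwise_gof(stats::setNames(as.integer(sc), names(sc))),
        error = function(e) NULL)
    }
    rep_tables$interactions <- interactions
  } else {
    rep_tables$scenario_counts <- NULL
  }

  out <- structure(list(tables = rep_tables, stats = stats_block),
                   class = "swarm_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(rep_tables)) {
      if (is.data.frame(rep_tables[[nm]]))
        utils::write.csv(rep_tables[[nm]],
                         file.path(out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
    }
    txt <- utils::capture.output(print(out))
    writeLines(txt, file.path(out_dir, "summary.txt"))
  }
  out
}

#' @export
print.swarm_report <- function(x, ...) {
  cat("== Swarm acoustics report ==\n\n-- Per-period tone summary --\n")
  print(x$tables$period_summary, row.names = FALSE)
  cat("\n-- Interaction events per period --\n")
  print(x$tables$event_counts, row.names = FALSE)
  if (!is.null(x$tables$scenario_counts)) {
    cat("\n-- Outcome scenarios (5-min cadence) --\n")
    print(x$tables$scenario_counts, row.names = FALSE)
    if (!is.null(x$stats$scenario_gof))
      cat(sprintf("\nGOF chi-square = %.3f, df = %d, p = %.4g\n",
                  x$stats$scenario_gof$statistic, x$stats$scenario_gof$df,
                  x$stats$scenario_gof$p_value))
  } else {
    cat("\n(no sampled interactions: scenario table unavailable)\n")
  }
  invisible(x)
}
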