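#' Deterministic file outputs
#'
#' Runs are written as plain text: `records.csv` (one life-history row per
#' agent), `events.csv`, `yearly.csv` and `run_meta.json` (config echo,
#' seed, package version, conservation counters) — enough to reproduce the
#' run byte-for-byte. Floating-point columns are written at 6 significant
#' digits for stable diffs.
#'
#' @name cli_io
NULL

round6 <- function(df) {
  for (cl in names(df)) {
    if (is.double(df[[cl]])) df[[cl]] <- signif(df[[cl]], 6)
  }
  df
}

#' Write a run to a directory
#'
#' @param x an `allosim` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_run <- function(x, dir) {
  stopifnot(inherits(x, "allosim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("records.csv", "events.csv", "yearly.csv",
                            "run_meta.json"))
  utils::write.csv(round6(x$records), paths[1], row.names = FALSE)
  utils::write.csv(round6(x$events), paths[2], row.names = FALSE)
  utils::write.csv(round6(x$yearly), paths[3], row.names = FALSE)
  cfg <- unclass(x$config)
  meta <- list(
    seed = x$seed,
    package_version = as.character(utils::packageVersion("allosim")),
    config = cfg[setdiff(names(cfg), "trait_table")],
    trait_table = x$config$trait_table,
    counters = x$counters,
    annual_spawns = x$annual_spawns
  )
  jsonlite::write_json(meta, paths[4], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Read a records file back
#'
#' @param path path to a `records.csv` written by [write_run()].
#' @return records data.frame, validated for the columns the analysis
#'   layer needs.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("no such records file: ", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(rec) == 0L) stop("records file is empty: ", path)
  need <- c("id", "offspring", "mean_mass", trait_names())
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    stop("records file is missing required columns: ",
         paste(miss, collapse = ", "))
  }
  rec
}

#' Summarise a run (or a records file) to disk
#'
#' Writes `summary.json` with the headline selection statistics, a
#' `lrs_bin_table.csv` replica of the offspring-binned trait means, and —
#' when yearly snapshots are available — `composition.csv`.
#'
#' @param records an `allosim` object, a records data.frame, or the path
#'   to a `records.csv`.
#' @param out_dir output directory.
#' @param yearly optional yearly data.frame (taken from the run object
#'   automatically when `records` is one).
#' @return the summary list, invisibly.
#' @export
analyze_records <- function(records, out_dir, yearly = NULL) {
  if (is.character(records)) records <- read_records(records)
  if (inherits(records, "allosim")) {
    if (is.null(yearly)) yearly <- records$yearly
    records <- records$records
  }
  tab <- fitness_table(records)
  succ <- successful_mass_mean(tab)
  summ <- list(
    agents_produced = nrow(tab),
    zero_offspring_fraction = zero_offspring_fraction(tab),
    max_offspring = max(tab$offspring),
    tailfat_probabilities =
      as.list(offspring_probability(tab, "tailfat", 35, k = 1)),
    tailfat_fitness_ratio = fitness_ratio(tab, "tailfat", 35, k = 1),
    bite_force_probabilities =
      as.list(offspring_probability(tab, "bite_force", 0.11, k = 1)),
    bite_force_fitness_ratio = fitness_ratio(tab, "bite_force", 0.11, k = 1),
    successful_mean_mass = succ$mass,
    successful_mean_tailfat = succ$tailfat,
    successful_n = succ$n
  )
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(round6(bin_summary(tab)),
                   file.path(out_dir, "lrs_bin_table.csv"),
                   row.names = FALSE)
  if (!is.null(yearly)) {
    utils::write.csv(round6(composition_timeseries(yearly)),
                     file.path(out_dir, "composition.csv"),
                     row.names = FALSE)
  }
  invisible(summ)
}
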