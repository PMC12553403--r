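#' Time-control settings
#'
#' A time control `S+I` gives each player `S` seconds on a countdown clock at
#' the start of the game and adds back `I` seconds ("increment") after each of
#' their moves. A player whose clock reaches zero loses ("flagging").
#'
#' @param start_seconds Starting clock time S, in seconds (> 0).
#' @param increment_seconds Per-move increment I, in seconds (>= 0).
#' @return An object of class `time_control` with fields `start_seconds`,
#'   `increment_seconds` and the rendered `label` `"S+I"`.
#' @examples
#' time_control(300, 0)
#' time_control(60, 3)$label
#' @export
time_control <- function(start_seconds, increment_seconds = 0) {
  if (!is.numeric(start_seconds) || length(start_seconds) != 1 ||
      start_seconds <= 0) {
    stop("`start_seconds` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(increment_seconds) || length(increment_seconds) != 1 ||
      increment_seconds < 0) {
    stop("`increment_seconds` must be a single non-negative number",
         call. = FALSE)
  }
  structure(
    list(start_seconds = start_seconds,
         increment_seconds = increment_seconds,
         label = sprintf("%g+%g", start_seconds, increment_seconds)),
    class = "time_control"
  )
}

#' @export
print.time_control <- function(x, ...) {
  cat("<time_control>", x$label, "\n")
  invisible(x)
}

#' Run configuration
#'
#' Holds the tunable analysis parameters shared across pipeline stages:
#' binning resolutions for the empirical value function, the consideration-set
#' size, the ply window used to exclude openings and deep endgames, the
#' opponent-clock floor for value-grid estimation, the offer time scaling
#' factor, and the clock-recording convention.
#'
#' @param time_bin_seconds Width of time-left bins, seconds (default 3).
#' @param utility_bin_width Width of advantage bins, utility units
#'   (default 0.03).
#' @param consideration_size Number of candidate moves per position
#'   (default 5).
#' @param ply_min,ply_max Inclusive ply window for analysis (defaults 15, 75).
#' @param opponent_min_clock Minimum opponent clock (seconds) for a move to
#'   enter the value grid. `NULL` (default) means 60 s, or 30 s for the 60+0
#'   time control; a number overrides both.
#' @param offer_scale_s Dimensionless scaling applied to raw offer times
#'   (default 20000).
#' @param min_count Minimum moves per value-grid cell for the cell's win
#'   proportion to count as estimable (default 50).
#' @param motor_time Baseline non-deliberative time per move, seconds, used
#'   when marginalizing policies into implied mean move times (default 0).
#' @param seed Optional integer seed.
#' @param clock_convention `"post_increment"` (default): recorded clocks obey
#'   `clock_after = clock_before - t + I`. `"subtract_increment"`: the increment is
#'   subtracted from the raw clock difference.
#' @return An object of class `run_config` (a named list).
#' @examples
#' run_config()
#' run_config(utility_bin_width = 0.05)$utility_bin_width
#' @export
run_config <- function(time_bin_seconds = 3,
                       utility_bin_width = 0.03,
                       consideration_size = 5,
                       ply_min = 15,
                       ply_max = 75,
                       opponent_min_clock = NULL,
                       offer_scale_s = 20000,
                       min_count = 50,
                       motor_time = 0,
                       seed = NULL,
                       clock_convention = c("post_increment",
                                            "subtract_increment")) {
  clock_convention <- match.arg(clock_convention)
  check_pos <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
      stop(sprintf("`%s` must be a single positive number", name),
           call. = FALSE)
    }
  }
  check_pos(time_bin_seconds, "time_bin_seconds")
  check_pos(utility_bin_width, "utility_bin_width")
  check_pos(consideration_size, "consideration_size")
  check_pos(offer_scale_s, "offer_scale_s")
  check_pos(min_count, "min_count")
  if (!is.numeric(motor_time) || motor_time < 0) {
    stop("`motor_time` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(ply_min) || !is.numeric(ply_max) || ply_min >= ply_max) {
    stop("`ply_min` must be less than `ply_max`", call. = FALSE)
  }
  if (!is.null(opponent_min_clock)) {
    check_pos(opponent_min_clock, "opponent_min_clock")
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(time_bin_seconds = time_bin_seconds,
         utility_bin_width = utility_bin_width,
         consideration_size = as.integer(consideration_size),
         ply_min = as.integer(ply_min),
         ply_max = as.integer(ply_max),
         opponent_min_clock = opponent_min_clock,
         offer_scale_s = offer_scale_s,
         min_count = as.integer(min_count),
         motor_time = motor_time,
         seed = seed,
         clock_convention = clock_convention),
    class = "run_config"
  )
}

# Effective opponent-clock floor: 60 s by default, 30 s for 60+0 games.
opponent_clock_floor <- function(config, tc_label) {
  if (!is.null(config$opponent_min_clock)) return(config$opponent_min_clock)
  if (identical(tc_label, "60+0")) 30 else 60
}

#' Read a run configuration from a YAML key:value file
#'
#' Unspecified keys take the [run_config()] defaults; unknown keys produce a
#' warning and are ignored; type-invalid values are fatal, naming the key.
#'
#' @param path Path to a YAML file of `key: value` pairs.
#' @return A [run_config()] object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, vals[intersect(names(vals), known)])
}

## ---- Move tables ----------------------------------------------------------

# Fixed column schema for move-level tables. The consideration set is stored
# wide: move_id_k / shallow_k / deep_k for k = 1..K, ordered by descending
# shallow value.
move_table_columns <- function(k) {
  c("game_id", "ply", "elo", "opp_clock", "clock_before", "clock_after",
    "tc_start", "tc_inc", "outcome",
    paste0("move_id_", seq_len(k)),
    paste0("shallow_", seq_len(k)),
    paste0("deep_", seq_len(k)))
}

outcome_levels <- c("win", "loss", "draw")

# Infer the consideration-set size from the columns of a table/header.
infer_consideration_size <- function(cols) {
  k <- 0L
  while (all(c(paste0("move_id_", k + 1L), paste0("shallow_", k + 1L),
               paste0("deep_", k + 1L)) %in% cols)) {
    k <- k + 1L
  }
  k
}

numeric_table_columns <- function(k) {
  c("ply", "elo", "opp_clock", "clock_before", "clock_after",
    "tc_start", "tc_inc", paste0("shallow_", seq_len(k)),
    paste0("deep_", seq_len(k)))
}

#' Read a move-level game table
#'
#' Reads the CSV schema written by [write_move_table()]: one row per move
#' event, carrying clocks, time control, the mover's Elo, the game outcome
#' from the mover's perspective, and the wide consideration-set columns
#' (`move_id_k`, `shallow_k`, `deep_k`). Rows whose required numeric fields
#' fail to parse (C locale, decimal points only) are skipped and counted; a
#' skip rate above 50% triggers a warning. Missing files or missing required
#' columns are fatal.
#'
#' @param path Path to a CSV move table.
#' @return A tibble of move records in file order, with attribute
#'   `n_skipped`.
#' @seealso [write_move_table()]
#' @export
read_move_table <- function(path) {
  if (!file.exists(path)) {
    stop("move table not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, stringsAsFactors = FALSE)
  k <- infer_consideration_size(names(raw))
  required_base <- c("game_id", "ply", "elo", "opp_clock", "clock_before",
                     "clock_after", "tc_start", "tc_inc", "outcome")
  missing_cols <- setdiff(required_base, names(raw))
  if (length(missing_cols) > 0) {
    stop("move table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (k < 1) {
    stop("move table is missing required column(s): move_id_1, shallow_1, ",
         "deep_1", call. = FALSE)
  }
  if (nrow(raw) == 0) {
    out <- empty_move_table(k)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  num_cols <- numeric_table_columns(k)
  parsed <- lapply(raw[num_cols], function(x) suppressWarnings(as.numeric(x)))
  bad_numeric <- Reduce(`|`, lapply(parsed, is.na))
  bad_outcome <- !(raw$outcome %in% outcome_levels)
  keep <- !(bad_numeric | bad_outcome)
  n_skipped <- sum(!keep)
  out <- tibble::tibble(game_id = raw$game_id[keep])
  for (col in num_cols) out[[col]] <- parsed[[col]][keep]
  out$outcome <- raw$outcome[keep]
  for (col in paste0("move_id_", seq_len(k))) out[[col]] <- raw[[col]][keep]
  if ("observed_move_id" %in% names(raw)) {
    out$observed_move_id <- raw$observed_move_id[keep]
  }
  out <- out[, intersect(c(move_table_columns(k), "observed_move_id"),
                         names(out))]
  out$ply <- as.integer(out$ply)
  voc_log("read_move_table",
          sprintf("%d records, %d skipped (%s)", nrow(out), n_skipped, path))
  if (nrow(raw) > 0 && n_skipped > nrow(raw) / 2) {
    warning(sprintf("more than half of rows skipped (%d of %d) in %s",
                    n_skipped, nrow(raw), path), call. = FALSE)
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

empty_move_table <- function(k) {
  cols <- move_table_columns(k)
  out <- tibble::as_tibble(
    stats::setNames(rep(list(numeric(0)), length(cols)), cols)
  )
  out$game_id <- character(0)
  out$ply <- integer(0)
  out$outcome <- character(0)
  for (col in paste0("move_id_", seq_len(k))) out[[col]] <- character(0)
  out[, cols]
}

#' Write a move-level game table
#'
#' Writes records in the documented column order (`game_id`, `ply`, `elo`,
#' `opp_clock`, `clock_before`, `clock_after`, `tc_start`, `tc_inc`,
#' `outcome`, then `move_id_k`/`shallow_k`/`deep_k`). RFC-4180-style quoting
#' via [utils::write.csv()]. Clocks are stored as decimal seconds.
#'
#' @param records A move-table tibble (as from [read_move_table()] or
#'   [generate_dataset()]).
#' @param path Output CSV path.
#' @return The number of data rows written, invisibly.
#' @export
write_move_table <- function(records, path) {
  k <- infer_consideration_size(names(records))
  if (k < 1) stop("records lack consideration-set columns", call. = FALSE)
  cols <- intersect(c(move_table_columns(k), "observed_move_id"),
                    names(records))
  missing_cols <- setdiff(move_table_columns(k), names(records))
  if (length(missing_cols) > 0) {
    stop("records are missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ok <- tryCatch({
    utils::write.csv(as.data.frame(records[, cols]), path, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("could not write move table to ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  }
  voc_log("write_move_table", sprintf("%d records (%s)", nrow(records), path))
  invisible(nrow(records))
}

#' Best-effort import shim for externally formatted move tables
#'
#' Maps a table with foreign column names onto the package schema using a
#' synonym dictionary (e.g. `white_elo`/`active_elo` to `elo`,
#' `pre_move_clock` to `clock_before`). Columns that cannot be mapped are
#' dropped with a message. The clock-recording semantics of external exports
#' (pre- versus post-increment) are often undocumented; pass the convention
#' explicitly when computing move times downstream.
#'
#' @param df A data frame with foreign column names.
#' @param extra_map Optional named character vector of additional
#'   `foreign = "canonical"` mappings, applied after the built-in ones.
#' @return A tibble using the package's column names.
#' @export
import_move_table <- function(df, extra_map = NULL) {
  synonyms <- c(
    gameid = "game_id", game = "game_id",
    move_ply = "ply", halfmove = "ply",
    active_elo = "elo", player_elo = "elo", white_elo = "elo",
    opp_clock_s = "opp_clock", opponent_clock = "opp_clock",
    pre_move_clock = "clock_before", clock = "clock_before",
    post_move_clock = "clock_after",
    time_control_start = "tc_start", base_time = "tc_start",
    time_control_increment = "tc_inc", increment = "tc_inc",
    result = "outcome"
  )
  if (!is.null(extra_map)) synonyms <- c(synonyms, extra_map)
  nm <- names(df)
  mapped <- ifelse(nm %in% names(synonyms), unname(synonyms[nm]), nm)
  dup <- duplicated(mapped)
  if (any(dup)) {
    voc_log("import_move_table",
            "dropping duplicate-mapped column(s): ",
            paste(nm[dup], collapse = ", "))
    df <- df[, !dup, drop = FALSE]
    mapped <- mapped[!dup]
  }
  names(df) <- mapped
  known <- c(move_table_columns(infer_consideration_size(mapped)),
             "observed_move_id")
  unknown <- setdiff(mapped, known)
  if (length(unknown) > 0) {
    voc_log("import_move_table", "dropping unmapped column(s): ",
            paste(unknown, collapse = ", "))
  }
  tibble::as_tibble(df[, intersect(known, mapped), drop = FALSE])
}
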