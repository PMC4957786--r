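# Canonical trial-table CSV: one row per choice trial.

TRIAL_COLUMNS <- c("participant_id", "age", "gender", "phase", "trial_index",
                   "role", "R0", "RD", "D_days", "choice", "other_choice",
                   "feedback", "k_o_true")

#' Write a cohort to the canonical trial-table CSV
#'
#' One row per trial with columns `participant_id, age, gender, phase,
#' trial_index, role, R0, RD, D_days, choice, other_choice, feedback,
#' k_o_true`. A `#`-prefixed header line records the generating seed.
#'
#' @param pop a `did_population` or single `participant_dataset`.
#' @param path output file.
#' @param seed seed recorded in the file header (defaults to the population's
#'   seed attribute).
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(pop, path, seed = attr(pop, "seed")) {
  if (inherits(pop, "participant_dataset")) pop <- list(pop)
  rows <- do.call(rbind, lapply(pop, function(d) {
    tr <- d$trials
    data.frame(participant_id = tr$participant_id,
               age = d$truth$age %||% NA_real_,
               gender = d$truth$gender %||% NA_character_,
               phase = tr$phase, trial_index = tr$trial_index,
               role = tr$role, R0 = tr$R0, RD = tr$RD, D_days = tr$D,
               choice = tr$choice, other_choice = tr$other_choice,
               feedback = tr$feedback,
               k_o_true = d$truth$k_o %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tasteshift trial table; seed: %s",
                     if (is.null(seed)) "NA" else seed), con)
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a canonical trial-table CSV
#'
#' Validates the schema and the protocol invariants (phase-1 rows are
#' self-role without feedback; phase-2 rows are other-role with feedback and
#' the Other's revealed choice; choices coded 0/1), reporting offending rows,
#' and groups rows into per-participant datasets.
#'
#' @param path CSV file written by [write_trial_table()] (or by an external
#'   converter producing the same schema).
#' @return A `did_population` list of `participant_dataset`s.
#' @export
read_trial_table <- function(path) {
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(TRIAL_COLUMNS, names(raw))
  if (length(missing))
    stop("trial table lacks required columns: ", paste(missing, collapse = ", "))
  bad <- function(cond, what) {
    if (any(cond))
      stop("invalid trial table: ", what, " (rows ",
           paste(utils::head(which(cond), 5), collapse = ", "), ")")
  }
  bad(!raw$phase %in% 1:3, "phase must be 1, 2 or 3")
  bad(!raw$role %in% c("self", "other"), "role must be self/other")
  bad(!raw$choice %in% c(0, 1), "choice must be coded 0/1")
  bad(raw$phase == 1 & raw$role != "self", "phase-1 rows must be self-role")
  bad(raw$phase == 1 & !is.na(raw$feedback), "phase-1 rows carry no feedback")
  bad(raw$phase == 2 & raw$role != "other", "phase-2 rows must be other-role")
  bad(raw$phase == 2 & (is.na(raw$feedback) | is.na(raw$other_choice)),
      "phase-2 rows need feedback and the Other's choice")
  bad(raw$role == "other" & !is.na(raw$other_choice) &
        !raw$other_choice %in% c(0, 1), "other_choice must be 0/1")
  bad(raw$R0 <= 0 | raw$D_days <= 0 | raw$RD <= raw$R0,
      "options must satisfy RD > R0 > 0, D > 0")
  ids <- unique(raw$participant_id)
  out <- lapply(ids, function(id) {
    g <- raw[raw$participant_id == id, ]
    g <- g[order(g$trial_index), ]
    trials <- data.frame(participant_id = g$participant_id, phase = g$phase,
                         trial_index = g$trial_index, role = g$role,
                         R0 = g$R0, RD = g$RD, D = g$D_days,
                         choice = g$choice, other_choice = g$other_choice,
                         feedback = g$feedback, stringsAsFactors = FALSE)
    structure(list(id = id, trials = trials,
                   truth = list(k_o = g$k_o_true[1], age = g$age[1],
                                gender = g$gender[1])),
              class = "participant_dataset")
  })
  structure(out, class = "did_population")
}

#' Serialise fit results
#'
#' @param fits a `did_fits` list.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_fits <- function(fits, path) {
  utils::write.csv(fits_table(fits), path, row.names = FALSE)
  invisible(path)
}

#' Write a report as JSON
#'
#' @param report a [results_report()] (or any JSON-serialisable list).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
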