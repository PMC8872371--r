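# Decision-task grids and the certainty-equivalent observation table,
# with validated CSV readers/writers.

#' Define a decision task
#'
#' A decision task is a 5 x 5 (in the default instrument) grid of loss
#' scenarios: each cell pairs an occurrence probability with a loss
#' magnitude, and the respondent chooses an infection-prevention
#' investment from a fixed menu; the chosen amount is read as the
#' certainty equivalent of the loss prospect.
#'
#' @param task_id integer task identifier.
#' @param probabilities strictly increasing occurrence probabilities,
#'   all in (0, 1).
#' @param losses_usd strictly increasing positive loss magnitudes (USD).
#' @param menu_usd strictly increasing offered investment amounts (USD);
#'   the largest offer may not exceed the largest loss.
#' @param money_scale positive normalization constant (USD per model
#'   unit); all monetary values are divided by this before entering the
#'   value function.
#' @return An object of class \code{"decision_task"}.
#' @seealso \code{\link{default_tasks}}
#' @export
decision_task <- function(task_id, probabilities, losses_usd, menu_usd,
                          money_scale = 1e5) {
  task_id <- as.integer(task_id)
  if (length(task_id) != 1L || is.na(task_id))
    cpt_abort("`task_id` must be a single integer", "cpt_task_error")
  if (any(probabilities <= 0) || any(probabilities >= 1) ||
      any(diff(probabilities) <= 0))
    cpt_abort("probabilities must be strictly increasing, all in (0, 1)",
              "cpt_task_error")
  if (any(losses_usd <= 0) || any(diff(losses_usd) <= 0))
    cpt_abort("losses must be strictly increasing, all > 0", "cpt_task_error")
  if (any(diff(menu_usd) <= 0))
    cpt_abort("menu must be strictly increasing", "cpt_task_error")
  if (max(menu_usd) > max(losses_usd))
    cpt_abort("max(menu) must not exceed max(losses)", "cpt_task_error")
  if (!is.numeric(money_scale) || length(money_scale) != 1L || money_scale <= 0)
    cpt_abort("`money_scale` must be a positive number", "cpt_task_error")
  structure(
    list(task_id = task_id,
         probabilities = as.numeric(probabilities),
         losses_usd = as.numeric(losses_usd),
         menu_usd = as.numeric(menu_usd),
         money_scale = as.numeric(money_scale)),
    class = "decision_task"
  )
}

#' @export
print.decision_task <- function(x, ...) {
  cat(sprintf("Decision task %d: %d probabilities x %d losses (%d scenarios)\n",
              x$task_id, length(x$probabilities), length(x$losses_usd),
              length(x$probabilities) * length(x$losses_usd)))
  cat("  probabilities:", paste(format(x$probabilities), collapse = ", "), "\n")
  cat("  losses (USD): ", paste(format(x$losses_usd, big.mark = ","),
                                collapse = ", "), "\n")
  cat("  menu (USD):   ", paste(format(x$menu_usd, big.mark = ","),
                                collapse = ", "), "\n")
  cat(sprintf("  money scale:   %s USD per model unit\n",
              format(x$money_scale, big.mark = ",")))
  invisible(x)
}

#' The two default decision tasks
#'
#' Task 1 frames the entrance of possibly infected stakeholders:
#' probabilities 1\%--90\%, losses USD 10,000--130,000, investment menu
#' USD 1,000--100,000. Task 2 frames asymptomatic entrants with much
#' rarer probabilities (0.1\%--9\%) and losses of USD 0.2--1.4 million,
#' menu USD 10,000--1,000,000. Task 2's three intermediate probabilities
#' are taken as a x3 ladder (0.3\%, 1\%, 3\%) mirroring Task 1 scaled by
#' one tenth; only the endpoints of its range are fixed by the
#' instrument, so the grid is configurable through
#' \code{\link{decision_task}}.
#'
#' @return A named list of two \code{\link{decision_task}} objects,
#'   \code{task1} and \code{task2}, each exposing 25 scenarios.
#' @examples
#' default_tasks()$task1
#' @export
default_tasks <- function() {
  list(
    task1 = decision_task(
      1L,
      probabilities = c(0.01, 0.03, 0.10, 0.30, 0.90),
      losses_usd = c(10000, 40000, 70000, 100000, 130000),
      menu_usd = c(1000, 3000, 10000, 30000, 100000)),
    task2 = decision_task(
      2L,
      probabilities = c(0.001, 0.003, 0.01, 0.03, 0.09),
      losses_usd = c(200000, 500000, 800000, 1100000, 1400000),
      menu_usd = c(10000, 30000, 100000, 300000, 1000000))
  )
}

#' Scenario grid of a task
#'
#' @param task a \code{\link{decision_task}}.
#' @return A data frame with one row per scenario: \code{scenario_id}
#'   (\code{"j.k"}, j indexing the probability, k the loss),
#'   \code{probability}, \code{loss_usd}.
#' @export
task_scenarios <- function(task) {
  stopifnot(inherits(task, "decision_task"))
  g <- expand.grid(j = seq_along(task$probabilities),
                   k = seq_along(task$losses_usd))
  data.frame(
    scenario_id = sprintf("%d.%d", g$j, g$k),
    probability = task$probabilities[g$j],
    loss_usd = task$losses_usd[g$k],
    stringsAsFactors = FALSE
  )
}

task_registry <- function(tasks) {
  if (inherits(tasks, "decision_task")) tasks <- list(tasks)
  ids <- vapply(tasks, function(t) t$task_id, integer(1))
  names(tasks) <- as.character(ids)
  tasks
}

#' Serialize a decision task to JSON
#'
#' @inheritParams task_scenarios
#' @param path optional file path to write to.
#' @return JSON string (invisibly when written to a file).
#' @export
task_to_json <- function(task, path = NULL) {
  stopifnot(inherits(task, "decision_task"))
  js <- jsonlite::toJSON(
    list(task_id = task$task_id, probabilities = task$probabilities,
         losses_usd = task$losses_usd, menu_usd = task$menu_usd,
         money_scale = task$money_scale),
    auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read a decision task from JSON
#'
#' @param x JSON string or path to a JSON file.
#' @return A \code{\link{decision_task}}.
#' @export
task_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  decision_task(obj$task_id, obj$probabilities, obj$losses_usd,
                obj$menu_usd, obj$money_scale)
}

obs_columns <- c("respondent_id", "task_id", "scenario_id",
                 "probability", "loss_usd", "ce_usd")

#' Validate certainty-equivalent observations against their task grids
#'
#' Checks, row by row, that the task is known, that the
#' (probability, loss) pair is a grid cell of that task consistent with
#' the scenario id, and that the certainty equivalent lies in
#' (0, loss]. Each failure raises a distinct classed condition
#' (\code{cpt_unknown_task}, \code{cpt_off_grid}, \code{cpt_ce_bounds},
#' \code{cpt_malformed_row}) naming the offending row.
#'
#' @param obs a data frame of observations with columns
#'   \code{respondent_id, task_id, scenario_id, probability, loss_usd,
#'   ce_usd}.
#' @param tasks a \code{\link{decision_task}} or list of tasks.
#' @return `obs`, invisibly, with class \code{"ce_observations"} added.
#' @export
validate_observations <- function(obs, tasks = default_tasks()) {
  tasks <- task_registry(tasks)
  missing_cols <- setdiff(obs_columns, names(obs))
  if (length(missing_cols))
    cpt_abort(paste("missing columns:", paste(missing_cols, collapse = ", ")),
              "cpt_malformed_row")
  for (col in c("task_id", "probability", "loss_usd", "ce_usd")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(obs[[col]]))))
    if (length(bad))
      cpt_abort(sprintf("row %d: column `%s` is not a finite number",
                        bad[1], col), "cpt_malformed_row")
  }
  for (i in seq_len(nrow(obs))) {
    tid <- as.character(obs$task_id[i])
    task <- tasks[[tid]]
    if (is.null(task))
      cpt_abort(sprintf("row %d: unknown task_id %s", i, tid),
                "cpt_unknown_task")
    j <- match_grid(obs$probability[i], task$probabilities)
    k <- match_grid(obs$loss_usd[i], task$losses_usd)
    if (is.na(j) || is.na(k))
      cpt_abort(sprintf(
        "row %d: (probability, loss) = (%g, %g) is not a grid cell of task %s",
        i, obs$probability[i], obs$loss_usd[i], tid), "cpt_off_grid")
    sid <- sprintf("%d.%d", j, k)
    if (!is.na(obs$scenario_id[i]) && nzchar(obs$scenario_id[i]) &&
        obs$scenario_id[i] != sid)
      cpt_abort(sprintf(
        "row %d: scenario_id %s does not match grid cell %s",
        i, obs$scenario_id[i], sid), "cpt_off_grid")
    ce <- obs$ce_usd[i]
    if (ce <= 0 || ce > obs$loss_usd[i])
      cpt_abort(sprintf(
        "row %d: ce_usd = %g outside (0, loss] with loss %g",
        i, ce, obs$loss_usd[i]), "cpt_ce_bounds")
  }
  class(obs) <- unique(c("ce_observations", class(obs)))
  invisible(obs)
}

match_grid <- function(value, grid, rtol = 1e-9) {
  hit <- which(abs(grid - value) <= rtol * pmax(abs(grid), 1))
  if (length(hit) == 1L) hit else NA_integer_
}

#' Read certainty-equivalent observations from CSV
#'
#' The file must carry a header row with columns
#' \code{respondent_id,task_id,scenario_id,probability,loss_usd,ce_usd}
#' (comma separator, dot decimal, UTF-8). Every row is validated
#' against its task grid; see \code{\link{validate_observations}} for
#' the conditions raised.
#'
#' @param path path to the CSV file.
#' @param tasks a \code{\link{decision_task}} or list of tasks the rows
#'   must refer to.
#' @return A data frame of observations, in file order, with class
#'   \code{"ce_observations"}.
#' @export
read_observations <- function(path, tasks = default_tasks()) {
  if (!file.exists(path))
    cpt_abort(sprintf("file not found: %s", path), "cpt_io_error")
  obs <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(respondent_id = "character",
                                        scenario_id = "character")[
                           intersect(c("respondent_id", "scenario_id"),
                                     scan_header(path))])
  # fix storage modes so a write/read round trip is bit-exact
  for (col in intersect(c("probability", "loss_usd", "ce_usd"), names(obs)))
    obs[[col]] <- as.numeric(obs[[col]])
  if ("task_id" %in% names(obs))
    obs$task_id <- as.integer(obs$task_id)
  obs <- validate_observations(obs, tasks)
  obs
}

scan_header <- function(path) {
  strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
}

#' Write certainty-equivalent observations to CSV
#'
#' Numeric fields are written with 17 significant digits so that
#' \code{read_observations(write_observations(x))} reproduces every
#' value bit-exactly.
#'
#' @param obs a validated observations data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  missing_cols <- setdiff(obs_columns, names(obs))
  if (length(missing_cols))
    cpt_abort(paste("missing columns:", paste(missing_cols, collapse = ", ")),
              "cpt_malformed_row")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(obs_columns, collapse = ","), con)
  if (nrow(obs)) {
    lines <- sprintf("%s,%d,%s,%s,%s,%s",
                     obs$respondent_id,
                     as.integer(obs$task_id),
                     obs$scenario_id,
                     num17(obs$probability),
                     num17(obs$loss_usd),
                     num17(obs$ce_usd))
    writeLines(lines, con)
  }
  invisible(path)
}

num17 <- function(x) sprintf("%.17g", x)
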