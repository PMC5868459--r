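# Trial-level data schema and I/O for double-probe retrocueing experiments.
#
# A trial holds four memorised orientations, an optional retrocue, the two
# probed item indices, and the two continuous-report responses. Cohorts are
# stored as one long data frame (one row per trial), with a `trial_cohort`
# class wrapper; files are plain comma-separated UTF-8 with one header row,
# angles in degrees, missing values as empty fields, item indices 1-based.

TRIAL_COLUMNS <- c(
  "subject_id", "experiment", "block", "trial", "condition", "order_cued",
  "item1_deg", "item2_deg", "item3_deg", "item4_deg",
  "cued_item", "probe1_item", "probe2_item",
  "response1_deg", "response2_deg", "rt1_ms", "rt2_ms")

CONDITIONS <- c("neutral", "cued_first", "cued_second")

#' Construct a trial cohort from a long data frame
#'
#' Validates the schema and per-row invariants and attaches the
#' `trial_cohort` class. Rarely called directly; [read_trials()] and
#' [simulate_cohort()] return cohorts already.
#'
#' @param trials Data frame with the columns listed under [read_trials()].
#' @return The validated data frame with class `trial_cohort`.
#' @export
trial_cohort <- function(trials) {
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols))
    stop("trial_cohort: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(trials), TRIAL_COLUMNS)
  if (length(extra)) {
    warning("trial_cohort: ignoring extra column(s): ",
            paste(extra, collapse = ", "))
    trials <- trials[TRIAL_COLUMNS]
  }
  trials$subject_id <- as.character(trials$subject_id)
  trials$experiment <- as.character(trials$experiment)
  trials$condition <- as.character(trials$condition)
  trials$order_cued <- as.logical(trials$order_cued)
  for (col in c("block", "trial", "cued_item", "probe1_item", "probe2_item"))
    trials[[col]] <- as.integer(trials[[col]])
  for (col in c("item1_deg", "item2_deg", "item3_deg", "item4_deg",
                "response1_deg", "response2_deg", "rt1_ms", "rt2_ms"))
    trials[[col]] <- as.numeric(trials[[col]])
  validate_trials(trials)
  class(trials) <- c("trial_cohort", "data.frame")
  trials
}

# per-row invariant checks; stops with row-numbered diagnostics
validate_trials <- function(trials) {
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      stop(sprintf("invalid trials (%s) at row(s): %s", what,
                   paste(utils::head(rows, 10), collapse = ", ")),
           call. = FALSE)
  }
  ang_cols <- c("item1_deg", "item2_deg", "item3_deg", "item4_deg")
  for (col in ang_cols)
    bad(is.na(trials[[col]]) | trials[[col]] < 0 | trials[[col]] >= 360,
        paste(col, "not in [0, 360)"))
  for (col in c("response1_deg", "response2_deg"))
    bad(!is.na(trials[[col]]) & (trials[[col]] < 0 | trials[[col]] >= 360),
        paste(col, "out of [0, 360)"))
  bad(!trials$condition %in% CONDITIONS, "unknown condition")
  bad(is.na(trials$probe1_item) | is.na(trials$probe2_item) |
        !trials$probe1_item %in% 1:4 | !trials$probe2_item %in% 1:4,
      "probe item index not in 1..4")
  bad(trials$probe1_item == trials$probe2_item,
      "probe1_item equals probe2_item")
  neutral <- trials$condition == "neutral"
  bad(neutral & !is.na(trials$cued_item), "cued_item set on neutral trial")
  bad(!neutral & (is.na(trials$cued_item) | !trials$cued_item %in% 1:4),
      "cued_item missing or out of range on cue trial")
  bad(trials$condition == "cued_first" &
        trials$probe1_item != trials$cued_item,
      "cued_first trial whose first probe is not the cued item")
  bad(trials$condition == "cued_second" &
        trials$probe2_item != trials$cued_item,
      "cued_second trial whose second probe is not the cued item")
  bad(!is.na(trials$rt1_ms) & trials$rt1_ms < 0, "negative rt1_ms")
  bad(!is.na(trials$rt2_ms) & trials$rt2_ms < 0, "negative rt2_ms")
  dup <- duplicated(trials[c("subject_id", "experiment", "block", "trial")])
  bad(dup, "duplicate (subject, experiment, block, trial)")
  invisible(trials)
}

#' Read trial-level data from CSV
#'
#' Reads a long-form trial file (one row per trial) and validates every
#' invariant of the schema. Columns, in order: `subject_id`, `experiment`,
#' `block`, `trial`, `condition` (`neutral`/`cued_first`/`cued_second`),
#' `order_cued`, `item1_deg` .. `item4_deg`, `cued_item`, `probe1_item`,
#' `probe2_item`, `response1_deg`, `response2_deg`, `rt1_ms`, `rt2_ms`.
#' Angles are degrees in [0, 360); missing responses are empty fields.
#' Extra columns are dropped with a warning; invariant violations raise an
#' error naming the offending rows.
#'
#' @param path Path to a CSV file.
#' @return A `trial_cohort` data frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("read_trials: no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = "", encoding = "UTF-8")
  trial_cohort(raw)
}

#' Write trial-level data to CSV
#'
#' Inverse of [read_trials()]: writes the documented column order, degrees
#' with 6 decimal places, missing values as empty fields.
#'
#' @param trials A `trial_cohort` (or conforming data frame).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trials <- function(trials, path) {
  trials <- trial_cohort(as.data.frame(trials))
  out <- as.data.frame(trials)
  for (col in c("item1_deg", "item2_deg", "item3_deg", "item4_deg",
                "response1_deg", "response2_deg"))
    out[[col]] <- ifelse(is.na(out[[col]]), NA,
                         sprintf("%.6f", out[[col]]))
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Label the two responses of a trial by cue role
#'
#' On `cued_first` trials response 1 recalls the cued item and response 2 an
#' uncued item; on `cued_second` trials the roles are swapped; on neutral
#' trials both responses are neutral.
#'
#' @param condition Character vector of trial conditions.
#' @return Data frame with one row per trial and columns `role1`, `role2`
#'   (each `"cued"`, `"uncued"`, or `"neutral"`).
#' @examples
#' label_responses(c("neutral", "cued_first", "cued_second"))
#' @export
label_responses <- function(condition) {
  if (is.data.frame(condition)) condition <- condition$condition
  if (!all(condition %in% CONDITIONS))
    stop("label_responses: unknown condition")
  data.frame(
    role1 = c(neutral = "neutral", cued_first = "cued",
              cued_second = "uncued")[condition],
    role2 = c(neutral = "neutral", cued_first = "uncued",
              cued_second = "cued")[condition],
    row.names = NULL)
}

#' Long table of signed response errors
#'
#' Expands a cohort into one row per response with the signed error (radians)
#' of the response about its target, the response's cue role, and the
#' relative orientation `delta` (radians) of the trial's *other* probed item
#' with respect to this response's target. Responses that were not given are
#' dropped.
#'
#' @param trials A `trial_cohort`.
#' @return Data frame with columns `subject_id`, `experiment`, `block`,
#'   `trial`, `condition`, `order_cued`, `response_index`, `role`, `error`,
#'   `delta`, `abs_error`.
#' @export
response_errors <- function(trials) {
  trials <- as.data.frame(trials)
  roles <- label_responses(trials$condition)
  items <- as.matrix(trials[c("item1_deg", "item2_deg",
                              "item3_deg", "item4_deg")])
  n <- nrow(trials)
  target1 <- deg2rad(items[cbind(seq_len(n), trials$probe1_item)])
  target2 <- deg2rad(items[cbind(seq_len(n), trials$probe2_item)])
  one <- function(idx, resp, target, other, role) {
    keep <- !is.na(resp)
    data.frame(
      subject_id = trials$subject_id[keep],
      experiment = trials$experiment[keep],
      block = trials$block[keep], trial = trials$trial[keep],
      condition = trials$condition[keep],
      order_cued = trials$order_cued[keep],
      response_index = idx, role = role[keep],
      error = signed_error(deg2rad(resp[keep]), target[keep]),
      delta = relative_orientation(other[keep], target[keep]),
      row.names = NULL)
  }
  out <- rbind(
    one(1L, trials$response1_deg, target1, target2, roles$role1),
    one(2L, trials$response2_deg, target2, target1, roles$role2))
  out$abs_error <- abs(out$error)
  out[order(out$subject_id, out$block, out$trial, out$response_index), ,
      drop = FALSE]
}

#' Apply the performance-based participant exclusion rule
#'
#' A participant is excluded when the Rayleigh test on their pooled signed
#' response errors is not significant at `alpha` (i.e. the response
#' distribution is indistinguishable from uniform guessing). By default both
#' responses from all conditions are pooled; `responses` restricts the pool.
#'
#' @param trials A `trial_cohort`.
#' @param alpha Significance level of the Rayleigh test (default 0.01).
#' @param responses `"both"` (default), `"first"`, or `"second"`.
#' @return List with `retained` (a `trial_cohort` of surviving subjects) and
#'   `report` (data frame: `subject_id`, `n`, `rayleigh_z`, `p`, `excluded`).
#' @export
exclude_participants <- function(trials, alpha = 0.01,
                                 responses = c("both", "first", "second")) {
  responses <- match.arg(responses)
  errs <- response_errors(trials)
  errs <- switch(responses,
                 both = errs,
                 first = errs[errs$response_index == 1L, ],
                 second = errs[errs$response_index == 2L, ])
  counts <- table(errs$subject_id)
  short <- names(counts)[counts < 10]
  if (length(short))
    stop("exclude_participants: fewer than 10 responses for subject(s): ",
         paste(short, collapse = ", "))
  report <- do.call(rbind, lapply(split(errs$error, errs$subject_id),
    function(e) {
      rt <- rayleigh_test(e)
      data.frame(n = length(e), rayleigh_z = unname(rt$statistic),
                 p = rt$p.value)
    }))
  report <- data.frame(subject_id = rownames(report), report,
                       row.names = NULL)
  report$excluded <- report$p > alpha
  keep <- report$subject_id[!report$excluded]
  retained <- trials[as.data.frame(trials)$subject_id %in% keep, ,
                     drop = FALSE]
  class(retained) <- c("trial_cohort", "data.frame")
  list(retained = retained, report = report)
}

#' @export
print.trial_cohort <- function(x, ...) {
  d <- as.data.frame(x)
  cat(sprintf("Trial cohort: %d trials, %d subject(s), experiment(s): %s\n",
              nrow(d), length(unique(d$subject_id)),
              paste(unique(d$experiment), collapse = ", ")))
  print(utils::head(d, 4))
  invisible(x)
}
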