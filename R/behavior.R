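#' Collapse 4-point confidence responses to old/new judgments
#'
#' "Probably" and "definitely" responses are collapsed: 3 and 4 count as
#' "old", 1 and 2 as "new".
#'
#' @param responses integer vector on the 1-4 scale.
#' @return character vector of `"old"` / `"new"`.
#' @export
collapse_confidence <- function(responses) {
  r <- suppressWarnings(as.integer(responses))
  bad <- is.na(r) | !(r %in% 1:4)
  if (any(bad))
    stop("responses outside the 1-4 scale at position(s): ",
         paste(which(bad), collapse = ", "))
  ifelse(r >= 3L, "old", "new")
}

#' False-alarm tendency of one participant
#'
#' A participant's false-alarm tendency is their mean confidence response to
#' new items on the 4-point scale. A one-sample t test against 2 ("probably
#' new") identifies participants who regularly and confidently judged new
#' items old: the participant is flagged when the mean exceeds 2 with
#' two-sided p < .05.
#'
#' @param new_item_responses integer responses (1-4) to new items; at least
#'   2 with nonzero variance.
#' @return A `bias_summary`: list with `mean_new`, `se_new`, `t`
#'   (`(mean - 2)/SE`, df = n - 1), `p` (two-sided), `flagged`.
#' @export
false_alarm_tendency <- function(new_item_responses) {
  r <- as.numeric(new_item_responses)
  if (length(r) < 2) stop("need >= 2 new-item responses")
  if (stats::sd(r) == 0)
    stop("degenerate input: new-item responses have zero variance")
  m <- mean(r)
  se <- stats::sd(r) / sqrt(length(r))
  t <- (m - 2) / se
  p <- 2 * stats::pt(-abs(t), df = length(r) - 1)
  structure(list(mean_new = m, se_new = se, t = t, p = p,
                 flagged = m > 2 && p < 0.05, n = length(r)),
            class = "bias_summary")
}

#' Per-participant bias report from a trial table
#'
#' @param trials trial table including retrieval responses to new items.
#' @return data frame with one row per participant: `participant`, `n_new`,
#'   `mean_new`, `se_new`, `t`, `p`, `flagged`.
#' @export
behavior_bias_table <- function(trials) {
  new_rows <- trials[trials$phase == "retrieval" & trials$status == "new", ]
  parts <- unique(trials$participant)
  out <- do.call(rbind, lapply(parts, function(pp) {
    b <- false_alarm_tendency(new_rows$response[new_rows$participant == pp])
    data.frame(participant = pp, n_new = b$n, mean_new = b$mean_new,
               se_new = b$se_new, t = b$t, p = b$p, flagged = b$flagged,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Resolve remembered/forgotten labels, demoting biased "probably old" hits
#'
#' Recomputes the `memory` column of a trial table from the retrieval
#' confidence responses. For unflagged participants the label is the plain
#' confidence collapse (3-4 remembered, 1-2 forgotten). For participants
#' flagged with a false-alarm tendency, every old item answered "probably
#' old" (3) is demoted to forgotten; "definitely old" (4) is never demoted.
#' Both the encoding and retrieval rows of an item receive the same label
#' (encoding rows carry subsequent-memory status). Invalid trials are left
#' untouched.
#'
#' @param table trial table.
#' @param flags named logical vector, one entry per participant (as from
#'   `behavior_bias_table()$flagged` named by participant).
#' @return the table with its `memory` column resolved.
#' @export
adjust_memory_labels <- function(table, flags) {
  unknown <- setdiff(names(flags), unique(table$participant))
  if (length(unknown))
    stop("flag(s) for unknown participant(s): ", paste(unknown, collapse = ", "))
  ret_old <- table$phase == "retrieval" & table$status == "target" & table$valid
  resp <- suppressWarnings(as.integer(table$response[ret_old]))
  lab <- ifelse(resp >= 3L, "remembered", "forgotten")
  flagged_here <- flags[table$participant[ret_old]]
  flagged_here[is.na(flagged_here)] <- FALSE
  lab[flagged_here & resp == 3L] <- "forgotten"
  key <- paste(table$participant, table$concept_id)
  lab_by_item <- stats::setNames(lab, key[ret_old])
  old_valid <- table$status == "target" & table$valid
  table$memory[old_valid] <- unname(lab_by_item[key[old_valid]])
  table
}

#' Per-participant hit counts from an adjusted trial table
#'
#' `hits` counts valid old items judged old (response 3 or 4); so-called
#' `adjusted_hits` counts those still labeled remembered after the
#' false-alarm-tendency demotion.
#'
#' @param trials trial table whose memory labels have been resolved.
#' @return data frame with `participant`, `valid_trials`, `hits`,
#'   `adjusted_hits`.
#' @export
hit_counts <- function(trials) {
  ret_old <- trials[trials$phase == "retrieval" & trials$status == "target" &
                      trials$valid, ]
  parts <- unique(trials$participant)
  out <- do.call(rbind, lapply(parts, function(pp) {
    x <- ret_old[ret_old$participant == pp, ]
    resp <- suppressWarnings(as.integer(x$response))
    data.frame(participant = pp, valid_trials = nrow(x),
               hits = sum(resp >= 3L, na.rm = TRUE),
               adjusted_hits = sum(x$memory == "remembered"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Summarize adjusted hit rates across participants
#'
#' @param counts data frame with columns `participant`, `valid_trials` and
#'   `adjusted_hits` (as from [hit_counts()], or any published per-
#'   participant count table).
#' @return A `hit_summary`: list with `per_participant` (adds `rate` =
#'   adjusted hits / valid trials), `group_mean`, and `group_se` (sample SD
#'   of the rates over the square root of n; `NA` for a single participant).
#' @export
summarize_hit_rates <- function(counts) {
  stopifnot(all(c("participant", "valid_trials", "adjusted_hits") %in% names(counts)))
  if (nrow(counts) < 1) stop("need >= 1 participant")
  zero <- counts$valid_trials == 0
  if (any(zero))
    stop("zero valid trials for participant(s): ",
         paste(counts$participant[zero], collapse = ", "))
  counts$rate <- counts$adjusted_hits / counts$valid_trials
  n <- nrow(counts)
  structure(list(per_participant = counts,
                 group_mean = mean(counts$rate),
                 group_se = if (n > 1) stats::sd(counts$rate) / sqrt(n) else NA_real_),
            class = "hit_summary")
}

#' @export
print.hit_summary <- function(x, ...) {
  cat(sprintf("<hit_summary> %d participants: mean adjusted hit rate %.3f (SE %.3f)\n",
              nrow(x$per_participant), x$group_mean, x$group_se))
  invisible(x)
}

#' Bundled recognition-memory behavioral summary (19 participants)
#'
#' Per-participant counts from the conceptual (word) recognition test of a
#' 19-participant picture-encoding / word-retrieval memory study: valid old
#' trials, raw hits, hits after the false-alarm-tendency adjustment, and the
#' new-item response summary (mean, SE, one-sample t against 2 and its p)
#' used to flag old-biased participants.
#'
#' @return data frame with columns `participant`, `valid_trials`, `hits`,
#'   `adjusted_hits`, `mean_new`, `se_new`, `t`, `p`, `flagged`.
#' @export
example_behavior_counts <- function() {
  path <- system.file("extdata", "recognition_behavior_19.csv",
                      package = "memrsa")
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$flagged <- as.logical(out$flagged)
  out
}
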