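#' @title Session tables
#' @description
#' The canonical container of this package is the *session table*: a data
#' frame with one row per trial, ordered by `session_id` and
#' `trial_index`, holding the stimulus columns (`block`, `category`,
#' `strength`, `evidence`, `frame_1...frame_F`) and, once an agent or an
#' animal has responded, `response` (-1 left / +1 right, `NA` for invalid
#' trials) and `outcome` (`"correct"` / `"error"`, `NA` for invalid
#' trials). All analysis functions consume this format and nothing else.
#' @name session_table
NULL

frame_cols <- function(session) {
  grep("^frame_[0-9]+$", names(session), value = TRUE)
}

# Sum of the per-frame instantaneous evidence (the agent's net stimulus
# evidence for a trial).
stim_sum <- function(session) {
  fc <- frame_cols(session)
  if (length(fc) == 0) stop("session table has no frame_* columns")
  rowSums(as.matrix(session[, fc, drop = FALSE]))
}

# TRUE where a new session starts (latents reset there).
new_session_flags <- function(session) {
  sid <- as.character(session$session_id)
  c(TRUE, sid[-1] != sid[-length(sid)])
}

#' Validate a session table
#'
#' Checks the structural invariants: required columns present,
#' `trial_index` strictly increasing within each session, categories and
#' responses in `{-1, +1}`, frames in `[-1, 1]`, `evidence == category *
#' strength`, and `outcome == "correct"` exactly when `response ==
#' category`. Invalid trials (missing response) must also have a missing
#' outcome; they are retained but flagged.
#'
#' @param session A session table.
#' @param require_responses If `TRUE`, at least one valid response column
#'   must be present.
#' @return The validated table (invisibly), with class `session_table`.
#' @export
validate_session <- function(session, require_responses = FALSE) {
  required <- c("session_id", "trial_index", "block", "category",
                "strength", "evidence")
  missing_cols <- setdiff(required, names(session))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (length(frame_cols(session)) == 0) {
    stop("missing required columns: frame_1, ...")
  }
  idx_ok <- tapply(session$trial_index, as.character(session$session_id),
                   function(i) all(diff(i) > 0))
  if (!all(unlist(idx_ok))) {
    stop("`trial_index` must be strictly increasing within each session")
  }
  if (!all(session$category %in% c(-1L, 1L))) {
    stop("`category` must be -1 or +1")
  }
  if (max(abs(session$evidence - session$category * session$strength)) > 1e-8) {
    stop("`evidence` must equal `category * strength`")
  }
  fr <- as.matrix(session[, frame_cols(session), drop = FALSE])
  if (any(abs(fr) > 1 + 1e-12)) stop("frame evidence must lie in [-1, 1]")
  if ("response" %in% names(session)) {
    valid <- !is.na(session$response)
    if (!all(session$response[valid] %in% c(-1L, 1L))) {
      stop("`response` must be -1, +1 or NA")
    }
    if (!"outcome" %in% names(session)) stop("`outcome` column required with `response`")
    if (any(is.na(session$outcome[valid]))) {
      stop("valid trials must carry an outcome")
    }
    expected <- ifelse(session$response[valid] == session$category[valid],
                       "correct", "error")
    if (!all(session$outcome[valid] == expected)) {
      stop("`outcome` must be \"correct\" exactly when response == category")
    }
  } else if (require_responses) {
    stop("session table carries no responses")
  }
  class(session) <- unique(c("session_table", class(session)))
  invisible(session)
}

# Derived history columns (NA at session starts / after invalid trials).
add_history_columns <- function(session) {
  ns <- new_session_flags(session)
  prev_response <- c(NA_integer_, session$response[-nrow(session)])
  prev_outcome <- c(NA_character_, session$outcome[-nrow(session)])
  prev_response[ns] <- NA_integer_
  prev_outcome[ns] <- NA_character_
  session$prev_response <- prev_response
  session$prev_outcome <- prev_outcome
  session
}

#' Write / read a session table
#'
#' Session tables are stored as UTF-8 comma-separated text with a header
#' row; missing values (invalid trials) are empty fields. The round trip is
#' lossless for all columns.
#'
#' @param session A session table (validated before writing).
#' @param path File path.
#' @return `write_session` returns `path` invisibly; `read_session` returns
#'   a validated `session_table`.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  keep <- setdiff(names(session), c("prev_response", "prev_outcome"))
  out <- as.data.frame(session)[, keep]
  # 17 significant digits make the double round trip lossless
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), NA_character_,
                         sprintf("%.17g", out[[j]]))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if ("response" %in% names(tab)) tab$response <- as.integer(tab$response)
  if ("category" %in% names(tab)) tab$category <- as.integer(tab$category)
  if ("trial_index" %in% names(tab)) tab$trial_index <- as.integer(tab$trial_index)
  # all remaining measurement columns are doubles, even when their stored
  # values happen to be integral (e.g. a saturated gating trace)
  int_cols <- c("session_id", "trial_index", "block", "category",
                "response", "outcome")
  for (j in setdiff(names(tab), int_cols)) tab[[j]] <- as.double(tab[[j]])
  validate_session(tab)
  class(tab) <- c("session_table", "data.frame")
  tab
}

#' Adapter stub for externally deposited session data
#'
#' Extension point for mapping externally archived behavioral tables onto
#' the session-table format. The column layout of such deposits is not
#' standardized, so this function only documents the contract: implement a
#' mapper returning the columns described in [session_table] and pass its
#' output through [validate_session()].
#'
#' @param path Path to a deposited data file.
#' @export
read_external_session <- function(path) {
  stop("no adapter implemented for external deposits; ",
       "map your table to the session_table columns and call validate_session()")
}
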