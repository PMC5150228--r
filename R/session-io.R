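#' Write one session to CSV
#'
#' One row per sample, header \code{sample_index,TP9,AF7,AF8,TP10}, values
#' in uV rounded to 1e-4 uV (the stored precision of the on-disk format).
#'
#' @param session a \code{raw_session} (see \code{\link{render_session}}).
#' @param path output file path.
#' @export
write_session <- function(session, path) {
  s <- round(session$samples, 4)
  df <- data.frame(sample_index = seq_len(nrow(s)) - 1L, s, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' Parses and validates a manifest CSV (columns \code{user_id, session_id,
#' order, task, age, sex, line_freq, path}). Users younger than 18 or with
#' missing age are excluded and counted; duplicate \code{(user_id,
#' session_id)} pairs, unknown task / sex / line-frequency codes and
#' non-numeric fields are errors naming the offending line.
#'
#' @param path manifest CSV path; session paths are resolved relative to
#'   its directory.
#' @return list with \code{sessions} (validated entries ordered by user and
#'   session order, with absolute \code{path}), \code{users} (one row per
#'   retained user) and \code{n_excluded_underage} (users removed by the
#'   age rule).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("user_id", "session_id", "order", "task", "age", "sex",
                "line_freq", "path")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0)
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(m), required)
  if (length(extra) > 0)
    warning("ignoring unknown manifest column(s): ", paste(extra, collapse = ", "))
  if (nrow(m) == 0) {
    warning("manifest is empty")
    return(list(sessions = m[required], users = m[c("user_id", "age", "sex")],
                n_excluded_underage = 0L))
  }
  line_no <- seq_len(nrow(m)) + 1L  # header is line 1
  for (col in c("order", "age", "sex", "line_freq")) {
    bad <- which(!is.na(m[[col]]) & is.na(suppressWarnings(as.numeric(m[[col]]))))
    if (length(bad) > 0)
      stop("non-numeric ", col, " at manifest line ", line_no[bad[1]])
  }
  bad <- which(!m$task %in% c("CAL", "NFB"))
  if (length(bad) > 0)
    stop("unknown task '", m$task[bad[1]], "' at manifest line ", line_no[bad[1]])
  bad <- which(!m$sex %in% c(0, 1))
  if (length(bad) > 0)
    stop("unknown sex code '", m$sex[bad[1]], "' at manifest line ", line_no[bad[1]])
  bad <- which(!m$line_freq %in% c(50, 60))
  if (length(bad) > 0)
    stop("unknown line_freq '", m$line_freq[bad[1]], "' at manifest line ",
         line_no[bad[1]])
  dup <- duplicated(m[c("user_id", "session_id")])
  if (any(dup))
    stop("duplicate (user_id, session_id) at manifest line ", line_no[which(dup)[1]])
  underage <- is.na(m$age) | m$age < 18
  excluded_users <- unique(m$user_id[underage])
  n_excluded <- length(excluded_users)
  if (n_excluded > 0) {
    message("excluding ", n_excluded, " user(s) under 18 or with missing age")
    m <- m[!m$user_id %in% excluded_users, , drop = FALSE]
  }
  m <- m[order(m$user_id, m$order, m$task), , drop = FALSE]
  m$path <- file.path(normalizePath(dirname(path)), m$path)
  users <- unique(m[c("user_id", "age", "sex", "line_freq")])
  rownames(m) <- rownames(users) <- NULL
  list(sessions = m, users = users, n_excluded_underage = n_excluded)
}

#' Read one session CSV
#'
#' Reads a session file and returns it as a \code{raw_session} with channel
#' columns normalized to canonical order (TP9, AF7, AF8, TP10) regardless of
#' their order in the file. Missing channel columns and non-finite samples
#' are errors (the latter naming the first offending row).
#'
#' @param entry one manifest row (list or 1-row data frame with at least
#'   \code{path}; metadata columns are attached when present), or a file
#'   path.
#' @param fs sampling rate to assume, Hz.
#' @return a \code{raw_session}.
#' @export
read_session <- function(entry, fs = 220) {
  if (is.character(entry)) entry <- list(path = entry)
  path <- entry$path
  if (!file.exists(path))
    stop("session file not found: ", path,
         if (!is.null(entry$session_id)) paste0(" (session ", entry$session_id, ")"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(eeg_channels, names(df))
  if (length(missing) > 0)
    stop("session ", path, " is missing channel column(s): ",
         paste(missing, collapse = ", "))
  samples <- as.matrix(df[, eeg_channels, drop = FALSE])
  if (!is.numeric(samples))
    stop("non-numeric sample values in ", path)
  bad <- which(!is.finite(samples), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-finite sample at row ", bad[1, 1], " of ", path)
  grab <- function(field, default = NULL)
    if (!is.null(entry[[field]]) && !is.na(entry[[field]])) entry[[field]] else default
  structure(list(samples = samples, fs = fs,
                 task = grab("task"), order = grab("order"),
                 line_freq = grab("line_freq"), user_id = grab("user_id"),
                 age = grab("age"), sex = grab("sex"),
                 artifact_windows = NULL),
            class = "raw_session")
}

#' @export
print.raw_session <- function(x, ...) {
  cat(sprintf("<raw_session> %s%s: %d samples x %d channels at %g Hz (%.1f s)\n",
              if (is.null(x$user_id)) "" else paste0(x$user_id, " "),
              if (is.null(x$task)) "" else x$task,
              nrow(x$samples), ncol(x$samples), x$fs, nrow(x$samples) / x$fs))
  invisible(x)
}
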