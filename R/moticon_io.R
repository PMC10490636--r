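#' Parse a recording filename into its key
#'
#' Recording files are named `<w>lbs_<activity><iter>.txt`, e.g.
#' `0lbs_sitting.txt` (iteration 1 — an absent iteration suffix means the
#' first iteration) or `11lbs_standing2.txt` (second iteration of the 11 lbs
#' reading). The weight field is the carried dumbbell weight in pounds; 0
#' means the participant carried nothing.
#'
#' @param name Filename (basename; a path is accepted and reduced to its
#'   basename).
#' @return A `recording_key`: list with `carried_weight` (lbs), `activity`
#'   (`"sitting"`, `"standing"` or `"walking"`) and `iteration` (an
#'   integer, at least 1).
#' @examples
#' parse_filename("0lbs_sitting.txt")
#' parse_filename("11lbs_standing2.txt")$iteration  # 2
#' @seealso [format_filename()] — the inverse.
#' @export
parse_filename <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  base <- basename(name)
  m <- regmatches(base, regexec("^([0-9]+)lbs_([a-z]+?)([0-9]*)\\.txt$", base))[[1]]
  if (length(m) == 0L) {
    stop("malformed recording filename: ", sQuote(base),
         " (expected '<int>lbs_<activity>[<int>].txt')", call. = FALSE)
  }
  activity <- m[3]
  if (!activity %in% .activities) {
    stop("malformed recording filename ", sQuote(base), ": unknown activity ",
         sQuote(activity), call. = FALSE)
  }
  iter <- if (nzchar(m[4])) as.integer(m[4]) else 1L
  if (iter < 1L) {
    stop("malformed recording filename ", sQuote(base),
         ": iteration must be >= 1", call. = FALSE)
  }
  recording_key(as.numeric(m[2]), activity, iter)
}

#' Construct a recording key
#'
#' @param carried_weight Carried dumbbell weight in lbs (non-negative).
#' @param activity One of `"sitting"`, `"standing"`, `"walking"`.
#' @param iteration Experimental iteration, integer >= 1.
#' @return A `recording_key` object.
#' @export
recording_key <- function(carried_weight, activity = "standing", iteration = 1L) {
  stopifnot(is.numeric(carried_weight), length(carried_weight) == 1L,
            carried_weight >= 0)
  activity <- match.arg(activity, .activities)
  iteration <- as.integer(iteration)
  stopifnot(iteration >= 1L)
  structure(list(carried_weight = as.numeric(carried_weight),
                 activity = activity, iteration = iteration),
            class = "recording_key")
}

#' @export
print.recording_key <- function(x, ...) {
  cat(sprintf("<recording_key> %s, %g lbs carried, iteration %d\n",
              x$activity, x$carried_weight, x$iteration))
  invisible(x)
}

#' Format a recording key back into its filename
#'
#' Inverse of [parse_filename()]: `parse_filename(format_filename(k))`
#' recovers `k` for every valid key.
#'
#' @param key A `recording_key`.
#' @return Filename string, e.g. `"11lbs_standing2.txt"`.
#' @export
format_filename <- function(key) {
  stopifnot(inherits(key, "recording_key"))
  suffix <- if (key$iteration == 1L) "" else as.character(key$iteration)
  sprintf("%slbs_%s%s.txt", format(key$carried_weight, scientific = FALSE),
          key$activity, suffix)
}

#' Load one insole recording from a delimited text export
#'
#' Reads a whitespace- or tab-delimited numeric text file with 51 columns
#' (see [insole_channels()]). If the file has a header, columns may appear
#' in any order and are normalized to the canonical schema (optionally via
#' `col_map`); without a header the canonical column order is assumed.
#'
#' @param path Path to the `.txt` export.
#' @param key Optional `recording_key`; defaults to [parse_filename()] on
#'   the basename.
#' @param participant_id Optional participant identifier attached to the
#'   recording.
#' @param col_map Optional named character vector mapping file headers to
#'   canonical names (`c(file_name = "canonical_name", ...)`).
#' @return An `insole_recording`: a data.frame in canonical column order
#'   with attributes `key`, `participant_id` and `sampling_rate` (Hz,
#'   estimated from the timestamp column).
#' @export
load_recording <- function(path, key = NULL, participant_id = NULL,
                           col_map = NULL) {
  if (!file.exists(path)) stop("no such recording file: ", path, call. = FALSE)
  dt <- tryCatch(
    data.table::fread(path, header = "auto", sep = "auto",
                      colClasses = "numeric", data.table = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  canon <- insole_channels()
  if (ncol(dt) != length(canon)) {
    stop("schema error in ", path, ": expected ", length(canon),
         " columns, found ", ncol(dt), call. = FALSE)
  }
  if (all(grepl("^V[0-9]+$", names(dt)))) {
    names(dt) <- canon # headerless: canonical order assumed
  } else {
    if (!is.null(col_map)) {
      hit <- names(dt) %in% names(col_map)
      names(dt)[hit] <- unname(col_map[names(dt)[hit]])
    }
    if (!setequal(names(dt), canon)) {
      stop("schema error in ", path, ": header does not match the canonical ",
           "channel set; missing: ",
           paste(setdiff(canon, names(dt)), collapse = ", "), call. = FALSE)
    }
    dt <- dt[canon]
  }
  bad <- vapply(dt, function(x) !is.numeric(x) || anyNA(x), logical(1L))
  if (any(bad)) {
    col <- names(dt)[which(bad)[1L]]
    row <- which(!is.finite(as.numeric(dt[[col]])))[1L]
    stop("parse error in ", path, ": non-numeric or missing value in column ",
         sQuote(col), ", row ", row, call. = FALSE)
  }
  if (is.null(key)) key <- parse_filename(path)
  new_recording(dt, key = key, participant_id = participant_id, path = path)
}

# validate + class a canonical recording data.frame
new_recording <- function(df, key, participant_id = NULL, path = NULL) {
  stopifnot(is.data.frame(df), inherits(key, "recording_key"))
  if (nrow(df) < 1L) stop("recording has no samples", call. = FALSE)
  if (!identical(names(df), insole_channels())) {
    stop("recording columns are not the canonical 51-channel schema",
         call. = FALSE)
  }
  for (ch in .nonneg_channels()) {
    if (any(df[[ch]] < 0)) {
      stop("invalid recording", if (!is.null(path)) paste0(" ", path),
           ": negative value in ", sQuote(ch), call. = FALSE)
    }
  }
  if (is.unsorted(df$time)) {
    stop("invalid recording", if (!is.null(path)) paste0(" ", path),
         ": timestamps are not non-decreasing", call. = FALSE)
  }
  rate <- if (nrow(df) > 1L) 1 / stats::median(diff(df$time)) else NA_real_
  structure(df, key = key, participant_id = participant_id,
            sampling_rate = rate,
            class = c("insole_recording", "data.frame"))
}

#' Write a recording as a tab-delimited text export
#'
#' Writes the canonical 51-column schema with a header line; the file
#' round-trips value-exactly through [load_recording()].
#'
#' @param recording An `insole_recording` (or canonical data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(identical(names(recording), insole_channels()))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(as.data.frame(recording), path, sep = "\t")
  invisible(path)
}

#' Load a participant ground-truth weight table
#'
#' Accepts either a CSV or an XLSX file with columns `participant_id` and
#' `body_weight_lbs` (a two-column file with any header is accepted in that
#' order).
#'
#' @param path Path to `.csv` or `.xlsx`.
#' @return data.frame with character `participant_id` and numeric
#'   `body_weight_lbs` (> 0).
#' @export
load_ground_truth <- function(path) {
  if (!file.exists(path)) stop("no ground-truth table at ", path, call. = FALSE)
  gt <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    as.data.frame(readxl::read_excel(path))
  } else {
    data.table::fread(path, data.table = FALSE)
  }
  if (ncol(gt) < 2L) stop("ground-truth table needs 2 columns", call. = FALSE)
  gt <- gt[, 1:2]
  names(gt) <- c("participant_id", "body_weight_lbs")
  gt$participant_id <- as.character(gt$participant_id)
  gt$body_weight_lbs <- as.numeric(gt$body_weight_lbs)
  if (anyNA(gt$body_weight_lbs) || any(gt$body_weight_lbs <= 0)) {
    stop("ground-truth body weights must be positive numbers", call. = FALSE)
  }
  gt
}

#' Scan a dataset directory into an inventory
#'
#' Walks the study layout `root/<participant>/<activity>/<w>lbs_<activity><i>.txt`
#' and builds a manifest of every recording file. Unknown activity folders
#' and malformed filenames are reported as issues and skipped, never
#' silently dropped.
#'
#' @param root Dataset root (one experimental-setup folder).
#' @param ground_truth Path to the ground-truth weight table; default
#'   `file.path(root, "ground_truth.csv")`; `NULL` to skip.
#' @return An `insole_inventory`: list with `root`, `manifest` (data.frame:
#'   `participant_id`, `activity`, `carried_weight`, `iteration`, `path`),
#'   `ground_truth` (data.frame or `NULL`) and `issues` (character).
#' @export
scan_dataset <- function(root, ground_truth = file.path(root, "ground_truth.csv")) {
  issues <- character()
  rows <- list()
  if (!dir.exists(root)) stop("dataset root does not exist: ", root, call. = FALSE)
  participants <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(participants) == 0L) {
    warning("empty dataset root: ", root, call. = FALSE)
  }
  for (pid in participants) {
    acts <- sort(list.dirs(file.path(root, pid), recursive = FALSE,
                           full.names = FALSE))
    for (act in acts) {
      if (!act %in% .activities) {
        issues <- c(issues, sprintf("skipping unknown activity folder %s/%s",
                                    pid, act))
        next
      }
      files <- sort(list.files(file.path(root, pid, act), pattern = "\\.txt$",
                               full.names = TRUE))
      for (f in files) {
        key <- tryCatch(parse_filename(f), error = function(e) {
          issues <<- c(issues, conditionMessage(e))
          NULL
        })
        if (is.null(key)) next
        if (key$activity != act) {
          issues <- c(issues, sprintf(
            "activity mismatch: file %s under folder %s/%s", basename(f), pid, act))
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, activity = key$activity,
          carried_weight = key$carried_weight, iteration = key$iteration,
          path = f, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant_id = character(), activity = character(),
               carried_weight = numeric(), iteration = integer(),
               path = character(), stringsAsFactors = FALSE)
  gt <- if (!is.null(ground_truth) && file.exists(ground_truth)) {
    load_ground_truth(ground_truth)
  } else {
    if (!is.null(ground_truth)) {
      issues <- c(issues, paste("no ground-truth table at", ground_truth))
    }
    NULL
  }
  for (msg in issues) warning(msg, call. = FALSE)
  structure(list(root = root, manifest = manifest, ground_truth = gt,
                 issues = issues),
            class = "insole_inventory")
}

#' @export
print.insole_inventory <- function(x, ...) {
  cat(sprintf("<insole_inventory> %s\n  %d recordings, %d participants, %d issue(s)\n",
              x$root, nrow(x$manifest), length(unique(x$manifest$participant_id)),
              length(x$issues)))
  invisible(x)
}

#' Select participants eligible for personalized modeling
#'
#' A participant is eligible when at least `min_iterations` of their
#' experimental iterations are *complete*: an iteration must contain a
#' recording for every carried weight in the participant's weight class
#' (the union of weights seen across their recordings), so that one
#' iteration can train/validate and another can test. The rationale is the
#' study rule that each participant needs at least two iteration readings
#' with no missing weight files.
#'
#' @param inventory An `insole_inventory` (or its manifest data.frame).
#' @param min_iterations Minimum number of complete iterations (>= 2).
#' @param activities Activities considered (default `"standing"`, the
#'   evaluated protocol).
#' @return Character vector of eligible participant ids (possibly empty).
#' @export
select_participants <- function(inventory, min_iterations = 2L,
                                activities = "standing") {
  stopifnot(min_iterations >= 2L)
  manifest <- if (inherits(inventory, "insole_inventory")) inventory$manifest
              else inventory
  manifest <- manifest[manifest$activity %in% activities, , drop = FALSE]
  if (nrow(manifest) == 0L) return(character())
  keep <- vapply(split(manifest, manifest$participant_id), function(m) {
    wc <- sort(unique(m$carried_weight))
    complete <- vapply(split(m, m$iteration),
                       function(it) setequal(it$carried_weight, wc), logical(1L))
    sum(complete) >= min_iterations
  }, logical(1L))
  sort(names(keep)[keep])
}
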