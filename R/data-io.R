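#' Read one Bonn EEG subset from a directory of ASCII recordings
#'
#' Each Bonn subset (A/B/C/D/E, file prefixes Z/O/N/F/S respectively) holds
#' 100 plain-text single-channel recordings of 4097 samples, one numeric
#' value per line.
#'
#' @param dir directory containing the subset's `.txt`/`.TXT` files.
#' @param set_letter subset letter in `A`–`E`.
#' @param expected_len required samples per recording (4097; set `NULL` to
#'   accept any uniform length, e.g. for down-sampled fixtures).
#' @return Tibble: `recording_id`, `set`, `signal` (list-column of numeric
#'   vectors).
#' @export
read_bonn_set <- function(dir, set_letter, expected_len = 4097) {
  set_letter <- toupper(set_letter)
  if (!set_letter %in% c("A", "B", "C", "D", "E")) {
    stop("set_letter must be one of A, B, C, D, E", call. = FALSE)
  }
  files <- sort(list.files(dir, pattern = "\\.(txt|TXT)$", full.names = TRUE))
  if (length(files) == 0L) {
    stop(sprintf("no .txt recordings found in %s", dir), call. = FALSE)
  }
  sigs <- lapply(files, function(f) {
    v <- suppressWarnings(as.numeric(readLines(f, warn = FALSE)))
    if (anyNA(v)) {
      stop(sprintf("non-numeric line in %s", basename(f)), call. = FALSE)
    }
    if (!is.null(expected_len) && length(v) != expected_len) {
      stop(sprintf("%s has %d samples, expected %d",
                   basename(f), length(v), expected_len), call. = FALSE)
    }
    v
  })
  tibble::tibble(
    recording_id = paste0(set_letter, "_", sub("\\.(txt|TXT)$", "", basename(files))),
    set = set_letter,
    signal = sigs
  )
}

#' Read the UCI epileptic-seizure-recognition CSV
#'
#' Expects 178 sample columns `X1..X178` plus an integer label column `y`
#' in 1..5 (1 = seizure); an optional leading id column provides recording
#' ids (its subject prefix before the first dot, when formatted like
#' `X21.V1.791`). Emits the binary task label: 1 for seizure (`y == 1`),
#' 0 otherwise.
#'
#' @param path CSV path.
#' @return Tibble: `recording_id`, `signal` (list-column, length 178),
#'   `y_raw` (original 1–5 code), `label` (binary 0/1).
#' @export
read_uci_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  xcols <- paste0("X", seq_len(178))
  if (!all(xcols %in% names(df))) {
    missing <- setdiff(xcols, names(df))
    stop(sprintf("missing sample columns (e.g. %s); expected X1..X178",
                 missing[1]), call. = FALSE)
  }
  if (!"y" %in% names(df)) stop("missing label column `y`", call. = FALSE)
  idcol <- setdiff(names(df), c(xcols, "y"))
  if (length(idcol) > 1L) {
    stop(sprintf("unexpected extra columns: %s", paste(idcol, collapse = ", ")),
         call. = FALSE)
  }
  ids <- if (length(idcol) == 1L) {
    raw <- as.character(df[[idcol]])
    # subject prefix: drop the leading chunk index ("X21.V1.791" -> "V1.791")
    sub("^[^.]*\\.", "", raw)
  } else {
    as.character(seq_len(nrow(df)))
  }
  y <- as.integer(df$y)
  if (any(y < 1L | y > 5L)) stop("label column y must be in 1..5", call. = FALSE)
  X <- as.matrix(df[xcols])
  tibble::tibble(
    recording_id = ids,
    signal = lapply(seq_len(nrow(X)), function(i) as.double(X[i, ])),
    y_raw = y,
    label = as.integer(y == 1L)
  )
}

#' Parse a hyphenated class-combination task name
#'
#' `"AB-CD-E"` maps sets A and B to class 1, C and D to class 2, and E to
#' class 3. Groups must be non-empty, pairwise disjoint and drawn from
#' A–E.
#'
#' @param task task string such as `"A-E"` or `"AB-CD-E"`.
#' @return A `task_spec`: list with `groups` (list of letter vectors),
#'   `n_classes` and `task` (the canonical string).
#' @export
parse_task <- function(task) {
  parts <- strsplit(toupper(task), "-", fixed = TRUE)[[1]]
  if (length(parts) < 2L) stop("a task needs at least two class groups", call. = FALSE)
  groups <- lapply(parts, function(p) strsplit(p, "")[[1]])
  all_letters <- unlist(groups)
  if (!all(all_letters %in% c("A", "B", "C", "D", "E"))) {
    stop("task groups may only use set letters A-E", call. = FALSE)
  }
  if (anyDuplicated(all_letters)) {
    stop("task groups must be pairwise disjoint", call. = FALSE)
  }
  if (any(lengths(groups) == 0L)) stop("empty class group", call. = FALSE)
  structure(list(groups = groups, n_classes = length(groups),
                 task = paste(vapply(groups, paste0, "", collapse = ""),
                              collapse = "-")),
            class = "task_spec")
}

#' @export
format.task_spec <- function(x, ...) x$task

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("<task_spec> %s (%d classes)\n", x$task, x$n_classes))
  invisible(x)
}

#' Build a windowed classification task from Bonn recordings
#'
#' Selects the sets named in the task, windows each recording into
#' `floor(len / window_len)` non-overlapping segments (windows never cross
#' recording boundaries), applies per-window normalization, and labels each
#' window with its group's class index (1-based, in task order).
#'
#' @param records tibble of recordings as returned by [read_bonn_set()]
#'   (rows from several sets concatenated).
#' @param task task string or [parse_task()] result.
#' @param window_len samples per window (default 178, the UCI chunking
#'   convention; use 4097 for whole-recording segments).
#' @param normalize `"zscore"`, `"minmax"` or `"none"` per-window scaling.
#' @return Tibble: `signal` (list-column), `label`, `recording_id`, `set`,
#'   `window`.
#' @export
make_task <- function(records, task, window_len = 178,
                      normalize = c("zscore", "minmax", "none")) {
  normalize <- match.arg(normalize)
  spec <- if (inherits(task, "task_spec")) task else parse_task(task)
  needed <- unlist(spec$groups)
  have <- unique(records$set)
  if (!all(needed %in% have)) {
    stop(sprintf("task %s needs sets %s but only %s are loaded", spec$task,
                 paste(needed, collapse = ""), paste(have, collapse = "")),
         call. = FALSE)
  }
  rows <- list()
  for (ci in seq_along(spec$groups)) {
    for (letter in spec$groups[[ci]]) {
      sel <- records[records$set == letter, ]
      for (r in seq_len(nrow(sel))) {
        sig <- sel$signal[[r]]
        nw <- length(sig) %/% window_len
        if (nw < 1L) {
          stop(sprintf("recording %s shorter than window_len", sel$recording_id[r]),
               call. = FALSE)
        }
        for (w in seq_len(nw)) {
          seg <- sig[((w - 1L) * window_len + 1L):(w * window_len)]
          seg <- normalize_window(seg, normalize)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            signal = list(seg), label = ci,
            recording_id = sel$recording_id[r], set = letter, window = w)
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

normalize_window <- function(x, method) {
  switch(method,
         none = x,
         zscore = {
           s <- stats::sd(x)
           if (s < 1e-12) x * 0 else (x - mean(x)) / s
         },
         minmax = {
           r <- range(x)
           if (diff(r) < 1e-12) x * 0 else (x - r[1]) / diff(r)
         })
}

#' Write a segment table in the UCI CSV dialect
#'
#' Columns `id`, `X1..Xn`, `y`, so that [read_uci_csv()] round-trips tables
#' with 178-sample segments.
#'
#' @param data tibble with `signal` list-column, `label` and optionally
#'   `recording_id`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_eeg_csv <- function(data, path) {
  n <- nrow(data)
  len <- if (n > 0L) length(data$signal[[1]]) else 178L
  X <- if (n > 0L) do.call(rbind, data$signal) else
    matrix(numeric(0), 0, len)
  colnames(X) <- paste0("X", seq_len(len))
  ids <- if ("recording_id" %in% names(data)) data$recording_id else
    as.character(seq_len(n))
  out <- tibble::as_tibble(as.data.frame(X))
  out <- dplyr::bind_cols(tibble::tibble(id = paste0("w.", ids)), out)
  out$y <- if (n > 0L) data$label else integer(0)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
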