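# Cardiac-cycle label containers and the Audacity label-track format.
#
# The four states follow the operational definitions used throughout:
#   systole  = S1 onset -> S2 onset
#   diastole = S2 onset -> next S1 onset
# so systolic + diastolic duration equals cycle duration exactly, S1 is
# contained in systole and S2 in diastole. All intervals are half-open
# [start, end) in seconds.

.hs_states <- c("S1", "SYSTOLE", "S2", "DIASTOLE")
.hs_state_labels <- c(S1 = "S1", SYSTOLE = "systole", S2 = "S2",
                      DIASTOLE = "diastole")

#' Typed time interval for one cardiac-cycle state
#'
#' @param start_s start time in seconds (>= 0).
#' @param end_s end time in seconds; must exceed `start_s`. The interval is
#'   half-open `[start_s, end_s)`.
#' @param state one of `"S1"`, `"SYSTOLE"`, `"S2"`, `"DIASTOLE"`.
#' @return a `segment_interval` (named list).
#' @export
segment_interval <- function(start_s, end_s, state) {
  state <- as.character(state)
  if (!state %in% .hs_states)
    hs_error("hs_unknown_label", sprintf("unknown segment state: %s", state))
  if (!is.finite(start_s) || !is.finite(end_s) || start_s < 0)
    hs_error("hs_bad_interval", "interval times must be finite and start_s >= 0")
  if (start_s >= end_s)
    hs_error("hs_bad_interval",
             sprintf("interval start (%.6f) must precede end (%.6f)", start_s, end_s))
  structure(list(start_s = start_s, end_s = end_s, state = state),
            class = "segment_interval")
}

#' Cycle segmentation: ordered four-state labels per cardiac cycle
#'
#' Validates and canonicalizes a table of labeled intervals into a
#' `cycle_segmentation`. Each cycle holds exactly one S1, SYSTOLE, S2 and
#' DIASTOLE interval obeying the state definitions; equalities that the
#' definitions force (systole start = S1 start, systole end = diastole
#' start = S2 start, diastole end = next S1 start) are checked to `tol` and
#' then snapped exact, so downstream duration bookkeeping is exact rather
#' than merely close.
#'
#' @param intervals data.frame with columns `cycle` (integer), `state`
#'   (S1/SYSTOLE/S2/DIASTOLE), `start_s`, `end_s`. May have zero rows.
#' @param tol tolerance for the forced equalities before snapping.
#' @return a `cycle_segmentation`: the canonicalized data.frame (rows
#'   ordered cycle, then S1, SYSTOLE, S2, DIASTOLE).
#' @export
cycle_segmentation <- function(intervals, tol = 1e-6) {
  cols <- c("cycle", "state", "start_s", "end_s")
  if (!is.data.frame(intervals) || !all(cols %in% names(intervals)))
    hs_error("hs_bad_interval",
             "intervals must be a data.frame with columns cycle, state, start_s, end_s")
  df <- intervals[, cols, drop = FALSE]
  df$state <- as.character(df$state)
  if (nrow(df) == 0L) {
    df <- data.frame(cycle = integer(), state = character(),
                     start_s = numeric(), end_s = numeric(),
                     stringsAsFactors = FALSE)
    return(structure(df, class = c("cycle_segmentation", "data.frame")))
  }
  if (!all(df$state %in% .hs_states))
    hs_error("hs_unknown_label", sprintf(
      "unknown state label(s): %s",
      paste(unique(setdiff(df$state, .hs_states)), collapse = ", ")))
  if (any(!is.finite(df$start_s)) || any(!is.finite(df$end_s)))
    hs_error("hs_bad_interval", "non-finite interval times")
  if (any(df$start_s >= df$end_s))
    hs_error("hs_bad_interval", "every interval needs start_s < end_s")

  cycles <- sort(unique(df$cycle))
  out <- vector("list", length(cycles))
  prev_dia_end <- NULL
  for (i in seq_along(cycles)) {
    k <- cycles[i]
    ck <- df[df$cycle == k, , drop = FALSE]
    if (nrow(ck) != 4L || !setequal(ck$state, .hs_states))
      hs_error("hs_sequencing_error", sprintf(
        "cycle %s must hold exactly one S1, SYSTOLE, S2 and DIASTOLE interval", k))
    g <- function(st, fld) ck[[fld]][ck$state == st]
    s1s <- g("S1", "start_s"); s1e <- g("S1", "end_s")
    sys_ <- c(g("SYSTOLE", "start_s"), g("SYSTOLE", "end_s"))
    s2s <- g("S2", "start_s"); s2e <- g("S2", "end_s")
    dia <- c(g("DIASTOLE", "start_s"), g("DIASTOLE", "end_s"))
    ok <- abs(sys_[1] - s1s) <= tol && abs(sys_[2] - s2s) <= tol &&
      abs(dia[1] - s2s) <= tol && s1e <= sys_[2] + tol && s2e <= dia[2] + tol
    if (!ok)
      hs_error("hs_sequencing_error", sprintf(
        "cycle %s violates the state definitions (systole = S1 onset to S2 onset, diastole = S2 onset to next S1 onset)", k))
    # consecutive cycles must be contiguous (diastole end = next S1 start);
    # a forward gap is tolerated where an intervening cycle was dropped
    # (e.g. missing S2), but overlap is never valid
    if (!is.null(prev_dia_end) && prev_dia_end - s1s > tol)
      hs_error("hs_sequencing_error", sprintf(
        "cycle %s starts before the previous diastole ends (overlap)", k))
    prev_dia_end <- dia[2]
    # snap forced equalities exact
    out[[i]] <- data.frame(
      cycle = rep(i, 4L),
      state = .hs_states,
      start_s = c(s1s, s1s, s2s, s2s),
      end_s = c(min(s1e, s2s), s2s, min(s2e, dia[2]), dia[2]),
      stringsAsFactors = FALSE
    )
    if (s1e > s2s + tol || s2e > dia[2] + tol)
      hs_error("hs_sequencing_error", sprintf(
        "cycle %s: S1 must end by the S2 onset and S2 by the next S1 onset", k))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("cycle_segmentation", "data.frame"))
}

#' Number of complete cycles in a segmentation
#' @param segmentation a `cycle_segmentation`.
#' @return integer count.
#' @export
n_cycles <- function(segmentation) {
  if (nrow(segmentation) == 0L) return(0L)
  length(unique(segmentation$cycle))
}

#' Per-cycle durations of each state
#'
#' @param segmentation a `cycle_segmentation`.
#' @return data.frame with one row per cycle: `cycle`, `s1`, `s2`,
#'   `systole`, `diastole`, `cycle_duration` (all seconds).
#' @export
cycle_durations <- function(segmentation) {
  stopifnot(inherits(segmentation, "cycle_segmentation"))
  if (nrow(segmentation) == 0L)
    return(data.frame(cycle = integer(), s1 = numeric(), s2 = numeric(),
                      systole = numeric(), diastole = numeric(),
                      cycle_duration = numeric()))
  dur <- function(st) {
    d <- segmentation[segmentation$state == st, , drop = FALSE]
    d <- d[order(d$cycle), , drop = FALSE]
    d$end_s - d$start_s
  }
  sys <- dur("SYSTOLE"); dia <- dur("DIASTOLE")
  data.frame(cycle = sort(unique(segmentation$cycle)),
             s1 = dur("S1"), s2 = dur("S2"),
             systole = sys, diastole = dia,
             cycle_duration = sys + dia)
}

#' Write a segmentation as an Audacity label track
#'
#' One line per interval: `start<TAB>end<TAB>label`, times in seconds with 6
#' decimal places, labels `S1`/`systole`/`S2`/`diastole` (case-sensitive),
#' lines in time order (ties broken S1, systole, S2, diastole), each line
#' newline-terminated. An empty segmentation produces an empty file.
#'
#' @param segmentation a `cycle_segmentation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_track <- function(segmentation, path) {
  stopifnot(inherits(segmentation, "cycle_segmentation"))
  con <- tryCatch(file(path, "wb"), condition = function(e)
    hs_error("hs_unwritable_path", sprintf("cannot open for writing: %s", path)))
  on.exit(close(con))
  if (nrow(segmentation) > 0L) {
    ord <- order(segmentation$start_s,
                 match(segmentation$state, .hs_states))
    seg <- segmentation[ord, , drop = FALSE]
    lines <- sprintf("%.6f\t%.6f\t%s", seg$start_s, seg$end_s,
                     .hs_state_labels[seg$state])
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read an Audacity label track as a cycle segmentation
#'
#' Inverse of [write_label_track()]: parses tab-separated
#' `start<TAB>end<TAB>label` lines, groups them into cardiac cycles (a new
#' cycle begins at each `S1` label) and validates every cycle-segmentation
#' invariant. Round-tripping through [write_label_track()] is the identity
#' at 6-decimal time precision.
#'
#' @param path path to the label file.
#' @return a [cycle_segmentation()].
#' @export
read_label_track <- function(path) {
  if (!file.exists(path))
    hs_error("hs_missing_file", sprintf("label file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(cycle_segmentation(data.frame(cycle = integer(), state = character(),
                                         start_s = numeric(), end_s = numeric())))
  label_to_state <- stats::setNames(names(.hs_state_labels), .hs_state_labels)
  rows <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3L)
      hs_error("hs_malformed_label", sprintf(
        "line %d: expected 3 tab-separated fields, got %d", i, length(parts)))
    t0 <- suppressWarnings(as.numeric(parts[1]))
    t1 <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(t0) || is.na(t1))
      hs_error("hs_malformed_label", sprintf("line %d: non-numeric time field", i))
    if (t0 >= t1)
      hs_error("hs_bad_interval", sprintf(
        "line %d: start (%s) must precede end (%s)", i, parts[1], parts[2]))
    if (!parts[3] %in% names(label_to_state))
      hs_error("hs_unknown_label", sprintf(
        "line %d: unknown state label '%s'", i, parts[3]))
    data.frame(start_s = t0, end_s = t1,
               state = unname(label_to_state[parts[3]]),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$start_s, match(df$state, .hs_states)), , drop = FALSE]
  df$cycle <- cumsum(df$state == "S1")
  if (any(df$cycle == 0L))
    hs_error("hs_sequencing_error", "label track does not start with an S1 label")
  cycle_segmentation(df, tol = 5e-7)
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  nc <- n_cycles(x)
  cat(sprintf("<cycle_segmentation> %d cycle(s)\n", nc))
  if (nc > 0L) {
    d <- cycle_durations(x)
    cat(sprintf("  span %.3f - %.3f s; median cycle %.3f s\n",
                min(x$start_s), max(x$end_s),
                stats::median(d$cycle_duration)))
  }
  invisible(x)
}
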