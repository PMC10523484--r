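#' Construct a single pulling work trace
#'
#' A work trace records one steered-MD pulling trajectory: the moving
#' harmonic restraint center, the measured pulling coordinate and the
#' external work accumulated so far, sampled on a regular cadence.
#'
#' Internal units are fixed: time in ns, lengths in Angstrom, work in
#' kcal/mol.
#'
#' @param traj_id Character label identifying the trajectory.
#' @param time Sampling times in ns, strictly increasing.
#' @param restraint_center Harmonic restraint center in Angstrom, monotone
#'   non-decreasing within a pull.
#' @param coordinate Measured pulling coordinate in Angstrom.
#' @param accumulated_work External work accumulated up to each time, in
#'   kcal/mol; must start at 0 (within 1e-9).
#' @return A data frame of class `work_trace` with attribute `traj_id`.
#' @export
work_trace <- function(traj_id, time, restraint_center, coordinate,
                       accumulated_work) {
  tr <- data.frame(time = as.numeric(time),
                   restraint_center = as.numeric(restraint_center),
                   coordinate = as.numeric(coordinate),
                   accumulated_work = as.numeric(accumulated_work))
  attr(tr, "traj_id") <- as.character(traj_id)
  class(tr) <- c("work_trace", "data.frame")
  validate_work_trace(tr)
  tr
}

validate_work_trace <- function(tr) {
  n <- nrow(tr)
  if (n < 2L) stop("work trace must have at least 2 rows", call. = FALSE)
  dt <- diff(tr$time)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L] + 1L
    stop(sprintf("time not strictly increasing at row %d of trace '%s'",
                 bad, attr(tr, "traj_id")), call. = FALSE)
  }
  if (any(diff(tr$restraint_center) < 0)) {
    bad <- which(diff(tr$restraint_center) < 0)[1L] + 1L
    stop(sprintf("restraint center decreases at row %d of trace '%s'",
                 bad, attr(tr, "traj_id")), call. = FALSE)
  }
  if (abs(tr$accumulated_work[1L]) > 1e-9)
    stop(sprintf("accumulated work must start at 0 (trace '%s' starts at %g)",
                 attr(tr, "traj_id"), tr$accumulated_work[1L]), call. = FALSE)
  invisible(tr)
}

#' Construct one alchemical (FEP) lambda window
#'
#' Holds the energy-difference samples for one interval of the coupling
#' parameter.  The sign convention is fixed: `du` is always
#' U(lambda_to) - U(lambda_from), in whichever endpoint ensemble sampled
#' it.  `forward_du` was sampled in the `lambda_from` ensemble,
#' `reverse_du` in the `lambda_to` ensemble.
#'
#' @param lambda_from,lambda_to Window endpoints in `[0, 1]`, distinct.
#' @param forward_du Energy differences (kcal/mol) sampled at `lambda_from`.
#' @param reverse_du Energy differences (kcal/mol, same sign convention)
#'   sampled at `lambda_to`; may be empty for one-sided estimation.
#' @return An object of class `fep_window`.
#' @export
fep_window <- function(lambda_from, lambda_to, forward_du,
                       reverse_du = numeric()) {
  stopifnot(length(lambda_from) == 1L, length(lambda_to) == 1L)
  if (lambda_from < 0 || lambda_from > 1 || lambda_to < 0 || lambda_to > 1)
    stop("lambda values must lie in [0, 1]", call. = FALSE)
  if (lambda_from == lambda_to)
    stop("lambda_from and lambda_to must differ", call. = FALSE)
  if (length(forward_du) == 0L)
    stop("forward_du must be nonempty", call. = FALSE)
  structure(list(lambda_from = as.numeric(lambda_from),
                 lambda_to = as.numeric(lambda_to),
                 forward_du = as.numeric(forward_du),
                 reverse_du = as.numeric(reverse_du)),
            class = "fep_window")
}

#' Construct a donor-acceptor distance time series
#'
#' @param time Sampling times in ns.
#' @param distance Distances in Angstrom, strictly positive (e.g. the
#'   CoQ10-headgroup-center to N2-cluster-center distance).
#' @param label System tag, e.g. `"WT"` or `"A52T"`.
#' @return A data frame of class `distance_series` with attribute `label`.
#' @export
distance_series <- function(time, distance, label = "series") {
  if (length(time) != length(distance))
    stop("time and distance must have equal length", call. = FALSE)
  if (any(distance <= 0))
    stop(sprintf("distances must be strictly positive (row %d is %g)",
                 which(distance <= 0)[1L], distance[distance <= 0][1L]),
         call. = FALSE)
  ds <- data.frame(time = as.numeric(time), distance = as.numeric(distance))
  attr(ds, "label") <- as.character(label)
  class(ds) <- c("distance_series", "data.frame")
  ds
}

# ---------------------------------------------------------------------------
# Readers

#' Read pulling work traces
#'
#' Two dialects are supported:
#'
#' * `"tsv"`: a whitespace-separated table with a header line naming the
#'   columns `traj_id time restraint_center coordinate accumulated_work`
#'   (time in ns, lengths in Angstrom, work in kcal/mol); lines starting
#'   with `#` are comments.  Multiple trajectories are distinguished by
#'   `traj_id`.
#' * `"smd_log"`: an MD-engine log.  Only lines whose first token is the
#'   record keyword `SMD` are parsed; each carries
#'   `SMD <time_fs> <center_A> <coordinate_A> <work_kcal_mol>`.
#'   All other lines are ignored.  A new trajectory block starts whenever
#'   the time field does not increase (engines restart the clock per run).
#'   Times are converted from fs to ns.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"smd_log"`.
#' @return A list of [work_trace] objects, one per trajectory.
#' @export
read_work_traces <- function(path, dialect = c("tsv", "smd_log")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tsv") {
    tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                             stringsAsFactors = FALSE)
    need <- c("traj_id", "time", "restraint_center", "coordinate",
              "accumulated_work")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    ids <- unique(tab$traj_id)
    lapply(ids, function(id) {
      b <- tab[tab$traj_id == id, , drop = FALSE]
      work_trace(id, b$time, b$restraint_center, b$coordinate,
                 b$accumulated_work)
    })
  } else {
    lines <- readLines(path)
    rec <- grep("^SMD\\s", lines)
    if (!length(rec)) stop("no SMD records found in ", path, call. = FALSE)
    fields <- do.call(rbind, lapply(strsplit(trimws(lines[rec]), "\\s+"),
                                    function(tok) {
      if (length(tok) < 5L)
        stop("malformed SMD record: ", paste(tok, collapse = " "),
             call. = FALSE)
      as.numeric(tok[2:5])
    }))
    t_ns <- fields[, 1L] * 1e-6          # fs -> ns
    block <- cumsum(c(TRUE, diff(t_ns) <= 0))
    lapply(unique(block), function(b) {
      i <- block == b
      work_trace(sprintf("traj%d", b), t_ns[i], fields[i, 2L], fields[i, 3L],
                 fields[i, 4L])
    })
  }
}

#' Read alchemical window samples
#'
#' Two dialects are supported:
#'
#' * `"tsv"`: a whitespace-separated table with header
#'   `lambda_from lambda_to direction du`, where `direction` is
#'   `forward` (sampled at `lambda_from`) or `reverse` (sampled at
#'   `lambda_to`) and `du` = U(lambda_to) - U(lambda_from) in kcal/mol.
#' * `"fepout"`: an MD-engine FEP log.  Window metadata lines look like
#'   `#NEW FEP WINDOW: LAMBDA SET TO <l1> LAMBDA2 <l2>`; only data lines
#'   whose first token is the record keyword `FepEnergy:` are parsed, and
#'   the energy difference is taken from the last field
#'   (`FepEnergy: <step> ... <dE>`), reported by the engine as
#'   U(l2) - U(l1) in the l1 ensemble.  Runs with l2 > l1 are forward
#'   samples of the window (l1, l2); runs with l2 < l1 are reverse samples
#'   of the window (l2, l1) and are sign-flipped on input so that stored
#'   `du` always means U(lambda_to) - U(lambda_from).
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"fepout"`.
#' @return A list of [fep_window] objects sorted by `lambda_from`.
#' @export
read_fep_samples <- function(path, dialect = c("tsv", "fepout")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tsv") {
    tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                             stringsAsFactors = FALSE)
    need <- c("lambda_from", "lambda_to", "direction", "du")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    if (any(tab$lambda_from < 0 | tab$lambda_from > 1 |
            tab$lambda_to < 0 | tab$lambda_to > 1))
      stop("lambda values must lie in [0, 1]", call. = FALSE)
    key <- paste(format(tab$lambda_from, digits = 12),
                 format(tab$lambda_to, digits = 12))
    wins <- lapply(split(tab, key), function(b) {
      fwd <- b$du[b$direction == "forward"]
      rev <- b$du[b$direction == "reverse"]
      if (length(fwd) == 0L)
        stop(sprintf("window (%g, %g) has no forward samples",
                     b$lambda_from[1L], b$lambda_to[1L]), call. = FALSE)
      fep_window(b$lambda_from[1L], b$lambda_to[1L], fwd, rev)
    })
  } else {
    lines <- readLines(path)
    hdr <- grep("LAMBDA SET TO", lines)
    if (!length(hdr)) stop("no FEP window headers in ", path, call. = FALSE)
    run_of <- findInterval(seq_along(lines), hdr)
    lam <- t(vapply(lines[hdr], function(l) {
      m <- regexec(
        "LAMBDA SET TO\\s+([0-9.eE+-]+)\\s+LAMBDA2\\s+([0-9.eE+-]+)", l)
      tok <- regmatches(l, m)[[1L]]
      if (length(tok) != 3L)
        stop("malformed FEP window header: ", l, call. = FALSE)
      as.numeric(tok[2:3])
    }, numeric(2)))
    rec <- grep("^FepEnergy:", trimws(lines))
    if (!length(rec)) stop("no FepEnergy records in ", path, call. = FALSE)
    du <- vapply(strsplit(trimws(lines[rec]), "\\s+"),
                 function(tok) as.numeric(tok[length(tok)]), numeric(1))
    runs <- run_of[rec]
    if (any(runs == 0L))
      stop("FepEnergy record before any window header", call. = FALSE)
    acc <- list()
    for (r in unique(runs)) {
      l1 <- lam[r, 1L]; l2 <- lam[r, 2L]
      if (any(c(l1, l2) < 0 | c(l1, l2) > 1))
        stop("lambda values must lie in [0, 1]", call. = FALSE)
      x <- du[runs == r]
      lo <- min(l1, l2); hi <- max(l1, l2)
      key <- paste(format(lo, digits = 12), format(hi, digits = 12))
      slot <- if (l2 > l1) "forward" else "reverse"
      if (is.null(acc[[key]]))
        acc[[key]] <- list(lo = lo, hi = hi,
                           forward = numeric(), reverse = numeric())
      # reverse runs report U(lo) - U(hi); flip to the fixed convention
      acc[[key]][[slot]] <- c(acc[[key]][[slot]], if (l2 > l1) x else -x)
    }
    wins <- lapply(acc, function(a) {
      if (length(a$forward) == 0L)
        stop(sprintf("window (%g, %g) has no forward samples", a$lo, a$hi),
             call. = FALSE)
      fep_window(a$lo, a$hi, a$forward, a$reverse)
    })
  }
  wins <- unname(wins)
  wins[order(vapply(wins, `[[`, numeric(1), "lambda_from"))]
}

#' Read a donor-acceptor distance series
#'
#' Expects a two-column numeric table (time in ns, distance in Angstrom),
#' whitespace-separated, with an optional header line and `#` comments.
#'
#' @param path Path to the file.
#' @param label System tag to attach (e.g. `"WT"`, `"A52T"`).
#' @return A [distance_series].
#' @export
read_distance_series <- function(path, label = "series") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- utils::read.table(path, comment.char = "#", nrows = 1L,
                             stringsAsFactors = FALSE)
  has_header <- !all(vapply(first, is.numeric, logical(1)))
  tab <- utils::read.table(path, header = has_header, comment.char = "#")
  if (ncol(tab) < 2L) stop("expected a two-column table", call. = FALSE)
  distance_series(tab[[1L]], tab[[2L]], label)
}

# ---------------------------------------------------------------------------
# Writers

fmt10 <- function(x) formatC(x, format = "g", digits = 10)

#' Write pulling work traces as TSV
#' @param traces List of [work_trace] objects.
#' @param path Output path.
#' @export
write_work_traces <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    data.frame(traj_id = attr(tr, "traj_id"), time = fmt10(tr$time),
               restraint_center = fmt10(tr$restraint_center),
               coordinate = fmt10(tr$coordinate),
               accumulated_work = fmt10(tr$accumulated_work))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write alchemical window samples as TSV
#' @param windows List of [fep_window] objects.
#' @param path Output path.
#' @export
write_fep_samples <- function(windows, path) {
  rows <- lapply(windows, function(w) {
    data.frame(lambda_from = fmt10(w$lambda_from),
               lambda_to = fmt10(w$lambda_to),
               direction = rep(c("forward", "reverse"),
                               c(length(w$forward_du), length(w$reverse_du))),
               du = fmt10(c(w$forward_du, w$reverse_du)))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a distance series as TSV
#' @param series A [distance_series].
#' @param path Output path.
#' @export
write_distance_series <- function(series, path) {
  out <- data.frame(time = fmt10(series$time),
                    distance = fmt10(series$distance))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an analysis result record
#'
#' Serialises an analysis result (a named list, possibly nested, or a data
#' frame) either as JSON (full precision, stable key order) or as a TSV
#' table with numbers formatted to 10 significant digits.
#'
#' @param record Named list or data frame.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @export
write_results <- function(record, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(strip_classes(record), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    df <- as.data.frame(record)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], fmt10)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# drop S3 classes so jsonlite serialises plainly and key order is stable
strip_classes <- function(x) {
  if (is.data.frame(x)) { class(x) <- "data.frame"; return(x) }
  if (is.list(x)) { x <- unclass(x); return(lapply(x, strip_classes)) }
  x
}
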