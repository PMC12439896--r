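#' Per-run choice fractions over the last choices of a phase
#'
#' For each run, takes the final \code{window} hourly decisions within the
#' phase, buckets them by delay (the 1-based hour of the day), and computes
#' the fraction of choices going to each prey.  Roam choices stay in the
#' denominator, so a delay's fractions over prey need not sum to 1.
#'
#' @param records a records data.frame with columns run, day, hour, action
#'   and (for phased scenarios) phase.
#' @param phase which phase to analyse (NULL if records have no phases).
#' @param window number of final choices per run (default 10).
#' @return data.frame: run, delay_hours, object, fraction.  Runs with no
#'   choice at a given delay inside the window contribute NA there.
#' @seealso [choiceSummary()]
#' @export
choiceFractions <- function(records, phase = NULL, window = 10L) {
  if (!is.null(phase)) {
    if (!"phase" %in% names(records))
      stop("records have no 'phase' column", call. = FALSE)
    records <- records[records$phase == phase, , drop = FALSE]
    if (nrow(records) == 0L)
      stop("phase ", phase, " absent from records", call. = FALSE)
  }
  objects <- sort(unique(sub("^hunt_", "",
                             grep("^hunt_", records$action, value = TRUE))))
  delays <- sort(unique(records$hour)) + 1L
  runs <- sort(unique(records$run))
  out <- vector("list", length(runs))
  for (j in seq_along(runs)) {
    rr <- records[records$run == runs[j], , drop = FALSE]
    rr <- rr[order(rr$day, rr$hour), , drop = FALSE]
    rr <- utils::tail(rr, window)
    frac <- expand.grid(delay_hours = delays, object = objects,
                        stringsAsFactors = FALSE)
    frac$run <- runs[j]
    frac$fraction <- NA_real_
    for (i in seq_len(nrow(frac))) {
      sel <- rr$hour + 1L == frac$delay_hours[i]
      if (any(sel))
        frac$fraction[i] <-
          mean(rr$action[sel] == paste0("hunt_", frac$object[i]))
    }
    out[[j]] <- frac[, c("run", "delay_hours", "object", "fraction")]
  }
  do.call(rbind, out)
}

#' Boxplot summary of choice fractions across runs
#'
#' Median, first and third quartile, and whiskers extending to the most
#' extreme run within 1.5 x IQR beyond the quartiles (the usual boxplot
#' convention); NA runs are dropped per cell.
#'
#' @param fractions output of [choiceFractions()].
#' @return data.frame: delay_hours, object, n, median, q1, q3, whisker_lo,
#'   whisker_hi.
#' @export
choiceSummary <- function(fractions) {
  key <- interaction(fractions$delay_hours, fractions$object, drop = TRUE)
  out <- lapply(split(fractions, key), function(g) {
    x <- g$fraction[!is.na(g$fraction)]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3L] - q[1L]
    data.frame(delay_hours = g$delay_hours[1L], object = g$object[1L],
               n = length(x), median = q[2L], q1 = q[1L], q3 = q[3L],
               whisker_lo = min(x[x >= q[1L] - 1.5 * iqr]),
               whisker_hi = max(x[x <= q[3L] + 1.5 * iqr]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$object, out$delay_hours), , drop = FALSE]
}

# Outcome of each hour record as one of crab / shrimp / caught / NA.
.outcomeOf <- function(records) {
  if ("outcome" %in% names(records)) {
    c(ate_crab = "crab", ate_shrimp = "shrimp", caught = "caught",
      none = NA_character_)[records$outcome]
  } else if ("eaten" %in% names(records)) {
    ifelse(records$eaten == "none", NA_character_, records$eaten)
  } else {
    stop("records need an 'outcome' or 'eaten' column", call. = FALSE)
  }
}

#' Mean outcome counts per day bin across runs
#'
#' Bins days into windows of \code{bin_width} days and reports, per bin and
#' outcome type (crab, shrimp, caught), the mean count across runs with its
#' standard error sd/sqrt(runs).  With a single run the SE is undefined and
#' reported as 0 with \code{se_undefined = TRUE}.
#'
#' @param records a records data.frame (outcome or eaten column).
#' @param bin_width bin width in days (default 10).
#' @return data.frame: bin_start, bin_end, type, mean, se, n_runs,
#'   se_undefined, partial_bin.
#' @export
outcomesOverDays <- function(records, bin_width = 10L) {
  if (nrow(records) == 0L) stop("empty records", call. = FALSE)
  bin_width <- as.integer(bin_width)
  outc <- .outcomeOf(records)
  runs <- sort(unique(records$run))
  nDays <- max(records$day) + 1L
  bins <- 0:((nDays - 1L) %/% bin_width)
  types <- c("crab", "shrimp",
             if ("outcome" %in% names(records)) "caught")
  grid <- expand.grid(bin = bins, type = types, stringsAsFactors = FALSE)
  counts <- array(0L, dim = c(length(runs), nrow(grid)))
  binOf <- records$day %/% bin_width
  for (i in seq_len(nrow(grid))) {
    sel <- !is.na(outc) & outc == grid$type[i] & binOf == grid$bin[i]
    if (any(sel))
      counts[, i] <- tabulate(match(records$run[sel], runs),
                              nbins = length(runs))
  }
  mn <- colMeans(counts)
  se <- if (length(runs) > 1L) apply(counts, 2L, stats::sd) /
    sqrt(length(runs)) else rep(0, nrow(grid))
  data.frame(bin_start = grid$bin * bin_width,
             bin_end = pmin(grid$bin * bin_width + bin_width - 1L,
                            nDays - 1L),
             type = grid$type, mean = mn, se = se,
             n_runs = length(runs), se_undefined = length(runs) == 1L,
             partial_bin = (grid$bin * bin_width + bin_width) > nDays,
             stringsAsFactors = FALSE)
}

#' Mean action counts per hour over a day window
#'
#' For each (hour, action), the mean and standard deviation across runs of
#' the number of times the action was chosen at that hour within the day
#' window -- e.g. the first or last 20 days.
#'
#' @param records a records data.frame.
#' @param day_window inclusive day range c(first, last), 0-based.
#' @return data.frame: hour, action, mean, sd, n_runs.
#' @export
actionsPerHour <- function(records, day_window) {
  stopifnot(length(day_window) == 2L)
  sel <- records$day >= day_window[1L] & records$day <= day_window[2L]
  if (!any(sel)) stop("empty day window", call. = FALSE)
  records <- records[sel, , drop = FALSE]
  runs <- sort(unique(records$run))
  actions <- sort(unique(records$action))
  hours <- sort(unique(records$hour))
  grid <- expand.grid(hour = hours, action = actions,
                      stringsAsFactors = FALSE)
  counts <- array(0L, dim = c(length(runs), nrow(grid)))
  for (i in seq_len(nrow(grid))) {
    s <- records$hour == grid$hour[i] & records$action == grid$action[i]
    if (any(s))
      counts[, i] <- tabulate(match(records$run[s], runs),
                              nbins = length(runs))
  }
  data.frame(hour = grid$hour, action = grid$action,
             mean = colMeans(counts),
             sd = if (length(runs) > 1L) apply(counts, 2L, stats::sd)
                  else rep(0, nrow(grid)),
             n_runs = length(runs), stringsAsFactors = FALSE)
}

#' Mental-time-travel query table of a learned memory
#'
#' Exhaustively lists the memory's expected values as rows of (hour,
#' object, where_x, where_y, value), optionally dropping zero entries and
#' filtering by object and/or hour.  Scanning the table across hours
#' reconstructs past value landscapes or anticipates future ones -- the
#' model's rudimentary mental time travel.
#'
#' @param mem an [EpisodicMemory-class].
#' @param nonzeroOnly drop rows with value 0 (default TRUE).
#' @param object optional object label filter.
#' @param hour optional 0-based hour filter.
#' @return data.frame: hour (0-based), object, where_x, where_y, value.
#' @export
mttTable <- function(mem, nonzeroOnly = TRUE, object = NULL, hour = NULL) {
  v <- memValues(mem)
  d <- dim(v)
  labs <- dimnames(v)[[1L]]
  xy <- cellCoords(seq_len(d[3L]), gridWidth(mem))
  out <- data.frame(
    hour = rep(seq_len(d[2L]) - 1L, each = d[1L], times = d[3L]),
    object = rep(labs, times = d[2L] * d[3L]),
    where_x = rep(xy[, "x"], each = d[1L] * d[2L]),
    where_y = rep(xy[, "y"], each = d[1L] * d[2L]),
    value = as.vector(v),
    stringsAsFactors = FALSE)
  if (!is.null(object)) out <- out[out$object %in% object, , drop = FALSE]
  if (!is.null(hour)) out <- out[out$hour %in% hour, , drop = FALSE]
  if (nonzeroOnly) out <- out[out$value != 0, , drop = FALSE]
  out <- out[order(out$object, out$hour, out$where_y, out$where_x), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
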