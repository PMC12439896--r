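# Independent brute-force oracles used across the suite.  These deliberately
# re-derive quantities with plain loops so tests never share code paths with
# the implementation they check.

# Gather/reduce a tensor entry set with explicit loops.
bruteQuery <- function(v, what = NULL, when = NULL, where = NULL,
                       reduction = "none") {
  selWhat <- if (is.null(what)) seq_len(dim(v)[1]) else what
  selWhen <- if (is.null(when)) seq_len(dim(v)[2]) else when
  selWhere <- if (is.null(where)) seq_len(dim(v)[3]) else where
  out <- numeric(0)
  for (k in selWhere) for (j in selWhen) for (i in selWhat)
    out <- c(out, unname(v[i, j, k]))
  switch(reduction, none = out, max = max(out), sum = sum(out),
         mean = mean(out))
}

# Iterate the delta rule k times from v0 with constant reward r.
iterateDelta <- function(v0, alpha, r, k) {
  v <- v0
  for (i in seq_len(k)) v <- v + alpha * (r - v)
  v
}

# Tally choice fractions for one run's last `window` rows of a phase.
bruteChoiceFractions <- function(records, phase, window, run, delay, object) {
  rr <- records[records$run == run & records$phase == phase, ]
  rr <- rr[order(rr$day, rr$hour), ]
  if (nrow(rr) > window) rr <- rr[(nrow(rr) - window + 1):nrow(rr), ]
  sel <- rr$hour + 1 == delay
  if (!any(sel)) return(NA_real_)
  sum(rr$action[sel] == paste0("hunt_", object)) / sum(sel)
}

# Tiny configs used by scenario tests (small worlds, short hours).
toyElmConfig <- function(...) elmConfig(days = 4, phase1_days = 2, runs = 2,
                                        steps_per_hour = 20, ...)
toyPpConfig <- function(mode = "what_when", ...)
  ppConfig(mode, days = 4, runs = 2, steps_per_hour = 30, ...)
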