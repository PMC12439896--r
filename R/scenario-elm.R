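#' Action values for the delayed-reward scenario
#'
#' At the start of each hour the agent queries its memory for every prey at
#' the current hour and takes the maximum expected value across locations;
#' roaming has a fixed value.  The resulting vector feeds
#' [softmaxProbabilities()].
#'
#' @param mem an [EpisodicMemory-class] whose objects are the prey kinds.
#' @param hour 0-based hour of the day.
#' @param roam_value fixed value of the roam action (default 0.5).
#' @return named numeric vector: one \code{hunt_<kind>} per object, then
#'   \code{roam}.
#' @export
elmActionValues <- function(mem, hour, roam_value = 0.5) {
  labs <- whatLabels(mem)
  vals <- vapply(labs, function(w)
    queryMemory(mem, what = w, when = hour + 1L, reduction = "max"),
    numeric(1L))
  c(stats::setNames(vals, paste0("hunt_", labs)), roam = roam_value)
}

#' Sample one action in the delayed-reward scenario
#'
#' @inheritParams elmActionValues
#' @param beta softmax inverse temperature.
#' @return the chosen action name, e.g. \code{"hunt_shrimp"}.
#' @export
elmChooseAction <- function(mem, hour, beta = 1, roam_value = 0.5) {
  vals <- elmActionValues(mem, hour, roam_value)
  names(vals)[selectAction(softmaxProbabilities(vals, beta))]
}

# One hour of the delayed-reward scenario, with the action already chosen.
# M is the raw tensor [what, when, where]; returns the updated tensor and
# what (if anything) was eaten.  action: 1 = hunt crab, 2 = hunt shrimp,
# 3 = roam.  The agent starts the hour at cfg$agent_start; prey sit at
# fixed cells.  At every step any available prey within the agent's vision
# (Chebyshev distance < agent_vision) is eaten -- at most one per hour --
# and the prey's value at its own cell is updated with its reward.  A hunt
# that arrives at the remembered cell without finding its target applies
# one extinction update (r = 0) there.
.elmHour <- function(M, hour, phase, cfg, action) {
  h1 <- hour + 1L
  W <- cfg$width; H <- cfg$height; S <- cfg$steps_per_hour
  alpha <- cfg$alpha
  vis <- cfg$agent_vision - 1L
  cx <- cfg$crab_cell[1L]; cy <- cfg$crab_cell[2L]
  sx <- cfg$shrimp_cell[1L]; sy <- cfg$shrimp_cell[2L]
  shrimpAvail <- phase == 1L || hour == cfg$hours_per_day - 1L
  ax <- cfg$agent_start[1L]; ay <- cfg$agent_start[2L]
  eaten <- "none"

  tryEat <- function(ax, ay) {
    if (max(abs(ax - cx), abs(ay - cy)) <= vis) "crab"
    else if (shrimpAvail && max(abs(ax - sx), abs(ay - sy)) <= vis) "shrimp"
    else "none"
  }
  applyEat <- function(kind) {
    if (kind == "crab") {
      i <- cy * W + cx + 1L
      M[1L, h1, i] <<- M[1L, h1, i] + alpha * (cfg$crab_reward - M[1L, h1, i])
    } else {
      i <- sy * W + sx + 1L
      M[2L, h1, i] <<- M[2L, h1, i] +
        alpha * (cfg$shrimp_reward - M[2L, h1, i])
    }
    eaten <<- kind
  }

  if (action <= 2L) {
    t0 <- which.max(M[action, h1, ]) - 1L
    tx <- t0 %% W; ty <- t0 %/% W
    e <- tryEat(ax, ay)
    if (e != "none") applyEat(e)
    if (eaten == "none") {
      d <- max(abs(ax - tx), abs(ay - ty))
      for (s in seq_len(min(d, S))) {
        ax <- ax + sign(tx - ax); ay <- ay + sign(ty - ay)
        e <- tryEat(ax, ay)
        if (e != "none") { applyEat(e); break }
      }
      if (eaten == "none" && d <= S) {
        # arrived but the target was absent (or beyond reach): extinction
        i <- ay * W + ax + 1L
        M[action, h1, i] <- M[action, h1, i] + alpha * (0 - M[action, h1, i])
      }
    }
  } else {
    dirs <- sample.int(8L, S, replace = TRUE)
    for (s in seq_len(S)) {
      x <- ax + .DX[dirs[s]]; y <- ay + .DY[dirs[s]]
      ax <- if (x < 0L) 0L else if (x >= W) W - 1L else x
      ay <- if (y < 0L) 0L else if (y >= H) H - 1L else y
      e <- tryEat(ax, ay)
      if (e != "none") { applyEat(e); break }
    }
  }
  list(M = M, eaten = eaten)
}

# One full run: fresh memory, cfg$days x hours_per_day hourly decisions.
.elmRunSingle <- function(cfg, seed, run_id) {
  set.seed(seed)
  nWhen <- cfg$hours_per_day
  M <- array(0, dim = c(2L, nWhen, cfg$width * cfg$height),
             dimnames = list(c("crab", "shrimp"), NULL, NULL))
  n <- cfg$days * nWhen
  rDay <- integer(n); rHour <- integer(n); rPhase <- integer(n)
  rAction <- character(n); rEaten <- character(n)
  actNames <- c("hunt_crab", "hunt_shrimp", "roam")
  k <- 0L
  for (day in 0:(cfg$days - 1L)) {
    phase <- if (day < cfg$phase1_days) 1L else 2L
    for (hour in 0:(nWhen - 1L)) {
      h1 <- hour + 1L
      vals <- c(max(M[1L, h1, ]), max(M[2L, h1, ]), cfg$roam_value)
      z <- cfg$beta * vals
      e <- exp(z - max(z))
      act <- sample.int(3L, 1L, prob = e / sum(e))
      res <- .elmHour(M, hour, phase, cfg, act)
      M <- res$M
      k <- k + 1L
      rDay[k] <- day; rHour[k] <- hour; rPhase[k] <- phase
      rAction[k] <- actNames[act]; rEaten[k] <- res$eaten
    }
  }
  records <- data.frame(run = run_id, day = rDay, hour = rHour,
                        phase = rPhase, action = rAction, eaten = rEaten,
                        delay_hours = rHour + 1L,
                        stringsAsFactors = FALSE)
  mem <- new("EpisodicMemory", values = M, alpha = cfg$alpha,
             width = cfg$width, height = cfg$height)
  list(records = records, memory = mem)
}

#' Run the delayed-reward (episodic-like memory) scenario
#'
#' Simulates the two-phase foraging experiment: in phase 1 both prey are
#' available every hour; in phase 2 the preferred shrimp appears only after
#' the long delay (the final hour of the day).  Each hour the agent chooses
#' hunt crab / hunt shrimp / roam by softmax over its memory's maximum
#' expected values, moves on the grid, and updates its memory by the delta
#' rule whenever it eats (or fails to find) a prey.
#'
#' @param config an [elmConfig()].
#' @param seed base integer seed; run r uses seed + r - 1
#'   (see [deriveSeeds()]).
#' @param runs number of independent runs (default \code{config$runs}).
#' @return list of class \code{"cuttle_run"} with elements \code{records}
#'   (one data.frame over all runs: run, day, hour, phase, action, eaten,
#'   delay_hours), \code{memories} (list of final [EpisodicMemory-class]
#'   per run), \code{config}, \code{seeds}.
#' @examples
#' res <- runElm(elmConfig(days = 4, runs = 2), seed = 1)
#' head(res$records)
#' @export
runElm <- function(config = elmConfig(), seed, runs = config$runs) {
  stopifnot(inherits(config, "elm_config"))
  seeds <- deriveSeeds(seed, runs)
  out <- vector("list", runs)
  mems <- vector("list", runs)
  for (r in seq_len(runs)) {
    res <- .elmRunSingle(config, seeds[r], r)
    out[[r]] <- res$records
    mems[[r]] <- res$memory
  }
  structure(list(records = do.call(rbind, out), memories = mems,
                 config = config, seeds = seeds),
            class = "cuttle_run")
}

#' @export
print.cuttle_run <- function(x, ...) {
  cfg <- x$config
  cat("<cuttle_run> scenario ", cfg$scenario,
      if (!is.null(cfg$query_mode)) paste0(" (", cfg$query_mode, ")"),
      ": ", length(x$memories), " run(s), ", nrow(x$records),
      " hour records\n", sep = "")
  invisible(x)
}
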