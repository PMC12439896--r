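#' Action values for the predator-prey scenario
#'
#' Two read-out policies over the same memory.  In \code{"what_when"} mode
#' the value of hunting each prey is its expected value summed over all
#' locations at the current hour; hiding is driven by learned danger,
#' value(hide) = -(sum of the predator's entries), which is non-negative
#' because predator entries are learned from a negative reward; roaming has
#' a fixed value.  In \code{"when_where"} mode each region's value is the
#' sum over all objects and the region's cells -- so predator penalties
#' discount risky regions -- plus the fixed roam value.
#'
#' @param mem an [EpisodicMemory-class] with objects crab, shrimp, predator.
#' @param hour 0-based hour of the day.
#' @param query_mode \code{"what_when"} or \code{"when_where"}.
#' @param roam_value fixed value of the roam action.
#' @param blockSize region block size.
#' @return named numeric vector of action values.
#' @export
ppActionValues <- function(mem, hour, query_mode = c("what_when",
                                                     "when_where"),
                           roam_value = 0.5, blockSize = 4L) {
  query_mode <- match.arg(query_mode)
  h1 <- hour + 1L
  if (query_mode == "what_when") {
    c(hunt_crab = queryMemory(mem, "crab", h1, reduction = "sum"),
      hunt_shrimp = queryMemory(mem, "shrimp", h1, reduction = "sum"),
      hide = -queryMemory(mem, "predator", h1, reduction = "sum"),
      roam = roam_value)
  } else {
    W <- gridWidth(mem); H <- gridHeight(mem)
    nReg <- (W %/% blockSize) * (H %/% blockSize)
    vals <- vapply(seq_len(nReg) - 1L, function(r)
      queryMemory(mem, when = h1,
                  where = regionCells(r, W, H, blockSize),
                  reduction = "sum"),
      numeric(1L))
    c(stats::setNames(vals, paste0("go_region_", seq_len(nReg) - 1L)),
      roam = roam_value)
  }
}

# One hour of the predator-prey scenario with the action index already
# chosen.  placements is the list from placeForHour() for this hour.
# what_when actions: 1 hunt crab, 2 hunt shrimp, 3 hide, 4 roam.
# when_where actions: 1..nReg go to region (act - 1), nReg + 1 roam.
# Movement cadence: each step the agent moves first, then the predator; a
# prey within the agent's vision is eaten (once per hour) and its value at
# its actual cell updated; after the predator's move, an uncamouflaged
# agent at distance <= 1 is caught, the predator's cell gets the penalty
# update, and the hour ends.
.ppHour <- function(M, hour, cfg, act, placements) {
  h1 <- hour + 1L
  W <- cfg$width; H <- cfg$height; S <- cfg$steps_per_hour
  bs <- cfg$block_size
  alpha <- cfg$alpha
  visA <- cfg$agent_vision - 1L
  visP <- cfg$predator_vision
  perRow <- W %/% bs

  crab <- placements$crab
  shrimp <- placements$shrimp
  pred <- placements$predator
  ax <- cfg$agent_start[1L]; ay <- cfg$agent_start[2L]
  camo <- FALSE
  huntKind <- 0L          # 1 crab / 2 shrimp when hunting in what_when mode
  targetRegion <- -1L
  tx <- ty <- -1L
  bxmin <- bxmax <- bymin <- bymax <- 0L
  hasTarget <- FALSE

  if (cfg$query_mode == "what_when") {
    if (act <= 2L) {
      huntKind <- act
      cellVals <- M[act, h1, ]
      best <- -Inf; reg <- 0L
      for (r in 0:(perRow * (H %/% bs) - 1L)) {
        b <- regionBounds(r, W, H, bs)
        v <- sum(cellVals[(rep(b[3L]:b[4L], each = bs) * W +
                             rep(b[1L]:b[2L], times = bs)) + 1L])
        if (v > best) { best <- v; reg <- r }
      }
      targetRegion <- reg
      hasTarget <- TRUE
    } else if (act == 3L) {
      camo <- TRUE
    }
  } else {
    nReg <- perRow * (H %/% bs)
    if (act <= nReg) {
      targetRegion <- act - 1L
      hasTarget <- TRUE
    }
  }
  if (hasTarget) {
    b <- regionBounds(targetRegion, W, H, bs)
    bxmin <- b[1L]; bxmax <- b[2L]; bymin <- b[3L]; bymax <- b[4L]
    tx <- bxmin + 1L; ty <- bymin + 1L
  }

  adirs <- if (!camo) sample.int(8L, S, replace = TRUE)
  pdirs <- if (!is.null(pred)) sample.int(8L, S, replace = TRUE)
  px <- pred[1L]; py <- pred[2L]

  outcome <- "none"
  arrived <- FALSE
  for (s in seq_len(S)) {
    if (!camo) {
      if (hasTarget && !arrived) {
        ax <- ax + sign(tx - ax); ay <- ay + sign(ty - ay)
        if (ax == tx && ay == ty) {
          arrived <- TRUE
          if (huntKind > 0L) {
            prey <- if (huntKind == 1L) crab else shrimp
            absent <- is.null(prey) ||
              regionOfCell(prey[1L], prey[2L], W, bs) != targetRegion
            if (absent) {
              i <- ty * W + tx + 1L
              M[huntKind, h1, i] <- M[huntKind, h1, i] +
                alpha * (0 - M[huntKind, h1, i])
            }
          }
        }
      } else if (hasTarget) {
        x <- ax + .DX[adirs[s]]; y <- ay + .DY[adirs[s]]
        ax <- if (x < bxmin) bxmin else if (x > bxmax) bxmax else x
        ay <- if (y < bymin) bymin else if (y > bymax) bymax else y
      } else {
        x <- ax + .DX[adirs[s]]; y <- ay + .DY[adirs[s]]
        ax <- if (x < 0L) 0L else if (x >= W) W - 1L else x
        ay <- if (y < 0L) 0L else if (y >= H) H - 1L else y
      }
      if (!is.null(crab) &&
          max(abs(ax - crab[1L]), abs(ay - crab[2L])) <= visA) {
        i <- crab[2L] * W + crab[1L] + 1L
        M[1L, h1, i] <- M[1L, h1, i] + alpha * (cfg$crab_reward - M[1L, h1, i])
        outcome <- "ate_crab"
        break
      } else if (!is.null(shrimp) &&
                 max(abs(ax - shrimp[1L]), abs(ay - shrimp[2L])) <= visA) {
        i <- shrimp[2L] * W + shrimp[1L] + 1L
        M[2L, h1, i] <- M[2L, h1, i] +
          alpha * (cfg$shrimp_reward - M[2L, h1, i])
        outcome <- "ate_shrimp"
        break
      }
    }
    if (!is.null(pred)) {
      if (!camo && max(abs(px - ax), abs(py - ay)) < visP) {
        px <- px + sign(ax - px); py <- py + sign(ay - py)
      } else {
        x <- px + .DX[pdirs[s]]; y <- py + .DY[pdirs[s]]
        px <- if (x < 0L) 0L else if (x >= W) W - 1L else x
        py <- if (y < 0L) 0L else if (y >= H) H - 1L else y
      }
      if (!camo && max(abs(px - ax), abs(py - ay)) <= 1L) {
        i <- py * W + px + 1L
        M[3L, h1, i] <- M[3L, h1, i] +
          alpha * (-cfg$predator_penalty - M[3L, h1, i])
        outcome <- "caught"
        break
      }
    }
  }
  list(M = M, outcome = outcome,
       end_region = regionOfCell(ax, ay, W, bs))
}

# One full predator-prey run with a fresh memory.
.ppRunSingle <- function(cfg, seed, run_id) {
  set.seed(seed)
  nWhen <- cfg$hours_per_day
  L <- cfg$width * cfg$height
  M <- array(0, dim = c(3L, nWhen, L),
             dimnames = list(c("crab", "shrimp", "predator"), NULL, NULL))
  schedule <- ppSchedule(cfg)
  perRow <- cfg$width %/% cfg$block_size
  nReg <- perRow * (cfg$height %/% cfg$block_size)
  regIdx <- lapply(seq_len(nReg) - 1L, function(r)
    regionCells(r, cfg$width, cfg$height, cfg$block_size))
  whatWhen <- cfg$query_mode == "what_when"
  actNames <- if (whatWhen) c("hunt_crab", "hunt_shrimp", "hide", "roam")
    else c(paste0("go_region_", seq_len(nReg) - 1L), "roam")

  n <- cfg$days * nWhen
  rDay <- integer(n); rHour <- integer(n)
  rAction <- character(n); rOutcome <- character(n); rRegion <- integer(n)
  k <- 0L
  for (day in 0:(cfg$days - 1L)) {
    for (hour in 0:(nWhen - 1L)) {
      h1 <- hour + 1L
      placements <- placeForHour(schedule, hour, cfg$width, cfg$height,
                                 cfg$block_size)
      if (whatWhen) {
        vals <- c(sum(M[1L, h1, ]), sum(M[2L, h1, ]), -sum(M[3L, h1, ]),
                  cfg$roam_value)
      } else {
        cellTot <- .colSums(M[, h1, ], 3L, L)
        vals <- c(vapply(regIdx, function(i) sum(cellTot[i]), numeric(1L)),
                  cfg$roam_value)
      }
      z <- cfg$beta * vals
      e <- exp(z - max(z))
      act <- sample.int(length(vals), 1L, prob = e / sum(e))
      res <- .ppHour(M, hour, cfg, act, placements)
      M <- res$M
      k <- k + 1L
      rDay[k] <- day; rHour[k] <- hour
      rAction[k] <- actNames[act]; rOutcome[k] <- res$outcome
      rRegion[k] <- res$end_region
    }
  }
  records <- data.frame(run = run_id, day = rDay, hour = rHour,
                        action = rAction, outcome = rOutcome,
                        end_region = rRegion, stringsAsFactors = FALSE)
  mem <- new("EpisodicMemory", values = M, alpha = cfg$alpha,
             width = cfg$width, height = cfg$height)
  list(records = records, memory = mem)
}

#' Run the predator-prey scenario
#'
#' Simulates foraging under predation risk on a 12x12 grid of nine regions:
#' crab (reward 1) in region 8 all day, shrimp (reward 4) in region 6 hours
#' 2-5, predator (penalty 8) on the left half during hours 1-3.  Each hour
#' the agent picks an action by softmax over memory read-outs
#' ([ppActionValues()]), then hunts a region / hides / roams while the
#' predator pursues any uncamouflaged agent it can see.
#'
#' @param config a [ppConfig()] (fixes the query mode for all runs).
#' @param seed base integer seed.
#' @param runs number of independent runs (default \code{config$runs}).
#' @return list of class \code{"cuttle_run"}: \code{records} (run, day,
#'   hour, action, outcome, end_region), \code{memories}, \code{config},
#'   \code{seeds}.
#' @examples
#' res <- runPp(ppConfig("what_when", days = 3, runs = 2), seed = 1)
#' table(res$records$outcome)
#' @export
runPp <- function(config = ppConfig(), seed, runs = config$runs) {
  stopifnot(inherits(config, "pp_config"))
  seeds <- deriveSeeds(seed, runs)
  out <- vector("list", runs)
  mems <- vector("list", runs)
  for (r in seq_len(runs)) {
    res <- .ppRunSingle(config, seeds[r], r)
    out[[r]] <- res$records
    mems[[r]] <- res$memory
  }
  structure(list(records = do.call(rbind, out), memories = mems,
                 config = config, seeds = seeds),
            class = "cuttle_run")
}
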