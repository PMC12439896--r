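# King-move displacement table shared by all movement code.
.DX <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
.DY <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)

#' Chebyshev distance between two grid cells
#'
#' max(|dx|, |dy|): the number of king moves (8-direction steps) separating
#' two cells, which is the "steps" metric used for vision thresholds.
#'
#' @param a,b positions as c(x, y), 0-based.
#' @return non-negative integer.
#' @examples
#' chebyshevDistance(c(0, 0), c(3, 4))  # 4
#' @export
chebyshevDistance <- function(a, b) {
  max(abs(a[1L] - b[1L]), abs(a[2L] - b[2L]))
}

#' One random roaming step
#'
#' Displaces the position by one of the 8 king moves chosen uniformly, then
#' clips to the world (or to an optional rectangular bound, e.g. one region
#' when the agent searches within it).
#'
#' @param pos c(x, y), 0-based.
#' @param width,height world dimensions.
#' @param bounds optional c(xmin, xmax, ymin, ymax), inclusive, 0-based.
#' @return new position c(x, y).
#' @export
roamStep <- function(pos, width, height, bounds = NULL) {
  dir <- sample.int(8L, 1L)
  x <- pos[1L] + .DX[dir]
  y <- pos[2L] + .DY[dir]
  if (is.null(bounds)) {
    x <- min(max(x, 0L), width - 1L)
    y <- min(max(y, 0L), height - 1L)
  } else {
    x <- min(max(x, bounds[1L]), bounds[2L])
    y <- min(max(y, bounds[3L]), bounds[4L])
  }
  c(x, y)
}

#' One deterministic step toward a target
#'
#' Moves one king move with the sign of the remaining displacement on each
#' axis, so the target is reached in exactly [chebyshevDistance()] steps.
#' The agent is assumed to know how to reach a remembered location; this is
#' that assumption made concrete.
#'
#' @param pos,target positions as c(x, y), 0-based.
#' @return new position c(x, y); \code{pos} itself when already at target.
#' @examples
#' stepToward(c(0, 4), c(7, 7))  # c(1, 5)
#' @export
stepToward <- function(pos, target) {
  c(pos[1L] + sign(target[1L] - pos[1L]),
    pos[2L] + sign(target[2L] - pos[2L]))
}

#' One predator move
#'
#' The predator pursues (one sign-step toward the agent) when the agent is
#' visible -- not camouflaged and within the predator's vision, Chebyshev
#' distance < \code{vision} -- and otherwise roams one random king move over
#' the whole world.
#'
#' @param pred,agent positions as c(x, y), 0-based.
#' @param camouflaged is the agent hidden this hour?
#' @param width,height world dimensions.
#' @param vision exclusive vision threshold (default 4: pursues at
#'   distance <= 3).
#' @return new predator position c(x, y).
#' @export
predatorStep <- function(pred, agent, camouflaged, width, height,
                         vision = 4L) {
  if (!camouflaged && chebyshevDistance(pred, agent) < vision)
    stepToward(pred, agent)
  else
    roamStep(pred, width, height)
}

#' Region partition of a grid into square blocks
#'
#' The predator-prey world is a 12x12 grid tiled by nine 4x4 regions
#' numbered row-major 0-8 (region 1 top-middle, region 6 bottom-left,
#' region 8 bottom-right).
#'
#' @param x,y 0-based coordinates (vectors recycle).
#' @param width grid width.
#' @param blockSize side length of a square region block.
#' @return 0-based region id(s).
#' @examples
#' regionOfCell(0, 8)   # 6
#' regionOfCell(11, 11) # 8
#' @export
regionOfCell <- function(x, y, width = 12L, blockSize = 4L) {
  perRow <- as.integer(width) %/% as.integer(blockSize)
  (as.integer(y) %/% as.integer(blockSize)) * perRow +
    (as.integer(x) %/% as.integer(blockSize))
}

.checkRegion <- function(region, width, height, blockSize) {
  nReg <- (as.integer(width) %/% blockSize) * (as.integer(height) %/% blockSize)
  if (length(region) != 1L || is.na(region) || region < 0L || region >= nReg)
    stop("region ", region, " does not exist (grid has ", nReg, " regions)",
         call. = FALSE)
  invisible(nReg)
}

#' @describeIn regionOfCell bounding box c(xmin, xmax, ymin, ymax) of a
#'   region (0-based, inclusive).
#' @param region 0-based region id.
#' @param height grid height.
#' @export
regionBounds <- function(region, width = 12L, height = 12L, blockSize = 4L) {
  .checkRegion(region, width, height, blockSize)
  region <- as.integer(region)
  blockSize <- as.integer(blockSize)
  perRow <- as.integer(width) %/% blockSize
  bx <- (region %% perRow) * blockSize
  by <- (region %/% perRow) * blockSize
  c(bx, bx + blockSize - 1L, by, by + blockSize - 1L)
}

#' @describeIn regionOfCell 1-based flat cell indices of a region, for use
#'   as the \code{where} set of [queryMemory()].
#' @export
regionCells <- function(region, width = 12L, height = 12L, blockSize = 4L) {
  b <- regionBounds(region, width, height, blockSize)
  xs <- b[1L]:b[2L]
  ys <- b[3L]:b[4L]
  as.integer(outer(xs, ys, function(x, y) cellIndex(x, y, width)))
}

#' @describeIn regionOfCell the fixed "center" cell of a region: the
#'   upper-left of the four central candidates of a 4x4 block,
#'   (xmin + 1, ymin + 1).
#' @export
regionCenter <- function(region, width = 12L, height = 12L, blockSize = 4L) {
  b <- regionBounds(region, width, height, blockSize)
  c(b[1L] + 1L, b[3L] + 1L)
}

#' Place scheduled creatures for one hour
#'
#' A schedule is a list of entries, each
#' \code{list(kind =, hours =, rule =)} where \code{hours} is the 0-based
#' set of hours the creature is available and \code{rule} is one of
#' \code{list(type = "fixed", cell = c(x, y))},
#' \code{list(type = "region", region = r)} (uniform over the region's
#' cells) or \code{list(type = "halfplane", xmax = m)} (uniform over cells
#' with x < m).  Placements are drawn once at the start of the hour; prey
#' then stay stationary for the whole hour.
#'
#' @param schedule list of schedule entries (see [elmSchedule()],
#'   [ppSchedule()]).
#' @param hour 0-based hour of the day.
#' @param width,height world dimensions.
#' @param blockSize region block size (for region rules).
#' @return named list mapping each available kind to its position c(x, y);
#'   kinds not available this hour are omitted.
#' @export
placeForHour <- function(schedule, hour, width, height, blockSize = 4L) {
  out <- list()
  for (entry in schedule) {
    if (!(hour %in% entry$hours)) next
    rule <- entry$rule
    pos <- switch(rule$type,
      fixed = as.integer(rule$cell),
      region = {
        b <- regionBounds(rule$region, width, height, blockSize)
        c(b[1L] + sample.int(b[2L] - b[1L] + 1L, 1L) - 1L,
          b[3L] + sample.int(b[4L] - b[3L] + 1L, 1L) - 1L)
      },
      halfplane = c(sample.int(rule$xmax, 1L) - 1L,
                    sample.int(height, 1L) - 1L),
      stop("unknown placement rule type: ", rule$type, call. = FALSE))
    out[[entry$kind]] <- pos
  }
  out
}

#' Creature schedule for the delayed-reward scenario
#'
#' Crab at its fixed cell every hour; shrimp at its fixed cell every hour in
#' phase 1 but only the final hour of the day in phase 2.
#'
#' @param config an [elmConfig()].
#' @param phase 1 or 2.
#' @return schedule list for [placeForHour()].
#' @export
elmSchedule <- function(config, phase) {
  allHours <- 0:(config$hours_per_day - 1L)
  shrimpHours <- if (phase == 1L) allHours else config$hours_per_day - 1L
  list(
    list(kind = "crab", hours = allHours,
         rule = list(type = "fixed", cell = config$crab_cell)),
    list(kind = "shrimp", hours = shrimpHours,
         rule = list(type = "fixed", cell = config$shrimp_cell))
  )
}

#' Creature schedule for the predator-prey scenario
#'
#' Crab uniform in its region all day; shrimp uniform in its region during
#' its hours; predator uniform over the left half-plane (x < 6) during its
#' hours.
#'
#' @param config a [ppConfig()].
#' @return schedule list for [placeForHour()].
#' @export
ppSchedule <- function(config) {
  list(
    list(kind = "crab", hours = config$crab_hours,
         rule = list(type = "region", region = config$crab_region)),
    list(kind = "shrimp", hours = config$shrimp_hours,
         rule = list(type = "region", region = config$shrimp_region)),
    list(kind = "predator", hours = config$predator_hours,
         rule = list(type = "halfplane", xmax = config$predator_xmax))
  )
}
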