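#' Configuration for the delayed-reward (episodic-like memory) scenario
#'
#' Defaults are the published scenario parameters: an 8x8 grid, 3-hour days
#' of 100 steps, 100 days split into a 50-day phase 1 (shrimp available
#' every hour) and phase 2 (shrimp only the final hour), crab reward 1 at
#' (7,0), shrimp reward 4 at (7,7), roam value 0.5, alpha = 0.10,
#' beta = 1.0, agent vision < 2, 100 runs.
#'
#' @param ... overrides for any field (e.g. \code{days = 10, runs = 5}).
#' @return a validated config (list with class \code{"elm_config"}).
#' @examples
#' cfg <- elmConfig(days = 4, runs = 2)
#' @export
elmConfig <- function(...) {
  cfg <- list(
    scenario = "elm",
    width = 8L, height = 8L,
    days = 100L, hours_per_day = 3L, steps_per_hour = 100L,
    phase1_days = 50L,
    agent_start = c(0L, 4L),
    crab_cell = c(7L, 0L), crab_reward = 1.0,
    shrimp_cell = c(7L, 7L), shrimp_reward = 4.0,
    roam_value = 0.5,
    alpha = 0.10, beta = 1.0,
    agent_vision = 2L,
    runs = 100L
  )
  cfg <- .applyOverrides(cfg, list(...))
  .validateConfig(cfg)
}

#' Configuration for the predator-prey scenario
#'
#' Defaults are the published scenario parameters: a 12x12 grid of nine 4x4
#' regions, 6-hour days of 100 steps over 200 days; crab (reward 1) in
#' region 8 all day, shrimp (reward 4) in region 6 hours 2-5, predator
#' (penalty 8, stored as reward -8) in the left half (x < 6) hours 1-3;
#' roam value 0.5, alpha = 0.10, beta = 1.0, agent vision < 2, predator
#' vision < 4, 100 runs.
#'
#' @param query_mode \code{"what_when"} (actions hunt crab / hunt shrimp /
#'   hide / roam from per-object value sums) or \code{"when_where"}
#'   (actions go-to-region 0..8 / roam from per-region value sums).
#' @param ... overrides for any field.
#' @return a validated config (list with class \code{"pp_config"}).
#' @examples
#' cfg <- ppConfig("what_when", days = 5, runs = 2)
#' @export
ppConfig <- function(query_mode = c("what_when", "when_where"), ...) {
  query_mode <- match.arg(query_mode)
  cfg <- list(
    scenario = "pp",
    query_mode = query_mode,
    width = 12L, height = 12L, block_size = 4L,
    days = 200L, hours_per_day = 6L, steps_per_hour = 100L,
    agent_start = c(6L, 0L),
    crab_hours = 0:5, crab_region = 8L, crab_reward = 1.0,
    shrimp_hours = 2:5, shrimp_region = 6L, shrimp_reward = 4.0,
    predator_hours = 1:3, predator_xmax = 6L, predator_penalty = 8.0,
    roam_value = 0.5,
    alpha = 0.10, beta = 1.0,
    agent_vision = 2L, predator_vision = 4L,
    runs = 100L
  )
  cfg <- .applyOverrides(cfg, list(...))
  .validateConfig(cfg)
}

.applyOverrides <- function(cfg, dots) {
  if (length(dots) == 0L) return(cfg)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  cfg
}

.INT_FIELDS <- c("width", "height", "block_size", "days", "hours_per_day",
                 "steps_per_hour", "phase1_days", "agent_start", "crab_cell",
                 "shrimp_cell", "crab_hours", "shrimp_hours",
                 "predator_hours", "crab_region", "shrimp_region",
                 "predator_xmax", "agent_vision", "predator_vision", "runs")
.NUM_FIELDS <- c("alpha", "beta", "roam_value", "crab_reward",
                 "shrimp_reward", "predator_penalty")

.validateConfig <- function(cfg) {
  for (f in intersect(.INT_FIELDS, names(cfg))) cfg[[f]] <- as.integer(cfg[[f]])
  for (f in intersect(.NUM_FIELDS, names(cfg))) cfg[[f]] <- as.numeric(cfg[[f]])

  .fail <- function(field, why)
    stop("invalid config field '", field, "': ", why, call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha > 1) .fail("alpha", "must be in (0, 1]")
  if (cfg$beta < 0 || !is.finite(cfg$beta)) .fail("beta", "must be >= 0")
  if (cfg$width < 1L || cfg$height < 1L) .fail("width", "grid must be positive")
  if (cfg$days < 1L) .fail("days", "must be >= 1")
  if (cfg$hours_per_day < 1L) .fail("hours_per_day", "must be >= 1")
  if (cfg$steps_per_hour < 1L) .fail("steps_per_hour", "must be >= 1")
  if (cfg$runs < 1L) .fail("runs", "must be >= 1")
  inGrid <- function(p) length(p) == 2L && all(p >= 0L) &&
    p[1L] < cfg$width && p[2L] < cfg$height
  if (!inGrid(cfg$agent_start)) .fail("agent_start", "outside the grid")

  if (cfg$scenario == "elm") {
    if (cfg$phase1_days < 1L || cfg$phase1_days >= cfg$days)
      .fail("phase1_days", "must be in [1, days)")
    if (!inGrid(cfg$crab_cell)) .fail("crab_cell", "outside the grid")
    if (!inGrid(cfg$shrimp_cell)) .fail("shrimp_cell", "outside the grid")
    class(cfg) <- c("elm_config", "cuttle_config", "list")
  } else if (cfg$scenario == "pp") {
    if (cfg$width %% cfg$block_size != 0L || cfg$height %% cfg$block_size != 0L)
      .fail("block_size", "must tile the grid exactly")
    nReg <- (cfg$width %/% cfg$block_size) * (cfg$height %/% cfg$block_size)
    for (f in c("crab_region", "shrimp_region"))
      if (cfg[[f]] < 0L || cfg[[f]] >= nReg) .fail(f, "region does not exist")
    if (cfg$predator_xmax < 1L || cfg$predator_xmax > cfg$width)
      .fail("predator_xmax", "must be in [1, width]")
    hourOk <- function(h) all(h >= 0L & h < cfg$hours_per_day)
    for (f in c("crab_hours", "shrimp_hours", "predator_hours"))
      if (!hourOk(cfg[[f]])) .fail(f, "hours must be in [0, hours_per_day)")
    if (!cfg$query_mode %in% c("what_when", "when_where"))
      .fail("query_mode", "must be what_when or when_where")
    class(cfg) <- c("pp_config", "cuttle_config", "list")
  } else {
    .fail("scenario", "must be 'elm' or 'pp'")
  }
  cfg
}

#' @export
print.cuttle_config <- function(x, ...) {
  cat("<", class(x)[1L], ">\n", sep = "")
  flat <- vapply(unclass(x), function(v) paste(v, collapse = ","), "")
  cat(paste0("  ", format(names(flat)), " = ", flat, collapse = "\n"), "\n")
  invisible(x)
}

#' Read a scenario configuration from a YAML file
#'
#' The file is a flat key-value mapping mirroring the scenario parameter
#' tables; it must declare \code{scenario: elm} or \code{scenario: pp}.
#' Missing fields take the scenario defaults; unknown keys and out-of-range
#' values are rejected with the offending field named.
#'
#' @param path path to a YAML config file.
#' @return an [elmConfig()] or [ppConfig()] object.
#' @seealso [writeConfig()]
#' @export
parseConfig <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$scenario))
    stop("config must declare 'scenario: elm' or 'scenario: pp'",
         call. = FALSE)
  scen <- raw$scenario
  raw$scenario <- NULL
  if (identical(scen, "elm")) {
    do.call(elmConfig, raw)
  } else if (identical(scen, "pp")) {
    qm <- raw$query_mode
    raw$query_mode <- NULL
    if (is.null(qm)) do.call(ppConfig, raw)
    else do.call(ppConfig, c(list(query_mode = qm), raw))
  } else {
    stop("invalid config field 'scenario': must be 'elm' or 'pp'",
         call. = FALSE)
  }
}

#' Write a scenario configuration to a YAML file
#'
#' @param config an [elmConfig()] or [ppConfig()].
#' @param path output path.
#' @return \code{path}, invisibly.  \code{parseConfig(writeConfig(cfg))}
#'   reproduces \code{cfg} exactly.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Derive per-run seeds from one base seed
#'
#' A deterministic, collision-free sequence: base, base + 1, ...  Each run
#' seeds R's RNG once with its own seed, so runs are independent of how many
#' others execute before them.
#'
#' @param base_seed single integer.
#' @param runs number of runs (>= 1).
#' @return integer vector of length \code{runs}, all distinct.
#' @export
deriveSeeds <- function(base_seed, runs) {
  stopifnot(length(base_seed) == 1L, is.finite(base_seed), runs >= 1L)
  as.integer(base_seed) + seq_len(as.integer(runs)) - 1L
}
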