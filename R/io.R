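.sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path),
                                      ".json")

#' Write a memory tensor to CSV (with a JSON sidecar)
#'
#' The dump is a flat table with columns what_label, when (0-based hour),
#' where_x, where_y, value; values are printed with 17 significant digits
#' so the round trip through [readMemory()] is bit-exact.  A JSON sidecar
#' (same path with extension .json) records the shape, learning rate and
#' object labels.
#'
#' @param mem an [EpisodicMemory-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeMemory <- function(mem, path) {
  v <- memValues(mem)
  d <- dim(v)
  labs <- dimnames(v)[[1L]]
  xy <- cellCoords(seq_len(d[3L]), gridWidth(mem))
  df <- data.frame(
    what_label = rep(labs, times = d[2L] * d[3L]),
    when = rep(seq_len(d[2L]) - 1L, each = d[1L], times = d[3L]),
    where_x = rep(xy[, "x"], each = d[1L] * d[2L]),
    where_y = rep(xy[, "y"], each = d[1L] * d[2L]),
    value = sprintf("%.17g", as.vector(v)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(what_labels = labs, n_when = d[2L], width = gridWidth(mem),
               height = gridHeight(mem), alpha = learningRate(mem))
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a memory tensor written by [writeMemory()]
#'
#' @param path CSV path (the sidecar is found next to it).
#' @return an [EpisodicMemory-class] identical to the one written.
#' @export
readMemory <- function(path) {
  meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(what_label = "character",
                                       when = "integer",
                                       where_x = "integer",
                                       where_y = "integer",
                                       value = "character"))
  mem <- episodicMemory(meta$what_labels, meta$n_when, meta$width,
                        meta$height, meta$alpha)
  v <- mem@values
  iWhat <- match(df$what_label, meta$what_labels)
  if (anyNA(iWhat))
    stop("memory dump contains unknown object labels", call. = FALSE)
  v[cbind(iWhat, df$when + 1L,
          cellIndex(df$where_x, df$where_y, meta$width))] <-
    as.numeric(df$value)
  mem@values <- v
  validObject(mem)
  mem
}

.RECORD_SCHEMAS <- list(
  elm = c(run = "integer", day = "integer", hour = "integer",
          phase = "integer", action = "character", eaten = "character",
          delay_hours = "integer"),
  pp = c(run = "integer", day = "integer", hour = "integer",
         action = "character", outcome = "character",
         end_region = "integer")
)

#' Write hour records to CSV
#'
#' @param records a records data.frame from [runElm()] or [runPp()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.  Output is byte-deterministic for a
#'   given records table.
#' @export
writeRecords <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read hour records written by [writeRecords()]
#'
#' The header must carry all columns of one scenario's record schema;
#' otherwise a format error names the missing column(s).
#'
#' @param path CSV path.
#' @return records data.frame, field-for-field equal to what was written.
#' @export
readRecords <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  schema <- NULL
  for (s in .RECORD_SCHEMAS)
    if (all(names(s) %in% header)) { schema <- s; break }
  if (is.null(schema)) {
    missing <- lapply(.RECORD_SCHEMAS, function(s)
      setdiff(names(s), header))
    best <- which.min(lengths(missing))
    stop("record file ", path, ", line 1: missing column(s) ",
         paste(missing[[best]], collapse = ", "), call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = schema)
}

#' Write a run manifest
#'
#' A JSON snapshot that makes a batch reproducible: the full configuration,
#' base and per-run seeds, and the output files with md5 checksums.
#'
#' @param path output JSON path.
#' @param config the scenario config used.
#' @param base_seed base seed passed to the run function.
#' @param seeds per-run seeds ([deriveSeeds()]).
#' @param files character vector of produced files (checksummed).
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(path, config, base_seed, seeds, files = character()) {
  sums <- if (length(files)) as.list(tools::md5sum(files)) else NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("cuttlemem")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = unclass(config),
    base_seed = base_seed,
    seeds = seeds,
    files = sums)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
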