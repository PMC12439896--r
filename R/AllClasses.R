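#' @import methods
NULL

#' EpisodicMemory: a what x when x where expected-value tensor
#'
#' The core memory structure: a dense 3-D array of expected reward values
#' indexed by object identity ("what"), hour of the simulated day ("when")
#' and grid cell ("where", stored flat in row-major order, cell =
#' y * width + x with 0-based coordinates).  A freshly constructed memory is
#' all zeros; entries change only through [deltaUpdate()], which applies the
#' Rescorla-Wagner delta rule with the memory's learning rate.
#'
#' @slot values 3-D numeric array \code{[what, when, where]}; the first
#'   dimension carries the object labels as dimnames.
#' @slot alpha learning rate in (0, 1].
#' @slot width,height grid dimensions used to map the flat where index back
#'   to (x, y) coordinates.
#'
#' @seealso [episodicMemory()], [queryMemory()], [deltaUpdate()],
#'   [mttTable()]
#' @export
setClass("EpisodicMemory",
  representation(
    values = "array",
    alpha  = "numeric",
    width  = "integer",
    height = "integer"
  )
)

setValidity("EpisodicMemory", function(object) {
  v <- object@values
  msgs <- character()
  if (length(dim(v)) != 3L)
    msgs <- c(msgs, "values must be a 3-D array [what, when, where]")
  else {
    if (dim(v)[3L] != object@width * object@height)
      msgs <- c(msgs, "third dimension must equal width * height")
    if (is.null(dimnames(v)[[1L]]))
      msgs <- c(msgs, "first dimension must carry object labels")
  }
  if (!all(is.finite(v)))
    msgs <- c(msgs, "all entries must be finite")
  if (length(object@alpha) != 1L || !is.finite(object@alpha) ||
      object@alpha <= 0 || object@alpha > 1)
    msgs <- c(msgs, "alpha must be a single value in (0, 1]")
  if (object@width < 1L || object@height < 1L)
    msgs <- c(msgs, "width and height must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct an empty episodic memory
#'
#' All entries are initialized to exactly 0.0: the agent starts with no
#' expectations and acquires them only through delta-rule updates.
#'
#' @param whatLabels character vector of object labels (e.g.
#'   \code{c("crab", "shrimp")}).
#' @param nWhen number of hours in the simulated day.
#' @param width,height grid dimensions; the where dimension has
#'   \code{width * height} cells.
#' @param alpha learning rate in (0, 1].
#' @return An [EpisodicMemory-class] object.
#' @examples
#' mem <- episodicMemory(c("crab", "shrimp"), nWhen = 3, width = 8, height = 8)
#' nWhere(mem)
#' @export
episodicMemory <- function(whatLabels, nWhen, width, height, alpha = 0.10) {
  stopifnot(is.character(whatLabels), length(whatLabels) >= 1L,
            !anyDuplicated(whatLabels))
  nWhen <- as.integer(nWhen)
  width <- as.integer(width)
  height <- as.integer(height)
  v <- array(0, dim = c(length(whatLabels), nWhen, width * height),
             dimnames = list(whatLabels, NULL, NULL))
  new("EpisodicMemory", values = v, alpha = as.numeric(alpha),
      width = width, height = height)
}

#' @describeIn episodicMemory the raw value tensor (3-D array).
#' @param mem an EpisodicMemory.
#' @export
memValues <- function(mem) mem@values

#' @describeIn episodicMemory learning rate alpha.
#' @export
learningRate <- function(mem) mem@alpha

#' @describeIn episodicMemory object labels of the what dimension.
#' @export
whatLabels <- function(mem) dimnames(mem@values)[[1L]]

#' @describeIn episodicMemory number of objects.
#' @export
nWhat <- function(mem) dim(mem@values)[1L]

#' @describeIn episodicMemory number of hours.
#' @export
nWhen <- function(mem) dim(mem@values)[2L]

#' @describeIn episodicMemory number of grid cells.
#' @export
nWhere <- function(mem) dim(mem@values)[3L]

#' @describeIn episodicMemory grid width.
#' @export
gridWidth <- function(mem) mem@width

#' @describeIn episodicMemory grid height.
#' @export
gridHeight <- function(mem) mem@height

setMethod("show", "EpisodicMemory", function(object) {
  d <- dim(object@values)
  nz <- sum(object@values != 0)
  cat("EpisodicMemory: ", d[1L], " what x ", d[2L], " when x ", d[3L],
      " where (", object@width, "x", object@height, " grid)\n", sep = "")
  cat("  objects: ", paste(dimnames(object@values)[[1L]], collapse = ", "),
      "\n", sep = "")
  cat("  alpha: ", object@alpha, "; non-zero entries: ", nz, "/",
      length(object@values), "\n", sep = "")
  if (nz > 0) {
    rng <- range(object@values)
    cat("  value range: [", format(rng[1L]), ", ", format(rng[2L]), "]\n",
        sep = "")
  }
  invisible(NULL)
})

#' Flat cell index from grid coordinates
#'
#' Cells are stored row-major: \code{cell = y * width + x} with 0-based
#' \code{x} (column) and \code{y} (row), origin top-left.  The returned index
#' is 1-based for use with [queryMemory()] and [deltaUpdate()].
#'
#' @param x,y 0-based coordinates (vectors recycle).
#' @param width grid width.
#' @return integer vector of 1-based flat cell indices.
#' @examples
#' cellIndex(7, 7, width = 8)  # 64
#' @export
cellIndex <- function(x, y, width) as.integer(y) * as.integer(width) +
  as.integer(x) + 1L

#' Grid coordinates from a flat cell index
#'
#' Inverse of [cellIndex()].
#'
#' @param cell 1-based flat cell index.
#' @param width grid width.
#' @return matrix with columns \code{x}, \code{y} (0-based).
#' @export
cellCoords <- function(cell, width) {
  cell0 <- as.integer(cell) - 1L
  cbind(x = cell0 %% as.integer(width), y = cell0 %/% as.integer(width))
}
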