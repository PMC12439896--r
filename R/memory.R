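#' Query the episodic memory with a partial index
#'
#' A query binds any subset of the three dimensions and either gathers the
#' remaining entries (\code{reduction = "none"}) or collapses them to a
#' scalar with \code{max}, \code{sum} or \code{mean}.  This is the
#' content-addressable read-out used by both scenarios: e.g. binding
#' what = "shrimp" and one hour returns the expected value of shrimp at
#' every location for that hour.  The memory is never modified by a query.
#'
#' @param mem an [EpisodicMemory-class].
#' @param what object label or 1-based index, or NULL to leave unbound.
#' @param when 1-based hour index (hour h of the 0-based day narrative is
#'   index h + 1), or NULL.
#' @param where 1-based flat cell index or a vector of them (e.g. one
#'   region's cells from [regionCells()]), or NULL for all cells.
#' @param reduction one of "none", "max", "sum", "mean".  With "none",
#'   exactly one dimension must be unbound and a named value vector over it
#'   is returned; otherwise all selected entries are reduced to one number.
#' @return named numeric vector (reduction "none") or a single number.
#' @examples
#' mem <- episodicMemory(c("crab", "shrimp"), 3, 8, 8)
#' queryMemory(mem, what = "shrimp", when = 3)            # 64 zeros
#' queryMemory(mem, what = "shrimp", when = 3, reduction = "max")
#' @export
setGeneric("queryMemory", function(mem, what = NULL, when = NULL,
                                   where = NULL,
                                   reduction = c("none", "max", "sum", "mean"))
  standardGeneric("queryMemory"))

#' @rdname queryMemory
setMethod("queryMemory", "EpisodicMemory",
  function(mem, what = NULL, when = NULL, where = NULL,
           reduction = c("none", "max", "sum", "mean")) {
    reduction <- match.arg(reduction)
    d <- dim(mem@values)
    labs <- dimnames(mem@values)[[1L]]

    iWhat <- .resolveWhat(what, labs)
    iWhen <- .checkIndex(when, d[2L], "when")
    iWhere <- .checkIndex(where, d[3L], "where", allow_multi = TRUE)
    if (!is.null(where) && length(iWhere) == 0L)
      stop("empty cell set in 'where'", call. = FALSE)

    selWhat <- if (is.null(iWhat)) seq_len(d[1L]) else iWhat
    selWhen <- if (is.null(iWhen)) seq_len(d[2L]) else iWhen
    selWhere <- if (is.null(iWhere)) seq_len(d[3L]) else iWhere
    sub <- mem@values[selWhat, selWhen, selWhere, drop = FALSE]

    if (reduction == "none") {
      unbound <- c(is.null(iWhat), is.null(iWhen),
                   is.null(iWhere) || length(iWhere) > 1L)
      if (sum(unbound) != 1L)
        stop("reduction = \"none\" requires exactly one unbound dimension",
             call. = FALSE)
      out <- as.vector(sub)
      names(out) <- if (unbound[1L]) labs
        else if (unbound[2L]) as.character(seq_len(d[2L]) - 1L)
        else {
          xy <- cellCoords(selWhere, mem@width)
          paste0(xy[, "x"], ",", xy[, "y"])
        }
      return(out)
    }
    switch(reduction,
           max = max(sub), sum = sum(sub), mean = mean(sub))
  })

.resolveWhat <- function(what, labs) {
  if (is.null(what)) return(NULL)
  if (is.character(what)) {
    i <- match(what, labs)
    if (anyNA(i))
      stop("unknown 'what' label: ", paste(what[is.na(i)], collapse = ", "),
           call. = FALSE)
    return(i)
  }
  .checkIndex(what, length(labs), "what")
}

.checkIndex <- function(i, n, dimname, allow_multi = FALSE) {
  if (is.null(i)) return(NULL)
  i <- as.integer(i)
  if (!allow_multi && length(i) != 1L)
    stop("'", dimname, "' must be a single index", call. = FALSE)
  bad <- i < 1L | i > n
  if (any(bad))
    stop("'", dimname, "' index ", paste(i[bad], collapse = ", "),
         " out of range [1, ", n, "]", call. = FALSE)
  i
}

#' Delta-rule (Rescorla-Wagner) update of one memory entry
#'
#' Moves the stored expected value at (what, when, where) toward the
#' received reward \code{r}: entry <- entry + alpha * (r - entry), where
#' alpha is the memory's learning rate.  With r = 0 this is the extinction
#' update that decays a stale expectation.  All other entries are untouched.
#' The updated memory object is returned (R copy-on-modify semantics); read
#' the new entry back with [queryMemory()].
#'
#' @param mem an [EpisodicMemory-class].
#' @param what object label or 1-based index.
#' @param when 1-based hour index.
#' @param where 1-based flat cell index.
#' @param r reward (or penalty, as a negative value), finite.
#' @return the updated EpisodicMemory.
#' @examples
#' mem <- episodicMemory(c("crab", "shrimp"), 3, 8, 8, alpha = 0.10)
#' mem <- deltaUpdate(mem, "shrimp", 3, cellIndex(7, 7, 8), r = 4)
#' queryMemory(mem, "shrimp", 3, cellIndex(7, 7, 8), reduction = "sum")  # 0.4
#' @export
setGeneric("deltaUpdate", function(mem, what, when, where, r)
  standardGeneric("deltaUpdate"))

#' @rdname deltaUpdate
setMethod("deltaUpdate", "EpisodicMemory", function(mem, what, when, where, r) {
  labs <- dimnames(mem@values)[[1L]]
  d <- dim(mem@values)
  iWhat <- .resolveWhat(what, labs)
  iWhen <- .checkIndex(when, d[2L], "when")
  iWhere <- .checkIndex(where, d[3L], "where")
  if (is.null(iWhat) || is.null(iWhen) || is.null(iWhere))
    stop("deltaUpdate requires all three indices", call. = FALSE)
  if (length(r) != 1L || !is.finite(r))
    stop("'r' must be a single finite number", call. = FALSE)
  old <- mem@values[iWhat, iWhen, iWhere]
  mem@values[iWhat, iWhen, iWhere] <- old + mem@alpha * (r - old)
  mem
})

#' Softmax (Boltzmann) action probabilities
#'
#' p_i = exp(beta * v_i) / sum_j exp(beta * v_j), computed with a max-shift
#' so large values cannot overflow.  beta is the inverse temperature:
#' beta = 0 gives the uniform distribution, large beta approaches argmax.
#'
#' @param vals numeric vector of action values, finite, non-empty.
#' @param beta inverse temperature, finite and >= 0.
#' @return probability vector of the same length (and names), summing to 1.
#' @examples
#' softmaxProbabilities(c(1, 0), beta = 1)  # ~ c(0.731, 0.269)
#' @export
softmaxProbabilities <- function(vals, beta = 1) {
  if (length(vals) == 0L)
    stop("'vals' must be non-empty", call. = FALSE)
  if (!all(is.finite(vals)) || length(beta) != 1L || !is.finite(beta) ||
      beta < 0)
    stop("'vals' must be finite and 'beta' a single finite value >= 0",
         call. = FALSE)
  z <- beta * vals
  e <- exp(z - max(z))
  e / sum(e)
}

#' Sample an action index from a probability vector
#'
#' Draws one index i with probability probs[i] from R's global RNG stream,
#' so the draw is reproducible under set.seed().
#'
#' @param probs probability vector: non-negative, summing to 1 within
#'   \code{tol}.
#' @param tol tolerance on the sum (default 1e-6).
#' @return a single 1-based index.
#' @export
selectAction <- function(probs, tol = 1e-6) {
  if (length(probs) == 0L || !all(is.finite(probs)) || any(probs < 0))
    stop("'probs' must be non-negative and finite", call. = FALSE)
  if (abs(sum(probs) - 1) > tol)
    stop("'probs' must sum to 1 (got ", format(sum(probs)), ")",
         call. = FALSE)
  sample.int(length(probs), 1L, prob = probs)
}
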