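#' Construct a ResponseMatrix
#'
#' Validates and wraps an N x J matrix (or data.frame) of integer response
#' levels.
#'
#' @param values numeric matrix or data.frame of integer levels, persons in
#'   rows, items in columns.
#' @param levelMin,levelMax admissible level range (defaults 1 and 5).
#' @param itemLabels optional item names; defaults to existing column names
#'   or `item1 ... itemJ`.
#' @param groupInfo optional `data.frame` of per-person grouping columns.
#' @return a [ResponseMatrix-class].
#' @examples
#' m <- ResponseMatrix(rbind(c(1, 1, 1, 2, 1), c(5, 5, 5, 5, 5)),
#'                     itemLabels = c("MO", "SC", "UA", "PD", "AD"))
#' levelSumScore(m)
#' @export
ResponseMatrix <- function(values, levelMin = 1L, levelMax = 5L,
                           itemLabels = NULL, groupInfo = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (!is.null(itemLabels)) colnames(values) <- itemLabels
  if (is.null(colnames(values)))
    colnames(values) <- paste0("item", seq_len(ncol(values)))
  new("ResponseMatrix", values = values,
      levelMin = as.integer(levelMin), levelMax = as.integer(levelMax),
      groupInfo = groupInfo)
}

#' @rdname ResponseMatrix
#' @export
setMethod("responseValues", "ResponseMatrix", function(object) object@values)

#' @rdname ResponseMatrix
#' @export
setMethod("nPersons", "ResponseMatrix", function(object) nrow(object@values))

#' @rdname ResponseMatrix
#' @export
setMethod("nItems", "ResponseMatrix", function(object) ncol(object@values))

#' @rdname ResponseMatrix
#' @export
setMethod("itemLabels", "ResponseMatrix",
          function(object) colnames(object@values))

#' @rdname ResponseMatrix
#' @export
setMethod("levelBounds", "ResponseMatrix",
          function(object) c(min = object@levelMin, max = object@levelMax))

#' @rdname ResponseMatrix
#' @export
setMethod("groupInfo", "ResponseMatrix", function(object) object@groupInfo)

setMethod("dim", "ResponseMatrix", function(x) dim(x@values))

setMethod("show", "ResponseMatrix", function(object) {
  cat(sprintf("ResponseMatrix: %d persons x %d items, levels %d-%d\n",
              nrow(object@values), ncol(object@values),
              object@levelMin, object@levelMax))
  cat("items:", paste(colnames(object@values), collapse = ", "), "\n")
  lss <- rowSums(object@values)
  cat(sprintf("level sum score: range %d-%d, mean %.2f\n",
              min(lss), max(lss), mean(lss)))
  if (!is.null(object@groupInfo))
    cat("grouping columns:", paste(names(object@groupInfo), collapse = ", "),
        "\n")
})

#' Subset persons and/or items
#'
#' Returns a new [ResponseMatrix-class]; at least two items must remain.
#'
#' @param x a [ResponseMatrix-class].
#' @param i person indices; @param j item labels or indices.
#' @param ... ignored. @param drop ignored (never drops dimensions).
#' @export
setMethod("[", "ResponseMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  gi <- x@groupInfo
  if (!is.null(gi) && !missing(i)) gi <- gi[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  new("ResponseMatrix", values = v, levelMin = x@levelMin,
      levelMax = x@levelMax, groupInfo = gi)
})

#' Drop items from a response matrix
#'
#' Generic item-exclusion re-runs (e.g. the scale without the
#' anxiety/depression item) operate on the matrix returned here.
#'
#' @param m a [ResponseMatrix-class].
#' @param items labels or indices of items to remove.
#' @return a [ResponseMatrix-class] without those items.
#' @export
dropItems <- function(m, items) {
  idx <- resolveItems(m, items)
  keep <- setdiff(seq_len(nItems(m)), idx)
  if (length(keep) < 2L)
    stop("dropping ", length(idx), " item(s) would leave fewer than 2 items")
  m[, keep]
}

#' Transpose a response matrix (persons become items)
#'
#' The HT coefficient is the scale scalability of this transposed matrix.
#' Persons with zero response variance (constant patterns) carry no ordering
#' information and are removed first; the number removed is reported via
#' `message()`.
#'
#' @param m a [ResponseMatrix-class].
#' @param removeConstant drop constant-pattern persons first (default TRUE).
#' @return a [ResponseMatrix-class] with J rows and one column per retained
#'   person.
#' @export
transposeResponses <- function(m, removeConstant = TRUE) {
  v <- responseValues(m)
  if (removeConstant) {
    keep <- apply(v, 1L, function(r) length(unique(r)) > 1L)
    if (any(!keep))
      message(sum(!keep), " constant-pattern person(s) removed before transposition")
    v <- v[keep, , drop = FALSE]
  }
  if (nrow(v) < 2L)
    stop("fewer than 2 non-constant persons; transposed scalability undefined")
  tv <- t(v)
  colnames(tv) <- paste0("person", seq_len(ncol(tv)))
  ResponseMatrix(tv, levelMin = m@levelMin, levelMax = m@levelMax)
}

#' @rdname levelSumScore
#' @export
setMethod("levelSumScore", "ResponseMatrix",
          function(m) as.integer(rowSums(m@values)))

#' @rdname restScores
#' @export
setMethod("restScores", "ResponseMatrix", function(m, excludeItems) {
  idx <- resolveItems(m, excludeItems)
  if (length(idx) == 0L) stop("excludeItems must name at least one item")
  if (length(idx) >= nItems(m))
    stop("cannot exclude all items: the rest set would be empty")
  as.integer(rowSums(m@values) - rowSums(m@values[, idx, drop = FALSE]))
})

## Map labels or indices onto validated item indices.
resolveItems <- function(m, items) {
  labs <- itemLabels(m)
  if (is.character(items)) {
    idx <- match(items, labs)
    if (anyNA(idx))
      stop("unknown item(s): ", paste(items[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(items)
    if (any(idx < 1L | idx > length(labs)))
      stop("item index out of range 1..", length(labs))
  }
  unique(idx)
}
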