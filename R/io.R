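#' Read ordinal responses from delimited text
#'
#' Reads a CSV/TSV file with a header row, validates the item columns as
#' integer levels within bounds, and returns a [ResponseMatrix-class].
#' Missing item responses are handled per `missing`: `"listwise"` (default)
#' drops affected persons and reports the count, `"fail"` raises an error.
#'
#' @param path file path (delimiter auto-detected by [data.table::fread()]
#'   unless `sep` is given).
#' @param itemColumns character vector of item column names (required).
#' @param groupColumns optional character vector of grouping column names.
#' @param levelMin,levelMax admissible level bounds.
#' @param missing missing-data policy, `"listwise"` or `"fail"`.
#' @param sep optional delimiter override.
#' @return a [ResponseMatrix-class] (with `groupInfo` when `groupColumns`
#'   were requested).
#' @export
readResponses <- function(path, itemColumns, groupColumns = character(0),
                          levelMin = 1L, levelMax = 5L,
                          missing = c("listwise", "fail"), sep = "auto") {
  missing <- match.arg(missing)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, na.strings = c("", "NA"))
  absent <- setdiff(c(itemColumns, groupColumns), names(dt))
  if (length(absent))
    stop("column(s) not found in ", path, ": ", paste(absent, collapse = ", "))
  vals <- dt[, itemColumns, drop = FALSE]
  for (cn in itemColumns) {
    col <- vals[[cn]]
    if (!is.numeric(col)) {
      bad <- which(!is.na(col))[1L]
      stop(sprintf("non-integer response in column '%s' (e.g. row %d: '%s')",
                   cn, bad, as.character(col[bad])))
    }
    if (any(col[!is.na(col)] != round(col[!is.na(col)]))) {
      bad <- which(!is.na(col) & col != round(col))[1L]
      stop(sprintf("non-integer response in column '%s', row %d: %g",
                   cn, bad, col[bad]))
    }
  }
  vals <- as.matrix(vals)
  incomplete <- rowSums(is.na(vals)) > 0L
  if (any(incomplete)) {
    if (missing == "fail")
      stop(sum(incomplete), " person(s) with missing item responses")
    warning(sum(incomplete),
            " person(s) dropped by listwise deletion (missing item responses)")
    vals <- vals[!incomplete, , drop = FALSE]
  }
  gi <- NULL
  if (length(groupColumns)) {
    gi <- dt[, groupColumns, drop = FALSE]
    if (any(incomplete)) gi <- gi[!incomplete, , drop = FALSE]
    gi[] <- lapply(gi, as.character)
  }
  ResponseMatrix(vals, levelMin = levelMin, levelMax = levelMax,
                 groupInfo = gi)
}

#' Write a per-person score table
#'
#' Writes person id, level sum score and the single-item rest scores as
#' tab-separated text.
#'
#' @param m a [ResponseMatrix-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeScores <- function(m, path) {
  lss <- levelSumScore(m)
  rest <- vapply(seq_len(nItems(m)), function(i) restScores(m, i),
                 integer(nPersons(m)))
  colnames(rest) <- paste0("rest_", itemLabels(m))
  out <- data.frame(person = seq_len(nPersons(m)), lss = lss, rest,
                    check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
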