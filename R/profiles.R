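#' Encode a level vector as a health profile string
#'
#' An EQ-5D-5L style health profile writes one digit per item, e.g.
#' `c(1, 1, 1, 2, 1)` becomes `"11121"` (slight problems on pain/discomfort
#' only). The codec is bijective with length-J level vectors; it requires
#' single-digit levels (`levelMax <= 9`).
#'
#' @param levels integer vector of item levels.
#' @param levelMin,levelMax admissible bounds (defaults 1 and 5).
#' @return a single profile string of `length(levels)` digits.
#' @examples
#' encodeProfile(c(1, 1, 1, 1, 1))  # "11111", LSS 5
#' encodeProfile(c(5, 5, 5, 5, 5))  # "55555", LSS 25
#' @export
encodeProfile <- function(levels, levelMin = 1L, levelMax = 5L) {
  if (levelMax > 9L) stop("profile digits require levelMax <= 9")
  if (length(levels) < 1L || anyNA(levels) || any(levels != round(levels)))
    stop("levels must be a non-empty integer vector")
  bad <- which(levels < levelMin | levels > levelMax)
  if (length(bad))
    stop(sprintf("level %g at item %d outside bounds [%d, %d]",
                 levels[bad[1L]], bad[1L], levelMin, levelMax))
  paste(as.integer(levels), collapse = "")
}

#' Decode a health profile string
#'
#' Inverse of [encodeProfile()]: `decodeProfile(encodeProfile(x)) == x`.
#'
#' @param profile a digit string, one character per item.
#' @inheritParams encodeProfile
#' @return integer vector of levels.
#' @export
decodeProfile <- function(profile, levelMin = 1L, levelMax = 5L) {
  if (length(profile) != 1L || !is.character(profile) ||
      !grepl("^[0-9]+$", profile))
    stop("profile must be a single digit string")
  levels <- as.integer(strsplit(profile, "")[[1L]])
  bad <- which(levels < levelMin | levels > levelMax)
  if (length(bad))
    stop(sprintf("digit %d at position %d outside bounds [%d, %d]",
                 levels[bad[1L]], bad[1L], levelMin, levelMax))
  levels
}

#' Enumerate all health profiles
#'
#' All `(levelMax - levelMin + 1)^J` distinct profiles; for the EQ-5D-5L
#' (J = 5, levels 1-5) this yields the 3125 possible health states.
#'
#' @param j number of items.
#' @inheritParams encodeProfile
#' @return character vector of profile strings in lexicographic order.
#' @export
enumerateProfiles <- function(j, levelMin = 1L, levelMax = 5L) {
  if (levelMax > 9L) stop("profile digits require levelMax <= 9")
  grids <- rep(list(levelMin:levelMax), j)
  g <- do.call(expand.grid, rev(grids))[, j:1, drop = FALSE]
  apply(g, 1L, paste, collapse = "")
}

#' Tabulate observed profiles
#'
#' Counts the distinct response patterns present in the data (the MIC sample
#' showed 566 of the 3125 possible EQ-5D-5L patterns).
#'
#' @param m a [ResponseMatrix-class].
#' @return `data.frame` with columns `profile`, `n`, `share`, sorted by
#'   decreasing frequency.
#' @export
profileCounts <- function(m) {
  p <- apply(responseValues(m), 1L, paste, collapse = "")
  tab <- sort(table(p), decreasing = TRUE)
  data.frame(profile = names(tab), n = as.integer(tab),
             share = as.numeric(tab) / nPersons(m), row.names = NULL)
}
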