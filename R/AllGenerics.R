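#' @rdname ResponseMatrix
#' @param object,x a [ResponseMatrix-class].
#' @export
setGeneric("responseValues", function(object) standardGeneric("responseValues"))

#' @rdname ResponseMatrix
#' @export
setGeneric("nPersons", function(object) standardGeneric("nPersons"))

#' @rdname ResponseMatrix
#' @export
setGeneric("nItems", function(object) standardGeneric("nItems"))

#' @rdname ResponseMatrix
#' @export
setGeneric("itemLabels", function(object) standardGeneric("itemLabels"))

#' @rdname ResponseMatrix
#' @export
setGeneric("levelBounds", function(object) standardGeneric("levelBounds"))

#' @rdname ResponseMatrix
#' @export
setGeneric("groupInfo", function(object) standardGeneric("groupInfo"))

#' Level sum score
#'
#' The unweighted sum of a person's item levels; for the EQ-5D-5L this is the
#' LSS ranging 5 ("11111", no problems on any dimension) to 25 ("55555",
#' extreme problems on all dimensions). Higher scores indicate worse health.
#'
#' @param m a [ResponseMatrix-class].
#' @return integer vector of length N.
#' @export
setGeneric("levelSumScore", function(m) standardGeneric("levelSumScore"))

#' Rest scores
#'
#' Level sum score minus the entries of the item(s) under inspection — the
#' manifest conditioning variable for monotonicity and item-ordering checks.
#' Pairwise item-ordering checks exclude two items at once.
#'
#' @param m a [ResponseMatrix-class].
#' @param excludeItems item labels or indices to subtract (non-empty, must
#'   leave at least one item in the rest set).
#' @return integer vector of length N.
#' @export
setGeneric("restScores", function(m, excludeItems) standardGeneric("restScores"))

#' @rdname hAccessors
#' @export
setGeneric("hPair", function(object) standardGeneric("hPair"))

#' @rdname hAccessors
#' @export
setGeneric("hItem", function(object) standardGeneric("hItem"))

#' Accessors for scalability coefficients
#'
#' @param object a [ScalabilityResult-class].
#' @name hAccessors
#' @export
setGeneric("hScale", function(object) standardGeneric("hScale"))

#' @rdname hAccessors
#' @export
setGeneric("seItem", function(object) standardGeneric("seItem"))

#' @rdname hAccessors
#' @export
setGeneric("seScale", function(object) standardGeneric("seScale"))

#' @rdname AispResult-class
#' @param object an [AispResult-class].
#' @export
setGeneric("scaleAssignment", function(object) standardGeneric("scaleAssignment"))
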