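#' Plot item step response functions and the item response function
#'
#' One panel per item in the tradition of Mokken monotonicity figures: the
#' estimated ISRFs P(X >= k | rest-score group) as separate lines over the
#' group midpoints, with the IRF (conditional mean) overlaid on a secondary
#' scale. Requires ggplot2.
#'
#' @param report a [MonotonicityReport-class].
#' @param items item labels to plot (default: all in the report).
#' @return a ggplot object.
#' @export
plotIsrf <- function(report, items = names(report@isrf)) {
  requireGgplot()
  dat <- do.call(rbind, lapply(items, function(it)
    cbind(item = it, report@isrf[[it]])))
  dat$step <- factor(dat$step)
  ggplot2::ggplot(dat, ggplot2::aes(x = restMid, y = prob,
                                    colour = step)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~item) +
    ggplot2::labs(x = "rest-score group (midpoint)",
                  y = "P(X >= k | group)", colour = "step k") +
    ggplot2::ylim(0, 1)
}

#' Plot paired item response functions
#'
#' The two conditional-mean curves of [pairedIrf()] over the shared
#' rest-score groups; crossing curves indicate an item-ordering violation.
#'
#' @param m a [ResponseMatrix-class].
#' @param itemA,itemB the item pair.
#' @param minsize minimum rest-score group size.
#' @return a ggplot object.
#' @export
plotPairedIrf <- function(m, itemA, itemB,
                          minsize = defaultMinsize(nPersons(m))) {
  requireGgplot()
  tab <- pairedIrf(m, itemA, itemB, minsize = minsize)
  labs <- itemLabels(m)[c(resolveItems(m, itemA), resolveItems(m, itemB))]
  long <- data.frame(
    restMid = rep(tab$restMid, 2L),
    irf = c(tab$meanA, tab$meanB),
    item = rep(labs, each = nrow(tab)))
  ggplot2::ggplot(long, ggplot2::aes(x = restMid, y = irf,
                                     colour = item)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "rest-score group (midpoint)",
                  y = "E[X | group]", colour = NULL)
}

requireGgplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package")
}
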