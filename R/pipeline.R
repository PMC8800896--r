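#' Default analysis configuration
#'
#' @return named list of the tunable analysis parameters with their
#'   defaults: `minvi` (0.03), `miioMinvi` (`NULL` = steps x 0.03),
#'   `minsize` (`NULL` = [defaultMinsize()]), `alpha` (0.05), `aispLbound`
#'   (0.3), `sweepGrid` (0, 0.05, ..., 0.55), `bootstrapB` (0 = no bootstrap
#'   SEs), `excludeItems` (none), `minStratumN` (200), `doSweep` (TRUE).
#' @export
defaultAnalysisConfig <- function() {
  list(minvi = 0.03, miioMinvi = NULL, minsize = NULL, alpha = 0.05,
       aispLbound = 0.3, sweepGrid = seq(0, 0.55, 0.05), bootstrapB = 0L,
       excludeItems = character(0), minStratumN = 200L, doSweep = TRUE)
}

## One full Mokken battery on a single (sub)sample.
analysisBlock <- function(m, cfg, seed) {
  n <- nPersons(m)
  minsize <- cfg$minsize %||% defaultMinsize(n)
  sc <- if (cfg$bootstrapB > 0L)
    scalabilitySE(m, B = cfg$bootstrapB, seed = deriveSeed(seed, 1L))
  else computeHScale(m)
  aisp <- runAisp(m, lbound = cfg$aispLbound, alpha = cfg$alpha)
  sweep <- if (isTRUE(cfg$doSweep))
    sweepLbound(m, min(cfg$sweepGrid), max(cfg$sweepGrid),
                diff(cfg$sweepGrid[1:2]), alpha = cfg$alpha) else NULL
  mono <- checkMonotonicity(m, minvi = cfg$minvi, minsize = minsize,
                            alpha = cfg$alpha)
  miio <- checkMiio(m, minvi = cfg$miioMinvi, minsize = minsize,
                    alpha = cfg$alpha)
  back <- backwardSelection(m, report = miio, minvi = cfg$miioMinvi,
                            minsize = minsize, alpha = cfg$alpha)
  rel <- scaleReliability(m)
  lss <- levelSumScore(m)
  block <- list(
    n = n, scalability = sc,
    classification = tryCatch(classifyScale(hScale(sc)),
                              error = function(e) "undefined"),
    aisp = aisp, sweep = sweep, monotonicity = mono, miio = miio,
    backward = back, ht = miio@ht, reliability = rel,
    lss = c(min = min(lss), max = max(lss), mean = mean(lss),
            sd = stats::sd(lss)))
  if (length(cfg$excludeItems)) {
    sub <- dropItems(m, cfg$excludeItems)
    subsc <- if (cfg$bootstrapB > 0L)
      scalabilitySE(sub, B = cfg$bootstrapB, seed = deriveSeed(seed, 2L))
    else computeHScale(sub)
    block$without <- list(
      items = cfg$excludeItems, scalability = subsc,
      classification = tryCatch(classifyScale(hScale(subsc)),
                                error = function(e) "undefined"),
      ht = if (nItems(sub) >= 3L)
        suppressMessages(coefficientHt(sub)) else NA_real_,
      miio = if (nItems(sub) >= 3L)
        checkMiio(sub, minvi = cfg$miioMinvi, minsize = minsize,
                  alpha = cfg$alpha) else NULL,
      reliability = scaleReliability(sub))
  }
  block
}

#' Run the full Mokken analysis battery
#'
#' Executes, for the pooled sample and each stratum of every grouping
#' column: scalability coefficients (optionally with bootstrap SEs), the
#' AISP at the configured bound plus a lower-bound sweep, manifest
#' monotonicity per item, manifest invariant item ordering with backward
#' selection, the HT coefficient, reliability (rho, lambda-2) and a
#' level-sum-score summary. When `excludeItems` is configured (e.g. the
#' anxiety/depression item), the scalability / HT / reliability battery is
#' re-run on the reduced scale as a generic item-exclusion comparison.
#' Strata smaller than `minStratumN` are skipped with a warning. The run is
#' deterministic given `seed`.
#'
#' @param m a [ResponseMatrix-class] (grouping columns taken from its
#'   `groupInfo`).
#' @param config named list overriding entries of
#'   [defaultAnalysisConfig()].
#' @param seed master seed for the bootstrap stages.
#' @return a [StudyReport-class].
#' @export
runFullAnalysis <- function(m, config = list(), seed = 1L) {
  cfg <- utils::modifyList(defaultAnalysisConfig(), config)
  unknown <- setdiff(names(config), names(defaultAnalysisConfig()))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  if (length(cfg$excludeItems)) resolveItems(m, cfg$excludeItems)
  results <- list(pooled = analysisBlock(m, cfg, seed))
  gi <- groupInfo(m)
  if (!is.null(gi)) {
    k <- 10L
    for (col in names(gi)) {
      for (val in sort(unique(gi[[col]]))) {
        sel <- which(gi[[col]] == val)
        label <- paste0(col, ":", val)
        if (length(sel) < cfg$minStratumN) {
          warning("stratum ", label, " has n = ", length(sel),
                  " < ", cfg$minStratumN, "; skipped")
          next
        }
        k <- k + 1L
        results[[label]] <- analysisBlock(m[sel, ], cfg, deriveSeed(seed, k))
      }
    }
  }
  new("StudyReport", results = results, config = cfg, seed = as.numeric(seed))
}

setMethod("show", "StudyReport", function(object) {
  cat(sprintf("StudyReport: %d analysis block(s), seed %g\n",
              length(object@results), object@seed))
  for (nm in names(object@results)) {
    b <- object@results[[nm]]
    cat(sprintf("  %-24s n=%6d  Hs=%.3f [%s]  HT=%.3f  vi(mono)=%d  vi(miio)=%d\n",
                nm, b$n, hScale(b$scalability), b$classification, b$ht,
                sum(b$monotonicity@summary$vi),
                sum(b$miio@itemSummary$vi)))
  }
})

## --- report tables ---------------------------------------------------------

itemSummaryTable <- function(report) {
  do.call(rbind, lapply(names(report@results), function(nm) {
    b <- report@results[[nm]]
    sc <- b$scalability
    ms <- b$monotonicity@summary
    is <- b$miio@itemSummary
    df <- data.frame(
      stratum = nm, item = names(hItem(sc)),
      mean = colMeansFromSummary(ms, names(hItem(sc))),
      Hi = as.numeric(hItem(sc)), seHi = as.numeric(seItem(sc)),
      monoAc = ms$ac[match(names(hItem(sc)), ms$item)],
      monoVi = ms$vi[match(names(hItem(sc)), ms$item)],
      monoCrit = ms$crit[match(names(hItem(sc)), ms$item)],
      miioAc = is$ac[match(names(hItem(sc)), is$item)],
      miioVi = is$vi[match(names(hItem(sc)), is$item)],
      miioCrit = is$crit[match(names(hItem(sc)), is$item)])
    scale <- data.frame(
      stratum = nm, item = c("Hs", "Rho", "Lambda", "HT"),
      mean = NA_real_,
      Hi = c(hScale(sc), b$reliability@msRho, b$reliability@lambda2, b$ht),
      seHi = c(seScale(sc), NA_real_, NA_real_, NA_real_),
      monoAc = NA_integer_, monoVi = NA_integer_, monoCrit = NA_real_,
      miioAc = NA_integer_, miioVi = NA_integer_, miioCrit = NA_real_)
    rbind(df, scale)
  }))
}

colMeansFromSummary <- function(ms, items) ms$mean[match(items, ms$item)]

pairTableAll <- function(report) {
  do.call(rbind, lapply(names(report@results), function(nm) {
    tab <- scalabilityTable(report@results[[nm]]$scalability)
    tab <- tab[tab$level == "pair", c("itemA", "itemB", "estimate", "se", "z")]
    cbind(stratum = nm, tab)
  }))
}

stratifiedTable <- function(report) {
  do.call(rbind, lapply(names(report@results), function(nm) {
    b <- report@results[[nm]]
    row <- data.frame(stratum = nm, n = b$n)
    for (it in names(hItem(b$scalability)))
      row[[paste0("Hi_", it)]] <- as.numeric(hItem(b$scalability)[it])
    row$Hs <- hScale(b$scalability)
    row$HT <- b$ht
    row$rho <- b$reliability@msRho
    row$lambda2 <- b$reliability@lambda2
    if (!is.null(b$without)) {
      for (it in names(hItem(b$without$scalability)))
        row[[paste0("Hi_noexcl_", it)]] <-
          as.numeric(hItem(b$without$scalability)[it])
      row$Hs_noexcl <- hScale(b$without$scalability)
      row$HT_noexcl <- b$without$ht
      row$rho_noexcl <- b$without$reliability@msRho
      row$lambda2_noexcl <- b$without$reliability@lambda2
    }
    row
  }))
}

excludedPairTable <- function(report) {
  out <- lapply(names(report@results), function(nm) {
    b <- report@results[[nm]]
    if (is.null(b$without)) return(NULL)
    excl <- b$without$items
    sc <- b$scalability
    do.call(rbind, lapply(excl, function(e) {
      others <- setdiff(names(hItem(sc)), excl)
      data.frame(stratum = nm, excluded = e, item = others,
                 Hij = hPair(sc)[e, others],
                 se = sc@sePair[e, others], row.names = NULL)
    }))
  })
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Write study report tables
#'
#' Writes tab-separated tables (per-item summary with monotonicity and
#' ordering violation columns; pairwise coefficients; the stratified
#' with/without-exclusion comparison; pairwise coefficients of excluded
#' items by stratum) plus a machine-readable JSON twin of all tables.
#' Output is deterministic: re-running an identical configuration and seed
#' reproduces the files byte for byte.
#'
#' @param report a [StudyReport-class].
#' @param outdir output directory (created if needed).
#' @return invisibly, the named list of written file paths.
#' @export
writeReports <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tables <- list(item_summary = itemSummaryTable(report),
                 pairwise_h = pairTableAll(report),
                 stratified = stratifiedTable(report))
  ex <- excludedPairTable(report)
  if (!is.null(ex)) tables$excluded_pairs <- ex
  paths <- list()
  for (nm in names(tables)) {
    p <- file.path(outdir, paste0(nm, ".tsv"))
    data.table::fwrite(tables[[nm]], p, sep = "\t", na = "NA")
    paths[[nm]] <- p
  }
  jp <- file.path(outdir, "report.json")
  jsonlite::write_json(
    c(tables, list(meta = list(seed = report@seed,
                               config = report@config[
                                 !vapply(report@config, is.null, logical(1))]))),
    jp, digits = NA, auto_unbox = TRUE, dataframe = "columns", null = "null")
  paths$json <- jp
  invisible(paths)
}

#' Read back the JSON study tables
#'
#' Round-trip companion to [writeReports()]: the returned tables equal the
#' in-memory ones that were written.
#'
#' @param path path to `report.json`.
#' @return named list of data frames (plus `meta`).
#' @export
readReportJson <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(raw[setdiff(names(raw), "meta")], as.data.frame)
  out$meta <- raw$meta
  out
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file whose keys match [defaultAnalysisConfig()].
#' @return config list (validated key names).
#' @export
readAnalysisConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(defaultAnalysisConfig()))
  if (length(unknown))
    stop("unknown config entries in ", path, ": ",
         paste(unknown, collapse = ", "))
  cfg
}
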