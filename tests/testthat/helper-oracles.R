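## Independent oracles used to freeze expected values.

## Exhaustive maximum covariance: enumerate every integer coupling
## (contingency table) with the given margins and take the largest
## covariance. Only feasible for small N and few levels.
compositionsBounded <- function(total, bounds) {
  if (length(bounds) == 1L) {
    if (total <= bounds) return(list(total))
    return(list())
  }
  out <- list()
  for (v in 0:min(total, bounds[1L]))
    for (rest in compositionsBounded(total - v, bounds[-1L]))
      out[[length(out) + 1L]] <- c(v, rest)
  out
}

oracleMaxCov <- function(freqI, freqJ, levels) {
  maxS <- -Inf
  rec <- function(r, cols, acc) {
    if (r > length(freqI)) {
      if (all(cols == 0)) maxS <<- max(maxS, acc)
      return(invisible())
    }
    for (cmp in compositionsBounded(freqI[r], cols))
      rec(r + 1L, cols - cmp, acc + levels[r] * sum(cmp * levels))
  }
  rec(1L, freqJ, 0)
  n <- sum(freqI)
  maxS / n - sum(freqI * levels) / n * sum(freqJ * levels) / n
}

## Linear-program oracle for larger marginals: the transportation LP
## max sum_ab l_a l_b n_ab subject to the margins, solved by scipy's HiGHS
## interface. Returns one covariance per marginal pair.
lpMaxCov <- function(pairs) {
  payload <- tempfile(fileext = ".json")
  jsonlite::write_json(pairs, payload, digits = NA)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "pairs = json.load(open(sys.argv[1]))",
    "out = []",
    "for d in pairs:",
    "    fi = np.array(d['fi'], float); fj = np.array(d['fj'], float)",
    "    lev = np.array(d['lev'], float)",
    "    nI, nJ = len(fi), len(fj)",
    "    c = -np.outer(lev, lev).ravel()",
    "    A = []; b = []",
    "    for i in range(nI):",
    "        row = np.zeros(nI * nJ); row[i*nJ:(i+1)*nJ] = 1",
    "        A.append(row); b.append(fi[i])",
    "    for j in range(nJ):",
    "        row = np.zeros(nI * nJ); row[j::nJ] = 1",
    "        A.append(row); b.append(fj[j])",
    "    r = linprog(c, A_eq=np.array(A), b_eq=np.array(b),",
    "                bounds=(0, None), method='highs')",
    "    N = fi.sum()",
    "    out.append(-r.fun / N - (fi @ lev / N) * (fj @ lev / N))",
    "print(json.dumps(out))"), script)
  res <- system2("python", c(script, payload), stdout = TRUE)
  unlist(jsonlite::fromJSON(res[length(res)]))
}

## Random level-frequency marginal with total n over the given levels.
randomMarginal <- function(n, nLevels) {
  repeat {
    f <- as.integer(tabulate(sample.int(nLevels, n, replace = TRUE), nLevels))
    if (sum(f > 0) >= 2L) return(f)
  }
}
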