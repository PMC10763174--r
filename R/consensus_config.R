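#' Configuration for the consensus statistics
#'
#' Bundles every tunable of the appropriateness analysis: which percentiles
#' summarise the panel, how they are interpolated, the disagreement-index
#' constants, the agreement threshold and the appropriateness band edges.
#' Defaults reproduce the customary RAND/UCLA analysis on a 1-9 scale.
#'
#' @param q_low,q_high Percentile fractions summarising the spread of the
#'   panel. Defaults 0.30 and 0.70 (the 30th and 70th percentiles).
#' @param method Percentile interpolation method. `"linear"` (default) is
#'   linear interpolation at plotting position `(n - 1) q + 1`
#'   ([stats::quantile()] type 7); `"nearest"` is the nearest-rank /
#'   inverse-ECDF rule (type 1); `"weibull"` interpolates at `(n + 1) q`
#'   (type 6). Configurable because published panels rarely state which
#'   convention their software used.
#' @param di_threshold Disagreement-index value at or above which the panel
#'   is declared in disagreement. Default 1; a DI exactly equal to the
#'   threshold counts as disagreement.
#' @param band_edges Numeric length-2, the cut points on the median
#'   separating the inappropriate / equivocal / appropriate bands. The
#'   defaults `c(3.5, 6.5)` place integer medians 1-3, 4-6 and 7-9 in the
#'   three bands and send half-integer medians (2.5, 4.5, ...) to the band
#'   of their nearest integers; medians exactly on an edge fall to
#'   equivocal.
#' @param ipras_intercept,ipras_slope Constants of the interpercentile range
#'   adjusted for symmetry, `IPRAS = intercept + slope * AI` with
#'   `AI = |5 - IPRCP|`. Defaults 2.35 and 1.5.
#' @param scale_mid Midpoint of the rating scale used in the asymmetry
#'   index. Default 5 (for the 1-9 scale).
#'
#' @return A list with class `"consensus_config"`.
#' @seealso [read_consensus_config()] to load one from YAML or JSON.
#' @export
#' @examples
#' consensus_config()
#' consensus_config(method = "weibull", di_threshold = 1.2)
consensus_config <- function(q_low = 0.30, q_high = 0.70,
                             method = c("linear", "nearest", "weibull"),
                             di_threshold = 1,
                             band_edges = c(3.5, 6.5),
                             ipras_intercept = 2.35, ipras_slope = 1.5,
                             scale_mid = 5) {
  method <- match.arg(method)
  if (!is.numeric(q_low) || !is.numeric(q_high) ||
      q_low <= 0 || q_low >= 1 || q_high <= 0 || q_high >= 1) {
    abort_config("`q_low` and `q_high` must be fractions strictly inside (0, 1)")
  }
  if (q_low > q_high) abort_config("`q_low` must not exceed `q_high`")
  if (length(band_edges) != 2 || band_edges[1] > band_edges[2]) {
    abort_config("`band_edges` must be two non-decreasing cut points")
  }
  if (di_threshold <= 0) abort_config("`di_threshold` must be positive")
  structure(
    list(q_low = q_low, q_high = q_high, method = method,
         di_threshold = di_threshold,
         band_edges = as.numeric(band_edges),
         ipras_intercept = ipras_intercept, ipras_slope = ipras_slope,
         scale_mid = scale_mid),
    class = "consensus_config"
  )
}

#' Read a consensus configuration from YAML or JSON
#'
#' Unknown keys are rejected so typos do not silently fall back to defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys are the
#'   arguments of [consensus_config()].
#' @return A `consensus_config` object.
#' @export
read_consensus_config <- function(path) {
  if (!file.exists(path)) abort_config(paste0("config file not found: ", path))
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(consensus_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort_config(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  }
  do.call(consensus_config, vals)
}

#' @export
print.consensus_config <- function(x, ...) {
  cat("<consensus_config>\n")
  cat(sprintf("  percentiles: %.2f / %.2f (%s interpolation)\n",
              x$q_low, x$q_high, x$method))
  cat(sprintf("  IPRAS = %.2f + %.2f * |%g - IPRCP|; disagreement at DI >= %g\n",
              x$ipras_intercept, x$ipras_slope, x$scale_mid, x$di_threshold))
  cat(sprintf("  bands: inappropriate < %g <= equivocal <= %g < appropriate\n",
              x$band_edges[1], x$band_edges[2]))
  invisible(x)
}
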