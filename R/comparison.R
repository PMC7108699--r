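#' Symmetric percent difference between two effective doses
#'
#' \code{100 * |a - b| / ((a + b) / 2)}: the absolute difference relative
#' to the two-method mean. Symmetric in its arguments and invariant under
#' a common positive scaling.
#'
#' @param a,b effective doses (uSv), both >= 0 with \code{a + b > 0}.
#'   Vectorized.
#' @return percent difference in [0, 200).
#' @examples
#' percentDifference(181.4, 160.9)  # ~12.0
#' @export
percentDifference <- function(a, b) {
  if (any(!is.finite(a) | !is.finite(b) | a < 0 | b < 0))
    stop("effective doses must be finite and >= 0")
  if (any(a + b == 0))
    stop("percent difference undefined for a + b = 0")
  100 * abs(a - b) / ((a + b) / 2)
}

#' Build the method-comparison report
#'
#' Pairs up the two arms' effective doses per protocol and computes the
#' percent-difference column plus the min/max summary. Internally the
#' doses are kept as raw doubles; report cells are rounded to one decimal
#' only at assembly. When every percent difference is below 25 the pair of
#' methods is conventionally described as in good agreement.
#'
#' @param osld named list of \linkS4class{EffectiveDoseResult} (method
#'   \code{"OSLD"}), names are protocol identifiers.
#' @param mc named list of \linkS4class{EffectiveDoseResult} (method
#'   \code{"MC"}), same names.
#' @param protocolOrder optional character vector fixing the row order;
#'   defaults to the order of \code{osld}.
#' @return a \linkS4class{ComparisonReport}.
#' @export
buildReport <- function(osld, mc, protocolOrder = names(osld)) {
  if (is.null(names(osld)) || is.null(names(mc)))
    stop("osld and mc must be named by protocol")
  rows <- lapply(protocolOrder, function(id) {
    if (!id %in% names(osld))
      stop("missing OSLD result for protocol '", id, "'")
    if (!id %in% names(mc))
      stop("missing MC result for protocol '", id, "'")
    a <- effectiveDoseUSv(osld[[id]])
    b <- effectiveDoseUSv(mc[[id]])
    data.frame(protocol = id,
               E_OSLD_uSv = round(a, 1),
               E_MC_uSv = round(b, 1),
               percent_difference = round(percentDifference(a, b), 1))
  })
  rows <- do.call(rbind, rows)
  higher <- ifelse(rows$E_OSLD_uSv > rows$E_MC_uSv, "OSLD",
                   ifelse(rows$E_OSLD_uSv < rows$E_MC_uSv, "MC", "equal"))
  annotation <- sprintf("%s: %s method read higher", rows$protocol, higher)
  new("ComparisonReport",
      rows = rows,
      summaryRange = c(min(rows$percent_difference),
                       max(rows$percent_difference)),
      annotation = annotation)
}

#' Comparison-report rows
#' @param report a \linkS4class{ComparisonReport}.
#' @return data.frame with protocol, E_OSLD_uSv, E_MC_uSv,
#'   percent_difference.
#' @export
reportRows <- function(report) report@rows

#' Min/max percent difference of a report
#' @param report a \linkS4class{ComparisonReport}.
#' @return numeric length 2 (min, max).
#' @export
reportRange <- function(report) report@summaryRange

setMethod("show", "ComparisonReport", function(object) {
  cat("ComparisonReport (effective dose, uSv):\n")
  print(object@rows, row.names = FALSE)
  cat(sprintf("  percent difference range: %.1f-%.1f\n",
              object@summaryRange[1], object@summaryRange[2]))
})
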