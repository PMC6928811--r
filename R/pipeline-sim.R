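#' @include synthetic-cells.R
NULL

#' Per-layer pipeline phase durations
#'
#' @param config,fetch,calc numeric vectors (one entry per layer) of the
#'   configuration, data-fetch and calculation phase durations in
#'   microseconds
#' @return data.frame with columns config, fetch, calc
#' @export
phaseTimes <- function(config, fetch, calc) {
  if (any(c(config, fetch, calc) < 0))
    stop("phase durations must be non-negative", call. = FALSE)
  if (length(unique(c(length(config), length(fetch), length(calc)))) != 1L)
    stop("config, fetch and calc must have one entry per layer", call. = FALSE)
  data.frame(config = as.numeric(config), fetch = as.numeric(fetch),
             calc = as.numeric(calc))
}

.scheduleResult <- function(common, overlap) {
  new("ScheduleResult", commonTotal = common,
      dualRegTotal = common - overlap, overlap = overlap,
      savedPct = if (common > 0) 100 * overlap / common else 0)
}

setMethod("show", "ScheduleResult", function(object) {
  cat(sprintf(paste0("ScheduleResult: common %.0f us, dual-reg %.0f us, ",
                     "overlap %.0f us, %.2f%% saved\n"),
              object@commonTotal, object@dualRegTotal, object@overlap,
              object@savedPct))
})

#' Sequential (single register group) schedule
#'
#' Without a second configuration register group every layer's
#' configuration, data fetch and calculation run strictly one after the
#' other, because a layer needs its predecessor's result before anything
#' of it can start: the total is simply the sum of all phases and nothing
#' overlaps.
#'
#' @param phases data.frame from [phaseTimes()] (per-layer durations)
#' @return a [ScheduleResult-class] with zero overlap
#' @export
simulateCommon <- function(phases) {
  if (any(unlist(phases) < 0))
    stop("phase durations must be non-negative", call. = FALSE)
  .scheduleResult(sum(phases$config, phases$fetch, phases$calc), 0)
}

#' Dual configuration register group schedule
#'
#' With two alternating register banks, layer k+1's configuration and data
#' fetch can be loaded into the idle bank while layer k is still
#' calculating, so per layer k the time hidden is
#' `min(config[k+1] + fetch[k+1], calc[k])` - one-layer lookahead only,
#' because there are exactly two banks. When only aggregate phase totals
#' are available (no per-layer breakdown), pass the measured `overlap`
#' and the simulator reduces to `dualreg = common - overlap`.
#'
#' @param phases data.frame from [phaseTimes()]; per-layer rows, or a
#'   single row of aggregate totals when `overlap` is supplied
#' @param overlap measured aggregate overlap in microseconds (aggregate
#'   mode); NULL for the per-layer model
#' @return a [ScheduleResult-class]
#' @export
simulateDualReg <- function(phases, overlap = NULL) {
  common <- simulateCommon(phases)@commonTotal
  if (!is.null(overlap)) {
    if (overlap < 0 || overlap > common)
      stop("overlap must be between 0 and the common-mode total",
           call. = FALSE)
    return(.scheduleResult(common, overlap))
  }
  nl <- nrow(phases)
  ov <- 0
  if (nl > 1L)
    for (k in seq_len(nl - 1L))
      ov <- ov + min(phases$config[k + 1L] + phases$fetch[k + 1L],
                     phases$calc[k])
  .scheduleResult(common, ov)
}

#' Export a dual-register schedule timeline as CSV
#'
#' Writes per-layer start/end times of each phase under the dual register
#' group model (layer k+1's config + fetch start when layer k's
#' calculation starts, bounded by its completion).
#'
#' @param phases data.frame from [phaseTimes()]
#' @param file CSV path
#' @return invisibly, the timeline data.frame
#' @export
exportTimeline <- function(phases, file) {
  nl <- nrow(phases)
  t <- 0
  rows <- NULL
  prepDone <- 0
  for (k in seq_len(nl)) {
    prepLen <- phases$config[k] + phases$fetch[k]
    prepStart <- if (k == 1L) t else prepDone
    prepEnd <- prepStart + prepLen
    calcStart <- max(prepEnd, t)
    calcEnd <- calcStart + phases$calc[k]
    rows <- rbind(rows, data.frame(layer = k, prepStart = prepStart,
                                   prepEnd = prepEnd, calcStart = calcStart,
                                   calcEnd = calcEnd))
    prepDone <- calcStart   # next layer's prep may begin alongside this calc
    t <- calcEnd
  }
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(rows)
}
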