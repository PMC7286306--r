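#' Frequency band specification
#'
#' @param name Band label (e.g. `"theta"`).
#' @param lo,hi Band edges in Hz, `0 < lo < hi`. Validity against the Nyquist
#'   frequency is checked at filtering time.
#' @return A `frequency_band` object (named list).
#' @examples
#' frequency_band("alpha", 8, 12)
#' @export
frequency_band <- function(name, lo, hi) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(lo), is.numeric(hi), lo > 0, hi > lo)
  structure(list(name = name, lo = lo, hi = hi), class = "frequency_band")
}

#' @export
print.frequency_band <- function(x, ...) {
  cat(sprintf("<frequency_band> %s: %g-%g Hz\n", x$name, x$lo, x$hi))
  invisible(x)
}

#' Canonical frequency-band presets
#'
#' Two presets of resting-state band definitions ship with the package. The
#' `"methods"` preset (theta 4-8, alpha 8-12, beta 13-30, low-gamma 35-60 Hz)
#' is the default used throughout; the `"abstract"` variant (theta 4-7,
#' alpha 8-13, beta 15-25, gamma 30-60 Hz) is an alternative convention kept
#' for comparability.
#'
#' @param preset `"methods"` (default) or `"abstract"`.
#' @return Named list of [frequency_band()] objects.
#' @export
band_presets <- function(preset = c("methods", "abstract")) {
  preset <- match.arg(preset)
  defs <- switch(preset,
    methods = list(theta = c(4, 8), alpha = c(8, 12),
                   beta = c(13, 30), gamma = c(35, 60)),
    abstract = list(theta = c(4, 7), alpha = c(8, 13),
                    beta = c(15, 25), gamma = c(30, 60))
  )
  lapply(stats::setNames(names(defs), names(defs)),
         function(nm) frequency_band(nm, defs[[nm]][1], defs[[nm]][2]))
}

#' Resting-state network definitions (AAL regions)
#'
#' Bilateral region-of-interest lists for three resting-state networks drawn
#' from the AAL atlas: the fronto-parietal network (FPN, 10 ROIs: middle
#' frontal gyrus, pars triangularis, inferior and superior parietal gyri,
#' angular gyrus), the default-mode network (DMN, 10 ROIs: orbitofrontal
#' cortex, anterior and posterior cingulate, precuneus, angular gyrus) and
#' the sensorimotor network (SMN, 6 ROIs: pre- and postcentral gyri,
#' supplementary motor area). Suffixes `.L`/`.R` mark hemisphere.
#'
#' @param network One of `"FPN"`, `"DMN"`, `"SMN"`; if missing, all three.
#' @return Character vector of ROI labels, or a named list of them.
#' @examples
#' length(network_rois("FPN")) # 10
#' @export
network_rois <- function(network) {
  nets <- list(
    FPN = c("MFG.L", "MFG.R", "PTr.L", "PTr.R", "IPG.L", "IPG.R",
            "SPG.L", "SPG.R", "AG.L", "AG.R"),
    DMN = c("OFC.L", "OFC.R", "ACC.L", "ACC.R", "PCC.L", "PCC.R",
            "pCUN.L", "pCUN.R", "AG.L", "AG.R"),
    SMN = c("preCG.L", "preCG.R", "postCG.L", "postCG.R", "SMA.L", "SMA.R")
  )
  if (missing(network)) return(nets)
  network <- match.arg(network, names(nets))
  nets[[network]]
}
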