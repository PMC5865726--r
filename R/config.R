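#' Default pipeline configuration
#'
#' Returns the parameter set shared by the pipeline stages.  Values can be
#' overridden by passing named arguments, e.g. `rap_config(min_region_coverage
#' = 40)`.
#'
#' @param ... named overrides for individual parameters.
#'
#' @details
#' Peak-caller parameters: `min_span`/`max_span` (mate-pair 5'-end distance
#' bounds, nt, inclusive), `min_region_coverage` (reads per base required for
#' a candidate region), `kernel_window` (Gaussian taps, odd),
#' `kernel_sigma` (kernel spread, bases), `min_peak_len`/`max_peak_len`
#' (peak length bounds, nt, inclusive).
#'
#' Enrichment parameters: `n_boot` randomized placements.
#'
#' Occupancy parameters: `trim` (nt removed from each gene end),
#' `n_deciles`, `alpha` (significance threshold for the up/down rate test),
#' `n_background_genes` (placements per RAP for the randomized background),
#' `min_flank` (minimum up/downstream region length, nt).
#'
#' Expression parameters: `tpm_bounds`, the inner TPM segment boundaries.
#'
#' @return a named list of parameters (class `rap_config`).
#' @export
rap_config <- function(...) {
  cfg <- list(
    min_span            = 20L,
    max_span            = 500L,
    min_region_coverage = 5,
    kernel_window       = 5L,
    kernel_sigma        = 1.0,
    min_peak_len        = 20L,
    max_peak_len        = 500L,
    n_boot              = 100000L,
    trim                = 200L,
    n_deciles           = 10L,
    alpha               = 0.01,
    n_background_genes  = 100L,
    min_flank           = 20L,
    tpm_bounds          = c(1, 30, 80)
  )
  override <- list(...)
  if (length(override)) {
    bad <- setdiff(names(override), names(cfg))
    if (length(bad)) stop("unknown config parameter(s): ", paste(bad, collapse = ", "))
    cfg[names(override)] <- override
  }
  stopifnot(
    cfg$min_span > 0, cfg$min_span < cfg$max_span,
    cfg$min_region_coverage > 0,
    cfg$kernel_window >= 1, cfg$kernel_window %% 2 == 1,
    cfg$kernel_sigma > 0,
    cfg$min_peak_len > 0, cfg$min_peak_len < cfg$max_peak_len,
    cfg$n_boot >= 0,
    cfg$trim >= 0, cfg$n_deciles >= 2,
    cfg$alpha > 0, cfg$alpha < 1,
    cfg$n_background_genes > 0,
    length(cfg$tpm_bounds) >= 1, !is.unsorted(cfg$tpm_bounds)
  )
  class(cfg) <- "rap_config"
  cfg
}
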