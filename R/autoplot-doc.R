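#' Plot methods for vesimech result objects
#'
#' `autoplot()` methods returning ggplot objects: undulation spectra
#' (power vs degree with optional fit overlay), contour Legendre spectra,
#' wave amplitude series with detected extrema, and radial density
#' profiles.
#'
#' @param object A vesimech result object.
#' @param fit Optional `helfrich_fit` overlaid on an undulation spectrum.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-vesimech
NULL
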