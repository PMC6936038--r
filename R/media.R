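# Lineage bands and media models for the band classifier.

#' Lineage bands and media models
#'
#' A lineage band assigns commitment to lineage `x` whenever the
#' time-averaged cytoskeletal free energy falls in `centre ± half_width`.
#' A media model is a set of bands plus `Nc`, the number of decorrelated
#' microstates the cell assumes over the 24-48 h commitment window.
#'
#' `growth_media()` and `mixed_media()` return the reference band values
#' for hMSCs in growth medium (osteoblast 2.59 ± 0.14, myoblast
#' 1.87 ± 0.05) and mixed medium (osteoblast 2.59 ± 0.37, adipocyte
#' 1.61 ± 0.44), both with `Nc = 15`. These centres live on the energy
#' scale of the calibration that produced them; when forecasting with a
#' differently normalized energy model, recalibrate with
#' [calibrate_bands()] first (the default workflow does).
#'
#' @param lineage Lineage name.
#' @param centre Band centre (dimensionless energy).
#' @param half_width Band half-width (>= 0).
#' @return `lineage_band()`: one-row tibble; `media_model()`: a
#'   `media_model` object (tibble of bands + attributes).
#' @examples
#' growth_media()
#' @export
lineage_band <- function(lineage, centre, half_width) {
  stopifnot(half_width >= 0)
  tibble::tibble(lineage = lineage, centre = centre,
                 half_width = half_width)
}

#' @rdname lineage_band
#' @param bands A tibble of bands (rows from [lineage_band()]).
#' @param Nc Number of decorrelated microstates (>= 1).
#' @param media Media name.
#' @export
media_model <- function(bands, Nc = 15L, media = "custom") {
  stopifnot(Nc >= 1, all(bands$half_width >= 0),
            !anyDuplicated(bands$lineage))
  structure(tibble::as_tibble(bands),
            Nc = as.integer(Nc), media = media,
            class = c("media_model", class(tibble::tibble())))
}

#' @rdname lineage_band
#' @export
growth_media <- function() {
  media_model(dplyr::bind_rows(
    lineage_band("osteoblast", 2.59, 0.14),
    lineage_band("myoblast", 1.87, 0.05)),
    Nc = 15L, media = "growth")
}

#' @rdname lineage_band
#' @export
mixed_media <- function() {
  media_model(dplyr::bind_rows(
    lineage_band("osteoblast", 2.59, 0.37),
    lineage_band("adipocyte", 1.61, 0.44)),
    Nc = 15L, media = "mixed")
}

#' @export
print.media_model <- function(x, ...) {
  cat(sprintf("<media_model> media = %s, Nc = %d\n",
              attr(x, "media"), attr(x, "Nc")))
  NextMethod()
}

#' Reference differentiation fractions used for band calibration
#'
#' Approximate measured lineage fractions for hMSCs, the calibration
#' inputs of the band classifier. For growth media these summarize the
#' classic stiffness-sweep measurements: the osteoblast fraction peaks
#' at about 0.8 on 30 kPa substrates (about 20% of cells remain
#' undifferentiated there) and the myoblast fraction peaks at about 0.8
#' near 10 kPa, with near-zero commitment elsewhere. For mixed media
#' they summarize the stiffness-dependent measurements: adipocytes
#' favoured on soft substrates, osteoblasts on stiff ones. Values
#' between the text-anchored points are smooth synthetic
#' interpolations, not digitized data.
#'
#' @param media `"growth"` or `"mixed"`; in both cases the conditions are
#'   substrate stiffness values in kPa, the cue family on which bands are
#'   calibrated before predicting island responses.
#' @return A tibble with columns `condition`, `lineage`, `fraction`.
#' @export
reference_fractions <- function(media = c("growth", "mixed")) {
  media <- match.arg(media)
  if (media == "growth") {
    tibble::tibble(
      condition = rep(c(1, 3, 10, 30, 70), times = 2),
      lineage = rep(c("osteoblast", "myoblast"), each = 5),
      fraction = c(0, 0, 0.02, 0.80, 0.10,
                   0, 0.05, 0.80, 0.02, 0))
  } else {
    tibble::tibble(
      condition = rep(c(1, 3, 10, 30, 70), times = 2),
      lineage = rep(c("osteoblast", "adipocyte"), each = 5),
      fraction = c(0, 0.02, 0.10, 0.50, 0.55,
                   0.45, 0.50, 0.20, 0.02, 0))
  }
}
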