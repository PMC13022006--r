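#' Trophic-position calibration constants
#'
#' Calibration for the amino-acid trophic-position equations: the autotroph
#' intercept beta (the Glu-Phe or Ala-Phe delta15N difference of a pure
#' photoautotroph) and the trophic discrimination factor (TDF, the per-step
#' 15N enrichment of the trophic amino acid relative to phenylalanine).
#' Defaults are the canonical Chikaraishi-style constants: beta 3.4 permil
#' and TDF 7.6 permil for glutamic acid + glutamine, beta 3.2 permil and TDF
#' 5.7 permil for alanine.
#'
#' @param beta_glu,tdf_glu Glutamic-acid intercept and TDF (permil).
#' @param beta_ala,tdf_ala Alanine intercept and TDF (permil).
#' @return An object of class `trophic_calibration`: a list with elements
#'   `glu` and `ala`, each holding `beta1` and `tdf`.
#' @examples
#' calib <- trophic_calibration()
#' calib$glu$tdf  # 7.6
#' @export
trophic_calibration <- function(beta_glu = 3.4, tdf_glu = 7.6,
                                beta_ala = 3.2, tdf_ala = 5.7) {
  stopifnot(is.finite(beta_glu), is.finite(tdf_glu), tdf_glu > 0,
            is.finite(beta_ala), is.finite(tdf_ala), tdf_ala > 0)
  structure(list(glu = list(beta1 = beta_glu, tdf = tdf_glu),
                 ala = list(beta1 = beta_ala, tdf = tdf_ala)),
            class = "trophic_calibration")
}

.calib_for <- function(aa, calib) {
  aa <- match.arg(aa, c("glu", "ala"))
  calib[[aa]]
}

#' Trophic position from a trophic/source amino-acid delta15N pair
#'
#' TP = (d15N_trophic - d15N_phe - beta) / TDF + 1, linear in the delta
#' difference and not clipped: values below 1 or above 2 are returned as
#' computed. Vectorised over the delta arguments.
#'
#' @param d_trophic delta15N of the trophic amino acid (Glu or Ala), permil
#'   vs air.
#' @param d_phe delta15N of phenylalanine, permil vs air.
#' @param aa `"glu"` or `"ala"`.
#' @param calib A [trophic_calibration()].
#' @return Trophic position(s); `NA` where either delta is missing or
#'   non-finite.
#' @examples
#' trophic_position(11.0, 0, "glu")  # 2.0
#' @export
trophic_position <- function(d_trophic, d_phe, aa = c("glu", "ala"),
                             calib = trophic_calibration()) {
  cc <- .calib_for(match.arg(aa), calib)
  tp <- (d_trophic - d_phe - cc$beta1) / cc$tdf + 1
  tp[!is.finite(d_trophic) | !is.finite(d_phe)] <- NA_real_
  tp
}

#' Trophocline y-intercept for a given trophic position
#'
#' A trophocline is the slope-1 line in the (d15N_Phe, d15N_trophic) plane
#' along which the trophic position is constant; its intercept is
#' beta + TDF * (TP - 1).
#'
#' @inheritParams trophic_position
#' @param tp Trophic position.
#' @return Intercept in permil.
#' @examples
#' trophocline_intercept(1.5, "glu")  # 7.2
#' trophocline_intercept(2.0, "ala")  # 8.9
#' @export
trophocline_intercept <- function(tp, aa = c("glu", "ala"),
                                  calib = trophic_calibration()) {
  cc <- .calib_for(match.arg(aa), calib)
  cc$beta1 + cc$tdf * (tp - 1)
}

#' Expected trophic amino-acid delta15N at a given trophic position
#'
#' Inverse of [trophic_position()]: the delta15N a trophic amino acid is
#' expected to carry when phenylalanine sits at `d_phe` and the organism is
#' at trophic position `tp`.
#'
#' @inheritParams trophocline_intercept
#' @param d_phe delta15N of phenylalanine, permil.
#' @return delta15N in permil.
#' @export
expected_delta <- function(tp, d_phe, aa = c("glu", "ala"),
                           calib = trophic_calibration()) {
  d_phe + trophocline_intercept(tp, aa, calib)
}

#' First-order uncertainty of a trophic position
#'
#' Propagates independent analytical SDs of the two delta measurements
#' through the linear TP equation: sd_TP = sqrt(sd_trophic^2 + sd_phe^2)/TDF.
#'
#' @inheritParams trophic_position
#' @param sd_trophic,sd_phe Analytical standard deviations, permil (>= 0).
#' @return SD of the trophic position.
#' @export
tp_uncertainty <- function(sd_trophic, sd_phe, aa = c("glu", "ala"),
                           calib = trophic_calibration()) {
  if (any(stats::na.omit(c(sd_trophic, sd_phe)) < 0))
    stop("analytical SDs must be non-negative")
  cc <- .calib_for(match.arg(aa), calib)
  sqrt(sd_trophic^2 + sd_phe^2) / cc$tdf
}

#' Nutritional-mode classification bands
#'
#' Band edges on the two TP axes. On the Glu axis, TP_Glu below
#' `glu_auto_max` is the autotroph side, the closed band
#' [`glu_mixo_min`, `glu_mixo_max`] is the osmotroph (Glu-mixotroph) side,
#' and values above it are labelled heterotroph-dominated. On the Ala axis,
#' TP_Ala at or above `ala_phago_min` flags phagotrophy. The Ala edge
#' defaults to 1.4, a half-width of 0.1 around the 1.5 archetype mirroring
#' the printed Glu band.
#'
#' @param glu_auto_max,glu_mixo_min,glu_mixo_max,ala_phago_min Band edges
#'   (trophic-position units).
#' @return An object of class `mode_bands`.
#' @export
mode_bands <- function(glu_auto_max = 1.4, glu_mixo_min = 1.4,
                       glu_mixo_max = 1.6, ala_phago_min = 1.4) {
  stopifnot(glu_auto_max <= glu_mixo_min, glu_mixo_min <= glu_mixo_max,
            ala_phago_min > 1, ala_phago_min < 2)
  structure(list(glu_auto_max = glu_auto_max, glu_mixo_min = glu_mixo_min,
                 glu_mixo_max = glu_mixo_max, ala_phago_min = ala_phago_min),
            class = "mode_bands")
}

#' The six nutritional-mode labels
#' @return Character vector of valid mode labels.
#' @export
trophic_modes <- function() {
  c("photoautotroph", "osmo_photoautotroph", "phago_photoautotroph",
    "osmo_phago_photoautotroph", "heterotroph_dominated", "indeterminate")
}

#' Classify nutritional mode from the two trophic positions
#'
#' The Glu axis separates autotrophy (TP_Glu below the band) from
#' osmotrophy-augmented autotrophy (within the band) and heterotroph
#' dominance (above it); the Ala axis flags protistan phagotrophy. Their
#' combination yields the four nutritional modes of unicellular plankton:
#' photoautotroph, osmo-photoautotroph, phago-photoautotroph and
#' osmo-phago-photoautotroph (mixoplankton). A missing TP on either axis
#' gives `indeterminate`. Vectorised.
#'
#' @param tp_glu,tp_ala Trophic positions from [trophic_position()].
#' @param bands A [mode_bands()].
#' @return Character vector of modes (see [trophic_modes()]).
#' @examples
#' classify_trophic_mode(1.5, 1.5)  # mixoplankton signature
#' @export
classify_trophic_mode <- function(tp_glu, tp_ala, bands = mode_bands()) {
  n <- max(length(tp_glu), length(tp_ala))
  tp_glu <- rep_len(tp_glu, n)
  tp_ala <- rep_len(tp_ala, n)
  out <- rep(NA_character_, n)
  miss <- !is.finite(tp_glu) | !is.finite(tp_ala)
  out[miss] <- "indeterminate"
  phago <- tp_ala >= bands$ala_phago_min
  auto <- tp_glu < bands$glu_auto_max
  osmo <- tp_glu >= bands$glu_mixo_min & tp_glu <= bands$glu_mixo_max
  het <- tp_glu > bands$glu_mixo_max
  ok <- !miss
  out[ok & het] <- "heterotroph_dominated"
  out[ok & auto & !phago] <- "photoautotroph"
  out[ok & auto & phago] <- "phago_photoautotroph"
  out[ok & osmo & !phago] <- "osmo_photoautotroph"
  out[ok & osmo & phago] <- "osmo_phago_photoautotroph"
  # a half-open gap between glu_auto_max and glu_mixo_min can only occur
  # with non-default bands; map it to the autotroph side
  gap <- ok & !auto & !osmo & !het
  out[gap & !phago] <- "photoautotroph"
  out[gap & phago] <- "phago_photoautotroph"
  out
}

#' Per-sample trophic calls for a table of amino-acid profiles
#'
#' Applies [trophic_position()], [tp_uncertainty()] (when analytical SDs are
#' present) and [classify_trophic_mode()] to a profile table.
#'
#' @param profiles Data frame with columns `d15n_phe`, `d15n_glu`,
#'   `d15n_ala` and optionally `sd_phe`, `sd_glu`, `sd_ala` (see
#'   [read_aa_table()]).
#' @param bands A [mode_bands()].
#' @param calib A [trophic_calibration()].
#' @return The input with columns `tp_glu`, `tp_ala`, `sd_tp_glu`,
#'   `sd_tp_ala` and `mode` appended.
#' @export
trophic_calls <- function(profiles, bands = mode_bands(),
                          calib = trophic_calibration()) {
  stopifnot(is.data.frame(profiles),
            all(c("d15n_phe", "d15n_glu", "d15n_ala") %in% names(profiles)))
  out <- profiles
  out$tp_glu <- trophic_position(profiles$d15n_glu, profiles$d15n_phe,
                                 "glu", calib)
  out$tp_ala <- trophic_position(profiles$d15n_ala, profiles$d15n_phe,
                                 "ala", calib)
  if (all(c("sd_glu", "sd_phe") %in% names(profiles))) {
    out$sd_tp_glu <- tp_uncertainty(profiles$sd_glu, profiles$sd_phe,
                                    "glu", calib)
  }
  if (all(c("sd_ala", "sd_phe") %in% names(profiles))) {
    out$sd_tp_ala <- tp_uncertainty(profiles$sd_ala, profiles$sd_phe,
                                    "ala", calib)
  }
  out$mode <- classify_trophic_mode(out$tp_glu, out$tp_ala, bands)
  out
}

#' Overlay samples and end members on the reference trophoclines
#'
#' For each record and each trophic amino acid, finds the reference
#' trophocline (TP 1.0, 1.5, 2.0) nearest to the point in the
#' (d15N_Phe, d15N_trophic) plane and reports the distance to it. Distance
#' to a slope-1 line is perpendicular by default, |delta_diff - intercept| /
#' sqrt(2); ties go to the lower TP.
#'
#' @param profiles Data frame with `sample_id` (or `organism`), `d15n_phe`,
#'   `d15n_glu`, `d15n_ala`. Literature end-member tables (see
#'   [read_endmember_table()]) work unchanged.
#' @param tps Reference trophic positions of the trophoclines.
#' @param distance `"perpendicular"` or `"vertical"`.
#' @param calib A [trophic_calibration()].
#' @return Long data frame: one row per record x amino acid with the nearest
#'   trophocline `tp` and its `distance` (permil).
#' @export
endmember_overlay <- function(profiles, tps = c(1.0, 1.5, 2.0),
                              distance = c("perpendicular", "vertical"),
                              calib = trophic_calibration()) {
  distance <- match.arg(distance)
  stopifnot(is.data.frame(profiles), nrow(profiles) > 0, length(tps) > 0)
  id <- if ("sample_id" %in% names(profiles)) profiles$sample_id
        else if ("organism" %in% names(profiles)) profiles$organism
        else seq_len(nrow(profiles))
  tps <- sort(tps)
  scale <- if (distance == "perpendicular") sqrt(2) else 1
  res <- lapply(c("glu", "ala"), function(aa) {
    dcol <- paste0("d15n_", aa)
    if (!dcol %in% names(profiles)) return(NULL)
    dd <- profiles[[dcol]] - profiles$d15n_phe
    ints <- trophocline_intercept(tps, aa, calib)
    dmat <- abs(outer(dd, ints, "-")) / scale
    # ties toward lower TP, with a tolerance so exact midpoints are ties
    best <- apply(dmat, 1, function(d) which(d <= min(d) + 1e-9)[1])
    data.frame(sample_id = id, aa = aa, tp = tps[best],
               distance = dmat[cbind(seq_along(best), best)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
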