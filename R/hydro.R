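#' Surface-referenced potential density anomaly from T and S
#'
#' EOS-80 one-atmosphere density polynomial (Millero & Poisson) minus 1000
#' kg/m3. Adequate for the shallow casts this package targets; supply
#' sigma_theta directly when a full equation of state has already been
#' applied.
#'
#' @param temperature deg C.
#' @param salinity Practical salinity.
#' @return sigma-theta in kg/m3.
#' @export
sigma_theta_surface <- function(temperature, salinity) {
  t <- temperature
  s <- salinity
  rho_w <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  A <- 8.24493e-1 - 4.0899e-3 * t + 7.6438e-5 * t^2 -
    8.2467e-7 * t^3 + 5.3875e-9 * t^4
  B <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  C <- 4.8314e-4
  rho_w + A * s + B * s^1.5 + C * s^2 - 1000
}

.ctd_sigma <- function(profile) {
  if (!is.null(profile$sigma_theta)) return(profile$sigma_theta)
  if (all(c("temperature", "salinity") %in% names(profile)))
    return(sigma_theta_surface(profile$temperature, profile$salinity))
  stop("profile needs sigma_theta or temperature and salinity")
}

#' Brunt-Vaisala (buoyancy) frequency squared of a cast
#'
#' N2(z) = (g/rho0) * d sigma_theta / dz evaluated by finite differences at
#' the midpoints between adjacent levels (g = 9.81 m/s2, rho0 = 1025
#' kg/m3). Positive where density increases downward.
#'
#' @param profile Data frame with `depth` (m, strictly increasing from the
#'   surface) and `sigma_theta` (kg/m3) or `temperature` and `salinity`.
#' @return Data frame with `depth` (midpoints, m) and `n2` (1/s2).
#' @export
buoyancy_frequency <- function(profile) {
  stopifnot(is.data.frame(profile), nrow(profile) >= 3)
  z <- profile$depth
  if (any(diff(z) <= 0)) stop("depth must be strictly increasing")
  sig <- .ctd_sigma(profile)
  g <- 9.81
  rho0 <- 1025
  n2 <- (g / rho0) * diff(sig) / diff(z)
  data.frame(depth = (z[-1] + z[-length(z)]) / 2, n2 = n2)
}

#' Mixed-layer depth from the buoyancy-frequency maximum
#'
#' The depth of the primary (global) maximum of N2; on ties within 1e-12
#' the shallowest is taken. A cast with no stratification signal (all N2
#' zero or non-finite) yields NA with a warning.
#'
#' @param n2 N2 values (1/s2).
#' @param depths Depths of the N2 values (m); defaults are taken from a
#'   data frame passed as `n2` (the output of [buoyancy_frequency()]).
#' @return MLD in metres, or NA.
#' @export
mixed_layer_depth <- function(n2, depths = NULL) {
  if (is.data.frame(n2)) {
    depths <- n2$depth
    n2 <- n2$n2
  }
  ok <- is.finite(n2)
  if (!any(ok) || all(n2[ok] == 0)) {
    warning("no buoyancy-frequency maximum: MLD undefined")
    return(NA_real_)
  }
  m <- max(n2[ok])
  cand <- which(ok & n2 >= m - 1e-12)
  depths[cand[which.min(depths[cand])]]
}

#' Depth at which a concentration profile first reaches a threshold
#'
#' Nutricline depth rule: zero when the surface concentration already
#' meets or exceeds the threshold; otherwise the linearly interpolated
#' depth of the first downward crossing; NA when the threshold is never
#' reached.
#'
#' @param depth Depths (m), increasing.
#' @param conc Concentrations (uM); NA levels are dropped.
#' @param threshold Threshold concentration (uM).
#' @return Depth in metres, 0, or NA.
#' @export
cline_depth <- function(depth, conc, threshold) {
  ok <- is.finite(depth) & is.finite(conc)
  depth <- depth[ok]
  conc <- conc[ok]
  if (!length(depth)) return(NA_real_)
  if (conc[1] >= threshold) return(0)
  for (i in seq_len(length(depth) - 1)) {
    if (conc[i + 1] >= threshold) {
      return(depth[i] + (threshold - conc[i]) *
               (depth[i + 1] - depth[i]) / (conc[i + 1] - conc[i]))
    }
  }
  NA_real_
}

#' Nitrate availability index
#'
#' Piecewise index of nitrate supply: equal to the surface nitrate+nitrite
#' concentration (uM) when that is at least 0.5 uM; otherwise minus the
#' interpolated depth (m) at which NOx reaches 2 uM; otherwise minus the
#' bottom depth of the cast. The mixed units (uM above, negative metres
#' below) are intentional and kept raw downstream.
#'
#' @param nutrients Data frame with `depth` and `nox` (uM); optional
#'   `bottom_depth` column or attribute, defaulting to the deepest level.
#' @param surface_threshold,z_threshold Branch thresholds (uM).
#' @return The index, or NA when surface NOx is missing.
#' @export
nai <- function(nutrients, surface_threshold = 0.5, z_threshold = 2) {
  ok <- is.finite(nutrients$depth) & is.finite(nutrients$nox)
  d <- nutrients$depth[ok]
  x <- nutrients$nox[ok]
  if (!length(d)) return(NA_real_)
  if (x[1] >= surface_threshold) return(x[1])
  z2 <- cline_depth(d, x, z_threshold)
  if (is.finite(z2)) return(-z2)
  bottom <- if (!is.null(nutrients$bottom_depth))
    nutrients$bottom_depth[1] else max(d)
  -bottom
}

#' Oxygen solubility at atmospheric equilibrium
#'
#' Garcia and Gordon combined-fit polynomial (Benson-Krause data,
#' umol/kg coefficient set) for the solubility of oxygen in seawater at
#' one atmosphere, converted to mM using a reference density of
#' 1025 kg/m3.
#'
#' @param temperature deg C (fit range roughly 0-40).
#' @param salinity Practical salinity (fit range roughly 0-42).
#' @return Saturation concentration in mM (mmol/L).
#' @export
o2_saturation <- function(temperature, salinity) {
  if (any(temperature < -2 | temperature > 40 |
            salinity < 0 | salinity > 42, na.rm = TRUE))
    warning("temperature or salinity outside the solubility fit range")
  a <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)
  b <- c(-7.01577e-3, -7.70028e-3, -1.13864e-2, -9.51519e-3)
  c0 <- -2.75915e-7
  ts <- log((298.15 - temperature) / (273.15 + temperature))
  lnc <- a[1] + a[2] * ts + a[3] * ts^2 + a[4] * ts^3 + a[5] * ts^4 +
    a[6] * ts^5 +
    salinity * (b[1] + b[2] * ts + b[3] * ts^2 + b[4] * ts^3) +
    c0 * salinity^2
  exp(lnc) * 1.025 / 1000  # umol/kg -> mmol/L at rho = 1025 kg/m3
}

#' Thickness of the buoyant low-salinity plume
#'
#' Interpolated depth at which salinity first reaches the threshold (the
#' plume-extent criterion of sea-surface salinity below 35). NA when the
#' surface is already at or above the threshold (no plume); when the whole
#' cast stays fresher than the threshold the bottom depth is returned with
#' attribute `censored = TRUE`.
#'
#' @param profile Data frame with `depth` and `salinity`.
#' @param threshold_salinity Salinity bounding the plume (default 35).
#' @return Thickness in metres, possibly with attribute `censored`.
#' @export
plume_thickness <- function(profile, threshold_salinity = 35) {
  ok <- is.finite(profile$depth) & is.finite(profile$salinity)
  d <- profile$depth[ok]
  s <- profile$salinity[ok]
  if (!length(d) || s[1] >= threshold_salinity) return(NA_real_)
  z <- cline_depth(d, s, threshold_salinity)
  if (is.finite(z)) return(z)
  structure(max(d), censored = TRUE)
}

#' Station-level environmental feature vector
#'
#' Assembles the predictors used by the trophic-mode classifier from a CTD
#' cast, a nutrient cast, and the surface chlorophyll a concentration.
#' Missing inputs propagate to missing features; the classifier stage
#' tolerates them. "Surface" values are taken at the topmost valid level.
#'
#' @param ctd Data frame with `depth`, `temperature`, `salinity`, and
#'   optionally `sigma_theta`, `oxygen` (mM) and `fluorescence`.
#' @param nutrients Optional data frame with `depth`, `nox`, `po4`, `si`.
#' @param surface_chla Optional surface chlorophyll a (ug/L).
#' @return One-row data frame of features: `mld`, `n2_max`,
#'   `n2_max_depth`, `nai`, `nitracline`, `phosphocline`, `silicacline`,
#'   `plume_thickness`, `surface_oxygen`, `o2_saturation`,
#'   `surface_temperature`, `surface_salinity`, `surface_chla`,
#'   `dcm_depth`.
#' @export
station_features <- function(ctd, nutrients = NULL, surface_chla = NA_real_) {
  stopifnot(is.data.frame(ctd))
  bv <- buoyancy_frequency(ctd)
  mld <- suppressWarnings(mixed_layer_depth(bv))
  n2max <- if (any(is.finite(bv$n2))) max(bv$n2, na.rm = TRUE) else NA_real_
  top <- which(is.finite(ctd$depth))[1]
  sst <- if ("temperature" %in% names(ctd)) ctd$temperature[top] else NA_real_
  sss <- if ("salinity" %in% names(ctd)) ctd$salinity[top] else NA_real_
  surf_o2 <- if ("oxygen" %in% names(ctd)) ctd$oxygen[top] else NA_real_
  o2sat <- if (is.finite(sst) && is.finite(sss))
    o2_saturation(sst, sss) else NA_real_
  dcm <- if ("fluorescence" %in% names(ctd) &&
               any(is.finite(ctd$fluorescence)))
    ctd$depth[which.max(ctd$fluorescence)] else NA_real_
  pt <- if (is.finite(sss)) as.numeric(plume_thickness(ctd)) else NA_real_
  nitr <- phos <- sil <- nai_v <- NA_real_
  if (!is.null(nutrients)) {
    if (!is.null(nutrients$nox)) {
      nitr <- cline_depth(nutrients$depth, nutrients$nox, 1)
      nai_v <- nai(nutrients)
    }
    if (!is.null(nutrients$po4))
      phos <- cline_depth(nutrients$depth, nutrients$po4, 0.1)
    if (!is.null(nutrients$si))
      sil <- cline_depth(nutrients$depth, nutrients$si, 2)
  }
  data.frame(mld = mld, n2_max = n2max, n2_max_depth = mld, nai = nai_v,
             nitracline = nitr, phosphocline = phos, silicacline = sil,
             plume_thickness = pt, surface_oxygen = surf_o2,
             o2_saturation = o2sat, surface_temperature = sst,
             surface_salinity = sss, surface_chla = surface_chla,
             dcm_depth = dcm)
}
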