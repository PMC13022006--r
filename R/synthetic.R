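#' Archetype trophic-position signatures of the nutritional modes
#'
#' The (TP_Glu, TP_Ala) pairs that generate synthetic amino-acid profiles:
#' the four nutritional modes of microalgae-dominated seston, plus the two
#' literature end-member archetypes (strict protistan grazers, whose Glu
#' signal stays near the autotroph line while Ala records the trophic
#' step, and DON-grown heterotrophic microbes, the converse).
#'
#' @return Data frame with `mode`, `tp_glu`, `tp_ala`, `group`,
#'   `n_source`.
#' @export
archetype_tps <- function() {
  data.frame(
    mode = c("photoautotroph", "osmo_photoautotroph",
             "phago_photoautotroph", "osmo_phago_photoautotroph",
             "protozooplankton", "don_heterotroph"),
    tp_glu = c(1.0, 1.5, 1.0, 1.5, 1.2, 2.0),
    tp_ala = c(1.0, 1.0, 1.5, 1.5, 2.0, 1.5),
    group = c("microalgae", "microalgae", "microalgae", "microalgae",
              "protozooplankton", "bacteria"),
    n_source = c("DIN", "DON", "prey", "DON", "prey", "DON"),
    stringsAsFactors = FALSE)
}

#' Generate synthetic amino-acid delta15N profiles with known modes
#'
#' Draws, per sample, a phenylalanine baseline from `phe_range` (the
#' spread of nitrogen-source baselines across a river plume), places Glu
#' and Ala on the trophoclines of the generating mode's archetype TPs, and
#' adds independent Gaussian analytical noise of SD `aa_noise_sd` to each
#' reported delta. With `n_replicates > 1` the reported value is the mean
#' of that many replicate draws, emulating triplicate analysis.
#'
#' @param n_per_mode Samples per mode.
#' @param modes Modes to generate (subset of [archetype_tps()]).
#' @param aa_noise_sd Analytical SD per replicate measurement (permil),
#'   default 1.
#' @param n_replicates Replicates averaged into each reported delta.
#' @param phe_range Range of the true phenylalanine baseline (permil).
#' @param seed Integer seed; the output is reproducible given it.
#' @param calib A [trophic_calibration()].
#' @return Data frame in the amino-acid profile schema (`sample_id`,
#'   `station`, `year`, `size_fraction`, `habitat`, deltas and SDs) plus
#'   truth columns `true_mode`, `true_tp_glu`, `true_tp_ala`,
#'   `d15n_phe_true`.
#' @export
gen_aa_profiles <- function(n_per_mode = 10,
                            modes = c("photoautotroph",
                                      "osmo_photoautotroph",
                                      "phago_photoautotroph",
                                      "osmo_phago_photoautotroph"),
                            aa_noise_sd = 1.0, n_replicates = 1,
                            phe_range = c(2, 12), seed = 1,
                            calib = trophic_calibration()) {
  arch <- archetype_tps()
  stopifnot(all(modes %in% arch$mode), aa_noise_sd >= 0, n_replicates >= 1)
  set.seed(seed)
  arch <- arch[match(modes, arch$mode), ]
  n <- n_per_mode * length(modes)
  true_mode <- rep(arch$mode, each = n_per_mode)
  tp_glu <- rep(arch$tp_glu, each = n_per_mode)
  tp_ala <- rep(arch$tp_ala, each = n_per_mode)
  phe_true <- stats::runif(n, phe_range[1], phe_range[2])
  sdm <- aa_noise_sd / sqrt(n_replicates)
  noise <- function() stats::rnorm(n, 0, sdm)
  d_phe <- phe_true + noise()
  d_glu <- expected_delta(tp_glu, phe_true, "glu", calib) + noise()
  d_ala <- expected_delta(tp_ala, phe_true, "ala", calib) + noise()
  data.frame(
    sample_id = sprintf("syn%03d", seq_len(n)),
    station = sprintf("st%02d", rep(seq_along(modes), each = n_per_mode)),
    year = 2018L,
    size_fraction = "total",
    habitat = "unknown",
    d15n_phe = d_phe, d15n_glu = d_glu, d15n_ala = d_ala,
    sd_phe = aa_noise_sd, sd_glu = aa_noise_sd, sd_ala = aa_noise_sd,
    n_replicates = n_replicates,
    true_mode = true_mode, true_tp_glu = tp_glu, true_tp_ala = tp_ala,
    d15n_phe_true = phe_true,
    stringsAsFactors = FALSE)
}

#' Generate a literature-style end-member table
#'
#' Small synthetic stand-in for a literature end-member compilation:
#' organisms of each archetype group with deltas generated like
#' [gen_aa_profiles()].
#'
#' @param n_per_group Records per archetype.
#' @param aa_noise_sd Spread of the literature values (permil).
#' @param seed Integer seed.
#' @return Data frame with `organism`, `group`, `n_source` and the three
#'   deltas.
#' @export
gen_endmembers <- function(n_per_group = 8, aa_noise_sd = 1.0, seed = 1) {
  arch <- archetype_tps()
  arch <- arch[arch$mode %in% c("photoautotroph", "don_heterotroph",
                                "protozooplankton"), ]
  prof <- gen_aa_profiles(n_per_group, modes = arch$mode,
                          aa_noise_sd = aa_noise_sd, seed = seed)
  data.frame(
    organism = prof$sample_id,
    group = rep(arch$group, each = n_per_group),
    n_source = rep(arch$n_source, each = n_per_group),
    d15n_phe = prof$d15n_phe, d15n_glu = prof$d15n_glu,
    d15n_ala = prof$d15n_ala, stringsAsFactors = FALSE)
}

#' Generate pigment samples from known class mixtures
#'
#' Pigment vector of a sample = total chl a x (fractions %*% ratio rows),
#' each cell then multiplied by (1 + N(0, cv)) and truncated at zero.
#'
#' @param fractions Samples x classes mixing fractions (rows sum to 1), or
#'   the number of random mixtures to draw from a flat Dirichlet.
#' @param ratio_matrix Generating ratio matrix (classes x pigments).
#' @param chla_total Total chlorophyll a per sample (ug/L); recycled.
#' @param cv Multiplicative noise coefficient of variation.
#' @param seed Integer seed.
#' @return List with `pigments` (samples x pigments matrix) and
#'   `fractions` (the truth, rows summing to 1).
#' @export
gen_pigment_samples <- function(fractions, ratio_matrix = ratio_matrix_final(),
                                chla_total = 1, cv = 0.01, seed = 1) {
  set.seed(seed)
  k <- nrow(ratio_matrix)
  if (length(fractions) == 1 && is.numeric(fractions)) {
    g <- matrix(stats::rgamma(fractions * k, shape = 1), ncol = k)
    fractions <- g / rowSums(g)
    colnames(fractions) <- rownames(ratio_matrix)
  }
  fractions <- as.matrix(fractions)
  stopifnot(ncol(fractions) == k, all(fractions >= 0),
            all(abs(rowSums(fractions) - 1) < 1e-8), cv >= 0)
  S <- (chla_total * fractions) %*% ratio_matrix
  if (cv > 0)
    S <- S * (1 + matrix(stats::rnorm(length(S), 0, cv), nrow(S)))
  S[S < 0] <- 0
  rownames(S) <- sprintf("syn%03d", seq_len(nrow(S)))
  list(pigments = S, fractions = fractions)
}

#' Generate a two-layer plume CTD and nutrient cast
#'
#' Density and salinity follow a tanh transition centred at the prescribed
#' pycnocline depth (the true mixed-layer depth), so the
#' buoyancy-frequency maximum recovers it to within one grid step. The
#' nitrate+nitrite profile stays at `nox_surface` above the prescribed
#' nitracline and ramps linearly to `nox_deep` below it, letting any of
#' the three nitrate-availability branches be planted.
#'
#' @param mld Pycnocline depth (m).
#' @param depth_max,dz Cast extent and grid step (m).
#' @param sigma_surface,sigma_deep Potential density anomaly of the two
#'   layers (kg/m3).
#' @param sal_surface,sal_deep Salinity of the two layers.
#' @param temp_surface,temp_deep Temperature of the two layers (deg C).
#' @param transition_width tanh half-width (m).
#' @param nox_surface,nox_deep,nitracline Nutrient profile parameters (uM,
#'   uM, m).
#' @param oxygen_surface Surface oxygen (mM) for the oxygen column;
#'   NA omits it.
#' @return List with `ctd` and `nutrients` data frames.
#' @export
gen_ctd_cast <- function(mld = 20, depth_max = 120, dz = 1,
                         sigma_surface = 20, sigma_deep = 24,
                         sal_surface = 30, sal_deep = 36,
                         temp_surface = 28, temp_deep = 20,
                         transition_width = 2,
                         nox_surface = 0.1, nox_deep = 10,
                         nitracline = 40, oxygen_surface = 0.2) {
  z <- seq(0, depth_max, by = dz)
  mix <- (1 + tanh((z - mld) / transition_width)) / 2
  ctd <- data.frame(
    depth = z,
    temperature = temp_surface + (temp_deep - temp_surface) * mix,
    salinity = sal_surface + (sal_deep - sal_surface) * mix,
    sigma_theta = sigma_surface + (sigma_deep - sigma_surface) * mix)
  if (is.finite(oxygen_surface))
    ctd$oxygen <- oxygen_surface * (1 - 0.3 * mix)
  # Gaussian fluorescence bump below the pycnocline: a deep chl maximum
  ctd$fluorescence <- 0.1 + exp(-((z - (mld + 15)) / 10)^2)
  zn <- seq(0, depth_max, by = max(dz * 5, 5))
  nox <- ifelse(zn <= nitracline, nox_surface,
                nox_surface + (nox_deep - nox_surface) *
                  (zn - nitracline) / max(depth_max - nitracline, 1))
  nutrients <- data.frame(depth = zn, nox = nox,
                          po4 = pmax(nox / 16, 0.02),
                          si = pmax(nox * 1.2, 0.5),
                          bottom_depth = depth_max)
  list(ctd = ctd, nutrients = nutrients)
}

#' Generate a labeled station feature table with planted rules
#'
#' Dominant-mixotroph stations are drawn with mixed-layer depth at or
#' below `mld_mixo_max` and surface chlorophyll a above `chla_mixo_min`;
#' dominant-autotroph stations violate at least one of the two rules. All
#' other predictors are drawn from habitat-typical ranges and carry no
#' class signal, so with zero noise a correct tree learner must recover
#' the two planted thresholds.
#'
#' @param n Number of stations.
#' @param frac_mixo Fraction of mixotroph-dominated stations.
#' @param mld_mixo_max,chla_mixo_min The planted thresholds (m, ug/L).
#' @param seed Integer seed.
#' @return Data frame of features with a `mode` label column
#'   (`"Dominant Mixotroph"` / `"Dominant Autotroph"`).
#' @export
gen_station_set <- function(n = 100, frac_mixo = 0.5, mld_mixo_max = 37,
                            chla_mixo_min = 0.171, seed = 1) {
  set.seed(seed)
  n_mix <- round(n * frac_mixo)
  n_aut <- n - n_mix
  mixo <- rep(c(TRUE, FALSE), c(n_mix, n_aut))
  mld <- numeric(n)
  chla <- numeric(n)
  mld[mixo] <- stats::runif(n_mix, 8, mld_mixo_max)
  chla[mixo] <- stats::runif(n_mix, chla_mixo_min * 1.05, 1.5)
  # autotroph stations: deep mixed layer, or shallow with low chl a;
  # deep mixed layers are the commoner violation, making MLD the
  # strongest single predictor
  deep <- stats::runif(n_aut) < 0.7
  mld[!mixo] <- ifelse(deep, stats::runif(n_aut, mld_mixo_max * 1.05, 90),
                       stats::runif(n_aut, 8, mld_mixo_max))
  chla[!mixo] <- ifelse(deep, stats::runif(n_aut, 0.02, 1.5),
                        stats::runif(n_aut, 0.02, chla_mixo_min * 0.95))
  feats <- data.frame(
    mld = mld,
    surface_chla = chla,
    n2_max = stats::runif(n, 1e-4, 0.05),
    plume_thickness = stats::runif(n, 2, 40),
    surface_oxygen = stats::runif(n, 0.17, 0.24),
    surface_temperature = stats::runif(n, 26, 30),
    surface_salinity = stats::runif(n, 5, 37),
    dcm_depth = stats::runif(n, 20, 120),
    nitracline = stats::runif(n, 0, 120),
    phosphocline = stats::runif(n, 0, 120),
    silicacline = stats::runif(n, 0, 120),
    no3_po4 = stats::runif(n, 0.5, 30),
    no3_si = stats::runif(n, 0.1, 3),
    size_index = stats::runif(n, 1, 3))
  feats$mode <- ifelse(mixo, "Dominant Mixotroph", "Dominant Autotroph")
  # shuffle so row order carries no signal
  feats[sample.int(n), , drop = FALSE]
}
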