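# Pollen-fertility phenotype prediction and the stained-pollen observation
# model (I2-KI staining with possible misscoring of arrested grains).

FERTILITY_CLASSES <- c("sterile", "semisterile", "partial_sterile", "fertile")

#' Pollen-scoring observation model
#'
#' Arrested pollen grains can be misscored as fertile under I2-KI staining
#' with probability `gamma`, inflating observed fertility above the true
#' surviving fraction. `baseline_f0` is the stained fraction of a fully
#' fertile plant (field-grown fertile plants rarely reach 100%).
#'
#' @param gamma Probability an aborted grain is scored as fertile, in `[0, 1]`.
#' @param baseline_f0 Fertility of a fully fertile plant, in `[0, 1]`.
#' @return An object of class `observation_model`.
#' @export
observation_model <- function(gamma = 0.2, baseline_f0 = 0.95) {
  stopifnot(is.numeric(gamma), gamma >= 0, gamma <= 1,
            is.numeric(baseline_f0), baseline_f0 >= 0, baseline_f0 <= 1)
  structure(list(gamma = gamma, baseline_f0 = baseline_f0),
            class = "observation_model")
}

#' Predict pollen fertility of a multilocus sporophyte genotype
#'
#' For the set of systems active in the sporophyte (see
#' [killer_is_active()]), the non-targeted half of the pollen survives
#' collateral killing with probability `prod(1 - c_m)` and the targeted half
#' survives with probability `prod(s_m)`; the true surviving fraction is
#' `0.5 * prod(1 - c_m) + 0.5 * prod(s_m)` (empty product = 1, i.e. a fully
#' fertile plant). Misscoring raises the observed fraction to
#' `true + gamma * (1 - true)`; both fractions are scaled by `baseline_f0`.
#'
#' @param sporophyte A [sporophyte()] covering all system loci.
#' @param systems List of [killer_system()] objects.
#' @param obs_model An [observation_model()]; default `gamma = 0`,
#'   `baseline_f0 = 1` (no observation distortion).
#' @return List with `true_fraction` and `observed_fraction` in `[0, 1]`,
#'   and `active` (names of active killer loci).
#' @examples
#' sys <- killer_system(locus("S35", "chr1", 3060000), locus("INK", "chr5", 1300000),
#'                      "activator", "J", survival_s = 0.1236)
#' predict_fertility(sporophyte(S35 = "H", INK = "H"), list(sys))
#' @export
predict_fertility <- function(sporophyte, systems,
                              obs_model = observation_model(0, 1)) {
  if (inherits(systems, "killer_system")) systems <- list(systems)
  stopifnot(inherits(obs_model, "observation_model"))
  active <- vapply(systems, killer_is_active, logical(1), sporophyte = sporophyte)
  act <- systems[active]
  surv_nontargeted <- prod(vapply(act, function(s) 1 - s$collateral_c, numeric(1)))
  surv_targeted <- prod(vapply(act, function(s) s$survival_s, numeric(1)))
  true_raw <- 0.5 * surv_nontargeted + 0.5 * surv_targeted
  obs_raw <- true_raw + obs_model$gamma * (1 - true_raw)
  list(
    true_fraction = obs_model$baseline_f0 * true_raw,
    observed_fraction = obs_model$baseline_f0 * obs_raw,
    active = vapply(act, function(s) s$killer$name, character(1))
  )
}

#' Classify a pollen-fertility percentage
#'
#' Fertility classes partition `[0, 100]`%: sterile `[0, 40)`, semisterile
#' `[40, 70)`, partial sterile `[70, 90)`, fertile `[90, 100]`. The upper
#' class owns each boundary (the conventional scoring bands "<40%, 40-70%,
#' 70-90%, >90%" are ambiguous exactly at 40/70/90); boundaries are
#' configurable.
#'
#' @param pct Fertility percentage(s) in `[0, 100]`.
#' @param boundaries Increasing class boundaries, default `c(40, 70, 90)`.
#' @return Factor with levels `sterile < semisterile < partial_sterile <
#'   fertile`.
#' @examples
#' classify_fertility(c(95, 43.1, 77.3))
#' @export
classify_fertility <- function(pct, boundaries = c(40, 70, 90)) {
  stopifnot(is.numeric(pct), length(boundaries) == 3L, !is.unsorted(boundaries))
  if (any(is.na(pct)) || any(pct < 0 | pct > 100))
    stop("pct must lie in [0, 100]")
  cut(pct, breaks = c(-Inf, boundaries, Inf), right = FALSE,
      labels = FERTILITY_CLASSES, ordered_result = TRUE)
}

#' Simulate a stained-pollen count
#'
#' Draws `n_stained ~ Binomial(n_scored, observed_fraction)` where the
#' observed fraction includes misscoring per the observation model.
#'
#' @param true_fraction True surviving-pollen fraction in `[0, 1]` (on the
#'   unscaled scale of [predict_fertility()]'s raw product; `baseline_f0`
#'   and `gamma` are applied here).
#' @param obs_model An [observation_model()].
#' @param n_scored Number of grains scored (> 0; >= 400 recommended).
#' @return List of class `pollen_observation`: `n_scored`, `n_stained`,
#'   `fertility_pct`.
#' @export
sample_pollen_counts <- function(true_fraction, obs_model = observation_model(0, 1),
                                 n_scored = 400L) {
  stopifnot(n_scored > 0, true_fraction >= 0, true_fraction <= 1)
  p <- obs_model$baseline_f0 *
    (true_fraction + obs_model$gamma * (1 - true_fraction))
  n_stained <- stats::rbinom(1L, n_scored, p)
  structure(
    list(n_scored = as.integer(n_scored), n_stained = n_stained,
         fertility_pct = 100 * n_stained / n_scored),
    class = "pollen_observation"
  )
}

#' Seed-set rate
#'
#' Number of filled grains over total filled plus unfilled grains.
#'
#' @param n_filled,n_unfilled Non-negative grain counts; total must be > 0.
#' @return Fraction in `[0, 1]`.
#' @examples
#' seed_set_rate(93, 7) # 0.93
#' @export
seed_set_rate <- function(n_filled, n_unfilled) {
  stopifnot(n_filled >= 0, n_unfilled >= 0)
  if (n_filled + n_unfilled <= 0) stop("total grain count must be positive")
  n_filled / (n_filled + n_unfilled)
}
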