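# Uncertainty budget: six uncorrelated components propagated in quadrature.
#
#   eps_total^2 = eps_v^2 + eps_t^2 + eps_ai^2 + eps_af^2 + eps_ox^2 + eps_sf^2
#
# eps_v  flux-measurement variability (CV of corrected measurements)
# eps_t  temperate/tropical soil-temperature threshold (20.0 +/- 2.5 deg C)
# eps_ai ice-out accumulation lag (60 +/- 15 d)
# eps_af fall-turnover accumulation lag (60 +/- 15 d)
# eps_ox oxidation fraction (swept 0.5-0.99)
# eps_sf large-lake scaling factor (swept 0-0.25)
#
# Threshold/lag components are half the absolute spread of the global total
# across the two endpoint runs; range components are the SD of totals over an
# evenly spaced sweep; eps_v combines per-stratum emission x CV in quadrature.

#' Combine uncertainty components in quadrature
#'
#' @param components Named numeric vector of the six epsilon terms
#'   (Tg CH4 yr^-1), all non-negative.
#' @return List: `components`, `total` (quadrature sum), `shares` (each
#'   component's fraction of the total variance).
#' @export
combine_uncertainty <- function(components) {
  if (any(components < 0)) stop("uncertainty components must be non-negative")
  total <- sqrt(sum(components^2))
  shares <- if (total > 0) components^2 / total^2 else components * 0
  list(components = components, total = total, shares = shares)
}

#' Half-spread epsilon from two endpoint scenario runs
#'
#' @param totals Length-2 numeric: global totals at the parameter's endpoint
#'   values.
#' @return Half the absolute spread (Tg).
#' @export
epsilon_half_spread <- function(totals) {
  stopifnot(length(totals) == 2)
  abs(diff(totals)) / 2
}

#' Sweep-SD epsilon for a range parameter
#'
#' @param totals Totals over an evenly spaced parameter sweep.
#' @return Standard deviation of the totals (Tg).
#' @export
epsilon_sweep_sd <- function(totals) {
  stats::sd(totals)
}

#' Flux-measurement variability epsilon
#'
#' Per-stratum (type x pathway) open-water emissions scaled by the stratum's
#' coefficient of variation of corrected measurements, combined in
#' quadrature across independent strata:
#' `eps_v = sqrt(sum_s (E_s * CV_s)^2)`.
#'
#' @param de_Tg Named list `[[lake_type]][[pathway]]` of open-water
#'   emissions (Tg) from [pipeline_total()] with `breakdown = TRUE`.
#' @param stratum_cv Matching named list of CVs.
#' @return eps_v in Tg.
#' @export
epsilon_flux_variability <- function(de_Tg, stratum_cv) {
  s2 <- 0
  for (ty in names(de_Tg)) {
    for (pw in names(de_Tg[[ty]])) {
      cv <- stratum_cv[[ty]][[pw]]
      if (is.null(cv) || !is.finite(cv)) cv <- 0
      s2 <- s2 + (de_Tg[[ty]][[pw]] * cv)^2
    }
  }
  sqrt(s2)
}

#' Propagate the six-component uncertainty budget for a world
#'
#' Runs the scenario propagation on a prepared pipeline state: endpoint runs
#' for the temperate/tropical threshold (+/- 2.5 deg C) and the two
#' accumulation lags (+/- 15 d), 11-point sweeps for the oxidation fraction
#' (0.5-0.99, applied to both spring and fall) and the large-lake factor
#' (0-0.25), and the measurement-variability term from per-stratum CVs.
#'
#' @param state A `pipeline_state` from [prepare_pipeline()], or a
#'   `synthetic_world` (then prepared internally with `config`).
#' @param config Pipeline config (used only when `state` is a world).
#' @param n_sweep Points in each range sweep (default 11).
#' @return List: `baseline_Tg`, `components` (named, Tg), `total`, `shares`.
#' @export
propagate_uncertainty <- function(state, config = pipeline_config(),
                                  n_sweep = 11) {
  if (!inherits(state, "pipeline_state")) state <- prepare_pipeline(state, config)
  base <- pipeline_total(state, breakdown = TRUE)

  eps_t <- epsilon_half_spread(c(pipeline_total(state, t_trop = 17.5),
                                 pipeline_total(state, t_trop = 22.5)))
  eps_ai <- epsilon_half_spread(c(pipeline_total(state, lag_spring = 45),
                                  pipeline_total(state, lag_spring = 75)))
  eps_af <- epsilon_half_spread(c(pipeline_total(state, lag_fall = 45),
                                  pipeline_total(state, lag_fall = 75)))
  ox_grid <- seq(0.5, 0.99, length.out = n_sweep)
  eps_ox <- epsilon_sweep_sd(vapply(ox_grid, function(o)
    pipeline_total(state, ox_spring = o, ox_fall = o), numeric(1)))
  sf_grid <- seq(0, 0.25, length.out = n_sweep)
  eps_sf <- epsilon_sweep_sd(vapply(sf_grid, function(s)
    pipeline_total(state, scale_large = s), numeric(1)))
  eps_v <- epsilon_flux_variability(base$de_Tg, state$stratum_cv)

  comp <- c(eps_v = eps_v, eps_t = eps_t, eps_ai = eps_ai, eps_af = eps_af,
            eps_ox = eps_ox, eps_sf = eps_sf)
  out <- combine_uncertainty(comp)
  out$baseline_Tg <- base$total_Tg
  out
}

#' Monte-Carlo cross-check of the quadrature propagation
#'
#' Samples all perturbed parameters jointly (threshold and lags uniform on
#' their stated ranges, oxidation uniform on 0.5-0.99, large-lake factor
#' uniform on 0-0.25, and per-stratum flux multipliers normal with the
#' stratum CV, truncated at zero) and returns the SD of the resulting global
#' totals for comparison with the quadrature total.
#'
#' @param state A `pipeline_state`.
#' @param n Number of draws (default 1000).
#' @param seed RNG seed.
#' @return List: `sd_Tg`, `mean_Tg`, `totals`.
#' @export
monte_carlo_uncertainty <- function(state, n = 1000, seed = 1) {
  set.seed(seed)
  types <- names(state$curves$curves)
  totals <- vapply(seq_len(n), function(i) {
    fm <- lapply(stats::setNames(types, types), function(ty) {
      lapply(stats::setNames(c("diffusion", "ebullition"),
                             c("diffusion", "ebullition")), function(pw) {
        cv <- state$stratum_cv[[ty]][[pw]]
        if (is.null(cv) || !is.finite(cv)) cv <- 0
        max(0, stats::rnorm(1, 1, cv))
      })
    })
    ox <- stats::runif(1, 0.5, 0.99)
    pipeline_total(state,
                   t_trop = stats::runif(1, 17.5, 22.5),
                   lag_spring = stats::runif(1, 45, 75),
                   lag_fall = stats::runif(1, 45, 75),
                   ox_spring = ox, ox_fall = ox,
                   flux_multiplier = fm,
                   scale_large = stats::runif(1, 0, 0.25))
  }, numeric(1))
  list(sd_Tg = stats::sd(totals), mean_Tg = mean(totals), totals = totals)
}
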