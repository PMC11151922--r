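# Synthetic two-trophic metacommunity generator.
#
# Causal structure: correlated multi-year flower abundances per plant
# species and site -> pollinator visits driven by floral availability and
# per-pollinator preferences -> fruit set as a saturating function of visits
# per flower. Every knob maps to a quantity the partition pipeline is meant
# to recover: the exchangeable correlations set species and spatial
# synchrony, taylor_b sets the mean-variance scaling exponent, and the
# saturating response couples the trophic levels.
#
# Annual abundances are generated on the log scale (positive, right-skewed,
# as count-like ecological data are), with the log-normal moments matched so
# the raw-scale mean is mu_s and the raw-scale SD is c * mu_s^taylor_b
# before rounding. The closed-form synchrony targets of expected_synchrony()
# are exact for the underlying Gaussian field and approximate after
# exponentiation and rounding.

#' Configuration for the synthetic metacommunity generator
#'
#' Defaults emulate the motivating field design: a Mediterranean shrubland
#' metacommunity of 5 woodland sites surveyed over 8 biweekly rounds per
#' flowering season for 2 years, with fruit set scored on 8 focal shrub
#' species from ~7 marked individuals per plant-site-year.
#'
#' @param S Number of plant species.
#' @param A Number of pollinator species.
#' @param M Number of sites (patches).
#' @param T Number of years.
#' @param R Sampling rounds per year.
#' @param rho_species Within-site between-species correlation of log
#'   abundance fluctuations, in `[0, 1)`.
#' @param rho_spatial Between-site correlation of the same species' log
#'   fluctuations, in `[0, 1)`.
#' @param mu_range Length-2 positive range from which species mean annual
#'   flower abundances are drawn log-uniformly.
#' @param taylor_b Target mean-variance scaling exponent: raw-scale species
#'   SD is proportional to `mean^taylor_b`.
#' @param cv_ref Coefficient of variation at the reference (geometric mean)
#'   abundance; sets the proportionality constant of the scaling law.
#' @param preference_concentration Dirichlet concentration shaping each
#'   pollinator's preference vector over plants (small = specialized,
#'   large = uniform).
#' @param visit_rate Expected visits per flower per round for a pollinator
#'   with uniform preference and average activity.
#' @param halfsat Half-saturation point of the fruit-set response, in annual
#'   visits per flower.
#' @param fruitset_max Asymptotic fruit set, in `(0, 1]`.
#' @param noise_sd SD of the logit-scale individual noise on fruit set.
#' @param n_individuals Marked individuals per plant-site-year.
#' @param n_subplots Subplots per site over which observations are scattered.
#' @param count_model `"round"` (default): continuous log-normal abundances
#'   rounded to counts, so `taylor_b` is controlled exactly up to rounding;
#'   `"poisson"`: i.i.d. Poisson counts with time-constant rates, so the
#'   temporal variance equals the temporal mean by construction (scaling
#'   exponent 0.5 under the sd-vs-mean convention).
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(S = 8L, A = 12L, M = 5L, T = 2L, R = 8L,
                         rho_species = 0.3, rho_spatial = 0.3,
                         mu_range = c(5, 100),
                         taylor_b = 0.5, cv_ref = 0.35,
                         preference_concentration = 1,
                         visit_rate = 0.05, halfsat = 0.5,
                         fruitset_max = 0.8, noise_sd = 0.3,
                         n_individuals = 7L, n_subplots = 400L,
                         count_model = c("round", "poisson"),
                         seed = 1L) {
  count_model <- match.arg(count_model)
  cfg <- list(S = as.integer(S), A = as.integer(A), M = as.integer(M),
              T = as.integer(T), R = as.integer(R),
              rho_species = rho_species, rho_spatial = rho_spatial,
              mu_range = as.numeric(mu_range), taylor_b = taylor_b,
              cv_ref = cv_ref,
              preference_concentration = preference_concentration,
              visit_rate = visit_rate, halfsat = halfsat,
              fruitset_max = fruitset_max, noise_sd = noise_sd,
              n_individuals = as.integer(n_individuals),
              n_subplots = as.integer(n_subplots),
              count_model = count_model, seed = as.integer(seed))
  with(cfg, {
    stopifnot(S >= 1, A >= 1, M >= 1, T >= 2, R >= 1,
              n_individuals >= 1, n_subplots >= 1,
              rho_species >= 0, rho_species < 1,
              rho_spatial >= 0, rho_spatial < 1,
              length(mu_range) == 2, all(mu_range > 0),
              mu_range[1] <= mu_range[2],
              cv_ref > 0, visit_rate >= 0, halfsat > 0,
              fruitset_max > 0, fruitset_max <= 1, noise_sd >= 0)
  })
  structure(cfg, class = "synth_config")
}

species_means <- function(cfg) {
  lo <- cfg$mu_range[1]; hi <- cfg$mu_range[2]
  if (lo == hi) rep(lo, cfg$S) else exp(runif(cfg$S, log(lo), log(hi)))
}

# Exchangeable-correlation Gaussian field Z[s, m, t] with unit variance:
# var components g (global), w (site), u (species), e (idiosyncratic) chosen
# so that corr(species pairs within a site) = rho_species and corr(same
# species across sites) = rho_spatial (separable structure).
correlated_field <- function(cfg) {
  g <- cfg$rho_species * cfg$rho_spatial
  w <- cfg$rho_species * (1 - cfg$rho_spatial)
  u <- cfg$rho_spatial * (1 - cfg$rho_species)
  e <- (1 - cfg$rho_species) * (1 - cfg$rho_spatial)
  S <- cfg$S; M <- cfg$M; T <- cfg$T
  G <- rnorm(T)
  W <- matrix(rnorm(M * T), M, T)
  U <- matrix(rnorm(S * T), S, T)
  E <- array(rnorm(S * M * T), c(S, M, T))
  Z <- array(0, c(S, M, T))
  for (t in seq_len(T)) {
    Z[, , t] <- sqrt(g) * G[t] +
      sqrt(w) * matrix(W[, t], S, M, byrow = TRUE) +
      sqrt(u) * matrix(U[, t], S, M) +
      sqrt(e) * E[, , t]
  }
  Z
}

#' Simulate annual flower counts and scatter them over rounds and subplots
#'
#' Generates correlated multi-year flower abundances per plant species and
#' site and returns them as a long-format flowers survey table. Species mean
#' abundances are drawn log-uniformly from `mu_range`; per-species raw-scale
#' SD follows `sd = c * mean^taylor_b` with `c` anchored by `cv_ref`. The
#' annual total of each (species, site, year) is split multinomially over
#' the `R` rounds and recorded in the subplot where that population sits
#' (one fixed subplot per species-site, as for sessile shrubs).
#'
#' @param config A [synth_config()].
#' @return A `survey_table` of kind `"flowers"`. Zero-count rows are
#'   omitted, exactly as on a field sheet; the downstream tensor zero-fills
#'   them.
#' @export
simulate_flowers <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  S <- config$S; M <- config$M; T <- config$T; R <- config$R
  mu <- species_means(config)

  if (config$count_model == "poisson") {
    N <- array(rpois(S * M * T, lambda = rep(mu, M * T)), c(S, M, T))
  } else {
    mu_ref <- exp(mean(log(config$mu_range)))
    cc <- config$cv_ref * mu_ref^(1 - config$taylor_b)
    sd_target <- cc * mu^config$taylor_b
    sigma2 <- log(1 + (sd_target / mu)^2)        # log-normal moment match
    Z <- correlated_field(config)
    N <- array(0, c(S, M, T))
    for (s in seq_len(S)) {
      N[s, , ] <- exp(log(mu[s]) - sigma2[s] / 2 + sqrt(sigma2[s]) * Z[s, , ])
    }
    N <- round(N)
  }

  home_subplot <- matrix(sample.int(config$n_subplots, S * M, replace = TRUE),
                         S, M)
  cells <- which(N > 0, arr.ind = TRUE)   # columns: unit, patch, time
  if (nrow(cells) == 0) {
    return(as_survey_table(
      tibble(year = integer(), round = integer(), site = character(),
             subplot = integer(), plant = character(), count = integer()),
      "flowers", quiet = TRUE))
  }
  if (R == 1) {
    scat <- cbind(cell = seq_len(nrow(cells)), round = 1L,
                  count = N[cells])
  } else {
    scat <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      pr <- as.vector(rmultinom(1, N[cells[i, , drop = FALSE]], rep(1 / R, R)))
      keep <- which(pr > 0)
      cbind(cell = i, round = keep, count = pr[keep])
    }))
  }
  ci <- cells[scat[, "cell"], , drop = FALSE]
  out <- tibble(
    year = 2019L + ci[, 3],
    round = scat[, "round"],
    site = sprintf("site%02d", ci[, 2]),
    subplot = home_subplot[ci[, c(1, 2), drop = FALSE]],
    plant = sprintf("plant%02d", ci[, 1]),
    count = scat[, "count"])
  as_survey_table(out, "flowers", quiet = TRUE)
}

#' Simulate pollinator visits given a flowers table
#'
#' Each pollinator species gets a Dirichlet-distributed preference vector
#' over plants (`preference_concentration` controls specialization) and a
#' log-normal activity fluctuation per site-year. Expected visits of
#' pollinator `a` to a flower record are
#' `visit_rate * count * S * preference(a, plant) * activity(a, site, year)`
#' (the factor `S` makes `visit_rate` a per-flower rate for a uniform
#' preference of `1/S`); realized visits are Poisson.
#'
#' @param config A [synth_config()].
#' @param flowers A flowers `survey_table`, normally from
#'   [simulate_flowers()] with the same config.
#' @return A `survey_table` of kind `"visits"` (zero-visit rows omitted).
#' @export
simulate_visits <- function(config, flowers) {
  stopifnot(inherits(config, "synth_config"))
  stopifnot(identical(survey_kind(flowers), "flowers"))
  set.seed(config$seed + 1L)
  S <- config$S; A <- config$A

  plants <- sprintf("plant%02d", seq_len(S))
  pollinators <- sprintf("poll%02d", seq_len(A))
  pref <- matrix(rgamma(A * S, shape = config$preference_concentration), A, S)
  pref <- pref / rowSums(pref)
  colnames(pref) <- plants
  rownames(pref) <- pollinators

  if (nrow(flowers) == 0 || config$visit_rate == 0) {
    return(as_survey_table(
      tibble(year = integer(), round = integer(), site = character(),
             subplot = integer(), plant = character(),
             pollinator = character(), visits = integer()),
      "visits", quiet = TRUE))
  }

  sites <- sort(unique(flowers$site))
  years <- sort(unique(flowers$year))
  # activity[a, site, year]: log-normal, mean 1
  act <- array(exp(rnorm(A * length(sites) * length(years), -0.125, 0.5)),
               c(A, length(sites), length(years)),
               dimnames = list(pollinators, sites, as.character(years)))

  fl <- tibble::as_tibble(unclass_survey(flowers))
  expanded <- tidyr::crossing(fl, pollinator = pollinators) |>
    mutate(lambda = config$visit_rate * .data$count * S *
             pref[cbind(.data$pollinator, .data$plant)] *
             act[cbind(.data$pollinator, .data$site, as.character(.data$year))],
           visits = rpois(dplyr::n(), .data$lambda)) |>
    filter(.data$visits > 0) |>
    select("year", "round", "site", "subplot", "plant", "pollinator", "visits")
  as_survey_table(expanded, "visits", quiet = TRUE)
}

#' Simulate fruit set from realized visitation
#'
#' Per plant-site-year, the expected fruit set follows a saturating
#' (Michaelis-Menten) response to annual visits per flower `v`:
#' `fruitset_max * v / (v + halfsat)`. For each of `n_individuals` marked
#' individuals, a flowers-marked total is drawn and fruits are binomial
#' around the expectation with logit-scale noise (`noise_sd`); fruits never
#' exceed flowers marked. Plant-site-years with no flowers produce no
#' individuals (the fruit-set cell stays missing, not zero).
#'
#' @param config A [synth_config()].
#' @param visits A visits `survey_table` from [simulate_visits()].
#' @param flowers The flowers `survey_table` the visits were generated from
#'   (needed to express visitation per flower).
#' @return A `survey_table` of kind `"fruitset"`.
#' @export
simulate_fruitset <- function(config, visits, flowers) {
  stopifnot(inherits(config, "synth_config"))
  stopifnot(identical(survey_kind(visits), "visits"),
            identical(survey_kind(flowers), "flowers"))
  set.seed(config$seed + 2L)

  fl <- tibble::as_tibble(unclass_survey(flowers)) |>
    group_by(.data$plant, .data$site, .data$year) |>
    summarise(flowers = sum(.data$count), .groups = "drop")
  vi <- tibble::as_tibble(unclass_survey(visits)) |>
    group_by(.data$plant, .data$site, .data$year) |>
    summarise(visits = sum(.data$visits), .groups = "drop")
  cells <- fl |>
    left_join(vi, by = c("plant", "site", "year")) |>
    mutate(visits = tidyr::replace_na(.data$visits, 0L)) |>
    filter(.data$flowers > 0) |>
    mutate(v_per_flower = .data$visits / .data$flowers,
           p = config$fruitset_max * .data$v_per_flower /
             (.data$v_per_flower + config$halfsat))

  n_ind <- config$n_individuals
  eps <- 1e-9
  out <- cells |>
    tidyr::uncount(n_ind, .id = "individual") |>
    mutate(flowers_marked = 1L + rpois(dplyr::n(), 9),
           p_i = ifelse(.data$p <= 0, 0,
                        plogis(qlogis(pmin(pmax(.data$p, eps), 1 - eps)) +
                                 rnorm(dplyr::n(), 0, config$noise_sd))),
           fruits = rbinom(dplyr::n(), .data$flowers_marked, .data$p_i),
           individual = paste(.data$plant, .data$site, .data$year,
                              .data$individual, sep = "_")) |>
    select("year", "site", "plant", "individual", "flowers_marked", "fruits")
  as_survey_table(out, "fruitset", quiet = TRUE)
}

#' Simulate a complete survey dataset
#'
#' Runs [simulate_flowers()], [simulate_visits()] and [simulate_fruitset()]
#' in sequence; all randomness is derived from `config$seed`, so the same
#' config reproduces the same three tables.
#'
#' @param config A [synth_config()].
#' @return A list with elements `flowers`, `visits`, `fruitset` (three
#'   `survey_table`s) and `config`.
#' @examples
#' dat <- simulate_metacommunity(synth_config(seed = 42))
#' sapply(dat[1:3], nrow)
#' @export
simulate_metacommunity <- function(config = synth_config()) {
  flowers <- simulate_flowers(config)
  visits <- simulate_visits(config, flowers)
  fruitset <- simulate_fruitset(config, visits, flowers)
  list(flowers = flowers, visits = visits, fruitset = fruitset,
       config = config)
}

#' Ground-truth synchrony implied by a generator configuration
#'
#' Closed-form large-`T` expectations on the log-fluctuation scale for
#' equal-SD species: species synchrony
#' `sqrt((1 + (S - 1) * rho_species) / S)` and spatial synchrony
#' `sqrt((1 + (M - 1) * rho_spatial) / M)`. These are exact for the
#' underlying Gaussian field and approximate for the realized counts after
#' exponentiation and rounding; recovery tests use an absolute tolerance
#' accordingly.
#'
#' @param config A [synth_config()].
#' @return A tibble with columns `phi_species` and `phi_spatial`.
#' @export
expected_synchrony <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  tibble(
    phi_species = sqrt((1 + (config$S - 1) * config$rho_species) / config$S),
    phi_spatial = sqrt((1 + (config$M - 1) * config$rho_spatial) / config$M)
  )
}
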