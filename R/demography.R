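#' Vital rates of the tiger population
#'
#' Bundles the stage-structured vital rates used by the simulation, with
#' defaults from long-term field studies of tigers (largely Chitwan National
#' Park): annual survival by class, annual breeding probabilities of resident
#' females, the litter-size distribution, the birth sex ratio, gestation,
#' infanticide probabilities following a male takeover, death probabilities in
#' male challenges, and the female-female cell take-over probability.
#'
#' The model ticks monthly; annual survival `s` is applied as the monthly
#' probability `s^(1/12)` and an annual breeding probability `P` as the
#' monthly hazard `1 - (1 - P)^(1/12)`.
#'
#' @param annual_survival named vector of annual survival rates.
#' @param breed_prob_age3,breed_prob_age4plus annual probability that a
#'   3-year-old (resp. 4+) resident female breeds.
#' @param litter_sizes,litter_probs litter-size distribution.
#' @param female_birth_prob probability a newborn is female.
#' @param gestation_months possible gestation lengths, drawn uniformly.
#' @param infanticide_prob_cub,infanticide_prob_juvenile probability a cub
#'   (resp. juvenile) dies by infanticide after its mother's range is taken
#'   over by a new male.
#' @param challenge_death_transient,challenge_death_breeder probability that a
#'   transient/dispersing (resp. breeding) male dies after losing a challenge.
#' @param conception_block_age months during which a living offspring blocks
#'   its mother's next conception. The default of 18 reproduces the observed
#'   interbirth interval of about 21.6 months in Chitwan (18 months plus the
#'   3-4 month gestation); offspring remain in the natal territory, and die
#'   with their mother, until 24 months.
#' @param female_takeover_prob per-tick probability that the dominant of two
#'   adjacent females takes one territory cell from the subordinate.
#' @param age_win_slope slope (per year of age difference) of the logistic
#'   probability that the older/challenging animal wins an age-based contest.
#' @return an object of class `vital_rates`.
#' @export
vital_rates <- function(
    annual_survival = c(breeding_male = 0.8, breeding_female = 0.9,
                        dispersal_male = 0.65, transient_male = 0.65,
                        transient_female = 0.7, juvenile = 0.9, cub = 0.6),
    breed_prob_age3 = 0.9, breed_prob_age4plus = 1,
    litter_sizes = 2:5, litter_probs = c(0.23, 0.58, 0.17, 0.02),
    female_birth_prob = 0.5,
    gestation_months = c(3L, 4L),
    infanticide_prob_cub = 0.79, infanticide_prob_juvenile = 0.24,
    challenge_death_transient = 0.25, challenge_death_breeder = 0.6,
    conception_block_age = 18L,
    female_takeover_prob = 0.25,
    age_win_slope = 0.5) {
  if (abs(sum(litter_probs) - 1) > 1e-9)
    stop("litter_probs must sum to 1")
  probs <- c(annual_survival, breed_prob_age3, breed_prob_age4plus,
             litter_probs, female_birth_prob, infanticide_prob_cub,
             infanticide_prob_juvenile, challenge_death_transient,
             challenge_death_breeder, female_takeover_prob)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  vr <- list(annual_survival = annual_survival,
             monthly_survival = vapply(annual_survival,
                                       monthly_survival_probability, 0),
             breed_prob_age3 = breed_prob_age3,
             breed_prob_age4plus = breed_prob_age4plus,
             monthly_conception_age3 = monthly_conception_probability(breed_prob_age3),
             monthly_conception_age4plus = monthly_conception_probability(breed_prob_age4plus),
             litter_sizes = litter_sizes, litter_probs = litter_probs,
             female_birth_prob = female_birth_prob,
             gestation_months = gestation_months,
             infanticide_prob_cub = infanticide_prob_cub,
             infanticide_prob_juvenile = infanticide_prob_juvenile,
             challenge_death_transient = challenge_death_transient,
             challenge_death_breeder = challenge_death_breeder,
             conception_block_age = as.integer(conception_block_age),
             female_takeover_prob = female_takeover_prob,
             age_win_slope = age_win_slope)
  structure(vr, class = "vital_rates")
}

#' Monthly survival from an annual rate
#'
#' `annual^(1/12)`: applying the monthly rate 12 times reproduces the annual
#' rate, the natural conversion for a monthly tick.
#'
#' @param annual annual survival probability in `[0, 1]`.
#' @export
monthly_survival_probability <- function(annual) {
  if (any(annual < 0 | annual > 1)) stop("annual survival must lie in [0, 1]")
  annual^(1 / 12)
}

#' Monthly conception hazard from an annual breeding probability
#'
#' `1 - (1 - annual)^(1/12)`; an annual probability of 1 gives a monthly
#' hazard of 1.
#'
#' @param annual annual breeding probability in `[0, 1]`.
#' @export
monthly_conception_probability <- function(annual) {
  if (any(annual < 0 | annual > 1)) stop("annual probability must lie in [0, 1]")
  1 - (1 - annual)^(1 / 12)
}

#' Stage class from age in months
#'
#' Cub below 12 months, juvenile 12–23, transient 24–35, breeding age from 36
#' months (3 years).
#'
#' @param age_months age(s) in months.
#' @return character vector: `"cub"`, `"juvenile"`, `"transient"`, `"breeder"`.
#' @export
stage_of <- function(age_months) {
  cut(age_months, breaks = c(-1, 11, 23, 35, Inf),
      labels = c("cub", "juvenile", "transient", "breeder")) |> as.character()
}

#' Draw a litter: size and sexes
#'
#' Size from the empirical litter-size distribution (sizes 2–5; singletons do
#' not occur), each sex an independent fair draw at the default 50:50 birth
#' sex ratio.
#'
#' @param vr a [vital_rates()].
#' @return list with `size` and `sexes` (`"F"`/`"M"` character vector).
#' @export
draw_litter <- function(vr = vital_rates()) {
  size <- sample(vr$litter_sizes, 1, prob = vr$litter_probs)
  sexes <- ifelse(runif(size) < vr$female_birth_prob, "F", "M")
  list(size = size, sexes = sexes)
}

#' Infanticide draws for the offspring of taken-over females
#'
#' After a new male takes over a female's range, each of her dependent
#' offspring dies independently: cubs (under 12 months) with probability
#' 0.79, juveniles with probability 0.24.
#'
#' @param ages_months ages of the dependent offspring.
#' @param vr a [vital_rates()].
#' @return logical vector: which offspring die.
#' @export
infanticide_deaths <- function(ages_months, vr = vital_rates()) {
  p <- ifelse(ages_months < 12, vr$infanticide_prob_cub,
              vr$infanticide_prob_juvenile)
  runif(length(ages_months)) < p
}

#' Probability that the focal animal wins an age-based contest
#'
#' Logistic in the age difference (years): `1 / (1 + exp(-k * d_age))` with
#' slope `k = age_win_slope`. Monotone in age, symmetric and bounded.
#'
#' @param age_months,opponent_age_months ages in months.
#' @param vr a [vital_rates()].
#' @export
age_win_probability <- function(age_months, opponent_age_months,
                                vr = vital_rates()) {
  d <- (age_months - opponent_age_months) / 12
  1 / (1 + exp(-vr$age_win_slope * d))
}
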