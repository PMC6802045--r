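#' Female energetic intake rule
#'
#' A female utilizes a fixed proportion (default 0.1) of the prey biomass
#' production inside her territory. The minimum threshold (basal metabolic
#' rate, 76 kg/month = 2.5 kg/day) defines starvation; the maximum threshold
#' (satiation, 167.3 kg/month = 5.5 kg/day) is the default growth target: a
#' female keeps enlarging her territory (at most 48 cells = 3 km^2 per month)
#' until her intake reaches it.
#'
#' @param utilization proportion of within-territory prey utilized.
#' @param t_min minimum intake threshold, kg/month.
#' @param t_max maximum intake threshold, kg/month.
#' @param growth_target `"max"` (grow until intake reaches `t_max`, the
#'   default) or `"min"` (stop at `t_min`).
#' @param max_cells_per_tick cells a female can add (or swap) per month.
#' @param territory_cap hard cap on territory size, cells.
#' @return an object of class `intake_rule`.
#' @export
intake_rule <- function(utilization = 0.1,
                        t_min = prey_threshold_monthly(2.5),
                        t_max = prey_threshold_monthly(5.5),
                        growth_target = c("max", "min"),
                        max_cells_per_tick = 48L,
                        territory_cap = 960L) {
  if (utilization <= 0 || utilization > 1)
    stop("utilization must be in (0, 1]")
  if (t_min >= t_max) stop("t_min must be below t_max")
  structure(list(utilization = utilization, t_min = t_min, t_max = t_max,
                 growth_target = match.arg(growth_target),
                 max_cells_per_tick = as.integer(max_cells_per_tick),
                 territory_cap = as.integer(territory_cap)),
            class = "intake_rule")
}

#' Monthly prey threshold from a daily consumption rate
#'
#' `(kg/day * 365) / 12`: 2.5 kg/day (basal metabolic rate of a female
#' Bengal tiger) gives 76.04 kg/month and 5.5 kg/day gives 167.3 kg/month.
#'
#' @param kg_per_day daily prey consumption, kg.
#' @return kg/month.
#' @export
prey_threshold_monthly <- function(kg_per_day) kg_per_day * 365 / 12

#' Effective monthly intake of a territory
#'
#' @param prey_sum total prey biomass production of the territory cells,
#'   kg/month (or a territory result carrying `$sum`).
#' @param rule an [intake_rule()].
#' @return utilization-scaled intake, kg/month.
#' @export
effective_intake <- function(prey_sum, rule = intake_rule()) {
  if (is.list(prey_sum)) prey_sum <- prey_sum$sum
  rule$utilization * prey_sum
}

# prey sum a growing female aims for (on the utilization-scaled ladder)
growth_target_sum <- function(rule) {
  tgt <- if (rule$growth_target == "max") rule$t_max else rule$t_min
  tgt / rule$utilization
}

#' Search for a territory origin cell
#'
#' A newly mature (36-month) female inspects all free inside cells within 33
#' km of her natal cell and picks the one with the highest mean prey over its
#' 8-neighbourhood (plus itself) that has no cell of another female's
#' territory within 2 km — enough open space to establish a territory without
#' immediate competition. If no cell qualifies she relaxes the exclusion to
#' 1 km; if still none, she fails (and, in the simulation, dies — the
#' landscape is too crowded for her to feed herself). Exact ties are broken
#' uniformly at random.
#'
#' @param grid a [landscape_grid()].
#' @param occ integer occupancy vector (0 = free, otherwise owning female id).
#' @param natal natal cell index.
#' @param score optional per-cell suitability score; defaults to the
#'   neighbourhood mean prey.
#' @param search_radius,excl_primary,excl_secondary radii in metres.
#' @return the chosen cell index, or `NA` if none qualifies.
#' @export
find_territory_origin <- function(grid, occ, natal, score = NULL,
                                  search_radius = 33000,
                                  excl_primary = 2000,
                                  excl_secondary = 1000) {
  if (is.null(score))
    score <- cpp_neigh_mean(grid$prey, grid$mask, grid$nrow, grid$ncol)
  for (excl in c(excl_primary, excl_secondary)) {
    cand <- cpp_origin_candidates(occ, score, grid$mask, grid$nrow, grid$ncol,
                                  natal, search_radius / grid$cell_side,
                                  excl / grid$cell_side)
    if (length(cand) > 0)
      return(if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)])
  }
  NA_integer_
}

#' Grow a female territory towards her intake target
#'
#' Greedily adds the free adjoining inside cell with the highest prey biomass
#' production, at most `max_cells_per_tick` (48) cells per call, stopping when
#' the utilization-scaled intake reaches the growth target, the territory cap
#' is hit, or no free adjoining cell remains (`blocked`). The occupancy
#' vector is updated in place.
#'
#' @param grid a [landscape_grid()].
#' @param occ occupancy vector, modified in place.
#' @param cells current territory cell indices.
#' @param owner owning female id.
#' @param rule an [intake_rule()].
#' @param prey_sum current territory prey sum (computed if omitted).
#' @param target_sum prey-sum target; defaults to the rule's growth target.
#' @return list with `cells`, `added`, `sum`, `blocked`.
#' @export
grow_territory <- function(grid, occ, cells, owner, rule = intake_rule(),
                           prey_sum = sum(grid$prey[cells]),
                           target_sum = growth_target_sum(rule)) {
  cpp_grow(occ, grid$prey, grid$mask, grid$nrow, grid$ncol,
           as.integer(cells), as.integer(owner), rule$max_cells_per_tick,
           target_sum, prey_sum, rule$territory_cap)
}

#' Adjust a territory by swapping low-prey cells for better neighbours
#'
#' While a free adjoining cell holds strictly more prey than the territory's
#' lowest-prey removable cell (origin excluded; removal must keep the
#' territory 8-connected), drop the low cell and add the better one. Bounded
#' by 48 changed cells (24 swaps) per call; each swap strictly increases the
#' territory prey sum, so intake never drops. The occupancy vector is updated
#' in place.
#'
#' @inheritParams grow_territory
#' @param origin the territory origin cell (never dropped).
#' @return list with `cells`, `sum`, `swaps`.
#' @export
adjust_territory <- function(grid, occ, cells, owner, origin,
                             rule = intake_rule(),
                             prey_sum = sum(grid$prey[cells])) {
  cpp_adjust(occ, grid$prey, grid$mask, grid$nrow, grid$ncol,
             as.integer(cells), as.integer(owner), as.integer(origin),
             rule$max_cells_per_tick %/% 2L, prey_sum)
}

#' Shed territory surplus above the maximum intake threshold
#'
#' A female whose intake exceeds the satiation maximum (167.3 kg/month) has
#' no use for the surplus and does not pay the cost of defending it: her
#' lowest-prey removable cells (origin excluded, connectivity preserved) are
#' dropped while intake stays at or above the maximum, bounded by
#' `max_cells_per_tick` drops. The occupancy vector is updated in place.
#'
#' @inheritParams adjust_territory
#' @return list with `cells`, `sum`, `dropped`.
#' @export
trim_territory <- function(grid, occ, cells, owner, origin,
                           rule = intake_rule(),
                           prey_sum = sum(grid$prey[cells])) {
  cpp_trim(occ, grid$prey, grid$nrow, grid$ncol, as.integer(cells),
           as.integer(owner), as.integer(origin),
           rule$t_max / rule$utilization, prey_sum, rule$max_cells_per_tick)
}

#' Contest between two adjacent female territories
#'
#' With probability `female_takeover_prob` (0.25) per contacting pair per
#' tick a contest occurs; the winner is drawn with the age-based logistic
#' probability ([age_win_probability()], older favoured) and takes the
#' loser's highest-prey cell on their shared border — provided the loser's
#' territory stays connected and keeps its origin; otherwise the next-best
#' border cell is taken, or none. The occupancy vector is updated in place.
#'
#' @param grid a [landscape_grid()].
#' @param occ occupancy vector, modified in place.
#' @param a,b lists describing the two females: `id`, `cells`, `origin`,
#'   `age` (months).
#' @param vr a [vital_rates()].
#' @return `NULL` if no transfer, else list with `cell`, `winner`, `loser`.
#' @export
female_challenge <- function(grid, occ, a, b, vr = vital_rates()) {
  if (runif(1) >= vr$female_takeover_prob) return(NULL)
  if (runif(1) >= age_win_probability(a$age, b$age, vr)) {
    tmp <- a; a <- b; b <- tmp
  }
  cell <- cpp_take_border_cell(occ, grid$prey, grid$nrow, grid$ncol,
                               as.integer(b$cells), as.integer(b$origin),
                               as.integer(a$id), as.integer(b$id))
  if (cell == 0) return(NULL)
  list(cell = cell, winner = a$id, loser = b$id)
}

#' Outcome of a male-male challenge
#'
#' The challenger wins with the logistic age-based probability
#' ([age_win_probability()]). The loser dies with the class-appropriate
#' probability: 0.25 for a transient/dispersing male, 0.6 for a breeding
#' male.
#'
#' @param challenger_age,incumbent_age ages in months.
#' @param vr a [vital_rates()].
#' @return list with `win` (challenger won), `challenger_dies`,
#'   `incumbent_dies`.
#' @export
male_challenge_outcome <- function(challenger_age, incumbent_age,
                                   vr = vital_rates()) {
  win <- runif(1) < age_win_probability(challenger_age, incumbent_age, vr)
  if (win) {
    list(win = TRUE, challenger_dies = FALSE,
         incumbent_dies = runif(1) < vr$challenge_death_breeder)
  } else {
    list(win = FALSE,
         challenger_dies = runif(1) < vr$challenge_death_transient,
         incumbent_dies = FALSE)
  }
}

#' Combine female sets after a male takeover, enforcing the 6-female cap
#'
#' The winner keeps his own females plus the loser's, truncated to the
#' maximum of 6; surplus females (chosen at random) are released as unowned.
#'
#' @param winner_females,loser_females integer vectors of female ids.
#' @param cap maximum females per male.
#' @return list with `kept` and `released`.
#' @export
merge_female_sets <- function(winner_females, loser_females, cap = 6L) {
  all_f <- c(winner_females, loser_females)
  if (length(all_f) <= cap) return(list(kept = all_f, released = integer(0)))
  keep_idx <- sample.int(length(all_f), cap)
  list(kept = all_f[keep_idx], released = all_f[-keep_idx])
}
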