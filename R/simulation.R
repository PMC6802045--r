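CAUSES <- c("natural", "starvation", "challenge", "infanticide",
            "dependent_loss", "no_territory")

#' Simulation configuration
#'
#' @param landscape a [landscape_grid()]; defaults to the 1,000 km^2 stylized
#'   circle with uniform prey of 4.84 kg/month/cell.
#' @param n_females,n_males initial breeding-age females and males (14 and 7,
#'   chosen to avoid large initial population cycles).
#' @param burn_in ticks (months) before depletion (200).
#' @param horizon_post ticks after depletion (480 = 40 years).
#' @param depletion a [depletion_spec()], or `NULL` for a control run.
#' @param seed integer seed driving every stochastic element of the run.
#' @param vr a [vital_rates()].
#' @param rule an [intake_rule()].
#' @param search_radius_f,search_radius_m maximum dispersal distance from the
#'   natal range for females (33 km) and males (66 km), metres.
#' @param excl_primary,excl_secondary origin-search exclusion radii (2 km,
#'   1 km).
#' @param male_expand_radius radius in which breeding males search for nearby
#'   unowned breeding females (3 km).
#' @param max_females_per_male cap on female territories a male can overlap.
#' @param init_age_range initial adult ages, months (uniform draw).
#' @param random_p constant probability of the `random` depletion function.
#' @param check_invariants validate the full state after every tick (slow;
#'   used in tests).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(landscape = NULL,
                       n_females = 14L, n_males = 7L,
                       burn_in = 200L, horizon_post = 480L,
                       depletion = NULL, seed = 1L,
                       vr = vital_rates(), rule = intake_rule(),
                       search_radius_f = 33000, search_radius_m = 66000,
                       excl_primary = 2000, excl_secondary = 1000,
                       male_expand_radius = 3000,
                       max_females_per_male = 6L,
                       init_age_range = c(36L, 120L),
                       random_p = 0.5,
                       check_invariants = FALSE) {
  if (burn_in < 0 || horizon_post < 0)
    stop("burn_in and horizon_post must be non-negative")
  if (!is.null(depletion) && !inherits(depletion, "depletion_spec"))
    stop("depletion must be a depletion_spec or NULL")
  structure(list(landscape = landscape, n_females = as.integer(n_females),
                 n_males = as.integer(n_males), burn_in = as.integer(burn_in),
                 horizon_post = as.integer(horizon_post),
                 depletion = depletion, seed = as.integer(seed), vr = vr,
                 rule = rule, search_radius_f = search_radius_f,
                 search_radius_m = search_radius_m,
                 excl_primary = excl_primary,
                 excl_secondary = excl_secondary,
                 male_expand_radius = male_expand_radius,
                 max_females_per_male = as.integer(max_females_per_male),
                 init_age_range = init_age_range, random_p = random_p,
                 check_invariants = isTRUE(check_invariants)),
            class = "sim_config")
}

# ---- internal state helpers -------------------------------------------------

ensure_capacity <- function(st, need) {
  cap <- length(st$a_sex)
  if (need <= cap) return(invisible())
  new_cap <- max(need, 2L * cap)
  grow <- function(v, fill) c(v, rep(fill, new_cap - length(v)))
  st$a_sex <- grow(st$a_sex, 0L)
  st$a_age <- grow(st$a_age, 0L)
  st$a_alive <- grow(st$a_alive, FALSE)
  st$a_mother <- grow(st$a_mother, 0L)
  st$a_natal <- grow(st$a_natal, 0L)
  st$a_gest <- grow(st$a_gest, 0L)
  st$a_origin <- grow(st$a_origin, 0L)
  st$a_cause <- grow(st$a_cause, 0L)
  st$a_death <- grow(st$a_death, NA_integer_)
  st$tsum <- grow(st$tsum, 0)
  st$owner_of <- grow(st$owner_of, 0L)
  st$established <- grow(st$established, FALSE)
  length(st$terr) <- new_cap
  length(st$females_of) <- new_cap
  length(st$lost_to) <- new_cap
  invisible()
}

add_agent <- function(st, sex, age, mother = 0L, natal = 0L) {
  id <- st$n_agents + 1L
  ensure_capacity(st, id)
  st$n_agents <- id
  st$a_sex[id] <- sex
  st$a_age[id] <- as.integer(age)
  st$a_alive[id] <- TRUE
  st$a_mother[id] <- as.integer(mother)
  st$a_natal[id] <- as.integer(natal)
  st$a_gest[id] <- 0L
  st$a_origin[id] <- 0L
  id
}

log_event <- function(st, tick, id, event, cause = 0L) {
  i <- st$ev_n + 1L
  if (i > length(st$ev_tick)) {
    grow <- function(v) c(v, rep(v[1] * 0L, length(v)))
    st$ev_tick <- grow(st$ev_tick)
    st$ev_id <- grow(st$ev_id)
    st$ev_event <- grow(st$ev_event)
    st$ev_cause <- grow(st$ev_cause)
  }
  st$ev_n <- i
  st$ev_tick[i] <- tick
  st$ev_id[i] <- id
  st$ev_event[i] <- event  # 1 birth, 2 death
  st$ev_cause[i] <- cause
  invisible()
}

release_territory <- function(st, id) {
  cells <- st$terr[[id]]
  if (!is.null(cells) && length(cells)) st$occ[cells] <- 0L
  st$terr[id] <- list(NULL)
  st$tsum[id] <- 0
  st$a_origin[id] <- 0L
  invisible()
}

kill_agents <- function(st, ids, cause_code) {
  for (id in ids) {
    if (!st$a_alive[id]) next
    st$a_alive[id] <- FALSE
    st$a_cause[id] <- cause_code
    st$a_death[id] <- st$tick
    st$tick_deaths <- st$tick_deaths + 1L
    if (cause_code %in% c(2L, 6L) && st$a_sex[id] == 1L &&
        st$a_age[id] >= 36L)
      st$tick_starv <- st$tick_starv + 1L
    log_event(st, st$tick, id, 2L, cause_code)
    if (st$a_sex[id] == 1L) {
      if (st$a_origin[id] > 0L) release_territory(st, id)
      own <- st$owner_of[id]
      if (own > 0L) {
        st$females_of[[own]] <- setdiff(st$females_of[[own]], id)
        st$owner_of[id] <- 0L
      }
    } else {
      fs <- st$females_of[[id]]
      if (!is.null(fs) && length(fs)) st$owner_of[fs] <- 0L
      st$females_of[id] <- list(NULL)
    }
  }
  invisible()
}

dependents_of <- function(st, mothers) {
  dep <- which(st$a_alive[seq_len(st$n_agents)] &
                 st$a_age[seq_len(st$n_agents)] < 24L &
                 st$a_mother[seq_len(st$n_agents)] %in% mothers)
  dep
}

# counts per mother of living offspring young enough to block conception
dependent_counts <- function(st) {
  n <- st$n_agents
  block <- st$cfg$vr$conception_block_age
  idx <- which(st$a_alive[seq_len(n)] & st$a_age[seq_len(n)] < block &
                 st$a_mother[seq_len(n)] > 0L)
  tabulate(st$a_mother[idx], nbins = n)
}

shuffled <- function(x) if (length(x) <= 1L) x else x[sample.int(length(x))]

# ---- initialization ---------------------------------------------------------

#' Initialize a simulation state
#'
#' Seeds the RNG, places the initial breeding-age females (each draws a
#' random natal cell, then runs the territory-origin search) and males (at
#' randomly chosen female origins), with ages uniform on the configured
#' range. Females hold only their origin cell at tick 0; territories grow in
#' the first ticks.
#'
#' @param config a [sim_config()].
#' @return a simulation state (environment of class `tiger_state`).
#' @export
sim_init <- function(config) {
  grid <- config$landscape
  if (is.null(grid)) grid <- make_circle_landscape(1000, 4.84)
  if (!inherits(grid, "landscape_grid")) stop("landscape must be a landscape_grid")
  if (total_prey(grid) <= 0)
    stop("infeasible landscape: total prey is zero")
  set.seed(config$seed)
  st <- new.env(parent = emptyenv())
  class(st) <- "tiger_state"
  st$cfg <- config
  st$grid <- grid
  st$score <- cpp_neigh_mean(grid$prey, grid$mask, grid$nrow, grid$ncol)
  st$occ <- integer(grid$nrow * grid$ncol)
  st$tick <- 0L
  st$tick_deaths <- 0L
  st$tick_starv <- 0L
  st$n_agents <- 0L
  st$a_sex <- integer(0); st$a_age <- integer(0); st$a_alive <- logical(0)
  st$a_mother <- integer(0); st$a_natal <- integer(0); st$a_gest <- integer(0)
  st$a_origin <- integer(0); st$a_cause <- integer(0)
  st$a_death <- integer(0)
  st$tsum <- numeric(0); st$owner_of <- integer(0)
  st$established <- logical(0)
  st$terr <- list(); st$females_of <- list(); st$lost_to <- list()
  ensure_capacity(st, 256L)
  st$ev_n <- 0L
  st$ev_tick <- integer(1024L); st$ev_id <- integer(1024L)
  st$ev_event <- integer(1024L); st$ev_cause <- integer(1024L)
  st$morans_i <- NA_real_
  st$times_depleted <- NULL
  total <- config$burn_in + config$horizon_post
  st$series <- matrix(0, nrow = total, ncol = 13,
                      dimnames = list(NULL, c(
                        "tick", "n_total", "n_cub", "n_juvenile",
                        "n_transient", "n_adult_f", "n_adult_m",
                        "n_breeding_m", "adult_f_start", "starv_f",
                        "births", "deaths", "total_prey")))
  ages <- config$init_age_range
  for (i in seq_len(config$n_females)) {
    natal <- grid$inside[sample.int(length(grid$inside), 1)]
    id <- add_agent(st, 1L, sample(ages[1]:ages[2], 1), natal = natal)
    origin <- find_territory_origin(grid, st$occ, natal, score = st$score,
                                    search_radius = config$search_radius_f,
                                    excl_primary = config$excl_primary,
                                    excl_secondary = config$excl_secondary)
    if (!is.na(origin)) {
      st$a_origin[id] <- origin
      st$occ[origin] <- id
      st$terr[[id]] <- origin
      st$tsum[id] <- grid$prey[origin]
    }
  }
  f_origins <- st$a_origin[seq_len(st$n_agents)]
  f_origins <- f_origins[f_origins > 0L]
  for (i in seq_len(config$n_males)) {
    natal <- if (length(f_origins)) f_origins[sample.int(length(f_origins), 1)]
             else grid$inside[sample.int(length(grid$inside), 1)]
    add_agent(st, 2L, sample(ages[1]:ages[2], 1), natal = natal)
  }
  st
}

#' @export
print.tiger_state <- function(x, ...) {
  alive <- which(x$a_alive[seq_len(x$n_agents)])
  cat(sprintf("tiger_state: tick %d, %d tigers alive (%d F, %d M), %d territories\n",
              x$tick, length(alive), sum(x$a_sex[alive] == 1L),
              sum(x$a_sex[alive] == 2L),
              sum(x$a_origin[alive] > 0L & x$a_sex[alive] == 1L)))
  invisible(x)
}

# ---- tick phases ------------------------------------------------------------

phase_survival <- function(st) {
  n <- st$n_agents
  alive <- which(st$a_alive[seq_len(n)])
  if (!length(alive)) return(invisible())
  ms <- st$cfg$vr$monthly_survival
  age <- st$a_age[alive]
  sex <- st$a_sex[alive]
  p <- numeric(length(alive))
  p[age < 12L] <- ms[["cub"]]
  p[age >= 12L & age < 24L] <- ms[["juvenile"]]
  tf <- age >= 24L & age < 36L & sex == 1L
  tm <- age >= 24L & age < 36L & sex == 2L
  p[tf] <- ms[["transient_female"]]
  p[tm] <- ms[["transient_male"]]
  bf <- age >= 36L & sex == 1L
  p[bf] <- ms[["breeding_female"]]
  am <- which(age >= 36L & sex == 2L)
  for (j in am) {
    id <- alive[j]
    fs <- st$females_of[[id]]
    p[j] <- if (!is.null(fs) && length(fs)) ms[["breeding_male"]]
            else ms[["dispersal_male"]]
  }
  dead <- alive[runif(length(alive)) >= p]
  if (length(dead)) kill_agents(st, dead, 1L)
  invisible()
}

orphan_ids <- function(st) {
  n <- st$n_agents
  idx <- seq_len(n)
  mom <- st$a_mother[idx]
  mother_alive <- rep(TRUE, n)
  mother_alive[mom > 0L] <- st$a_alive[mom[mom > 0L]]
  which(st$a_alive[idx] & st$a_age[idx] < 24L & mom > 0L & !mother_alive)
}

phase_orphans <- function(st) {
  orphan <- orphan_ids(st)
  if (length(orphan)) kill_agents(st, orphan, 5L)
  invisible()
}

phase_female_settlement <- function(st) {
  n <- st$n_agents
  idx <- seq_len(n)
  newf <- which(st$a_alive[idx] & st$a_sex[idx] == 1L &
                  st$a_age[idx] >= 36L & st$a_origin[idx] == 0L)
  for (id in shuffled(newf)) {
    origin <- find_territory_origin(st$grid, st$occ, st$a_natal[id],
                                    score = st$score,
                                    search_radius = st$cfg$search_radius_f,
                                    excl_primary = st$cfg$excl_primary,
                                    excl_secondary = st$cfg$excl_secondary)
    if (is.na(origin)) {
      kill_agents(st, id, 6L)  # no territory: starvation-class mortality
    } else {
      st$a_origin[id] <- origin
      st$occ[origin] <- id
      st$terr[[id]] <- origin
      st$tsum[id] <- st$grid$prey[origin]
    }
  }
  invisible()
}

phase_territories <- function(st) {
  rule <- st$cfg$rule
  grid <- st$grid
  prey <- grid$prey
  n <- st$n_agents
  idx <- seq_len(n)
  owners <- which(st$a_alive[idx] & st$a_sex[idx] == 1L & st$a_origin[idx] > 0L)
  starving <- integer(0)
  target <- growth_target_sum(rule)
  min_sum <- rule$t_min / rule$utilization
  max_sum <- rule$t_max / rule$utilization
  half_budget <- rule$max_cells_per_tick %/% 2L
  for (id in shuffled(owners)) {
    tsum <- st$tsum[id]
    # growth is an establishment phase: a female enlarges her territory until
    # she first reaches the intake target, after which she only rearranges it
    # — unless her intake later falls below the starvation minimum, when she
    # expands again to meet her energetic requirement
    if ((!st$established[id] && tsum < target) || tsum < min_sum) {
      res <- cpp_grow(st$occ, prey, grid$mask, grid$nrow, grid$ncol,
                      st$terr[[id]], id, rule$max_cells_per_tick, target,
                      tsum, rule$territory_cap)
      st$terr[[id]] <- res$cells
      st$tsum[id] <- res$sum
      if (res$sum >= target) st$established[id] <- TRUE
      blocked <- res$blocked || length(res$cells) >= rule$territory_cap
      if (blocked && res$sum < min_sum)
        starving <- c(starving, id)
    } else {
      res <- cpp_adjust(st$occ, prey, grid$mask, grid$nrow, grid$ncol,
                        st$terr[[id]], id, st$a_origin[id], half_budget, tsum)
      st$terr[[id]] <- res$cells
      st$tsum[id] <- res$sum
      if (res$sum > max_sum) {
        tr <- cpp_trim(st$occ, prey, grid$nrow, grid$ncol, res$cells, id,
                       st$a_origin[id], max_sum, res$sum,
                       rule$max_cells_per_tick)
        st$terr[[id]] <- tr$cells
        st$tsum[id] <- tr$sum
      }
    }
  }
  # female-female contests along shared borders
  pairs <- cpp_contacts(st$occ, grid$nrow, grid$ncol)
  if (nrow(pairs) > 0) {
    vr <- st$cfg$vr
    for (i in shuffled(seq_len(nrow(pairs)))) {
      a <- pairs[i, 1]; b <- pairs[i, 2]
      if (!st$a_alive[a] || !st$a_alive[b]) next
      res <- female_challenge(
        grid, st$occ,
        a = list(id = a, cells = st$terr[[a]], origin = st$a_origin[a],
                 age = st$a_age[a]),
        b = list(id = b, cells = st$terr[[b]], origin = st$a_origin[b],
                 age = st$a_age[b]),
        vr = vr)
      if (!is.null(res)) {
        st$terr[[res$loser]] <- setdiff(st$terr[[res$loser]], res$cell)
        st$terr[[res$winner]] <- c(st$terr[[res$winner]], res$cell)
        pr <- prey[res$cell]
        st$tsum[res$loser] <- st$tsum[res$loser] - pr
        st$tsum[res$winner] <- st$tsum[res$winner] + pr
      }
    }
  }
  starving
}

phase_starvation <- function(st, starving) {
  rule <- st$cfg$rule
  conf <- starving[st$a_alive[starving] &
                     effective_intake(st$tsum[starving], rule) < rule$t_min]
  if (length(conf)) kill_agents(st, conf, 2L)
  invisible()
}

apply_infanticide <- function(st, female_ids) {
  if (!length(female_ids)) return(invisible())
  vr <- st$cfg$vr
  dep <- dependents_of(st, female_ids)
  if (!length(dep)) return(invisible())
  victims <- dep[infanticide_deaths(st$a_age[dep], vr)]
  if (length(victims)) kill_agents(st, victims, 4L)
  invisible()
}

claim_females <- function(st, m, fs) {
  cap <- st$cfg$max_females_per_male
  cur <- st$females_of[[m]]
  if (is.null(cur)) cur <- integer(0)
  room <- cap - length(cur)
  fs <- fs[seq_len(min(length(fs), room))]
  if (!length(fs)) return(invisible())
  st$females_of[[m]] <- c(cur, fs)
  st$owner_of[fs] <- m
  invisible()
}

phase_males <- function(st) {
  n <- st$n_agents
  idx <- seq_len(n)
  grid <- st$grid
  vr <- st$cfg$vr
  males <- which(st$a_alive[idx] & st$a_sex[idx] == 2L & st$a_age[idx] >= 36L)
  nf <- function(id) { fs <- st$females_of[[id]]; if (is.null(fs)) 0L else length(fs) }
  seekers <- males[vapply(males, nf, 0L) < st$cfg$max_females_per_male]
  for (m in shuffled(seekers)) {
    if (!st$a_alive[m]) next
    fem <- which(st$a_alive[idx] & st$a_sex[idx] == 1L & st$a_origin[idx] > 0L)
    if (!length(fem)) break
    d <- cell_distance(grid, st$a_natal[m], st$a_origin[fem])
    in_range <- fem[d <= st$cfg$search_radius_m]
    d <- d[d <= st$cfg$search_radius_m]
    if (!length(in_range)) next
    owner <- st$owner_of[in_range]
    un <- owner == 0L
    if (any(un)) {
      du <- d[un]
      best <- which(du == min(du))
      pick <- in_range[un][best[if (length(best) > 1) sample.int(length(best), 1) else 1]]
      claim_females(st, m, pick)
      next
    }
    if (nf(m) > 0L) next  # only females-less males challenge
    lost <- st$lost_to[[m]]
    ok <- !(owner %in% lost) & owner != m & st$a_alive[owner]
    if (!any(ok)) next
    dok <- d[ok]
    best <- which(dok == min(dok))
    f_target <- in_range[ok][best[if (length(best) > 1) sample.int(length(best), 1) else 1]]
    inc <- st$owner_of[f_target]
    out <- male_challenge_outcome(st$a_age[m], st$a_age[inc], vr)
    if (out$win) {
      taken <- st$females_of[[inc]]
      st$females_of[inc] <- list(NULL)
      st$owner_of[taken] <- 0L
      st$lost_to[[inc]] <- unique(c(st$lost_to[[inc]], m))
      sets <- merge_female_sets(st$females_of[[m]] %||% integer(0), taken,
                                cap = st$cfg$max_females_per_male)
      st$females_of[[m]] <- integer(0)
      claim_females(st, m, sets$kept)
      apply_infanticide(st, taken)
      if (out$incumbent_dies) kill_agents(st, inc, 3L)
    } else {
      st$lost_to[[m]] <- unique(c(st$lost_to[[m]], inc))
      if (out$challenger_dies) kill_agents(st, m, 3L)
    }
  }
  # breeding males gather nearby unowned females: a female qualifies when any
  # cell of one of the male's females' territories lies within 3 km of her
  # territory origin (his range encompasses his females' territories)
  breeders <- males[st$a_alive[males] & vapply(males, nf, 0L) > 0L]
  if (length(breeders)) {
    fem <- which(st$a_alive[idx] & st$a_sex[idx] == 1L &
                   st$a_origin[idx] > 0L & st$owner_of[idx] == 0L)
    if (length(fem)) {
      rad <- st$cfg$male_expand_radius / grid$cell_side
      near_owners <- lapply(fem, function(f)
        cpp_owners_within(st$occ, grid$nrow, grid$ncol, st$a_origin[f], rad))
      for (m in shuffled(breeders)) {
        fs <- st$females_of[[m]]
        if (length(fs) >= st$cfg$max_females_per_male) next
        ok <- which(st$owner_of[fem] == 0L &
                      vapply(near_owners, function(o) any(o %in% fs), TRUE))
        if (length(ok)) claim_females(st, m, fem[shuffled(ok)])
      }
    }
  }
  invisible()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

phase_reproduction <- function(st) {
  n <- st$n_agents
  idx <- seq_len(n)
  vr <- st$cfg$vr
  births <- 0L
  pregnant <- which(st$a_alive[idx] & st$a_gest[idx] > 0L)
  st$a_gest[pregnant] <- st$a_gest[pregnant] - 1L
  due <- pregnant[st$a_gest[pregnant] == 0L]
  for (mom in due) {
    lit <- draw_litter(vr)
    for (s in lit$sexes) {
      id <- add_agent(st, if (s == "F") 1L else 2L, 0L, mother = mom,
                      natal = st$a_origin[mom])
      log_event(st, st$tick, id, 1L)
      births <- births + 1L
    }
  }
  depn <- dependent_counts(st)
  eligible <- which(st$a_alive[idx] & st$a_sex[idx] == 1L &
                      st$a_age[idx] >= 36L & st$a_origin[idx] > 0L &
                      st$a_gest[idx] == 0L & st$owner_of[idx] > 0L &
                      depn[idx] == 0L)
  if (length(eligible)) {
    hz <- ifelse(st$a_age[eligible] < 48L, vr$monthly_conception_age3,
                 vr$monthly_conception_age4plus)
    conceive <- eligible[runif(length(eligible)) < hz]
    for (f in conceive)
      st$a_gest[f] <- sample(vr$gestation_months, 1)
  }
  births
}

record_tick <- function(st, adult_f_start, births) {
  n <- st$n_agents
  alive <- which(st$a_alive[seq_len(n)])
  age <- st$a_age[alive]
  sex <- st$a_sex[alive]
  bm <- sum(vapply(alive[sex == 2L & age >= 36L], function(id) {
    fs <- st$females_of[[id]]
    !is.null(fs) && length(fs) > 0
  }, TRUE))
  st$series[st$tick, ] <- c(st$tick, length(alive), sum(age < 12L),
                            sum(age >= 12L & age < 24L),
                            sum(age >= 24L & age < 36L),
                            sum(sex == 1L & age >= 36L),
                            sum(sex == 2L & age >= 36L), bm,
                            adult_f_start, st$tick_starv, births,
                            st$tick_deaths, total_prey(st$grid))
  invisible()
}

#' Advance a simulation state by one month
#'
#' Phases, in order: (1) aging, (2) natural survival, (3) orphan deaths,
#' (4) female dispersal and origin search, (5) territory growth/adjustment
#' and female contests, (6) starvation, (7) male dispersal, acquisition and
#' challenges with infanticide on takeover, (8) gestation, births and
#' conception, (9) orphan sweep and recording.
#'
#' @param st a state from [sim_init()].
#' @return the state, invisibly (modified in place).
#' @export
sim_step <- function(st) {
  st$tick <- st$tick + 1L
  st$tick_deaths <- 0L
  st$tick_starv <- 0L
  n <- st$n_agents
  alive <- st$a_alive[seq_len(n)]
  st$a_age[seq_len(n)][alive] <- st$a_age[seq_len(n)][alive] + 1L
  adult_f_start <- sum(alive & st$a_sex[seq_len(n)] == 1L &
                         st$a_age[seq_len(n)] >= 36L)
  phase_survival(st)
  phase_orphans(st)
  phase_female_settlement(st)
  starving <- phase_territories(st)
  phase_starvation(st, starving)
  phase_males(st)
  births <- phase_reproduction(st)
  phase_orphans(st)
  if (st$tick <= nrow(st$series)) record_tick(st, adult_f_start, births)
  if (st$cfg$check_invariants) validate_state(st)
  invisible(st)
}

#' Validate all structural invariants of a simulation state
#'
#' Checks territory/occupancy consistency, 8-connectivity, origin
#' membership, cached prey sums, the male-female ownership maps and caps,
#' the orphan rule, and the energetic population ceiling (disjoint settled
#' territories each hold at least the minimum prey sum). Errors with the
#' tick and agent id on the first violation.
#'
#' @param st a `tiger_state`.
#' @return `TRUE`, invisibly.
#' @export
validate_state <- function(st) {
  n <- st$n_agents
  idx <- seq_len(n)
  fail <- function(id, what)
    stop(sprintf("invariant violation at tick %d, agent %d: %s",
                 st$tick, id, what))
  owners <- which(st$a_alive[idx] & st$a_sex[idx] == 1L & st$a_origin[idx] > 0L)
  n_occ <- 0L
  for (id in owners) {
    cells <- st$terr[[id]]
    if (is.null(cells) || !length(cells)) fail(id, "empty territory")
    if (!all(st$occ[cells] == id)) fail(id, "occupancy mismatch")
    if (!(st$a_origin[id] %in% cells)) fail(id, "origin not in territory")
    if (abs(st$tsum[id] - sum(st$grid$prey[cells])) > 1e-6)
      fail(id, "stale prey sum")
    if (!cpp_connected(st$occ, st$grid$nrow, st$grid$ncol, id,
                       st$a_origin[id], length(cells)))
      fail(id, "territory not 8-connected")
    n_occ <- n_occ + length(cells)
  }
  if (n_occ != sum(st$occ > 0L)) fail(0L, "orphaned occupancy cells")
  for (id in idx[st$a_alive[idx] & st$a_sex[idx] == 2L]) {
    fs <- st$females_of[[id]]
    if (is.null(fs)) next
    if (length(fs) > st$cfg$max_females_per_male) fail(id, "female cap exceeded")
    if (!all(st$owner_of[fs] == id)) fail(id, "ownership map mismatch")
  }
  fowned <- which(st$owner_of[idx] > 0L)
  for (f in fowned)
    if (!st$a_alive[f] || !st$a_alive[st$owner_of[f]])
      fail(f, "dead agent in ownership map")
  orphans <- orphan_ids(st)
  if (length(orphans)) fail(orphans[1], "living dependent with dead mother")
  rule <- st$cfg$rule
  settled <- owners[effective_intake(st$tsum[owners], rule) >= rule$t_min]
  ceiling_n <- floor(total_prey(st$grid) / (rule$t_min / rule$utilization))
  if (length(settled) > ceiling_n)
    fail(0L, "settled females exceed the energetic ceiling")
  invisible(TRUE)
}

#' Run a full simulation
#'
#' Executes `burn_in` ticks, applies the depletion experiment (if any)
#' instantaneously to the landscape, then runs `horizon_post` further ticks.
#' Fully deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return an object of class `run_record`: list with `series` (one row per
#'   tick), `events` (birth/death log), `final_population`,
#'   `final_territory_cells` (per surviving female), `mean_territory_km2`,
#'   `morans_i` (of the post-depletion landscape; `NA` for controls and
#'   zero-variance surfaces), `times_depleted`, and the `config`.
#' @export
sim_run <- function(config) {
  st <- sim_init(config)
  if (is.null(config$depletion))
    st$morans_i <- tryCatch(morans_i(st$grid), error = function(e) NA_real_)
  total <- config$burn_in + config$horizon_post
  for (t in seq_len(total)) {
    sim_step(st)
    if (t == config$burn_in && !is.null(config$depletion)) {
      res <- apply_depletion(st$grid, config$depletion,
                             random_p = config$random_p)
      st$grid <- res$grid
      st$times_depleted <- res$times_depleted
      st$morans_i <- tryCatch(morans_i(st$grid), error = function(e) NA_real_)
      st$score <- cpp_neigh_mean(st$grid$prey, st$grid$mask, st$grid$nrow,
                                 st$grid$ncol)
      for (id in which(st$a_alive[seq_len(st$n_agents)] &
                         st$a_origin[seq_len(st$n_agents)] > 0L))
        st$tsum[id] <- sum(st$grid$prey[st$terr[[id]]])
    }
  }
  as_run_record(st)
}

as_run_record <- function(st) {
  n <- st$n_agents
  alive <- which(st$a_alive[seq_len(n)])
  fterr <- alive[st$a_sex[alive] == 1L & st$a_origin[alive] > 0L]
  sizes <- vapply(fterr, function(id) length(st$terr[[id]]), 0L)
  ev <- seq_len(st$ev_n)
  events <- data.frame(
    tick = st$ev_tick[ev], id = st$ev_id[ev],
    event = c("birth", "death")[st$ev_event[ev]],
    cause = c(NA, CAUSES)[st$ev_cause[ev] + 1L],
    sex = c("F", "M")[st$a_sex[st$ev_id[ev]]],
    age = st$a_age[st$ev_id[ev]])
  structure(list(
    series = as.data.frame(st$series),
    events = events,
    final_population = length(alive),
    final_territory_cells = sizes,
    mean_territory_km2 = if (length(sizes))
      mean(sizes) * cell_area_km2(st$grid) else NA_real_,
    morans_i = st$morans_i,
    times_depleted = st$times_depleted,
    config = st$cfg), class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("run_record: %d ticks, final population %d, mean female territory %.2f km2\n",
              nrow(x$series), x$final_population, x$mean_territory_km2))
  if (!is.na(x$morans_i))
    cat(sprintf("post-depletion Moran's I: %.3f\n", x$morans_i))
  invisible(x)
}
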