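# Hand-built simulation states for exercising single phases.

blank_state <- function(grid, seed = 1) {
  sim_init(sim_config(landscape = grid, n_females = 0L, n_males = 0L,
                      seed = seed, burn_in = 1L, horizon_post = 1L))
}

# settled breeding female with an explicit territory
add_test_female <- function(st, age, origin, cells = origin) {
  id <- tigerscape:::add_agent(st, 1L, age, natal = origin)
  st$a_origin[id] <- as.integer(origin)
  st$occ[cells] <- id
  st$terr[[id]] <- as.integer(cells)
  st$tsum[id] <- sum(st$grid$prey[cells])
  st$established[id] <- TRUE
  id
}

add_test_male <- function(st, age, natal) {
  tigerscape:::add_agent(st, 2L, age, natal = natal)
}

own_female <- function(st, m, f) {
  st$females_of[[m]] <- c(st$females_of[[m]], f)
  st$owner_of[f] <- m
}

cell_at <- function(grid, row, col) (row - 1L) * grid$ncol + col
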