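test_that("prey thresholds convert daily consumption to monthly", {
  expect_equal(prey_threshold_monthly(2.5), 2.5 * 365 / 12)
  expect_lt(abs(prey_threshold_monthly(2.5) - 76), 0.05)
  expect_lt(abs(prey_threshold_monthly(5.5) - 167.3), 0.05)
  rule <- intake_rule()
  expect_equal(rule$utilization, 0.1)
  expect_error(intake_rule(utilization = 0), "utilization")
  expect_error(intake_rule(t_min = 200, t_max = 100), "t_min")
})

test_that("effective intake is the utilization-scaled prey sum", {
  rule <- intake_rule()
  expect_equal(effective_intake(158 * 4.84, rule), 76.472)
  expect_equal(effective_intake(0, rule), 0)
  expect_equal(effective_intake(10.46, intake_rule(utilization = 1)), 10.46)
})

test_that("territory origin search maximizes neighbourhood prey", {
  # two prey bumps: the better one wins
  prey <- matrix(1, 21, 21)
  prey[4:6, 4:6] <- 5
  prey[14:16, 14:16] <- 4.8
  g <- square_landscape(prey)
  occ <- integer(21 * 21)
  set.seed(1)
  pick <- find_territory_origin(g, occ, natal = cell_at(g, 10, 10))
  expect_equal(pick, cell_at(g, 5, 5))
  # homogeneous and empty: some inside cell is returned
  g2 <- make_circle_landscape(50, 4.84)
  set.seed(2)
  pick2 <- find_territory_origin(g2, integer(g2$nrow * g2$ncol),
                                 natal = g2$inside[1])
  expect_true(pick2 %in% g2$inside)
})

test_that("origin search fails when all space is too crowded", {
  g <- square_landscape(matrix(1, 7, 7))
  occ <- integer(49)
  occ[c(cell_at(g, 3, 3), cell_at(g, 3, 5),
        cell_at(g, 5, 3), cell_at(g, 5, 5))] <- 99L
  # every free cell lies within 1 km (4 cells) of an occupied cell
  expect_true(is.na(find_territory_origin(g, occ, natal = cell_at(g, 4, 4))))
})

test_that("territory growth is greedy, bounded and stops at the target", {
  g <- square_landscape(matrix(4.84, 50, 50))
  occ <- integer(2500)
  origin <- cell_at(g, 25, 25)
  occ[origin] <- 1L
  rule <- intake_rule(growth_target = "min")
  cells <- origin
  sum_ <- g$prey[origin]
  sizes <- integer(4)
  for (i in 1:4) {
    res <- grow_territory(g, occ, cells, 1L, rule, prey_sum = sum_)
    cells <- res$cells
    sum_ <- res$sum
    sizes[i] <- length(cells)
  }
  # 48 cells per month until the 76 kg/month minimum: 158 cells in 4 months
  expect_equal(sizes, c(49L, 97L, 145L, 158L))
  expect_gte(effective_intake(sum_, rule), 76)
  # at the target no further cells are added
  res <- grow_territory(g, occ, cells, 1L, rule, prey_sum = sum_)
  expect_length(res$added, 0)
  expect_false(res$blocked)
})

test_that("fully enclosed territories cannot grow and are flagged", {
  g <- square_landscape(matrix(4.84, 5, 5))
  occ <- rep(2L, 25)
  center <- cell_at(g, 3, 3)
  occ[center] <- 1L
  res <- grow_territory(g, occ, center, 1L, intake_rule())
  expect_true(res$blocked)
  expect_length(res$added, 0)
})

test_that("adjustment swaps worse cells for better adjoining ones", {
  prey <- matrix(1, 4, 4)
  g <- square_landscape(prey)
  g$prey[cell_at(g, 1, 1)] <- 5
  g$prey[cell_at(g, 1, 2)] <- 2
  g$prey[cell_at(g, 2, 2)] <- 10
  occ <- integer(16)
  cells <- c(cell_at(g, 1, 1), cell_at(g, 1, 2))
  occ[cells] <- 1L
  res <- adjust_territory(g, occ, cells, 1L, origin = cell_at(g, 1, 1))
  expect_equal(res$swaps, 1)
  expect_setequal(res$cells, c(cell_at(g, 1, 1), cell_at(g, 2, 2)))
  expect_equal(res$sum, 15)
  # homogeneous: no strict improvement, no swaps
  g2 <- square_landscape(matrix(4.84, 6, 6))
  occ2 <- integer(36)
  cells2 <- c(cell_at(g2, 3, 3), cell_at(g2, 3, 4))
  occ2[cells2] <- 1L
  res2 <- adjust_territory(g2, occ2, cells2, 1L, origin = cells2[1])
  expect_equal(res2$swaps, 0)
})

test_that("adjustment never decreases the prey sum and keeps connectivity", {
  set.seed(77)
  for (i in 1:5) {
    g <- square_landscape(matrix(runif(400, 1, 10), 20, 20))
    occ <- integer(400)
    origin <- cell_at(g, 10, 10)
    occ[origin] <- 1L
    res <- grow_territory(g, occ, origin, 1L,
                          intake_rule(growth_target = "min"))
    before <- res$sum
    adj <- adjust_territory(g, occ, res$cells, 1L, origin,
                            prey_sum = before)
    expect_gte(adj$sum, before)
    expect_true(tigerscape:::cpp_connected(occ, g$nrow, g$ncol, 1L, origin,
                                           length(adj$cells)))
    expect_true(origin %in% adj$cells)
  }
})

test_that("surplus above the satiation maximum is shed", {
  g <- square_landscape(matrix(4.84, 50, 50))
  occ <- integer(2500)
  origin <- cell_at(g, 25, 25)
  occ[origin] <- 1L
  cells <- origin
  sum_ <- g$prey[origin]
  for (i in 1:10) {
    res <- grow_territory(g, occ, cells, 1L, intake_rule(), prey_sum = sum_)
    cells <- res$cells
    sum_ <- res$sum
  }
  rule <- intake_rule()
  # grow well past the satiation ceiling
  res <- grow_territory(g, occ, cells, 1L,
                        intake_rule(max_cells_per_tick = 400L),
                        prey_sum = sum_, target_sum = 1e9)
  cells <- res$cells
  sum_ <- res$sum
  expect_gt(effective_intake(sum_, rule), rule$t_max)
  tr <- trim_territory(g, occ, cells, 1L, origin, rule, prey_sum = sum_)
  expect_gte(effective_intake(tr$sum, rule), rule$t_max)
  expect_lt(length(tr$cells), length(cells))
  expect_true(tigerscape:::cpp_connected(occ, g$nrow, g$ncol, 1L, origin,
                                         length(tr$cells)))
})

test_that("female contests transfer one border cell at the stated rate", {
  g <- square_landscape(matrix(4.84, 3, 4))
  occ <- integer(12)
  a_cells <- c(cell_at(g, 1, 1), cell_at(g, 2, 1), cell_at(g, 3, 1),
               cell_at(g, 1, 2), cell_at(g, 2, 2), cell_at(g, 3, 2))
  b_cells <- c(cell_at(g, 1, 3), cell_at(g, 2, 3), cell_at(g, 3, 3),
               cell_at(g, 1, 4), cell_at(g, 2, 4), cell_at(g, 3, 4))
  occ[a_cells] <- 1L
  occ[b_cells] <- 2L
  a <- list(id = 1L, cells = a_cells, origin = cell_at(g, 2, 1), age = 60L)
  b <- list(id = 2L, cells = b_cells, origin = cell_at(g, 2, 4), age = 60L)
  set.seed(10)
  vr <- vital_rates()
  n <- 100000
  hits <- 0L
  for (i in seq_len(n)) {
    res <- female_challenge(g, occ, a, b, vr)
    if (!is.null(res)) {
      hits <- hits + 1L
      expect_equal(sort(c(res$winner, res$loser)), c(1L, 2L))
      occ[res$cell] <- res$loser  # undo the transfer for the next trial
    }
  }
  expect_equal(hits / n, 0.25, tolerance = 0.02)
})

test_that("contested territories stay connected and keep their origins", {
  set.seed(20)
  g <- square_landscape(matrix(runif(100, 1, 10), 10, 10))
  occ <- integer(100)
  a_cells <- as.integer(outer((0:4) * 10, 1:5, `+`))   # rows 1-5, cols 1-5
  b_cells <- as.integer(outer((0:4) * 10, 6:10, `+`))  # rows 1-5, cols 6-10
  occ[a_cells] <- 1L
  occ[b_cells] <- 2L
  a <- list(id = 1L, cells = a_cells, origin = a_cells[1], age = 80L)
  b <- list(id = 2L, cells = b_cells, origin = b_cells[1], age = 50L)
  for (i in 1:200) {
    res <- female_challenge(g, occ, a, b, vital_rates())
    if (is.null(res)) next
    if (res$loser == 1L) {
      a$cells <- setdiff(a$cells, res$cell)
      b$cells <- c(b$cells, res$cell)
    } else {
      b$cells <- setdiff(b$cells, res$cell)
      a$cells <- c(a$cells, res$cell)
    }
    for (side in list(a, b)) {
      if (!length(side$cells)) next
      expect_true(side$origin %in% side$cells)
      expect_true(tigerscape:::cpp_connected(occ, g$nrow, g$ncol, side$id,
                                             side$origin, length(side$cells)))
    }
  }
})

test_that("the female cap truncates takeovers and releases the surplus", {
  set.seed(4)
  m <- merge_female_sets(1:4, 5:8, cap = 6L)
  expect_length(m$kept, 6)
  expect_length(m$released, 2)
  expect_setequal(c(m$kept, m$released), 1:8)
  m2 <- merge_female_sets(integer(0), 11:13, cap = 6L)
  expect_equal(sort(m2$kept), 11:13)
  expect_length(m2$released, 0)
})

test_that("males claim the nearest unowned female, one per month", {
  g <- square_landscape(matrix(4.84, 60, 60))
  st <- blank_state(g, seed = 3)
  f_near <- add_test_female(st, 60L, cell_at(g, 30, 38))   # 2 km east
  f_far <- add_test_female(st, 60L, cell_at(g, 30, 55))    # 6 km east
  m <- add_test_male(st, 60L, cell_at(g, 30, 30))
  tigerscape:::phase_males(st)
  expect_equal(st$owner_of[f_near], m)
  expect_equal(st$owner_of[f_far], 0L)
  # next month he claims the next one
  tigerscape:::phase_males(st)
  expect_equal(st$owner_of[f_far], m)
})

test_that("a male at the six-female cap claims no more", {
  g <- square_landscape(matrix(4.84, 60, 60))
  st <- blank_state(g, seed = 5)
  m <- add_test_male(st, 60L, cell_at(g, 30, 30))
  for (i in 1:6) {
    f <- add_test_female(st, 60L, cell_at(g, 5 + 8 * (i - 1), 5))
    own_female(st, m, f)
  }
  f_extra <- add_test_female(st, 60L, cell_at(g, 30, 32))
  tigerscape:::phase_males(st)
  expect_equal(st$owner_of[f_extra], 0L)
  expect_length(st$females_of[[m]], 6)
})

test_that("challenges transfer all females and record losses", {
  takeovers <- 0L
  rebuffs <- 0L
  for (sd in 1:60) {
    g <- square_landscape(matrix(4.84, 40, 40))
    st <- blank_state(g, seed = 100 + sd)
    f1 <- add_test_female(st, 60L, cell_at(g, 20, 18))
    f2 <- add_test_female(st, 60L, cell_at(g, 20, 30))
    inc <- add_test_male(st, 60L, cell_at(g, 20, 18))
    own_female(st, inc, f1)
    own_female(st, inc, f2)
    chal <- add_test_male(st, 60L, cell_at(g, 20, 24))
    tigerscape:::phase_males(st)
    if (identical(st$owner_of[f1], chal)) {
      takeovers <- takeovers + 1L
      expect_equal(st$owner_of[f2], chal)  # winner takes all
      expect_length(st$lost_to[[inc]], 1)
    } else if (st$a_alive[chal]) {
      expect_true(inc %in% st$lost_to[[chal]])
      rebuffs <- rebuffs + 1L
    }
  }
  expect_gt(takeovers, 5)
  expect_gt(rebuffs, 5)
})
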