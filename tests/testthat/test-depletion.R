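test_that("depletion probability functions have the stated shape", {
  dmax <- 10000
  expect_equal(depletion_probability("linear", 0, dmax), 1)
  expect_equal(depletion_probability("linear", dmax, dmax), 0)
  # ordering at half depth mandated by the penetration continuum
  p_half <- vapply(c("exponential", "logarithm", "linear",
                     "inverse_distance_weighted", "one_minus_exponential"),
                   function(f) depletion_probability(f, dmax / 2, dmax), 0)
  expect_true(all(diff(p_half) > 0))
  # all five distance functions: p(0) maximal, monotone non-increasing
  d <- seq(0, dmax, length.out = 101)
  for (f in setdiff(depletion_functions(), "random")) {
    p <- depletion_probability(f, d, dmax)
    expect_true(all(p >= 0 & p <= 1), info = f)
    expect_true(all(diff(p) <= 1e-12), info = f)
    expect_equal(p[1], max(p), info = f)
  }
  # random is constant in distance
  expect_equal(depletion_probability("random", d, dmax), rep(0.5, 101))
  expect_error(depletion_probability("nope", 0, dmax), "unknown")
  expect_error(depletion_probability("linear", -1, dmax), "\\[0, d_max\\]")
})

test_that("depletion spec validates its factors", {
  expect_error(depletion_spec("nope", 0.1, 0.5), "unknown")
  expect_error(depletion_spec("linear", 0, 0.5), "landscape_fraction")
  expect_error(depletion_spec("linear", 0.1, 0), "cell_fraction")
  expect_s3_class(depletion_spec("linear", 0.25, 1), "depletion_spec")
})

test_that("depletion removes exactly the landscape-level target", {
  circ <- make_circle_landscape(300, 4.84)
  pre <- total_prey(circ)
  set.seed(11)
  res <- apply_depletion(circ, depletion_spec("logarithm", 0.25, 0.5))
  expect_equal(total_prey(res$grid) / pre, 0.75, tolerance = 1e-6)
  expect_equal(res$removed_total + total_prey(res$grid), pre,
               tolerance = 1e-9 * pre)
  expect_equal(res$removed_total, 0.25 * pre, tolerance = 1e-9 * pre)
  # untouched cells keep their original prey
  untouched <- res$times_depleted == 0 & circ$mask
  expect_identical(res$grid$prey[untouched], circ$prey[untouched])
})

test_that("full per-cell depletion empties hit cells except the final clamp", {
  circ <- make_circle_landscape(300, 4.84)
  set.seed(3)
  res <- apply_depletion(circ, depletion_spec("linear", 0.2, 1))
  hit <- which(res$times_depleted > 0)
  nonzero_hit <- sum(res$grid$prey[hit] > 0)
  expect_lte(nonzero_hit, 1)  # at most the clamped final event
  # a second visit to an emptied cell removes nothing
  rehit <- which(res$times_depleted > 1)
  expect_true(all(res$grid$prey[rehit] == 0))
})

test_that("border-hugging depletion revisits cells to reach deep targets", {
  circ <- make_circle_landscape(300, 4.84)
  set.seed(4)
  res <- apply_depletion(circ, depletion_spec("exponential", 0.25, 0.25))
  expect_gt(max(res$times_depleted), 1)
  expect_gt(res$passes, 1)
})

test_that("unreachable targets raise a non-convergence error", {
  # prey only at the maximum-distance cell, where the linear probability is 0
  circ <- make_circle_landscape(50, 0)
  ctr <- circ$inside[which.max(circ$dist_border[circ$inside])]
  circ$prey[ctr] <- 5
  set.seed(1)
  expect_error(apply_depletion(circ, depletion_spec("linear", 0.5, 1)),
               "did not converge")
  empty <- make_circle_landscape(50, 0)
  expect_error(apply_depletion(empty, depletion_spec("linear", 0.5, 1)),
               "no prey")
})

test_that("Moran's I matches the brute-force double sum on 5x5 grids", {
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(runif(25), 5, 5)
    g <- square_landscape(m)
    expect_equal(morans_i(g), bf_morans_i(m, matrix(TRUE, 5, 5)),
                 tolerance = 1e-12)
  }
  # with a masked (non-rectangular) support: inside-only restriction matches
  # the oracle on the masked support; the default whole-rectangle convention
  # matches the oracle over the full lattice with zeros outside
  mask <- matrix(runif(25) < 0.7, 5, 5)
  m <- matrix(runif(25), 5, 5)
  m[!mask] <- 0
  g <- landscape_grid(prey = m, mask = mask, cell_side = 250)
  expect_equal(morans_i(g, include_outside = FALSE), bf_morans_i(m, mask),
               tolerance = 1e-12)
  expect_equal(morans_i(g), bf_morans_i(m, matrix(TRUE, 5, 5)),
               tolerance = 1e-12)
})

test_that("Moran's I sign reflects aggregation", {
  chk <- matrix(rep(c(1, 2), 8), 4, 4)        # checkerboard columns-ish
  chk <- outer(1:4, 1:4, function(r, c) (r + c) %% 2)
  expect_lt(morans_i(square_landscape(chk)), 0)
  blocks <- cbind(matrix(1, 6, 3), matrix(9, 6, 3))
  expect_gt(morans_i(square_landscape(blocks)), 0.5)
  expect_error(morans_i(square_landscape(matrix(4.84, 4, 4))), "undefined")
  expect_error(morans_i(square_landscape(matrix(1, 1, 1))), "two inside")
})

test_that("penetration depth follows the stated function ordering", {
  circ <- make_circle_landscape(300, 4.84)
  fns <- c("exponential", "logarithm", "linear",
           "inverse_distance_weighted", "one_minus_exponential")
  depth <- sapply(fns, function(f) {
    mean(sapply(1:10, function(sd) {
      set.seed(1000 + sd)
      res <- apply_depletion(circ, depletion_spec(f, 0.15, 0.5))
      removed <- circ$prey - res$grid$prey
      sum(circ$dist_border * removed) / sum(removed)
    }))
  })
  expect_true(all(diff(depth) > 0))
})

test_that("random depletion is spatially uniform", {
  circ <- make_circle_landscape(1000, 4.84)
  cors <- sapply(1:3, function(sd) {
    set.seed(sd)
    res <- apply_depletion(circ, depletion_spec("random", 0.1, 0.5))
    cor(res$times_depleted[circ$inside], circ$dist_border[circ$inside])
  })
  expect_lt(max(abs(cors)), 0.05)
})

test_that("spatial heterogeneity falls with depletion intensity", {
  circ <- make_circle_landscape(300, 4.84)
  mi <- function(cf, lf) {
    mean(sapply(1:10, function(sd) {
      set.seed(2000 + sd)
      morans_i(apply_depletion(circ, depletion_spec("linear", lf, cf))$grid)
    }))
  }
  by_cell <- vapply(c(0.25, 0.5, 0.75, 1), mi, 0, lf = 0.25)
  expect_true(all(diff(by_cell) < 0))
  by_landscape <- vapply(c(0.1, 0.25), mi, 0, cf = 0.5)
  expect_gt(by_landscape[1], by_landscape[2])
})

test_that("depletion is deterministic given a seed", {
  circ <- make_circle_landscape(200, 4.84)
  r1 <- apply_depletion(circ, depletion_spec("linear", 0.2, 0.5, seed = 8))
  r2 <- apply_depletion(circ, depletion_spec("linear", 0.2, 0.5, seed = 8))
  expect_identical(r1$grid$prey, r2$grid$prey)
  expect_identical(r1$times_depleted, r2$times_depleted)
})
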