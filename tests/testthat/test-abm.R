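# The simulator keeps its state in an environment; several tests set up a
# scenario, surgically adjust one village field, run a single step and check
# the resulting behaviour against the model rules.

uniform_grid <- function(n = 30, value = 0.7, threshold = 0.5)
  synth_landscape(n, n, "uniform", value = value, threshold = threshold)

test_that("initialisation creates one village at the fission threshold", {
  g <- uniform_grid()
  p <- sim_params(k_star = 60, catchment_km = 10, fission_threshold = 150,
                  leap_km = 0, permanence = 20)
  st <- init_run(p, g, c(15, 15), 3000, seed = 1)
  expect_equal(st$n, 1L)
  expect_equal(st$pop[1], 150)
  expect_equal(st$arrival[15, 15], 3000)
  expect_equal(sum(!is.na(st$arrival)), 1)
  # immediate fission on the first step
  step_sim(st)
  expect_gte(st$n, 2L)

  expect_error(init_run(p, g, c(15, 15), 400, seed = 1), "500")
  g0 <- uniform_grid(value = 0.2, threshold = 0.5)
  expect_error(init_run(p, g0, c(15, 15), 3000), "settleable")
})

test_that("parameter ranges are enforced", {
  expect_error(sim_params(k_star = 10), "k_star")
  expect_error(sim_params(catchment_km = 50), "catchment_km")
  expect_error(sim_params(leap_km = 100), "leap_km")
  expect_silent(sim_params(leap_km = 0))
  expect_silent(sim_params(leap_km = 250))
})

test_that("annual growth multiplies population by 1 + a", {
  g <- uniform_grid()
  p <- sim_params(k_star = 100, catchment_km = 10, fission_threshold = 300,
                  leap_km = 0, permanence = 30)
  st <- init_run(p, g, c(15, 15), 3000, seed = 2)
  st$pop[1] <- 80          # below ceiling and threshold: pure growth
  step_sim(st)
  expect_equal(st$pop[1], 80 * 1.025)
  expect_equal(st$n, 1L)
})

test_that("an over-ceiling village claims a cell instead of clamping", {
  g <- uniform_grid()
  p <- sim_params(k_star = 20, catchment_km = 10, fission_threshold = 300,
                  leap_km = 0, permanence = 30)
  st <- init_run(p, g, c(15, 15), 3000, seed = 3)
  st$pop[1] <- 25          # ceiling is 20 x 1 claimed cell
  step_sim(st)
  expect_equal(st$pop[1], 25 * 1.025)   # not clamped: a cell was claimed
  expect_equal(length(st$claims[[1]]), 2L)
  expect_equal(sum(st$claimed > 0), 2L)
})

test_that("a village with no space clamps to its ceiling and deactivates", {
  m <- matrix(0, 20, 20); m[10, 10] <- 0.9   # a single settleable cell
  g <- suit_grid(m, threshold = 0.5)
  p <- sim_params(k_star = 20, catchment_km = 10, fission_threshold = 50,
                  leap_km = 0, permanence = 30)
  st <- init_run(p, g, c(10, 10), 3000, seed = 4)
  step_sim(st)
  expect_equal(st$pop[1], 20)     # decreased back to maximum density
  expect_false(st$active[1])
  expect_equal(st$n, 1L)
})

test_that("population grows past the threshold when fission is impossible", {
  # settleable patch = origin plus its catchment only: claimable cells exist
  # but the adjacency ring is barren, so the village cannot fission
  m <- matrix(0, 20, 20)
  m[10, 9:11] <- 0.9; m[9:11, 10] <- 0.9   # plus-shaped patch, radius 10 km
  g <- suit_grid(m, threshold = 0.5)
  p <- sim_params(k_star = 100, catchment_km = 10, fission_threshold = 50,
                  leap_km = 0, permanence = 30)
  st <- init_run(p, g, c(10, 10), 3000, seed = 5)
  for (k in 1:10) step_sim(st)
  expect_equal(st$n, 1L)
  expect_gt(st$pop[1], 50)
})

test_that("fission is blocked above six neighbouring villages", {
  g <- uniform_grid(40)
  p <- sim_params(k_star = 100, catchment_km = 10, fission_threshold = 150,
                  leap_km = 0, permanence = 30)
  near <- rbind(c(19, 20), c(21, 20), c(20, 19), c(20, 21),
                c(19, 19), c(21, 21), c(19, 21))  # 7 homes within 2R
  st <- init_run(p, g, c(20, 20), 3000, seed = 6)
  st$homes[near] <- 1L
  step_sim(st)
  expect_equal(st$n, 1L)          # blocked, and no leap fallback
  # with six neighbours the fission proceeds
  st2 <- init_run(p, g, c(20, 20), 3000, seed = 6)
  st2$homes[near[1:6, ]] <- 1L
  step_sim(st2)
  expect_equal(st2$n, 2L)
  expect_equal(st2$pop[1], st2$pop[2])  # even split
})

test_that("relocation triggers strictly after the permanence time", {
  g <- uniform_grid()
  p <- sim_params(k_star = 100, catchment_km = 10, fission_threshold = 300,
                  leap_km = 0, permanence = 10)
  st <- init_run(p, g, c(15, 15), 3000, seed = 7)
  st$pop[1] <- 60
  st$yrs[1] <- 10L
  step_sim(st)                      # yrs == permanence: stays
  expect_equal(c(st$hr[1], st$hc[1]), c(15L, 15L))
  expect_equal(st$yrs[1], 11L)
  step_sim(st)                      # yrs > permanence: moves
  moved <- c(st$hr[1], st$hc[1])
  expect_false(all(moved == c(15, 15)))
  d <- sqrt(sum((moved - c(15, 15))^2)) * 10
  expect_true(d > 10 && d <= 20)    # ring adjacency of the catchment
  expect_equal(st$yrs[1], 0L)       # clock reset
  expect_equal(length(st$claims[[1]]), 1L)  # old claims released
  expect_equal(sum(st$claimed > 0), 1L)
  expect_false(is.na(st$arrival[moved[1], moved[2]]))
})

test_that("identical seeds give bitwise-identical trajectories", {
  g <- uniform_grid(40)
  p <- sim_params(k_star = 40, catchment_km = 10, fission_threshold = 100,
                  leap_km = 0, permanence = 15)
  r1 <- run_expansion(p, g, c(20, 20), 900, seed = 77)
  r2 <- run_expansion(p, g, c(20, 20), 900, seed = 77)
  expect_identical(r1$arrival, r2$arrival)
  expect_identical(r1$pop_history, r2$pop_history)
  expect_identical(r1$n_villages, r2$n_villages)
})

test_that("claimed cells stay disjoint and population stays bounded", {
  g <- uniform_grid(50)
  p <- sim_params(k_star = 50, catchment_km = 10, fission_threshold = 120,
                  leap_km = 0, permanence = 12)
  st <- init_run(p, g, c(25, 25), 1200, seed = 9)
  for (k in 1:700) {
    step_sim(st)
    if (k %% 100 == 0) {
      cl <- unlist(st$claims[seq_len(st$n)])
      expect_equal(anyDuplicated(cl), 0L)
      expect_identical(sort(cl), sort(which(st$claimed > 0)))
      expect_lte(sum(st$pop[seq_len(st$n)]),
                 p$k_star * sum(g$settleable) + 1e-9)
    }
  }
})

test_that("without leapfrogging the front advances only through adjacency", {
  g <- uniform_grid(50)
  p <- sim_params(k_star = 50, catchment_km = 10, fission_threshold = 120,
                  leap_km = 0, permanence = 12)
  res <- run_expansion(p, g, c(25, 25), 1000, seed = 10)
  idx <- which(!is.na(res$arrival))
  rr <- ((idx - 1) %% 50) + 1
  cc <- ((idx - 1) %/% 50) + 1
  yr <- res$arrival[idx]
  ord <- order(-yr)
  rr <- rr[ord]; cc <- cc[ord]; yr <- yr[ord]
  # every settlement (after the first) lies within catchment + cell size of
  # an equally-old-or-older settlement
  max_reach <- (p$catchment_km + 10) / 10  # in cells
  for (i in seq_along(idx)[-1]) {
    prev <- which(yr >= yr[i])
    prev <- prev[prev != i]
    dmin <- min(sqrt((rr[prev] - rr[i])^2 + (cc[prev] - cc[i])^2))
    expect_lte(dmin, max_reach + 1e-9)
  }
  # arrival gets later with distance from the origin, roughly radially
  d <- sqrt((rr - 25)^2 + (cc - 25)^2) * 10
  expect_lt(cor(d, yr), -0.9)
})

test_that("leapfrogging crosses a barrier onto better land; otherwise not", {
  m <- matrix(0.5, 60, 60)
  m[, 15:20] <- 0                 # 60-km barrier, too wide for adjacency
  m[, 21:60] <- 0.7               # better land beyond
  g <- suit_grid(m, threshold = 0.4)
  base <- list(k_star = 60, catchment_km = 10, fission_threshold = 100,
               permanence = 15)
  p_leap <- do.call(sim_params, c(base, leap_km = 200))
  p_stay <- do.call(sim_params, c(base, leap_km = 0))
  r_leap <- run_expansion(p_leap, g, c(30, 5), 1300, seed = 11)
  r_stay <- run_expansion(p_stay, g, c(30, 5), 1300, seed = 11)
  expect_gt(sum(!is.na(r_leap$arrival[, 21:60])), 0)
  expect_equal(sum(!is.na(r_stay$arrival[, 21:60])), 0)
})

test_that("a one-step run only settles near the origin", {
  g <- uniform_grid(30)
  p <- sim_params(k_star = 60, catchment_km = 10, fission_threshold = 150,
                  leap_km = 0, permanence = 20)
  res <- run_expansion(p, g, c(15, 15), 501, seed = 12)
  idx <- which(!is.na(res$arrival))
  rr <- ((idx - 1) %% 30) + 1; cc <- ((idx - 1) %/% 30) + 1
  d <- sqrt((rr - 15)^2 + (cc - 15)^2) * 10
  expect_true(all(d <= 20))
})
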