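# Agent-based simulator of village growth, fission, relocation and
# leapfrogging on a suitability grid, producing a first-arrival raster.
#
# Each agent is a village with a real-valued population, a home cell and an
# exclusive set of claimed cells inside its catchment. One step = one year;
# the simulation clock runs backwards in sim BP and stops at 500 sim BP.
# First arrival is recorded when a cell is first occupied, whether settled
# as a home or claimed into a catchment, and is never overwritten.
# The step loop is written as a single closure over local state: simulations
# cover thousands of years and tens of thousands of villages, so the inner
# loop avoids per-village function-call and environment-lookup overhead.

#' Demographic parameter set for the expansion simulator
#'
#' Ranges follow the ethnographically motivated bounds used to initialise
#' the optimizer: maximum population density `k_star` 20-100 individuals per
#' 100 km^2 cell (0.2-1 km^-2), catchment radius 10-30 km, leap distance 0
#' (no leapfrogging) or 150-250 km, fission threshold 50-300 individuals,
#' maximum permanence 10-30 years. The annual growth rate is fixed at 0.025.
#'
#' @param k_star Maximum population density, individuals per cell (100 km^2).
#' @param catchment_km Catchment radius, km.
#' @param fission_threshold Village population triggering fission.
#' @param leap_km Leap distance, km (0 disables leapfrogging).
#' @param permanence Maximum years in place before relocation is attempted.
#' @param a Annual intrinsic growth rate (fixed).
#' @return A named list of class `sim_params`.
#' @export
sim_params <- function(k_star = 60, catchment_km = 20,
                       fission_threshold = 150, leap_km = 0,
                       permanence = 20, a = 0.025) {
  chk <- function(v, lo, hi, nm) {
    if (!is.finite(v) || v < lo || v > hi)
      stop(nm, " = ", v, " outside admissible range [", lo, ", ", hi, "]",
           call. = FALSE)
  }
  chk(k_star, 20, 100, "k_star")
  chk(catchment_km, 10, 30, "catchment_km")
  chk(fission_threshold, 50, 300, "fission_threshold")
  chk(permanence, 10, 30, "permanence")
  if (!(leap_km == 0 || (leap_km >= 150 && leap_km <= 250)))
    stop("leap_km must be 0 or in [150, 250]", call. = FALSE)
  if (!is.finite(a) || a <= 0) stop("growth rate a must be > 0", call. = FALSE)
  structure(list(k_star = k_star, catchment_km = catchment_km,
                 fission_threshold = fission_threshold, leap_km = leap_km,
                 permanence = permanence, a = a),
            class = "sim_params")
}

# (dr, dc) cell offsets with centre distance in (lo, hi] km, excluding the
# centre cell; dlin are linear-index deltas, m the bounding half-width
.offsets <- function(cell_km, lo, hi, nr) {
  m <- ceiling(hi / cell_km)
  dr <- rep(-m:m, times = 2 * m + 1)
  dc <- rep(-m:m, each = 2 * m + 1)
  d <- sqrt(dr^2 + dc^2) * cell_km
  keep <- d > max(lo, 0) & d <= hi & !(dr == 0 & dc == 0)
  list(dr = dr[keep], dc = dc[keep], dlin = dc[keep] * nr + dr[keep],
       m = max(abs(c(dr[keep], dc[keep], 0L))))
}

#' Initialise an expansion simulation
#'
#' Creates one village at the origin cell with population equal to the
#' fission threshold, so that it fissions immediately and the expansion
#' starts at once. Its arrival year is recorded.
#'
#' @param params A [sim_params] object.
#' @param grid A `suit_grid`.
#' @param origin_cell `c(row, col)` of the founding cell (must be
#'   settleable).
#' @param start_year Start of the run, sim BP (> 500).
#' @param seed Optional integer seed.
#' @return A `sim_state` environment.
#' @export
init_run <- function(params, grid, origin_cell, start_year, seed = NULL) {
  stopifnot(inherits(params, "sim_params"), inherits(grid, "suit_grid"))
  if (start_year <= 500)
    stop("start_year must exceed the 500 sim BP termination bound",
         call. = FALSE)
  r <- as.integer(origin_cell[1]); c <- as.integer(origin_cell[2])
  if (r < 1 || r > grid$nrow || c < 1 || c > grid$ncol ||
      !grid$settleable[r, c])
    stop("origin cell is not settleable", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$grid <- grid
  st$year <- as.integer(start_year)
  st$start_year <- as.integer(start_year)
  nr <- grid$nrow; nc <- grid$ncol
  st$claimed <- matrix(0L, nr, nc)    # claiming village id, 0 = free
  st$homes <- matrix(0L, nr, nc)      # home-cell indicator
  st$arrival <- matrix(NA_real_, nr, nc)
  ck <- grid$cell_km
  st$off <- list(
    claim = .offsets(ck, -1, params$catchment_km, nr),
    ring = .offsets(ck, params$catchment_km, params$catchment_km + ck, nr),
    leap = if (params$leap_km > 0)
      .offsets(ck, params$leap_km - ck, params$leap_km + ck, nr),
    neigh = .offsets(ck, 0, 2 * params$catchment_km, nr))
  cap <- 1024L
  st$n <- 1L
  st$pop <- numeric(cap)
  st$hr <- integer(cap); st$hc <- integer(cap)
  st$yrs <- integer(cap)
  st$active <- logical(cap)
  st$claims <- vector("list", cap)
  lin <- (c - 1L) * nr + r
  st$pop[1] <- params$fission_threshold
  st$hr[1] <- r; st$hc[1] <- c
  st$active[1] <- TRUE
  st$claims[[1]] <- lin
  st$claimed[lin] <- 1L
  st$homes[lin] <- 1L
  st$arrival[lin] <- start_year
  class(st) <- "sim_state"
  st
}

# advance the simulation k steps; returns the total-population history
.run_steps <- function(st, k) {
  grid <- st$grid
  nr <- grid$nrow; nc <- grid$ncol
  suit <- grid$suitability; settle <- grid$settleable
  prm <- st$params
  kstar <- prm$k_star
  thr <- prm$fission_threshold
  perm <- prm$permanence
  gfac <- 1 + prm$a
  o_claim <- st$off$claim; o_ring <- st$off$ring
  o_leap <- st$off$leap; o_neigh <- st$off$neigh
  leap_on <- !is.null(o_leap)
  claimed <- st$claimed; homes <- st$homes; arrival <- st$arrival
  pop <- st$pop; hr <- st$hr; hc <- st$hc
  yrs <- st$yrs; active <- st$active; claims <- st$claims
  n <- st$n; year <- st$year
  hist <- numeric(k)

  # in-bounds candidate linear indices around (r, c); fast path away from
  # the grid edge
  cand <- function(r, c, off) {
    if (r > off$m && r <= nr - off$m && c > off$m && c <= nc - off$m)
      return((c - 1L) * nr + r + off$dlin)
    rr <- r + off$dr; cc <- c + off$dc
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    (cc[ok] - 1L) * nr + rr[ok]
  }
  # best free settleable candidate (highest suitability, random tie-break);
  # 0 if none. min_suit filters leap targets to better land than home.
  best_free <- function(lin, min_suit = -Inf) {
    lin <- lin[claimed[lin] == 0L & settle[lin]]
    if (!length(lin)) return(0L)
    s <- suit[lin]
    if (min_suit > -Inf) {
      keep <- s > min_suit
      lin <- lin[keep]; s <- s[keep]
      if (!length(lin)) return(0L)
    }
    top <- lin[s == max(s)]
    if (length(top) > 1L) top <- top[sample.int(length(top), 1L)]
    top
  }

  for (s in seq_len(k)) {
    ids <- which(active[seq_len(n)])
    if (length(ids) > 1L) ids <- ids[sample.int(length(ids))]
    for (i in ids) {
      r <- hr[i]; c <- hc[i]
      hlin <- (c - 1L) * nr + r
      # -- growth (with incremental cell claiming) --
      pop_i <- pop[i] * gfac
      clamped <- FALSE
      if (pop_i > kstar * length(claims[[i]])) {
        tgt <- best_free(cand(r, c, o_claim))
        if (tgt > 0L) {
          claimed[tgt] <- i
          claims[[i]] <- c(claims[[i]], tgt)
          if (is.na(arrival[tgt])) arrival[tgt] <- year
        } else {
          pop_i <- kstar * length(claims[[i]])
          clamped <- TRUE
        }
      }
      pop[i] <- pop_i
      # -- fission --
      if (pop_i >= thr) {
        tgt <- 0L
        if (sum(homes[cand(r, c, o_neigh)]) <= 6L)
          tgt <- best_free(cand(r, c, o_ring))
        if (tgt == 0L && leap_on)
          tgt <- best_free(cand(r, c, o_leap), min_suit = suit[hlin])
        if (tgt > 0L) {
          half <- pop_i / 2
          pop[i] <- half
          n <- n + 1L
          if (n > length(pop)) {
            len <- length(pop)
            pop <- c(pop, numeric(len)); hr <- c(hr, integer(len))
            hc <- c(hc, integer(len)); yrs <- c(yrs, integer(len))
            active <- c(active, logical(len))
            claims <- c(claims, vector("list", len))
          }
          pop[n] <- half
          hr[n] <- ((tgt - 1L) %% nr) + 1L
          hc[n] <- ((tgt - 1L) %/% nr) + 1L
          yrs[n] <- 0L
          active[n] <- TRUE
          claims[[n]] <- tgt
          claimed[tgt] <- n
          homes[tgt] <- 1L
          if (is.na(arrival[tgt])) arrival[tgt] <- year
        }
        # else: no space and no leap target; population may exceed the
        # fission threshold and keep growing toward its ceiling
      }
      # -- relocation --
      moved <- FALSE
      if (yrs[i] > perm) {
        tgt <- best_free(cand(r, c, o_ring))
        if (tgt == 0L && leap_on)
          tgt <- best_free(cand(r, c, o_leap), min_suit = suit[hlin])
        if (tgt > 0L) {
          claimed[claims[[i]]] <- 0L
          homes[hlin] <- 0L
          hr[i] <- ((tgt - 1L) %% nr) + 1L
          hc[i] <- ((tgt - 1L) %/% nr) + 1L
          claims[[i]] <- tgt
          claimed[tgt] <- i
          homes[tgt] <- 1L
          if (is.na(arrival[tgt])) arrival[tgt] <- year
          yrs[i] <- 0L
          moved <- TRUE
        }
      }
      if (!moved) yrs[i] <- yrs[i] + 1L
      # -- deactivation: at ceiling with nowhere to claim, settle or move --
      if (clamped && !moved) {
        r <- hr[i]; c <- hc[i]
        if (best_free(cand(r, c, o_ring)) == 0L &&
            (!leap_on ||
             best_free(cand(r, c, o_leap), min_suit = suit[hlin]) == 0L))
          active[i] <- FALSE
      }
    }
    year <- year - 1L
    hist[s] <- sum(pop[seq_len(n)])
  }

  st$claimed <- claimed; st$homes <- homes; st$arrival <- arrival
  st$pop <- pop; st$hr <- hr; st$hc <- hc
  st$yrs <- yrs; st$active <- active; st$claims <- claims
  st$n <- n; st$year <- year
  hist
}

#' Advance the simulation by one year
#'
#' Each active village, in seeded-random order, grows (claiming one more
#' catchment cell per over-ceiling year when space allows, otherwise
#' clamped to its ceiling), attempts fission once at the fission threshold
#' (blocked above six neighbouring villages, falling back to leapfrogging
#' onto strictly better land), and attempts relocation once past its
#' permanence time. Villages at their ceiling with nowhere left to claim,
#' settle or move become inactive. The clock then decreases by one year.
#'
#' @param st A `sim_state` environment.
#' @return `st`, invisibly (modified in place).
#' @export
step_sim <- function(st) {
  stopifnot(inherits(st, "sim_state"))
  if (st$year <= 500) stop("simulation already at the 500 sim BP bound",
                           call. = FALSE)
  .run_steps(st, 1L)
  invisible(st)
}

#' Run an expansion simulation to 500 sim BP
#'
#' Steps the model from `start_year` down to 500 sim BP (the approximate
#' horizon of European contact) and collects the first-arrival raster and
#' the total-population trajectory.
#'
#' @inheritParams init_run
#' @return A list of class `sim_result` with `arrival` (matrix of first
#'   settlement years in sim BP, NA where never settled), `pop_history`
#'   (total population per step, named by sim BP year), `n_villages`,
#'   `params`, and the final `state`.
#' @export
run_expansion <- function(params, grid, origin_cell, start_year,
                          seed = NULL) {
  st <- init_run(params, grid, origin_cell, start_year, seed = seed)
  n_steps <- st$start_year - 500L
  hist <- .run_steps(st, n_steps)
  names(hist) <- seq.int(st$start_year - 1L, by = -1L, length.out = n_steps)
  structure(list(arrival = st$arrival, pop_history = hist,
                 n_villages = st$n, params = params, state = st),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Expansion simulation: ", x$n_villages, " villages founded, ",
      sum(!is.na(x$arrival)), " cells settled; final population ",
      round(utils::tail(x$pop_history, 1)), "\n", sep = "")
  invisible(x)
}

#' Realized front speed of a simulated expansion
#'
#' Fits an ordinary regression of front distance against elapsed time, where
#' the front distance at each year is the largest origin distance among cells
#' settled up to that year. The earliest `burn_in` fraction of the run is
#' discarded before fitting.
#'
#' @param result A `sim_result`.
#' @param origin_cell `c(row, col)` used for the run.
#' @param burn_in Fraction of the elapsed run discarded as burn-in.
#' @return List with `speed_kmyr`, `r_squared`, and the `front` data.frame
#'   (year, distance km).
#' @export
front_speed <- function(result, origin_cell, burn_in = 0.2) {
  arr <- result$arrival
  st <- result$state
  ck <- st$grid$cell_km
  idx <- which(!is.na(arr))
  rr <- ((idx - 1L) %% nrow(arr)) + 1L
  cc <- ((idx - 1L) %/% nrow(arr)) + 1L
  d <- sqrt((rr - origin_cell[1])^2 + (cc - origin_cell[2])^2) * ck
  yr <- arr[idx]
  front <- vapply(split(d, -yr), max, numeric(1))
  year_seq <- sort(unique(yr), decreasing = TRUE)
  front <- cummax(front)
  elapsed <- st$start_year - year_seq
  keep <- elapsed >= burn_in * max(elapsed)
  fit <- stats::lm(front[keep] ~ elapsed[keep])
  list(speed_kmyr = unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared,
       front = data.frame(year = year_seq, dist_km = front))
}
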