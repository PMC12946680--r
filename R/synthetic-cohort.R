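# Simulated flower cohorts. Fates follow sequential Bernoulli gates:
# every flower sheds its petals; with probability p_flowerPP the whole
# flower is shed at the pedicel-peduncle (PP) junction; survivors undergo
# calyx abscission, after which the developing fruit is shed at the fruit
# PP gate with probability p_fruitPP or retained to final fruit set.
# Event days (DPA, days post-anthesis) are Normal per event, truncated at
# zero and forced monotone along each flower's path by resampling. Fruit
# and seed sizes are log-normal with a reduced mean in abscised groups.

#' Parameters of a simulated flower cohort
#'
#' Defaults describe a Yoshino-cherry-like season: 42.6% of flowers shed
#' at the flower PP gate, 73.0% of calyx-abscised fruits shed at the fruit
#' PP gate (final fruit set ~15.6%), event timing centered at ~3.5 / 9 /
#' 14.5 / 19 / 29 DPA for petal, flower PP, calyx, fruit PP and peduncle
#' events, abscised fruits ~38.5% the size of retained ones (seeds ~16.7%),
#' and peduncles abscising with probability 0.95 once all their pedicels
#' are gone (never while one remains).
#'
#' @param n_flowers number of flowers.
#' @param p_flowerPP probability of shedding at the flower pedicel-peduncle
#'   gate (vs surviving to calyx abscission).
#' @param p_fruitPP probability a calyx-abscised fruit is shed at the fruit
#'   pedicel-peduncle gate.
#' @param timing data.frame with columns `event` (petal, flowerPP, calyx,
#'   fruitPP, peduncle), `mean_dpa`, `sd_dpa`.
#' @param size_ratio_abscised ratio of mean fruit size, abscised vs
#'   retained, in (0, 1].
#' @param seed_size_ratio_abscised same ratio for seed size.
#' @param size_cv coefficient of variation of the log-normal sizes.
#' @param fruit_size_mean_mm,seed_size_mean_mm mean sizes of retained
#'   fruits/seeds in mm.
#' @param petals_at_flowerPP species flag: `TRUE` if petals are still
#'   attached when the flower PP gate fires (whole-flower abscission, as in
#'   *P. sargentii*); `FALSE` if petals are shed beforehand.
#' @param p_peduncle probability a peduncle abscises once all of its
#'   pedicels have been shed.
#' @param flowers_per_peduncle integer vector of possible pedicel counts
#'   per peduncle (sampled uniformly).
#' @param n_trees number of trees flowers are spread over.
#' @param seed RNG seed; a single seeded stream drives the whole cohort.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n_flowers = 500,
                          p_flowerPP = 0.426,
                          p_fruitPP = 0.730,
                          timing = data.frame(
                            event = c("petal", "flowerPP", "calyx", "fruitPP",
                                      "peduncle"),
                            mean_dpa = c(3.5, 9, 14.5, 19, 29),
                            sd_dpa = c(0.8, 1.5, 1.5, 2, 3)),
                          size_ratio_abscised = 0.385,
                          seed_size_ratio_abscised = 0.167,
                          size_cv = 0.25,
                          fruit_size_mean_mm = 8,
                          seed_size_mean_mm = 4,
                          petals_at_flowerPP = FALSE,
                          p_peduncle = 0.95,
                          flowers_per_peduncle = 2:4,
                          n_trees = 5,
                          seed = 1L) {
  if (n_flowers <= 0) stop("n_flowers must be positive", call. = FALSE)
  stopifnot(p_flowerPP >= 0, p_flowerPP <= 1, p_fruitPP >= 0, p_fruitPP <= 1,
            p_peduncle >= 0, p_peduncle <= 1,
            size_ratio_abscised > 0, size_ratio_abscised <= 1,
            seed_size_ratio_abscised > 0, seed_size_ratio_abscised <= 1,
            size_cv > 0, all(timing$sd_dpa > 0),
            all(c("petal", "flowerPP", "calyx", "fruitPP", "peduncle")
                %in% timing$event))
  structure(list(n_flowers = as.integer(n_flowers), p_flowerPP = p_flowerPP,
                 p_fruitPP = p_fruitPP, timing = timing,
                 size_ratio_abscised = size_ratio_abscised,
                 seed_size_ratio_abscised = seed_size_ratio_abscised,
                 size_cv = size_cv, fruit_size_mean_mm = fruit_size_mean_mm,
                 seed_size_mean_mm = seed_size_mean_mm,
                 petals_at_flowerPP = isTRUE(petals_at_flowerPP),
                 p_peduncle = p_peduncle,
                 flowers_per_peduncle = as.integer(flowers_per_peduncle),
                 n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "cohort_params")
}

# Draw n rows of monotone non-negative event-day paths, one column per
# event, by whole-path resampling (preserves marginals approximately).
draw_monotone_paths <- function(n, means, sds, max_try = 100L) {
  k <- length(means)
  out <- matrix(NA_real_, n, k)
  todo <- seq_len(n)
  for (a in seq_len(max_try)) {
    if (!length(todo)) break
    m <- matrix(rnorm(length(todo) * k,
                      mean = rep(means, each = length(todo)),
                      sd = rep(sds, each = length(todo))),
                ncol = k)
    ok <- rowSums(m < 0) == 0L
    if (k > 1L)
      for (j in 2:k) ok <- ok & (m[, j] >= m[, j - 1L])
    out[todo[ok], ] <- m[ok, , drop = FALSE]
    todo <- todo[!ok]
  }
  if (length(todo))
    stop("could not draw ordered event times in ", max_try,
         " attempts; check timing means/SDs", call. = FALSE)
  out
}

# mean-parameterized log-normal: E[X] = m, CV = cv
rlnorm_mean_cv <- function(n, m, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a flower cohort with known gate probabilities
#'
#' Draws each flower's fate through the sequential abscission gates of
#' [cohort_params()], with monotone truncated-Normal event days and
#' log-normal sizes, grouped into peduncles of 2-4 pedicels on a handful of
#' trees. Output satisfies all record invariants checked by
#' [validate_records()] and is byte-reproducible given the seed.
#'
#' @param params a [cohort_params()].
#' @return A data.frame with one row per flower and the cohort-table
#'   schema (`flower_id`, `tree_id`, `peduncle_id`, `pollinated`,
#'   `petal_abscission_dpa`, `flowerPP_dpa`, `calyx_dpa`, `fruitPP_dpa`,
#'   `retained`, `fruit_size_mm`, `seed_size_mm`, `n_petals_at_flowerPP`);
#'   the per-peduncle event table is attached as attribute `"peduncles"`
#'   (accessor [cohort_peduncles()]).
#' @export
simulate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  tm <- function(ev) p$timing$mean_dpa[match(ev, p$timing$event)]
  ts <- function(ev) p$timing$sd_dpa[match(ev, p$timing$event)]

  with_local_seed(p$seed, {
    n <- p$n_flowers
    # peduncle structure
    sizes <- integer(0)
    while (sum(sizes) < n)
      sizes <- c(sizes, if (length(p$flowers_per_peduncle) == 1L)
        p$flowers_per_peduncle else sample(p$flowers_per_peduncle, 1L))
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
    ped_id <- rep(seq_along(sizes), sizes)
    tree_id <- ((seq_along(sizes) - 1L) %% p$n_trees + 1L)[ped_id]

    fate_flowerPP <- runif(n) < p$p_flowerPP
    fate_fruitPP <- !fate_flowerPP & (runif(n) < p$p_fruitPP)
    retained <- !fate_flowerPP & !fate_fruitPP

    petal <- rep(NA_real_, n); fpp <- rep(NA_real_, n)
    calyx <- rep(NA_real_, n); frpp <- rep(NA_real_, n)

    nf <- sum(fate_flowerPP)
    if (nf) {
      if (p$petals_at_flowerPP) {
        # petals still attached: shed together with the pedicel
        d <- draw_monotone_paths(nf, tm("flowerPP"), ts("flowerPP"))
        petal[fate_flowerPP] <- d[, 1]
        fpp[fate_flowerPP] <- d[, 1]
      } else {
        d <- draw_monotone_paths(nf, c(tm("petal"), tm("flowerPP")),
                                 c(ts("petal"), ts("flowerPP")))
        petal[fate_flowerPP] <- d[, 1]
        fpp[fate_flowerPP] <- d[, 2]
      }
    }
    nr <- sum(retained)
    if (nr) {
      d <- draw_monotone_paths(nr, c(tm("petal"), tm("calyx")),
                               c(ts("petal"), ts("calyx")))
      petal[retained] <- d[, 1]; calyx[retained] <- d[, 2]
    }
    nq <- sum(fate_fruitPP)
    if (nq) {
      d <- draw_monotone_paths(nq,
                               c(tm("petal"), tm("calyx"), tm("fruitPP")),
                               c(ts("petal"), ts("calyx"), ts("fruitPP")))
      petal[fate_fruitPP] <- d[, 1]; calyx[fate_fruitPP] <- d[, 2]
      frpp[fate_fruitPP] <- d[, 3]
    }

    fruit_size <- numeric(n)
    abscised <- fate_flowerPP | fate_fruitPP
    fruit_size[abscised] <- rlnorm_mean_cv(sum(abscised),
      p$fruit_size_mean_mm * p$size_ratio_abscised, p$size_cv)
    fruit_size[retained] <- rlnorm_mean_cv(nr, p$fruit_size_mean_mm, p$size_cv)

    seed_size <- rep(NA_real_, n)
    seed_size[fate_fruitPP] <- rlnorm_mean_cv(nq,
      p$seed_size_mean_mm * p$seed_size_ratio_abscised, p$size_cv)
    seed_size[retained] <- rlnorm_mean_cv(nr, p$seed_size_mean_mm, p$size_cv)

    npet <- rep(NA_integer_, n)
    npet[fate_flowerPP] <- if (p$petals_at_flowerPP)
      rbinom(nf, 5L, 0.9) else 0L

    flowers <- data.frame(
      flower_id = sprintf("F%05d", seq_len(n)),
      tree_id = sprintf("T%02d", tree_id),
      peduncle_id = sprintf("P%04d", ped_id),
      pollinated = !fate_flowerPP,
      petal_abscission_dpa = round(petal, 2),
      flowerPP_dpa = round(fpp, 2),
      calyx_dpa = round(calyx, 2),
      fruitPP_dpa = round(frpp, 2),
      retained = retained,
      fruit_size_mm = round(fruit_size, 3),
      seed_size_mm = round(seed_size, 3),
      n_petals_at_flowerPP = npet,
      stringsAsFactors = FALSE)

    # peduncle events: abscission only once every pedicel has been shed
    shed <- abscised
    n_shed <- tapply(shed, ped_id, sum)
    n_ped <- tabulate(ped_id)
    empty <- as.vector(n_shed) == n_ped
    absc <- empty & (runif(length(sizes)) < p$p_peduncle)
    last_day <- tapply(pmax(fpp, frpp, na.rm = TRUE), ped_id,
                       function(x) suppressWarnings(max(x, na.rm = TRUE)))
    ped_day <- rep(NA_real_, length(sizes))
    if (any(absc)) {
      draw <- rnorm(sum(absc), tm("peduncle"), ts("peduncle"))
      floor_day <- ifelse(is.finite(last_day[absc]), last_day[absc], 0)
      ped_day[absc] <- round(pmax(pmax(draw, 0), floor_day), 2)
    }
    peduncles <- data.frame(
      peduncle_id = sprintf("P%04d", seq_along(sizes)),
      tree_id = sprintf("T%02d", (seq_along(sizes) - 1L) %% p$n_trees + 1L),
      n_pedicels = n_ped,
      n_pedicels_shed = as.integer(n_shed),
      all_pedicels_shed = empty,
      peduncle_abscised = absc,
      peduncle_dpa = ped_day,
      stringsAsFactors = FALSE)

    attr(flowers, "peduncles") <- peduncles
    attr(flowers, "params") <- p
    flowers
  })
}

#' Per-peduncle event table of a simulated cohort
#'
#' @param cohort output of [simulate_cohort()].
#' @return The peduncle event data.frame.
#' @export
cohort_peduncles <- function(cohort) {
  ped <- attr(cohort, "peduncles")
  if (is.null(ped)) stop("cohort carries no peduncle table", call. = FALSE)
  ped
}
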