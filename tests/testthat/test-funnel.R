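# hand-built toy cohort: 4 shed at flower PP, 6 calyx-abscised of which
# 3 shed at fruit PP and 3 retained
toy_cohort <- function() {
  data.frame(
    flower_id = sprintf("F%02d", 1:10),
    tree_id = "T01",
    peduncle_id = rep(c("P01", "P02", "P03"), c(4, 3, 3)),
    pollinated = c(rep(FALSE, 4), rep(TRUE, 6)),
    petal_abscission_dpa = 3,
    flowerPP_dpa = c(9, 9.5, 8, 10, rep(NA, 6)),
    calyx_dpa = c(rep(NA, 4), 14, 15, 14, 15, 14, 15),
    fruitPP_dpa = c(rep(NA, 4), 19, 20, 19, NA, NA, NA),
    retained = c(rep(FALSE, 7), TRUE, TRUE, TRUE),
    fruit_size_mm = 5,
    seed_size_mm = NA,
    n_petals_at_flowerPP = NA,
    stringsAsFactors = FALSE)
}

test_that("the ten-flower toy funnel matches hand-computed proportions", {
  fs <- funnel_summary(toy_cohort())
  g <- fs$gates
  expect_equal(g$absolute[g$gate == "flowerPP"], 0.4)
  expect_equal(g$conditional[g$gate == "fruitPP"], 0.5)
  expect_equal(fs$retained$absolute, 0.3)
  expect_equal(g$entering, c(10, 6, 6))
  expect_equal(sum(fs$fate_counts), 10)
})

test_that("an all-retained cohort has zero abscission at the branching gates", {
  co <- toy_cohort()
  co$flowerPP_dpa <- NA
  co$fruitPP_dpa <- NA
  co$calyx_dpa <- 14
  co$retained <- TRUE
  fs <- funnel_summary(co)
  expect_equal(fs$gates$conditional[fs$gates$gate == "flowerPP"], 0)
  expect_equal(fs$gates$conditional[fs$gates$gate == "fruitPP"], 0)
  expect_equal(fs$retained$absolute, 1)
})

test_that("fate classification is deterministic on each path", {
  co <- toy_cohort()
  expect_equal(classify_fate(co[1, ]), "shed_at_flowerPP")
  expect_equal(classify_fate(co[5, ]), "shed_at_fruitPP")
  expect_equal(classify_fate(co[8, ]), "retained")
  bad <- co[1, ]
  bad$flowerPP_dpa <- NA
  expect_error(classify_fate(bad), "unclassifiable")
})

test_that("validation flags rule violations and passes clean records", {
  co <- toy_cohort()
  co$calyx_dpa[1] <- 14            # both flowerPP and calyx
  co$fruitPP_dpa[5] <- 10          # fruit PP before calyx
  rep <- validate_records(co)
  expect_true("mutually exclusive fates" %in% rep$violations$rule)
  expect_true("event order" %in% rep$violations$rule)
  expect_equal(nrow(rep$clean), 8)
  expect_equal(nrow(validate_records(toy_cohort())$violations), 0)
})

test_that("censored flowers are excluded from denominators but reported", {
  co <- toy_cohort()
  cens <- co[1, ]
  cens$flower_id <- "F99"
  cens$flowerPP_dpa <- NA
  cens$petal_abscission_dpa <- NA
  fs <- funnel_summary(rbind(co, cens))
  expect_equal(fs$n_censored, 1)
  expect_equal(fs$n_total, 10)
  expect_equal(fs$gates$absolute[1], 0.4)
})

test_that("timing summaries use the sample SD and demand n >= 2", {
  co <- toy_cohort()
  co$petal_abscission_dpa <- c(3, 4, 5, rep(NA, 7))
  ts <- timing_summary(co, "petal")
  expect_equal(ts$mean_dpa, 4)
  expect_equal(ts$sd_dpa, 1)
  expect_equal(ts$n, 3)

  co$calyx_dpa[!is.na(co$calyx_dpa)] <- 14
  expect_equal(timing_summary(co, "calyx")$sd_dpa, 0)

  co$fruitPP_dpa <- c(rep(NA, 9), 19)
  expect_error(timing_summary(co, "fruitPP"), "fewer than 2")
})

test_that("summaries are invariant to record order", {
  co <- simulate_cohort(cohort_params(n_flowers = 300, seed = 8))
  fs1 <- funnel_summary(co)
  fs2 <- funnel_summary(co[rev(seq_len(nrow(co))), ])
  expect_equal(fs1$gates, fs2$gates)
  expect_equal(fs1$timing, fs2$timing)
})

test_that("the absolute fruit PP proportion factorizes along the path", {
  co <- simulate_cohort(cohort_params(n_flowers = 1234, seed = 9))
  g <- funnel_summary(co)$gates
  expect_equal(g$absolute[g$gate == "fruitPP"],
               (1 - g$conditional[g$gate == "flowerPP"]) *
                 g$conditional[g$gate == "calyx"] *
                 g$conditional[g$gate == "fruitPP"],
               tolerance = 1e-12)
})

test_that("the peduncle rule report separates empty and occupied peduncles", {
  co <- toy_cohort()
  # P01: all four pedicels shed; P02: all three shed; P03: retains pedicels
  co$fruitPP_dpa[5:7] <- 19
  peds <- data.frame(peduncle_id = c("P01", "P02", "P03"),
                     peduncle_abscised = c(TRUE, FALSE, FALSE))
  rep <- peduncle_rule(co, peds)
  expect_equal(rep$aggregate$n_empty, 2)
  expect_equal(rep$aggregate$prop_abscised_when_empty, 0.5)
  expect_equal(rep$aggregate$prop_abscised_with_pedicel, 0)

  # orphan peduncle id in the records
  co$peduncle_id[1] <- "P99"
  expect_error(peduncle_rule(co, peds), "unknown peduncle")

  # peduncle with zero flowers excluded with a warning
  peds2 <- rbind(peds, data.frame(peduncle_id = "P04",
                                  peduncle_abscised = FALSE))
  expect_warning(peduncle_rule(toy_cohort(), peds2), "zero flowers")
})

test_that("simulated peduncle abscission recovers the generating probability", {
  co <- simulate_cohort(cohort_params(n_flowers = 4000, seed = 10,
                                      p_peduncle = 0.9))
  rep <- peduncle_rule(co, cohort_peduncles(co))
  n_empty <- rep$aggregate$n_empty
  se <- sqrt(0.9 * 0.1 / n_empty)
  expect_lt(abs(rep$aggregate$prop_abscised_when_empty - 0.9), 3 * se)
  expect_equal(rep$aggregate$prop_abscised_with_pedicel, 0)
})
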