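# The abscission funnel: sequential retention accounting across the
# hierarchy petal -> flower PP -> calyx -> fruit PP -> final fruit set.
# Petal shedding is summarized (timing, petals present at the flower PP
# gate) but is not a branching gate, since it occurs on both fates; the
# branching gates are flower PP (whole-flower loss), then, among
# calyx-abscised fruits, fruit PP (fruit loss) vs retention.

COHORT_COLUMNS <- c("flower_id", "tree_id", "peduncle_id", "pollinated",
                    "petal_abscission_dpa", "flowerPP_dpa", "calyx_dpa",
                    "fruitPP_dpa", "retained", "fruit_size_mm",
                    "seed_size_mm", "n_petals_at_flowerPP")

#' Validate flower fate records
#'
#' Checks every record against the longitudinal-fate invariants: the flower
#' PP and calyx fates are mutually exclusive; a fruit PP event requires a
#' prior calyx event and cannot precede it; event days are non-negative and
#' non-decreasing along the path petal -> flower PP / calyx -> fruit PP;
#' a retained flower cannot also carry a shedding event.
#'
#' @param records cohort data.frame (see [simulate_cohort()] for schema).
#' @return List with `violations` (data.frame `flower_id`, `rule`) and
#'   `clean` (the records free of violations).
#' @export
validate_records <- function(records) {
  missing_cols <- setdiff(c("flower_id", "flowerPP_dpa", "calyx_dpa",
                            "fruitPP_dpa", "retained"), names(records))
  if (length(missing_cols))
    stop("records lack required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  v <- list()
  bad <- function(mask, rule) {
    if (any(mask, na.rm = TRUE))
      v[[length(v) + 1L]] <<- data.frame(
        flower_id = records$flower_id[which(mask)], rule = rule)
  }
  has_f <- !is.na(records$flowerPP_dpa)
  has_c <- !is.na(records$calyx_dpa)
  has_q <- !is.na(records$fruitPP_dpa)
  bad(has_f & has_c, "mutually exclusive fates")
  bad(has_q & !has_c, "fruit PP event without calyx event")
  bad(has_q & has_c & records$fruitPP_dpa < records$calyx_dpa, "event order")
  bad(records$retained & (has_f | has_q), "retained flower with shedding event")
  pet <- records$petal_abscission_dpa
  if (!is.null(pet)) {
    bad(!is.na(pet) & pet < 0, "negative event day")
    bad(!is.na(pet) & has_f & records$flowerPP_dpa < pet, "event order")
    bad(!is.na(pet) & has_c & records$calyx_dpa < pet, "event order")
  }
  for (col in c("flowerPP_dpa", "calyx_dpa", "fruitPP_dpa"))
    bad(!is.na(records[[col]]) & records[[col]] < 0, "negative event day")
  violations <- if (length(v)) {
    out <- do.call(rbind, v); rownames(out) <- NULL; out
  } else data.frame(flower_id = character(0), rule = character(0))
  dirty <- records$flower_id %in% violations$flower_id
  list(violations = violations, clean = records[!dirty, , drop = FALSE])
}

# vectorized fate classification; "censored" = no gate information at all
classify_fates <- function(records) {
  has_f <- !is.na(records$flowerPP_dpa)
  has_c <- !is.na(records$calyx_dpa)
  has_q <- !is.na(records$fruitPP_dpa)
  ret <- !is.na(records$retained) & records$retained
  fate <- rep("censored", nrow(records))
  fate[has_f] <- "shed_at_flowerPP"
  fate[!has_f & has_c & has_q] <- "shed_at_fruitPP"
  fate[!has_f & has_c & !has_q & ret] <- "retained"
  factor(fate, levels = c("shed_at_flowerPP", "shed_at_fruitPP",
                          "retained", "censored"))
}

#' Terminal fate of a single flower record
#'
#' Deterministic mapping from event flags to one of `shed_at_flowerPP`,
#' `shed_at_fruitPP` or `retained`.
#'
#' @param record a one-row cohort data.frame.
#' @return Character scalar, the terminal fate.
#' @export
classify_fate <- function(record) {
  stopifnot(nrow(record) == 1L)
  f <- as.character(classify_fates(record))
  if (f == "censored")
    stop("record ", record$flower_id,
         " is unclassifiable: no flower PP, no calyx event, not retained",
         call. = FALSE)
  f
}

#' Summarize the abscission funnel of a cohort
#'
#' Builds the gate-by-gate retention summary: entering counts, event
#' counts, absolute proportions (of all classifiable flowers) and
#' conditional proportions (of gate entrants), plus per-event timing
#' (mean, sample SD, n). Flowers carrying no gate information are counted
#' in a separate censored bucket and excluded from all denominators.
#'
#' @param records cohort data.frame.
#' @return A `funnel_summary`: list with `n_total` (classifiable flowers),
#'   `n_censored`, `gates` (data.frame `gate`, `entering`, `events`,
#'   `absolute`, `conditional`), `retained` (count + proportions), and
#'   `timing` (per-event mean/sd/n).
#' @export
funnel_summary <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop("no records supplied", call. = FALSE)
  fate <- classify_fates(records)
  n_cens <- sum(fate == "censored")
  used <- records[fate != "censored", , drop = FALSE]
  fate <- fate[fate != "censored"]
  n <- nrow(used)
  if (n == 0L) stop("all records are censored", call. = FALSE)

  n_fpp <- sum(fate == "shed_at_flowerPP")
  n_calyx_entering <- n - n_fpp
  n_calyx <- sum(!is.na(used$calyx_dpa))
  n_frpp <- sum(fate == "shed_at_fruitPP")
  n_ret <- sum(fate == "retained")

  gates <- data.frame(
    gate = c("flowerPP", "calyx", "fruitPP"),
    entering = c(n, n_calyx_entering, n_calyx),
    events = c(n_fpp, n_calyx, n_frpp),
    absolute = c(n_fpp, n_calyx, n_frpp) / n,
    conditional = c(n_fpp / n,
                    if (n_calyx_entering > 0) n_calyx / n_calyx_entering else NA,
                    if (n_calyx > 0) n_frpp / n_calyx else NA))

  ev_cols <- c(petal = "petal_abscission_dpa", flowerPP = "flowerPP_dpa",
               calyx = "calyx_dpa", fruitPP = "fruitPP_dpa")
  timing <- do.call(rbind, lapply(names(ev_cols), function(ev) {
    x <- used[[ev_cols[[ev]]]]
    x <- x[!is.na(x)]
    data.frame(event = ev, n = length(x),
               mean_dpa = if (length(x)) mean(x) else NA_real_,
               sd_dpa = if (length(x) > 1) sd(x) else NA_real_)
  }))

  structure(list(
    n_total = n, n_censored = n_cens, gates = gates,
    retained = list(count = n_ret, absolute = n_ret / n,
                    conditional = if (n_calyx > 0) n_ret / n_calyx else NA),
    fate_counts = c(shed_at_flowerPP = n_fpp, shed_at_fruitPP = n_frpp,
                    retained = n_ret),
    timing = timing), class = "funnel_summary")
}

#' @export
print.funnel_summary <- function(x, ...) {
  pc <- function(p) sprintf("%.1f%%", 100 * p)
  g <- x$gates
  cat(sprintf("Abscission funnel (n = %d flowers%s)\n", x$n_total,
              if (x$n_censored) sprintf(", %d censored", x$n_censored) else ""))
  cat(sprintf("  flowers --%s--> shed at flower PP   [%d/%d, abs %s]\n",
              pc(g$conditional[1]), g$events[1], g$entering[1], pc(g$absolute[1])))
  cat(sprintf("      \\--%s--> calyx abscission      [%d/%d, abs %s]\n",
              pc(g$conditional[2]), g$events[2], g$entering[2], pc(g$absolute[2])))
  cat(sprintf("          --%s--> shed at fruit PP   [%d/%d, abs %s]\n",
              pc(g$conditional[3]), g$events[3], g$entering[3], pc(g$absolute[3])))
  cat(sprintf("          \\-----> retained (fruit set) [%d, abs %s]\n",
              x$retained$count, pc(x$retained$absolute)))
  cat("Event timing (DPA):\n")
  for (i in seq_len(nrow(x$timing)))
    cat(sprintf("  %-9s mean %5.2f  SD %5.2f  (n = %d)\n",
                x$timing$event[i], x$timing$mean_dpa[i],
                x$timing$sd_dpa[i], x$timing$n[i]))
  invisible(x)
}

#' Timing of one abscission event
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of the event day over
#' records where the event occurred.
#'
#' @param records cohort data.frame.
#' @param event one of `"petal"`, `"flowerPP"`, `"calyx"`, `"fruitPP"`.
#' @return List `mean_dpa`, `sd_dpa`, `n`.
#' @export
timing_summary <- function(records, event = c("petal", "flowerPP", "calyx",
                                              "fruitPP")) {
  event <- match.arg(event)
  col <- c(petal = "petal_abscission_dpa", flowerPP = "flowerPP_dpa",
           calyx = "calyx_dpa", fruitPP = "fruitPP_dpa")[[event]]
  x <- records[[col]]
  x <- x[!is.na(x)]
  if (length(x) < 2L)
    stop("fewer than 2 records with a ", event, " event", call. = FALSE)
  list(mean_dpa = mean(x), sd_dpa = sd(x), n = length(x))
}

#' Peduncle abscission rule check
#'
#' Tests the all-pedicels-gone rule: peduncles whose pedicels have all been
#' shed abscise at high frequency, while a single remaining pedicel keeps
#' the peduncle intact. A pedicel counts as shed when its flower's fate is
#' `shed_at_flowerPP` or `shed_at_fruitPP`.
#'
#' @param records cohort data.frame with `peduncle_id`.
#' @param peduncles per-peduncle event table with columns `peduncle_id` and
#'   `peduncle_abscised` (see [cohort_peduncles()]).
#' @return A `peduncle_report`: list with `per_peduncle` (data.frame
#'   `peduncle_id`, `n_pedicels`, `n_shed`, `all_shed`, `abscised`) and
#'   `aggregate` (`prop_abscised_when_empty`,
#'   `prop_abscised_with_pedicel`, counts).
#' @export
peduncle_rule <- function(records, peduncles) {
  stopifnot(!is.null(records$peduncle_id), !is.null(peduncles$peduncle_id))
  orphan <- setdiff(records$peduncle_id, peduncles$peduncle_id)
  if (length(orphan))
    stop("records reference unknown peduncle ids: ",
         paste(head(orphan, 5), collapse = ", "), call. = FALSE)
  fate <- classify_fates(records)
  shed <- fate %in% c("shed_at_flowerPP", "shed_at_fruitPP")
  n_ped <- tapply(rep(1L, nrow(records)), records$peduncle_id, sum)
  n_shed <- tapply(shed, records$peduncle_id, sum)
  ids <- names(n_ped)
  empty_ped <- setdiff(peduncles$peduncle_id, ids)
  if (length(empty_ped))
    warning("excluding ", length(empty_ped), " peduncle(s) with zero flowers")
  absc <- peduncles$peduncle_abscised[match(ids, peduncles$peduncle_id)]
  per <- data.frame(peduncle_id = ids,
                    n_pedicels = as.integer(n_ped),
                    n_shed = as.integer(n_shed),
                    all_shed = as.vector(n_shed) == as.vector(n_ped),
                    abscised = absc,
                    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  agg <- list(
    n_empty = sum(per$all_shed),
    n_with_pedicel = sum(!per$all_shed),
    prop_abscised_when_empty =
      if (any(per$all_shed)) mean(per$abscised[per$all_shed]) else NA_real_,
    prop_abscised_with_pedicel =
      if (any(!per$all_shed)) mean(per$abscised[!per$all_shed]) else NA_real_)
  structure(list(per_peduncle = per, aggregate = agg),
            class = "peduncle_report")
}

#' @export
print.peduncle_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("Peduncle rule: %.1f%% of %d fully-shed peduncles abscised; %.1f%% of %d peduncles retaining >= 1 pedicel abscised\n",
              100 * a$prop_abscised_when_empty, a$n_empty,
              100 * a$prop_abscised_with_pedicel, a$n_with_pedicel))
  invisible(x)
}
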