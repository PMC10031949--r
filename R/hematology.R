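#' Per-animal baseline cell counts
#'
#' Baseline is the unweighted mean over all pre-irradiation occasions
#' (records with `day < 0`) for each animal. Animals with no pre-irradiation
#' record are excluded with a warning.
#'
#' @param table Cell-count table (columns `animal`, `day`, `cell_type`,
#'   `count`; see [read_cellcount_table()]).
#' @param cell_type Cell-type label to summarize.
#' @return Data frame with columns `animal` and `baseline`.
#' @export
hema_baseline <- function(table, cell_type) {
  table <- validate_cellcount_table(table)
  sub <- table[table$cell_type == cell_type, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no records for cell type '", cell_type, "'", call. = FALSE)
  animals <- unique(sub$animal)
  pre <- sub[sub$day < 0, , drop = FALSE]
  base <- tapply(pre$count, pre$animal, mean)
  missing <- setdiff(as.character(animals), names(base))
  if (length(missing) > 0L)
    warning("animal(s) with no pre-irradiation record excluded: ",
            paste(missing, collapse = ", "), call. = FALSE)
  if (length(base) == 0L) stop("no animal has a pre-irradiation baseline", call. = FALSE)
  data.frame(animal = names(base), baseline = as.numeric(base),
             row.names = NULL)
}

#' Paired t-tests of each post-irradiation day against baseline
#'
#' Two-sided paired t-test of per-animal counts at each post-irradiation day
#' against the per-animal baseline ([hema_baseline()]). Days with fewer than
#' 3 complete pairs get a missing p-value; degenerate days (zero variance of
#' the paired differences) are reported non-significant with a warning.
#'
#' @inheritParams hema_baseline
#' @param alpha Significance threshold.
#' @return Data frame per post-irradiation day: `day`, `n_pairs`, `mean`,
#'   `sem`, `p`, `significant`.
#' @export
paired_tests <- function(table, cell_type, alpha = 0.05) {
  table <- validate_cellcount_table(table)
  sub <- table[table$cell_type == cell_type, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no records for cell type '", cell_type, "'", call. = FALSE)
  base <- hema_baseline(sub, cell_type)
  days <- sort(unique(sub$day[sub$day > 0]))
  rows <- lapply(days, function(d) {
    dd <- sub[sub$day == d, , drop = FALSE]
    # average replicates within animal-day before pairing
    val <- tapply(dd$count, dd$animal, mean)
    m <- merge(base, data.frame(animal = names(val), value = as.numeric(val)),
               by = "animal")
    n <- nrow(m)
    mu <- mean(m$value)
    sem <- if (n > 1) stats::sd(m$value) / sqrt(n) else NA_real_
    if (n < 3L) return(data.frame(day = d, n_pairs = n, mean = mu, sem = sem,
                                  p = NA_real_, significant = FALSE))
    diffs <- m$value - m$baseline
    if (stats::sd(diffs) == 0) {
      warning("day ", d, ": zero variance of paired differences; reported non-significant",
              call. = FALSE)
      return(data.frame(day = d, n_pairs = n, mean = mu, sem = sem,
                        p = NA_real_, significant = FALSE))
    }
    p <- stats::t.test(m$value, m$baseline, paired = TRUE)$p.value
    data.frame(day = d, n_pairs = n, mean = mu, sem = sem, p = p,
               significant = p < alpha)
  })
  do.call(rbind, rows)
}

#' Percent change of the day mean from the baseline mean
#'
#' `100 * (mean(day) - mean(baseline)) / mean(baseline)`, where both means
#' are taken over animals (each animal contributing its mean at the day, and
#' its pre-irradiation baseline).
#'
#' @inheritParams hema_baseline
#' @param day Post-irradiation day.
#' @return A single percentage (negative = decline).
#' @export
percent_change <- function(table, cell_type, day) {
  table <- validate_cellcount_table(table)
  sub <- table[table$cell_type == cell_type, , drop = FALSE]
  base <- hema_baseline(sub, cell_type)
  mb <- mean(base$baseline)
  if (mb == 0) stop("baseline mean is zero; percent change undefined", call. = FALSE)
  dd <- sub[sub$day == day, , drop = FALSE]
  if (nrow(dd) == 0L) stop("no records at day ", day, call. = FALSE)
  md <- mean(tapply(dd$count, dd$animal, mean))
  100 * (md - mb) / mb
}

#' Nadir and recovery day of a cell-count time course
#'
#' The nadir is the post-irradiation day with the minimum mean count (ties
#' broken to the earliest day). The recovery day is the first day after the
#' nadir at which the paired test against baseline is non-significant
#' (`p >= alpha`, with degenerate/missing p counting as non-significant) AND
#' the day mean is at least `recovery_fraction` of the baseline mean. Both
#' thresholds are configurable; if no day qualifies the recovery day is `NA`.
#'
#' @inheritParams paired_tests
#' @param recovery_fraction Minimum fraction of baseline the mean must reach.
#' @return A list with `nadir_day` and `recovery_day` (`NA` if unattained),
#'   plus the per-day summary table as `summary`.
#' @export
nadir_recovery <- function(table, cell_type, alpha = 0.05,
                           recovery_fraction = 0.8) {
  table <- validate_cellcount_table(table)
  sub <- table[table$cell_type == cell_type, , drop = FALSE]
  tests <- paired_tests(sub, cell_type, alpha = alpha)
  if (nrow(tests) < 3L) stop("need >= 3 post-irradiation days", call. = FALSE)
  base_mean <- mean(hema_baseline(sub, cell_type)$baseline)
  nadir_day <- tests$day[which.min(tests$mean)]  # which.min takes the earliest tie
  after <- tests[tests$day > nadir_day, , drop = FALSE]
  ok <- (is.na(after$p) | after$p >= alpha) &
        after$mean >= recovery_fraction * base_mean
  recovery_day <- if (any(ok)) after$day[which(ok)[1]] else NA_integer_
  list(nadir_day = nadir_day, recovery_day = recovery_day, summary = tests)
}
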