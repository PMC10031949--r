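#' Inverse-SEM-squared regression weights for an MN table
#'
#' Computes, for every observation in a micronucleus table, a regression
#' weight proportional to `1 / SEM(day)^2`, where `SEM(day)` is the standard
#' error of the mean of the MN/BN proportions across the animals sampled on
#' that day. Weights are normalized so their mean over all observations is
#' exactly 1; the normalization makes the weighted fit invariant to any
#' overall rescaling of the raw `1/SEM^2` values.
#'
#' Days with fewer than two observations, or with a zero SEM (identical
#' proportions), cannot provide a finite raw weight; such days fall back to
#' the median SEM across the remaining days, with a warning. If no day yields
#' a usable SEM (for example a single-day table), all weights are 1.
#'
#' @param table MN table: a data frame with columns `animal`, `day`, `bn`,
#'   `mn` (see [read_mn_table()]). Days `<= 0` are treated as day 0.
#' @return A data frame with one row per observation and columns `day`
#'   (mapped day), `sem` (the day-level SEM used) and `weight`.
#' @examples
#' tab <- data.frame(animal = rep(1:3, 2), day = rep(c(0, 5), each = 3),
#'                   bn = 500, mn = c(10, 12, 14, 50, 60, 70))
#' w <- compute_weights(tab)
#' mean(w$weight)  # exactly 1
#' @export
compute_weights <- function(table) {
  table <- validate_mn_table(table)
  day <- pmax(table$day, 0)
  prop <- table$mn / table$bn
  sem_by_day <- tapply(prop, day, function(x) {
    if (length(x) < 2L) NA_real_ else stats::sd(x) / sqrt(length(x))
  })
  sem <- as.numeric(sem_by_day[as.character(day)])
  bad <- is.na(sem) | sem == 0
  if (all(bad)) {
    if (length(unique(day)) > 1L)
      warning("no day has a usable SEM; all weights set to 1", call. = FALSE)
    sem[] <- NA_real_
    w <- rep(1, length(day))
  } else {
    if (any(bad)) {
      fallback <- stats::median(sem[!bad])
      warning(sprintf("%d day(s) with <2 observations or zero SEM; using median SEM %.4g",
                      length(unique(day[bad])), fallback), call. = FALSE)
      sem[bad] <- fallback
    }
    w <- 1 / sem^2
    w <- w * length(w) / sum(w)
  }
  data.frame(day = day, sem = sem, weight = w)
}
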