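#' Two-proportion test on micronucleus counts
#'
#' Compares two MN/BN proportions with the chi-square test on the 2x2 table
#' of (micronucleus, micronucleus-free) cell counts — the classical
#' two-proportions Z-test squared — via [stats::prop.test()]. The Yates
#' continuity correction is on by default and never decreases the p-value.
#'
#' @param mn1,bn1 Micronucleus and binucleate-cell counts for sample 1
#'   (`mn1 <= bn1`).
#' @param mn2,bn2 Counts for sample 2.
#' @param continuity Apply the continuity correction.
#' @return A list of class `prop_test_result`: `statistic` (chi-square),
#'   `p`, `estimate_1`, `estimate_2`, `continuity`.
#' @export
two_proportion_test <- function(mn1, bn1, mn2, bn2, continuity = TRUE) {
  if (bn1 < 1 || bn2 < 1) stop("binucleate counts must be >= 1", call. = FALSE)
  if (mn1 > bn1 || mn2 > bn2)
    stop("mn must not exceed bn (the test treats MN/BN as a proportion)", call. = FALSE)
  if (mn1 < 0 || mn2 < 0) stop("counts must be non-negative", call. = FALSE)
  p1 <- mn1 / bn1; p2 <- mn2 / bn2
  pooled <- (mn1 + mn2) / (bn1 + bn2)
  if (pooled == 0 || pooled == 1) {
    # no information against equality; avoid 0/0 in the chi-square
    res <- list(statistic = 0, p = 1)
  } else {
    pt <- suppressWarnings(
      stats::prop.test(c(mn1, mn2), c(bn1, bn2), correct = continuity))
    res <- list(statistic = unname(pt$statistic), p = pt$p.value)
  }
  structure(c(res, list(estimate_1 = p1, estimate_2 = p2,
                        continuity = continuity)),
            class = "prop_test_result")
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)`, order-preserving, with the family size `m`
#' defaulting to the number of p-values supplied.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param m Family size (>= `length(p_values)`).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < length(p_values))
    stop("family size 'm' must be at least the number of p-values", call. = FALSE)
  stats::p.adjust(p_values, method = "bonferroni", n = m)
}

# Pool replicate wells: total mn and bn per animal at the given (mapped) days.
.pool_counts <- function(table, animal, days, label = NULL) {
  sel <- table$animal == animal & table$day %in% days
  if (!is.null(label)) sel <- sel & table$anticoagulant == label
  c(mn = sum(table$mn[sel]), bn = sum(table$bn[sel]))
}

#' Per-animal late-day versus baseline proportion tests
#'
#' For each animal, pools micronucleus and binucleate counts at the baseline
#' day(s) and at the late day, tests the two proportions against each other,
#' and applies a Bonferroni correction with family size equal to the number
#' of animals actually tested. Animals missing either time point are skipped
#' with a warning. Pre-irradiation days (`day <= 0`) all count as baseline.
#'
#' @param table MN table (columns `animal`, `day`, `bn`, `mn`).
#' @param day_late The late sampling day to compare against baseline.
#' @param alpha Significance threshold applied to the adjusted p-values.
#' @param continuity Passed to [two_proportion_test()].
#' @return Data frame with one row per tested animal: `animal`,
#'   `prop_baseline`, `prop_late`, `statistic`, `p`, `p_adj`, `significant`.
#' @export
day56_vs_baseline <- function(table, day_late = 56L, alpha = 0.05,
                              continuity = TRUE) {
  table <- validate_mn_table(table)
  animals <- unique(table$animal)
  rows <- list(); skipped <- character()
  for (a in animals) {
    base <- .pool_counts(table, a, unique(table$day[table$day <= 0]))
    late <- .pool_counts(table, a, day_late)
    if (base[["bn"]] == 0 || late[["bn"]] == 0) {
      skipped <- c(skipped, as.character(a)); next
    }
    tt <- two_proportion_test(base[["mn"]], base[["bn"]],
                              late[["mn"]], late[["bn"]], continuity = continuity)
    rows[[length(rows) + 1L]] <- data.frame(
      animal = a, prop_baseline = tt$estimate_1, prop_late = tt$estimate_2,
      statistic = tt$statistic, p = tt$p)
  }
  if (length(skipped) > 0L)
    warning("animal(s) missing a time point, skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  if (length(rows) == 0L) stop("no animal has both time points", call. = FALSE)
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni_adjust(out$p)
  out$significant <- out$p_adj < alpha
  out
}

#' Per-animal anticoagulant comparison at one day
#'
#' Tests, for each animal, whether the MN/BN proportion at the given day
#' differs between the two anticoagulant labels present in the table
#' (e.g. heparin vs EDTA), pooling replicate wells per label. Bonferroni
#' correction uses the number of animals tested. The `higher` column records
#' which label has the larger proportion.
#'
#' @param table MN table with an `anticoagulant` column carrying exactly two
#'   labels among the tested rows.
#' @param day The sampling day to compare at.
#' @param alpha Significance threshold on adjusted p-values.
#' @param continuity Passed to [two_proportion_test()].
#' @return Data frame per tested animal: `animal`, the two per-label
#'   proportions, `higher`, `statistic`, `p`, `p_adj`, `significant`.
#' @export
anticoagulant_comparison <- function(table, day, alpha = 0.05,
                                     continuity = TRUE) {
  table <- validate_mn_table(table)
  labels <- sort(unique(table$anticoagulant[table$day == day]))
  if (length(labels) != 2L)
    stop("expected exactly two anticoagulant labels at day ", day,
         ", found: ", paste(labels, collapse = ", "), call. = FALSE)
  animals <- unique(table$animal)
  rows <- list(); skipped <- character()
  for (a in animals) {
    c1 <- .pool_counts(table, a, day, labels[1])
    c2 <- .pool_counts(table, a, day, labels[2])
    if (c1[["bn"]] == 0 || c2[["bn"]] == 0) {
      skipped <- c(skipped, as.character(a)); next
    }
    tt <- two_proportion_test(c1[["mn"]], c1[["bn"]], c2[["mn"]], c2[["bn"]],
                              continuity = continuity)
    rows[[length(rows) + 1L]] <- data.frame(
      animal = a, label_1 = labels[1], prop_1 = tt$estimate_1,
      label_2 = labels[2], prop_2 = tt$estimate_2,
      higher = if (tt$estimate_1 == tt$estimate_2) NA_character_
               else labels[if (tt$estimate_1 > tt$estimate_2) 1 else 2],
      statistic = tt$statistic, p = tt$p)
  }
  if (length(skipped) > 0L)
    warning("animal(s) missing an anticoagulant label at day ", day,
            ", skipped: ", paste(skipped, collapse = ", "), call. = FALSE)
  if (length(rows) == 0L) stop("no animal has both labels at day ", day, call. = FALSE)
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni_adjust(out$p)
  out$significant <- out$p_adj < alpha
  out
}
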