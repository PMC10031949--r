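#' Configuration for differential-molecule calling
#'
#' Defaults mirror common practice for the two modalities: transcripts are
#' typically called at a Benjamini--Hochberg FDR below 0.005 with no fold
#' change floor, proteins at a permutation-based FDR below 0.05 with an
#' absolute log2 fold change of at least 0.58 (1.5-fold).
#'
#' @param method `"bh_fdr"` or `"permutation_fdr"`.
#' @param fdr_threshold Adjusted-p cutoff, in (0, 1).
#' @param lfc_threshold Minimum absolute log2 fold change (>= 0).
#' @param n_perm Number of label permutations (permutation method only).
#' @param seed Seed for the permutation draw.
#' @return An object of class `diff_call_config`.
#' @export
differential_call_config <- function(method = c("bh_fdr", "permutation_fdr"),
                                     fdr_threshold = 0.005, lfc_threshold = 0,
                                     n_perm = 1000L, seed = 1L) {
  method <- match.arg(method)
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    stop("'fdr_threshold' must be in (0, 1)", call. = FALSE)
  if (lfc_threshold < 0) stop("'lfc_threshold' must be >= 0", call. = FALSE)
  structure(list(method = method, fdr_threshold = fdr_threshold,
                 lfc_threshold = lfc_threshold, n_perm = as.integer(n_perm),
                 seed = seed),
            class = "diff_call_config")
}

# Vectorized per-row Welch t statistics for a two-group matrix.
.row_welch <- function(x, g2) {
  x1 <- x[, !g2, drop = FALSE]; x2 <- x[, g2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, lfc = m2 - m1, degenerate = se2 == 0)
}

#' Call differential molecules from a two-group log2 expression matrix
#'
#' Per-feature two-sided unpaired (Welch) t-test of group 2 vs group 1, with
#' p-values adjusted either by Benjamini--Hochberg or by the pooled
#' permutation scheme of [permutation_fdr()]. A feature is called when its
#' adjusted p-value is below `fdr_threshold` and its absolute log2 fold
#' change (`mean(group2) - mean(group1)`, data already on log2 scale) is at
#' least `lfc_threshold`. Zero-variance features cannot be tested; they are
#' flagged and excluded from the adjustment family.
#'
#' @param x Numeric matrix, features x samples, log2 scale; or the list
#'   returned by [simulate_expression_matrix()].
#' @param group Factor/vector with two levels ordering the columns
#'   (comparison is level 2 minus level 1). Taken from `x$group` when `x` is
#'   a simulation result.
#' @param config A [differential_call_config()].
#' @param day,modality Labels stored in the returned molecule list.
#' @return A molecule-list data frame (`molecule`, `day`, `modality`,
#'   `log2fc`, `direction`) of the called features, with the full per-feature
#'   table (columns `molecule`, `log2fc`, `t`, `p`, `p_adj`, `degenerate`,
#'   `called`) as attribute `"table"`.
#' @export
call_differential <- function(x, group = NULL,
                              config = differential_call_config(),
                              day = NA_integer_, modality = "mrna") {
  if (is.list(x) && !is.null(x$x)) { group <- group %||% x$group; x <- x$x }
  if (is.null(group)) stop("'group' is required", call. = FALSE)
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("'group' must have exactly two levels", call. = FALSE)
  if (min(table(group)) < 2L) stop("need >= 2 samples per group", call. = FALSE)
  g2 <- group == levels(group)[2]
  st <- .row_welch(x, g2)
  p <- rep(NA_real_, nrow(x))
  ok <- !st$degenerate
  p[ok] <- 2 * stats::pt(-abs(st$t[ok]), st$df[ok])
  p_adj <- rep(NA_real_, nrow(x))
  if (config$method == "bh_fdr") {
    p_adj[ok] <- stats::p.adjust(p[ok], method = "BH")
  } else {
    p_adj[ok] <- permutation_fdr(x[ok, , drop = FALSE], group,
                                 n_perm = config$n_perm, seed = config$seed)
  }
  called <- ok & !is.na(p_adj) & p_adj < config$fdr_threshold &
            abs(st$lfc) >= config$lfc_threshold
  ids <- rownames(x) %||% sprintf("F%05d", seq_len(nrow(x)))
  full <- data.frame(molecule = ids, log2fc = st$lfc, t = st$t, p = p,
                     p_adj = p_adj, degenerate = st$degenerate, called = called,
                     row.names = NULL)
  n_hit <- sum(called)
  hits <- data.frame(molecule = ids[called], day = rep(day, n_hit),
                     modality = rep(modality, n_hit),
                     log2fc = st$lfc[called],
                     direction = ifelse(st$lfc[called] >= 0, "up", "down"),
                     row.names = NULL)
  attr(hits, "table") <- full
  hits
}

#' Permutation-based FDR-adjusted p-values
#'
#' Per-feature permutation p-values from relabeling the two groups: each
#' feature's observed absolute Welch t statistic is compared against the
#' null distribution of permuted statistics pooled across all features, and
#' the resulting p-values are Benjamini--Hochberg adjusted. When the number
#' of distinct label assignments is below 100 the full assignment space is
#' enumerated; otherwise `n_perm` (>= 100) random relabelings are drawn.
#'
#' @inheritParams call_differential
#' @param n_perm Number of random permutations when not exhaustive.
#' @param seed Integer seed for the permutation draw.
#' @return Numeric vector of adjusted p-values (one per feature), with raw
#'   permutation p-values as attribute `"p_perm"`.
#' @export
permutation_fdr <- function(x, group, n_perm = 1000L, seed = 1L) {
  group <- as.factor(group)
  g2 <- group == levels(group)[2]
  n <- length(g2); n2 <- sum(g2)
  n_distinct <- choose(n, n2)
  exhaustive <- n_distinct < 100
  if (!exhaustive && n_perm < 100)
    stop("'n_perm' must be >= 100 when the assignment space is not enumerated",
         call. = FALSE)
  obs <- abs(.row_welch(x, g2)$t)
  perm_idx <- if (exhaustive) {
    utils::combn(n, n2, simplify = FALSE)
  } else {
    with_local_seed(seed, replicate(n_perm, sample.int(n, n2), simplify = FALSE))
  }
  pool <- unlist(lapply(perm_idx, function(ii) {
    gg <- rep(FALSE, n); gg[ii] <- TRUE
    abs(.row_welch(x, gg)$t)
  }))
  pool <- pool[is.finite(pool)]
  # pooled null: p = fraction of permuted |t| at least as extreme
  ord <- sort(pool)
  p_perm <- (length(ord) - findInterval(obs, ord, left.open = TRUE)) / length(ord)
  p_perm[!is.finite(obs)] <- NA_real_
  p_adj <- stats::p.adjust(p_perm, method = "BH")
  attr(p_adj, "p_perm") <- p_perm
  p_adj
}

# extract the molecule ID column from a molecule-list data frame
.list_ids <- function(l) unique(as.character(l$molecule))

#' Set algebra over molecule lists
#'
#' Exact union/intersection bookkeeping over the molecule IDs of one or more
#' per-day lists, as used to summarize how many differential molecules are
#' shared across a time course.
#'
#' @param lists A list of molecule-list data frames (columns including
#'   `molecule`), e.g. from [simulate_molecule_lists()] or
#'   [call_differential()].
#' @return A list with `union_size`, `intersection_size`, `pairwise`
#'   (symmetric matrix of pairwise intersection sizes; diagonal = list
#'   sizes) and `members` (IDs common to all lists).
#' @export
intersect_lists <- function(lists) {
  if (inherits(lists, "data.frame")) lists <- list(lists)
  if (length(lists) < 1L) stop("need at least one list", call. = FALSE)
  ids <- lapply(lists, .list_ids)
  k <- length(ids)
  pw <- matrix(0L, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    pw[i, j] <- length(intersect(ids[[i]], ids[[j]]))
  nm <- names(lists) %||% paste0("list", seq_len(k))
  dimnames(pw) <- list(nm, nm)
  members <- Reduce(intersect, ids)
  list(union_size = length(Reduce(union, ids)),
       intersection_size = length(members),
       pairwise = pw, members = members)
}

#' Overlap between an mRNA list and a protein list at one day
#'
#' Harmonizes IDs (case-folded symbol equality by default, or an explicit
#' two-column map from source ID to target ID) and intersects the two lists.
#' Both lists must refer to the same day. Many-to-one map entries collapse
#' onto the target ID and each molecule counts once.
#'
#' @param mrna,protein Molecule-list data frames (columns `molecule`,
#'   `day`, `log2fc`).
#' @param id_map Optional data frame with columns `from`, `to` applied to
#'   both lists before matching.
#' @param concordant If `TRUE`, keep only molecules whose fold changes have
#'   the same sign in both modalities.
#' @return Data frame with `molecule` (harmonized ID), `log2fc_mrna`,
#'   `log2fc_protein`.
#' @export
cross_modality_overlap <- function(mrna, protein, id_map = NULL,
                                   concordant = FALSE) {
  if (nrow(mrna) == 0L || nrow(protein) == 0L)
    return(data.frame(molecule = character(0), log2fc_mrna = numeric(0),
                      log2fc_protein = numeric(0)))
  d1 <- unique(mrna$day); d2 <- unique(protein$day)
  if (length(d1) != 1L || length(d2) != 1L || d1 != d2)
    stop("both lists must refer to the same single day", call. = FALSE)
  harmonize <- function(ids) {
    ids <- as.character(ids)
    if (!is.null(id_map)) {
      hit <- match(ids, as.character(id_map$from))
      ids[!is.na(hit)] <- as.character(id_map$to)[hit[!is.na(hit)]]
    }
    toupper(trimws(ids))
  }
  a <- data.frame(id = harmonize(mrna$molecule), lfc = mrna$log2fc)
  b <- data.frame(id = harmonize(protein$molecule), lfc = protein$log2fc)
  # a molecule counts once: keep first record per harmonized ID
  a <- a[!duplicated(a$id), ]; b <- b[!duplicated(b$id), ]
  m <- merge(a, b, by = "id", suffixes = c("_mrna", "_protein"))
  if (concordant) m <- m[sign(m$lfc_mrna) == sign(m$lfc_protein), , drop = FALSE]
  data.frame(molecule = m$id, log2fc_mrna = m$lfc_mrna,
             log2fc_protein = m$lfc_protein, row.names = NULL)
}

#' Filter molecules whose fold changes decline with time in both modalities
#'
#' Computes the Pearson correlation of log2 fold change against day, per
#' molecule and per modality, restricted to days `<= max_day`, and returns
#' the molecules with `r < threshold` in BOTH modalities. Molecules with
#' fewer than 3 distinct days in either modality, or a constant fold-change
#' series (undefined correlation), are excluded and noted in the records.
#'
#' @param series Long data frame with columns `molecule`, `modality`, `day`,
#'   `log2fc` covering two modalities.
#' @param threshold Correlation cutoff (default -0.5; molecules pass when
#'   `r` is strictly below it).
#' @param max_day Only days up to this value enter the correlation.
#' @return Character vector of passing molecule IDs, with the per-molecule,
#'   per-modality correlation records (`molecule`, `modality`, `r`,
#'   `n_days`, `status`) as attribute `"records"`.
#' @export
time_correlation_filter <- function(series, threshold = -0.5, max_day = 7) {
  need <- c("molecule", "modality", "day", "log2fc")
  if (!all(need %in% names(series)))
    stop("'series' must have columns ", paste(need, collapse = ", "), call. = FALSE)
  series <- series[series$day <= max_day, , drop = FALSE]
  recs <- do.call(rbind, lapply(
    split(series, list(series$molecule, series$modality), drop = TRUE),
    function(s) {
      nd <- length(unique(s$day))
      if (nd < 3L)
        return(data.frame(molecule = s$molecule[1], modality = s$modality[1],
                          r = NA_real_, n_days = nd, status = "too_few_days"))
      if (stats::sd(s$log2fc) == 0)
        return(data.frame(molecule = s$molecule[1], modality = s$modality[1],
                          r = NA_real_, n_days = nd, status = "constant"))
      data.frame(molecule = s$molecule[1], modality = s$modality[1],
                 r = stats::cor(s$day, s$log2fc), n_days = nd, status = "ok")
    }))
  rownames(recs) <- NULL
  mods <- unique(recs$modality)
  if (length(mods) != 2L)
    stop("'series' must contain exactly two modalities, found: ",
         paste(mods, collapse = ", "), call. = FALSE)
  ok <- recs[recs$status == "ok" & recs$r < threshold, , drop = FALSE]
  pass <- intersect(ok$molecule[ok$modality == mods[1]],
                    ok$molecule[ok$modality == mods[2]])
  structure(sort(pass), records = recs)
}
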