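#' Sampling design for a simulated micronucleus experiment
#'
#' @param animals Vector of animal IDs.
#' @param days Integer vector of sampling days since irradiation (>= 0);
#'   sorted ascending.
#' @param bn_range Inclusive integer range for the number of binucleate cells
#'   scored per sample. Defaults to 200--1000, a typical scoring depth for
#'   cytokinesis-block micronucleus assays.
#' @param anticoagulant Anticoagulant label(s), recycled over samples.
#' @return An object of class `mn_design`.
#' @export
mn_design <- function(animals, days, bn_range = c(200L, 1000L),
                      anticoagulant = "EDTA") {
  if (length(animals) < 1L) stop("need at least one animal", call. = FALSE)
  if (any(days < 0) || any(days != floor(days)))
    stop("'days' must be non-negative integers", call. = FALSE)
  if (length(bn_range) != 2L || bn_range[1] < 1L || bn_range[2] < bn_range[1])
    stop("'bn_range' must be an increasing integer pair with lower bound >= 1",
         call. = FALSE)
  structure(list(animals = animals, days = sort(unique(as.integer(days))),
                 bn_range = as.integer(bn_range), anticoagulant = anticoagulant),
            class = "mn_design")
}

#' Default generating parameters for study-like micronucleus simulations
#'
#' A mixture-model parameter set whose curve tracks the typical MN/BN time
#' course after an acute 4 Gy whole-body exposure: a near-zero baseline, a
#' peak of about 0.5 at day 3 driven by the fast quadratic-decay component,
#' a drop to about 0.3 by day 6, a slowly declining plateau through day 28,
#' and about 0.1 by day 56.
#'
#' @return A [kinetic_params()] object.
#' @export
default_mn_params <- function() {
  kinetic_params(C = 0.01, Kprod = 0.37, Kdec1 = 0.07, Kdec2 = 0.12, P = 0.21)
}

#' Count-noise family for simulated micronucleus data
#'
#' @param family One of `"binomial"` (micronucleus count drawn as
#'   `Binomial(bn, p)`, so MN/BN <= 1), `"beta-binomial"` (binomial with a
#'   Beta-distributed per-sample proportion; `rho = 0` reduces exactly to
#'   binomial) or `"poisson-per-cell"` (`Poisson(bn * p)`, permitting more
#'   than one micronucleus per cell as in real scoring).
#' @param rho Overdispersion for the beta-binomial family, in \[0, 1).
#' @return An object of class `dispersion_spec`.
#' @export
dispersion_spec <- function(family = c("binomial", "beta-binomial", "poisson-per-cell"),
                            rho = 0) {
  family <- match.arg(family)
  stopifnot_scalar_number(rho, "rho", lower = 0, upper = 1 - 1e-12)
  structure(list(family = family, rho = rho), class = "dispersion_spec")
}

#' Simulate a micronucleus table from the kinetic model
#'
#' Draws one observation per animal and day with expected MN/BN equal to
#' [model_mn()] evaluated at that day, a uniformly drawn binucleate-cell
#' count within `design$bn_range`, and count noise from the chosen
#' dispersion family. Identical seeds give identical tables.
#'
#' @param params A [kinetic_params()] object (the generating truth).
#' @param design An [mn_design()].
#' @param noise A [dispersion_spec()].
#' @param seed Integer seed.
#' @return MN table: data frame with columns `animal`, `day`,
#'   `anticoagulant`, `bn`, `mn`.
#' @export
simulate_mn <- function(params, design, noise = dispersion_spec("binomial"),
                        seed = 1L) {
  if (!inherits(design, "mn_design")) stop("'design' must be an mn_design", call. = FALSE)
  if (!inherits(noise, "dispersion_spec"))
    stop("'noise' must be a dispersion_spec", call. = FALSE)
  p_by_day <- model_mn(params, design$days)
  if (noise$family %in% c("binomial", "beta-binomial") && any(p_by_day > 1))
    stop(sprintf("expected MN/BN exceeds 1 (max %.3f) at a design day; the %s family cannot represent it -- use 'poisson-per-cell'",
                 max(p_by_day), noise$family), call. = FALSE)
  grid <- expand.grid(animal = design$animals, day = design$days,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$animal, grid$day), , drop = FALSE]
  n <- nrow(grid)
  p <- model_mn(params, grid$day)
  with_local_seed(seed, {
    bn_vals <- seq.int(design$bn_range[1], design$bn_range[2])
    bn <- bn_vals[sample.int(length(bn_vals), n, replace = TRUE)]
    mn <- switch(noise$family,
      "binomial" = stats::rbinom(n, bn, p),
      "beta-binomial" = {
        if (noise$rho == 0) stats::rbinom(n, bn, p)
        else {
          s <- (1 - noise$rho) / noise$rho
          pp <- ifelse(p %in% c(0, 1), p, stats::rbeta(n, p * s, (1 - p) * s))
          stats::rbinom(n, bn, pp)
        }
      },
      "poisson-per-cell" = stats::rpois(n, bn * p))
    data.frame(animal = grid$animal, day = grid$day,
               anticoagulant = rep_len(design$anticoagulant, n),
               bn = bn, mn = mn, row.names = NULL)
  })
}

#' Trajectory profile for one blood-cell type
#'
#' Describes a cell-count time course that sits at `baseline_mean` before
#' irradiation, declines to `nadir_fraction` of baseline at `nadir_day`,
#' and returns to baseline at `recovery_day`, interpolating log-linearly
#' between those anchor points.
#'
#' @param cell_type Label (e.g. `"lymphocyte"`).
#' @param baseline_mean Baseline absolute count (x10^9/L).
#' @param nadir_day Day of the trajectory minimum (> 0).
#' @param nadir_fraction Fraction of baseline at the nadir, in (0, 1\].
#' @param recovery_day Day of return to baseline (> `nadir_day`).
#' @param cv Lognormal coefficient of variation of multiplicative noise.
#' @return An object of class `hema_profile`.
#' @export
hema_profile <- function(cell_type, baseline_mean, nadir_day, nadir_fraction,
                         recovery_day, cv = 0) {
  stopifnot_scalar_number(baseline_mean, "baseline_mean", lower = 0)
  stopifnot_scalar_number(nadir_fraction, "nadir_fraction",
                          lower = .Machine$double.xmin, upper = 1)
  stopifnot_scalar_number(cv, "cv", lower = 0)
  if (nadir_day >= recovery_day)
    stop("'nadir_day' must precede 'recovery_day'", call. = FALSE)
  if (nadir_day <= 0) stop("'nadir_day' must be positive", call. = FALSE)
  structure(list(cell_type = cell_type, baseline_mean = baseline_mean,
                 nadir_day = nadir_day, nadir_fraction = nadir_fraction,
                 recovery_day = recovery_day, cv = cv),
            class = "hema_profile")
}

# Piecewise log-linear trajectory: 1 for day <= 0 and day >= recovery_day,
# nadir_fraction at nadir_day.
hema_trajectory <- function(profile, day) {
  lf <- log(profile$nadir_fraction)
  lval <- ifelse(day <= 0, 0,
          ifelse(day <= profile$nadir_day, lf * day / profile$nadir_day,
          ifelse(day < profile$recovery_day,
                 lf * (profile$recovery_day - day) /
                      (profile$recovery_day - profile$nadir_day),
                 0)))
  exp(lval)
}

#' Simulate hematology cell-count trajectories
#'
#' Each count equals `baseline_mean * trajectory(day) * noise`, where the
#' trajectory is the piecewise log-linear dip-and-recover curve of the
#' profile and the noise is lognormal with unit mean (the lognormal
#' mean-correction `exp(-sdlog^2/2)` is applied, so the expected count is
#' exactly the noiseless trajectory). With `cv = 0` counts equal the
#' trajectory exactly.
#'
#' @param profiles List of [hema_profile()] objects (one per cell type).
#' @param animals Vector of animal IDs.
#' @param days Integer vector of sampling days (negative = pre-irradiation).
#' @param seed Integer seed.
#' @return Cell-count table: data frame with columns `animal`, `day`,
#'   `cell_type`, `count`.
#' @export
simulate_hematology <- function(profiles, animals, days, seed = 1L) {
  if (inherits(profiles, "hema_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L) stop("'profiles' must be non-empty", call. = FALSE)
  lapply(profiles, function(p) {
    if (!inherits(p, "hema_profile")) stop("each profile must be a hema_profile", call. = FALSE)
  })
  with_local_seed(seed, {
    out <- lapply(profiles, function(p) {
      grid <- expand.grid(animal = animals, day = as.integer(days),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      mu <- p$baseline_mean * hema_trajectory(p, grid$day)
      if (p$cv > 0) {
        sdlog <- sqrt(log(1 + p$cv^2))
        noise <- exp(stats::rnorm(nrow(grid), -sdlog^2 / 2, sdlog))
      } else noise <- 1
      data.frame(animal = grid$animal, day = grid$day,
                 cell_type = p$cell_type, count = mu * noise)
    })
    do.call(rbind, out)
  })
}

#' Overlap design for simulated per-day molecule lists
#'
#' @param universe_size Size of the molecule universe.
#' @param core_size Number of molecules shared by every day's list.
#' @param per_day_extra Number of day-specific extra molecules.
#' @param days Integer vector of days.
#' @return An object of class `overlap_design`.
#' @export
overlap_design <- function(universe_size, core_size, per_day_extra, days) {
  if (core_size + per_day_extra > universe_size)
    stop("core_size + per_day_extra must not exceed universe_size", call. = FALSE)
  if (core_size < 0 || per_day_extra < 0) stop("sizes must be non-negative", call. = FALSE)
  structure(list(universe_size = as.integer(universe_size),
                 core_size = as.integer(core_size),
                 per_day_extra = as.integer(per_day_extra),
                 days = as.integer(days)),
            class = "overlap_design")
}

#' Simulate per-day molecule lists with controlled intersection structure
#'
#' Every day's list contains the same randomly chosen core of
#' `core_size` molecules plus `per_day_extra` extras from the remainder of
#' the universe. With `extras = "random"` extras are drawn independently per
#' day (pairwise extra-overlap has hypergeometric expectation
#' `per_day_extra^2 / (universe_size - core_size)`); with
#' `extras = "disjoint"` the extras partition the remainder, so every
#' pairwise intersection equals exactly the core.
#'
#' @param design An [overlap_design()].
#' @param seed Integer seed.
#' @param extras `"random"` or `"disjoint"`.
#' @param modality Modality label stored in the lists.
#' @return A list (one element per day) of molecule-list data frames with
#'   columns `molecule`, `day`, `modality`, `log2fc`, `direction`.
#' @export
simulate_molecule_lists <- function(design, seed = 1L,
                                    extras = c("random", "disjoint"),
                                    modality = "mrna") {
  if (!inherits(design, "overlap_design"))
    stop("'design' must be an overlap_design", call. = FALSE)
  extras <- match.arg(extras)
  if (extras == "disjoint" &&
      design$core_size + length(design$days) * design$per_day_extra > design$universe_size)
    stop("disjoint extras need core_size + n_days * per_day_extra <= universe_size",
         call. = FALSE)
  universe <- sprintf("MOL%05d", seq_len(design$universe_size))
  with_local_seed(seed, {
    core <- sample(universe, design$core_size)
    rest <- setdiff(universe, core)
    lists <- vector("list", length(design$days))
    for (i in seq_along(design$days)) {
      extra <- if (design$per_day_extra == 0L) character(0)
               else if (extras == "random") sample(rest, design$per_day_extra)
               else rest[seq.int((i - 1L) * design$per_day_extra + 1L,
                                 i * design$per_day_extra)]
      ids <- c(core, extra)
      lfc <- stats::rnorm(length(ids), 0, 1.5)
      lfc[abs(lfc) < 0.1] <- 0.1  # keep direction well-defined
      lists[[i]] <- data.frame(
        molecule = ids, day = design$days[i], modality = modality,
        log2fc = lfc, direction = ifelse(lfc >= 0, "up", "down"))
    }
    names(lists) <- paste0("day", design$days)
    lists
  })
}

#' Simulate a two-group expression matrix with planted effects
#'
#' Generates a `n_features x 2*n_per_group` log2-scale matrix of Gaussian
#' noise with SD `sigma`; the first `n_true` features receive an additive
#' shift of `effect` in group 2. The planted-truth labels are returned so
#' downstream differential calling can be scored for recall and false
#' discovery proportion.
#'
#' @param n_features Number of features (rows).
#' @param n_per_group Samples per group.
#' @param n_true Number of features carrying the shift (<= `n_features`).
#' @param effect Log2-scale shift added to group 2.
#' @param sigma Noise SD (> 0).
#' @param seed Integer seed.
#' @return A list with `x` (matrix, features x samples), `group` (factor of
#'   `"g1"`/`"g2"`) and `truth` (logical vector over features).
#' @export
simulate_expression_matrix <- function(n_features, n_per_group, n_true,
                                       effect, sigma, seed = 1L) {
  if (n_true > n_features) stop("'n_true' must not exceed 'n_features'", call. = FALSE)
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  n <- 2L * n_per_group
  with_local_seed(seed, {
    x <- matrix(stats::rnorm(n_features * n, 0, sigma), n_features, n)
    if (n_true > 0 && effect != 0)
      x[seq_len(n_true), seq.int(n_per_group + 1L, n)] <-
        x[seq_len(n_true), seq.int(n_per_group + 1L, n)] + effect
    rownames(x) <- sprintf("F%05d", seq_len(n_features))
    colnames(x) <- paste0(rep(c("g1", "g2"), each = n_per_group), "_s",
                          rep(seq_len(n_per_group), 2))
    list(x = x,
         group = factor(rep(c("g1", "g2"), each = n_per_group)),
         truth = c(rep(effect != 0, n_true), rep(FALSE, n_features - n_true)))
  })
}
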