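#' Kinetic parameters for the micronucleus time-course model
#'
#' Bundles the five parameters of the production--decay model for the
#' micronuclei-per-binucleate-cell (MN/BN) ratio after acute irradiation:
#' a pre-irradiation baseline `C`, a production term `Kprod`, a linear
#' exponential decay rate `Kdec1` (per day), a quadratic exponential decay
#' rate `Kdec2` (per day squared), and the mixture fraction `P` of decay
#' governed by `Kdec1`.
#'
#' @param C Baseline MN/BN value before irradiation (>= 0).
#' @param Kprod Micronucleus production term, per day (>= 0).
#' @param Kdec1 Linear exponential decay rate, per day (>= 0).
#' @param Kdec2 Quadratic exponential decay rate, per day^2 (>= 0).
#' @param P Fraction of decay using `Kdec1`, in \[0, 1\].
#' @return An object of class `kinetic_params` (a named list).
#' @examples
#' kinetic_params(C = 0.05, Kprod = 0.2, Kdec1 = 0.1, Kdec2 = 0.001, P = 0.5)
#' @export
kinetic_params <- function(C, Kprod = 0, Kdec1 = 0, Kdec2 = 0, P = 1) {
  stopifnot_scalar_number(C, "C", lower = 0)
  stopifnot_scalar_number(Kprod, "Kprod", lower = 0)
  stopifnot_scalar_number(Kdec1, "Kdec1", lower = 0)
  stopifnot_scalar_number(Kdec2, "Kdec2", lower = 0)
  stopifnot_scalar_number(P, "P", lower = 0, upper = 1)
  structure(list(C = C, Kprod = Kprod, Kdec1 = Kdec1, Kdec2 = Kdec2, P = P),
            class = "kinetic_params")
}

#' Predicted MN/BN ratio at a given day
#'
#' Evaluates the mixture production--decay model
#' \deqn{MN/BN(d) = C + Kprod \cdot d \left( P e^{-Kdec_1 d} +
#'   (1 - P) e^{-Kdec_2 d^2} \right)}
#' at one or more days since irradiation. At day 0 the prediction equals the
#' baseline `C` exactly, and for `Kprod >= 0` the prediction never falls
#' below `C`.
#'
#' @param params A [kinetic_params()] object.
#' @param day Numeric vector of non-negative days since irradiation.
#' @return Numeric vector of predicted MN/BN values.
#' @examples
#' p <- kinetic_params(C = 0.05, Kprod = 0.1, Kdec1 = 0.2, Kdec2 = 0.01, P = 1)
#' model_mn(p, 5)  # 0.05 + 0.5 * exp(-1)
#' @export
model_mn <- function(params, day) {
  if (!inherits(params, "kinetic_params")) params <- do.call(kinetic_params, as.list(params))
  if (any(!is.finite(day)) || any(day < 0))
    stop("'day' must be non-negative and finite", call. = FALSE)
  with(params, C + Kprod * day * (P * exp(-Kdec1 * day) + (1 - P) * exp(-Kdec2 * day^2)))
}

# --- model family registry ---------------------------------------------------
#
# Four candidate formalisms with different power dependences on time. Only the
# mixture model M3 uses all five parameters; the others are 3-parameter curves.
#   M1_lin_decay : C + Kprod * d * exp(-Kdec1 * d)
#   M2_quad_decay: C + Kprod * d * exp(-Kdec2 * d^2)
#   M3_mixture   : C + Kprod * d * (P exp(-Kdec1 d) + (1-P) exp(-Kdec2 d^2))
#   M4_quad_prod : C + Kprod * d^2 * exp(-Kdec1 * d)

.mn_models <- list(
  M1_lin_decay = list(
    pars = c("C", "Kprod", "Kdec1"), k = 3L,
    f = function(th, d) th[["C"]] + th[["Kprod"]] * d * exp(-th[["Kdec1"]] * d),
    grad = function(th, d) {
      e1 <- exp(-th[["Kdec1"]] * d)
      cbind(C = rep(1, length(d)), Kprod = d * e1,
            Kdec1 = -th[["Kprod"]] * d^2 * e1)
    }),
  M2_quad_decay = list(
    pars = c("C", "Kprod", "Kdec2"), k = 3L,
    f = function(th, d) th[["C"]] + th[["Kprod"]] * d * exp(-th[["Kdec2"]] * d^2),
    grad = function(th, d) {
      e2 <- exp(-th[["Kdec2"]] * d^2)
      cbind(C = rep(1, length(d)), Kprod = d * e2,
            Kdec2 = -th[["Kprod"]] * d^3 * e2)
    }),
  M3_mixture = list(
    pars = c("C", "Kprod", "Kdec1", "Kdec2", "P"), k = 5L,
    f = function(th, d)
      th[["C"]] + th[["Kprod"]] * d *
        (th[["P"]] * exp(-th[["Kdec1"]] * d) + (1 - th[["P"]]) * exp(-th[["Kdec2"]] * d^2)),
    grad = function(th, d) {
      e1 <- exp(-th[["Kdec1"]] * d); e2 <- exp(-th[["Kdec2"]] * d^2)
      mix <- th[["P"]] * e1 + (1 - th[["P"]]) * e2
      cbind(C = rep(1, length(d)),
            Kprod = d * mix,
            Kdec1 = -th[["Kprod"]] * th[["P"]] * d^2 * e1,
            Kdec2 = -th[["Kprod"]] * (1 - th[["P"]]) * d^3 * e2,
            P = th[["Kprod"]] * d * (e1 - e2))
    }),
  M4_quad_prod = list(
    pars = c("C", "Kprod", "Kdec1"), k = 3L,
    f = function(th, d) th[["C"]] + th[["Kprod"]] * d^2 * exp(-th[["Kdec1"]] * d),
    grad = function(th, d) {
      e1 <- exp(-th[["Kdec1"]] * d)
      cbind(C = rep(1, length(d)), Kprod = d^2 * e1,
            Kdec1 = -th[["Kprod"]] * d^3 * e1)
    })
)

#' Names of the candidate micronucleus time-course models
#'
#' @return Character vector of the four model names understood by
#'   [fit_mn()] and [compare_models()].
#' @export
mn_model_names <- function() names(.mn_models)

.get_model <- function(spec) {
  if (inherits(spec, "mn_fit")) spec <- spec$spec
  if (!is.character(spec) || length(spec) != 1L || !spec %in% names(.mn_models))
    stop("unknown model spec; use one of: ", paste(names(.mn_models), collapse = ", "),
         call. = FALSE)
  c(.mn_models[[spec]], list(name = spec))
}

# Map a fitted coefficient vector onto the full 5-parameter set, fixing the
# parameters a reduced model does not use so that model_mn() reproduces it.
.full_params <- function(spec, coefs) {
  th <- as.list(coefs)
  switch(spec,
    M1_lin_decay  = kinetic_params(th$C, th$Kprod, Kdec1 = th$Kdec1, Kdec2 = 0, P = 1),
    M2_quad_decay = kinetic_params(th$C, th$Kprod, Kdec1 = 0, Kdec2 = th$Kdec2, P = 0),
    M3_mixture    = kinetic_params(th$C, th$Kprod, th$Kdec1, th$Kdec2, th$P),
    M4_quad_prod  = NULL)  # not expressible in the mixture parameterization
}
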