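# 1:1 Langmuir biolayer-interferometry kinetics: closed-form phase model,
# K_D = k_dis/k_on, global association-dissociation fitting, and the
# binding-call / competition-call decision rules.

#' Convert a mass concentration to molarity
#'
#' M = (c in g/L) / (molar mass in g/mol); 1 mg/mL = 1 g/L.
#'
#' @param c_mg_ml Concentration in mg per mL (must be positive).
#' @param molar_mass Molar mass in g/mol; the default 150000 is a whole IgG.
#' @return Concentration in mol/L.
#' @examples
#' mg_per_ml_to_molar(0.2)     # 1.333e-06 M
#' @export
mg_per_ml_to_molar <- function(c_mg_ml, molar_mass = 150000) {
  if (any(!is.finite(c_mg_ml)) || any(c_mg_ml <= 0)) {
    stop("concentration must be positive")
  }
  if (!is.finite(molar_mass) || molar_mass <= 0) stop("molar mass must be positive")
  c_mg_ml / molar_mass
}

#' Equilibrium dissociation constant from rate constants
#'
#' K_D = k_dis / k_on, in M when k_on is in 1/(M s) and k_dis in 1/s.
#' A zero dissociation rate gives K_D = 0 (infinite affinity).
#'
#' @param k_on Association rate constant, 1/(M s); must be > 0.
#' @param k_dis Dissociation rate constant, 1/s; must be >= 0.
#' @return K_D in M.
#' @examples
#' compute_KD(9.52e3, 2.29e-3)   # 2.41e-07 M
#' @export
compute_KD <- function(k_on, k_dis) {
  if (any(!is.finite(k_on)) || any(k_on <= 0)) stop("k_on must be positive")
  if (any(!is.finite(k_dis)) || any(k_dis < 0)) stop("k_dis must be non-negative")
  k_dis / k_on
}

#' Closed-form 1:1 Langmuir phase response
#'
#' Association at analyte concentration C:
#' \deqn{R(t) = R_{eq} (1 - e^{-(k_{on} C + k_{dis}) t}), \quad
#'       R_{eq} = R_{max} \frac{k_{on} C}{k_{on} C + k_{dis}}}
#' Dissociation from level R0: \eqn{R(t) = R_0 e^{-k_{dis} t}}. Both solve
#' dR/dt = k_on C (R_max - R) - k_dis R with the appropriate C and initial
#' condition. Time is measured from the phase start.
#'
#' @param t Time in seconds since the phase start (>= 0).
#' @param C Analyte concentration in M (>= 0; ignored during dissociation).
#' @param k_on,k_dis,R_max Kinetic parameters (positive; R_max in nm).
#' @param phase `"association"` or `"dissociation"`.
#' @param R0 Response level at the start of dissociation (nm).
#' @return Response in nm.
#' @export
langmuir_response <- function(t, C, k_on, k_dis, R_max,
                              phase = c("association", "dissociation"), R0 = NULL) {
  phase <- match.arg(phase)
  if (any(t < 0)) stop("t must be measured from the phase start (>= 0)")
  stopifnot(k_on > 0, k_dis >= 0, R_max > 0)
  if (phase == "association") {
    if (!is.finite(C) || C < 0) stop("C must be non-negative")
    kobs <- k_on * C + k_dis
    R_eq <- if (kobs > 0) R_max * k_on * C / kobs else 0
    R_eq * (1 - exp(-kobs * t))
  } else {
    if (is.null(R0)) stop("dissociation requires R0")
    R0 * exp(-k_dis * t)
  }
}

#' Assay configuration for kinetic analysis
#'
#' @param molar_mass Analyte molar mass in g/mol (default: whole IgG, 150000).
#' @param concentrations Analyte concentration series in mg/mL; the default is
#'   a five-step two-fold series from 0.0125 to 0.2.
#' @param binding_call_threshold Displacement threshold in nm above which a
#'   binding event is called (default 0.02, inclusive).
#' @param r2_min Minimum pooled R squared for a fit to be flagged reliable
#'   (default 0.85).
#' @return List of class `assay_config`.
#' @export
assay_config <- function(molar_mass = 150000,
                         concentrations = c(0.0125, 0.025, 0.05, 0.1, 0.2),
                         binding_call_threshold = 0.02,
                         r2_min = 0.85) {
  stopifnot(binding_call_threshold > 0, all(concentrations > 0),
            !anyDuplicated(concentrations), molar_mass > 0)
  structure(list(molar_mass = molar_mass, concentrations = concentrations,
                 binding_call_threshold = binding_call_threshold, r2_min = r2_min),
            class = "assay_config")
}

# extract association/dissociation cycles from a sensorgram, baseline-zeroed:
# each association step is offset by the mean of the final second of the
# preceding baseline step (if one exists)
kinetic_cycles <- function(sgram) {
  steps <- sgram$steps
  phases <- vapply(steps, `[[`, character(1), "phase")
  cycles <- list()
  for (i in which(phases == "association")) {
    st <- steps[[i]]
    if (is.null(st$conc_molar) || st$conc_molar <= 0) next
    zero <- 0
    if (i > 1 && phases[i - 1] == "baseline") {
      bl <- steps[[i - 1]]
      tail_s <- bl$times >= max(bl$times) - 1
      zero <- mean(bl$responses[tail_s])
    }
    cyc <- list(conc = st$conc_molar,
                t_assoc = st$times - st$times[1],
                r_assoc = st$responses - zero,
                t_dissoc = numeric(0), r_dissoc = numeric(0))
    if (i < length(steps) && phases[i + 1] == "dissociation") {
      ds <- steps[[i + 1]]
      cyc$t_dissoc <- ds$times - ds$times[1]
      cyc$r_dissoc <- ds$responses - zero
    }
    cycles[[length(cycles) + 1L]] <- cyc
  }
  cycles
}

#' Global 1:1 fit of an association-dissociation concentration series
#'
#' Fits a single (k_on, k_dis, R_max) to all association and dissociation
#' phases of a multi-concentration sensorgram by nonlinear least squares
#' (L-BFGS-B on log10 parameters with a Nelder-Mead polish). The dissociation
#' start level of each cycle is the model's own association end point, as in a
#' full kinetic global fit. Regeneration, loading and baseline steps are
#' excluded from the fit; baselines are only used to zero the following
#' association step. R squared is pooled over all fitted points:
#' 1 - SS_res/SS_tot.
#'
#' @param sensorgrams A `sensorgram` object or a list of them (cycles are
#'   pooled).
#' @param config An [assay_config()].
#' @return Object of class `kinetic_fit`: list with `k_on`, `k_dis`, `K_D`,
#'   `R_max`, `r_squared`, `status` (`"converged"`/`"not_converged"`/
#'   `"no_signal"`), `reliable` (R squared >= `r2_min` and converged) and
#'   `n_points`.
#' @export
fit_kinetics <- function(sensorgrams, config = assay_config()) {
  sg_list <- if (inherits(sensorgrams, "sensorgram")) list(sensorgrams) else sensorgrams
  cycles <- do.call(c, lapply(sg_list, kinetic_cycles))
  if (length(cycles) < 2L) stop("need association phases at >= 2 concentrations")

  obs <- unlist(lapply(cycles, function(cy) c(cy$r_assoc, cy$r_dissoc)))
  n_points <- length(obs)
  ss_tot <- sum((obs - mean(obs))^2)

  predict_all <- function(k_on, k_dis, R_max) {
    unlist(lapply(cycles, function(cy) {
      kobs <- k_on * cy$conc + k_dis
      R_eq <- R_max * k_on * cy$conc / kobs
      pa <- R_eq * (1 - exp(-kobs * cy$t_assoc))
      r0 <- R_eq * (1 - exp(-kobs * max(cy$t_assoc)))
      pd <- r0 * exp(-k_dis * cy$t_dissoc)
      c(pa, pd)
    }))
  }
  sse <- function(theta) {
    p <- 10^theta
    sum((obs - predict_all(p[1], p[2], p[3]))^2)
  }

  r_top <- max(obs, 1e-4)
  init <- log10(c(k_on = 1e4, k_dis = 1e-3, R_max = r_top))
  lower <- log10(c(1, 1e-7, 1e-6))
  upper <- log10(c(1e9, 1, 10))
  fit <- stats::optim(init, sse, method = "L-BFGS-B", lower = lower,
                      upper = upper, control = list(maxit = 500, factr = 1e4))
  # derivative-free polish; Nelder-Mead ignores bounds, so clamp afterwards
  polish <- stats::optim(fit$par, sse, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-14))
  if (polish$value < fit$value) fit <- polish
  theta <- pmin(pmax(fit$par, lower), upper)

  p <- 10^theta
  ss_res <- sum((obs - predict_all(p[1], p[2], p[3]))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  status <- if (!is.na(r2) && max(abs(obs)) < 1e-6) "no_signal"
            else if (ss_tot == 0) "no_signal"
            else if (fit$convergence == 0) "converged"
            else "not_converged"
  structure(list(
    k_on = unname(p[1]), k_dis = unname(p[2]),
    K_D = unname(compute_KD(p[1], p[2])), R_max = unname(p[3]),
    r_squared = r2, status = status,
    reliable = identical(status, "converged") && !is.na(r2) && r2 >= config$r2_min,
    n_points = n_points
  ), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> k_on = %.3g 1/(M s), k_dis = %.3g 1/s, K_D = %.3g M\n",
              x$k_on, x$k_dis, x$K_D))
  cat(sprintf("  R_max = %.3g nm, R^2 = %.4f, status = %s, reliable = %s\n",
              x$R_max, x$r_squared, x$status, x$reliable))
  invisible(x)
}

#' Binding call from an association step
#'
#' Binding has occurred when the maximum displacement during association
#' reaches the threshold; the comparison is inclusive (a signal of exactly
#' 0.02 nm is called bound).
#'
#' @param step A sensorgram step (list with `responses`), or a numeric vector
#'   of responses.
#' @param config An [assay_config()].
#' @return `"bound"` or `"not_bound"`.
#' @export
binding_call <- function(step, config = assay_config()) {
  r <- if (is.list(step)) step$responses else step
  if (length(r) == 0L) stop("empty association step")
  if (max(r) >= config$binding_call_threshold) "bound" else "not_bound"
}

#' Competition call from an SPA-capture / ligand-challenge trace
#'
#' In the competition assay the sensor carries SPA, captures IgG (the first
#' association step), and is then challenged with the DNA ligand (subsequent
#' association steps). The ligand competes for the same site when the
#' challenge step shows an absolute signal change of at least the threshold -
#' positive (additional binding) or negative (displacement of the captured
#' antibody). A sub-threshold trace means no competition, i.e. the ligand and
#' SPA share an overlapping Fc binding site already occupied.
#'
#' @param sgram A `sensorgram` whose association steps are, in order, the IgG
#'   capture followed by one or more ligand-challenge steps.
#' @param config An [assay_config()].
#' @return `"competes"` or `"no_competition"`.
#' @export
competition_call <- function(sgram, config = assay_config()) {
  phases <- vapply(sgram$steps, `[[`, character(1), "phase")
  assoc <- which(phases == "association")
  if (length(assoc) < 2L) {
    stop("missing capture step: need an IgG-capture association followed by a ligand challenge")
  }
  challenge <- sgram$steps[assoc[-1]]
  deltas <- vapply(challenge, function(st) {
    if (length(st$responses) < 2L) stop("zero-length ligand-challenge step")
    max(abs(st$responses - st$responses[1]))
  }, numeric(1))
  if (max(deltas) >= config$binding_call_threshold) "competes" else "no_competition"
}
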