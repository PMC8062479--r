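#' Consumer-resource model parameters
#'
#' Container for the model constants, with experiment-derived defaults: an
#' energy-to-growth conversion `g = 1` and resource energy content `w = 1e8`
#' sized so a community starting at 6e6 CFU/mL per species in 1.5 g/mL of
#' carbon reaches ~2.4e8 CFU/mL within a batch; Monod half-velocity
#' `k = 1e4` g/mL (far above the working resource concentrations, so kinetics
#' are near-linear); leakage fraction `l = 0.8`; and a serial-passaging
#' regime of 6 batches of 48 h with a 10-in-300 (1/30) dilution, integrated
#' at `dt = 0.01` h.
#'
#' The maintenance default `m = 0.01` /h is calibrated on community yields at
#' steady state: it keeps maintenance an order of magnitude below the ~1/h
#' characteristic growth rates, so final-batch yields sit near the
#' resource-energy bound `g w (1 - l) R_total0` and the yield of a
#' fully-generalist community is additive across environment combinations.
#' Larger values burn most of the attainable biomass between resource
#' exhaustion and passage end and break that additivity.
#'
#' @param g Per-species energy-to-growth conversion (scalar or vector).
#' @param w Per-resource energy content.
#' @param m Per-species maintenance (minimum energy requirement) in /h;
#'   species whose leakage-discounted energy uptake falls below it decay.
#' @param l Per-resource leakage fraction in `[0, 1]`.
#' @param k Monod half-velocity constant (resource-concentration units).
#' @param dt Integration timestep, hours.
#' @param passage_interval Hours per batch.
#' @param n_passages Number of serial batches.
#' @param dilution_factor Fraction of culture carried into fresh medium.
#' @param N0 Initial per-species abundance (CFU/mL).
#' @param R_total0 Total initial resource (g/mL equivalent across the
#'   environment).
#' @param uptake_scale Magnitude bound of nonzero uptake-matrix entries.
#' @param byproduct_transition Probability that a given byproduct is produced
#'   from a given primary resource.
#' @param survival_threshold Relative abundance above which a species counts
#'   as surviving at experiment end.
#' @return An object of class `crm_params`.
#' @export
crm_params <- function(g = 1, w = 1e8, m = 0.01, l = 0.8, k = 1e4,
                       dt = 0.01, passage_interval = 48, n_passages = 6,
                       dilution_factor = 1 / 30, N0 = 6e6, R_total0 = 1.5,
                       uptake_scale = 1e-3, byproduct_transition = 0.25,
                       survival_threshold = 1e-3) {
  p <- list(g = g, w = w, m = m, l = l, k = k, dt = dt,
            passage_interval = passage_interval, n_passages = n_passages,
            dilution_factor = dilution_factor, N0 = N0, R_total0 = R_total0,
            uptake_scale = uptake_scale,
            byproduct_transition = byproduct_transition,
            survival_threshold = survival_threshold)
  if (any(p$l < 0 | p$l > 1)) stop("leakage fraction must be in [0, 1]")
  if (p$dt <= 0) stop("dt must be > 0")
  if (p$dilution_factor <= 0 || p$dilution_factor > 1)
    stop("dilution_factor must be in (0, 1]")
  if (any(c(p$k, p$w, p$g, p$N0, p$R_total0, p$uptake_scale) <= 0))
    stop("k, w, g, N0, R_total0, uptake_scale must be > 0")
  if (any(p$m < 0)) stop("maintenance m must be >= 0")
  if (p$byproduct_transition < 0 || p$byproduct_transition > 1)
    stop("byproduct_transition must be in [0, 1]")
  structure(p, class = "crm_params")
}

expand_param <- function(x, n) {
  if (length(x) == 1) rep(as.numeric(x), n)
  else if (length(x) == n) as.numeric(x)
  else stop("parameter of length ", length(x), " cannot map to ", n)
}

#' Random resource-utilization (uptake) matrix
#'
#' Each entry of the S x (M_primary + M_byproduct) matrix is nonzero with
#' probability `theta_i` (the fraction of resources usable by species *i*;
#' low values make specialists), with nonzero magnitudes drawn uniformly on
#' `(0, uptake_scale]`. Byproduct columns are populated by the same rule.
#'
#' @param S Number of species.
#' @param M_primary Number of primary resources.
#' @param M_byproduct Number of secreted-byproduct resources.
#' @param theta Utilization probability, scalar or per-species vector in
#'   `[0, 1]`.
#' @param uptake_scale Magnitude of nonzero entries.
#' @param seed Optional RNG seed (otherwise the current RNG stream is used).
#' @return An object of class `uptake_matrix` with elements `C`, `theta`,
#'   `M_primary`, `M_byproduct`, `uptake_scale`.
#' @export
generate_uptake_matrix <- function(S, M_primary, M_byproduct = 0,
                                   theta = 0.5, uptake_scale = 1e-3,
                                   seed = NULL) {
  if (S < 1 || M_primary < 1) stop("need at least one species and resource")
  theta <- expand_param(theta, S)
  if (any(theta < 0 | theta > 1)) stop("theta must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  M <- M_primary + M_byproduct
  p_util <- matrix(stats::runif(S * M), S, M)
  mag <- matrix(stats::runif(S * M), S, M) * uptake_scale
  C <- (p_util < theta) * mag  # theta recycled down columns (per species)
  structure(list(C = C, theta = theta, M_primary = M_primary,
                 M_byproduct = M_byproduct, uptake_scale = uptake_scale),
            class = "uptake_matrix")
}

#' Random byproduct conversion tensor
#'
#' For each species and primary resource, each byproduct is selected with
#' `transition_probability`; selected entries receive equal weight and the
#' column is normalized to sum 1 (conservation of mass). Columns with no
#' selected byproduct stay all-zero (no conversion drawn). Byproducts are
#' never converted further.
#'
#' @param S Number of species.
#' @param M_primary Number of primary resources.
#' @param M_byproduct Number of byproducts (>= 1).
#' @param transition_probability Per-entry selection probability (default
#'   0.25).
#' @param seed Optional RNG seed.
#' @return A numeric array `D` of dimension
#'   `(M_byproduct, M_primary, S)`, class `byproduct_tensor`.
#' @export
generate_byproduct_tensor <- function(S, M_primary, M_byproduct,
                                      transition_probability = 0.25,
                                      seed = NULL) {
  if (M_byproduct < 1) stop("need at least one byproduct")
  if (transition_probability < 0 || transition_probability > 1)
    stop("transition_probability must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  sel <- array(stats::runif(M_byproduct * M_primary * S) < transition_probability,
               dim = c(M_byproduct, M_primary, S))
  cnt <- apply(sel, c(2, 3), sum)
  D <- array(0, dim = c(M_byproduct, M_primary, S))
  for (i in seq_len(S)) {
    for (b in seq_len(M_primary)) {
      if (cnt[b, i] > 0) D[sel[, b, i], b, i] <- 1 / cnt[b, i]
    }
  }
  structure(D, class = c("byproduct_tensor", "array"))
}

empty_byproduct_tensor <- function(S, M_primary) {
  structure(array(0, dim = c(0, M_primary, S)),
            class = c("byproduct_tensor", "array"))
}

as_tensor_array <- function(D, S, M_primary) {
  if (is.null(D)) return(empty_byproduct_tensor(S, M_primary))
  stopifnot(length(dim(D)) == 3, dim(D)[2] == M_primary, dim(D)[3] == S)
  D
}

#' Right-hand side of the consumer-resource dynamics
#'
#' Pure-R reference implementation of the growth and resource equations, used
#' as the oracle against the compiled integrator. Per-capita growth of
#' species *i* is the leakage-discounted energy uptake
#' \eqn{\sum_a w_a (1-l_a) C_{ia} R_a/(k_a+R_a)} minus maintenance
#' \eqn{m_i}, scaled by \eqn{g_i}. Resources deplete through consumption and
#' byproducts gain the leaked fraction of primary-resource flux routed
#' through the conversion tensor.
#'
#' @param N Species abundances (length S).
#' @param R Resource abundances (length `M_primary + M_byproduct`).
#' @param U An `uptake_matrix`.
#' @param D A `byproduct_tensor` or NULL.
#' @param params A `crm_params`.
#' @return A list with `dN` and `dR`.
#' @export
crm_rhs <- function(N, R, U, D = NULL, params = crm_params()) {
  stopifnot(inherits(U, "uptake_matrix"))
  C <- U$C; S <- nrow(C); M <- ncol(C); Mp <- U$M_primary
  if (length(N) != S || length(R) != M) stop("state dimensions do not match C")
  D <- as_tensor_array(D, S, Mp)
  g <- expand_param(params$g, S); m <- expand_param(params$m, S)
  w <- expand_param(params$w, M); l <- expand_param(params$l, M)
  k <- expand_param(params$k, M)
  mon <- R / (k + R)
  dN <- numeric(S); dR <- numeric(M)
  for (i in seq_len(S)) {
    uptake_energy <- sum(w * (1 - l) * C[i, ] * mon)
    dN[i] <- g[i] * N[i] * (uptake_energy - m[i])
  }
  for (a in seq_len(M)) {
    dR[a] <- -sum(C[, a] * N) * mon[a]
  }
  Mb <- M - Mp
  if (Mb > 0) {
    for (a in seq_len(Mb)) {
      prod <- 0
      for (i in seq_len(S)) {
        for (b in seq_len(Mp)) {
          prod <- prod + D[a, b, i] * (w[b] / w[Mp + a]) * l[b] *
            C[i, b] * N[i] * mon[b]
        }
      }
      dR[Mp + a] <- dR[Mp + a] + prod
    }
  }
  list(dN = dN, dR = dR)
}

#' Integrate one batch of growth
#'
#' Fixed-step explicit Euler at `params$dt`; any negative component produced
#' by a step is clamped to zero. The trajectory (when recorded) includes
#' t = 0 and t = duration.
#'
#' @param N0,R0 Initial species and resource abundances.
#' @param U An `uptake_matrix`.
#' @param D A `byproduct_tensor` or NULL (no byproducts).
#' @param params A `crm_params`.
#' @param duration Batch duration in hours (default
#'   `params$passage_interval`).
#' @param thin Record the trajectory every `thin` steps (0 = endpoint only).
#' @return A list with endpoint `N`, `R`, `t`, and when `thin > 0` also
#'   `times`, `N_traj`, `R_traj` (rows are recorded timepoints).
#' @export
integrate_batch <- function(N0, R0, U, D = NULL, params = crm_params(),
                            duration = params$passage_interval, thin = 0) {
  stopifnot(inherits(U, "uptake_matrix"))
  C <- U$C; S <- nrow(C); M <- ncol(C); Mp <- U$M_primary
  if (length(N0) != S || length(R0) != M)
    stop("state dimensions do not match C")
  if (duration < 0) stop("duration must be >= 0")
  if (duration == 0) return(list(N = as.numeric(N0), R = as.numeric(R0), t = 0))
  D <- as_tensor_array(D, S, Mp)
  res <- cpp_integrate_batch(C, D, as.numeric(N0), as.numeric(R0), Mp,
                             expand_param(params$g, S),
                             expand_param(params$m, S),
                             expand_param(params$w, M),
                             expand_param(params$l, M),
                             expand_param(params$k, M),
                             params$dt, duration, as.integer(thin))
  res$N <- as.numeric(res$N)
  res$R <- as.numeric(res$R)
  res
}

#' Simulate serial batch passaging in one environment
#'
#' Runs `n_passages` batches of `passage_interval` hours. Between batches the
#' species abundances are diluted by `dilution_factor`, primary resources are
#' reset to the environment's concentrations and byproducts to zero —
#' emulating transfer of a 10 ul aliquot into 290 ul of fresh medium. All
#' species start at `N0`.
#'
#' @param concentrations Named numeric vector of primary-resource
#'   concentrations (names are resource ids, i.e. column indices of `C`), for
#'   example one element of `scheme$concentrations`.
#' @param U An `uptake_matrix`.
#' @param D A `byproduct_tensor` or NULL.
#' @param params A `crm_params`.
#' @return A list: endpoint `N`, `R`, `rel_abundance`, `survivors` (species
#'   indices at or above `survival_threshold` relative abundance), `yield`
#'   (biomass gained over the final batch, CFU/mL scale), `richness`,
#'   `shannon`, and `passages` (per-passage start/end biomass and yields).
#' @export
simulate_passaged <- function(concentrations, U, D = NULL,
                              params = crm_params()) {
  stopifnot(inherits(U, "uptake_matrix"))
  S <- nrow(U$C); Mp <- U$M_primary; Mb <- U$M_byproduct
  R0p <- numeric(Mp)
  ids <- as.integer(names(concentrations))
  if (any(is.na(ids)) || any(ids < 1 | ids > Mp))
    stop("environment resources do not map onto columns of C")
  R0p[ids] <- as.numeric(concentrations)

  N <- rep(params$N0, S)
  pass <- vector("list", params$n_passages)
  for (p in seq_len(params$n_passages)) {
    start_biomass <- sum(N)
    res <- integrate_batch(N, c(R0p, numeric(Mb)), U, D, params)
    pass[[p]] <- data.frame(passage = p, t_end = p * params$passage_interval,
                            biomass_start = start_biomass,
                            biomass_end = sum(res$N),
                            yield = sum(res$N) - start_biomass)
    N <- res$N
    if (p < params$n_passages) N <- N * params$dilution_factor
  }
  total <- sum(res$N)
  rel <- if (total > 0) res$N / total else numeric(S)
  survivors <- which(rel >= params$survival_threshold)
  list(N = res$N, R = res$R, rel_abundance = rel, survivors = survivors,
       yield = pass[[params$n_passages]]$yield,
       richness = length(survivors),
       shannon = if (total > 0) shannon_entropy(rel) else 0,
       passages = do.call(rbind, pass))
}
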