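#' Niche overlap of a resource-utilization matrix
#'
#' \eqn{\rho = \mu_C^2 / (\mu_C^2 + \sigma_C^2)}, with the mean and
#' (population) variance taken over all primary-resource entries of the
#' uptake matrix, zeros included. The metric is 0 when organisms share no
#' resource use (all-zero matrix, by convention) and 1 when utilization
#' profiles are identical constants; it is invariant to rescaling the
#' matrix.
#'
#' @param U An `uptake_matrix`, or a plain numeric matrix (all columns
#'   treated as primary).
#' @return Niche overlap in `[0, 1]`.
#' @export
niche_overlap <- function(U) {
  Cp <- if (inherits(U, "uptake_matrix"))
    U$C[, seq_len(U$M_primary), drop = FALSE] else as.matrix(U)
  if (length(Cp) == 0) stop("empty uptake matrix")
  mu <- mean(Cp)
  if (mu == 0) return(0)
  s2 <- mean((Cp - mu)^2)
  mu^2 / (mu^2 + s2)
}

#' Ensemble of passaged community simulations over a scheme
#'
#' Simulates a statistical ensemble of random communities in every
#' environment of a combinatorial scheme. For each replicate (and each
#' byproduct count) a fresh uptake matrix and conversion tensor are drawn,
#' and the community is passaged in every environment. Two regimes mirror
#' the generalist/specialist contrast: `theta_mode = "uniform"` gives every
#' species the same utilization probability (CRM-A style, default 0.5),
#' while `"sampled_range"` draws a per-species `theta_i` uniformly on
#' `theta_range` each replicate, emulating monoculture-informed
#' generalist-specialist spread (CRM-B style); `"vector"` uses a supplied
#' per-species vector as-is.
#'
#' @param scheme An `env_scheme` (its resources define the primary-resource
#'   columns).
#' @param S Number of species (default 13).
#' @param theta Utilization probability: scalar (uniform mode), per-species
#'   vector (vector mode), ignored for `"sampled_range"`.
#' @param theta_mode `"uniform"`, `"vector"`, or `"sampled_range"`.
#' @param theta_range Bounds for `"sampled_range"` (default `c(0.15, 0.95)`).
#' @param n_replicates Replicates with freshly drawn matrices (default 50).
#' @param byproduct_counts Byproduct pool sizes to simulate and later average
#'   over (default `1:10`).
#' @param params A `crm_params`.
#' @param seed Optional RNG seed for the whole ensemble.
#' @param keep_abundances Keep per-species endpoint relative abundances
#'   (needed for outcome classification)?
#' @return An object of class `crm_ensemble`: `summary` (one row per
#'   replicate x byproduct count x environment: `yield`, `richness`,
#'   `shannon`), `rho` (one row per replicate x byproduct count),
#'   `abundances` (optional matrix of relative abundances, rows =
#'   `replicate.byproduct.env`), `env` (environment/complexity lookup), and
#'   `config`.
#' @export
run_crm_ensemble <- function(scheme, S = 13, theta = 0.5,
                             theta_mode = c("uniform", "vector",
                                            "sampled_range"),
                             theta_range = c(0.15, 0.95),
                             n_replicates = 50, byproduct_counts = 1:10,
                             params = crm_params(), seed = NULL,
                             keep_abundances = TRUE) {
  stopifnot(inherits(scheme, "env_scheme"))
  theta_mode <- match.arg(theta_mode)
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  Mp <- nrow(scheme$resources)
  env_ids <- scheme$environments$env_id
  complexity <- scheme$environments$complexity

  rows <- list(); rhos <- list(); ab <- list()
  for (rep in seq_len(n_replicates)) {
    theta_rep <- switch(theta_mode,
      uniform = rep(theta[1], S),
      vector = expand_param(theta, S),
      sampled_range = stats::runif(S, theta_range[1], theta_range[2]))
    for (mb in byproduct_counts) {
      U <- generate_uptake_matrix(S, Mp, mb, theta_rep, params$uptake_scale)
      D <- if (mb > 0)
        generate_byproduct_tensor(S, Mp, mb, params$byproduct_transition)
      else NULL
      rhos[[length(rhos) + 1]] <- data.frame(
        replicate = rep, byproduct_count = mb, rho = niche_overlap(U))
      for (e in seq_along(env_ids)) {
        sim <- simulate_passaged(scheme$concentrations[[e]], U, D, params)
        rows[[length(rows) + 1]] <- data.frame(
          replicate = rep, byproduct_count = mb, env_id = env_ids[e],
          complexity = complexity[e], yield = sim$yield,
          richness = sim$richness, shannon = sim$shannon,
          stringsAsFactors = FALSE)
        if (keep_abundances)
          ab[[length(ab) + 1]] <- sim$rel_abundance
      }
    }
  }
  summary <- do.call(rbind, rows)
  abund <- NULL
  if (keep_abundances) {
    abund <- do.call(rbind, ab)
    colnames(abund) <- sprintf("sp%d", seq_len(S))
  }
  structure(list(summary = summary, rho = do.call(rbind, rhos),
                 abundances = abund,
                 env = scheme$environments,
                 config = list(S = S, theta = theta, theta_mode = theta_mode,
                               theta_range = theta_range,
                               n_replicates = n_replicates,
                               byproduct_counts = byproduct_counts,
                               params = unclass(params), seed = seed)),
            class = "crm_ensemble")
}

#' @export
print.crm_ensemble <- function(x, ...) {
  cat(sprintf("CRM ensemble: %d species, %d replicates x %d byproduct counts x %d environments (theta mode '%s')\n",
              x$config$S, x$config$n_replicates,
              length(x$config$byproduct_counts), nrow(x$env),
              x$config$theta_mode))
  invisible(x)
}

#' Average ensemble measures over byproduct counts
#'
#' Per (replicate, environment) mean of yield, richness and entropy across
#' the simulated byproduct pool sizes; results are presented as this average.
#'
#' @param ensemble A `crm_ensemble`.
#' @return data.frame with one row per replicate x environment.
#' @export
average_over_byproducts <- function(ensemble) {
  s <- ensemble$summary
  key <- interaction(s$replicate, s$env_id, drop = TRUE)
  agg <- stats::aggregate(s[, c("yield", "richness", "shannon")],
                          by = list(replicate = s$replicate,
                                    env_id = s$env_id), FUN = mean)
  agg$complexity <- ensemble$env$complexity[match(agg$env_id,
                                                  ensemble$env$env_id)]
  agg[order(agg$replicate, agg$complexity, agg$env_id), , drop = FALSE]
}

#' Complexity-scaling summary of an ensemble
#'
#' Mean and standard error of growth yield, species richness and Shannon
#' entropy per environmental-complexity level, after averaging each
#' replicate-environment cell over byproduct counts. Rows are ordered by
#' complexity.
#'
#' @param ensemble A `crm_ensemble`.
#' @return data.frame with columns `complexity`, `n`, and
#'   `{yield,richness,shannon}_{mean,sd,se}`.
#' @export
scaling_summary <- function(ensemble) {
  stopifnot(inherits(ensemble, "crm_ensemble"))
  a <- average_over_byproducts(ensemble)
  if (nrow(a) == 0) stop("empty ensemble")
  lv <- sort(unique(a$complexity))
  out <- lapply(lv, function(k) {
    sub <- a[a$complexity == k, , drop = FALSE]
    stat <- function(v) c(mean = mean(v), sd = stats::sd(v),
                          se = stats::sd(v) / sqrt(length(v)))
    y <- stat(sub$yield); r <- stat(sub$richness); h <- stat(sub$shannon)
    data.frame(complexity = k, n = nrow(sub),
               yield_mean = y["mean"], yield_sd = y["sd"], yield_se = y["se"],
               richness_mean = r["mean"], richness_sd = r["sd"],
               richness_se = r["se"],
               shannon_mean = h["mean"], shannon_sd = h["sd"],
               shannon_se = h["se"], row.names = NULL)
  })
  do.call(rbind, out)
}

#' Epistasis distributions from an ensemble
#'
#' Computes the chosen epistasis metric over every scheme edge for each
#' (replicate, byproduct count), then averages the per-edge scores across
#' byproduct counts within each replicate (per-count scores first, averages
#' second).
#'
#' @param ensemble A `crm_ensemble`.
#' @param scheme The `env_scheme` the ensemble was run on.
#' @param metric `"yield"`, `"richness"` or `"shannon"`.
#' @return data.frame with one row per replicate x edge: `replicate`,
#'   `env_id`, `E`.
#' @export
ensemble_epistasis <- function(ensemble, scheme,
                               metric = c("yield", "richness", "shannon")) {
  stopifnot(inherits(ensemble, "crm_ensemble"))
  metric <- match.arg(metric)
  s <- ensemble$summary
  out <- list()
  for (rep in unique(s$replicate)) {
    per_count <- list()
    for (mb in unique(s$byproduct_count)) {
      sub <- s[s$replicate == rep & s$byproduct_count == mb, , drop = FALSE]
      meas <- data.frame(env_id = sub$env_id, yield = sub$yield,
                         richness = sub$richness, shannon = sub$shannon,
                         stringsAsFactors = FALSE)
      eps <- epistasis_over_tree(scheme, meas, metric)
      per_count[[length(per_count) + 1]] <- eps$E
      edge_ids <- eps$env_id
    }
    Em <- rowMeans(do.call(cbind, per_count))
    out[[length(out) + 1]] <- data.frame(replicate = rep, env_id = edge_ids,
                                         E = Em, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Outcome-type prevalences from an ensemble
#'
#' Derives survivor sets from the stored endpoint relative abundances (at the
#' ensemble's survival threshold) and classifies every scheme edge for every
#' replicate x byproduct count.
#'
#' @param ensemble A `crm_ensemble` run with `keep_abundances = TRUE`.
#' @param scheme The `env_scheme` the ensemble was run on.
#' @return A list: `labels` (data.frame replicate, byproduct_count, env_id,
#'   type) and `prevalence` (fraction of edges per type).
#' @export
ensemble_outcomes <- function(ensemble, scheme) {
  stopifnot(inherits(ensemble, "crm_ensemble"))
  if (is.null(ensemble$abundances))
    stop("ensemble was run without keep_abundances")
  s <- ensemble$summary
  thr <- ensemble$config$params$survival_threshold
  species <- colnames(ensemble$abundances)
  out <- list()
  for (rep in unique(s$replicate)) {
    for (mb in unique(s$byproduct_count)) {
      idx <- which(s$replicate == rep & s$byproduct_count == mb)
      surv <- lapply(idx, function(i)
        species[ensemble$abundances[i, ] >= thr])
      names(surv) <- s$env_id[idx]
      lab <- classify_over_tree(scheme, surv)
      lab$replicate <- rep; lab$byproduct_count <- mb
      out[[length(out) + 1]] <- lab
    }
  }
  labels <- do.call(rbind, out)
  tab <- table(factor(labels$type, levels = c("I", "II", "III", "IV")))
  list(labels = labels, prevalence = as.numeric(tab) / sum(tab),
       prevalence_pct = stats::setNames(100 * as.numeric(tab) / sum(tab),
                                        names(tab)))
}
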