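#' Synthetic monoculture growth-yield profile
#'
#' Emulates single-organism, single-carbon-source growth assays: organism *i*
#' grows on a `theta_i` fraction of the resources (Bernoulli per resource),
#' with yields drawn uniformly on `[0.1, 0.6]` OD where it grows and 0
#' elsewhere. The empirical usable fraction per organism is recoverable from
#' the matrix, which is how monoculture-informed utilization probabilities
#' are produced.
#'
#' @param S Number of organisms.
#' @param M Number of resources.
#' @param theta Usable-resource fraction, scalar or per-organism vector in
#'   `[0, 1]`.
#' @param seed Optional RNG seed.
#' @return S x M numeric matrix of OD yields.
#' @export
synth_monoculture_profile <- function(S, M, theta = 0.5, seed = NULL) {
  theta <- expand_param(theta, S)
  if (any(theta < 0 | theta > 1)) stop("theta must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  usable <- matrix(stats::runif(S * M), S, M) < theta  # recycled per row
  yield <- matrix(stats::runif(S * M, 0.1, 0.6), S, M)
  out <- usable * yield
  dimnames(out) <- list(sprintf("org%d", seq_len(S)),
                        sprintf("cs%d", seq_len(M)))
  out
}

#' Additive per-environment true yields for a scheme
#'
#' Propagates singleton yields up a combination scheme under the equal-carbon
#' additive expectation (each composite's yield is the mean of its two
#' constituents'), giving a ground truth whose yield epistasis is exactly
#' zero everywhere — the natural base on which to plant offsets.
#'
#' @param scheme An `env_scheme`.
#' @param leaf_yields Named numeric vector: yield per complexity-1
#'   environment id.
#' @return Named numeric vector of yields for every environment.
#' @export
synth_additive_truth <- function(scheme, leaf_yields) {
  leaves <- scheme$environments$env_id[scheme$environments$complexity ==
                                         min(scheme$environments$complexity)]
  if (!all(leaves %in% names(leaf_yields)))
    stop("leaf_yields must cover every base-level environment")
  truth <- leaf_yields
  ord <- order(scheme$environments$complexity)
  for (id in scheme$environments$env_id[ord]) {
    if (id %in% names(truth)) next
    e <- scheme$edges[scheme$edges$env_id == id, , drop = FALSE][1, ]
    truth[id] <- (truth[[e$constituent_a]] + truth[[e$constituent_b]]) / 2
  }
  truth[scheme$environments$env_id]
}

#' Synthetic plate-reader dataset for a scheme
#'
#' Builds a `plate_table` of raw OD readings with the statistical structure
#' of the experimental tables: per-environment truth plus Gaussian replicate
#' noise (truncated at zero corrected OD), a plate blank, negative-control
#' wells, optional planted yield-epistasis offsets on composite environments
#' and optional planted single-replicate outliers for filter testing.
#'
#' @param scheme An `env_scheme`.
#' @param true_yields Named numeric vector of true corrected-OD yields per
#'   environment id (e.g. from [synth_additive_truth()] or a rescaled CRM
#'   run).
#' @param replicate_noise_sd Gaussian replicate noise sd, OD units (default
#'   0.01, plate-reader repeatability scale).
#' @param planted_EY Optional named vector of offsets added to composite
#'   environments' true yields (the planted yield epistasis).
#' @param planted_outliers Optional named vector: environment id -> shift in
#'   sd units applied to that environment's first replicate.
#' @param n_replicates Replicates per environment (default 3).
#' @param blank_od Plate blank (medium-only OD, default 0.04).
#' @param seed Optional RNG seed.
#' @return A list: `plate` (a `plate_table`), `truth` (the per-environment
#'   true yields after offsets), `manifest` (planting record).
#' @export
synth_community_plates <- function(scheme, true_yields,
                                   replicate_noise_sd = 0.01,
                                   planted_EY = NULL, planted_outliers = NULL,
                                   n_replicates = 3, blank_od = 0.04,
                                   seed = NULL) {
  stopifnot(inherits(scheme, "env_scheme"))
  env_ids <- scheme$environments$env_id
  if (!all(env_ids %in% names(true_yields)))
    stop("true_yields must cover every environment")
  if (!is.null(seed)) set.seed(seed)
  truth <- true_yields[env_ids]
  if (!is.null(planted_EY)) {
    comp <- intersect(names(planted_EY), scheme$edges$env_id)
    if (length(comp) < length(planted_EY))
      stop("planted_EY names must be composite environment ids")
    truth[comp] <- truth[comp] + planted_EY[comp]
  }
  rows <- list()
  for (id in env_ids) {
    corrected <- truth[[id]] + stats::rnorm(n_replicates, 0, replicate_noise_sd)
    if (!is.null(planted_outliers) && id %in% names(planted_outliers))
      corrected[1] <- corrected[1] + planted_outliers[[id]] * replicate_noise_sd
    corrected <- pmax(corrected, 0)
    rows[[id]] <- data.frame(environment_id = id,
                             replicate = seq_len(n_replicates),
                             od_raw = blank_od + corrected,
                             stringsAsFactors = FALSE)
  }
  negctrl <- blank_od + abs(stats::rnorm(n_replicates, 0, replicate_noise_sd))
  plate <- plate_table(do.call(rbind, rows), blank_od = blank_od,
                       negative_controls = negctrl)
  list(plate = plate, truth = truth,
       manifest = list(replicate_noise_sd = replicate_noise_sd,
                       planted_EY = planted_EY,
                       planted_outliers = planted_outliers,
                       n_replicates = n_replicates, blank_od = blank_od,
                       seed = seed))
}

#' Synthetic 16S-style abundance table by multinomial read sampling
#'
#' Emulates amplicon sequencing of community endpoints: for each environment
#' and replicate, `read_depth` reads are drawn multinomially from the true
#' composition and converted back to relative abundances.
#'
#' @param compositions Taxa x environments matrix of true relative abundances
#'   (columns need not be normalized; they are).
#' @param read_depth Reads per sample (default 10000).
#' @param n_replicates Independent draws per environment (default 3).
#' @param seed Optional RNG seed.
#' @return An `abundance_table`.
#' @export
synth_abundance_table <- function(compositions, read_depth = 10000,
                                  n_replicates = 3, seed = NULL) {
  stopifnot(is.matrix(compositions), !is.null(colnames(compositions)))
  if (any(compositions < 0)) stop("abundances must be nonnegative")
  if (read_depth < 1) stop("read_depth must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  taxa <- rownames(compositions)
  if (is.null(taxa)) taxa <- sprintf("sp%d", seq_len(nrow(compositions)))
  cols <- list(); meta <- list()
  for (e in colnames(compositions)) {
    p <- compositions[, e]
    if (sum(p) == 0) stop("environment ", e, " has zero total abundance")
    p <- p / sum(p)
    for (r in seq_len(n_replicates)) {
      counts <- stats::rmultinom(1, read_depth, p)[, 1]
      sid <- sprintf("%s|r%d", e, r)
      cols[[sid]] <- counts / read_depth
      meta[[sid]] <- data.frame(sample_id = sid, environment_id = e,
                                replicate = r, stringsAsFactors = FALSE)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- taxa
  abundance_table(m, do.call(rbind, meta))
}
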