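#' Shannon entropy of a community composition
#'
#' \eqn{H = -\sum_i p_i \log_2 p_i}, in bits, with zero abundances skipped.
#'
#' @param p Relative-abundance vector: nonnegative, summing to 1 (tolerance
#'   1e-9 absolute).
#' @return Entropy in bits, between 0 and `log2` of the number of nonzero
#'   entries.
#' @export
shannon_entropy <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0)) stop("relative abundances must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9) stop("relative abundances must sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Species richness above a detection threshold
#'
#' @param p Abundance vector (relative or absolute), nonnegative.
#' @param threshold Detection threshold; entries strictly above it count.
#' @return Integer count of detected taxa.
#' @export
species_richness <- function(p, threshold = 0) {
  p <- as.numeric(p)
  if (any(p < 0)) stop("abundances must be nonnegative")
  if (threshold < 0) stop("threshold must be >= 0")
  sum(p > threshold)
}

#' Yield epistasis between combined and constituent environments
#'
#' Deviation of the growth yield on the combined environment AB from the
#' additive expectation under equal total carbon: since A, B and AB all carry
#' the same carbon, the expected yield on AB is the average of the yields on
#' A and B. \eqn{E_Y = Y_{AB} - (Y_A + Y_B)/2}.
#'
#' @param Y_AB,Y_A,Y_B Nonnegative finite yields (OD or simulated-biomass
#'   scale).
#' @return The epistasis score (same units as the yields).
#' @export
epistasis_yield <- function(Y_AB, Y_A, Y_B) {
  vals <- c(Y_AB, Y_A, Y_B)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("yields must be finite and >= 0")
  Y_AB - (Y_A + Y_B) / 2
}

#' Species-richness epistasis
#'
#' The null expectation is a lower bound: a community on AB should be at least
#' as rich as the richer of A and B. \eqn{E_S = S_{AB} - \max(S_A, S_B)}.
#'
#' @param S_AB,S_A,S_B Nonnegative richness values.
#' @return The epistasis score (species).
#' @export
epistasis_richness <- function(S_AB, S_A, S_B) {
  vals <- c(S_AB, S_A, S_B)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("richness values must be finite and >= 0")
  S_AB - max(S_A, S_B)
}

#' Shannon-entropy epistasis
#'
#' \eqn{E_H = H_{AB} - \max(H_A, H_B)}, the analogue of
#' [epistasis_richness()] for community balance.
#'
#' @param H_AB,H_A,H_B Nonnegative entropies (bits).
#' @return The epistasis score (bits).
#' @export
epistasis_shannon <- function(H_AB, H_A, H_B) {
  vals <- c(H_AB, H_A, H_B)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("entropies must be finite and >= 0")
  H_AB - max(H_A, H_B)
}

#' Epistasis scores over every edge of a combination scheme
#'
#' Applies one of the three epistasis metrics to every (composite,
#' constituent A, constituent B) edge of a scheme, given per-environment
#' measurements.
#'
#' No-growth environments (`growth_flag` FALSE) contribute richness 0 and
#' entropy 0. For the yield metric the measured yield is used as-is by
#' default (`no_growth_yield = "measured"`); `"zero"` substitutes 0.
#' A composite without a measurement produces a row with `E = NA` (an
#' explicit gap); an edge whose *constituents* are unmeasured is a structural
#' error.
#'
#' @param scheme An `env_scheme`.
#' @param measurements A data.frame with column `env_id` plus, depending on
#'   `metric`, `yield`, `richness` or `shannon`; optionally `growth_flag`
#'   (assumed TRUE when absent).
#' @param metric One of `"yield"`, `"richness"`, `"shannon"`.
#' @param no_growth_yield `"measured"` or `"zero"` (yield metric only).
#' @return A data.frame with one row per edge: `env_id`, `constituent_a`,
#'   `constituent_b`, `metric`, `observed`, `expected`, `E`.
#' @export
epistasis_over_tree <- function(scheme, measurements,
                                metric = c("yield", "richness", "shannon"),
                                no_growth_yield = c("measured", "zero")) {
  stopifnot(inherits(scheme, "env_scheme"))
  metric <- match.arg(metric)
  no_growth_yield <- match.arg(no_growth_yield)
  col <- switch(metric, yield = "yield", richness = "richness",
                shannon = "shannon")
  if (!all(c("env_id", col) %in% names(measurements)))
    stop(sprintf("measurements need columns env_id and %s", col))
  if (anyDuplicated(measurements$env_id))
    stop("one measurement row per environment required")
  gf <- if ("growth_flag" %in% names(measurements))
    as.logical(measurements$growth_flag) else rep(TRUE, nrow(measurements))

  value_of <- function(id) {
    j <- match(id, measurements$env_id)
    if (is.na(j)) return(NA_real_)
    v <- measurements[[col]][j]
    if (!gf[j]) {
      if (metric != "yield") return(0)
      if (no_growth_yield == "zero") return(0)
    }
    v
  }

  edges <- scheme$edges
  missing_con <- character(0)
  res <- vector("list", nrow(edges))
  for (i in seq_len(nrow(edges))) {
    va <- value_of(edges$constituent_a[i])
    vb <- value_of(edges$constituent_b[i])
    vab <- value_of(edges$env_id[i])
    if (is.na(va) || is.na(vb))
      missing_con <- c(missing_con, edges$env_id[i])
    expected <- if (metric == "yield") (va + vb) / 2 else max(va, vb)
    res[[i]] <- data.frame(
      env_id = edges$env_id[i],
      constituent_a = edges$constituent_a[i],
      constituent_b = edges$constituent_b[i],
      metric = metric, observed = vab, expected = expected,
      E = vab - expected, stringsAsFactors = FALSE)
  }
  if (length(missing_con) > 0)
    stop("composites measured without their constituents: ",
         paste(unique(missing_con), collapse = ", "))
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(env_id = character(0), constituent_a = character(0),
                      constituent_b = character(0), metric = character(0),
                      observed = numeric(0), expected = numeric(0),
                      E = numeric(0), stringsAsFactors = FALSE)
  out
}

#' Classify the taxonomic outcome of combining two environments
#'
#' Compares the survivor set on the combined environment AB with those on its
#' constituents A and B, assigning one of four mutually exclusive types in
#' precedence order:
#' \describe{
#'   \item{I}{AB contains an organism observed in neither A nor B.}
#'   \item{II}{AB equals the union of the survivors of A and B.}
#'   \item{III}{AB equals the survivor set of the less diverse constituent
#'     (either one on a richness tie).}
#'   \item{IV}{any other pattern of diversity loss.}
#' }
#' Three empty sets classify as Type II (vacuous union).
#'
#' @param surv_A,surv_B,surv_AB Character vectors of surviving taxa, drawn
#'   from a shared universe.
#' @return A list with `label` (`"I"`..`"IV"`) and the three survivor sets.
#' @export
classify_outcome <- function(surv_A, surv_B, surv_AB) {
  surv_A <- unique(as.character(surv_A))
  surv_B <- unique(as.character(surv_B))
  surv_AB <- unique(as.character(surv_AB))
  un <- union(surv_A, surv_B)
  label <-
    if (length(setdiff(surv_AB, un)) > 0) "I"
    else if (setequal(surv_AB, un)) "II"
    else {
      least <- if (length(surv_A) <= length(surv_B)) surv_A else surv_B
      other <- if (length(surv_A) <= length(surv_B)) surv_B else surv_A
      matches_least <- setequal(surv_AB, least) ||
        (length(surv_A) == length(surv_B) && setequal(surv_AB, other))
      if (matches_least) "III" else "IV"
    }
  list(label = label, surv_A = surv_A, surv_B = surv_B, surv_AB = surv_AB)
}

#' Outcome types over every edge of a scheme
#'
#' @param scheme An `env_scheme`.
#' @param survivors Named list mapping environment id to a character vector of
#'   surviving taxa (empty vectors for no-growth environments).
#' @return A data.frame with one row per edge: `env_id`, `constituent_a`,
#'   `constituent_b`, `type`.
#' @export
classify_over_tree <- function(scheme, survivors) {
  stopifnot(inherits(scheme, "env_scheme"))
  edges <- scheme$edges
  need <- unique(c(edges$env_id, edges$constituent_a, edges$constituent_b))
  miss <- setdiff(need, names(survivors))
  if (length(miss) > 0)
    stop("survivor sets missing for: ", paste(miss, collapse = ", "))
  type <- character(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    type[i] <- classify_outcome(survivors[[edges$constituent_a[i]]],
                                survivors[[edges$constituent_b[i]]],
                                survivors[[edges$env_id[i]]])$label
  }
  data.frame(env_id = edges$env_id, constituent_a = edges$constituent_a,
             constituent_b = edges$constituent_b, type = type,
             stringsAsFactors = FALSE)
}

#' Summary statistics for an epistasis distribution
#'
#' Mean, standard deviation, a one-sample t-test of the mean against zero,
#' and (when a baseline is supplied) a one-sided paired t-test against the
#' baseline distribution. Pairing is by composite environment id when both
#' vectors are named; with unequal lengths or no names an unpaired Welch test
#' is used and flagged.
#'
#' @param E Numeric vector of epistasis scores (optionally named by composite
#'   environment id).
#' @param baseline Optional numeric vector to compare against.
#' @param alternative Direction of the one-sided tests (applies to both the
#'   zero test and the baseline comparison), `"less"`, `"greater"` or
#'   `"two.sided"`.
#' @return A list: `n`, `mean`, `sd`, `p_zero`, and when a baseline is given
#'   `p_baseline` plus `paired` (logical flag).
#' @export
distribution_stats <- function(E, baseline = NULL,
                               alternative = c("less", "greater",
                                               "two.sided")) {
  alternative <- match.arg(alternative)
  E <- E[is.finite(E)]
  if (length(E) < 2) stop("need at least two finite epistasis values")
  out <- list(n = length(E), mean = mean(E), sd = stats::sd(E),
              alternative = alternative)
  out$p_zero <- if (out$sd == 0) {
    if (out$mean == 0) 1
    else if (alternative == "two.sided" ||
             (out$mean < 0) == (alternative == "less")) 0
    else 1
  } else {
    stats::t.test(E, mu = 0, alternative = alternative)$p.value
  }
  if (!is.null(baseline)) {
    baseline <- baseline[is.finite(baseline)]
    paired_p <- function(a, b) {
      d <- a - b
      degenerate <- function() {
        md <- mean(d)
        if (isTRUE(all.equal(md, 0))) 0.5
        else if (alternative == "two.sided" ||
                 (md < 0) == (alternative == "less")) 0
        else 1
      }
      if (stats::sd(d) == 0) return(degenerate())
      tryCatch(stats::t.test(a, b, paired = TRUE,
                             alternative = alternative)$p.value,
               error = function(e) degenerate())
    }
    paired <- FALSE
    if (!is.null(names(E)) && !is.null(names(baseline))) {
      common <- intersect(names(E), names(baseline))
      if (length(common) >= 2) {
        paired <- TRUE
        out$p_baseline <- paired_p(E[common], baseline[common])
      }
    }
    if (!paired) {
      if (length(E) == length(baseline) && is.null(names(E))) {
        paired <- TRUE
        out$p_baseline <- paired_p(E, baseline)
      } else {
        out$p_baseline <- stats::t.test(E, baseline,
                                        alternative = alternative)$p.value
      }
    }
    out$paired <- paired
  }
  out
}
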