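#' Define a set of carbon-source resources
#'
#' Creates the resource table used by the combinatorial environment schemes.
#' Each resource carries a `rank_score`, typically a monoculture growth yield,
#' used to pair weak with strong carbon sources when building the hierarchical
#' scheme.
#'
#' @param names Character vector of resource labels.
#' @param rank_scores Numeric vector of nonnegative, finite scores (one per
#'   resource). Defaults to `seq_along(names)`.
#' @return A data.frame with columns `id`, `name`, `rank_score`.
#' @export
resource_set <- function(names, rank_scores = seq_along(names)) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("resource names must be unique")
  if (length(rank_scores) != length(names))
    stop("rank_scores must match names in length")
  rank_scores <- as.numeric(rank_scores)
  if (any(!is.finite(rank_scores)) || any(rank_scores < 0))
    stop("rank_scores must be finite and >= 0")
  data.frame(id = seq_along(names), name = names, rank_score = rank_scores,
             stringsAsFactors = FALSE)
}

validate_resources <- function(resources) {
  if (!is.data.frame(resources) ||
      !all(c("id", "name", "rank_score") %in% names(resources)))
    stop("resources must be a data.frame with columns id, name, rank_score")
  if (anyDuplicated(resources$id)) stop("duplicate resource ids")
  if (any(!is.finite(resources$rank_score)))
    stop("rank_score must be finite")
  invisible(resources)
}

new_scheme <- function(type, resources, environments, members, concentrations,
                       edges, total_carbon) {
  structure(
    list(type = type, resources = resources, environments = environments,
         members = members, concentrations = concentrations, edges = edges,
         total_carbon = total_carbon),
    class = "env_scheme")
}

#' @export
print.env_scheme <- function(x, ...) {
  lv <- table(x$environments$complexity)
  cat(sprintf("Combinatorial environment scheme ('%s')\n", x$type))
  cat(sprintf("  %d resources, %d environments, %d epistasis edges\n",
              nrow(x$resources), nrow(x$environments), nrow(x$edges)))
  cat(sprintf("  total carbon per environment: %g\n", x$total_carbon))
  cat("  environments per complexity level:\n")
  for (k in names(lv)) cat(sprintf("    %s carbon source(s): %d\n", k, lv[[k]]))
  invisible(x)
}

#' Equal-carbon concentration assignment
#'
#' Splits a fixed total carbon budget equally among the member resources of an
#' environment, so that every environment in a scheme carries the same amount
#' of carbon irrespective of its complexity.
#'
#' @param resource_ids Integer vector of member resource ids (nonempty).
#' @param total_carbon Positive total carbon (carbon-equivalent units, e.g.
#'   mM C).
#' @return Named numeric vector of concentrations (names are resource ids).
#' @export
equal_carbon_concentrations <- function(resource_ids, total_carbon) {
  if (length(resource_ids) == 0) stop("environment has no resources")
  if (!is.numeric(total_carbon) || total_carbon <= 0)
    stop("total_carbon must be > 0")
  conc <- rep(total_carbon / length(resource_ids), length(resource_ids))
  names(conc) <- as.character(resource_ids)
  conc
}

#' Hierarchical combinatorial environment scheme
#'
#' Builds the nested design used for the 32-carbon-source experiments: all
#' singleton environments, then pairs matching the lowest-ranked resource with
#' the highest (second-lowest with second-highest, and so on), then merges of
#' adjacent pairs, doubling complexity at each level up to the full resource
#' set. On `2^k` resources this produces `2^(k+1) - 1` environments (63 for
#' 32 resources). Every composite environment records its two constituent
#' environments, which is the structure the epistasis metrics consume.
#'
#' @param resources Resource table from [resource_set()]; its length must be a
#'   power of two.
#' @param total_carbon Total carbon per environment (default 1.5, matching an
#'   initial resource concentration of 1.5 g/mL in the simulations; 50 mM C in
#'   the experimental media).
#' @return An object of class `env_scheme`.
#' @export
build_hierarchical_scheme <- function(resources, total_carbon = 1.5) {
  validate_resources(resources)
  n <- nrow(resources)
  if (n < 2 || bitwAnd(n, n - 1L) != 0L)
    stop("hierarchical scheme requires a power-of-two number of resources")

  members <- list()
  edges_env <- character(0); edges_a <- character(0); edges_b <- character(0)

  # level 1: singletons, in input order
  lvl_ids <- sprintf("1-%d", seq_len(n))
  for (j in seq_len(n)) members[[lvl_ids[j]]] <- resources$id[j]

  # level 2: pair rank extremes (lowest with highest, ...); ties by id
  ord <- order(resources$rank_score, resources$id)
  lo <- ord[seq_len(n / 2)]
  hi <- rev(ord)[seq_len(n / 2)]
  l2_ids <- sprintf("2-%d", seq_len(n / 2))
  for (j in seq_len(n / 2)) {
    members[[l2_ids[j]]] <- sort(c(resources$id[lo[j]], resources$id[hi[j]]))
    edges_env <- c(edges_env, l2_ids[j])
    edges_a <- c(edges_a, lvl_ids[lo[j]])
    edges_b <- c(edges_b, lvl_ids[hi[j]])
  }

  # higher levels: merge adjacent pairs in listing order
  prev_ids <- l2_ids
  level <- 4L
  while (level <= n) {
    cur_ids <- sprintf("%d-%d", level, seq_len(n / level))
    for (j in seq_along(cur_ids)) {
      a <- prev_ids[2 * j - 1]; b <- prev_ids[2 * j]
      members[[cur_ids[j]]] <- sort(c(members[[a]], members[[b]]))
      edges_env <- c(edges_env, cur_ids[j])
      edges_a <- c(edges_a, a)
      edges_b <- c(edges_b, b)
    }
    prev_ids <- cur_ids
    level <- level * 2L
  }

  env_ids <- names(members)
  environments <- data.frame(
    env_id = env_ids,
    complexity = vapply(members, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  concentrations <- lapply(members, equal_carbon_concentrations, total_carbon)
  edges <- data.frame(env_id = edges_env, constituent_a = edges_a,
                      constituent_b = edges_b, stringsAsFactors = FALSE)
  new_scheme("hierarchical", resources, environments, members, concentrations,
             edges, total_carbon)
}

#' All-subsets combinatorial environment scheme
#'
#' Builds every nonempty subset of up to 12 resources as an environment (the
#' 5-carbon-source design: 5 singletons, 10 pairs, 10 triples, 5 quadruples
#' and the full set, 31 environments in all). For epistasis each subset of
#' size two or more is linked to a disjoint bipartition (A, B): by default the
#' canonical split (subset minus its highest-ranked member, that member);
#' with `all_bipartitions = TRUE` every unordered bipartition is enumerated.
#'
#' @param resources Resource table from [resource_set()], at most 12 rows.
#' @param total_carbon Total carbon per environment.
#' @param all_bipartitions Enumerate every disjoint bipartition per subset?
#' @return An object of class `env_scheme`.
#' @export
build_full_subset_scheme <- function(resources, total_carbon = 1.5,
                                     all_bipartitions = FALSE) {
  validate_resources(resources)
  n <- nrow(resources)
  if (n < 1) stop("need at least one resource")
  if (n > 12) stop("all-subsets scheme limited to 12 resources")

  subset_id <- function(ids) paste(sort(ids), collapse = "+")

  members <- list()
  for (mask in seq_len(2^n - 1)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    members[[subset_id(resources$id[sel])]] <- sort(resources$id[sel])
  }

  edges_env <- character(0); edges_a <- character(0); edges_b <- character(0)
  for (id in names(members)) {
    ids <- members[[id]]
    s <- length(ids)
    if (s < 2) next
    if (all_bipartitions) {
      # enumerate unordered bipartitions: first member always goes to side A
      rest <- ids[-1]
      for (mask in 0:(2^(s - 1) - 1)) {
        sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(s - 1) - 1L)) != 0L)
        a <- c(ids[1], rest[sel]); b <- setdiff(ids, a)
        if (length(b) == 0) next
        edges_env <- c(edges_env, id)
        edges_a <- c(edges_a, subset_id(a))
        edges_b <- c(edges_b, subset_id(b))
      }
    } else {
      rk <- resources$rank_score[match(ids, resources$id)]
      top <- ids[order(rk, ids, decreasing = TRUE)[1]]
      edges_env <- c(edges_env, id)
      edges_a <- c(edges_a, subset_id(setdiff(ids, top)))
      edges_b <- c(edges_b, subset_id(top))
    }
  }

  environments <- data.frame(
    env_id = names(members),
    complexity = vapply(members, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  concentrations <- lapply(members, equal_carbon_concentrations, total_carbon)
  edges <- data.frame(env_id = edges_env, constituent_a = edges_a,
                      constituent_b = edges_b, stringsAsFactors = FALSE)
  new_scheme(if (all_bipartitions) "full_subset_all" else "full_subset",
             resources, environments, members, concentrations, edges,
             total_carbon)
}

#' Validate the structural invariants of a scheme
#'
#' Checks, for every epistasis edge, that the composite's resource set is the
#' disjoint union of its constituents', and that every environment carries the
#' scheme's fixed total carbon.
#'
#' @param scheme An `env_scheme`.
#' @return `TRUE` invisibly; errors describe the first violated invariant.
#' @export
validate_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "env_scheme"))
  for (i in seq_len(nrow(scheme$edges))) {
    ab <- scheme$members[[scheme$edges$env_id[i]]]
    a <- scheme$members[[scheme$edges$constituent_a[i]]]
    b <- scheme$members[[scheme$edges$constituent_b[i]]]
    if (is.null(a) || is.null(b))
      stop(sprintf("edge %d references unknown constituents", i))
    if (length(intersect(a, b)) > 0)
      stop(sprintf("constituents of %s overlap", scheme$edges$env_id[i]))
    if (!setequal(union(a, b), ab))
      stop(sprintf("constituents of %s do not union to the composite",
                   scheme$edges$env_id[i]))
  }
  tc <- vapply(scheme$concentrations, sum, numeric(1))
  if (any(abs(tc - scheme$total_carbon) > 1e-9 * scheme$total_carbon))
    stop("total carbon differs across environments")
  invisible(TRUE)
}

#' Serialize a scheme to plain-text files
#'
#' Writes a long-format delimited table (environment id, resource id,
#' concentration) and a JSON sidecar holding the resource table, the epistasis
#' edge list and the scheme metadata. [read_scheme()] restores the object
#' exactly.
#'
#' @param scheme An `env_scheme`.
#' @param path_table Path for the TSV concentration table.
#' @param path_json Path for the JSON sidecar (default: `path_table` with a
#'   `.json` extension).
#' @return Invisibly, the two paths.
#' @export
write_scheme <- function(scheme, path_table,
                         path_json = sub("\\.[^.]*$", ".json", path_table)) {
  stopifnot(inherits(scheme, "env_scheme"))
  rows <- do.call(rbind, lapply(names(scheme$members), function(id) {
    data.frame(env_id = id,
               resource_id = scheme$members[[id]],
               concentration = sprintf("%.17g", scheme$concentrations[[id]]),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(type = scheme$type,
               total_carbon = scheme$total_carbon,
               resources = scheme$resources,
               env_order = names(scheme$members),
               edges = scheme$edges)
  jsonlite::write_json(meta, path_json, auto_unbox = TRUE, digits = NA)
  invisible(c(path_table, path_json))
}

#' Read a scheme written by [write_scheme()]
#'
#' @param path_table Path to the TSV concentration table.
#' @param path_json Path to the JSON sidecar.
#' @return An `env_scheme`, identical to the one serialized.
#' @export
read_scheme <- function(path_table,
                        path_json = sub("\\.[^.]*$", ".json", path_table)) {
  rows <- utils::read.table(path_table, sep = "\t", header = TRUE,
                            colClasses = c("character", "integer", "character"),
                            stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(path_json, simplifyVector = TRUE)
  members <- list(); concentrations <- list()
  for (id in meta$env_order) {
    sub <- rows[rows$env_id == id, , drop = FALSE]
    o <- order(sub$resource_id)
    members[[id]] <- sub$resource_id[o]
    conc <- as.numeric(sub$concentration[o])
    names(conc) <- as.character(sub$resource_id[o])
    concentrations[[id]] <- conc
  }
  environments <- data.frame(
    env_id = meta$env_order,
    complexity = vapply(members, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  edges <- as.data.frame(meta$edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0)
    edges <- data.frame(env_id = character(0), constituent_a = character(0),
                        constituent_b = character(0), stringsAsFactors = FALSE)
  resources <- as.data.frame(meta$resources, stringsAsFactors = FALSE)
  new_scheme(meta$type, resources, environments, members, concentrations,
             edges, meta$total_carbon)
}
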