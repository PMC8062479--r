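#' Construct a plate-reader yield table
#'
#' Long-format container for endpoint OD readings: one row per (environment,
#' replicate), plus the per-plate blank reading (uninoculated medium), the
#' corrected negative-control readings (inoculated, no carbon) used for the
#' growth significance test, and optional evaporation-control readings.
#'
#' @param data data.frame with columns `environment_id`, `replicate`,
#'   `od_raw`.
#' @param blank_od Single blank OD for the plate.
#' @param negative_controls Raw OD readings of inoculated no-carbon wells.
#' @param evap_control_od Optional evaporation-control readings; their mean is
#'   subtracted during correction.
#' @return An object of class `plate_table`.
#' @export
plate_table <- function(data, blank_od, negative_controls = numeric(0),
                        evap_control_od = NULL) {
  stopifnot(is.data.frame(data),
            all(c("environment_id", "replicate", "od_raw") %in% names(data)))
  if (!all(is.finite(data$od_raw))) stop("od_raw must be finite")
  if (!is.numeric(blank_od) || length(blank_od) != 1 || !is.finite(blank_od))
    stop("blank_od must be a single finite value")
  structure(list(data = data, blank_od = blank_od,
                 negative_controls = as.numeric(negative_controls),
                 evap_control_od = if (is.null(evap_control_od)) NULL
                                   else as.numeric(evap_control_od)),
            class = "plate_table")
}

#' @export
print.plate_table <- function(x, ...) {
  cat(sprintf("Plate table: %d readings over %d environments (blank OD %.3f, %d negative controls)\n",
              nrow(x$data), length(unique(x$data$environment_id)),
              x$blank_od, length(x$negative_controls)))
  invisible(x)
}

# reserved environment ids used in the on-disk dialect
.PLATE_BLANK <- "__blank__"
.PLATE_NEGCTRL <- "__negctrl__"
.PLATE_EVAP <- "__evap__"

#' Write / read the plate-table dialect
#'
#' Long-format delimited text with header `environment_id, replicate, value`;
#' control wells are stored under the reserved ids `__blank__`, `__negctrl__`
#' and `__evap__`. Comma- or tab-delimited, autodetected on read from the
#' header line. Round-trips exactly.
#'
#' @param plate A `plate_table`.
#' @param path Output file.
#' @param sep Field separator, `"\t"` or `","`.
#' @return The path, invisibly.
#' @export
write_plate_table <- function(plate, path, sep = "\t") {
  stopifnot(inherits(plate, "plate_table"))
  ctrl <- function(id, v) if (length(v) == 0) NULL else
    data.frame(environment_id = id, replicate = seq_along(v),
               value = sprintf("%.17g", v), stringsAsFactors = FALSE)
  rows <- rbind(
    data.frame(environment_id = plate$data$environment_id,
               replicate = plate$data$replicate,
               value = sprintf("%.17g", plate$data$od_raw),
               stringsAsFactors = FALSE),
    ctrl(.PLATE_BLANK, plate$blank_od),
    ctrl(.PLATE_NEGCTRL, plate$negative_controls),
    ctrl(.PLATE_EVAP, plate$evap_control_od))
  utils::write.table(rows, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1)
  if (grepl("\t", header)) "\t" else ","
}

#' @rdname write_plate_table
#' @export
read_plate_table <- function(path) {
  sep <- sniff_sep(path)
  rows <- utils::read.table(path, sep = sep, header = TRUE,
                            colClasses = c("character", "integer", "character"),
                            stringsAsFactors = FALSE)
  rows$value <- as.numeric(rows$value)
  is_ctrl <- rows$environment_id %in% c(.PLATE_BLANK, .PLATE_NEGCTRL, .PLATE_EVAP)
  evap <- rows$value[rows$environment_id == .PLATE_EVAP]
  plate_table(
    data = data.frame(environment_id = rows$environment_id[!is_ctrl],
                      replicate = rows$replicate[!is_ctrl],
                      od_raw = rows$value[!is_ctrl], stringsAsFactors = FALSE),
    blank_od = rows$value[rows$environment_id == .PLATE_BLANK][1],
    negative_controls = rows$value[rows$environment_id == .PLATE_NEGCTRL],
    evap_control_od = if (length(evap) == 0) NULL else evap)
}

#' MAD-based outlier filter for replicate measurements
#'
#' Computes a modified Z-score for each measurement,
#' \eqn{M_i = 0.6745 (x_i - \tilde x) / \mathrm{median}(|x_i - \tilde x|)},
#' where \eqn{\tilde x} is the replicate median, and removes measurements with
#' \eqn{|M_i|} above the cutoff. When the median absolute deviation is zero
#' the score is undefined and nothing is removed.
#'
#' @param x Numeric vector of replicate measurements (length >= 2).
#' @param cutoff Removal threshold on \eqn{|M_i|} (default 3.5).
#' @return A list: `kept` (values), `kept_idx`, `removed_idx`, `z` (scores;
#'   NA when MAD is zero).
#' @export
mad_outlier_filter <- function(x, cutoff = 3.5) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least two measurements")
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  if (mad0 == 0) {
    return(list(kept = x, kept_idx = seq_along(x),
                removed_idx = integer(0), z = rep(NA_real_, length(x))))
  }
  z <- 0.6745 * (x - med) / mad0
  removed <- which(abs(z) > cutoff)
  kept <- setdiff(seq_along(x), removed)
  list(kept = x[kept], kept_idx = kept, removed_idx = removed, z = z)
}

#' Blank correction, outlier removal and growth calls for a plate
#'
#' Per environment: subtracts the plate blank (and the mean evaporation
#' control when present) from the raw readings, removes replicate outliers
#' with [mad_outlier_filter()], then tests for growth above the negative
#' controls with a one-tailed two-sample t-test. The growth flag is TRUE only
#' when the test is significant at `alpha` *and* the mean corrected OD
#' reaches `growth_threshold`.
#'
#' @param plate A `plate_table`.
#' @param growth_threshold Minimum mean corrected OD for a growth call
#'   (default 0.05).
#' @param alpha Significance level of the one-tailed test (default 0.05).
#' @param mad_cutoff Passed to [mad_outlier_filter()].
#' @return data.frame with one row per environment: `environment_id`,
#'   `yield`, `yield_sd`, `n_used`, `n_removed`, `p_growth`, `growth_flag`,
#'   `usable`.
#' @export
correct_and_call_growth <- function(plate, growth_threshold = 0.05,
                                    alpha = 0.05, mad_cutoff = 3.5) {
  stopifnot(inherits(plate, "plate_table"))
  evap <- if (is.null(plate$evap_control_od)) 0 else mean(plate$evap_control_od)
  ctrl <- plate$negative_controls - plate$blank_od - evap
  envs <- unique(plate$data$environment_id)
  out <- vector("list", length(envs))
  for (j in seq_along(envs)) {
    raw <- plate$data$od_raw[plate$data$environment_id == envs[j]]
    corrected <- raw - plate$blank_od - evap
    filt <- if (length(corrected) >= 2) mad_outlier_filter(corrected, mad_cutoff)
            else list(kept = corrected, removed_idx = integer(0))
    kept <- filt$kept
    usable <- length(kept) > 0
    ymean <- if (usable) mean(kept) else NA_real_
    ysd <- if (length(kept) > 1) stats::sd(kept) else NA_real_
    p <- NA_real_
    if (usable) {
      if (length(ctrl) >= 2 && length(kept) >= 2 &&
          (stats::sd(kept) > 0 || stats::sd(ctrl) > 0)) {
        p <- stats::t.test(kept, ctrl, alternative = "greater")$p.value
      } else if (length(kept) >= 2 && stats::sd(kept) > 0) {
        mu0 <- if (length(ctrl) > 0) mean(ctrl) else 0
        p <- stats::t.test(kept, mu = mu0, alternative = "greater")$p.value
      } else {
        # degenerate: no variance anywhere; call on the means alone
        mu0 <- if (length(ctrl) > 0) mean(ctrl) else 0
        p <- if (ymean > mu0) 0 else 1
      }
    }
    grows <- usable && !is.na(p) && p < alpha && ymean >= growth_threshold
    out[[j]] <- data.frame(environment_id = envs[j], yield = ymean,
                           yield_sd = ysd, n_used = length(kept),
                           n_removed = length(filt$removed_idx),
                           p_growth = p, growth_flag = grows,
                           usable = usable, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Construct a taxon relative-abundance table
#'
#' Taxa-by-samples matrix of relative abundances with per-sample metadata.
#' Reads assigned to no genus ("Unassigned") are removed and tracked as a
#' per-sample fraction, and columns are renormalized to sum to 1.
#'
#' @param abund Numeric matrix, taxa in rows (rownames required), samples in
#'   columns (colnames required); columns are normalized to sum 1.
#' @param meta data.frame with columns `sample_id`, `environment_id`,
#'   `replicate`, one row per column of `abund`.
#' @param unassigned_label Taxon row treated as unassigned reads.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(abund, meta, unassigned_label = "Unassigned") {
  stopifnot(is.matrix(abund), !is.null(rownames(abund)),
            !is.null(colnames(abund)))
  stopifnot(all(c("sample_id", "environment_id", "replicate") %in% names(meta)),
            nrow(meta) == ncol(abund),
            all(meta$sample_id == colnames(abund)))
  if (any(abund < 0)) stop("abundances must be nonnegative")
  unassigned <- rep(0, ncol(abund))
  if (unassigned_label %in% rownames(abund)) {
    tot <- colSums(abund)
    unassigned <- ifelse(tot > 0, abund[unassigned_label, ] / tot, 0)
    abund <- abund[setdiff(rownames(abund), unassigned_label), , drop = FALSE]
  }
  cs <- colSums(abund)
  if (any(cs == 0)) stop("samples with zero total abundance: ",
                         paste(colnames(abund)[cs == 0], collapse = ", "))
  abund <- sweep(abund, 2, cs, "/")
  structure(list(abund = abund, meta = meta, unassigned = unassigned),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("Abundance table: %d taxa x %d samples (%d environments)\n",
              nrow(x$abund), ncol(x$abund),
              length(unique(x$meta$environment_id))))
  invisible(x)
}

#' Write / read the abundance-table dialect
#'
#' Wide delimited text: a leading `taxon` column then one column per sample,
#' named `<environment_id>|r<replicate>`. Separator autodetected on read.
#'
#' @param table An `abundance_table`.
#' @param path Output file.
#' @param sep Field separator.
#' @return The path, invisibly.
#' @export
write_abundance_table <- function(table, path, sep = "\t") {
  stopifnot(inherits(table, "abundance_table"))
  cols <- sprintf("%s|r%s", table$meta$environment_id, table$meta$replicate)
  m <- table$abund
  df <- data.frame(taxon = rownames(m),
                   matrix(sprintf("%.17g", m), nrow = nrow(m)),
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("taxon", cols)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_table
#' @export
read_abundance_table <- function(path) {
  sep <- sniff_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  taxa <- df$taxon
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- taxa
  parts <- strsplit(colnames(m), "|", fixed = TRUE)
  meta <- data.frame(
    sample_id = colnames(m),
    environment_id = vapply(parts, `[`, character(1), 1),
    replicate = as.integer(sub("^r", "", vapply(parts, `[`, character(1), 2))),
    stringsAsFactors = FALSE)
  abundance_table(m, meta)
}

#' Average replicate compositions per environment
#'
#' Arithmetic mean of the relative-abundance columns belonging to each
#' environment, renormalized to sum 1.
#'
#' @param table An `abundance_table`.
#' @return Numeric matrix, taxa x environments.
#' @export
average_replicates <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  envs <- unique(table$meta$environment_id)
  out <- sapply(envs, function(e) {
    cols <- table$meta$sample_id[table$meta$environment_id == e]
    v <- rowMeans(table$abund[, cols, drop = FALSE])
    v / sum(v)
  })
  out <- matrix(out, nrow = nrow(table$abund),
                dimnames = list(rownames(table$abund), envs))
  out
}

#' Survivor sets from averaged compositions
#'
#' @param composition Taxa x environments matrix of relative abundances (for
#'   example from [average_replicates()]).
#' @param threshold Presence threshold on relative abundance (default 1e-3).
#' @return Named list mapping environment id to a character vector of taxa.
#' @export
survivor_sets <- function(composition, threshold = 1e-3) {
  lapply(stats::setNames(colnames(composition), colnames(composition)),
         function(e) rownames(composition)[composition[, e] >= threshold])
}

#' UPGMA clustering of environments by community composition
#'
#' Computes Spearman correlations between per-environment composition
#' vectors, then agglomerates with UPGMA (average linkage) on Euclidean
#' distances between the correlation-matrix rows. Environments with constant
#' composition vectors (undefined correlations) are dropped with a warning.
#' Input columns are sorted by environment id first, so the result is
#' invariant to input ordering.
#'
#' @param composition Taxa x environments matrix of relative abundances.
#' @return A list: `hclust` (the tree), `order` (leaf ids in dendrogram
#'   order), `cor` (the Spearman matrix), `dropped` (ids removed).
#' @export
cluster_environments <- function(composition) {
  stopifnot(is.matrix(composition), !is.null(colnames(composition)))
  composition <- composition[, order(colnames(composition)), drop = FALSE]
  cst <- apply(composition, 2, function(v) stats::sd(v) == 0)
  dropped <- colnames(composition)[cst]
  if (length(dropped) > 0) {
    warning("dropping constant composition vectors: ",
            paste(dropped, collapse = ", "))
    composition <- composition[, !cst, drop = FALSE]
  }
  if (ncol(composition) < 3) stop("need at least three non-degenerate environments")
  rho <- stats::cor(composition, method = "spearman")
  hc <- stats::hclust(stats::dist(rho, method = "euclidean"),
                      method = "average")
  list(hclust = hc, order = hc$labels[hc$order], cor = rho, dropped = dropped)
}

#' Export a dendrogram in Newick format
#'
#' @param clustering Result of [cluster_environments()] (or any `hclust`).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  hc <- if (inherits(clustering, "hclust")) clustering else clustering$hclust
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Convert between OD and CFU/mL
#'
#' Linear conversion at 8e8 CFU/mL per OD unit (an endpoint community of
#' 2.4e8 CFU/mL reads OD 0.3).
#'
#' @param value Nonnegative OD or CFU/mL value(s).
#' @param direction `"od_to_cfu"` or `"cfu_to_od"`.
#' @return Converted value(s).
#' @export
cfu_od_convert <- function(value, direction = c("od_to_cfu", "cfu_to_od")) {
  direction <- match.arg(direction)
  if (any(value < 0)) stop("value must be >= 0")
  k <- 8e8
  if (direction == "od_to_cfu") value * k else value / k
}
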