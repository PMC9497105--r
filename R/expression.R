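#' Median-of-ratios size factors
#'
#' The standard count-normalization estimator: for each sample, the median
#' over genes (restricted to genes with positive counts in every sample)
#' of the ratio of its count to the gene's geometric mean across samples,
#' computed on the log scale. Normalized counts are counts divided by the
#' size factor.
#'
#' @param counts A nonnegative genes x samples matrix with dimnames.
#' @return A named positive numeric vector, one size factor per sample.
#' @export
size_factors <- function(counts) {
  validate_counts(counts)
  if (ncol(counts) < 2) {
    rlang::abort("Need at least 2 samples.",
                 class = "nociphys_invalid_parameter")
  }
  if (nrow(counts) < 2) {
    rlang::warn("Fewer than 2 genes: size-factor estimation is degenerate.")
  }
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) {
    rlang::abort(
      "No gene has positive counts in all samples; cannot estimate size factors.",
      class = "nociphys_estimation_error")
  }
  apply(counts, 2, function(x) {
    exp(stats::median(log(x[use]) - log_geo[use]))
  })
}

#' @rdname size_factors
#' @param sf Size factors; estimated from `counts` when omitted.
#' @return For `normalize_counts()`: the matrix of normalized counts.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  sweep(counts, 2, sf, "/")
}

#' Marker-relative expression per condition
#'
#' Each gene's normalized count is divided by a pan-population marker's
#' (e.g. the pan-sensory marker ISL1) normalized count in the same sample,
#' then averaged over the replicates of each condition. Because the marker
#' ratio is formed within a sample, the result is invariant to any
#' per-sample rescaling; normalization upstream is belt-and-braces.
#'
#' @param norm A genes x samples matrix of normalized counts.
#' @param marker Gene identifier of the reference marker; must have
#'   positive values in every sample.
#' @param replicate_groups Named character vector mapping sample id to
#'   condition label (or a data frame with columns `sample`, `condition`).
#' @return A tibble: `gene` plus one column per condition (in order of
#'   first appearance).
#' @export
marker_relative <- function(norm, marker, replicate_groups) {
  if (is.data.frame(replicate_groups)) {
    replicate_groups <- stats::setNames(replicate_groups$condition,
                                        replicate_groups$sample)
  }
  missing <- setdiff(colnames(norm), names(replicate_groups))
  if (length(missing) > 0) {
    rlang::abort(paste0("No condition assigned to sample(s): ",
                        paste(missing, collapse = ", ")),
                 class = "nociphys_format_error")
  }
  if (!marker %in% rownames(norm)) {
    rlang::abort(sprintf("Marker '%s' not found.", marker),
                 class = "nociphys_format_error")
  }
  mk <- norm[marker, ]
  if (any(mk <= 0)) {
    bad <- colnames(norm)[mk <= 0][[1]]
    rlang::abort(
      sprintf("Marker '%s' has no counts in sample '%s'.", marker, bad),
      class = "nociphys_estimation_error")
  }
  ratios <- sweep(norm, 2, mk, "/")
  conds <- unname(replicate_groups[colnames(norm)])
  cond_levels <- unique(conds)
  avg <- vapply(cond_levels, function(cn) {
    rowMeans(ratios[, conds == cn, drop = FALSE])
  }, numeric(nrow(norm)))
  out <- tibble::as_tibble(avg, .name_repair = "minimal")
  names(out) <- cond_levels
  dplyr::bind_cols(tibble::tibble(gene = rownames(norm)), out)
}

#' Center and scale gene rows for heatmap display
#'
#' Per gene: subtract the row mean and divide by the row standard
#' deviation across conditions (population SD, i.e. denominator `n`).
#' Constant rows become all zeros and are flagged in the `constant`
#' column.
#'
#' @param table A tibble as returned by [marker_relative()] (`gene` column
#'   plus numeric condition columns), or a numeric matrix with gene
#'   rownames.
#' @return A tibble of the same shape with an added logical `constant`
#'   column; every non-constant row has mean 0 and SD 1.
#' @export
center_scale <- function(table) {
  if (is.matrix(table)) {
    table <- dplyr::bind_cols(tibble::tibble(gene = rownames(table)),
                              tibble::as_tibble(table))
  }
  value_cols <- setdiff(names(table), "gene")
  if (length(value_cols) < 2) {
    rlang::abort("Need at least 2 conditions to center-scale.",
                 class = "nociphys_invalid_parameter")
  }
  m <- as.matrix(table[, value_cols])
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  constant <- sd_pop == 0
  scaled <- (m - mu) / ifelse(constant, 1, sd_pop)
  scaled[constant, ] <- 0
  out <- dplyr::bind_cols(tibble::tibble(gene = table$gene),
                          tibble::as_tibble(scaled, .name_repair = "minimal"))
  out$constant <- constant
  out
}
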