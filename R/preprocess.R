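#' Construct a genus-by-sample count table
#'
#' Light container for integer 16S count data: genera as rows, samples as
#' columns, optional sample-to-group assignment. IDs must be unique and
#' counts must be non-negative integers.
#'
#' @param counts Numeric matrix of non-negative integers with genus row
#'   names and sample column names.
#' @param group_of Optional character vector of group labels, named by
#'   sample ID (or in column order).
#' @return A `count_table` object.
#' @export
count_table <- function(counts, group_of = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' needs genus row names and sample column names")
  if (anyDuplicated(rownames(counts))) stop("duplicate genus IDs")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample IDs")
  if (any(is.na(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8))
    stop("'counts' must be non-negative integers")
  storage.mode(counts) <- "integer"
  if (!is.null(group_of)) {
    if (is.null(names(group_of))) names(group_of) <- colnames(counts)
    if (!all(colnames(counts) %in% names(group_of)))
      stop("'group_of' must cover every sample")
    group_of <- group_of[colnames(counts)]
  }
  structure(list(counts = counts, group_of = group_of),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d genera x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$group_of)) {
    tab <- table(x$group_of)
    cat("groups:", paste(sprintf("%s (n=%d)", names(tab), tab),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Coerce a synthetic dataset to a count table
#' @param ds A `synthetic_dataset`.
#' @return A [count_table()].
#' @export
as_count_table <- function(ds) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  count_table(ds$counts, ds$group_of)
}

#' Filtering thresholds for taxa and samples
#'
#' Defaults keep genera whose mean per-sample relative abundance is at
#' least 0.001% and that are observed in at least 1% of samples, and keep
#' samples with at least 10,000 reads. `abundance_rule = "literal"`
#' switches the abundance criterion to mean raw reads per genus relative to
#' the grand total of reads.
#'
#' @param min_mean_rel_abundance Minimum mean per-sample relative abundance
#'   (default 1e-5, i.e. 0.001%).
#' @param min_prevalence Minimum fraction of samples with a non-zero count
#'   (default 0.01).
#' @param min_sample_depth Minimum per-sample read total (default 10,000).
#' @param abundance_rule `"relative"` (scale-free, default) or `"literal"`.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_mean_rel_abundance = 1e-5,
                          min_prevalence = 0.01,
                          min_sample_depth = 10000,
                          abundance_rule = c("relative", "literal")) {
  stopifnot(min_mean_rel_abundance >= 0, min_prevalence >= 0,
            min_prevalence <= 1, min_sample_depth >= 0)
  structure(list(min_mean_rel_abundance = min_mean_rel_abundance,
                 min_prevalence = min_prevalence,
                 min_sample_depth = as.integer(min_sample_depth),
                 abundance_rule = match.arg(abundance_rule)),
            class = "filter_config")
}

#' Filter samples and genera of a count table
#'
#' Samples with fewer than `min_sample_depth` total reads are removed
#' first; then a genus is kept only if its mean per-sample relative
#' abundance (over the retained samples) reaches
#' `min_mean_rel_abundance` *and* it is observed (count > 0) in at least a
#' `min_prevalence` fraction of the retained samples. Filters are applied
#' in a single pass, not iterated.
#'
#' @param table A [count_table()].
#' @param config A [filter_config()].
#' @return List with the filtered `table` and a `report` recording the
#'   number of samples/genera before and after each rule, in order.
#' @export
filter_counts <- function(table, config = filter_config()) {
  stopifnot(inherits(table, "count_table"))
  cts <- table$counts
  if (nrow(cts) == 0 || ncol(cts) == 0) stop("empty count table")
  depth <- colSums(cts)
  keep_s <- depth >= config$min_sample_depth
  if (!any(keep_s)) stop("all samples removed by the depth filter")
  cts2 <- cts[, keep_s, drop = FALSE]
  depth2 <- depth[keep_s]

  if (config$abundance_rule == "relative") {
    rel <- sweep(cts2, 2, depth2, "/")
    mean_rel <- rowMeans(rel)
    pass_ab <- mean_rel >= config$min_mean_rel_abundance
  } else {
    pass_ab <- rowMeans(cts2) >= config$min_mean_rel_abundance * sum(cts2)
  }
  prevalence <- rowMeans(cts2 > 0)
  pass_prev <- prevalence >= config$min_prevalence
  keep_g <- pass_ab & pass_prev
  if (!any(keep_g)) stop("all genera removed by the abundance/prevalence filters")

  out <- count_table(cts2[keep_g, , drop = FALSE],
                     if (is.null(table$group_of)) NULL else
                       table$group_of[keep_s])
  report <- list(
    samples_before = ncol(cts),
    samples_after_depth = ncol(cts2),
    genera_before = nrow(cts),
    genera_failing_abundance = sum(!pass_ab),
    genera_failing_prevalence = sum(!pass_prev),
    genera_after = sum(keep_g),
    config = unclass(config))
  list(table = out, report = report)
}

#' Bayesian-multiplicative zero replacement
#'
#' Converts integer counts to strictly positive compositions. Per sample,
#' zero counts are imputed by the Dirichlet-posterior expectation under a
#' uniform prior over genera with total prior strength `s(n)` (default the
#' square root of the sample's read depth, a weak data-driven prior):
#' an unobserved genus receives `s/(D*(n+s))` of the composition. Non-zero
#' parts are multiplicatively rescaled so each column still sums to one.
#'
#' @param table A [count_table()] (usually filtered).
#' @param prior_strength Function of the read depth giving the total
#'   Dirichlet prior strength; default `sqrt`.
#' @return A strictly positive genus-by-sample matrix of class
#'   `composition` whose columns sum to 1.
#' @export
zero_replace <- function(table, prior_strength = sqrt) {
  stopifnot(inherits(table, "count_table"))
  cts <- table$counts
  depth <- colSums(cts)
  if (any(depth == 0)) stop("sample with all-zero counts cannot form a composition")
  D <- nrow(cts)
  comp <- matrix(0, D, ncol(cts), dimnames = dimnames(cts))
  for (s in seq_len(ncol(cts))) {
    x <- cts[, s]
    n <- depth[s]
    str <- prior_strength(n)
    zero <- x == 0
    imputed <- str / (D * (n + str))
    p <- numeric(D)
    p[zero] <- imputed
    p[!zero] <- (x[!zero] / n) * (1 - imputed * sum(zero))
    comp[, s] <- p
  }
  stopifnot(all(comp > 0), all(abs(colSums(comp) - 1) < 1e-9))
  structure(comp, class = c("composition", "matrix", "array"))
}

#' Centered log-ratio transformation
#'
#' Per sample, the log of each fraction minus the mean of the logs, so that
#' every column of the result sums to zero.
#'
#' @param comp Strictly positive genus-by-sample matrix (e.g. from
#'   [zero_replace()]).
#' @return Genus-by-sample real matrix with zero column sums.
#' @export
clr_transform <- function(comp) {
  comp <- unclass(comp)
  if (any(comp <= 0)) stop("CLR requires strictly positive entries")
  lg <- log(comp)
  out <- sweep(lg, 2, colMeans(lg), "-")
  stopifnot(all(abs(colSums(out)) < 1e-9))
  out
}

#' Per-sample alpha diversity (Shannon and Chao1)
#'
#' Shannon entropy (natural log) is computed on per-sample relative
#' abundances; Chao1 richness uses the bias-corrected estimator
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, where `F1` and `F2` count
#' singleton and doubleton genera, which remains defined when there are no
#' doubletons. The classic `S_obs + F1^2 / (2 F2)` form is available via
#' `chao1 = "classic"`.
#'
#' @param table A [count_table()].
#' @param chao1 `"bias_corrected"` (default) or `"classic"`.
#' @return Data frame with `sample_id`, `richness`, `shannon`, `chao1`.
#' @export
alpha_diversity <- function(table, chao1 = c("bias_corrected", "classic")) {
  stopifnot(inherits(table, "count_table"))
  chao1 <- match.arg(chao1)
  cts <- table$counts
  if (any(colSums(cts) == 0)) stop("zero-depth sample")
  shannon <- vegan::diversity(t(cts), index = "shannon")
  s_obs <- colSums(cts > 0)
  f1 <- colSums(cts == 1)
  f2 <- colSums(cts == 2)
  ch <- if (chao1 == "bias_corrected") {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    ifelse(f2 > 0, s_obs + f1^2 / (2 * f2),
           s_obs + f1 * (f1 - 1) / 2)
  }
  data.frame(sample_id = colnames(cts), richness = as.integer(s_obs),
             shannon = unname(shannon), chao1 = unname(ch),
             row.names = NULL)
}

#' Compare alpha diversity between two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per diversity index.
#' The exact null distribution is used for small samples without ties,
#' otherwise the tie-corrected normal approximation.
#'
#' @param div Output of [alpha_diversity()].
#' @param groups Character vector of group labels named by (or ordered as)
#'   `div$sample_id`; exactly two groups, each with at least two samples.
#' @param indices Diversity columns to compare.
#' @return Data frame with `index`, `statistic` (Mann-Whitney U of the
#'   first group) and two-sided `p_value`.
#' @export
compare_diversity <- function(div, groups,
                              indices = c("shannon", "chao1")) {
  if (!is.null(names(groups))) groups <- groups[div$sample_id]
  groups <- as.character(groups)
  lev <- unique(groups[!is.na(groups)])
  if (length(lev) != 2) stop("exactly two groups are required")
  n1 <- sum(groups == lev[1]); n2 <- sum(groups == lev[2])
  if (n1 < 2 || n2 < 2) stop("each group needs at least two samples")
  res <- lapply(indices, function(ix) {
    x <- div[[ix]][groups == lev[1]]
    y <- div[[ix]][groups == lev[2]]
    if (length(unique(c(x, y))) == 1) {
      # completely tied data: no evidence against the null
      return(data.frame(index = ix, statistic = length(x) * length(y) / 2,
                        p_value = 1))
    }
    wt <- suppressWarnings(wilcox.test(x, y))
    data.frame(index = ix, statistic = unname(wt$statistic),
               p_value = wt$p.value)
  })
  do.call(rbind, res)
}
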