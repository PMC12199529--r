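#' Specify a latent basis-correlation network for synthetic count data
#'
#' Defines the ground-truth correlation structure from which synthetic
#' genus-level count tables are simulated: a modular random graph with
#' optional designated hub genera that receive additional edges, signed
#' correlation magnitudes, and a seed. The default dimension of 87 genera
#' mirrors the scale of a genus-level 16S table after typical
#' abundance/prevalence filtering.
#'
#' @param n_genera Number of genera (nodes of the latent network).
#' @param n_modules Number of modules; genera are assigned to contiguous
#'   blocks of (near-)equal size.
#' @param p_within Edge probability for pairs in the same module.
#' @param p_between Edge probability for pairs in different modules; must
#'   not exceed `p_within`.
#' @param hub_ids Integer indices of genera designated as hubs.
#' @param hub_extra_degree Number of additional edges attached to each hub
#'   (drawn uniformly among its non-neighbors).
#' @param corr_magnitude_range Length-2 numeric in (0, 1): range from which
#'   absolute planted correlations are drawn uniformly.
#' @param negative_edge_fraction Fraction of planted edges whose sign is
#'   flipped to negative.
#' @param seed Integer seed controlling the edge draw.
#'
#' @return An object of class `basis_network_spec`.
#' @seealso [generate_basis_correlation()]
#' @export
basis_network_spec <- function(n_genera = 87,
                               n_modules = 5,
                               p_within = 0.2,
                               p_between = 0.01,
                               hub_ids = integer(0),
                               hub_extra_degree = 0L,
                               corr_magnitude_range = c(0.4, 0.7),
                               negative_edge_fraction = 0.2,
                               seed = 1L) {
  stopifnot(length(n_genera) == 1, n_genera >= 2,
            length(n_modules) == 1, n_modules >= 1,
            length(corr_magnitude_range) == 2)
  if (p_within < 0 || p_within > 1 || p_between < 0 || p_between > 1)
    stop("edge probabilities must lie in [0, 1]")
  if (p_within < p_between)
    stop("'p_within' must be >= 'p_between'")
  if (corr_magnitude_range[1] <= 0 || corr_magnitude_range[2] >= 1 ||
      corr_magnitude_range[1] > corr_magnitude_range[2])
    stop("'corr_magnitude_range' must be an increasing pair inside (0, 1)")
  if (negative_edge_fraction < 0 || negative_edge_fraction > 1)
    stop("'negative_edge_fraction' must lie in [0, 1]")
  hub_ids <- as.integer(hub_ids)
  if (length(hub_ids) && (any(hub_ids < 1) || any(hub_ids > n_genera)))
    stop("'hub_ids' must be genus indices in 1..n_genera")
  if (anyDuplicated(hub_ids)) stop("'hub_ids' must be unique")
  hub_extra_degree <- as.integer(hub_extra_degree)
  if (hub_extra_degree < 0) stop("'hub_extra_degree' must be non-negative")
  if (hub_extra_degree > n_genera - 1)
    stop("'hub_extra_degree' exceeds n_genera - 1; no node can have that many edges")
  structure(list(n_genera = as.integer(n_genera),
                 n_modules = as.integer(n_modules),
                 p_within = p_within,
                 p_between = p_between,
                 hub_ids = hub_ids,
                 hub_extra_degree = hub_extra_degree,
                 corr_magnitude_range = corr_magnitude_range,
                 negative_edge_fraction = negative_edge_fraction,
                 seed = as.integer(seed)),
            class = "basis_network_spec")
}

# Contiguous-block module assignment.
.module_assignment <- function(n, m) {
  rep(seq_len(m), each = ceiling(n / m))[seq_len(n)]
}

#' Generate a positive-definite basis correlation matrix with planted edges
#'
#' Draws the latent genus-genus correlation matrix described by a
#' [basis_network_spec()]: module edges with probability `p_within` /
#' `p_between`, extra edges attached to each hub, magnitudes uniform in
#' `corr_magnitude_range` with a fraction negated. If the raw matrix is not
#' positive definite it is repaired by flooring eigenvalues at `pd_floor`
#' and re-standardizing to unit diagonal; the set of true edges is then
#' recomputed from the repaired matrix at tolerance `edge_tol`, so the
#' reported ground truth always refers to the matrix actually used for
#' simulation.
#'
#' @param spec A [basis_network_spec()].
#' @param pd_floor Eigenvalue floor used in the positive-definite repair.
#' @param edge_tol Absolute correlation above which an entry of the
#'   (possibly repaired) matrix counts as a true edge.
#'
#' @return A `ground_truth` object: list with `basis_correlation`
#'   (n x n positive-definite correlation matrix), `module_of`, `true_hubs`,
#'   `true_edges` (data frame `i`, `j`, `rho` with `i < j`) and
#'   `planted_edges` (the pre-repair draw).
#' @export
generate_basis_correlation <- function(spec, pd_floor = 1e-6, edge_tol = 1e-3) {
  stopifnot(inherits(spec, "basis_network_spec"))
  n <- spec$n_genera
  set.seed(spec$seed)
  module_of <- .module_assignment(n, spec$n_modules)

  adj <- matrix(FALSE, n, n)
  pairs <- which(upper.tri(adj), arr.ind = TRUE)
  same <- module_of[pairs[, 1]] == module_of[pairs[, 2]]
  prob <- ifelse(same, spec$p_within, spec$p_between)
  on <- runif(nrow(pairs)) < prob
  adj[pairs[on, , drop = FALSE]] <- TRUE

  # attach extra edges to each hub among its current non-neighbors
  adj <- adj | t(adj)
  for (h in spec$hub_ids) {
    candidates <- setdiff(which(!adj[h, ]), h)
    extra <- min(spec$hub_extra_degree, length(candidates))
    if (extra > 0) {
      sel <- if (length(candidates) == 1) candidates else
        sample(candidates, extra)
      adj[h, sel] <- TRUE
      adj[sel, h] <- TRUE
    }
  }

  rho <- matrix(0, n, n)
  up <- which(upper.tri(adj) & adj)
  if (length(up)) {
    mag <- runif(length(up), spec$corr_magnitude_range[1],
                 spec$corr_magnitude_range[2])
    sign <- ifelse(runif(length(up)) < spec$negative_edge_fraction, -1, 1)
    rho[up] <- mag * sign
    rho <- rho + t(rho)
  }
  diag(rho) <- 1
  planted <- .edge_list(rho, tol = edge_tol)

  ev <- eigen(rho, symmetric = TRUE)
  if (min(ev$values) <= 0) {
    vals <- pmax(ev$values, pd_floor)
    rho <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(rho))
    rho <- rho / outer(d, d)
    rho <- (rho + t(rho)) / 2
    diag(rho) <- 1
  }
  ids <- sprintf("g%03d", seq_len(n))
  dimnames(rho) <- list(ids, ids)

  structure(list(basis_correlation = rho,
                 module_of = setNames(module_of, ids),
                 true_hubs = ids[spec$hub_ids],
                 true_edges = .edge_list(rho, tol = edge_tol),
                 planted_edges = planted,
                 spec = spec),
            class = "ground_truth")
}

# Upper-triangle entries of a symmetric matrix above a tolerance.
.edge_list <- function(rho, tol) {
  up <- which(upper.tri(rho) & abs(rho) > tol, arr.ind = FALSE)
  idx <- arrayInd(up, dim(rho))
  data.frame(i = idx[, 1], j = idx[, 2], rho = rho[up])
}

#' Describe the read-depth distribution for synthetic samples
#'
#' By default read depths are log-normal around 30,000 and truncated below
#' at 10,000, mirroring a common per-sample quality floor for 16S data.
#'
#' @param type `"lognormal"` or `"constant"`.
#' @param meanlog,sdlog Parameters of the log-normal depth law.
#' @param floor Minimum admissible depth; log-normal draws below it are
#'   redrawn (truncation).
#' @param depth Fixed depth used when `type = "constant"`.
#' @return A `depth_law` list.
#' @export
depth_law <- function(type = c("lognormal", "constant"),
                      meanlog = log(30000), sdlog = 0.35,
                      floor = 10000, depth = 10000) {
  type <- match.arg(type)
  structure(list(type = type, meanlog = meanlog, sdlog = sdlog,
                 floor = as.integer(floor), depth = as.integer(depth)),
            class = "depth_law")
}

.draw_depths <- function(law, n) {
  if (law$type == "constant") return(rep(law$depth, n))
  out <- integer(n)
  need <- seq_len(n)
  # rejection sampling below the floor (truncated log-normal)
  while (length(need)) {
    d <- as.integer(round(rlnorm(length(need), law$meanlog, law$sdlog)))
    ok <- d >= law$floor
    out[need[ok]] <- d[ok]
    need <- need[!ok]
  }
  out
}

#' Simulate genus-level counts from a latent correlation structure
#'
#' Logistic-normal-multinomial sampler: per sample a latent Gaussian vector
#' with covariance `diag(sd_log) %*% R %*% diag(sd_log)` (R the basis
#' correlation) is drawn, shifted by `mean_log_abundance`, exponentiated,
#' closed to a composition, and integer counts are obtained from a
#' multinomial draw at the sample's read depth. Zeros therefore arise only
#' through the multinomial sampling.
#'
#' @param truth A `ground_truth` object from [generate_basis_correlation()].
#' @param n_samples Number of samples (>= 2).
#' @param mean_log_abundance Per-genus mean of the latent log-abundance;
#'   recycled if length 1.
#' @param sd_log Per-genus latent log-scale standard deviation; recycled.
#' @param depths A [depth_law()] describing per-sample read depths.
#' @param seed Integer seed.
#' @param group Group label attached to every sample.
#'
#' @return A `synthetic_dataset`: list with integer `counts`
#'   (genus x sample), `group_of`, `read_depths`, `truth_per_group`, `seed`.
#' @export
sample_counts <- function(truth, n_samples,
                          mean_log_abundance = 0,
                          sd_log = 1,
                          depths = depth_law(),
                          seed = 1L,
                          group = "groupA") {
  stopifnot(inherits(truth, "ground_truth"), n_samples >= 2)
  R <- truth$basis_correlation
  n <- nrow(R)
  mu <- rep_len(mean_log_abundance, n)
  sds <- rep_len(sd_log, n)
  if (any(sds <= 0)) stop("'sd_log' must be positive")
  Sigma <- R * outer(sds, sds)
  L <- tryCatch(chol(Sigma), error = function(e)
    stop("latent covariance matrix is not positive definite", call. = FALSE))

  set.seed(seed)
  depth <- .draw_depths(depths, n_samples)
  Z <- matrix(rnorm(n_samples * n), n_samples, n) %*% L
  logabun <- sweep(Z, 2, mu, "+")
  abun <- exp(logabun)
  comp <- abun / rowSums(abun)
  counts <- vapply(seq_len(n_samples),
                   function(s) rmultinom(1, depth[s], comp[s, ])[, 1],
                   integer(n))
  rownames(counts) <- rownames(R)
  colnames(counts) <- sprintf("%s_s%04d", group, seq_len(n_samples))
  group_of <- setNames(rep(group, n_samples), colnames(counts))
  truths <- list(truth); names(truths) <- group
  structure(list(counts = counts, group_of = group_of,
                 read_depths = setNames(depth, colnames(counts)),
                 truth_per_group = truths, seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' Simulate a two-group case/control dataset
#'
#' Generates one latent network per group from the two specs (which must
#' agree on `n_genera`), simulates counts for each group, and concatenates
#' them with group labels. The per-group ground truths are retained so that
#' downstream network inference can be checked against the planted
#' structure.
#'
#' @param spec_a,spec_b [basis_network_spec()] objects for the two groups.
#' @param n_a,n_b Samples per group (each >= 2).
#' @param seed Integer seed; per-group seeds are derived from it.
#' @param groups Length-2 character vector of group labels.
#' @param mean_log_abundance,sd_log,depths Passed to [sample_counts()].
#' @return A `synthetic_dataset` with both groups.
#' @export
generate_case_control <- function(spec_a, spec_b, n_a, n_b, seed = 1L,
                                  groups = c("control", "case"),
                                  mean_log_abundance = 0, sd_log = 1,
                                  depths = depth_law()) {
  stopifnot(inherits(spec_a, "basis_network_spec"),
            inherits(spec_b, "basis_network_spec"))
  if (spec_a$n_genera != spec_b$n_genera)
    stop("both specs must share 'n_genera'")
  if (n_a < 2 || n_b < 2) stop("each group needs at least 2 samples")
  truth_a <- generate_basis_correlation(spec_a)
  truth_b <- generate_basis_correlation(spec_b)
  ds_a <- sample_counts(truth_a, n_a, mean_log_abundance, sd_log, depths,
                        seed = .sub_seed(seed, 1), group = groups[1])
  ds_b <- sample_counts(truth_b, n_b, mean_log_abundance, sd_log, depths,
                        seed = .sub_seed(seed, 2), group = groups[2])
  truths <- c(ds_a$truth_per_group, ds_b$truth_per_group)
  structure(list(counts = cbind(ds_a$counts, ds_b$counts),
                 group_of = c(ds_a$group_of, ds_b$group_of),
                 read_depths = c(ds_a$read_depths, ds_b$read_depths),
                 truth_per_group = truths, seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits the count table TSV (genera as rows), the sample metadata TSV
#' (`sample_id`, `group`), one ground-truth edge list TSV per group
#' (`genus_i`, `genus_j`, `rho`), and a JSON sidecar recording the
#' generating specs and seed.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  f <- file.path(dir, "counts.tsv")
  write_counts(count_table(ds$counts, ds$group_of), f)
  files <- c(files, f)
  f <- file.path(dir, "metadata.tsv")
  write.table(data.frame(sample_id = names(ds$group_of),
                         group = unname(ds$group_of)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  for (g in names(ds$truth_per_group)) {
    tr <- ds$truth_per_group[[g]]
    ids <- rownames(tr$basis_correlation)
    ed <- tr$true_edges
    f <- file.path(dir, sprintf("true_edges_%s.tsv", g))
    write.table(data.frame(genus_i = ids[ed$i], genus_j = ids[ed$j],
                           rho = ed$rho),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, "spec.json")
  specs <- lapply(ds$truth_per_group, function(tr) unclass(tr$spec))
  jsonlite::write_json(list(seed = ds$seed, specs = specs), f,
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}
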