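#' Read a genus-by-sample count table from TSV
#'
#' Expects a header row of sample IDs and a first column of genus IDs.
#' Every cell must be a non-negative integer; violations are reported with
#' their row/column coordinates. CRLF line endings are tolerated.
#'
#' @param path Path to the TSV file.
#' @param metadata Optional path to a metadata TSV with columns
#'   `sample_id` and `group`.
#' @return A [count_table()].
#' @export
read_counts <- function(path, metadata = NULL) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character",
                    row.names = NULL)
  genus_ids <- raw[[1]]
  if (anyDuplicated(genus_ids))
    stop("duplicate genus IDs in ", path)
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(as.numeric(vals))
  bad <- is.na(num) | num < 0 | abs(num - round(num)) > 1e-9
  if (any(bad)) {
    at <- which(bad, arr.ind = FALSE)[1]
    rc <- arrayInd(at, dim(vals))
    stop(sprintf("non-integer count '%s' at genus '%s', sample '%s'",
                 vals[at], genus_ids[rc[1]], colnames(vals)[rc[2]]))
  }
  counts <- matrix(as.integer(num), nrow = nrow(vals),
                   dimnames = list(genus_ids, colnames(vals)))
  group_of <- if (!is.null(metadata)) read_metadata(metadata) else NULL
  count_table(counts, group_of)
}

#' Read sample metadata (sample_id, group) from TSV
#' @param path Path to the metadata TSV.
#' @return Named character vector of group labels.
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (!all(c("sample_id", "group") %in% colnames(md)))
    stop("metadata must have 'sample_id' and 'group' columns")
  if (anyDuplicated(md$sample_id)) stop("duplicate sample IDs in metadata")
  setNames(md$group, md$sample_id)
}

#' Write a count table to TSV
#' @param table A [count_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(genus = rownames(table$counts), table$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network to GraphML
#'
#' Node attribute `cluster` is attached when a cluster assignment is
#' given; edges carry `rho`, `weight` and `dissimilarity`.
#'
#' @param net Network from [build_network()].
#' @param path Output path.
#' @param clusters Optional [fast_greedy_clusters()] assignment.
#' @return Invisibly, `path`.
#' @export
write_network_graphml <- function(net, path, clusters = NULL) {
  if (!is.null(clusters))
    igraph::V(net)$cluster <- unname(clusters$membership[igraph::V(net)$name])
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Assemble a full pipeline configuration
#'
#' @param counts Path to a counts TSV, or a [count_table()] directly.
#' @param metadata Path to a metadata TSV (ignored when `counts` already
#'   carries groups).
#' @param out_dir Output directory for the report bundle.
#' @param filter A [filter_config()].
#' @param sparcc_exclusion_threshold,sparcc_max_iters SparCC settings.
#' @param sparsify `"lfdr"` or `"BH"`.
#' @param alpha Edge-significance level.
#' @param hub_quantile Quantile defining hubs.
#' @param core_detection,core_prevalence Conventional core thresholds.
#' @param graphlet_top_k Genera retained per orbit of interest.
#' @param graphlet_alpha Level for the GCM Fisher z-test.
#' @param permutation A [permutation_config()] or `NULL` to skip
#'   permutation testing.
#' @param local_tests If `TRUE` (and `permutation` is given), also run the
#'   per-genus centrality permutation test and write its TSV.
#' @param jaccard_n_perm Permutations for the hub Jaccard test.
#' @param seed Master seed recorded in every output.
#' @return A `run_config` list.
#' @export
run_config <- function(counts, metadata = NULL, out_dir,
                       filter = filter_config(),
                       sparcc_exclusion_threshold = 0.1,
                       sparcc_max_iters = 10,
                       sparsify = c("lfdr", "BH"),
                       alpha = 0.05,
                       hub_quantile = 0.90,
                       core_detection = 0.001,
                       core_prevalence = 0.5,
                       graphlet_top_k = 25,
                       graphlet_alpha = 0.05,
                       permutation = NULL,
                       local_tests = FALSE,
                       jaccard_n_perm = 1000,
                       seed = 1L) {
  if (is.character(counts) && !file.exists(counts))
    stop("counts file does not exist: ", counts)
  if (!is.null(metadata) && is.character(metadata) && !file.exists(metadata))
    stop("metadata file does not exist: ", metadata)
  structure(list(counts = counts, metadata = metadata, out_dir = out_dir,
                 filter = filter,
                 sparcc_exclusion_threshold = sparcc_exclusion_threshold,
                 sparcc_max_iters = as.integer(sparcc_max_iters),
                 sparsify = match.arg(sparsify), alpha = alpha,
                 hub_quantile = hub_quantile,
                 core_detection = core_detection,
                 core_prevalence = core_prevalence,
                 graphlet_top_k = as.integer(graphlet_top_k),
                 graphlet_alpha = graphlet_alpha,
                 permutation = permutation,
                 local_tests = isTRUE(local_tests),
                 jaccard_n_perm = as.integer(jaccard_n_perm),
                 seed = as.integer(seed)),
            class = "run_config")
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Per-group stage: preprocessing, SparCC, network, node and graphlet
# analyses; writes the group's artifacts and returns the objects needed
# for the cross-group comparison.
.run_group <- function(table, group, config, out_dir, log) {
  gdir <- file.path(out_dir, group)
  dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  log(sprintf("group %s: filtering %d genera x %d samples", group,
              nrow(table$counts), ncol(table$counts)))
  fl <- filter_counts(table, config$filter)
  tab <- fl$table
  files <- c(files, .write_tsv(
    data.frame(genus = rownames(tab$counts), tab$counts,
               check.names = FALSE),
    file.path(gdir, "counts_filtered.tsv")))
  jsonlite::write_json(fl$report, file.path(gdir, "filter_report.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(gdir, "filter_report.json"))

  comp <- zero_replace(tab)
  clr <- clr_transform(comp)
  files <- c(files, .write_tsv(
    data.frame(genus = rownames(clr), clr, check.names = FALSE),
    file.path(gdir, "clr.tsv")))
  div <- alpha_diversity(tab)
  files <- c(files, .write_tsv(div, file.path(gdir, "diversity.tsv")))

  log(sprintf("group %s: SparCC on %d genera, %d samples", group,
              nrow(comp), ncol(comp)))
  est <- sparcc(comp, config$sparcc_exclusion_threshold,
                config$sparcc_max_iters)
  test <- lfdr_adjust(edge_significance(est, alpha = config$alpha),
                      alpha = config$alpha, method = config$sparsify)
  files <- c(files, .write_tsv(
    data.frame(genus = rownames(est$rho), est$rho, check.names = FALSE),
    file.path(gdir, "sparcc_rho.tsv")))
  files <- c(files, .write_tsv(
    test[, c("genus_i", "genus_j", "rho", "t_stat", "p_value", "lfdr",
             "keep")],
    file.path(gdir, "edges.tsv")))

  net <- build_network(est, test, group_label = group)
  clusters <- fast_greedy_clusters(net)
  props <- global_properties(net, clusters)
  files <- c(files, write_network_graphml(net,
                                          file.path(gdir, "network.graphml"),
                                          clusters))
  jsonlite::write_json(unclass(props),
                       file.path(gdir, "global_properties.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(gdir, "global_properties.json"))

  centr <- centralities(net)
  files <- c(files, .write_tsv(
    data.frame(genus = rownames(centr), centr, check.names = FALSE),
    file.path(gdir, "centrality.tsv")))
  hub <- hubs(centr, config$hub_quantile)
  files <- c(files, .write_tsv(
    data.frame(genus = hub$genera),
    file.path(gdir, "hubs.tsv")))

  core1 <- core_def1(comp, config$core_detection, config$core_prevalence)
  core2 <- suppressWarnings(core_def2(centr, max(1, length(core1$genera))))
  cmp1 <- compare_cores(core1, tab, centr)
  cmp2 <- if (length(core2$genera)) compare_cores(core2, tab, centr) else
    list(definition = core2$definition, core_size = 0L,
         average_prevalence_pct = NA_real_,
         cumulative_abundance = NA_real_,
         mean_summed_centrality = NA_real_)
  files <- c(files, .write_tsv(
    data.frame(definition = c(rep("prevalence_abundance",
                                  length(core1$genera)),
                              rep("hub_quantile", length(core2$genera))),
               genus = c(core1$genera, core2$genera)),
    file.path(gdir, "core.tsv")))
  jsonlite::write_json(list(prevalence_abundance = unclass(cmp1),
                            hub_quantile = unclass(cmp2),
                            tuned_quantile = core2$params$quantile,
                            overlap = core_overlap(core1, core2)),
                       file.path(gdir, "core_comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(gdir, "core_comparison.json"))

  orb <- count_orbits(net)
  files <- c(files, .write_tsv(
    data.frame(genus = rownames(orb), unclass(orb), check.names = FALSE),
    file.path(gdir, "orbits.tsv")))
  g <- gcm(orb)
  files <- c(files, .write_tsv(
    data.frame(orbit = rownames(g), unclass(g), check.names = FALSE),
    file.path(gdir, "gcm.tsv")))

  list(table = tab, comp = comp, est = est, test = test, net = net,
       clusters = clusters, props = props, centr = centr, hub = hub,
       core1 = core1, core2 = core2, orbits = orb, gcm = g, div = div,
       files = files)
}

#' Run the full two-group comparison pipeline
#'
#' Executes, per group: filtering, zero replacement, CLR, alpha diversity,
#' SparCC, edge sparsification, network construction and clustering,
#' global properties, centralities and hubs, both core-microbiota
#' definitions, orbit counts and the GCM. Across groups it computes the
#' diversity comparison, the hub Jaccard test, the GCM difference with
#' orbit selection and genus mapping, and (optionally) the permutation
#' tests for global property differences. All artifacts are written under
#' `config$out_dir` together with a manifest (file list, seed, config
#' hash) and a plain-text log.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the per-group results and the
#'   cross-group comparison.
#' @export
run_comparison <- function(config) {
  stopifnot(inherits(config, "run_config"))
  table <- if (inherits(config$counts, "count_table")) config$counts else
    read_counts(config$counts, config$metadata)
  if (is.null(table$group_of))
    stop("no group assignment: supply metadata with a 'group' column")
  groups <- unique(unname(table$group_of))
  if (length(groups) != 2) stop("exactly two groups are required")

  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  log <- function(msg) writeLines(paste0(format(Sys.time(),
                                                "%Y-%m-%d %H:%M:%S "), msg),
                                  log_con)
  log("pipeline start")

  per_group <- list()
  for (g in groups) {
    sub <- count_table(table$counts[, unname(table$group_of) == g,
                                    drop = FALSE],
                       table$group_of[unname(table$group_of) == g])
    per_group[[g]] <- .run_group(sub, g, config, out_dir, log)
  }
  files <- unlist(lapply(per_group, `[[`, "files"), use.names = FALSE)

  g1 <- per_group[[groups[1]]]; g2 <- per_group[[groups[2]]]

  div_all <- alpha_diversity(count_table(
    table$counts[, colnames(table$counts) %in%
                   c(colnames(g1$table$counts), colnames(g2$table$counts)),
                 drop = FALSE]))
  div_cmp <- compare_diversity(div_all,
                               table$group_of[div_all$sample_id])

  universe <- union(rownames(g1$centr), rownames(g2$centr))
  jac <- jaccard_test(g1$hub$genera, g2$hub$genera, universe,
                      n_perm = config$jaccard_n_perm,
                      seed = .sub_seed(config$seed, 91))

  diff <- gcm_difference(g1$gcm, g2$gcm, alpha = config$graphlet_alpha)
  orbits_sel <- select_orbits(diff)
  terminal <- NULL
  if (length(orbits_sel)) {
    rep1 <- map_genera(g1$orbits, orbits_sel, config$graphlet_top_k)
    rep2 <- map_genera(g2$orbits, orbits_sel, config$graphlet_top_k)
    terminal <- list(report_1 = rep1, report_2 = rep2,
                     exclusive = terminal_exclusive(rep1, rep2))
    files <- c(files, .write_tsv(rep1, file.path(out_dir,
                                                 paste0("terminal_",
                                                        groups[1], ".tsv"))))
    files <- c(files, .write_tsv(rep2, file.path(out_dir,
                                                 paste0("terminal_",
                                                        groups[2], ".tsv"))))
  }
  files <- c(files, .write_tsv(diff, file.path(out_dir,
                                               "gcm_difference.tsv")))

  perm <- NULL
  if (!is.null(config$permutation)) {
    log("permutation tests")
    # refilter jointly so both groups share one node universe
    joint <- filter_counts(table, config$filter)$table
    perm <- property_difference_test(joint, config$permutation)
    perm_json <- lapply(perm[setdiff(names(perm), "n_failures")],
                        function(x) x[c("observed", "observed_diff",
                                        "p_value", "significant")])
    jsonlite::write_json(perm_json,
                         file.path(out_dir, "permutation_tests.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(out_dir, "permutation_tests.json"))
    if (isTRUE(config$local_tests)) {
      log("per-genus centrality permutation tests")
      local <- centrality_difference_test(joint, config$permutation)
      files <- c(files, .write_tsv(local,
                                   file.path(out_dir, "local_tests.tsv")))
      perm$local <- local
    }
  }

  comparison <- list(
    groups = groups,
    diversity = div_cmp,
    jaccard_hubs = unclass(jac),
    orbits_of_interest = orbits_sel,
    global_properties = setNames(
      list(unclass(g1$props), unclass(g2$props)), groups))
  jsonlite::write_json(comparison, file.path(out_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(out_dir, "comparison.json"))

  cfg_path <- file.path(out_dir, "config.json")
  cfg <- config
  cfg$counts <- if (is.character(cfg$counts)) cfg$counts else "<in-memory>"
  cfg$out_dir <- NULL   # implied by location; keeps reruns byte-identical
  cfg$permutation <- if (is.null(cfg$permutation)) NULL else
    unclass(cfg$permutation)
  cfg$filter <- unclass(cfg$filter)
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  files <- c(files, cfg_path)
  prefix <- paste0(normalizePath(out_dir, mustWork = FALSE), "/")
  full <- normalizePath(files, mustWork = FALSE)
  rel <- ifelse(startsWith(full, prefix),
                substring(full, nchar(prefix) + 1), full)
  manifest <- list(seed = config$seed,
                   config_hash = unname(tools::md5sum(cfg_path)),
                   files = sort(unname(rel)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log("pipeline done")
  invisible(list(per_group = per_group, comparison = comparison,
                 terminal = terminal, permutation = perm,
                 manifest = manifest))
}
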