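#' Configuration for the end-to-end pipeline
#'
#' Bundles the stage parameters with a single global seed. Every
#' stochastic stage derives its own seed deterministically from
#' `(seed, stage name)`, so changing one stage's parameters never shifts
#' another stage's random stream.
#'
#' @param cohort a [cohort_spec()] describing the synthetic cohort to
#'   simulate (its own seed is overridden by `seed`).
#' @param weight_policy weight policy for the network measures.
#' @param alpha edge-wise FDR level.
#' @param edge_n_perm permutations for the edge-wise test.
#' @param forming_alpha cluster-forming threshold.
#' @param cluster_n_perm permutations for the cluster test.
#' @param cluster_alpha significance level on cluster p-values.
#' @param k,repeats cross-validation folds and repetitions.
#' @param seed global seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            weight_policy = "absolute",
                            alpha = 1e-4, edge_n_perm = 2000L,
                            forming_alpha = 0.05, cluster_n_perm = 2000L,
                            cluster_alpha = 0.05,
                            k = 10L, repeats = 50L, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_spec"))
  structure(list(cohort = cohort, weight_policy = weight_policy,
                 alpha = alpha, edge_n_perm = as.integer(edge_n_perm),
                 forming_alpha = forming_alpha,
                 cluster_n_perm = as.integer(cluster_n_perm),
                 cluster_alpha = cluster_alpha,
                 k = as.integer(k), repeats = as.integer(repeats),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages: simulate the cohort; compute per-subject connectivity matrices;
#' compute the three node measures; edge-wise FDR test; cluster
#' permutation test for each measure; specific networks for both signs
#' (nodes pooled over the three measures' significant clusters, as in the
#' combined-measure figures) with BrainNet export; LDA cross-validation
#' for all five feature variants. All artifacts are written under
#' `out_dir` and a manifest (parameters, seeds, md5 hashes of every
#' output) closes the run.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  spec <- config$cohort
  spec$seed <- derive_seed(config$seed, "simulate")
  cohort <- generate_cohort(spec)
  write_cohort(cohort, file.path(out_dir, "cohort"))
  groups <- cohort$subject_table$group

  matrices <- lapply(cohort$subjects, function(s) pearson_connectivity(s$ts))
  mat_dir <- file.path(out_dir, "connectivity")
  dir.create(mat_dir, showWarnings = FALSE)
  for (m in matrices) {
    write_matrix(unclass(m), file.path(mat_dir, paste0(attr(m, "subject_id"), "_fc.tsv")))
  }

  msets <- lapply(matrices, node_measures, policy = config$weight_policy)
  means_tab <- data.frame(
    subject_id = vapply(msets, `[[`, "", "subject_id"),
    group = groups,
    t(vapply(msets, `[[`, numeric(3), "means"))
  )
  utils::write.csv(means_tab, file.path(out_dir, "network_means.csv"),
                   row.names = FALSE)
  global_tests <- lapply(c("clustering", "centrality", "strength"), function(nm) {
    gt <- global_measure_test(means_tab[[nm]][groups == "control"],
                              means_tab[[nm]][groups == "depression"])
    c(measure = nm, t = gt$t, p = gt$p)
  })

  edge_res <- edgewise_group_test(
    matrices, groups, alpha = config$alpha, n_perm = config$edge_n_perm,
    seed = derive_seed(config$seed, "edge-test"))
  utils::write.csv(edge_res$edges, file.path(out_dir, "edge_test.csv"),
                   row.names = FALSE)
  write_matrix(edge_res$mask, file.path(out_dir, "edge_mask.tsv"))

  regions <- synthetic_region_table(spec$n_regions)
  cluster_res <- list()
  all_sig <- NULL
  for (nm in c("clustering", "centrality", "strength")) {
    M <- measure_matrix(msets, nm)
    cr <- cluster_permutation_test(
      M, groups, forming_alpha = config$forming_alpha,
      n_perm = config$cluster_n_perm,
      seed = derive_seed(config$seed, paste0("cluster-", nm)),
      region_labels = regions$label, measure_name = nm)
    cluster_res[[nm]] <- cr
    utils::write.csv(cr$clusters, file.path(out_dir, paste0("clusters_", nm, ".csv")),
                     row.names = FALSE)
    sig <- significant_clusters(cr, config$cluster_alpha)
    if (nrow(sig) > 0) all_sig <- rbind(all_sig, sig)
  }
  if (is.null(all_sig)) {
    all_sig <- data.frame(sign = character(0), start = integer(0), end = integer(0))
  }
  networks <- list()
  for (sgn in c("positive", "negative")) {
    net <- build_specific_network(all_sig, sgn, edge_res$mask)
    networks[[sgn]] <- net
    export_brainnet(net, regions,
                    file.path(out_dir, paste0("network_", sgn, ".node")),
                    file.path(out_dir, paste0("network_", sgn, ".edge")))
  }

  variants <- c("full_fc", "significant_fc", "clustering", "strength", "centrality")
  reports <- list()
  rows <- list()
  for (v in variants) {
    feats <- if (v == "significant_fc") {
      build_features("full_fc", matrices = matrices)
    } else {
      build_features(v, matrices = matrices, measure_sets = msets,
                     mask = edge_res$mask)
    }
    selector <- if (v == "significant_fc") {
      fc_mask_selector(matrices, groups, alpha = 0.05)
    } else NULL
    rep <- cross_validate(feats, groups, k = config$k, repeats = config$repeats,
                          seed = derive_seed(config$seed, paste0("classify-", v)),
                          selector = selector)
    reports[[v]] <- rep
    rows[[v]] <- data.frame(variant = v, accuracy_mean = rep$accuracy_mean,
                            accuracy_sd = rep$accuracy_sd,
                            sensitivity = rep$sensitivity,
                            specificity = rep$specificity,
                            precision = rep$precision, auc = rep$auc)
  }
  report_tab <- do.call(rbind, rows)
  utils::write.csv(report_tab, file.path(out_dir, "classification.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(reports, function(r) list(auc = r$auc, roc = r$roc)),
    file.path(out_dir, "roc.json"), auto_unbox = TRUE, digits = NA, dataframe = "columns")

  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    seed = config$seed,
    parameters = unclass(config)[setdiff(names(unclass(config)), "cohort")],
    n_subjects = length(cohort$subjects),
    n_significant_edges = edge_res$n_significant_edges,
    n_involved_nodes = edge_res$n_involved_nodes,
    global_tests = global_tests,
    hashes = as.list(setNames(unname(tools::md5sum(files)),
                              sub(paste0("^", out_dir, "/?"), "", files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, matrices = matrices, measures = msets,
                 edge_test = edge_res, clusters = cluster_res,
                 networks = networks, reports = reports, manifest = manifest))
}
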