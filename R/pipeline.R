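#' Read and write connectivity matrices as delimited text
#'
#' Matrices are stored as square whitespace- or comma-delimited numeric
#' tables, optionally with a header row of node labels (written by
#' [write_connectivity_matrix()], and detected on read). Reading validates
#' strictly — square, exactly symmetric, zero diagonal, nonnegative — and a
#' malformed cell is reported with its row and column.
#'
#' @param path File path.
#' @returns `read_connectivity_matrix()`: a validated labeled matrix.
#' @export
read_connectivity_matrix <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("no such matrix file: %s", path))
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]", first)
  sep <- if (grepl(",", first)) "," else ""
  tab <- utils::read.table(path, header = has_header, sep = sep,
                           check.names = FALSE, comment.char = "#")
  m <- as.matrix(tab)
  if (!is.numeric(m)) {
    bad <- which(!vapply(tab, is.numeric, logical(1)))[1]
    rlang::abort(sprintf("non-numeric cell(s) in column %d of %s.", bad, path))
  }
  labels <- if (has_header) colnames(tab) else NULL
  as_connectivity_matrix(m, node_labels = labels)
}

#' @rdname read_connectivity_matrix
#' @param weights Connectivity matrix to write.
#' @returns `write_connectivity_matrix()`: `path`, invisibly.
#' @export
write_connectivity_matrix <- function(weights, path) {
  weights <- as_connectivity_matrix(weights)
  utils::write.table(weights, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a simulated cohort to disk as delimited text
#'
#' Lays out one matrix file per subject, a phenotype table, and a manifest
#' (subject_id, path, group) pointing at them — the on-disk layout
#' [read_cohort()] and the command-line interface consume.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @returns The manifest path, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat_dir <- file.path(dir, "matrices")
  dir.create(mat_dir, showWarnings = FALSE)
  paths <- vapply(names(sim$matrices), function(id) {
    p <- file.path(mat_dir, paste0(id, ".tsv"))
    write_connectivity_matrix(sim$matrices[[id]], p)
    p
  }, character(1))
  manifest <- tibble::tibble(
    subject_id = names(sim$matrices),
    path = file.path("matrices", paste0(names(sim$matrices), ".tsv")),
    group = sim$cohort$group[match(names(sim$matrices), sim$cohort$subject_id)]
  )
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  readr::write_tsv(sim$cohort, file.path(dir, "phenotypes.tsv"))
  invisible(file.path(dir, "manifest.tsv"))
}

#' Read a cohort from a manifest
#'
#' @param manifest_path Path to a TSV with columns `subject_id`, `path`
#'   (relative to the manifest's directory or absolute), `group`.
#' @param phenotypes_path Path to the phenotype TSV; defaults to
#'   `phenotypes.tsv` next to the manifest.
#' @returns List with `matrices` (named list) and `cohort` (tibble).
#' @export
read_cohort <- function(manifest_path,
                        phenotypes_path = file.path(dirname(manifest_path), "phenotypes.tsv")) {
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE)
  root <- dirname(manifest_path)
  full <- ifelse(grepl("^(/|[A-Za-z]:)", manifest$path), manifest$path,
                 file.path(root, manifest$path))
  missing <- manifest$subject_id[!file.exists(full)]
  if (length(missing) > 0) {
    rlang::abort(sprintf("matrix file missing for subject(s): %s.",
                         paste(missing, collapse = ", ")))
  }
  matrices <- purrr::map(full, read_connectivity_matrix)
  names(matrices) <- manifest$subject_id
  cohort <- readr::read_tsv(phenotypes_path, show_col_types = FALSE)
  list(matrices = matrices, cohort = cohort)
}

# all pairwise combinations of the four groups, in a fixed order
group_pairs <- function(groups) {
  pairs <- utils::combn(groups, 2)
  tibble::tibble(group_a = pairs[1, ], group_b = pairs[2, ])
}

#' Permutation contrasts of class-wise metrics between groups
#'
#' Runs the two-sample permutation test for every pairwise group contrast
#' and every metric column, then adjusts the whole family of p values by
#' Benjamini–Hochberg FDR. The family is all contrasts x all supplied
#' metrics, the widest (most conservative) choice.
#'
#' @param metrics Per-subject metric tibble containing `subject_id` and the
#'   metric columns.
#' @param cohort Phenotype tibble with `subject_id` and `group`.
#' @param metric_cols Character vector of metric column names.
#' @param n_perm Permutations per test.
#' @param seed Master seed; per-test seeds are derived by counter.
#' @returns Tibble: `group_a`, `group_b`, `metric`, `observed_diff`,
#'   `p_value`, `p_fdr`.
#' @export
permute_group_contrasts <- function(metrics, cohort,
                                    metric_cols = c("strength_rich", "strength_feeder",
                                                    "strength_local", "density_rich",
                                                    "density_feeder", "density_local"),
                                    n_perm = 10000, seed = 1) {
  dat <- dplyr::inner_join(metrics, cohort[c("subject_id", "group")], by = "subject_id")
  groups <- unique(dat$group)
  grid <- tidyr::crossing(group_pairs(groups), metric = metric_cols)
  purrr::pmap_dfr(grid, function(group_a, group_b, metric) {
    a <- dat[[metric]][dat$group == group_a]
    b <- dat[[metric]][dat$group == group_b]
    test_seed <- seed + 7919 * which(grid$group_a == group_a &
                                       grid$group_b == group_b &
                                       grid$metric == metric)[1]
    res <- permutation_test(a, b, n_perm = n_perm, seed = test_seed)
    tibble::tibble(group_a = group_a, group_b = group_b, metric = metric,
                   observed_diff = res$observed_diff, p_value = res$p_value)
  }) |>
    dplyr::mutate(p_fdr = fdr_correct(.data$p_value))
}

#' Covariate-adjusted correlations between metrics and clinical scores
#'
#' Partial correlations (age, sex as 0/1, education regressed out) between
#' each metric column and each score column, within the given subset of
#' subjects.
#'
#' @param metrics Per-subject metric tibble with `subject_id`.
#' @param cohort Phenotype tibble with `subject_id`, `age`, `sex`,
#'   `education` and the score columns.
#' @param score_cols Character vector of score column names.
#' @param metric_cols Character vector of metric column names.
#' @param subset Optional logical expression on cohort columns, e.g.
#'   `diagnosis == "MDD"`.
#' @returns Tibble: `score`, `metric`, `r`, `p_value`, `p_fdr`, `n`.
#' @export
correlate_metrics <- function(metrics, cohort, score_cols,
                              metric_cols = c("strength_rich", "strength_feeder",
                                              "strength_local", "density_rich",
                                              "density_feeder", "density_local"),
                              subset = NULL) {
  dat <- dplyr::inner_join(metrics, cohort, by = "subject_id")
  subset <- rlang::enquo(subset)
  if (!rlang::quo_is_null(subset)) dat <- dplyr::filter(dat, !!subset)
  covs <- data.frame(age = dat$age, sex = as.numeric(dat$sex == "F"),
                     education = dat$education)
  grid <- tidyr::crossing(score = score_cols, metric = metric_cols)
  purrr::pmap_dfr(grid, function(score, metric) {
    ok <- stats::complete.cases(dat[[score]], dat[[metric]], covs)
    res <- partial_correlation(dat[[score]][ok], dat[[metric]][ok], covs[ok, ])
    tibble::tibble(score = score, metric = metric, r = res$r,
                   p_value = res$p_value, n = res$n)
  }) |>
    dplyr::mutate(p_fdr = fdr_correct(.data$p_value))
}

#' End-to-end rich-club analysis of a connectome cohort
#'
#' Composes the full analysis sequence on subject matrices plus phenotypes:
#' edge thresholding; per-group group-averaged networks; per-group hub
#' identification (plus their intersection, the common hub set); per-subject
#' edge classification against the subject's own group's hub set and
#' class-wise strength/density; normalized rich-club profiles of the
#' group-averaged networks; permutation contrasts of the six class metrics
#' between all group pairs with FDR; nodal-degree contrasts at the common
#' hub regions; and covariate-adjusted correlations of the metrics with CTQ
#' scores (patients and controls separately) and with symptom scales
#' (patients only).
#'
#' @param matrices Named list of subject connectivity matrices.
#' @param cohort Phenotype tibble (see [simulate_cohort()] for the
#'   columns).
#' @param min_streamlines Edge-existence floor (default 3).
#' @param prevalence Group-network prevalence threshold (default 0.60).
#' @param hub_fraction Hub fraction (default 0.12).
#' @param survivor_rule Rich-club survivor rule, `"ge"` or `"gt"`.
#' @param n_random Null networks per rich-club profile (default 1000).
#' @param n_perm Permutations per contrast (default 10000).
#' @param seed Master seed.
#' @param compute_profiles Set `FALSE` to skip the (comparatively slow)
#'   normalized profiles.
#' @returns A `richclub_analysis` list: `group_networks`, `hubs`,
#'   `common_hubs`, `profiles`, `metrics`, `contrasts`, `nodal_degree`,
#'   `correlations`, `params`.
#' @export
run_richclub_analysis <- function(matrices, cohort,
                                  min_streamlines = 3, prevalence = 0.6,
                                  hub_fraction = 0.12,
                                  survivor_rule = c("ge", "gt"),
                                  n_random = 1000, n_perm = 10000, seed = 1,
                                  compute_profiles = TRUE) {
  survivor_rule <- match.arg(survivor_rule)
  if (!all(cohort$subject_id %in% names(matrices))) {
    missing <- setdiff(cohort$subject_id, names(matrices))
    rlang::abort(sprintf("no matrix for subject(s): %s.", paste(missing, collapse = ", ")))
  }
  matrices <- purrr::map(matrices[cohort$subject_id], threshold_matrix,
                         min_streamlines = min_streamlines)
  groups <- unique(cohort$group)

  group_networks <- purrr::map(setNames(groups, groups), function(g) {
    group_average_network(matrices[cohort$subject_id[cohort$group == g]], prevalence)
  })
  hubs <- purrr::map(group_networks, identify_rich_club_nodes,
                     hub_fraction = hub_fraction)
  common_hubs <- Reduce(intersect, hubs)

  profiles <- if (compute_profiles) {
    purrr::imap(group_networks, function(net, g) {
      normalized_rich_club(net, n_random = n_random, seed = seed,
                           rule = survivor_rule)
    })
  } else NULL

  hub_by_subject <- setNames(hubs[cohort$group], cohort$subject_id)
  metrics <- cohort_class_metrics(matrices, hub_by_subject)

  contrasts <- permute_group_contrasts(metrics, cohort, n_perm = n_perm, seed = seed)

  deg <- purrr::map_dfr(cohort$subject_id, function(id) {
    d <- node_degree(matrices[[id]])
    tibble::tibble(subject_id = id, !!!as.list(d[common_hubs]))
  })
  nodal_degree <- permute_group_contrasts(deg, cohort, metric_cols = common_hubs,
                                          n_perm = n_perm, seed = seed + 1)

  ctq_cols <- c("CTQ", names(ctq_cutoffs))
  correlations <- dplyr::bind_rows(
    MDD = correlate_metrics(metrics, cohort, ctq_cols, subset = .data$diagnosis == "MDD"),
    HC = correlate_metrics(metrics, cohort, ctq_cols, subset = .data$diagnosis == "HC"),
    MDD_symptoms = correlate_metrics(metrics, cohort, c("HAMD", "HAMA"),
                                     subset = .data$diagnosis == "MDD"),
    .id = "population"
  )

  structure(list(
    group_networks = group_networks, hubs = hubs, common_hubs = common_hubs,
    profiles = profiles, metrics = metrics, contrasts = contrasts,
    nodal_degree = nodal_degree, correlations = correlations,
    params = list(min_streamlines = min_streamlines, prevalence = prevalence,
                  hub_fraction = hub_fraction, survivor_rule = survivor_rule,
                  n_random = n_random, n_perm = n_perm, seed = seed,
                  n_subjects = nrow(cohort),
                  package_version = as.character(utils::packageVersion("richclubr")))
  ), class = "richclub_analysis")
}

#' @export
print.richclub_analysis <- function(x, ...) {
  cat("Rich-club connectome analysis\n")
  cat(sprintf("  subjects: %d in %d groups\n", x$params$n_subjects, length(x$hubs)))
  cat(sprintf("  common hub set (%d): %s\n", length(x$common_hubs),
              paste(x$common_hubs, collapse = ", ")))
  sig <- sum(x$contrasts$p_fdr < 0.05)
  cat(sprintf("  class-metric contrasts: %d of %d FDR-significant at 0.05\n",
              sig, nrow(x$contrasts)))
  invisible(x)
}

#' @method tidy richclub_analysis
#' @export
tidy.richclub_analysis <- function(x, ...) x$contrasts

#' @method glance richclub_analysis
#' @export
glance.richclub_analysis <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$params$n_subjects,
    n_groups = length(x$hubs),
    n_common_hubs = length(x$common_hubs),
    n_contrasts = nrow(x$contrasts),
    n_significant_fdr = sum(x$contrasts$p_fdr < 0.05),
    seed = x$params$seed
  )
}

#' Plot class-wise connectivity metrics by group
#'
#' @param metrics Per-subject metric tibble from the analysis.
#' @param cohort Phenotype tibble with `subject_id` and `group`.
#' @param measure `"strength"` or `"density"`.
#' @returns A ggplot.
#' @export
plot_class_metrics <- function(metrics, cohort, measure = c("strength", "density")) {
  measure <- match.arg(measure)
  cols <- paste0(measure, "_", c("rich", "feeder", "local"))
  dat <- dplyr::inner_join(metrics, cohort[c("subject_id", "group")], by = "subject_id") |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "class", values_to = "value") |>
    dplyr::mutate(class = factor(sub(paste0(measure, "_"), "", .data$class),
                                 levels = c("rich", "feeder", "local")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$value, fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~class, scales = "free_y") +
    ggplot2::labs(y = paste("connectivity", measure), x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   legend.position = "none")
}

# write one results table with '#' metadata header lines
write_result_table <- function(df, path, params) {
  meta <- c(
    sprintf("# generated by richclubr %s", params$package_version),
    sprintf("# seed=%d min_streamlines=%s prevalence=%s hub_fraction=%s rule=%s n_random=%d n_perm=%d",
            params$seed, params$min_streamlines, params$prevalence,
            params$hub_fraction, params$survivor_rule, params$n_random, params$n_perm)
  )
  writeLines(meta, path)
  suppressWarnings(readr::write_tsv(df, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

#' Write an analysis results bundle as TSV tables
#'
#' Emits `class_metrics.tsv`, `contrasts.tsv`, `nodal_degree.tsv`,
#' `correlations.tsv`, `hubs.tsv`, per-group `profile_<group>.tsv`, and a
#' `run_manifest.tsv` capturing every parameter and seed needed to
#' reproduce the run. Each table starts with `#`-prefixed metadata lines.
#'
#' @param result A `richclub_analysis`.
#' @param dir Output directory.
#' @returns `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- result$params
  write_result_table(result$metrics, file.path(dir, "class_metrics.tsv"), p)
  write_result_table(result$contrasts, file.path(dir, "contrasts.tsv"), p)
  write_result_table(result$nodal_degree, file.path(dir, "nodal_degree.tsv"), p)
  write_result_table(result$correlations, file.path(dir, "correlations.tsv"), p)
  hubs_tbl <- purrr::imap_dfr(result$hubs, function(h, g) {
    tibble::tibble(group = g, hub = h)
  }) |>
    dplyr::bind_rows(tibble::tibble(group = "common", hub = result$common_hubs))
  write_result_table(hubs_tbl, file.path(dir, "hubs.tsv"), p)
  if (!is.null(result$profiles)) {
    purrr::iwalk(result$profiles, function(prof, g) {
      write_result_table(tidy(prof),
                         file.path(dir, paste0("profile_", gsub("[^A-Za-z0-9]", "_", g), ".tsv")), p)
    })
  }
  manifest <- tibble::tibble(parameter = names(p),
                             value = vapply(p, as.character, character(1)))
  readr::write_tsv(manifest, file.path(dir, "run_manifest.tsv"))
  invisible(dir)
}
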