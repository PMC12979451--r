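#' Rich-club coefficient at a single degree level
#'
#' Nodes whose degree (computed on the full network) falls below `k` are
#' removed; among the S surviving nodes, the coefficient is the number of
#' original edges with both endpoints surviving divided by the S(S-1)/2
#' possible edges. With fewer than two survivors the coefficient is
#' undefined and `NA` is returned — never an error.
#'
#' The default survivor rule `"ge"` keeps nodes with degree >= k (removes
#' degree < k). Much of the classic rich-club literature instead keeps
#' degree > k; that variant is available as `rule = "gt"`.
#'
#' @param adj Binary (or weighted; binarized internally) adjacency matrix.
#' @param k Degree level, >= 0.
#' @param rule `"ge"` (default) keeps degree >= k; `"gt"` keeps degree > k.
#' @returns Coefficient in \[0, 1\], or `NA` when undefined.
#' @export
rich_club_coefficient <- function(adj, k, rule = c("ge", "gt")) {
  rule <- match.arg(rule)
  adj <- binarize(adj)
  if (length(k) != 1 || is.na(k) || k < 0) rlang::abort("`k` must be a single value >= 0.")
  deg <- rowSums(adj)
  keep <- if (rule == "ge") deg >= k else deg > k
  s <- sum(keep)
  if (s < 2) return(NA_real_)
  e_sub <- sum(adj[keep, keep]) / 2
  e_sub / (s * (s - 1) / 2)
}

#' Rich-club coefficient curve over the degree sweep
#'
#' Evaluates the coefficient at every integer k from the minimum
#' non-isolated degree to the maximum degree of the network. Undefined
#' levels are carried as `NA` rows, not dropped, so curves from networks
#' with identical degree sequences line up row for row.
#'
#' @inheritParams rich_club_coefficient
#' @returns Tibble with columns `k`, `n_survivors`, `phi`.
#' @export
rich_club_curve <- function(adj, rule = c("ge", "gt")) {
  rule <- match.arg(rule)
  adj <- binarize(adj)
  deg <- rowSums(adj)
  if (all(deg == 0)) rlang::abort("network has no edges; the degree sweep is empty.")
  ks <- seq.int(min(deg[deg > 0]), max(deg))
  tibble::tibble(
    k = as.integer(ks),
    n_survivors = vapply(ks, function(k) {
      sum(if (rule == "ge") deg >= k else deg > k)
    }, integer(1)),
    phi = vapply(ks, function(k) rich_club_coefficient(adj, k, rule), numeric(1))
  )
}

#' Degree-preserving randomization by edge swaps
#'
#' Produces a random simple network with exactly the same degree sequence by
#' repeated pairwise edge swaps (the standard Maslov–Sneppen null model for
#' rich-club normalization), delegating the swap loop to
#' [igraph::rewire()] with `keeping_degseq()`. Deterministic for a given
#' `seed`; the caller's RNG state is untouched.
#'
#' @param adj Binary adjacency matrix of a simple undirected network.
#' @param n_swap_per_edge Attempted swaps per edge (default 10).
#' @param seed Integer seed.
#' @returns Rewired binary adjacency matrix with the same labels. A network
#'   with fewer than two edges cannot be swapped and is returned unchanged
#'   with a warning.
#' @export
rewire_degree_preserving <- function(adj, n_swap_per_edge = 10, seed = 1) {
  adj <- binarize(adj)
  if (n_swap_per_edge == 0) return(adj)
  n_edges <- sum(adj) / 2
  if (n_edges < 2) {
    rlang::warn("fewer than 2 edges; no swap is possible, returning the network unchanged.")
    return(adj)
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  g <- withr::with_seed(
    seed,
    igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = n_swap_per_edge * n_edges))
  )
  out <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  out <- (out != 0) * 1
  dimnames(out) <- dimnames(adj)
  out
}

#' Normalized rich-club curve against a degree-preserving null ensemble
#'
#' Computes the observed coefficient curve, the mean curve over `n_random`
#' degree-preserving random networks, and their ratio. Because rewiring
#' conserves every node's degree, all null networks share the observed
#' network's k sweep. At each k the null mean averages only nulls where the
#' coefficient is defined; the normalized value is `NA` where the observed
#' coefficient is undefined or the null mean is zero. A ratio above 1 over a
#' contiguous range of high k is the signature of rich-club organization.
#'
#' Per-null seeds are derived from `seed` by counter, so the profile is
#' reproducible from the single master seed recorded in the result.
#'
#' @inheritParams rewire_degree_preserving
#' @param n_random Number of random networks (>= 1); 1000 is the
#'   conventional ensemble size, smaller ensembles are fine for exploration.
#' @param rule Survivor rule, see [rich_club_coefficient()].
#' @returns A `rich_club_profile`: tibble with columns `k`, `n_survivors`,
#'   `phi`, `phi_random`, `phi_norm` and attributes `n_random`, `seed`,
#'   `rule`. [tidy()] returns the tibble; [autoplot()] draws the curves.
#' @export
normalized_rich_club <- function(adj, n_random = 1000, n_swap_per_edge = 10,
                                 seed = 1, rule = c("ge", "gt")) {
  rule <- match.arg(rule)
  if (n_random < 1) rlang::abort("`n_random` must be >= 1.")
  adj <- binarize(adj)
  obs <- rich_club_curve(adj, rule)
  null_phi <- matrix(NA_real_, nrow(obs), n_random)
  for (r in seq_len(n_random)) {
    nul <- rewire_degree_preserving(adj, n_swap_per_edge, seed = seed + r)
    null_phi[, r] <- rich_club_curve(nul, rule)$phi
  }
  phi_random <- rowMeans(null_phi, na.rm = TRUE)
  phi_random[!is.finite(phi_random)] <- NA_real_
  phi_norm <- ifelse(!is.na(obs$phi) & !is.na(phi_random) & phi_random > 0,
                     obs$phi / phi_random, NA_real_)
  out <- tibble::tibble(
    k = obs$k, n_survivors = obs$n_survivors,
    phi = obs$phi, phi_random = phi_random, phi_norm = phi_norm
  )
  structure(out,
    class = c("rich_club_profile", class(out)),
    n_random = n_random, n_swap_per_edge = n_swap_per_edge,
    seed = seed, rule = rule
  )
}

#' @method tidy rich_club_profile
#' @export
tidy.rich_club_profile <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("k", "n_survivors", "phi", "phi_random", "phi_norm")])
}

#' @method glance rich_club_profile
#' @export
glance.rich_club_profile <- function(x, ...) {
  defined <- !is.na(x$phi_norm)
  tibble::tibble(
    n_k = nrow(x),
    n_random = attr(x, "n_random"),
    seed = attr(x, "seed"),
    rule = attr(x, "rule"),
    max_phi_norm = if (any(defined)) max(x$phi_norm[defined]) else NA_real_,
    k_range_above_1 = sum(defined & x$phi_norm > 1)
  )
}

#' @method autoplot rich_club_profile
#' @export
autoplot.rich_club_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object), c("phi", "phi_random", "phi_norm"),
                              names_to = "curve", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value, colour = .data$curve)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "degree level k", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Identify rich-club regions on a group-averaged network
#'
#' The hub set is the `round(hub_fraction * N)` nodes of highest binary
#' degree (round half up; at the conventional fraction 0.12 on 90 nodes this
#' is exactly 11 regions). Ties at the cut-off degree are broken by
#' ascending label order and reported with a message, so the selection is
#' deterministic and invariant to node permutation up to that documented
#' tie-break.
#'
#' @param group_adj Binary group-averaged adjacency matrix.
#' @param hub_fraction Fraction of nodes to take as hubs, in (0, 1).
#' @returns Character vector of hub node labels.
#' @export
identify_rich_club_nodes <- function(group_adj, hub_fraction = 0.12) {
  group_adj <- binarize(group_adj)
  if (length(hub_fraction) != 1 || hub_fraction <= 0 || hub_fraction >= 1) {
    rlang::abort("`hub_fraction` must be a single fraction in (0, 1).")
  }
  n <- nrow(group_adj)
  n_hub <- round_half_up(hub_fraction * n)
  if (n_hub < 1) rlang::abort("hub fraction yields zero hubs on this network.")
  deg <- node_degree(group_adj)
  ord <- order(-deg, names(deg))
  cut_deg <- deg[ord][n_hub]
  if (sum(deg == cut_deg) > 1 && n_hub < n && deg[ord][n_hub + 1] == cut_deg) {
    message(sprintf(
      "tie at the cut-off degree %d: %d nodes share it; broken by label order.",
      cut_deg, sum(deg == cut_deg)
    ))
  }
  names(deg)[ord][seq_len(n_hub)]
}

#' Classify edges as rich-club, feeder or local
#'
#' Every existing edge falls in exactly one class by the hub membership of
#' its endpoints: rich (both endpoints hubs), feeder (exactly one), local
#' (neither).
#'
#' @param weights Subject connectivity matrix.
#' @param hubs Character vector of hub labels, a subset of the node labels.
#' @returns Tibble of the network's undirected edges: `from`, `to` (labels,
#'   from earlier in label order), `weight`, `class` (factor
#'   rich/feeder/local).
#' @export
classify_edges <- function(weights, hubs) {
  weights <- as_connectivity_matrix(weights)
  labels <- rownames(weights)
  unknown <- setdiff(hubs, labels)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("unknown hub label(s): %s.", paste(unknown, collapse = ", ")))
  }
  idx <- which(upper.tri(weights) & weights != 0, arr.ind = TRUE)
  is_hub <- labels %in% hubs
  n_hub_ends <- is_hub[idx[, 1]] + is_hub[idx[, 2]]
  tibble::tibble(
    from = labels[idx[, 1]],
    to = labels[idx[, 2]],
    weight = weights[idx],
    class = factor(c("local", "feeder", "rich")[n_hub_ends + 1],
                   levels = c("rich", "feeder", "local"))
  )
}

#' Class-wise connectivity strength and density for one subject
#'
#' Strength of a class is the sum of its edge weights, each undirected edge
#' counted once; density is the class strength divided by whole-network
#' strength, so the three densities sum to 1 (all `NA` for an empty
#' network). Strengths use the subject's weighted edges even though the hub
#' set is defined on the binary group-averaged network.
#'
#' @inheritParams classify_edges
#' @param subject_id Optional identifier carried into the output row.
#' @returns One-row tibble: `subject_id`, `strength_rich`, `strength_feeder`,
#'   `strength_local`, `strength_total`, `density_rich`, `density_feeder`,
#'   `density_local`.
#' @export
class_metrics <- function(weights, hubs, subject_id = NA_character_) {
  edges <- classify_edges(weights, hubs)
  s <- vapply(c("rich", "feeder", "local"),
              function(cl) sum(edges$weight[edges$class == cl]), numeric(1))
  total <- sum(s)
  d <- if (total > 0) s / total else rep(NA_real_, 3)
  tibble::tibble(
    subject_id = subject_id,
    strength_rich = s[["rich"]], strength_feeder = s[["feeder"]],
    strength_local = s[["local"]], strength_total = total,
    density_rich = d[[1]], density_feeder = d[[2]], density_local = d[[3]]
  )
}

#' Class-wise connectivity metrics for a cohort
#'
#' @param mats Named list of subject connectivity matrices (names are
#'   subject ids).
#' @param hubs Either a character vector of hub labels applied to every
#'   subject, or a named list mapping each subject id to its hub set (e.g.
#'   the hub set of the subject's group).
#' @returns Tibble with one row per subject, columns as in
#'   [class_metrics()].
#' @export
cohort_class_metrics <- function(mats, hubs) {
  ids <- names(mats) %||% as.character(seq_along(mats))
  purrr::map2_dfr(mats, ids, function(m, id) {
    h <- if (is.list(hubs)) hubs[[id]] else hubs
    if (is.null(h)) rlang::abort(sprintf("no hub set supplied for subject '%s'.", id))
    class_metrics(m, h, subject_id = id)
  })
}
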