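#' Synthetic FC cohort specification
#'
#' Describes a two-group cohort of symmetric Fisher-z FC matrices: every
#' off-diagonal entry is \code{base_connectivity} plus i.i.d. Gaussian noise;
#' group-1 subjects get \code{effect_size} added on a chosen edge subset;
#' optional per-site offsets shift a subject's whole matrix. Effects are
#' injected directly in z-space (the pipeline consumes z), which keeps
#' recovery analyses linear.
#'
#' @param n_per_group Integer vector \code{c(g0, g1)}: group sizes.
#' @param n_regions Number of regions R (default 160, whole-brain atlas
#'   resolution).
#' @param base_connectivity Mean z of background edges (default 0.2, a
#'   typical resting-state level).
#' @param effect_edges m x 2 matrix of node pairs (1-based, i < j) carrying
#'   the group difference; \code{NULL} draws \code{n_effect_edges} edges as a
#'   randomly grown connected subgraph (avoids degenerate single-node
#'   signal).
#' @param n_effect_edges Number of effect edges drawn when
#'   \code{effect_edges} is \code{NULL} (default 50).
#' @param effect_size Mean z added to group 1 on the effect edges.
#' @param noise_sd Standard deviation of the per-edge Gaussian noise.
#' @param n_sites Number of acquisition sites (0 = none).
#' @param site_sd Standard deviation of the per-site mean offset.
#' @param seed Integer seed; cohorts are bitwise reproducible.
#' @return Object of class \code{synthetic_cohort_spec}.
#' @export
synthetic_cohort_spec <- function(n_per_group = c(100L, 100L),
                                  n_regions = 160L,
                                  base_connectivity = 0.2,
                                  effect_edges = NULL,
                                  n_effect_edges = 50L,
                                  effect_size = 0.5,
                                  noise_sd = 0.3,
                                  n_sites = 0L,
                                  site_sd = 0,
                                  seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  n_regions <- as.integer(n_regions)
  if (n_regions < 2L) stop("need at least 2 regions")
  if (length(n_per_group) != 2L || any(n_per_group < 1L))
    stop("n_per_group must be two positive integers")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (!is.null(effect_edges)) {
    effect_edges <- matrix(as.integer(effect_edges), ncol = 2L)
    if (any(effect_edges[, 1L] >= effect_edges[, 2L]) ||
        any(effect_edges < 1L) || any(effect_edges > n_regions))
      stop("effect_edges must be pairs with 1 <= i < j <= n_regions")
  }
  structure(list(n_per_group = n_per_group, n_regions = n_regions,
                 base_connectivity = base_connectivity,
                 effect_edges = effect_edges,
                 n_effect_edges = as.integer(n_effect_edges),
                 effect_size = effect_size, noise_sd = noise_sd,
                 n_sites = as.integer(n_sites), site_sd = site_sd,
                 seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

# grow a connected edge subset: start from one node, repeatedly connect a new
# or visited node, preferring unseen nodes until the graph is connected
.draw_effect_edges <- function(R, m) {
  m <- min(m, R * (R - 1L) %/% 2L)
  visited <- sample.int(R, 1L)
  chosen <- matrix(0L, 0L, 2L)
  have <- new.env(hash = TRUE)
  while (nrow(chosen) < m) {
    a <- visited[sample.int(length(visited), 1L)]
    cand <- if (length(visited) < R && stats::runif(1) < 0.7)
      setdiff(seq_len(R), visited) else setdiff(seq_len(R), a)
    b <- cand[sample.int(length(cand), 1L)]
    key <- paste(min(a, b), max(a, b))
    if (!is.null(have[[key]])) next
    have[[key]] <- TRUE
    chosen <- rbind(chosen, c(min(a, b), max(a, b)))
    if (!(b %in% visited)) visited <- c(visited, b)
  }
  chosen[order(chosen[, 1L], chosen[, 2L]), , drop = FALSE]
}

#' Generate a labelled synthetic FC cohort
#'
#' Per subject, \code{z[i, j] = base_connectivity + group * effect_size *
#' [ (i,j) in effect_edges ] + site_offset + N(0, noise_sd)}, symmetrised with
#' zero diagonal; KNN graphs are built from the matrices with \code{graph_cfg}.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param graph_cfg A [graph_config()] used to sparsify each matrix.
#' @return Object of class \code{fc_cohort}: \code{graphs} (list of
#'   [connectome_graph]), \code{labels}, \code{subject_ids}, \code{site},
#'   \code{fc} (the [fc_matrix] list), \code{positive_class = 1}, and
#'   \code{truth} (effect edges, effect size, per-site offsets, seed).
#' @export
generate_cohort <- function(spec, graph_cfg = graph_config()) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  R <- spec$n_regions
  n <- sum(spec$n_per_group)
  labels <- rep(c(0L, 1L), spec$n_per_group)
  ut <- upper.tri(matrix(0, R, R))
  .with_seed(spec$seed, {
    edges <- if (is.null(spec$effect_edges))
      .draw_effect_edges(R, spec$n_effect_edges) else spec$effect_edges
    site <- if (spec$n_sites > 0L) sample(rep_len(seq_len(spec$n_sites), n)) else rep(NA_integer_, n)
    site_offsets <- if (spec$n_sites > 0L) stats::rnorm(spec$n_sites, 0, spec$site_sd) else numeric(0)
    fc <- vector("list", n)
    for (s in seq_len(n)) {
      z <- matrix(0, R, R)
      z[ut] <- spec$base_connectivity + stats::rnorm(sum(ut), 0, spec$noise_sd)
      if (labels[s] == 1L && nrow(edges) > 0L)
        z[edges] <- z[edges] + spec$effect_size
      if (!is.na(site[s])) z[ut] <- z[ut] + site_offsets[site[s]]
      z <- z + t(z)
      fc[[s]] <- fc_matrix(z, subject_id = sprintf("sub%04d", s))
    }
    graphs <- lapply(seq_len(n), function(s)
      build_knn_graph(fc[[s]], graph_cfg, label = labels[s]))
    structure(list(graphs = graphs, labels = labels,
                   subject_ids = sprintf("sub%04d", seq_len(n)),
                   site = site, fc = fc, positive_class = 1L,
                   truth = list(effect_edges = edges,
                                effect_size = spec$effect_size,
                                site_offsets = site_offsets,
                                spec = unclass(spec)),
                   graph_config = graph_cfg),
              class = "fc_cohort")
  })
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat("<fc_cohort>", length(x$graphs), "subjects (",
      sum(x$labels == 0L), "class 0 /", sum(x$labels == 1L), "class 1 ),",
      x$graphs[[1L]]$n_nodes, "regions\n")
  invisible(x)
}

#' Named preset cohort specifications
#'
#' Fixed study conditions used throughout the package's own evaluation:
#' \describe{
#'   \item{separable}{effect 1.5, noise 0.2 — strong, recoverable signal.}
#'   \item{moderate}{effect 0.4, noise 0.3 — intermediate signal.}
#'   \item{null}{effect 0 — no group difference; classifiers should sit at
#'     chance.}
#'   \item{imbalanced}{group sizes 110/55 (mirroring a first-episode vs
#'     recurrent subgroup imbalance), effect 0.4, noise 0.3 — exercises the
#'     resampling modes.}
#' }
#'
#' @param n_regions Regions per subject (default 60; keeps the presets fast
#'   while leaving the pipeline identical to full-resolution use).
#' @param n_per_group Group sizes for the balanced presets.
#' @param seed Base seed; each preset derives its own.
#' @return Named list of [synthetic_cohort_spec()] objects.
#' @export
preset_cohorts <- function(n_regions = 60L, n_per_group = c(100L, 100L),
                           seed = 1L) {
  list(
    separable = synthetic_cohort_spec(n_per_group = n_per_group,
                                      n_regions = n_regions,
                                      effect_size = 1.5, noise_sd = 0.2,
                                      seed = seed),
    moderate = synthetic_cohort_spec(n_per_group = n_per_group,
                                     n_regions = n_regions,
                                     effect_size = 0.4, noise_sd = 0.3,
                                     seed = seed + 1L),
    null = synthetic_cohort_spec(n_per_group = n_per_group,
                                 n_regions = n_regions,
                                 effect_size = 0, noise_sd = 0.3,
                                 seed = seed + 2L),
    imbalanced = synthetic_cohort_spec(n_per_group = c(110L, 55L),
                                       n_regions = n_regions,
                                       effect_size = 0.4, noise_sd = 0.3,
                                       seed = seed + 3L))
}

#' Write a cohort through the standard on-disk layout
#'
#' One tab-separated R x R FC file per subject (\code{<subject_id>.tsv}), a
#' phenotype table \code{phenotype.tsv} (subject_id, label, site, subgroup)
#' and, for synthetic cohorts, a ground-truth sidecar
#' \code{ground_truth.tsv} listing the effect edges (0-based) and effect
#' size.
#'
#' @param cohort An \code{fc_cohort} carrying \code{fc} matrices.
#' @param dir Output directory (created if missing).
#' @param subgroup Optional character vector of subgroup tags per subject.
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir, subgroup = NULL) {
  stopifnot(inherits(cohort, "fc_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(cohort$fc)) stop("cohort carries no FC matrices to write")
  for (fc in cohort$fc) write_fc_matrix(fc, file.path(dir, paste0(fc$subject_id, ".tsv")))
  pheno <- data.frame(subject_id = cohort$subject_ids,
                      label = cohort$labels,
                      site = ifelse(is.na(cohort$site), "", cohort$site),
                      subgroup = if (is.null(subgroup)) "" else subgroup)
  utils::write.table(pheno, file.path(dir, "phenotype.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$truth)) {
    gt <- data.frame(i = cohort$truth$effect_edges[, 1L] - 1L,
                     j = cohort$truth$effect_edges[, 2L] - 1L,
                     effect_size = cohort$truth$effect_size)
    utils::write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a cohort from the standard on-disk layout
#'
#' @param dir Directory holding per-subject FC files and
#'   \code{phenotype.tsv}.
#' @param graph_cfg A [graph_config()] used to build the KNN graphs.
#' @param comparison Optional subgroup comparison: one of
#'   \code{"MDD_vs_HC"}, \code{"FEDN_vs_HC"}, \code{"REC_vs_HC"},
#'   \code{"FEDN_vs_REC"}. Requires a subgroup column; matching is
#'   case-insensitive. \code{NULL} keeps all subjects with their labels.
#' @return An \code{fc_cohort}.
#' @export
read_cohort <- function(dir, graph_cfg = graph_config(), comparison = NULL) {
  pheno_path <- file.path(dir, "phenotype.tsv")
  if (!file.exists(pheno_path)) stop("phenotype.tsv not found in ", dir)
  pheno <- utils::read.table(pheno_path, header = TRUE, sep = "\t",
                             colClasses = "character")
  pheno$label <- as.integer(pheno$label)
  if (!is.null(comparison)) pheno <- .filter_comparison(pheno, comparison)
  fc <- lapply(pheno$subject_id, function(id) {
    p <- file.path(dir, paste0(id, ".tsv"))
    if (!file.exists(p)) stop("FC file missing for subject ", id)
    read_fc_matrix(p, subject_id = id)
  })
  Rs <- vapply(fc, function(f) nrow(f$z), integer(1))
  if (length(unique(Rs)) != 1L)
    stop("subjects disagree on the number of regions: ",
         paste(unique(Rs), collapse = ", "))
  graphs <- lapply(seq_along(fc), function(s)
    build_knn_graph(fc[[s]], graph_cfg, label = pheno$label[s]))
  site <- if ("site" %in% names(pheno) && any(nzchar(pheno$site)))
    pheno$site else rep(NA_character_, nrow(pheno))
  structure(list(graphs = graphs, labels = pheno$label,
                 subject_ids = pheno$subject_id, site = site, fc = fc,
                 positive_class = 1L, truth = NULL, graph_config = graph_cfg),
            class = "fc_cohort")
}

# subgroup comparisons: relabel the selected subjects 1 = patient group,
# 0 = reference group; subgroup tags are matched case-insensitively
.filter_comparison <- function(pheno, comparison) {
  comparison <- match.arg(comparison,
                          c("MDD_vs_HC", "FEDN_vs_HC", "REC_vs_HC", "FEDN_vs_REC"))
  if (comparison == "MDD_vs_HC") return(pheno)
  if (!"subgroup" %in% names(pheno) || !any(nzchar(pheno$subgroup)))
    stop("comparison ", comparison, " needs a subgroup column in the phenotype table")
  sg <- toupper(trimws(pheno$subgroup))
  pick <- switch(comparison,
                 FEDN_vs_HC = list(pos = "FEDN", neg = "HC"),
                 REC_vs_HC = list(pos = "REC", neg = "HC"),
                 FEDN_vs_REC = list(pos = "FEDN", neg = "REC"))
  keep <- sg %in% c(pick$pos, pick$neg)
  out <- pheno[keep, , drop = FALSE]
  out$label <- as.integer(sg[keep] == pick$pos)
  out
}
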