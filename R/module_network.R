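ng_prior_default <- function() list(mu0 = 0, lambda0 = 0.1,
                                    alpha0 = 0.1, beta0 = 0.1)

#' Log score of a two-way (gene, sample-block) partition
#'
#' The Bayesian score optimized by the Gibbs sampler: the product over
#' (module, sample-block) cells of the Normal-Gamma marginal likelihood of
#' the cell's values. Exposed so the score of any assignment can be audited
#' (e.g., against exhaustive enumeration on tiny instances).
#'
#' @param expr gene-by-sample matrix (rows standardized for the sampler's
#'   use; this function scores whatever it is given).
#' @param module_of_gene integer module id per row (any coding).
#' @param sample_blocks optional list, one integer vector of block ids per
#'   module (in the order of `sort(unique(module_of_gene))`); default: one
#'   block containing all samples for each module.
#' @param prior Normal-Gamma prior parameters `mu0`, `lambda0`, `alpha0`,
#'   `beta0`.
#' @return scalar log score.
#' @export
partition_log_score <- function(expr, module_of_gene, sample_blocks = NULL,
                                prior = ng_prior_default()) {
  mods <- sort(unique(module_of_gene))
  z <- match(module_of_gene, mods) - 1L
  K <- length(mods)
  S <- ncol(expr)
  if (is.null(sample_blocks))
    sample_blocks <- rep(list(rep(1L, S)), K)
  B <- max(vapply(sample_blocks, max, 1L))
  w <- matrix(0L, K, S)
  for (k in seq_len(K)) w[k, ] <- as.integer(sample_blocks[[k]]) - 1L
  .partition_log_score_cpp(expr, as.integer(z), w, K, as.integer(B),
                           prior$mu0, prior$lambda0, prior$alpha0,
                           prior$beta0)
}

#' Two-way Gibbs sampling of co-expression modules
#'
#' Rows are standardized (mean 0, SD 1), then each chain alternates a gene
#' sweep (each gene reassigned among modules with probability proportional
#' to the marginal-likelihood change) and a sample sweep (each sample
#' reassigned among the module's sample blocks likewise). Each chain
#' returns its maximum-score sweep; the per-iteration trace reports the
#' best score so far and is therefore non-decreasing.
#'
#' @param expr_de gene-by-sample matrix of the genes to cluster (typically
#'   the differentially expressed genes over tumor samples).
#' @param n_modules number of modules available to the sampler.
#' @param n_sample_blocks sample blocks per module (default 2).
#' @param n_chains independent chains (default 10).
#' @param n_iter sweeps per chain (default 100).
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param prior Normal-Gamma prior (see [partition_log_score()]).
#' @param standardize standardize rows before sampling (default TRUE; set
#'   FALSE when the input is already on the intended scale).
#' @return list of per-chain assignments: `module` (named integer vector,
#'   1-based), `blocks` (module-by-sample block matrix), `log_score`,
#'   `trace`.
#' @export
gibbs_cluster <- function(expr_de, n_modules = 10, n_sample_blocks = 2,
                          n_chains = 10, n_iter = 100, seed = 1L,
                          prior = ng_prior_default(),
                          standardize = TRUE) {
  genes <- rownames(expr_de)
  if (nrow(expr_de) < 2) {
    chain <- list(module = setNames(rep(1L, nrow(expr_de)), genes),
                  blocks = matrix(1L, 1, ncol(expr_de)),
                  log_score = NA_real_, trace = numeric(0))
    return(rep(list(chain), n_chains))
  }
  x <- if (standardize) standardize_rows(expr_de) else expr_de
  lapply(seq_len(n_chains), function(ch) {
    set.seed(seed + ch - 1L)
    res <- .gibbs_chain_cpp(x, as.integer(n_modules),
                            as.integer(n_sample_blocks),
                            as.integer(n_iter),
                            prior$mu0, prior$lambda0, prior$alpha0,
                            prior$beta0)
    list(module = setNames(res$module + 1L, genes),
         blocks = res$blocks + 1L,
         log_score = res$log_score, trace = res$trace)
  })
}

#' Consensus ("tight") modules across Gibbs chains
#'
#' Genes are linked when their co-clustering frequency across chains
#' reaches `co_clustering_threshold`; connected components of the link
#' graph with at least `min_module_size` members become consensus modules
#' (numbered by decreasing size); all other genes are left unassigned
#' (module 0).
#'
#' @param chains output of [gibbs_cluster()] (>= 2 chains).
#' @param co_clustering_threshold link threshold in (0, 1\] (default 0.8).
#' @param min_module_size minimum consensus module size (default 5).
#' @return a `module_assignment`: list with `module_of_gene` (named
#'   integer, 0 = unassigned), `n_modules`, `coclustering` matrix.
#' @export
consensus_modules <- function(chains, co_clustering_threshold = 0.8,
                              min_module_size = 5) {
  stopifnot(length(chains) >= 2)
  genes <- names(chains[[1]]$module)
  G <- length(genes)
  co <- matrix(0, G, G, dimnames = list(genes, genes))
  for (ch in chains) {
    z <- ch$module[genes]
    co <- co + outer(z, z, "==")
  }
  co <- co / length(chains)
  adj <- co >= co_clustering_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  sizes <- comp$csize
  big <- which(sizes >= min_module_size)
  if (length(big) == 0)
    warning("consensus_modules: no component reaches min_module_size",
            call. = FALSE)
  big <- big[order(sizes[big], decreasing = TRUE)]
  module_of_gene <- setNames(integer(G), genes)
  for (i in seq_along(big))
    module_of_gene[comp$membership == big[i]] <- i
  structure(list(module_of_gene = module_of_gene,
                 n_modules = length(big), coclustering = co),
            class = "module_assignment")
}

# exact 1-D two-means split of a numeric vector: returns threshold
# (midpoint) minimizing within-group sum of squares
best_two_means_split <- function(v) {
  o <- order(v)
  x <- v[o]
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  tot <- cs[n]; tot2 <- cs2[n]
  i <- seq_len(n - 1)
  ssl <- cs2[i] - cs[i]^2 / i
  ssr <- (tot2 - cs2[i]) - (tot - cs[i])^2 / (n - i)
  k <- which.min(ssl + ssr)
  (x[k] + x[k + 1]) / 2
}

node_separation_scores <- function(profiles, left, right) {
  nl <- length(left); nr <- length(right)
  ml <- rowMeans(profiles[, left, drop = FALSE])
  mr <- rowMeans(profiles[, right, drop = FALSE])
  vl <- apply(profiles[, left, drop = FALSE], 1, var)
  vr <- apply(profiles[, right, drop = FALSE], 1, var)
  sp <- sqrt(((nl - 1) * vl + (nr - 1) * vr) / (nl + nr - 2))
  # zero pooled SD: perfect separation unless the profile is constant
  # across the whole node (then no information, score 0)
  t <- ifelse(sp > 0, abs(ml - mr) / sp,
              ifelse(ml != mr, Inf, 0))
  # logistic map of the separation statistic onto (0, 1), anchored at 0
  2 * plogis(t) - 1
}

#' Fit a regulation tree for one module
#'
#' The module's samples are recursively bisected by thresholding the module
#' mean profile at its exact two-means split; regulator profiles never
#' define the splits. At each internal node every candidate regulator gets
#' a soft separation score in (0, 1) (standardized mean difference between
#' the child blocks mapped through a logistic), calibrated by an empirical
#' p-value against `n_rand` random relabelings of the children.
#'
#' @param module_mean named numeric vector: module mean expression per
#'   sample.
#' @param profiles regulator-by-sample candidate profile matrix (columns
#'   must cover the samples of `module_mean`).
#' @param max_depth maximum tree depth (internal node levels, default 3).
#' @param min_leaf minimum samples per leaf (default 5).
#' @param n_rand random relabelings for the empirical p (default 100).
#' @param seed integer seed for the calibration.
#' @return a `regulation_tree`: list of internal nodes, each with
#'   `samples`, `threshold`, `left`, `right` (sample ids), `weight`
#'   (fraction of module samples at the node), `score` and `emp_p` per
#'   regulator.
#' @export
fit_regulation_tree <- function(module_mean, profiles, max_depth = 3,
                                min_leaf = 5, n_rand = 100, seed = 1L) {
  samples <- names(module_mean)
  stopifnot(!is.null(samples), all(samples %in% colnames(profiles)))
  profiles <- profiles[, samples, drop = FALSE]
  set.seed(seed)
  nodes <- list()
  recurse <- function(samp, depth) {
    if (depth > max_depth || length(samp) < 2 * min_leaf) return()
    v <- module_mean[samp]
    if (sd(v) == 0) return()
    thr <- best_two_means_split(v)
    left <- samp[v <= thr]; right <- samp[v > thr]
    if (length(left) < min_leaf || length(right) < min_leaf) return()
    obs <- node_separation_scores(profiles, left, right)
    nl <- length(left)
    ge <- rep(1, length(obs)) # observed counts as one of n_rand + 1
    for (r in seq_len(n_rand)) {
      perm <- sample(samp)
      sc <- node_separation_scores(profiles, perm[seq_len(nl)],
                                   perm[-seq_len(nl)])
      ge <- ge + (sc >= obs)
    }
    emp_p <- ge / (n_rand + 1)
    nodes[[length(nodes) + 1]] <<- list(
      samples = samp, threshold = thr, left = left, right = right,
      weight = length(samp) / length(samples),
      score = setNames(obs, rownames(profiles)),
      emp_p = setNames(emp_p, rownames(profiles)))
    recurse(left, depth + 1)
    recurse(right, depth + 1)
  }
  recurse(samples, 1)
  structure(list(nodes = nodes, samples = samples),
            class = "regulation_tree")
}

#' Regulator-to-module scores from regulation trees
#'
#' `score(r, m)` sums, over the internal nodes of module m's tree at which
#' regulator r's empirical p is at most `p_threshold`, the node weight
#' (fraction of module samples at the node) times r's node separation
#' score. `summed_score` is the row sum over modules.
#'
#' @param trees named list of `regulation_tree`s, one per module.
#' @param p_threshold node-significance cutoff (default 0.05).
#' @return a `regulator_score`: list with `score` (regulator x module
#'   matrix) and `summed_score`.
#' @export
score_regulators <- function(trees, p_threshold = 0.05) {
  stopifnot(length(trees) >= 1)
  regs <- names(trees[[1]]$nodes[[1]]$score)
  if (is.null(regs)) {
    for (tr in trees)
      for (nd in tr$nodes) if (!is.null(names(nd$score)))
        regs <- names(nd$score)
  }
  score <- matrix(0, length(regs), length(trees),
                  dimnames = list(regs, names(trees)))
  for (m in seq_along(trees)) {
    for (nd in trees[[m]]$nodes) {
      sig <- nd$emp_p <= p_threshold
      score[, m] <- score[, m] + nd$weight * nd$score * sig
    }
  }
  structure(list(score = score, summed_score = rowSums(score)),
            class = "regulator_score")
}

#' Select drivers from regulator scores by quantile rules
#'
#' Union of (a) per module, the top `ceiling(per_module_q * R)` regulators
#' by that module's score, zero scores excluded, boundary ties all kept;
#' and (b) the top `ceiling(global_q * R)` regulators by summed score
#' (likewise). Each driver records which rule selected it.
#'
#' @param scores a `regulator_score`.
#' @param per_module_q per-module quantile (default 0.01, the "top 1%").
#' @param global_q summed-score quantile (default 0.10, the "top 10%").
#' @return a `driver_list`: `drivers` data frame (`id`, `summed_score`,
#'   `n_modules_regulated`, `rule`), `per_module_selected` (list of id
#'   vectors), `global_selected`.
#' @export
select_drivers <- function(scores, per_module_q = 0.01, global_q = 0.10) {
  sc <- scores$score
  R <- nrow(sc)
  stopifnot(R >= 1)
  top_with_ties <- function(v, k) {
    pos <- v > 0
    if (!any(pos) || k < 1) return(character(0))
    vv <- sort(v[pos], decreasing = TRUE)
    cut <- vv[min(k, length(vv))]
    names(v)[pos & v >= cut]
  }
  k_m <- ceiling(per_module_q * R)
  per_module_selected <- lapply(seq_len(ncol(sc)), function(m)
    top_with_ties(sc[, m], k_m))
  names(per_module_selected) <- colnames(sc)
  global_selected <- top_with_ties(scores$summed_score,
                                   ceiling(global_q * R))
  ids <- union(unlist(per_module_selected), global_selected)
  n_mod <- vapply(ids, function(id)
    sum(vapply(per_module_selected, function(s) id %in% s, TRUE)), 0L)
  rule <- ifelse(ids %in% global_selected & n_mod > 0, "both",
                 ifelse(ids %in% global_selected, "global", "per_module"))
  drivers <- data.frame(id = ids,
                        summed_score = scores$summed_score[ids],
                        n_modules_regulated = n_mod, rule = rule,
                        row.names = NULL)
  drivers <- drivers[order(-drivers$summed_score), , drop = FALSE]
  rownames(drivers) <- NULL
  structure(list(drivers = drivers,
                 per_module_selected = per_module_selected,
                 global_selected = global_selected),
            class = "driver_list")
}

#' Number of modules each driver regulates
#'
#' Counts, per driver, the modules where it passed the per-module selection
#' rule; drivers selected only by the global rule report 0.
#'
#' @param driver_list a `driver_list` from [select_drivers()].
#' @return named integer vector over drivers.
#' @export
driver_module_counts <- function(driver_list) {
  setNames(driver_list$drivers$n_modules_regulated,
           driver_list$drivers$id)
}

#' Run the integrated driver-discovery pipeline on a cohort
#'
#' Differential expression selects the downstream genes; the Gibbs sampler
#' and chain consensus infer co-expression modules over tumor samples;
#' per-platform selectors assemble the candidate regulators; regulation
#' trees score every candidate against every module; the quantile rules
#' call drivers.
#'
#' @param cohort an `omics_cohort`.
#' @param alpha FDR for differential expression and the platform selectors.
#' @param n_modules,n_chains,n_iter,n_sample_blocks Gibbs parameters.
#' @param co_clustering_threshold,min_module_size consensus parameters.
#' @param max_depth,n_rand regulation-tree parameters.
#' @param per_module_q,global_q driver-selection quantiles.
#' @param min_mut_freq,min_cnv_freq frequency surrogates for the mutation
#'   and copy-number selectors.
#' @param candidates optional precomputed `candidate_set`; when supplied
#'   the platform selectors are skipped.
#' @param seed integer seed.
#' @return list: `de`, `chains`, `modules`, `candidates`, `trees`,
#'   `scores`, `drivers`, `module_mean`.
#' @export
run_driver_pipeline <- function(cohort, alpha = 0.05,
                                n_modules = 10, n_chains = 10,
                                n_iter = 100, n_sample_blocks = 2,
                                co_clustering_threshold = 0.8,
                                min_module_size = 5,
                                max_depth = 3, n_rand = 100,
                                per_module_q = 0.01, global_q = 0.10,
                                min_mut_freq = 0.02, min_cnv_freq = 0.1,
                                candidates = NULL, seed = 1L) {
  seeds <- stage_seeds(seed, 3L)
  tumors <- cohort$sample_ids[cohort$is_tumor]

  de <- differential_expression(cohort$expression, cohort$is_tumor, alpha)
  de_genes <- de$gene[de$significant]
  expr_de <- cohort$expression[de_genes, tumors, drop = FALSE]

  chains <- gibbs_cluster(expr_de, n_modules = n_modules,
                          n_sample_blocks = n_sample_blocks,
                          n_chains = n_chains, n_iter = n_iter,
                          seed = seeds[1])
  modules <- consensus_modules(chains, co_clustering_threshold,
                               min_module_size)

  if (is.null(candidates)) {
    mut <- tryCatch(
      mutation_candidates(cohort$mutation, min_frequency = min_mut_freq),
      warning = function(w) character(0))
    cn <- cnv_candidates(cohort$cnv, min_frequency = min_cnv_freq)
    meth <- differential_methylation(cohort$methylation, cohort$expression,
                                     cohort$is_tumor, alpha = alpha)
    mir <- mirna_candidates(cohort$mirna[, tumors, drop = FALSE],
                            cohort$expression[, tumors, drop = FALSE],
                            cohort$interactions, alpha = alpha)
    candidates <- assemble_candidates(
      cohort, mutation = mut, cnv_amp = cn$amp, cnv_del = cn$del,
      methylation = meth, mirna = mir$candidates,
      tf_list = cohort$tf_list)
  }
  if (nrow(candidates$entries) == 0 || modules$n_modules == 0)
    return(list(de = de, chains = chains, modules = modules,
                candidates = candidates, trees = list(), scores = NULL,
                drivers = structure(list(
                  drivers = data.frame(id = character(),
                                       summed_score = numeric(),
                                       n_modules_regulated = integer(),
                                       rule = character()),
                  per_module_selected = list(),
                  global_selected = character()), class = "driver_list")))

  xstd <- standardize_rows(expr_de)
  trees <- lapply(seq_len(modules$n_modules), function(m) {
    gi <- names(modules$module_of_gene)[modules$module_of_gene == m]
    mm <- colMeans(xstd[gi, , drop = FALSE])
    fit_regulation_tree(mm, candidates$profiles, max_depth = max_depth,
                        n_rand = n_rand, seed = seeds[2] + m)
  })
  names(trees) <- paste0("M", seq_len(modules$n_modules))
  trees <- trees[vapply(trees, function(t) length(t$nodes) > 0, TRUE)]
  if (length(trees) == 0)
    stop("run_driver_pipeline: no module produced a regulation tree")
  scores <- score_regulators(trees)
  drivers <- select_drivers(scores, per_module_q, global_q)
  list(de = de, chains = chains, modules = modules,
       candidates = candidates, trees = trees, scores = scores,
       drivers = drivers)
}

#' Driver selection restricted to a single platform
#'
#' Restricts the fitted candidate scores to one platform's entries and
#' re-applies the selection rules. Because regulation-tree splits are
#' defined by the module mean alone, the restricted run is identical to an
#' integrated run that had only that platform's candidates.
#'
#' @param fit result of [run_driver_pipeline()].
#' @param platform one of `"mutation"`, `"cnv"`, `"methylation"`,
#'   `"mirna"`, `"mrna"`.
#' @param per_module_q,global_q selection quantiles.
#' @return a `driver_list` (empty if the platform has no candidates).
#' @export
run_single_platform <- function(fit, platform,
                                per_module_q = 0.01, global_q = 0.10) {
  tags <- switch(platform,
                 mutation = "mutation",
                 cnv = c("cnv_amp", "cnv_del"),
                 methylation = "methylation",
                 mirna = "mirna",
                 mrna = c("tf", "literature"),
                 stop("run_single_platform: unknown platform ", platform))
  ent <- fit$candidates$entries
  keep <- paste(ent$id, ent$platform, sep = "|")[ent$platform %in% tags]
  keep <- intersect(keep, rownames(fit$scores$score))
  if (length(keep) == 0)
    return(structure(list(drivers = data.frame(id = character(),
                                               summed_score = numeric(),
                                               n_modules_regulated = integer(),
                                               rule = character()),
                          per_module_selected = list(),
                          global_selected = character()),
                     class = "driver_list"))
  sub <- structure(list(score = fit$scores$score[keep, , drop = FALSE],
                        summed_score = fit$scores$summed_score[keep]),
                   class = "regulator_score")
  select_drivers(sub, per_module_q, global_q)
}
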