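#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimal Lee-Seung Frobenius NMF used as the base clusterer for
#' non-negative platform matrices; cluster labels are the argmax rows of
#' the coefficient matrix.
#'
#' @param x non-negative feature-by-sample matrix.
#' @param k factorization rank.
#' @param n_iter multiplicative update iterations (default 100).
#' @param eps numerical floor.
#' @return list `W` (features x k), `H` (k x samples), `labels` (argmax of
#'   H per sample).
#' @export
nmf_factorize <- function(x, k, n_iter = 100, eps = 1e-9) {
  stopifnot(all(x >= 0), k >= 1)
  f <- nrow(x); s <- ncol(x)
  W <- matrix(runif(f * k, eps, 1), f, k)
  H <- matrix(runif(k * s, eps, 1), k, s)
  for (i in seq_len(n_iter)) {
    H <- H * (crossprod(W, x) / pmax(crossprod(W) %*% H, eps))
    W <- W * (x %*% t(H)) / pmax(W %*% tcrossprod(H), eps)
  }
  list(W = W, H = H, labels = apply(H, 2, which.max))
}

# consensus matrix from subsampled clusterings: entry (i,j) is the
# co-clustering frequency among resamples in which both i and j were drawn
consensus_from_resamples <- function(n, k, n_resamples, subsample,
                                     cluster_fun) {
  hits <- matrix(0, n, n)
  both <- matrix(0, n, n)
  m <- max(2, floor(subsample * n))
  for (r in seq_len(n_resamples)) {
    idx <- sort(sample.int(n, m))
    lab <- cluster_fun(idx, k)
    ii <- outer(lab, lab, "==")
    hits[idx, idx] <- hits[idx, idx] + ii
    both[idx, idx] <- both[idx, idx] + 1
  }
  cons <- ifelse(both > 0, hits / both, 0)
  diag(cons) <- 1
  cons
}

#' Consensus clustering of one molecular platform
#'
#' Repeated subsampled clustering (NMF for non-negative matrices, k-means
#' on standardized features otherwise) over a range of cluster numbers.
#' For each k the consensus matrix of co-clustering frequencies is formed;
#' k is chosen by the maximal cophenetic correlation between 1 - consensus
#' and its average-linkage dendrogram, and final labels come from cutting
#' that dendrogram at the chosen k.
#'
#' @param x feature-by-sample matrix (features restricted to driver genes
#'   in the intended use).
#' @param k_range candidate cluster numbers (default 2:6).
#' @param n_resamples subsampled clusterings per k (default 100).
#' @param subsample fraction of samples drawn per resample (default 0.8).
#' @param method `"auto"` (NMF when the matrix is non-negative, else
#'   k-means), `"kmeans"`, or `"nmf"`.
#' @param seed integer seed.
#' @return a `platform_clustering`: `labels` (named), `k`, `consensus`
#'   matrix, `cophenetic` per candidate k.
#' @export
consensus_cluster_platform <- function(x, k_range = 2:6,
                                       n_resamples = 100, subsample = 0.8,
                                       method = c("auto", "kmeans", "nmf"),
                                       seed = 1L) {
  method <- match.arg(method)
  n <- ncol(x)
  if (max(k_range) >= n)
    stop("consensus_cluster_platform: k must be below the sample count")
  if (method == "auto")
    method <- if (all(x >= 0)) "nmf" else "kmeans"
  xs <- if (method == "kmeans") standardize_rows(x) else x
  cluster_fun <- function(idx, k) {
    sub <- xs[, idx, drop = FALSE]
    if (method == "nmf") nmf_factorize(sub, k)$labels
    else kmeans(t(sub), centers = k, nstart = 2)$cluster
  }
  set.seed(seed)
  coph <- setNames(numeric(length(k_range)), k_range)
  consensus <- list()
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    cons <- consensus_from_resamples(n, k, n_resamples, subsample,
                                     cluster_fun)
    d <- as.dist(1 - cons)
    hc <- hclust(d, method = "average")
    coph[i] <- suppressWarnings(cor(cophenetic(hc), d))
    if (is.na(coph[i])) coph[i] <- 0 # degenerate (all-identical) distances
    consensus[[i]] <- cons
  }
  best <- which.max(coph)
  k <- k_range[best]
  cons <- consensus[[best]]
  dimnames(cons) <- list(colnames(x), colnames(x))
  hc <- hclust(as.dist(1 - cons), method = "average")
  labels <- setNames(cutree(hc, k = k), colnames(x))
  structure(list(labels = labels, k = k, consensus = cons,
                 cophenetic = coph, method = method),
            class = "platform_clustering")
}

# area under the empirical CDF of the upper-triangle consensus entries
consensus_cdf_area <- function(cons) {
  v <- sort(cons[upper.tri(cons)])
  n <- length(v)
  xs <- c(v, 1)
  sum(diff(c(0, xs)) * (seq_len(n + 1) - 1) / n)
}

#' Cluster-of-clusters (COCA) consensus subtyping
#'
#' Per-platform cluster labels are encoded as a binary sample-by-cluster
#' indicator matrix (samples missing a platform get an all-zero block).
#' The indicator matrix is consensus-clustered over a range of k; k is
#' chosen by the consensus-CDF criterion (largest k whose relative
#' delta-area exceeds `delta_threshold`), and final subclasses come from
#' the average-linkage cut of that consensus matrix. A single platform
#' input returns that platform's labels unchanged.
#'
#' @param clusterings list of per-platform label vectors (named by sample)
#'   or `platform_clustering` objects.
#' @param k_range candidate subclass numbers (default 2:8).
#' @param n_resamples,subsample consensus resampling parameters.
#' @param delta_threshold relative delta-area threshold (default 0.025).
#' @param seed integer seed.
#' @return a `subtype_assignment`: `coca_labels`, `k`, `indicator`,
#'   `cdf_area` and `delta_area` per candidate k, `consensus`.
#' @export
coca <- function(clusterings, k_range = 2:8, n_resamples = 100,
                 subsample = 0.8, delta_threshold = 0.025, seed = 1L) {
  stopifnot(length(clusterings) >= 1)
  labs <- lapply(clusterings, function(cl)
    if (inherits(cl, "platform_clustering")) cl$labels else cl)
  samples <- sort(unique(unlist(lapply(labs, names))))
  if (length(clusterings) == 1) {
    l <- labs[[1]]
    return(structure(list(coca_labels = l, k = length(unique(l)),
                          indicator = NULL, cdf_area = NULL,
                          delta_area = NULL, consensus = NULL),
                     class = "subtype_assignment"))
  }
  blocks <- lapply(seq_along(labs), function(p) {
    l <- labs[[p]]
    ks <- sort(unique(l))
    ind <- matrix(0L, length(samples), length(ks),
                  dimnames = list(samples,
                                  paste0("P", p, "C", ks)))
    present <- samples %in% names(l)
    if (any(!present))
      message("coca: ", sum(!present),
              " samples missing platform ", p, "; zero indicator block")
    ind[cbind(match(names(l), samples), match(l, ks))] <- 1L
    ind
  })
  indicator <- do.call(cbind, blocks)
  x <- t(indicator) # clusters-by-samples feature matrix
  n <- ncol(x)
  k_range <- k_range[k_range < n]
  # average-linkage hierarchical clustering as the base clusterer: cutting
  # an over-specified k peels outliers instead of bisecting tight groups,
  # which keeps the consensus matrix crisp beyond the true k
  cluster_fun <- function(idx, k)
    cutree(hclust(dist(t(x[, idx, drop = FALSE])), method = "average"),
           k = k)
  set.seed(seed)
  areas <- setNames(numeric(length(k_range)), k_range)
  consensus <- list()
  for (i in seq_along(k_range)) {
    cons <- consensus_from_resamples(n, k_range[i], n_resamples, subsample,
                                     cluster_fun)
    areas[i] <- consensus_cdf_area(cons)
    consensus[[i]] <- cons
  }
  delta <- c(areas[1], diff(areas) / areas[-length(areas)])
  names(delta) <- k_range
  ok <- which(delta > delta_threshold)
  best <- if (length(ok)) max(ok) else 1L
  k <- k_range[best]
  cons <- consensus[[best]]
  dimnames(cons) <- list(samples, samples)
  hc <- hclust(as.dist(1 - cons), method = "average")
  labels <- setNames(cutree(hc, k = k), samples)
  structure(list(coca_labels = labels, k = k, indicator = indicator,
                 cdf_area = areas, delta_area = delta, consensus = cons),
            class = "subtype_assignment")
}

#' Kaplan-Meier product-limit estimate
#'
#' @param records data frame with columns `time` (>= 0) and `event`
#'   (1 = event observed, 0 = censored).
#' @return data frame `time`, `n_risk`, `n_event`, `surv` at the distinct
#'   event/censoring times (via [survival::survfit()]).
#' @export
kaplan_meier <- function(records) {
  stopifnot(nrow(records) >= 1)
  if (any(records$time < 0)) stop("kaplan_meier: negative time")
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1, data = records)
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv)
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected statistic over distinct event times;
#' degrees of freedom = groups - 1. With no events at all the statistic is
#' 0 and p = 1.
#'
#' @param records data frame with `time`, `event`, and `group`.
#' @return list `chisq`, `df`, `p`.
#' @export
logrank_test <- function(records) {
  groups <- unique(records$group)
  stopifnot(length(groups) >= 2)
  df <- length(groups) - 1
  if (sum(records$event) == 0)
    return(list(chisq = 0, df = df, p = 1))
  sd <- survival::survdiff(
    survival::Surv(time, event) ~ group, data = records)
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Associate subtype labels with clinical variables
#'
#' Fisher's exact test for categorical variables (exact for 2x2; the
#' network algorithm, with a Monte-Carlo fallback, for larger tables) and
#' a one-way ANOVA F test for continuous variables, with BH correction
#' across variables. Variables with a single level (or zero variance) are
#' skipped and flagged.
#'
#' @param labels named subtype labels per sample.
#' @param clinical data frame with row-identifying column `sample`.
#' @param types named character vector mapping variable name to
#'   `"categorical"` or `"continuous"`.
#' @return data frame `variable`, `type`, `statistic`, `p`, `q`, `note`.
#' @export
associate_clinical <- function(labels, clinical, types) {
  stopifnot("sample" %in% colnames(clinical))
  idx <- match(clinical$sample, names(labels))
  keep <- !is.na(idx)
  cl <- clinical[keep, , drop = FALSE]
  grp <- factor(labels[idx[keep]])
  rows <- lapply(names(types), function(v) {
    x <- cl[[v]]
    if (types[[v]] == "categorical") {
      x <- factor(x)
      if (nlevels(x) < 2 || nlevels(grp) < 2)
        return(data.frame(variable = v, type = "categorical",
                          statistic = NA_real_, p = NA_real_,
                          note = "single level; skipped"))
      tab <- table(grp, x)
      ft <- tryCatch(fisher.test(tab),
                     error = function(e)
                       fisher.test(tab, simulate.p.value = TRUE,
                                   B = 10000))
      data.frame(variable = v, type = "categorical", statistic = NA_real_,
                 p = ft$p.value, note = "")
    } else {
      if (sd(x) == 0 || nlevels(grp) < 2)
        return(data.frame(variable = v, type = "continuous",
                          statistic = NA_real_, p = NA_real_,
                          note = "degenerate; skipped"))
      a <- anova(lm(x ~ grp))
      data.frame(variable = v, type = "continuous",
                 statistic = a$`F value`[1], p = a$`Pr(>F)`[1], note = "")
    }
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  tested <- !is.na(out$p)
  out$q[tested] <- adjust_bh(out$p[tested])
  out[, c("variable", "type", "statistic", "p", "q", "note")]
}
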