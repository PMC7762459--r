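#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT (name, description, genes...), via
#' [fgsea::gmtPathways()]. Empty sets are dropped, ids de-duplicated
#' within a set.
#'
#' @param path GMT file path.
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, unique)
  sets[lengths(sets) > 0]
}

#' Single-sample gene-set enrichment score (ssGSEA)
#'
#' Genes are ranked by expression (descending). The running sum gains
#' `|value|^weight_exponent`, normalized over the in-set genes, at each
#' set gene, and drops `1/(N - n_set)` at each non-set gene; the
#' enrichment score is the sum of the running-sum deviations (the
#' integrated form). With `weight_exponent = 0` the score depends only on
#' the ranking.
#'
#' @param expr named expression vector for one sample.
#' @param gene_set character vector of gene ids.
#' @param weight_exponent rank-weighting exponent (default 0.75).
#' @return scalar enrichment score.
#' @export
ssgsea <- function(expr, gene_set, weight_exponent = 0.75) {
  stopifnot(!is.null(names(expr)))
  inset <- names(expr) %in% gene_set
  if (!any(inset))
    stop("ssgsea: gene set does not intersect the expression genes")
  if (all(inset))
    stop("ssgsea: gene set covers every gene; no background remains")
  o <- order(expr, decreasing = TRUE)
  v <- expr[o]; hit <- inset[o]
  w <- abs(v)^weight_exponent
  inc <- ifelse(hit, w, 0)
  inc <- inc / sum(inc)
  dec <- ifelse(hit, 0, 1 / sum(!hit))
  sum(cumsum(inc - dec))
}

#' ssGSEA across all samples of an expression matrix
#'
#' @param expr gene-by-sample matrix.
#' @param gene_sets named list of gene-id vectors.
#' @param weight_exponent see [ssgsea()].
#' @return set-by-sample matrix of enrichment scores.
#' @export
ssgsea_matrix <- function(expr, gene_sets, weight_exponent = 0.75) {
  out <- vapply(colnames(expr), function(s)
    vapply(gene_sets, function(gs)
      ssgsea(setNames(expr[, s], rownames(expr)), gs, weight_exponent),
      0), numeric(length(gene_sets)))
  matrix(out, nrow = length(gene_sets),
         dimnames = list(names(gene_sets), colnames(expr)))
}

#' Four-way subgrouping by E2F expression and TP53 mutation
#'
#' The E2F score is the mean of the standardized E2F1/E2F2 expression
#' rows; samples above the cohort median are E2F-high. Crossing with the
#' TP53 mutation indicator yields the four groups TP53m.E2Fh, TP53m.E2Fl,
#' TP53w.E2Fh, TP53w.E2Fl. When a pathway-activity vector is supplied,
#' all pairwise Wilcoxon rank-sum comparisons between groups are
#' reported.
#'
#' @param e2f1,e2f2 named expression vectors over tumors.
#' @param tp53_mutated named binary/logical vector (NA = unknown; such
#'   samples are excluded with a message).
#' @param es optional named pathway enrichment-score vector.
#' @return list: `labels` (named factor), `es_by_group` (medians, when
#'   `es` given), `comparisons` (pairwise Wilcoxon table, when `es`
#'   given).
#' @export
subgroup_e2f_tp53 <- function(e2f1, e2f2, tp53_mutated, es = NULL) {
  samples <- intersect(names(e2f1), names(tp53_mutated))
  known <- samples[!is.na(tp53_mutated[samples])]
  if (length(known) < length(samples))
    message("subgroup_e2f_tp53: ",
            length(samples) - length(known),
            " samples lack TP53 status; excluded")
  z <- function(x) (x - mean(x)) / sd(x)
  score <- (z(e2f1[known]) + z(e2f2[known])) / 2
  high <- score > median(score)
  mut <- tp53_mutated[known] != 0
  labels <- factor(paste0(ifelse(mut, "TP53m", "TP53w"),
                          ".", ifelse(high, "E2Fh", "E2Fl")),
                   levels = c("TP53m.E2Fh", "TP53m.E2Fl",
                              "TP53w.E2Fh", "TP53w.E2Fl"))
  names(labels) <- known
  out <- list(labels = labels)
  if (!is.null(es)) {
    es <- es[known]
    out$es_by_group <- tapply(es, labels, median)
    grps <- levels(droplevels(labels))
    cmp <- list()
    for (i in seq_along(grps)) for (j in seq_along(grps))
      if (i < j) {
        xi <- es[labels == grps[i]]; xj <- es[labels == grps[j]]
        p <- suppressWarnings(wilcox.test(xi, xj)$p.value)
        cmp[[paste(grps[i], grps[j])]] <-
          data.frame(group1 = grps[i], group2 = grps[j],
                     n1 = length(xi), n2 = length(xj), p = p)
      }
    out$comparisons <- do.call(rbind, c(cmp, list(make.row.names = FALSE)))
  }
  out
}

#' One-sided mutual-exclusivity test for two binary alteration events
#'
#' Under independence the co-occurrence probability is the product of the
#' marginal frequencies; the p-value is the lower binomial tail
#' `P(X <= k)` of the observed co-occurrence count, so small p means fewer
#' co-occurrences than expected (exclusivity). A permutation alternative
#' shuffles one event vector.
#'
#' @param events_a,events_b binary/logical vectors on the same samples.
#' @param method `"binomial"` (default) or `"permutation"`.
#' @param n_perm permutations when `method = "permutation"`.
#' @return list: `p`, `observed` co-occurrences, `expected`, `n`.
#' @export
mutual_exclusivity <- function(events_a, events_b,
                               method = c("binomial", "permutation"),
                               n_perm = 10000) {
  method <- match.arg(method)
  stopifnot(length(events_a) == length(events_b))
  a <- as.logical(events_a); b <- as.logical(events_b)
  n <- length(a)
  fa <- mean(a); fb <- mean(b)
  k <- sum(a & b)
  if (fa == 0 || fb == 0) {
    warning("mutual_exclusivity: zero-frequency event; p = 1",
            call. = FALSE)
    return(list(p = 1, observed = k, expected = n * fa * fb, n = n))
  }
  p <- if (method == "binomial") {
    pbinom(k, n, fa * fb)
  } else {
    hits <- vapply(seq_len(n_perm),
                   function(i) sum(a & sample(b)) <= k, TRUE)
    (1 + sum(hits)) / (n_perm + 1)
  }
  list(p = p, observed = k, expected = n * fa * fb, n = n)
}

#' Over-representation analysis against a gene-set collection
#'
#' One-sided hypergeometric upper-tail test per set, BH-corrected across
#' sets. Sets disjoint from the background are skipped.
#'
#' @param query character vector of gene ids (must lie in the
#'   background).
#' @param gene_sets named list of gene-id vectors.
#' @param background character vector of background gene ids.
#' @return data frame `set`, `set_size`, `overlap`, `p`, `q`.
#' @export
ora <- function(query, gene_sets, background) {
  stopifnot(all(query %in% background))
  N <- length(background)
  n <- length(unique(query))
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], background)
    if (length(set) == 0) return(NULL)
    k <- length(intersect(query, set))
    p <- phyper(k - 1, length(set), N - length(set), n,
                lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = k, p = p)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(), set_size = integer(),
               overlap = integer(), p = numeric())
  out$q <- adjust_bh(out$p)
  out
}

#' Two-group rank tests
#'
#' Two-sided Wilcoxon rank-sum (exact when both groups have at most 8
#' values and no ties) or chi-square on a contingency table (no
#' continuity correction).
#'
#' @param x,y numeric group values (`wilcoxon`), or `x` a contingency
#'   table/matrix (`chi_square`, `y` ignored).
#' @param kind `"wilcoxon"` or `"chi_square"`.
#' @return list `statistic`, `p`.
#' @export
rank_tests <- function(x, y = NULL, kind = c("wilcoxon", "chi_square")) {
  kind <- match.arg(kind)
  if (kind == "wilcoxon") {
    if (length(x) < 1 || length(y) < 1)
      stop("rank_tests: empty group")
    ex <- length(x) <= 8 && length(y) <= 8
    wt <- suppressWarnings(wilcox.test(x, y, exact = ex))
    list(statistic = unname(wt$statistic), p = wt$p.value)
  } else {
    ct <- suppressWarnings(chisq.test(x, correct = FALSE))
    list(statistic = unname(ct$statistic), p = ct$p.value)
  }
}
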