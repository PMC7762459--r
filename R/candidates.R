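#' Differential expression between tumor and normal samples
#'
#' Per-gene Welch two-sample t test on log2 expression with
#' Benjamini-Hochberg FDR control. Genes with zero variance in both groups
#' are flagged degenerate and assigned p = 1.
#'
#' @param expr gene-by-sample log2 expression matrix.
#' @param tumor_flags logical vector over columns (TRUE = tumor).
#' @param alpha FDR threshold for the significance flag (default 0.05).
#' @return data frame: `gene`, `t`, `lfc` (mean log2 fold-change
#'   tumor - normal), `p`, `q`, `significant`, `direction` (up/down/na),
#'   `degenerate`.
#' @export
differential_expression <- function(expr, tumor_flags, alpha = 0.05) {
  stopifnot(length(tumor_flags) == ncol(expr))
  if (sum(tumor_flags) < 2 || sum(!tumor_flags) < 2)
    stop("differential_expression: need >= 2 tumors and >= 2 normals")
  if (is.null(rownames(expr)))
    rownames(expr) <- sprintf("gene%d", seq_len(nrow(expr)))
  xt <- expr[, tumor_flags, drop = FALSE]
  xn <- expr[, !tumor_flags, drop = FALSE]
  n1 <- ncol(xt); n2 <- ncol(xn)
  m1 <- rowMeans(xt); m2 <- rowMeans(xn)
  v1 <- apply(xt, 1, var); v2 <- apply(xn, 1, var)
  se2 <- v1 / n1 + v2 / n2
  degenerate <- se2 == 0
  tstat <- ifelse(degenerate, 0, (m1 - m2) / sqrt(pmax(se2, .Machine$double.eps)))
  df <- ifelse(degenerate, 1,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)))
  p <- 2 * pt(-abs(tstat), df)
  p[degenerate] <- 1
  q <- adjust_bh(p)
  lfc <- m1 - m2
  data.frame(gene = rownames(expr), t = tstat, lfc = lfc, p = p, q = q,
             significant = q < alpha & !degenerate,
             direction = ifelse(degenerate | lfc == 0, "na",
                                ifelse(lfc > 0, "up", "down")),
             degenerate = degenerate, row.names = NULL)
}

# fit a 1-3 component mixture to a vector of beta values, BIC-selected;
# falls back to a Gaussian mixture on logit-beta if EM on beta fails
mclust_fit <- function(v) {
  bic <- mclust::mclustBIC(v, G = 1:3, modelNames = c("E", "V"),
                           verbose = FALSE)
  mclust::Mclust(v, x = bic, verbose = FALSE)
}

fit_beta_mixture <- function(b) {
  fit <- tryCatch(mclust_fit(b), error = function(e) NULL)
  if (!is.null(fit)) return(list(means = as.numeric(fit$parameters$mean)))
  eps <- 1e-4
  lb <- logit(pmin(pmax(b, eps), 1 - eps))
  fit <- tryCatch(mclust_fit(lb), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  list(means = expit(as.numeric(fit$parameters$mean)))
}

#' Differentially methylated, transcriptionally predictive genes
#'
#' Simplified beta-mixture screen: per gene, a 1-3 component mixture
#' (BIC-selected) is fitted to tumor beta values; the gene is
#' hyper-/hypo-methylated if some component mean deviates from the normal
#' mean by at least `min_delta_beta`. "Transcriptionally predictive"
#' additionally requires a negative Spearman correlation between beta and
#' expression across tumors with BH q below `alpha`.
#'
#' @param beta gene-by-sample methylation beta matrix.
#' @param expr matched gene-by-sample log2 expression matrix (same genes).
#' @param tumor_flags logical over columns of both matrices.
#' @param alpha FDR threshold for the predictivity filter.
#' @param min_delta_beta minimum component-vs-normal beta difference.
#' @return data frame of candidates: `gene`, `direction`
#'   (hyper/hypo), `delta_beta`, `rho`, `p`, `q`.
#' @export
differential_methylation <- function(beta, expr, tumor_flags,
                                     alpha = 0.05, min_delta_beta = 0.1) {
  common <- intersect(rownames(beta), rownames(expr))
  if (length(common) == 0)
    stop("differential_methylation: no shared genes between beta and expr")
  beta <- beta[common, , drop = FALSE]
  expr <- expr[common, , drop = FALSE]
  bt <- beta[, tumor_flags, drop = FALSE]
  bn <- beta[, !tumor_flags, drop = FALSE]
  et <- expr[, tumor_flags, drop = FALSE]
  rows <- list()
  for (g in common) {
    b <- bt[g, ]
    if (sd(b) == 0) {
      warning("differential_methylation: constant beta for ", g,
              "; skipped", call. = FALSE)
      next
    }
    mix <- fit_beta_mixture(b)
    if (is.null(mix)) next
    dev <- mix$means - mean(bn[g, ])
    i <- which.max(abs(dev))
    if (abs(dev[i]) < min_delta_beta) next
    ct <- suppressWarnings(
      cor.test(b, et[g, ], method = "spearman",
               exact = length(b) <= 9, alternative = "less"))
    rows[[g]] <- data.frame(
      gene = g, direction = if (dev[i] > 0) "hyper" else "hypo",
      delta_beta = dev[i], rho = unname(ct$estimate), p = ct$p.value)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), direction = character(),
               delta_beta = numeric(), rho = numeric(), p = numeric())
  out$q <- adjust_bh(out$p)
  out <- out[out$rho < 0 & out$q < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' miRNA candidates from negative miRNA-target correlation
#'
#' Spearman correlation for every annotated miRNA-target pair across the
#' shared samples; pairs with negative rho and BH q below `alpha` are kept,
#' and a miRNA is a candidate if it retains at least one pair.
#'
#' @param mirna_expr miRNA-by-sample expression matrix.
#' @param mrna_expr gene-by-sample expression matrix.
#' @param interactions data frame with columns `mirna`, `target`.
#' @param alpha FDR threshold.
#' @return list: `candidates` (miRNA ids), `pairs` (per-pair table with
#'   `rho`, `p`, `q`, `kept`), `skipped` (interactions with unknown ids).
#' @export
mirna_candidates <- function(mirna_expr, mrna_expr, interactions,
                             alpha = 0.05) {
  stopifnot(all(c("mirna", "target") %in% colnames(interactions)))
  samp <- intersect(colnames(mirna_expr), colnames(mrna_expr))
  known <- interactions$mirna %in% rownames(mirna_expr) &
    interactions$target %in% rownames(mrna_expr)
  skipped <- interactions[!known, , drop = FALSE]
  if (nrow(skipped) > 0)
    message("mirna_candidates: skipped ", nrow(skipped),
            " interactions with unknown ids")
  ia <- unique(interactions[known, c("mirna", "target")])
  if (nrow(ia) == 0)
    return(list(candidates = character(), pairs = ia, skipped = skipped))
  res <- t(vapply(seq_len(nrow(ia)), function(i) {
    x <- mirna_expr[ia$mirna[i], samp]
    y <- mrna_expr[ia$target[i], samp]
    if (sd(x) == 0 || sd(y) == 0) return(c(NA_real_, 1))
    ct <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = length(x) <= 9))
    c(unname(ct$estimate), ct$p.value)
  }, numeric(2)))
  ia$rho <- res[, 1]
  ia$p <- res[, 2]
  ia$q <- adjust_bh(ia$p)
  ia$kept <- !is.na(ia$rho) & ia$rho < 0 & ia$q < alpha
  list(candidates = unique(ia$mirna[ia$kept]), pairs = ia,
       skipped = skipped)
}

#' Mutation candidates by recurrence frequency or external list
#'
#' When a precomputed list of significantly mutated genes is supplied (the
#' faithful path for real cohorts, where a covariate-aware background model
#' produced it), it is intersected with the matrix rows; otherwise genes
#' mutated in at least `min_frequency` of tumors are kept.
#'
#' @param mutation_matrix binary gene-by-tumor matrix.
#' @param min_frequency minimum mutated fraction of tumors (default 0.02).
#' @param external_list optional character vector of gene ids.
#' @return character vector of candidate genes.
#' @export
mutation_candidates <- function(mutation_matrix, min_frequency = 0.02,
                                external_list = NULL) {
  if (!is.null(external_list)) {
    out <- intersect(external_list, rownames(mutation_matrix))
  } else {
    freq <- rowMeans(mutation_matrix != 0)
    out <- rownames(mutation_matrix)[freq >= min_frequency]
  }
  if (length(out) == 0)
    warning("mutation_candidates: empty candidate set", call. = FALSE)
  out
}

#' Copy-number candidates by alteration frequency
#'
#' A gene is an amplification candidate if its state is >= +1 in at least
#' `min_frequency` of tumors, and a deletion candidate symmetrically; a gene
#' exceeding both thresholds appears in both lists.
#'
#' @param cnv_matrix integer-state gene-by-tumor matrix (states -2..2).
#' @param min_frequency minimum altered fraction (default 0.1).
#' @param external_regions optional list with elements `amp` and `del`
#'   (gene id vectors) from an external caller.
#' @return list with character vectors `amp` and `del`.
#' @export
cnv_candidates <- function(cnv_matrix, min_frequency = 0.1,
                           external_regions = NULL) {
  if (!is.null(external_regions)) {
    return(list(amp = intersect(external_regions$amp, rownames(cnv_matrix)),
                del = intersect(external_regions$del, rownames(cnv_matrix))))
  }
  famp <- rowMeans(cnv_matrix >= 1)
  fdel <- rowMeans(cnv_matrix <= -1)
  amp <- rownames(cnv_matrix)[famp >= min_frequency]
  del <- rownames(cnv_matrix)[fdel >= min_frequency]
  both <- intersect(amp, del)
  if (length(both) > 0)
    message("cnv_candidates: ", length(both),
            " genes pass both amplification and deletion thresholds")
  list(amp = amp, del = del)
}

#' Assemble the per-platform candidate lists into one regulator set
#'
#' Platform provenance is retained (a gene may carry several platform tags)
#' and each (id, platform) entry is given a profile row: the binary mutation
#' indicator, copy-number state, methylation beta, or miRNA expression for
#' the genomic platforms, and the expression row for TF / literature
#' candidates. Entries without any profile source are dropped with a
#' warning.
#'
#' @param cohort an `omics_cohort` (or any list with the same matrices).
#' @param mutation,cnv_amp,cnv_del character vectors of candidate ids.
#' @param methylation data frame from [differential_methylation()] or a
#'   character vector of gene ids.
#' @param mirna character vector of candidate miRNA ids.
#' @param tf_list,literature_list character vectors of gene ids whose
#'   expression profiles act as regulator covariates.
#' @return a `candidate_set`: list with `entries` (data frame `id`,
#'   `platform`, `direction`) and `profiles` (entry-by-tumor matrix whose
#'   row names are `id|platform`).
#' @export
assemble_candidates <- function(cohort, mutation = character(),
                                cnv_amp = character(),
                                cnv_del = character(),
                                methylation = character(),
                                mirna = character(),
                                tf_list = character(),
                                literature_list = character()) {
  tumors <- cohort$sample_ids[cohort$is_tumor]
  meth_ids <- if (is.data.frame(methylation)) methylation$gene else methylation
  meth_dir <- if (is.data.frame(methylation))
    setNames(methylation$direction, methylation$gene) else NULL
  entry_df <- function(ids, pf)
    data.frame(id = as.character(ids),
               platform = rep_len(pf, length(ids)))
  spec <- rbind(
    entry_df(mutation, "mutation"),
    entry_df(cnv_amp, "cnv_amp"),
    entry_df(cnv_del, "cnv_del"),
    entry_df(meth_ids, "methylation"),
    entry_df(mirna, "mirna"),
    entry_df(tf_list, "tf"),
    entry_df(literature_list, "literature"))
  spec <- unique(spec)
  if (nrow(spec) == 0)
    return(structure(list(entries = cbind(spec,
                                          direction = character(0)),
                          profiles = matrix(0, 0, length(tumors),
                                            dimnames = list(NULL, tumors))),
                     class = "candidate_set"))
  prof <- list(); keep <- logical(nrow(spec)); dirn <- character(nrow(spec))
  for (i in seq_len(nrow(spec))) {
    id <- spec$id[i]; pf <- spec$platform[i]
    row <- switch(pf,
      mutation = if (id %in% rownames(cohort$mutation))
        as.numeric(cohort$mutation[id, tumors] != 0),
      cnv_amp = ,
      cnv_del = if (id %in% rownames(cohort$cnv))
        as.numeric(cohort$cnv[id, tumors]),
      methylation = if (id %in% rownames(cohort$methylation))
        as.numeric(cohort$methylation[id, tumors]),
      mirna = if (id %in% rownames(cohort$mirna))
        as.numeric(cohort$mirna[id, tumors]),
      if (id %in% rownames(cohort$expression))
        as.numeric(cohort$expression[id, tumors]))
    if (is.null(row)) {
      warning("assemble_candidates: no profile source for ", id, " (",
              pf, "); dropped", call. = FALSE)
      keep[i] <- FALSE
    } else {
      keep[i] <- TRUE
      prof[[paste(id, pf, sep = "|")]] <- row
      dirn[i] <- switch(pf,
        cnv_amp = "up", cnv_del = "down",
        methylation = if (!is.null(meth_dir) && id %in% names(meth_dir) &&
                          meth_dir[[id]] == "hyper") "down" else "na",
        mirna = "down", "na")
    }
  }
  entries <- spec[keep, , drop = FALSE]
  entries$direction <- dirn[keep]
  rownames(entries) <- NULL
  profiles <- do.call(rbind, prof)
  if (is.null(profiles))
    profiles <- matrix(0, 0, length(tumors))
  colnames(profiles) <- tumors
  structure(list(entries = entries, profiles = profiles),
            class = "candidate_set")
}

#' Read a MAF-like table and collapse it to a binary gene-by-sample matrix
#'
#' Expects at least `Hugo_Symbol` and `Tumor_Sample_Barcode` columns;
#' `Variant_Classification` rows named "Silent" are ignored when present.
#'
#' @param path MAF file path (tab-separated, header).
#' @param samples optional sample universe for the columns.
#' @return binary integer matrix genes x samples.
#' @export
read_maf_matrix <- function(path, samples = NULL) {
  maf <- read.table(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, comment.char = "#")
  stopifnot(all(c("Hugo_Symbol", "Tumor_Sample_Barcode") %in% colnames(maf)))
  if ("Variant_Classification" %in% colnames(maf))
    maf <- maf[maf$Variant_Classification != "Silent", , drop = FALSE]
  genes <- sort(unique(maf$Hugo_Symbol))
  if (is.null(samples)) samples <- sort(unique(maf$Tumor_Sample_Barcode))
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  hit <- maf$Tumor_Sample_Barcode %in% samples
  m[cbind(match(maf$Hugo_Symbol[hit], genes),
          match(maf$Tumor_Sample_Barcode[hit], samples))] <- 1L
  m
}
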