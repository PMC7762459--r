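#' @useDynLib drivermod, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom mclust mclustBIC Mclust adjustedRandIndex
#' @importFrom stats pt p.adjust cor cor.test sd var median quantile rnorm
#'   runif rbinom rexp sample.int setNames aggregate kmeans hclust cutree
#'   as.dist cophenetic dist fisher.test wilcox.test chisq.test aov anova lm
#'   phyper pbinom dbinom plogis qnorm complete.cases
#' @importFrom utils read.table write.table head
NULL

#' Benjamini-Hochberg adjustment (shared implementation)
#'
#' All FDR control in the package routes through this wrapper around
#' [stats::p.adjust()] so that the step-up procedure is implemented (and
#' tested) exactly once.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted q-values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  stats::p.adjust(p, method = "BH")
}

logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

#' Derive a sequence of per-stage seeds from one global seed
#'
#' Stages of a simulation (expression, mutation, survival, ...) each receive
#' their own seed so a stage can be regenerated independently of the others.
#'
#' @param seed global integer seed.
#' @param n number of stage seeds required.
#' @return integer vector of length `n`, all below 2^31.
#' @export
stage_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement, used throughout to compare inferred partitions
#' with planted ground truth. Thin wrapper over
#' [mclust::adjustedRandIndex()].
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

# standardize matrix rows to mean 0, sd 1 (constant rows -> 0)
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  s[s == 0] <- 1
  sweep(sweep(x, 1, mu, "-"), 1, s, "/")
}

#' Read a genes-by-samples TSV matrix
#'
#' Row names in the first column, sample ids in the header.
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE)
  as.matrix(df)
}

#' Write a genes-by-samples matrix as TSV
#'
#' @param x matrix with row and column names.
#' @param path output file path.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
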