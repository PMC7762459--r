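#' Construct a fixed-width windowed signal track
#'
#' Windows are 0-based half-open, non-overlapping, sorted, of uniform
#' width; values are non-negative.
#'
#' @param chrom chromosome per window (recycled).
#' @param start,end 0-based half-open coordinates.
#' @param value non-negative signal per window.
#' @return data frame of class `signal_track`.
#' @export
signal_track <- function(chrom, start, end, value) {
  df <- data.frame(chrom = chrom, start = as.integer(start),
                   end = as.integer(end), value = as.numeric(value))
  w <- df$end - df$start
  if (any(w <= 0)) stop("signal_track: empty or negative-width window")
  if (length(unique(w)) > 1) stop("signal_track: window width not uniform")
  if (any(df$value < 0)) stop("signal_track: negative signal value")
  o <- order(df$chrom, df$start)
  df <- df[o, , drop = FALSE]
  same <- df$chrom[-1] == df$chrom[-nrow(df)]
  if (nrow(df) > 1 && any(same & df$start[-1] < df$end[-nrow(df)]))
    stop("signal_track: overlapping windows")
  rownames(df) <- NULL
  class(df) <- c("signal_track", "data.frame")
  df
}

track_granges <- function(track) {
  GenomicRanges::GRanges(track$chrom,
                         IRanges::IRanges(track$start + 1L, track$end))
}

#' Read a bedGraph file as a signal track
#'
#' @param path bedGraph path (chrom, 0-based half-open start/end, value).
#' @return a `signal_track`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  signal_track(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
               gr$score)
}

#' Write a signal track as bedGraph
#'
#' @param track a `signal_track`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  gr <- track_granges(track)
  gr$score <- track$value
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a BED3/BED4 file with per-line validation
#'
#' 0-based half-open intervals; the optional fourth column becomes the
#' `name` metadata (used for chromatin-state labels).
#'
#' @param path BED path.
#' @return a `GRanges` (1-based closed internally, converted from BED).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t")
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    ok <- length(f) >= 3 && !is.na(suppressWarnings(as.numeric(f[2]))) &&
      !is.na(suppressWarnings(as.numeric(f[3]))) &&
      as.numeric(f[2]) < as.numeric(f[3])
    if (!ok) stop("read_bed: malformed BED line ", i, " in ", path)
  }
  chrom <- vapply(fields, `[[`, "", 1)
  s <- as.integer(vapply(fields, `[[`, "", 2))
  e <- as.integer(vapply(fields, `[[`, "", 3))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s + 1L, e))
  if (all(lengths(fields) >= 4))
    gr$name <- vapply(fields, `[[`, "", 4)
  gr
}

#' Quantile-normalize signal tracks on a shared window grid
#'
#' Every track's values are replaced by the mean of the order statistics
#' across tracks at the matching rank (ties averaged), so the sorted value
#' vectors of all outputs are identical.
#'
#' @param tracks list of >= 2 `signal_track`s on identical windows.
#' @return list of normalized tracks.
#' @export
quantile_normalize <- function(tracks) {
  stopifnot(length(tracks) >= 2)
  grid <- tracks[[1]][, c("chrom", "start", "end")]
  for (t in tracks[-1])
    if (!identical(t[, c("chrom", "start", "end")], grid))
      stop("quantile_normalize: tracks are not on identical window grids")
  m <- do.call(cbind, lapply(tracks, `[[`, "value"))
  norm <- limma::normalizeQuantiles(m, ties = TRUE)
  out <- lapply(seq_along(tracks), function(i) {
    t <- tracks[[i]]
    t$value <- norm[, i]
    t
  })
  names(out) <- names(tracks)
  out
}

#' Remove windows overlapping blacklist or promoter intervals
#'
#' A window is removed when it overlaps any excluded interval by at least
#' 1 bp (half-open convention: `[100,150)` and `[150,200)` do not
#' overlap).
#'
#' @param track a `signal_track`.
#' @param blacklist,promoters optional `GRanges` (e.g., from
#'   [read_bed()]); `NULL` means no exclusion.
#' @return the filtered track.
#' @export
exclude_regions <- function(track, blacklist = NULL, promoters = NULL) {
  excl <- list(blacklist, promoters)
  excl <- excl[!vapply(excl, is.null, TRUE)]
  if (length(excl) == 0) return(track)
  gr <- track_granges(track)
  drop <- rep(FALSE, length(gr))
  for (e in excl)
    drop <- drop | IRanges::overlapsAny(gr, e)
  out <- track[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify windows into strong/weak enhancers from two histone marks
#'
#' A mark is "present" when the window value reaches the threshold
#' (default: the 75th percentile of the track's nonzero values). Windows
#' with both H3K4me1 and H3K27ac are strong enhancers, H3K4me1 only are
#' weak, anything else (including H3K27ac alone) is none. Adjacent windows
#' of the same non-none class are merged into regions.
#'
#' @param h3k4me1,h3k27ac `signal_track`s on the same grid, already
#'   filtered of promoters and blacklisted regions.
#' @param threshold_k4me1,threshold_k27ac absolute thresholds; `NULL` uses
#'   the per-track top quartile of nonzero values.
#' @return list: `windows` (the grid plus `class`), `regions` (merged
#'   data frame `chrom`, `start`, `end`, `class`).
#' @export
classify_enhancers <- function(h3k4me1, h3k27ac,
                               threshold_k4me1 = NULL,
                               threshold_k27ac = NULL) {
  stopifnot(identical(h3k4me1[, c("chrom", "start", "end")],
                      h3k27ac[, c("chrom", "start", "end")]))
  thr <- function(v, t) if (!is.null(t)) t else
    quantile(v[v > 0], 0.75, names = FALSE)
  k4 <- h3k4me1$value >= thr(h3k4me1$value, threshold_k4me1)
  k27 <- h3k27ac$value >= thr(h3k27ac$value, threshold_k27ac)
  cls <- ifelse(k4 & k27, "strong", ifelse(k4, "weak", "none"))
  win <- h3k4me1[, c("chrom", "start", "end")]
  win$class <- cls
  keep <- which(cls != "none")
  regions <- NULL
  if (length(keep) > 0) {
    w <- win[keep, , drop = FALSE]
    new_run <- c(TRUE, !(w$chrom[-1] == w$chrom[-nrow(w)] &
                           w$start[-1] == w$end[-nrow(w)] &
                           w$class[-1] == w$class[-nrow(w)]))
    run <- cumsum(new_run)
    regions <- data.frame(
      chrom = tapply(w$chrom, run, `[`, 1),
      start = as.integer(tapply(w$start, run, min)),
      end = as.integer(tapply(w$end, run, max)),
      class = tapply(w$class, run, `[`, 1), row.names = NULL)
  }
  list(windows = win, regions = regions)
}

#' Per-window differential enhancer status between tumor and normal
#'
#' Gain when `(tumor + eps) / (normal + eps) >= fold`, loss symmetrically,
#' else stable; the threshold is inclusive.
#'
#' @param tumor,normal normalized `signal_track`s on the same grid.
#' @param fold fold-change threshold (> 1, default 2).
#' @param pseudocount epsilon added to both values (default 1).
#' @return factor of gain/loss/stable per window.
#' @export
enhancer_differential <- function(tumor, normal, fold = 2,
                                  pseudocount = 1) {
  if (fold <= 1) stop("enhancer_differential: fold must be > 1")
  stopifnot(identical(tumor[, c("chrom", "start", "end")],
                      normal[, c("chrom", "start", "end")]))
  r <- (tumor$value + pseudocount) / (normal$value + pseudocount)
  factor(ifelse(r >= fold, "gain", ifelse(1 / r >= fold, "loss",
                                          "stable")),
         levels = c("gain", "loss", "stable"))
}

#' Map 18-state chromatin labels to active/inactive
#'
#' States E1-E12 are active, E13-E18 inactive; any other label is an
#' error.
#'
#' @param states character vector of labels `E1`..`E18` (or a `GRanges`
#'   with a `name` column of labels).
#' @return character vector (or `GRanges` with an added `activity`
#'   column).
#' @export
chromatin_activity <- function(states) {
  if (methods::is(states, "GRanges")) {
    states$activity <- chromatin_activity(states$name)
    return(states)
  }
  num <- suppressWarnings(as.integer(sub("^E", "", states)))
  if (any(is.na(num) | !grepl("^E\\d+$", states) | num < 1 | num > 18))
    stop("chromatin_activity: unknown chromatin state label")
  ifelse(num <= 12, "active", "inactive")
}

#' Build gene regulatory domains by the basal-plus-extension rule
#'
#' The basal domain covers `basal_up` bp upstream and `basal_down` bp
#' downstream of the TSS (strand-oriented). Each side is then extended
#' outward by up to `extension` bp, clipped at the nearest neighboring
#' gene's basal domain (and at coordinate 0), so a domain never invades a
#' neighbor's basal domain and always contains its own.
#'
#' @param genes data frame `gene`, `chrom`, `tss`, `strand` (+/-).
#' @param basal_up,basal_down basal distances in bp (defaults 5000/1000).
#' @param extension maximum extension per side in bp (default 20000).
#' @return data frame `gene`, `chrom`, `strand`, `basal_start`,
#'   `basal_end`, `ext_start`, `ext_end` (0-based half-open).
#' @export
build_regulatory_domains <- function(genes, basal_up = 5000,
                                     basal_down = 1000,
                                     extension = 20000) {
  if (anyDuplicated(genes$gene))
    stop("build_regulatory_domains: duplicate gene ids")
  up <- ifelse(genes$strand == "+", basal_up, basal_down)
  dn <- ifelse(genes$strand == "+", basal_down, basal_up)
  bs <- pmax(genes$tss - up, 0)
  be <- genes$tss + dn
  es <- pmax(bs - extension, 0)
  ee <- be + extension
  for (i in seq_len(nrow(genes))) {
    same <- which(genes$chrom == genes$chrom[i])
    same <- setdiff(same, i)
    left <- same[be[same] <= bs[i]]
    if (length(left) > 0)
      es[i] <- min(bs[i], max(es[i], max(be[left])))
    right <- same[bs[same] >= be[i]]
    if (length(right) > 0)
      ee[i] <- max(be[i], min(ee[i], min(bs[right])))
  }
  data.frame(gene = genes$gene, chrom = genes$chrom,
             strand = genes$strand,
             basal_start = as.integer(bs), basal_end = as.integer(be),
             ext_start = as.integer(es), ext_end = as.integer(ee))
}

#' Associate regions with genes through regulatory domains
#'
#' A region is associated with every gene whose extended domain it
#' overlaps by at least 1 bp.
#'
#' @param regions data frame `chrom`, `start`, `end` (0-based half-open).
#' @param domains output of [build_regulatory_domains()].
#' @return data frame `gene`, `region` (row index into `regions`).
#' @export
associate_regions_to_genes <- function(regions, domains) {
  rg <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
  dg <- GenomicRanges::GRanges(
    domains$chrom,
    IRanges::IRanges(domains$ext_start + 1L, domains$ext_end))
  ov <- GenomicRanges::findOverlaps(rg, dg)
  data.frame(gene = domains$gene[S4Vectors::subjectHits(ov)],
             region = S4Vectors::queryHits(ov))
}

#' Tumor-vs-normal expression grouped by enhancer class and status
#'
#' Gene-region pairs are partitioned by (enhancer class) x (differential
#' status); within each group the genes' tumor and normal expression
#' summaries are compared with a paired Wilcoxon signed-rank test.
#'
#' @param expr_tumor,expr_normal named per-gene expression summaries
#'   (e.g., mean log2 across samples).
#' @param gene_regions data frame `gene`, `region` from
#'   [associate_regions_to_genes()].
#' @param region_class character class per region (strong/weak/none).
#' @param region_status factor status per region (gain/loss/stable).
#' @return data frame `class`, `status`, `n`, `median_diff`, `p`.
#' @export
expression_by_enhancer_class <- function(expr_tumor, expr_normal,
                                         gene_regions, region_class,
                                         region_status) {
  gr <- gene_regions[gene_regions$gene %in% names(expr_tumor), ,
                     drop = FALSE]
  gr <- unique(gr)
  gr$class <- region_class[gr$region]
  gr$status <- as.character(region_status)[gr$region]
  gr <- gr[gr$class %in% c("strong", "weak"), , drop = FALSE]
  out <- list()
  for (cl in c("strong", "weak")) for (st in c("gain", "loss", "stable")) {
    genes <- unique(gr$gene[gr$class == cl & gr$status == st])
    if (length(genes) < 2) next
    xt <- expr_tumor[genes]; xn <- expr_normal[genes]
    p <- tryCatch(
      suppressWarnings(wilcox.test(xt, xn, paired = TRUE)$p.value),
      error = function(e) NA_real_)
    out[[paste(cl, st)]] <- data.frame(
      class = cl, status = st, n = length(genes),
      median_diff = median(xt - xn), p = p)
  }
  if (length(out) == 0)
    return(data.frame(class = character(), status = character(),
                      n = integer(), median_diff = numeric(),
                      p = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Explain driver expression changes by genomic or enhancer evidence
#'
#' A driver's change is genome-explained when down-regulation co-occurs
#' with mutation, hypermethylation or copy-number deletion, or
#' up-regulation with mutation or amplification; it is enhancer-explained
#' when down-regulation co-occurs with enhancer loss in the gene's
#' regulatory domain, or up-regulation with enhancer gain. The two
#' categories may overlap and are reported separately.
#'
#' @param drivers data frame `id`, `direction` (up/down; anything else is
#'   excluded with a message).
#' @param mutated,amplified,deleted,hypermethylated character vectors of
#'   gene ids carrying each alteration.
#' @param enhancer_gain,enhancer_loss gene ids whose domains overlap a
#'   gained / lost enhancer.
#' @return list: `records` (per-driver flags and evidence string),
#'   `fraction_genome`, `fraction_enhancer`, `fraction_both`,
#'   `fraction_either`.
#' @export
explain_driver_expression <- function(drivers, mutated = character(),
                                      amplified = character(),
                                      deleted = character(),
                                      hypermethylated = character(),
                                      enhancer_gain = character(),
                                      enhancer_loss = character()) {
  known <- drivers$direction %in% c("up", "down")
  if (any(!known))
    message("explain_driver_expression: ", sum(!known),
            " drivers without direction excluded")
  d <- drivers[known, , drop = FALSE]
  if (nrow(d) == 0)
    return(list(records = d, fraction_genome = NA_real_,
                fraction_enhancer = NA_real_, fraction_both = NA_real_,
                fraction_either = NA_real_))
  down <- d$direction == "down"
  genome <- ifelse(down,
                   d$id %in% c(mutated, hypermethylated, deleted),
                   d$id %in% c(mutated, amplified))
  enh <- ifelse(down, d$id %in% enhancer_loss, d$id %in% enhancer_gain)
  ev <- vapply(seq_len(nrow(d)), function(i) {
    e <- c(if (d$id[i] %in% mutated) "mutation",
           if (down[i] && d$id[i] %in% hypermethylated) "hypermethylation",
           if (down[i] && d$id[i] %in% deleted) "deletion",
           if (!down[i] && d$id[i] %in% amplified) "amplification",
           if (down[i] && d$id[i] %in% enhancer_loss) "enhancer_loss",
           if (!down[i] && d$id[i] %in% enhancer_gain) "enhancer_gain")
    paste(e, collapse = ";")
  }, "")
  records <- data.frame(id = d$id, direction = d$direction,
                        genome_explained = genome,
                        enhancer_explained = enh, evidence = ev,
                        row.names = NULL)
  list(records = records,
       fraction_genome = mean(genome),
       fraction_enhancer = mean(enh),
       fraction_both = mean(genome & enh),
       fraction_either = mean(genome | enh))
}
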