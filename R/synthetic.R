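#' Simulation configuration for a synthetic multi-omics cohort
#'
#' Describes a cohort with planted co-expression modules whose mean
#' expression is driven by regulators from different molecular platforms
#' (somatic mutation, copy-number dosage, promoter hypermethylation, miRNA
#' repression, transcription-factor expression), together with decoy
#' regulators that carry platform alterations but no downstream effect.
#'
#' @param n_tumor,n_normal tumor and normal sample counts.
#' @param n_genes total protein-coding genes in the expression matrix; must
#'   accommodate the module genes plus the background genes that host
#'   regulators and decoys.
#' @param n_modules number of planted co-expression modules.
#' @param genes_per_module module size (genes).
#' @param regulators_per_module planted regulators per module (1-3).
#' @param platform_mix named proportions over
#'   `c("mutation","cnv","methylation","mirna","expression")` from which the
#'   planted regulators' platforms are drawn (round-robin by proportion).
#' @param effect_size standardized shift (in units of `noise_sd`) that a
#'   fully active regulator induces on its module genes.
#' @param noise_sd residual SD of log2 expression.
#' @param de_shift tumor-vs-normal baseline shift of module genes (log2);
#'   defaults to `effect_size`, with a random sign per module.
#' @param mutation_fraction fraction of tumors carrying a planted mutation
#'   regulator's mutation (default 0.3, mimicking the low mutation
#'   frequencies that defeat single-platform mutation analysis).
#' @param cnv_fraction,meth_fraction,mirna_fraction fractions of tumors with
#'   the corresponding planted alteration.
#' @param decoys_per_platform decoy regulators per platform in
#'   `c("mutation","cnv","methylation","mirna")`.
#' @param tf_decoys decoy transcription factors (expression-profile decoys).
#' @param n_subtypes number of planted tumor subtypes (1 = none).
#' @param subtype_effect per-subtype mean shift applied to a random fifth of
#'   module genes (log2 units) when `n_subtypes > 1`.
#' @param subtype_hazard_ratios per-subtype relative hazards (length
#'   `n_subtypes`).
#' @param baseline_rate baseline exponential event rate for survival times.
#' @param censor_rate fraction of subjects censored.
#' @param seed global seed; every stage derives its own seed from it.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_tumor = 60, n_normal = 20,
                       n_genes = 240, n_modules = 5, genes_per_module = 40,
                       regulators_per_module = 1,
                       platform_mix = c(mutation = 0.2, cnv = 0.2,
                                        methylation = 0.2, mirna = 0.2,
                                        expression = 0.2),
                       effect_size = 2, noise_sd = 1, de_shift = NULL,
                       mutation_fraction = 0.3, cnv_fraction = 0.4,
                       meth_fraction = 0.5, mirna_fraction = 0.5,
                       decoys_per_platform = 8, tf_decoys = 5,
                       n_subtypes = 1, subtype_effect = 1,
                       subtype_hazard_ratios = rep(1, n_subtypes),
                       baseline_rate = 0.1, censor_rate = 0.2,
                       seed = 1L) {
  cfg <- list(n_tumor = n_tumor, n_normal = n_normal, n_genes = n_genes,
              n_modules = n_modules, genes_per_module = genes_per_module,
              regulators_per_module = regulators_per_module,
              platform_mix = platform_mix, effect_size = effect_size,
              noise_sd = noise_sd,
              de_shift = if (is.null(de_shift)) effect_size else de_shift,
              mutation_fraction = mutation_fraction,
              cnv_fraction = cnv_fraction, meth_fraction = meth_fraction,
              mirna_fraction = mirna_fraction,
              decoys_per_platform = decoys_per_platform,
              tf_decoys = tf_decoys,
              n_subtypes = n_subtypes, subtype_effect = subtype_effect,
              subtype_hazard_ratios = subtype_hazard_ratios,
              baseline_rate = baseline_rate, censor_rate = censor_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_tumor", "n_normal", "n_genes", "n_modules",
              "genes_per_module", "regulators_per_module", "n_subtypes")
  for (f in counts)
    if (cfg[[f]] <= 0) stop("sim_config: ", f, " must be > 0")
  if (abs(sum(cfg$platform_mix) - 1) > 1e-8)
    stop("sim_config: platform_mix proportions must sum to 1")
  if (!all(names(cfg$platform_mix) %in%
           c("mutation", "cnv", "methylation", "mirna", "expression")))
    stop("sim_config: unknown platform in platform_mix")
  if (cfg$n_modules * cfg$genes_per_module > cfg$n_genes)
    stop("sim_config: infeasible - more module genes (",
         cfg$n_modules * cfg$genes_per_module, ") than genes (",
         cfg$n_genes, ")")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop("sim_config: censor_rate must be in [0, 1)")
  if (length(cfg$subtype_hazard_ratios) != cfg$n_subtypes)
    stop("sim_config: need one hazard ratio per subtype")
  invisible(cfg)
}

# assign planted regulator platforms by the configured proportions:
# largest-remainder apportionment over the requested number of regulators
apportion_platforms <- function(mix, n) {
  raw <- mix * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(names(mix), times = base)
}

#' Generate a synthetic multi-omics cohort with planted ground truth
#'
#' Expression of the genes in module *m* follows
#' `baseline + de_shift * module_sign + effect_size * a_m(s) + N(0, noise_sd)`
#' in tumors, where the activation `a_m(s)` is realized by the module's
#' planted regulator(s): a binary mutation indicator, a copy-number state
#' scaled to dosage (state / 2), a methylation silencing indicator (negative
#' sign), an overexpressed repressing miRNA (negative sign), or a continuous
#' TF expression profile. Normal samples carry no activations or shifts.
#' Methylation is generated on the logit scale and inverse-transformed so
#' beta values stay inside \[0, 1\].
#'
#' @param config a [sim_config()].
#' @return list with elements `cohort` (an `omics_cohort`: `expression`,
#'   `mutation`, `cnv`, `methylation` beta, `mirna`, `clinical`,
#'   `sample_ids`, `is_tumor`, plus `interactions` and `tf_list`) and
#'   `truth` (a `ground_truth`: `module_of_gene` with 0 = background,
#'   `planted_regulators` data frame, `subtype_of_sample`).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  seeds <- stage_seeds(cfg$seed, 8L)

  n_mod_genes <- cfg$n_modules * cfg$genes_per_module
  n_bg <- cfg$n_genes - n_mod_genes
  n_planted <- cfg$n_modules * cfg$regulators_per_module
  platforms <- apportion_platforms(cfg$platform_mix, n_planted)
  n_host <- sum(platforms != "mirna") +
    2 * cfg$decoys_per_platform + # cnv + methylation decoys need expr rows
    cfg$decoys_per_platform +     # mutation decoys hosted on genes
    cfg$tf_decoys
  if (n_bg < n_host)
    stop("generate_cohort: need at least ", n_host,
         " background genes to host regulators and decoys; have ", n_bg)

  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  tumors <- sprintf("T%03d", seq_len(cfg$n_tumor))
  normals <- sprintf("N%03d", seq_len(cfg$n_normal))
  samples <- c(tumors, normals)
  is_tumor <- c(rep(TRUE, cfg$n_tumor), rep(FALSE, cfg$n_normal))
  nt <- cfg$n_tumor; nn <- cfg$n_normal; ns <- nt + nn

  module_of_gene <- setNames(integer(cfg$n_genes), genes)
  for (m in seq_len(cfg$n_modules)) {
    idx <- ((m - 1) * cfg$genes_per_module + 1):(m * cfg$genes_per_module)
    module_of_gene[idx] <- m
  }
  bg_genes <- genes[module_of_gene == 0]

  # --- subtype structure -------------------------------------------------
  set.seed(seeds[1])
  subtype_of_sample <- setNames(
    sample(rep_len(seq_len(cfg$n_subtypes), nt)), tumors)

  # --- regulator activations --------------------------------------------
  set.seed(seeds[2])
  host_pool <- bg_genes
  take_host <- function(k) {
    h <- host_pool[seq_len(k)]
    host_pool <<- host_pool[-seq_len(k)]
    h
  }
  reg <- list()      # planted regulator records
  activ <- matrix(0, n_planted, nt)  # per-regulator activation over tumors
  mut_rows <- list(); cnv_rows <- list(); meth_special <- list()
  mirna_rows <- list(); interactions <- list()
  cis_expr_shift <- list()  # host gene -> numeric shift over tumors
  mirna_id <- 0

  for (i in seq_len(n_planted)) {
    m <- ((i - 1) %% cfg$n_modules) + 1
    pf <- platforms[i]
    if (pf == "mutation") {
      id <- take_host(1)
      ind <- as.numeric(runif(nt) < cfg$mutation_fraction)
      if (sum(ind) < 2) ind[sample.int(nt, 2)] <- 1
      activ[i, ] <- ind
      mut_rows[[id]] <- ind
      reg[[i]] <- list(id = id, platform = "mutation", module = m, sign = 1)
    } else if (pf == "cnv") {
      id <- take_host(1)
      amp <- runif(1) < 0.5
      st <- integer(nt)
      alt <- runif(nt) < cfg$cnv_fraction
      st[alt] <- sample(1:2, sum(alt), replace = TRUE) * if (amp) 1L else -1L
      activ[i, ] <- st / 2
      cnv_rows[[id]] <- st
      cis_expr_shift[[id]] <- cfg$effect_size * st / 2
      reg[[i]] <- list(id = id, platform = "cnv", module = m,
                       sign = if (amp) 1 else -1)
    } else if (pf == "methylation") {
      id <- take_host(1)
      sil <- as.numeric(runif(nt) < cfg$meth_fraction)
      if (sum(sil) < 2) sil[sample.int(nt, 2)] <- 1
      activ[i, ] <- -sil
      meth_special[[id]] <- sil  # tumors with high beta
      cis_expr_shift[[id]] <- -cfg$effect_size * sil
      reg[[i]] <- list(id = id, platform = "methylation", module = m,
                       sign = -1)
    } else if (pf == "mirna") {
      mirna_id <- mirna_id + 1
      id <- sprintf("miR-%03d", mirna_id)
      over <- as.numeric(runif(nt) < cfg$mirna_fraction)
      if (sum(over) < 2) over[sample.int(nt, 2)] <- 1
      activ[i, ] <- -over
      mirna_rows[[id]] <- over  # overexpression indicator, scaled later
      targets <- genes[module_of_gene == m]
      interactions[[id]] <- data.frame(mirna = id, target = targets)
      reg[[i]] <- list(id = id, platform = "mirna", module = m, sign = -1)
    } else { # expression (TF)
      id <- take_host(1)
      z <- rnorm(nt)
      activ[i, ] <- z
      cis_expr_shift[[id]] <- cfg$effect_size * z  # the TF's own profile
      reg[[i]] <- list(id = id, platform = "expression", module = m,
                       sign = 1)
    }
  }
  tf_list <- vapply(reg[platforms == "expression"], `[[`, "", "id")

  # --- decoys ------------------------------------------------------------
  set.seed(seeds[3])
  dk <- cfg$decoys_per_platform
  decoy_mut <- take_host(dk)
  for (id in decoy_mut)
    mut_rows[[id]] <- as.numeric(runif(nt) < cfg$mutation_fraction)
  decoy_cnv <- take_host(dk)
  for (id in decoy_cnv) {
    st <- integer(nt)
    alt <- runif(nt) < cfg$cnv_fraction
    st[alt] <- sample(c(-2:-1, 1:2), sum(alt), replace = TRUE)
    cnv_rows[[id]] <- st
  }
  decoy_meth <- take_host(dk)
  for (id in decoy_meth)
    meth_special[[id]] <- as.numeric(runif(nt) < cfg$meth_fraction)
  for (j in seq_len(max(dk - 2, 0))) {
    mirna_id <- mirna_id + 1
    id <- sprintf("miR-%03d", mirna_id)
    mirna_rows[[id]] <- as.numeric(runif(nt) < cfg$mirna_fraction)
    targets <- sample(genes, min(10, cfg$n_genes))
    interactions[[id]] <- data.frame(mirna = id, target = targets)
  }
  decoy_tf <- take_host(cfg$tf_decoys)
  tf_list <- c(tf_list, decoy_tf)

  # --- expression --------------------------------------------------------
  set.seed(seeds[4])
  baseline <- rnorm(cfg$n_genes, mean = 8, sd = 1.5)
  expr <- matrix(rnorm(cfg$n_genes * ns, sd = cfg$noise_sd),
                 cfg$n_genes, ns, dimnames = list(genes, samples))
  expr <- expr + baseline
  # the tumor-vs-normal baseline shift of a module follows its (first)
  # regulator's direction: silencing regulators drive the module down
  module_sign <- vapply(seq_len(cfg$n_modules), function(m) {
    i <- which(vapply(reg, `[[`, 0, "module") == m)[1]
    if (is.na(i)) 1 else reg[[i]]$sign
  }, 0)
  for (m in seq_len(cfg$n_modules)) {
    gi <- which(module_of_gene == m)
    shift <- rep(0, nt)
    for (i in which(vapply(reg, `[[`, 0, "module") == m))
      shift <- shift + cfg$effect_size * activ[i, ]
    expr[gi, seq_len(nt)] <- expr[gi, seq_len(nt)] +
      rep(cfg$de_shift * module_sign[m] + shift, each = length(gi))
  }
  for (id in names(cis_expr_shift)) {
    expr[id, seq_len(nt)] <- expr[id, seq_len(nt)] + cis_expr_shift[[id]]
  }
  # subtype shifts on a random fifth of module genes per subtype
  if (cfg$n_subtypes > 1) {
    set.seed(seeds[5])
    for (st in seq_len(cfg$n_subtypes)) {
      gi <- sample(which(module_of_gene > 0),
                   max(1, round(n_mod_genes / 5)))
      cols <- tumors[subtype_of_sample == st]
      expr[gi, cols] <- expr[gi, cols] + cfg$subtype_effect
    }
  }

  # --- mutation / cnv matrices ------------------------------------------
  mutation <- matrix(0L, cfg$n_genes, nt, dimnames = list(genes, tumors))
  for (id in names(mut_rows)) mutation[id, ] <- as.integer(mut_rows[[id]])
  cnv <- matrix(0L, cfg$n_genes, nt, dimnames = list(genes, tumors))
  for (id in names(cnv_rows)) cnv[id, ] <- as.integer(cnv_rows[[id]])

  # --- methylation beta (logit-normal background) ------------------------
  set.seed(seeds[6])
  meth_logit <- matrix(rnorm(cfg$n_genes * ns, mean = logit(0.2), sd = 0.4),
                       cfg$n_genes, ns, dimnames = list(genes, samples))
  for (id in names(meth_special)) {
    sil <- meth_special[[id]]
    meth_logit[id, seq_len(nt)] <- meth_logit[id, seq_len(nt)] +
      sil * (logit(0.8) - logit(0.2))
  }
  methylation <- expit(meth_logit)

  # --- miRNA expression --------------------------------------------------
  set.seed(seeds[7])
  n_mirna <- length(mirna_rows)
  mirna <- matrix(rnorm(max(n_mirna, 1) * ns, mean = 5, sd = 0.5),
                  max(n_mirna, 1), ns,
                  dimnames = list(if (n_mirna)
                    names(mirna_rows) else "miR-000", samples))
  for (id in names(mirna_rows))
    mirna[id, seq_len(nt)] <- mirna[id, seq_len(nt)] + 2 * mirna_rows[[id]]

  # --- survival ----------------------------------------------------------
  clinical <- generate_survival(subtype_of_sample,
                                cfg$subtype_hazard_ratios,
                                baseline_rate = cfg$baseline_rate,
                                censor_rate = cfg$censor_rate,
                                seed = seeds[8])

  planted <- do.call(rbind, lapply(reg, function(r)
    data.frame(id = r$id, platform = r$platform, module = r$module,
               sign = r$sign)))

  cohort <- structure(list(
    sample_ids = samples, is_tumor = is_tumor,
    expression = expr, mutation = mutation, cnv = cnv,
    methylation = methylation, mirna = mirna, clinical = clinical,
    interactions = do.call(rbind, interactions),
    tf_list = tf_list), class = "omics_cohort")
  truth <- structure(list(
    module_of_gene = module_of_gene,
    planted_regulators = planted,
    subtype_of_sample = subtype_of_sample), class = "ground_truth")
  list(cohort = cohort, truth = truth)
}

#' Generate paired tumor/normal signal tracks with planted enhancer events
#'
#' Baseline window signal is log-normal and shared between the two tracks;
#' gain windows are multiplied by `fold` in the tumor track, loss windows
#' divided. Multiplicative log-normal noise with coefficient of variation
#' `noise_cv` is applied independently per track.
#'
#' @param n_windows number of fixed-width windows.
#' @param window_bp window width in bp (default 50).
#' @param n_gain,n_loss planted gain and loss windows.
#' @param fold planted fold change (must be >= 1; typical >= 2).
#' @param noise_cv coefficient of variation of multiplicative noise
#'   (0 = noise-free).
#' @param seed integer seed.
#' @param base_meanlog,base_sdlog log-normal baseline parameters.
#' @param base_floor minimum baseline signal. The windows emulate
#'   candidate regulatory windows with appreciable occupancy; the floor
#'   keeps a planted fold >= 2 identifiable relative to the pseudocount
#'   used by downstream differential calling, which an unbounded
#'   log-normal low tail would not.
#' @param chrom chromosome name for the synthetic contig.
#' @return list of `tumor` and `normal` tracks (data frames `chrom`,
#'   `start`, `end`, `value`, 0-based half-open, class `signal_track`) and
#'   `truth` (per-window status factor gain/loss/stable).
#' @export
generate_signal_tracks <- function(n_windows, window_bp = 50,
                                   n_gain = 0, n_loss = 0, fold = 2,
                                   noise_cv = 0.1, seed = 1L,
                                   base_meanlog = log(20),
                                   base_sdlog = 0.5, base_floor = 10,
                                   chrom = "chrS") {
  if (fold < 1) stop("generate_signal_tracks: fold must be >= 1")
  if (n_gain + n_loss > n_windows)
    stop("generate_signal_tracks: n_gain + n_loss exceeds n_windows")
  set.seed(seed)
  base <- pmax(exp(rnorm(n_windows, base_meanlog, base_sdlog)), base_floor)
  status <- rep("stable", n_windows)
  idx <- sample.int(n_windows, n_gain + n_loss)
  status[idx[seq_len(n_gain)]] <- "gain"
  if (n_loss > 0) status[idx[n_gain + seq_len(n_loss)]] <- "loss"
  noise <- function() {
    if (noise_cv <= 0) return(rep(1, n_windows))
    sdlog <- sqrt(log(1 + noise_cv^2))
    exp(rnorm(n_windows, -sdlog^2 / 2, sdlog))
  }
  tumor <- base * noise()
  normal <- base * noise()
  tumor[status == "gain"] <- tumor[status == "gain"] * fold
  tumor[status == "loss"] <- tumor[status == "loss"] / fold
  starts <- (seq_len(n_windows) - 1L) * window_bp
  mk <- function(v) signal_track(chrom, starts, starts + window_bp, v)
  list(tumor = mk(tumor), normal = mk(normal),
       truth = factor(status, levels = c("gain", "loss", "stable")))
}

#' Generate survival data for subtyped samples
#'
#' Event times are exponential with per-subtype rate
#' `baseline_rate * hazard_ratio`; each subject is independently censored
#' with probability `censor_rate`, in which case the observed time is
#' uniform on (0, event time).
#'
#' @param subtype_of_sample named vector mapping sample id to subtype.
#' @param hazard_ratios per-subtype relative hazards (length = number of
#'   subtypes).
#' @param baseline_rate baseline exponential rate (> 0).
#' @param censor_rate censoring probability in \[0, 1).
#' @param seed integer seed.
#' @return data frame `sample`, `subtype`, `time`, `event`.
#' @export
generate_survival <- function(subtype_of_sample, hazard_ratios,
                              baseline_rate = 0.1, censor_rate = 0.2,
                              seed = 1L) {
  st <- as.integer(subtype_of_sample)
  if (any(st < 1) || any(st > length(hazard_ratios)))
    stop("generate_survival: every subtype needs a hazard ratio")
  if (baseline_rate <= 0 || any(hazard_ratios <= 0))
    stop("generate_survival: rates must be positive")
  set.seed(seed)
  n <- length(st)
  rate <- baseline_rate * hazard_ratios[st]
  t_event <- rexp(n, rate)
  cens <- runif(n) < censor_rate
  time <- ifelse(cens, runif(n) * t_event, t_event)
  data.frame(sample = names(subtype_of_sample), subtype = st,
             time = time, event = as.integer(!cens),
             row.names = NULL)
}

#' Generate per-platform feature matrices with a planted subtype structure
#'
#' Each platform observes a (possibly merged) view of the true subtypes:
#' `merges[[p]]` maps each true subtype to the class that platform can
#' distinguish. Class centers are drawn once per platform with separation
#' controlled by `snr` (center SD in units of the unit residual SD).
#'
#' @param n_samples number of samples.
#' @param n_subtypes number of true subtypes (default 4).
#' @param merges list (one per platform) of integer vectors of length
#'   `n_subtypes` mapping subtype to platform-visible class. Default: four
#'   platforms, each a 2-way merge of 4 subtypes (12|34, 13|24, 14|23,
#'   12|34).
#' @param n_features features per platform.
#' @param snr class-center SD relative to unit noise.
#' @param seed integer seed.
#' @return list `platforms` (list of feature-by-sample matrices) and
#'   `subtype_of_sample` (named integer vector).
#' @export
generate_subtype_platforms <- function(n_samples, n_subtypes = 4,
                                       merges = NULL, n_features = 20,
                                       snr = 3, seed = 1L) {
  if (is.null(merges)) {
    stopifnot(n_subtypes == 4)
    merges <- list(c(1, 1, 2, 2), c(1, 2, 1, 2), c(1, 2, 2, 1),
                   c(1, 1, 2, 2))
  }
  set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n_samples))
  subtype <- setNames(sample(rep_len(seq_len(n_subtypes), n_samples)), ids)
  platforms <- lapply(seq_along(merges), function(p) {
    classes <- merges[[p]][subtype]
    k <- max(merges[[p]])
    centers <- matrix(rnorm(n_features * k, sd = snr), n_features, k)
    x <- centers[, classes, drop = FALSE] +
      matrix(rnorm(n_features * n_samples), n_features, n_samples)
    dimnames(x) <- list(sprintf("P%dF%03d", p, seq_len(n_features)), ids)
    x
  })
  names(platforms) <- sprintf("platform%d", seq_along(merges))
  list(platforms = platforms, subtype_of_sample = subtype)
}

#' Write a cohort's matrices and clinical table as TSV files
#'
#' @param cohort an `omics_cohort`.
#' @param truth optional `ground_truth` to write alongside.
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, truth = NULL, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  for (nm in c("expression", "mutation", "cnv", "methylation", "mirna")) {
    f <- file.path(outdir, paste0(nm, ".tsv"))
    write_matrix_tsv(cohort[[nm]], f)
    files <- c(files, f)
  }
  f <- file.path(outdir, "clinical.tsv")
  write.table(cohort$clinical, f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, f)
  f <- file.path(outdir, "interactions.tsv")
  write.table(cohort$interactions, f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, f)
  if (!is.null(truth)) {
    f <- file.path(outdir, "truth_modules.tsv")
    write.table(data.frame(gene = names(truth$module_of_gene),
                           module = truth$module_of_gene),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    f2 <- file.path(outdir, "truth_regulators.tsv")
    write.table(truth$planted_regulators, f2, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, f, f2)
  }
  invisible(files)
}
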