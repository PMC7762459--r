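test_that("shared BH implementation agrees exactly with step-up enumeration", {
  set.seed(1)
  for (i in 1:50) {
    n <- sample(1:20, 1)
    p <- round(runif(n), 3)
    expect_equal(adjust_bh(p), bh_oracle(p))
  }
  # worked example: p = [.01,.02,.03,.04], m = 4 -> all adjusted to 0.04
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
})

test_that("differential expression handles degenerate and null genes", {
  expr <- rbind(flat = rep(5, 10),
                same = c(rnorm(5), rnorm(5)))
  expr["same", 6:10] <- expr["same", 1:5] # identical groups
  flags <- rep(c(TRUE, FALSE), each = 5)
  de <- differential_expression(expr, flags)
  expect_equal(de$t[de$gene == "flat"], 0)
  expect_equal(de$p[de$gene == "flat"], 1)
  expect_true(de$degenerate[de$gene == "flat"])
  expect_equal(de$t[de$gene == "same"], 0)
  expect_equal(de$p[de$gene == "same"], 1)
  expect_error(differential_expression(expr, c(TRUE, rep(FALSE, 9))),
               ">= 2 tumors")
})

test_that("differential expression matches t.test and is powered on planted cohorts", {
  set.seed(7)
  expr <- matrix(rnorm(40), 4, 10)
  flags <- rep(c(TRUE, FALSE), each = 5)
  de <- differential_expression(expr, flags)
  for (i in 1:4) {
    tt <- t.test(expr[i, flags], expr[i, !flags])
    expect_equal(de$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(de$p[i], tt$p.value, tolerance = 1e-10)
  }
  sim <- generate_cohort(sim_config(n_tumor = 30, n_normal = 30,
                                    n_genes = 150, n_modules = 3,
                                    genes_per_module = 30,
                                    effect_size = 2, noise_sd = 1,
                                    decoys_per_platform = 4,
                                    tf_decoys = 3, seed = 99))
  de <- differential_expression(sim$cohort$expression,
                                sim$cohort$is_tumor)
  mg <- names(sim$truth$module_of_gene)[sim$truth$module_of_gene > 0]
  expect_gte(mean(de$significant[match(mg, de$gene)]), 0.95)
})

test_that("methylation screen finds planted silencers and rejects unpredictive genes", {
  sim <- tiny_cohort(seed = 21)
  co <- sim$cohort
  meth <- differential_methylation(co$methylation, co$expression,
                                   co$is_tumor)
  planted <- sim$truth$planted_regulators
  pm <- planted$id[planted$platform == "methylation"]
  expect_true(all(pm %in% meth$gene))
  expect_true(all(meth$direction[match(pm, meth$gene)] == "hyper"))

  # identical beta in tumors and normals: no candidates
  b <- co$methylation
  b[] <- rep(b[, 1], ncol(b))
  expect_warning(
    out <- differential_methylation(b + 0, co$expression, co$is_tumor),
    "constant")
  expect_equal(nrow(out), 0)

  # beta-differential but expression-shuffled genes fail predictivity
  rejected <- vapply(1:25, function(s) {
    set.seed(4000 + s)
    nt <- 40; nn <- 15
    beta <- matrix(expit(rnorm(nt + nn, logit(0.2), 0.3)), 1)
    beta[1, seq_len(nt)][seq_len(20)] <- expit(rnorm(20, logit(0.8), 0.3))
    rownames(beta) <- "g1"
    colnames(beta) <- sprintf("s%02d", seq_len(nt + nn))
    expr <- matrix(rnorm(nt + nn), 1,
                   dimnames = list("g1", colnames(beta)))
    out <- differential_methylation(beta, expr,
                                    rep(c(TRUE, FALSE), c(nt, nn)))
    nrow(out) == 0
  }, TRUE)
  expect_gte(mean(rejected), 0.9)
})

test_that("miRNA selection keeps only significant negative correlations", {
  # perfect anti-monotone pair has rho = -1
  mir <- matrix(c(1, 2, 3, 4), 1, dimnames = list("m1", paste0("s", 1:4)))
  ex <- matrix(c(8, 6, 4, 2), 1, dimnames = list("gA", paste0("s", 1:4)))
  ia <- data.frame(mirna = "m1", target = "gA")
  out <- mirna_candidates(mir, ex, ia, alpha = 1)
  expect_equal(out$pairs$rho, -1)

  # closed form 1 - 6*sum(d^2)/(n(n^2-1)) on tie-free data
  set.seed(3)
  x <- sample(100, 12); y <- sample(100, 12)
  d <- rank(x) - rank(y)
  rho_closed <- 1 - 6 * sum(d^2) / (12 * (12^2 - 1))
  mir2 <- matrix(x, 1, dimnames = list("m1", paste0("s", 1:12)))
  ex2 <- matrix(y, 1, dimnames = list("gA", paste0("s", 1:12)))
  out2 <- mirna_candidates(mir2, ex2, ia, alpha = 1)
  expect_equal(out2$pairs$rho, rho_closed, tolerance = 1e-12)

  # positively correlated pair excluded regardless of significance
  ex3 <- matrix(c(2, 4, 6, 8), 1, dimnames = list("gA", paste0("s", 1:4)))
  out3 <- mirna_candidates(mir, ex3, ia, alpha = 1)
  expect_false(out3$pairs$kept)
  expect_length(out3$candidates, 0)

  # unknown ids are skipped, not fatal
  ia2 <- rbind(ia, data.frame(mirna = "m1", target = "missing"))
  expect_message(out4 <- mirna_candidates(mir, ex, ia2), "skipped")
  expect_equal(nrow(out4$skipped), 1)
})

test_that("mutation and CNV frequency selectors follow their thresholds", {
  m <- matrix(0L, 2, 100,
              dimnames = list(c("gA", "gB"), sprintf("t%03d", 1:100)))
  m["gA", 1:3] <- 1L
  expect_equal(mutation_candidates(m, min_frequency = 0.02), "gA")
  expect_equal(mutation_candidates(m, external_list = c("gB", "gX")), "gB")
  expect_warning(mutation_candidates(m * 0L), "empty")

  cn <- matrix(0L, 3, 10, dimnames = list(c("amp", "mix", "flat"), NULL))
  cn["amp", 1:2] <- 2L
  cn["mix", 1:2] <- 1L; cn["mix", 3:4] <- -1L
  expect_message(out <- cnv_candidates(cn, min_frequency = 0.1), "both")
  expect_true("amp" %in% out$amp)
  expect_true("mix" %in% out$amp && "mix" %in% out$del)
  expect_false("flat" %in% c(out$amp, out$del))
})

test_that("candidate selection is monotone in its thresholds", {
  sim <- tiny_cohort(seed = 31)
  co <- sim$cohort
  de1 <- differential_expression(co$expression, co$is_tumor, alpha = 0.05)
  de2 <- differential_expression(co$expression, co$is_tumor, alpha = 0.01)
  expect_true(all(de2$gene[de2$significant] %in% de1$gene[de1$significant]))
  m1 <- mutation_candidates(co$mutation, min_frequency = 0.02)
  m2 <- mutation_candidates(co$mutation, min_frequency = 0.2)
  expect_true(all(m2 %in% m1))
  c1 <- cnv_candidates(co$cnv, min_frequency = 0.1)
  c2 <- cnv_candidates(co$cnv, min_frequency = 0.3)
  expect_true(all(c2$amp %in% c1$amp) && all(c2$del %in% c1$del))
})

test_that("selectors stay near the nominal false-positive rate under permuted labels", {
  fps <- vapply(1:50, function(s) {
    set.seed(7000 + s)
    sim <- tiny_cohort(seed = 41) # fixed cohort, permuted labels
    flags <- sample(sim$cohort$is_tumor)
    de <- differential_expression(sim$cohort$expression, flags)
    mean(de$significant)
  }, 0)
  expect_lte(mean(fps), 0.05)
})

test_that("assembled candidate sets keep platform provenance and profiles", {
  sim <- tiny_cohort(seed = 51)
  co <- sim$cohort
  cand <- assemble_candidates(co, cnv_amp = "G0091",
                              methylation = "G0091",
                              tf_list = co$tf_list)
  ent <- cand$entries
  expect_equal(sum(ent$id == "G0091"), 2)
  expect_setequal(ent$platform[ent$id == "G0091"],
                  c("cnv_amp", "methylation"))
  expect_equal(nrow(cand$profiles), nrow(ent))
  expect_identical(rownames(cand$profiles),
                   paste(ent$id, ent$platform, sep = "|"))
  # empty inputs are fine
  empty <- assemble_candidates(co)
  expect_equal(nrow(empty$entries), 0)
  # unknown id dropped with warning
  expect_warning(assemble_candidates(co, mirna = "miR-none"), "dropped")
})

test_that("planted regulators survive default-threshold assembly", {
  sim <- tiny_cohort(seed = 61)
  co <- sim$cohort
  tumors <- co$sample_ids[co$is_tumor]
  mut <- mutation_candidates(co$mutation)
  cn <- cnv_candidates(co$cnv)
  meth <- differential_methylation(co$methylation, co$expression,
                                   co$is_tumor)
  mir <- mirna_candidates(co$mirna[, tumors], co$expression[, tumors],
                          co$interactions)
  cand <- assemble_candidates(co, mutation = mut, cnv_amp = cn$amp,
                              cnv_del = cn$del, methylation = meth,
                              mirna = mir$candidates,
                              tf_list = co$tf_list)
  expect_true(all(sim$truth$planted_regulators$id %in% cand$entries$id))
})

test_that("MAF tables collapse to the expected binary matrix", {
  maf <- data.frame(
    Hugo_Symbol = c("TP53", "TP53", "CTNNB1", "TP53"),
    Tumor_Sample_Barcode = c("s1", "s2", "s1", "s1"),
    Variant_Classification = c("Missense_Mutation", "Nonsense_Mutation",
                               "Missense_Mutation", "Silent"))
  f <- withr::local_tempfile(fileext = ".maf")
  write.table(maf, f, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- read_maf_matrix(f)
  expect_equal(m["TP53", c("s1", "s2")], c(s1 = 1L, s2 = 1L))
  expect_equal(m["CTNNB1", c("s1", "s2")], c(s1 = 1L, s2 = 0L))
})
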