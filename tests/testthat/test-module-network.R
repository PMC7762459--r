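test_that("partition score equals the Normal-Gamma enumeration oracle on tiny instances", {
  set.seed(2)
  X <- matrix(rnorm(16), 4, 4)
  X[1:2, ] <- X[1:2, ] + rep(c(2, -2, 2, -2), each = 2)
  for (z in all_set_partitions(4)) {
    oracle <- sum(vapply(split(1:4, z),
                         function(g) ng_logml_oracle(as.vector(X[g, , drop = FALSE])),
                         0))
    expect_equal(partition_log_score(X, z), oracle, tolerance = 1e-12)
  }
})

test_that("partition score is invariant to exchanging genes within a module", {
  set.seed(4)
  X <- matrix(rnorm(60), 6, 10)
  z <- c(1, 1, 1, 2, 2, 2)
  blocks <- list(c(rep(1L, 5), rep(2L, 5)), rep(1L, 10))
  s1 <- partition_log_score(X, z, blocks)
  s2 <- partition_log_score(X[c(2, 1, 3, 4, 6, 5), ], z, blocks)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("noise-free planted blocks are recovered by every chain with ARI 1", {
  # two blocks of 20 genes with opposite +/-2 alternating sample means
  pattern <- rep(c(2, -2), length.out = 16)
  X <- rbind(matrix(rep(pattern, each = 20), 20, 16),
             matrix(rep(-pattern, each = 20), 20, 16))
  # tiny jitter so rows are not exactly constant duplicates
  set.seed(9)
  X <- X + matrix(rnorm(length(X), sd = 1e-6), nrow(X))
  rownames(X) <- sprintf("g%02d", 1:40)
  colnames(X) <- sprintf("s%02d", 1:16)
  truth <- rep(1:2, each = 20)
  chains <- gibbs_cluster(X, n_modules = 4, n_chains = 4, n_iter = 30,
                          seed = 17)
  for (ch in chains)
    expect_equal(adjusted_rand(ch$module, truth), 1)
  cons <- consensus_modules(chains)
  expect_equal(adjusted_rand(cons$module_of_gene, truth), 1)
})

test_that("best-so-far log-score traces are non-decreasing", {
  set.seed(5)
  X <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  chains <- gibbs_cluster(X, n_modules = 3, n_chains = 2, n_iter = 25,
                          seed = 2)
  for (ch in chains) {
    expect_true(all(diff(ch$trace) >= 0))
    expect_equal(max(ch$trace), ch$log_score)
  }
})

test_that("sampler is deterministic given the seed", {
  set.seed(6)
  X <- matrix(rnorm(300), 30, 10,
              dimnames = list(sprintf("g%02d", 1:30), NULL))
  a <- gibbs_cluster(X, n_chains = 2, n_iter = 20, seed = 33)
  b <- gibbs_cluster(X, n_chains = 2, n_iter = 20, seed = 33)
  expect_identical(a, b)
})

test_that("structureless matrices do not yield large tight modules", {
  set.seed(12)
  X <- matrix(rnorm(60 * 30), 60, 30,
              dimnames = list(sprintf("g%02d", 1:60), NULL))
  chains <- gibbs_cluster(X, n_modules = 6, n_chains = 5, n_iter = 50,
                          seed = 8)
  cons <- suppressWarnings(consensus_modules(chains))
  sizes <- table(cons$module_of_gene[cons$module_of_gene > 0])
  biggest <- if (length(sizes)) max(sizes) else 0
  expect_lt(biggest, 30) # no half-matrix module out of pure noise
})

test_that("consensus follows chain agreement and strictness rules", {
  mk_chain <- function(z) list(module = z, blocks = NULL,
                               log_score = 0, trace = 0)
  z <- setNames(rep(1:2, each = 6), sprintf("g%02d", 1:12))
  chains <- list(mk_chain(z), mk_chain(z), mk_chain(z))
  cons <- consensus_modules(chains, min_module_size = 5)
  expect_equal(adjusted_rand(cons$module_of_gene, z), 1)
  # one chain moves one gene; threshold 1.0 strands it
  z2 <- z; z2["g01"] <- 2
  cons2 <- consensus_modules(list(mk_chain(z), mk_chain(z2)),
                             co_clustering_threshold = 1.0,
                             min_module_size = 3)
  expect_equal(unname(cons2$module_of_gene["g01"]), 0L)
  # undersized components stay unassigned, with warning when none remain
  z3 <- setNames(rep(1:4, each = 2), sprintf("g%02d", 1:8))
  expect_warning(cons3 <- consensus_modules(list(mk_chain(z3),
                                                 mk_chain(z3)),
                                            min_module_size = 5),
                 "min_module_size")
  expect_true(all(cons3$module_of_gene == 0))
})

test_that("regulation trees honor depth limits and self-separation", {
  set.seed(21)
  n <- 40
  mm <- setNames(c(rnorm(20, 2), rnorm(20, -2)), sprintf("s%02d", 1:n))
  profiles <- rbind(self = mm,
                    noise1 = rnorm(n), noise2 = rnorm(n))
  colnames(profiles) <- names(mm)
  tr <- fit_regulation_tree(mm, profiles, max_depth = 1, seed = 3)
  expect_equal(length(tr$nodes), 1)
  root <- tr$nodes[[1]]
  expect_equal(length(root$left) + length(root$right), n)
  expect_equal(names(which.max(root$score)), "self")
  expect_lte(root$emp_p[["self"]], 0.05)
  # constant profile scores zero
  profiles2 <- rbind(profiles, flat = rep(1, n))
  tr2 <- fit_regulation_tree(mm, profiles2, max_depth = 1, seed = 3)
  expect_equal(unname(tr2$nodes[[1]]$score["flat"]), 0)
})

test_that("node-level empirical p for noise regulators is calibrated", {
  hits <- vapply(1:50, function(s) {
    set.seed(500 + s)
    n <- 30
    mm <- setNames(c(rnorm(15, 1.5), rnorm(15, -1.5)),
                   sprintf("s%02d", 1:n))
    profiles <- matrix(rnorm(n), 1, n,
                       dimnames = list("noise", names(mm)))
    tr <- fit_regulation_tree(mm, profiles, max_depth = 1,
                              n_rand = 100, seed = s)
    tr$nodes[[1]]$emp_p[["noise"]] <= 0.1
  }, TRUE)
  # nominal rate 10%; allow binomial slack over 50 seeds
  expect_lte(sum(hits), 11)
})

test_that("regulator scores aggregate significant nodes with module-sample weights", {
  nodes <- list(
    list(weight = 1, score = c(a = 0.9, b = 0.5),
         emp_p = c(a = 0.01, b = 0.5)),
    list(weight = 0.5, score = c(a = 0.8, b = 0.7),
         emp_p = c(a = 0.02, b = 0.01)))
  trees <- list(M1 = structure(list(nodes = nodes), class = "regulation_tree"))
  sc <- score_regulators(trees)
  expect_equal(unname(sc$score["a", "M1"]), 1 * 0.9 + 0.5 * 0.8)
  expect_equal(unname(sc$score["b", "M1"]), 0.5 * 0.7)
  expect_equal(sc$summed_score, rowSums(sc$score))
})

test_that("driver selection applies ceiling quantiles, tie inclusion and union semantics", {
  # R = 300 regulators: per-module rule keeps ceiling(3) = 3
  set.seed(31)
  sc <- matrix(runif(300 * 2), 300, 2,
               dimnames = list(sprintf("r%03d", 1:300), c("M1", "M2")))
  rs <- structure(list(score = sc, summed_score = rowSums(sc)),
                  class = "regulator_score")
  dl <- select_drivers(rs, per_module_q = 0.01, global_q = 0.1)
  expect_equal(length(dl$per_module_selected$M1), 3)
  expect_equal(length(dl$global_selected), 30)

  # all-zero scores: empty driver list
  sc0 <- matrix(0, 5, 2, dimnames = list(letters[1:5], c("M1", "M2")))
  rs0 <- structure(list(score = sc0, summed_score = rowSums(sc0)),
                   class = "regulator_score")
  expect_equal(nrow(select_drivers(rs0)$drivers), 0)

  # regulator top in one module but with low summed score is still selected
  sc2 <- matrix(c(1, 0, 0, 0,
                  0, 5, 4, 3), 4, 2,
                dimnames = list(letters[1:4], c("M1", "M2")))
  rs2 <- structure(list(score = sc2, summed_score = rowSums(sc2)),
                   class = "regulator_score")
  dl2 <- select_drivers(rs2, per_module_q = 0.01, global_q = 0.25)
  expect_true("a" %in% dl2$drivers$id)
  expect_equal(dl2$drivers$rule[dl2$drivers$id == "a"], "per_module")

  # boundary ties are all included
  sc3 <- matrix(c(2, 2, 1), 3, 1, dimnames = list(letters[1:3], "M1"))
  rs3 <- structure(list(score = sc3, summed_score = rowSums(sc3)),
                   class = "regulator_score")
  dl3 <- select_drivers(rs3, per_module_q = 0.01, global_q = 0.01)
  expect_setequal(dl3$per_module_selected$M1, c("a", "b"))
})

test_that("driver selection is monotone in both quantiles", {
  set.seed(41)
  sc <- matrix(rexp(50 * 3), 50, 3,
               dimnames = list(sprintf("r%02d", 1:50), paste0("M", 1:3)))
  sc[sample(length(sc), 30)] <- 0
  rs <- structure(list(score = sc, summed_score = rowSums(sc)),
                  class = "regulator_score")
  base <- select_drivers(rs, 0.02, 0.05)$drivers$id
  wider1 <- select_drivers(rs, 0.10, 0.05)$drivers$id
  wider2 <- select_drivers(rs, 0.02, 0.20)$drivers$id
  expect_true(all(base %in% wider1))
  expect_true(all(base %in% wider2))
})

test_that("driver module counts come from the per-module rule only", {
  sc <- matrix(c(3, 0,
                 2, 0,
                 0, 5), 3, 2, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("M1", "M2")))
  rs <- structure(list(score = sc, summed_score = rowSums(sc)),
                  class = "regulator_score")
  dl <- select_drivers(rs, per_module_q = 0.01, global_q = 0.67)
  counts <- driver_module_counts(dl)
  expect_equal(unname(counts["a"]), 1L)
  expect_equal(unname(counts["c"]), 1L)
  # driver b selected globally only -> count 0
  expect_equal(unname(counts["b"]), 0L)
})

test_that("single-platform restriction reproduces integrated scores for its entries", {
  sim <- tiny_cohort(seed = 71)
  fit <- suppressWarnings(run_driver_pipeline(sim$cohort, n_chains = 4,
                                              n_iter = 60, seed = 7))
  dl <- run_single_platform(fit, "mirna")
  for (id in dl$drivers$id)
    expect_equal(dl$drivers$summed_score[dl$drivers$id == id],
                 unname(fit$scores$summed_score[id]))
  # platform with no candidates yields an empty list, no crash
  fit2 <- fit
  keep <- fit$candidates$entries$platform != "mutation"
  fit2$candidates$entries <- fit$candidates$entries[keep, ]
  expect_equal(nrow(run_single_platform(fit2, "mutation")$drivers), 0)
})
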