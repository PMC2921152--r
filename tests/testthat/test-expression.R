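# build a minimal experiment directly from explicit intensity tables
manual_experiment <- function(M, A, arrays = NULL, printtip = 1L,
                              groups = NULL) {
  # M, A: matrices elements x arrays
  n_el <- nrow(M)
  n_ar <- ncol(M)
  if (is.null(arrays)) arrays <- sprintf("a%d", seq_len(n_ar))
  if (is.null(groups)) groups <- rep(c("mutant", "control"),
                                     length.out = n_ar)
  rows <- lapply(seq_len(n_ar), function(a) {
    data.frame(element_id = sprintf("e%03d", seq_len(n_el)),
               gene_id = sprintf("g%03d", seq_len(n_el)),
               array_id = arrays[a],
               printtip = rep_len(printtip, n_el),
               ch1 = 2^(A[, a] + M[, a] / 2),
               ch2 = 2^(A[, a] - M[, a] / 2),
               stringsAsFactors = FALSE)
  })
  array_experiment(do.call(rbind, rows),
                   data.frame(array_id = arrays, genotype_group = groups,
                              stringsAsFactors = FALSE))
}

test_that("low-intensity filter discards only both-channel-low elements", {
  el <- data.frame(element_id = sprintf("e%d", 1:5),
                   gene_id = sprintf("g%d", 1:5),
                   array_id = "a1", printtip = 1L,
                   ch1 = c(1, 2, 3, 4, 5),
                   ch2 = c(1, 5, 2, 4, 3))
  exp <- array_experiment(el, data.frame(array_id = "a1",
                                         genotype_group = "mutant"))
  f <- filter_low_intensity(exp)$elements$filtered
  # medians are 3 and 3: element 1 is below both; element 3 is below ch2
  # only (retained); element 2 below ch1 only (retained)
  expect_identical(f, c(TRUE, FALSE, FALSE, FALSE, FALSE))

  # all-equal intensities: nothing is strictly below the median
  el2 <- el
  el2$ch1 <- 7
  el2$ch2 <- 7
  exp2 <- array_experiment(el2, data.frame(array_id = "a1",
                                           genotype_group = "mutant"))
  expect_false(any(filter_low_intensity(exp2)$elements$filtered))
})

test_that("print-tip loess removes intensity-dependent distortion", {
  # constant M per tip group: residual identically zero
  withr::with_seed(5, {
    a <- runif(20, 6, 12)
  })
  A <- cbind(a, a, deparse.level = 0)
  M <- matrix(0.7, nrow = 20, ncol = 2)
  exp <- manual_experiment(M, A)
  norm <- normalize_within_array(exp)
  expect_equal(norm$data$M, rep(0, 40), tolerance = 1e-9)
  expect_equal(norm$data$A, c(A), tolerance = 1e-9)

  # identical arrays give identical normalized output
  expect_identical(norm$data$M[norm$data$array_id == "a1"],
                   norm$data$M[norm$data$array_id == "a2"])

  # known quadratic distortion, no noise: null genes end near M = 0
  cfg <- simulation_config(seed = 19, n_genes = 400, n_arrays = 4,
                           n_printtips = 4, de_fraction = 0, noise_sd = 0,
                           dye_bias_sd = 0.3, distortion_sd = 0.5)
  e <- generate_expression_experiment(cfg)
  n <- normalize_within_array(e)
  expect_lt(mean(abs(n$data$M)), 0.05)

  # an underpopulated print-tip group is reported by name
  bad <- manual_experiment(matrix(0, 25, 2), matrix(8, 25, 2),
                           printtip = rep(c(1L, 2L), c(20, 5)))
  expect_error(normalize_within_array(bad), "a1\\.2")
})

test_that("quantile normalisation maps arrays onto mean order statistics", {
  # hand-computable case: (1,2,3) and (3,4,5) both become (2,3,4)
  m <- cbind(c(1, 2, 3), c(3, 4, 5))
  expect_equal(ldbscreen:::quantile_normalize_matrix(m),
               cbind(c(2, 3, 4), c(2, 3, 4)))

  # permutations of the same values are unchanged up to order
  m2 <- cbind(c(5, 1, 3), c(1, 3, 5))
  q2 <- ldbscreen:::quantile_normalize_matrix(m2)
  expect_equal(sort(q2[, 1]), sort(q2[, 2]))
  expect_equal(q2[, 1], c(5, 1, 3))

  # full operation: idempotent within 1e-9 and errors on a single array
  cfg <- simulation_config(seed = 23, n_genes = 50, n_arrays = 4,
                           n_printtips = 1)
  e <- generate_expression_experiment(cfg)
  n1 <- normalize_between_arrays(normalize_within_array(e))
  n2 <- normalize_between_arrays(n1)
  expect_equal(n1$data$M, n2$data$M, tolerance = 1e-9)
  expect_equal(n1$data$A, n2$data$A, tolerance = 1e-9)
  # all arrays share the same sorted intensity vector afterwards
  l2 <- with(n1$data, split(c(A + M / 2, A - M / 2),
                            rep(array_id, 2)))
  sorted <- lapply(l2, sort)
  for (i in 2:4) expect_equal(sorted[[i]], sorted[[1]], tolerance = 1e-9)

  single <- manual_experiment(matrix(0, 20, 1), matrix(8, 20, 1))
  expect_error(normalize_between_arrays(normalize_within_array(single)),
               "at least 2")
})

test_that("per-gene ANOVA has the classical two-sample behaviour", {
  # balanced two-group design: F equals the squared t statistic
  withr::with_seed(8, {
    M <- matrix(rnorm(6 * 8, 0, 0.3), nrow = 6)
    M[1, ] <- M[1, ] + rep(c(1, 0), each = 4)
  })
  A <- matrix(9, 6, 8)
  exp <- manual_experiment(M, A, groups = rep(c("mutant", "control"),
                                              each = 4))
  # skip normalisation: wrap intensities directly
  norm <- structure(list(
    data = data.frame(element_id = exp$elements$element_id,
                      gene_id = exp$elements$gene_id,
                      array_id = exp$elements$array_id,
                      printtip = 1L, M = c(M), A = c(A), filtered = FALSE),
    design = exp$design), class = "NormalizedExperiment")
  de <- anova_differential(norm)
  for (g in seq_len(6)) {
    x <- M[g, 1:4]; y <- M[g, 5:8]
    tt <- t.test(x, y, var.equal = TRUE)
    i <- match(sprintf("g%03d", g), de$gene_id)
    expect_equal(de$F[i], unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(de$p[i], tt$p.value, tolerance = 1e-9)
  }
  expect_identical(de$direction[match("g001", de$gene_id)], "up")

  # constant zero response: F = 0, p = 1
  norm0 <- norm
  norm0$data$M <- 0
  de0 <- anova_differential(norm0)
  expect_true(all(de0$F == 0))
  expect_true(all(de0$p == 1))

  # a gene without replication in a group is excluded from testing
  norm1 <- norm
  norm1$data$filtered[norm1$data$gene_id == "g002" &
                      norm1$data$array_id %in% c("a1", "a2", "a3")] <- TRUE
  de1 <- anova_differential(norm1)
  expect_true(is.na(de1$p[match("g002", de1$gene_id)]))
  expect_false(anyNA(de1$p[de1$gene_id != "g002"]))
})

test_that("spiked genes outrank null genes by F", {
  cfg <- simulation_config(seed = 41, n_genes = 200, n_arrays = 8,
                           n_printtips = 2, de_fraction = 0.1,
                           de_log2_effect = 1, noise_sd = 0.25)
  e <- generate_expression_experiment(cfg)
  norm <- normalize_between_arrays(normalize_within_array(e))
  de <- anova_differential(norm)
  f <- setNames(de$F, de$gene_id)
  spiked <- f[e$truth$gene_id[e$truth$is_de]]
  null <- f[e$truth$gene_id[!e$truth$is_de]]
  frac <- mean(outer(spiked, null, ">"))
  expect_gte(frac, 0.95)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4), tolerance = 1e-12)
  expect_identical(fdr_adjust(1), 1)
  withr::with_seed(12, {
    for (i in 1:100) {
      p <- runif(sample(1:40, 1))
      q <- fdr_adjust(p)
      expect_equal(q, bh_stepup_oracle(p), tolerance = 1e-12)
      expect_true(all(q >= p - 1e-15))
      expect_true(all(q <= 1))
    }
  })
  expect_error(fdr_adjust(c(0.5, 1.2)), "0,1")
})

test_that("target selection partitions by direction and respects q", {
  de <- structure(data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    F = c(30, 25, 1, 20), p = c(0.001, 0.002, 0.9, 0.004),
    q = c(0.01, 0.02, 0.9, 0.04),
    direction = c("down", "up", "up", "down"),
    effect = c(-1, 1, 0.1, -0.8), n_obs = 8L,
    stringsAsFactors = FALSE), class = c("DEResult", "data.frame"))
  sel <- select_targets(de, 0.05)
  expect_setequal(sel$down, c("g1", "g4"))
  expect_setequal(sel$up, "g2")
  expect_setequal(sel$selected, c(sel$down, sel$up))

  de$q <- rep(1, 4)
  empty <- select_targets(de, 0.05)
  expect_length(empty$selected, 0)
})

test_that("raw p-values are calibrated under the global null", {
  cfg <- simulation_config(seed = 55, n_genes = 1000, n_arrays = 8,
                           n_printtips = 2, de_fraction = 0,
                           noise_sd = 0.25)
  e <- generate_expression_experiment(cfg)
  norm <- normalize_between_arrays(normalize_within_array(
    filter_low_intensity(e)))
  de <- anova_differential(norm)
  p <- de$p[!is.na(de$p)]
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / length(p)) + 0.01)
})
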