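test_that("wing severity rank test behaves at the extremes", {
  ctrl <- severity_distribution(c(50, 30, 10, 5, 3, 2))

  # identical distributions: p = 1, no direction
  res <- wing_severity_test(ctrl, ctrl)
  expect_equal(res$p, 1)
  expect_identical(res$direction, "none")

  # complete separation: enhancer with vanishing p
  all1 <- severity_distribution(c(100, 0, 0, 0, 0, 0))
  all6 <- severity_distribution(c(0, 0, 0, 0, 0, 100))
  res2 <- wing_severity_test(all6, all1)
  expect_identical(res2$direction, "enhancer")
  expect_lt(res2$p, 1e-6)

  # symmetry: swapping the samples flips direction, keeps p
  shifted <- severity_distribution(c(20, 20, 20, 15, 15, 10))
  a <- wing_severity_test(shifted, ctrl)
  b <- wing_severity_test(ctrl, shifted)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_identical(a$direction, "enhancer")
  expect_identical(b$direction, "suppressor")

  expect_error(wing_severity_test(
    severity_distribution(c(30, 5)), ctrl), "class schemes")
  expect_error(wing_severity_test(
    severity_distribution(c(3, 2, 1, 0, 0, 0)), ctrl), "at least 10")
})

test_that("wing rank test p matches a permutation oracle", {
  ctrl <- severity_distribution(c(50, 30, 10, 5, 3, 2))
  shifted <- severity_distribution(c(20, 20, 20, 15, 15, 10))
  p_pkg <- wing_severity_test(shifted, ctrl)$p
  p_perm <- perm_ranksum_p(c(20, 20, 20, 15, 15, 10),
                           c(50, 30, 10, 5, 3, 2), B = 10000, seed = 6)
  # Monte-Carlo error at B = 10000 around p ~ a few 1e-3
  expect_lt(abs(p_pkg - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 10000) +
            0.003)

  # and agrees with the standard rank-sum implementation
  x <- rep(1:6, c(20, 20, 20, 15, 15, 10))
  y <- rep(1:6, c(50, 30, 10, 5, 3, 2))
  p_ref <- suppressWarnings(
    wilcox.test(x, y, exact = FALSE, correct = FALSE))$p.value
  expect_equal(p_pkg, p_ref, tolerance = 1e-9)
})

test_that("wing test is calibrated under the null", {
  # test crosses drawn from the control distribution itself
  probs <- c(50, 30, 10, 5, 3, 2) / 100
  ctrl <- severity_distribution(c(500, 300, 100, 50, 30, 20))
  n_sim <- 1000
  rejections <- vapply(seq_len(n_sim), function(i) {
    cross <- simulate_wing_cross(probs, 0, 100, seed = 20000 + i)
    wing_severity_test(cross, ctrl)$p < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_sim) + 0.01)
})

test_that("interactor calling follows the two-sex / two-allele concordance rules", {
  row <- function(allele, sex, p, dir) {
    data.frame(allele = allele, sex = sex, p = p, direction = dir,
               stringsAsFactors = FALSE)
  }
  # one allele, both sexes significant enhancers: "+"
  r1 <- rbind(row("a1", "female", 0.01, "enhancer"),
              row("a1", "male", 0.02, "enhancer"))
  expect_identical(call_wing_interactor(r1)$code, "+")

  # second allele significant in one sex only, same direction: still "+"
  r2 <- rbind(r1,
              row("a2", "female", 0.01, "enhancer"),
              row("a2", "male", 0.4, "none"))
  expect_identical(call_wing_interactor(r2)$code, "+")

  # two alleles with opposite significant directions: "0" with conflict
  r3 <- rbind(r1,
              row("a2", "female", 0.01, "suppressor"),
              row("a2", "male", 0.01, "suppressor"))
  c3 <- call_wing_interactor(r3)
  expect_identical(c3$code, "0")
  expect_true(c3$conflict)

  # single allele significant in one sex only: not an interactor
  r4 <- rbind(row("a1", "female", 0.01, "enhancer"),
              row("a1", "male", 0.2, "enhancer"))
  expect_identical(call_wing_interactor(r4)$code, "0")

  # both alleles significant in one sex only: no allele anchors the call
  r5 <- rbind(row("a1", "female", 0.01, "enhancer"),
              row("a1", "male", 0.2, "none"),
              row("a2", "female", 0.01, "enhancer"),
              row("a2", "male", 0.3, "none"))
  expect_identical(call_wing_interactor(r5)$code, "0")

  # suppressor path
  r6 <- rbind(row("a1", "female", 0.001, "suppressor"),
              row("a1", "male", 0.002, "suppressor"))
  expect_identical(call_wing_interactor(r6)$code, "-")
})

test_that("bristle control rate and binomial tails match closed forms", {
  expect_equal(bristle_control_rate(bristle_cross(99, 3, role = "control")),
               0.04, tolerance = 1e-12)
  expect_equal(bristle_control_rate(bristle_cross(9, 0, role = "control")),
               0.1, tolerance = 1e-12)
  expect_equal(bristle_control_rate(bristle_cross(7, 7, role = "control")), 1)
  expect_error(bristle_cross(10, 11, role = "control"), "exceed")

  # suppression tail at d = 0 is (1 - p)^m
  t0 <- bristle_binomial_test(bristle_cross(50, 0, role = "test"), 0.04)
  expect_equal(t0$p_suppress, 0.96^50, tolerance = 1e-12)
  expect_identical(t0$direction, "suppressor")

  # enhancement tail at d = m is p^m
  tm <- bristle_binomial_test(bristle_cross(20, 20, role = "test"), 0.3)
  expect_equal(tm$p_enhance, 0.3^20, tolerance = 1e-12)
  expect_identical(tm$direction, "enhancer")

  # exact tails match direct summation
  p_hat <- 0.04
  m <- 50
  for (d in c(1, 3, 8)) {
    tt <- bristle_binomial_test(bristle_cross(m, d, role = "test"), p_hat)
    up <- sum(choose(m, d:m) * p_hat^(d:m) * (1 - p_hat)^(m - (d:m)))
    dn <- sum(choose(m, 0:d) * p_hat^(0:d) * (1 - p_hat)^(m - (0:d)))
    expect_equal(tt$p_enhance, up, tolerance = 1e-12)
    expect_equal(tt$p_suppress, dn, tolerance = 1e-12)
    # tails overlap in exactly the observed atom
    expect_equal(tt$p_enhance + tt$p_suppress -
                 dbinom(d, m, p_hat), 1, tolerance = 1e-12)
  }

  # enhancement p decreases monotonically in d
  ps <- vapply(0:20, function(d) {
    bristle_binomial_test(bristle_cross(20, d, role = "test"), 0.1)$p_enhance
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("bristle screen FDR calling controls the error rate", {
  # single strong test is called
  one <- bristle_fdr_and_call(list(
    g1 = bristle_binomial_test(bristle_cross(100, 30, role = "test"), 0.05)))
  expect_identical(one$code, "+")

  # twenty flat tests: nothing called
  flat <- lapply(1:20, function(i) list(p = 0.5, direction = "enhancer"))
  expect_true(all(bristle_fdr_and_call(flat)$code == "0"))

  # simulated screen with 10% true (doubled-rate) effects keeps FDR <= 0.1
  p0 <- 0.15
  n_seeds <- 20
  fp <- 0L
  called <- 0L
  for (s in seq_len(n_seeds)) {
    tests <- lapply(1:50, function(i) {
      truth <- i <= 5
      cross <- simulate_bristle_cross(if (truth) 2 * p0 else p0, 200,
                                      seed = s * 1000 + i)
      cross$role <- "test"
      bristle_binomial_test(cross, p0)
    })
    names(tests) <- sprintf("g%02d", 1:50)
    calls <- bristle_fdr_and_call(tests, 0.05)
    sel <- calls$code != "0"
    called <- called + sum(sel)
    fp <- fp + sum(sel & seq_len(50) > 5)
  }
  expect_gt(called, 0)
  expect_lte(fp / max(called, 1), 0.1)
})

test_that("the packaged screen table parses and summarises to the published counts", {
  tab <- ldb_screen_table()
  expect_identical(nrow(tab), 39L)
  expect_identical(attr(tab, "sensitizers"), c("Dlmo", "ssdp", "Chip"))
  xbp1 <- tab[tab$symbol == "xbp1", ]
  expect_identical(unname(unlist(xbp1[, c("Dlmo", "ssdp", "Chip")])),
                   c("+", "-", "-"))

  s <- summarize_screen(tab)
  per <- s$per_column
  dlmo <- per[per$sensitizer == "Dlmo", ]
  expect_identical(dlmo$tested, 39L)
  expect_identical(dlmo$interacting, 28L)
  expect_identical(dlmo$enhancers, 25L)
  expect_identical(dlmo$suppressors, 3L)
  expect_identical(per$interacting[per$sensitizer == "ssdp"], 14L)
  expect_identical(per$interacting[per$sensitizer == "Chip"], 14L)
  expect_identical(s$bristle$tested, 28L)
  expect_identical(s$bristle$suppressor_roles, 12L)
  expect_identical(s$bristle$enhancer_roles, 11L)
  expect_identical(unname(s$bristle$suppressors_by_column), c(5L, 10L))
  expect_identical(unname(s$bristle$enhancers_by_column), c(9L, 4L))
  # the table-vs-text discrepancy on the both-sensitizer overlap is noted
  expect_identical(s$bristle$interacting_both, 6L)
  expect_true(length(s$notes) == 1L)

  # malformed cells are rejected with coordinates
  bad <- withr::local_tempfile(lines = c(
    "DGRC\tsymbol\tDlmo\tssdp\tChip", "CG1\tfoo\t+\tx\t0"))
  expect_error(parse_screen_table(bad), "row 1, column 'ssdp'")

  # all-"n" table: zero everywhere
  alln <- withr::local_tempfile(lines = c(
    "DGRC\tsymbol\tDlmo\tssdp\tChip", "CG1\tfoo\tn\tn\tn"))
  s0 <- summarize_screen(parse_screen_table(alln))
  expect_true(all(s0$per_column$tested == 0))
  expect_true(all(s0$per_column$interacting == 0))
})
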