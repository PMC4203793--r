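test_that("the combined statistic matches the hand-worked instance", {
  r <- two_part_test(c(0, 0, 1, 2, 3), c(4, 5, 6, 7, 8))
  expect_equal(r$Zp_sq, 2.5)
  expect_equal(r$Zw_sq, 5)
  expect_equal(r$statistic, 7.5)
  expect_equal(r$df, 2L)
  expect_equal(r$parts_used, "both")
  expect_equal(r$p, exp(-3.75))
})

test_that("identical all-positive groups carry no signal", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  r <- two_part_test(x, x)
  expect_equal(r$statistic, 0)
  expect_equal(r$df, 1L)
  expect_equal(r$parts_used, "wilcoxon_only")
  expect_equal(r$p, 1)
})

test_that("degenerate presence patterns fall back to single-df parts", {
  # one group entirely zero: the rank part is undefined
  r <- two_part_test(c(0, 0, 0, 0), c(1, 2, 0, 3))
  expect_equal(r$parts_used, "presence_only")
  expect_equal(r$df, 1L)
  expect_equal(r$statistic, r$Zp_sq)
  # everything positive: the presence part is uninformative
  r2 <- two_part_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$parts_used, "wilcoxon_only")
  expect_equal(r2$df, 1L)
  expect_equal(r2$Zp_sq, 0)
  expect_error(two_part_test(c(0, 0), c(0, 0, 0)), "prevalence")
  expect_error(two_part_test(1, c(1, 2)), "at least 2")
})

test_that("the test is symmetric in its two groups", {
  set.seed(10)
  for (i in 1:30) {
    x <- rbinom(6, 1, 0.7) * rlnorm(6)
    y <- rbinom(8, 1, 0.6) * rlnorm(8)
    if (all(c(x, y) == 0)) next
    a <- two_part_test(x, y)
    b <- two_part_test(y, x)
    expect_equal(a$statistic, b$statistic)
    expect_equal(a$df, b$df)
    expect_equal(a$p, b$p)
  }
})

test_that("the presence part can only add evidence on the df = 2 branch", {
  set.seed(11)
  for (i in 1:30) {
    x <- rbinom(8, 1, 0.8) * rlnorm(8)
    y <- rbinom(8, 1, 0.5) * rlnorm(8)
    r <- tryCatch(two_part_test(x, y), error = function(e) NULL)
    if (is.null(r) || r$parts_used != "both") next
    expect_gte(r$statistic, r$Zw_sq)
    expect_gte(r$statistic, r$Zp_sq)
  }
})

test_that("statistics agree with an independent re-derivation on random data", {
  set.seed(12)
  for (i in 1:40) {
    n1 <- sample(3:9, 1); n2 <- sample(3:9, 1)
    pool <- rbinom(n1 + n2, 1, 0.6) * round(rlnorm(n1 + n2), 2)
    if (all(pool == 0)) pool[1] <- 1
    x <- pool[seq_len(n1)]; y <- pool[-seq_len(n1)]
    r <- two_part_test(x, y)
    o <- oracle_two_part_stat(pool, seq_along(pool) <= n1)
    expect_equal(r$statistic, o[1])
    expect_equal(r$df, as.integer(o[2]))
  }
})

test_that("the comparison fit filters, tests, adjusts and sorts", {
  sim <- simulate_counts(sim_config_pnali(), seed = 42)
  fit <- two_part(sim$table, "control", "treatment")
  res <- summary(fit)
  expect_true(all(diff(res$p_raw) >= 0))
  expect_equal(res$p_adj, bh_fdr(res$p_raw))
  expect_true(all(res$p_adj >= res$p_raw))
  expect_equal(res$sig_05, res$p_raw < 0.05)
  # the filter gate matches the standalone operation
  expect_setequal(res$taxon,
                  prevalence_filter(sim$table, "control", "treatment"))
  expect_equal(fit$n_filtered, ncol(sim$table) - nrow(res))
  expect_named(coef(fit))
  expect_output(print(fit), "prevalence filter")
})

test_that("a table where no taxon passes the filter warns and returns empty", {
  # every taxon in 1/4 of its group's samples: all below 50% prevalence
  m <- diag(8)
  dimnames(m) <- list(paste0("s", 1:8), paste0("t", 1:8))
  tt <- taxon_table(m, groups = setNames(rep(c("A", "B"), each = 4),
                                         rownames(m)))
  expect_warning(fit <- two_part(tt, "A", "B"), "prevalence")
  expect_equal(nrow(summary(fit)), 0)
})

test_that("false-positive flags under a null study track the nominal rate", {
  nsig <- vapply(1:40, function(r) {
    sim <- simulate_counts(sim_config(n_groups = 2, samples_per_group = 14,
                                      n_taxa = 40), seed = 4000 + r)
    fit <- two_part(sim$table, "groupA", "groupB")
    sum(fit$results$sig_05)
  }, numeric(1))
  # roughly 5% of the ~20-25 retained taxa: around one or two per study
  expect_gt(mean(nsig), 0.2)
  expect_lt(mean(nsig), 3)
})

test_that("Kruskal-Wallis wraps the tie-corrected rank test with the total-tie convention", {
  kr <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kr$H, 27 / 7, tolerance = 1e-10)  # = 3.857
  expect_equal(kr$df, 1)
  expect_equal(kr$p, stats::pchisq(27 / 7, 1, lower.tail = FALSE))
  tie <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(tie$H, 0)
  expect_equal(tie$p, 1)
  expect_equal(tie$df, 2)
  expect_error(kruskal_wallis(list(1:3)), "at least 2")
})

test_that("the across-group screen covers all taxa and adjusts over them", {
  sim <- simulate_counts(sim_config(n_groups = 3, samples_per_group = 6,
                                    n_taxa = 20), seed = 60)
  kw <- kw_screen(sim$table)
  expect_equal(nrow(kw), 20)
  expect_equal(kw$df, rep(2, 20))
  expect_equal(kw$p_adj, bh_fdr(kw$p_raw))
})

test_that("BH adjustment matches the step-up definition exactly", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  # brute-force oracle across permutations of a length-6 vector
  p <- c(0.011, 0.32, 0.007, 0.95, 0.2, 0.07)
  perms <- rbind(1:6, 6:1, c(2, 4, 6, 1, 3, 5), c(3, 1, 2, 6, 5, 4))
  set.seed(13)
  for (i in 1:20) perms <- rbind(perms, sample(6))
  for (i in seq_len(nrow(perms))) {
    v <- p[perms[i, ]]
    expect_equal(bh_fdr(v), oracle_bh(v))
  }
  # monotone non-decreasing in raw-p rank order, capped at 1
  set.seed(14)
  v <- runif(25)
  adj <- bh_fdr(v)
  expect_true(all(diff(adj[order(v)]) >= -1e-12))
  expect_true(all(adj <= 1))
})
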