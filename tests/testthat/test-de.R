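two_group_md <- function(n_a, n_b, a = "T2Di_minus", b = "HC") {
  tibble::tibble(unit_id = paste0("u", seq_len(n_a + n_b)),
                 sample_id = paste0("u", seq_len(n_a + n_b)),
                 group = c(rep(a, n_a), rep(b, n_b)))
}

test_that("two-group OLS matches the closed form", {
  # groups {1,2,3} vs {5,6,7}: beta = 2 - 6 = -4, pooled s2 = 1, d = 4
  expr <- matrix(c(1, 2, 3, 5, 6, 7), 1, 6,
                 dimnames = list("g1", paste0("u", 1:6)))
  md <- two_group_md(3, 3)
  fit <- fit_contrast(expr, md, contrast_spec("c", "T2Di_minus", "HC"))
  expect_equal(fit$table$beta, -4)
  expect_equal(fit$table$s2, 1)
  expect_equal(fit$table$df, 4)
  expect_equal(fit$table$mean_a, 2)
  expect_equal(fit$table$mean_b, 6)

  # identical group means give beta = 0
  expr0 <- matrix(c(1, 2, 3, 1, 2, 3), 1, 6,
                  dimnames = list("g1", paste0("u", 1:6)))
  expect_equal(fit_contrast(expr0, md, contrast_spec("c", "T2Di_minus", "HC"))$table$beta, 0)

  # swapping the groups negates beta and leaves s2 unchanged
  swap <- fit_contrast(expr, md, contrast_spec("c", "HC", "T2Di_minus"))
  expect_equal(swap$table$beta, 4)
  expect_equal(swap$table$s2, fit$table$s2)

  # fewer than 2 units per group is an error
  expect_error(fit_contrast(expr[, 1:3, drop = FALSE], md,
                            contrast_spec("c", "T2Di_minus", "HC")),
               ">= 2 units")
})

test_that("zero-variance genes are flagged untestable and excluded from BH", {
  expr <- rbind(g1 = c(1, 2, 3, 5, 6, 7), g2 = rep(2, 6))
  colnames(expr) <- paste0("u", 1:6)
  md <- two_group_md(3, 3)
  fit <- fit_contrast(expr, md, contrast_spec("c", "T2Di_minus", "HC"))
  expect_equal(fit$table$testable, c(TRUE, FALSE))
  mod <- suppressWarnings(ebayes_moderate(fit))
  expect_true(is.na(mod$table$p_value[2]))
})

test_that("moderation follows the posterior-variance formula on a toy fit", {
  expr <- rbind(g1 = c(1, 2, 3, 5, 6, 7),
                g2 = c(0, 1, 2, 2, 3, 4),
                g3 = c(10, 12, 14, 11, 13, 15))
  colnames(expr) <- paste0("u", 1:6)
  md <- two_group_md(3, 3)
  fit <- fit_contrast(expr, md, contrast_spec("c", "T2Di_minus", "HC"))
  mod <- ebayes_moderate(fit, d0 = 4, s02 = 1)
  d <- fit$table$df
  expected_s2post <- (4 * 1 + d * fit$table$s2) / (4 + d)
  expect_equal(mod$table$s2_post, expected_s2post, tolerance = 1e-12)
  su <- sqrt(1 / 3 + 1 / 3)
  expected_t <- fit$table$beta / (sqrt(expected_s2post) * su)
  expect_equal(mod$table$t, expected_t, tolerance = 1e-12)
  expect_equal(mod$table$p_value, 2 * pt(-abs(expected_t), df = 4 + d),
               tolerance = 1e-12)
})

test_that("moderated t has the ordinary-t and pooled-variance limits", {
  withr::with_seed(42, {
    expr <- matrix(rnorm(50 * 8), 50, 8,
                   dimnames = list(sprintf("g%02d", 1:50), paste0("u", 1:8)))
  })
  md <- two_group_md(4, 4)
  fit <- fit_contrast(expr, md, contrast_spec("c", "T2Di_minus", "HC"))
  su <- fit$stdev_unscaled

  at0 <- ebayes_moderate(fit, d0 = 0, s02 = 1)
  ordinary_t <- fit$table$beta / (sqrt(fit$table$s2) * su)
  expect_equal(at0$table$t, ordinary_t, tolerance = 1e-12)

  atInf <- ebayes_moderate(fit, d0 = Inf, s02 = 0.8)
  expect_equal(atInf$table$s2_post, rep(0.8, 50), tolerance = 1e-12)
  expect_equal(atInf$table$t, fit$table$beta / (sqrt(0.8) * su),
               tolerance = 1e-12)
  # df = Inf: p values come from the normal limit
  expect_equal(atInf$table$p_value,
               2 * pnorm(-abs(atInf$table$t)), tolerance = 1e-12)
})

test_that("estimated hyperparameters agree with the independent limma fit", {
  withr::with_seed(7, {
    n_genes <- 400
    s2_true <- 1 / rgamma(n_genes, shape = 3, rate = 3)  # genuine variance spread
    expr <- matrix(rnorm(n_genes * 10, sd = rep(sqrt(s2_true), 10)), n_genes, 10,
                   dimnames = list(sprintf("g%03d", 1:n_genes), paste0("u", 1:10)))
  })
  md <- two_group_md(5, 5)
  fit <- ebayes_moderate(fit_contrast(expr, md, contrast_spec("c", "T2Di_minus", "HC")))

  design <- cbind(1, as.integer(md$group == "T2Di_minus"))
  lfit <- limma::eBayes(limma::lmFit(expr, design))
  expect_equal(fit$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(fit$s02, lfit$s2.prior, tolerance = 1e-6)
  expect_equal(unname(fit$table$t), unname(lfit$t[, 2]), tolerance = 1e-8)
  expect_equal(unname(fit$table$p_value), unname(lfit$p.value[, 2]),
               tolerance = 1e-8)
})

test_that("trigamma_inverse inverts trigamma across scales", {
  y <- c(0.01, 0.5, 1, 5, 100, 1e4)
  expect_equal(trigamma_inverse(trigamma(y)), y, tolerance = 1e-8)
})

test_that("bh_adjust equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.8)),
               c(0.04, 0.04, 16 / 300, 0.8), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(99, {
    for (i in 1:100) {
      p <- runif(sample(1:50, 1))
      expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    }
  })
})

test_that("run_contrasts applies BH within each (contrast, segment) list", {
  withr::with_seed(3, {
    expr <- matrix(rnorm(30 * 12), 30, 12,
                   dimnames = list(sprintf("g%02d", 1:30), paste0("u", 1:12)))
  })
  md <- tibble::tibble(unit_id = paste0("u", 1:12),
                       sample_id = paste0("u", 1:12),
                       group = rep(c("HC", "T2Di_minus"), each = 6),
                       segment = rep(c("PT", "TAL"), 6))
  res <- run_contrasts(expr, md, contrast_spec("c1", "T2Di_minus", "HC"))
  expect_setequal(unique(res$segment), c("PT", "TAL"))
  for (seg in c("PT", "TAL")) {
    sub <- res[res$segment == seg, ]
    expect_equal(sub$fdr, bh_adjust(sub$p_value), tolerance = 1e-12)
  }
  # deterministic: same input, same output
  expect_identical(res, run_contrasts(expr, md, contrast_spec("c1", "T2Di_minus", "HC")))
})

test_that("type-I error is calibrated on a null simulation", {
  cfg <- sim_config(n_genes = 800, segments = "PT",
                    cells_per_sample_per_segment = 30,
                    n_suppressed = 0, n_enhanced = 0, pathway_size = 0,
                    n_markers_per_segment = 1, delta = 0, seed = 19)
  sim <- simulate_cohort(cfg)
  md <- sim$metadata
  md$segment <- "PT"
  pb <- pseudobulk(sim$counts, md)
  expr <- normalize_log_cpm(pb$counts, scale = 1e6)
  res <- run_contrasts(expr, pb$metadata,
                       contrast_spec("c1", "T2Di_minus", "HC"))
  frac <- mean(res$p_value < 0.05, na.rm = TRUE)
  expect_lt(abs(frac - 0.05), 0.025)
})

test_that("tidy and glance expose the fit", {
  expr <- matrix(c(1, 2, 3, 5, 6, 7), 1, 6,
                 dimnames = list("g1", paste0("u", 1:6)))
  md <- two_group_md(3, 3)
  fit <- suppressWarnings(
    ebayes_moderate(fit_contrast(expr, md, contrast_spec("c", "T2Di_minus", "HC")),
                    d0 = 2, s02 = 1))
  expect_s3_class(tidy(fit), "tbl_df")
  g <- glance(fit)
  expect_equal(g$n_genes, 1)
  expect_equal(g$d0, 2)
})
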