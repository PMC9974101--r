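test_that("ssGSEA matches step-by-step enumeration on the 5-gene example", {
  expr <- matrix(c(5, 4, 3, 2, 1), 5, 1,
                 dimnames = list(paste0("g", 1:5), "u1"))
  set <- c("g1", "g2")
  got <- ssgsea_score(expr, set, alpha = 0.25)
  # walk in decreasing rank: g1 (r=5), g2 (4), g3 (3), g4 (2), g5 (1)
  w1 <- 5^0.25; w2 <- 4^0.25; W <- w1 + w2
  running <- c(w1 / W - 0,
               1 - 0,
               1 - 1 / 3,
               1 - 2 / 3,
               1 - 1)
  expect_equal(unname(got), sum(running), tolerance = 1e-9)
  expect_equal(unname(got),
               ssgsea_oracle(expr[, 1], rownames(expr), set, 0.25),
               tolerance = 1e-9)
})

test_that("ssGSEA equals the enumeration oracle on random units with ties", {
  withr::with_seed(8, {
    expr <- matrix(rpois(40 * 6, 3), 40, 6,
                   dimnames = list(sprintf("g%02d", 1:40), paste0("u", 1:6)))
    set <- sample(rownames(expr), 7)
  })
  got <- ssgsea_score(expr, set, alpha = 0.25)
  for (j in 1:6) {
    expect_equal(unname(got[j]),
                 ssgsea_oracle(expr[, j], rownames(expr), set, 0.25),
                 tolerance = 1e-9)
  }
})

test_that("ssGSEA is rank-based and monotone in the in-set expression", {
  withr::with_seed(9, {
    expr <- matrix(rlnorm(30 * 4), 30, 4,
                   dimnames = list(sprintf("g%02d", 1:30), paste0("u", 1:4)))
  })
  set <- rownames(expr)[1:6]
  base <- ssgsea_score(expr, set)

  # identical expression vectors give identical scores
  dup <- cbind(expr[, 1], expr[, 1])
  colnames(dup) <- c("a", "b")
  sd_ <- ssgsea_score(dup, set)
  expect_equal(sd_[["a"]], sd_[["b"]])

  # invariant to gene-order permutation
  perm <- expr[sample(nrow(expr)), ]
  expect_equal(ssgsea_score(perm, set), base)

  # invariant to strictly monotone transforms of a unit's expression
  expect_equal(ssgsea_score(log1p(expr), set), base, tolerance = 1e-12)
  expect_equal(ssgsea_score(expr^3, set), base, tolerance = 1e-12)

  # raising all in-set genes in one unit strictly increases its score
  boosted <- expr
  boosted[set, 2] <- boosted[set, 2] + 100
  expect_gt(ssgsea_score(boosted, set)[[2]], base[[2]])

  # error paths
  expect_error(ssgsea_score(expr, c("zzz")), "no genes")
  expect_error(ssgsea_score(expr, rownames(expr)), "out-of-set")
})

test_that("delta scores are zero at the reference and track score shifts", {
  md <- tibble::tibble(unit_id = paste0("u", 1:12),
                       sample_id = rep(paste0("s", 1:6), each = 2),
                       group = rep(c("HC", "T2Di_minus", "T2Di_plus"), each = 4),
                       segment = "PT")
  scores <- tibble::tibble(unit_id = md$unit_id, sample_id = md$sample_id,
                           group = md$group, segment = md$segment,
                           set_name = "S",
                           score = c(1, 1, 1, 1, 3, 3, 3, 3, 2, 2, 2, 2))
  d <- delta_pathway_score(scores, reference_group = "HC")
  expect_equal(d$delta[as.character(d$group) == "HC"], 0)
  expect_equal(d$delta[as.character(d$group) == "T2Di_minus"], 2)
  expect_equal(d$delta[as.character(d$group) == "T2Di_plus"], 1)

  # uniformly lower scores give a negative delta
  scores2 <- scores
  scores2$score[scores2$group != "HC"] <- 0.5
  d2 <- delta_pathway_score(scores2)
  expect_true(all(d2$delta[as.character(d2$group) != "HC"] < 0))

  # a segment without the reference group is omitted with a warning
  scores3 <- scores
  scores3$segment[scores3$group != "HC"] <- "TAL"
  expect_warning(d3 <- delta_pathway_score(scores3), "omitted")
  expect_false("TAL" %in% d3$segment[as.character(d3$group) != "HC"] &&
                 any(d3$segment == "TAL"))
})

test_that("deltas on label-shuffled groups are centered at zero", {
  withr::with_seed(14, {
    expr <- matrix(rpois(60 * 30, 4), 60, 30,
                   dimnames = list(sprintf("g%02d", 1:60), paste0("u", 1:30)))
  })
  md <- tibble::tibble(unit_id = paste0("u", 1:30),
                       sample_id = paste0("s", rep(1:15, each = 2)),
                       group = rep(c("HC", "T2Di_minus", "T2Di_plus"), each = 10),
                       segment = "PT")
  set <- rownames(expr)[1:10]
  tab <- score_table(expr, md, set)
  deltas <- numeric(100)
  for (i in 1:100) {
    shuffled <- tab
    shuffled$group <- withr::with_seed(1000 + i, sample(tab$group))
    d <- delta_pathway_score(shuffled, "HC")
    deltas[i] <- mean(d$delta[as.character(d$group) != "HC"])
  }
  expect_lt(abs(mean(deltas)), 2 * sd(deltas) / sqrt(100) + 1e-9)
})

test_that("cell-level and pseudobulk scoring agree on the delta sign", {
  cfg <- sim_config(n_genes = 250, cells_per_sample_per_segment = 8,
                    samples_per_group = c(HC = 4, T2Di_minus = 4, T2Di_plus = 6),
                    segments = c("PT", "TAL"),
                    n_suppressed = 0, n_enhanced = 0,
                    n_markers_per_segment = 3,
                    pathway_size = 25, pathway_delta = 1.5, pathway_rho = 0.8,
                    seed = 23)
  sim <- simulate_cohort(cfg)
  md <- sim$metadata
  md$segment <- sim$truth$cell_segments$segment[
    match(md$unit_id, sim$truth$cell_segments$unit_id)]
  set <- sim$truth$pathway_genes

  cell_expr <- normalize_log_cpm(sim$counts)
  d_cell <- delta_pathway_score(score_table(cell_expr, md, set), "HC")

  pb <- pseudobulk(sim$counts, md)
  pb_expr <- normalize_log_cpm(pb$counts, scale = 1e6)
  d_pb <- delta_pathway_score(score_table(pb_expr, pb$metadata, set), "HC")

  joined <- dplyr::inner_join(
    dplyr::filter(d_cell, as.character(group) != "HC"),
    dplyr::filter(d_pb, as.character(group) != "HC"),
    by = c("set_name", "segment", "group"))
  expect_true(all(sign(joined$delta.x) == sign(joined$delta.y)))
  # activation in disease, partial restoration: treated delta below untreated
  for (seg in c("PT", "TAL")) {
    dm <- d_cell$delta[d_cell$segment == seg &
                         as.character(d_cell$group) == "T2Di_minus"]
    dp <- d_cell$delta[d_cell$segment == seg &
                         as.character(d_cell$group) == "T2Di_plus"]
    expect_gt(dm, 0)
    expect_lt(dp, dm)
  }
})
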