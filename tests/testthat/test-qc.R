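test_that("gene-count bounds are inclusive and the mito rule is strict", {
  # cells with 499 / 500 / 5000 / 5001 detected genes
  n_genes <- 5200
  detected <- c(499, 500, 5000, 5001)
  m <- matrix(0L, n_genes, 4)
  for (j in seq_along(detected)) m[seq_len(detected[j]), j] <- 1L
  cm <- make_counts(m)
  suppressMessages(kept <- qc_filter(cm, qc_thresholds(500, 5000, 0.5)))
  expect_equal(kept$units, c("u2", "u3"))

  # mito fractions 0.6, 0.5 (boundary) and 0.4 on cells passing gene bounds:
  # one mito gene carries the mito counts, 600 other genes carry 1 each
  genes <- c(paste0("MT-", 1:5), paste0("g", 1:995))
  mk_cell <- function(mito_counts) {
    v <- integer(1000)
    v[1] <- mito_counts
    v[6:605] <- 1L
    v
  }
  m3 <- cbind(mk_cell(900L),   # 900/1500 = 0.6 mito
              mk_cell(600L),   # 600/1200 = 0.5 exactly
              mk_cell(400L))   # 400/1000 = 0.4
  dimnames(m3) <- list(genes, c("c60", "c50", "c40"))
  cm3 <- count_matrix(m3, "cell")
  suppressMessages(kept3 <- qc_filter(cm3, qc_thresholds(100, 5000, 0.5)))
  expect_equal(kept3$units, "c40")
})

test_that("wide-open thresholds are the identity and qc_filter is idempotent", {
  withr::with_seed(2, {
    m <- matrix(rpois(50 * 20, 1), 50, 20)
  })
  cm <- make_counts(m)
  suppressMessages(all_kept <- qc_filter(cm, qc_thresholds(1, Inf, 1)))
  expect_equal(as.matrix(all_kept$counts), as.matrix(cm$counts))

  thr <- qc_thresholds(25, 35, 0.5)
  suppressMessages(once <- qc_filter(cm, thr))
  suppressMessages(twice <- qc_filter(once, thr))
  expect_identical(as.matrix(twice$counts), as.matrix(once$counts))

  empty <- subset_counts(cm, units = integer(0))
  expect_warning(out <- qc_filter(empty, thr), "empty")
  expect_equal(ncol(out$counts), 0)
})

test_that("log-CPM normalization matches direct arithmetic", {
  m <- matrix(c(10L, 990L, 0L, 500L, 400L, 100L), 3, 2)
  cm <- make_counts(m)
  e <- normalize_log_cpm(cm, scale = 1e4)
  # count 10 of a 1000-count unit at scale 1e4 -> log2(1 + 100) = log2(101)
  expect_equal(e["g1", "u1"], log2(101), tolerance = 1e-12)
  expect_equal(log2(101), 6.65821148, tolerance = 1e-6)
  expect_equal(e["g3", "u1"], 0)  # zero count maps to exactly 0
  # monotone transform: within-unit rank order preserved
  expect_equal(order(e[, "u2"]), order(m[, 2]))

  bad <- make_counts(matrix(c(1L, 0L, 0L, 0L), 2, 2))
  expect_error(normalize_log_cpm(bad), "u2")
})

test_that("segment assignment follows marker scores with deterministic ties", {
  panel <- marker_panel(list(PT = c("m_pt1", "m_pt2"), TAL = c("m_tal1")))
  expr <- rbind(
    m_pt1 = c(5, 0, 1),
    m_pt2 = c(4, 0, 1),
    m_tal1 = c(0, 6, 1),
    other = c(1, 1, 1)
  )
  colnames(expr) <- c("cellPT", "cellTAL", "cellTie")
  out <- assign_segments(expr, panel)
  expect_equal(out$segment[out$unit_id == "cellPT"], "PT")
  expect_equal(out$segment[out$unit_id == "cellTAL"], "TAL")

  # exact tie on every score: first panel segment wins
  tied <- matrix(1, 4, 3, dimnames = dimnames(expr))
  out_tied <- assign_segments(tied, panel)
  expect_true(all(out_tied$segment == "PT"))

  # invariant to gene order permutation
  perm <- expr[c(3, 1, 4, 2), ]
  expect_equal(assign_segments(perm, panel)$segment, out$segment)

  # absent markers: dropped with a warning; fully absent segment errors
  panel2 <- marker_panel(list(PT = c("m_pt1", "missing"), TAL = "m_tal1"))
  expect_warning(assign_segments(expr, panel2), "absent")
  panel3 <- marker_panel(list(PT = "nowhere", TAL = "m_tal1"))
  expect_error(assign_segments(expr, panel3), "no marker genes")
})

test_that("marker-based assignment recovers planted segments", {
  cfg <- sim_config(n_genes = 300, cells_per_sample_per_segment = 6,
                    samples_per_group = c(HC = 3, T2Di_minus = 3, T2Di_plus = 3),
                    n_suppressed = 0, n_enhanced = 0, pathway_size = 0,
                    n_markers_per_segment = 10, marker_fold = 8,
                    delta = 0, seed = 17)
  sim <- simulate_cohort(cfg)
  expr <- normalize_log_cpm(sim$counts)
  out <- assign_segments(expr, marker_panel(sim$truth$marker_panel))
  truth <- sim$truth$cell_segments
  agree <- mean(out$segment == truth$segment[match(out$unit_id, truth$unit_id)])
  expect_gte(agree, 0.9)
})

test_that("pseudobulk sums member cells and conserves the grand total", {
  m <- matrix(c(1L, 10L, 2L, 20L, 3L, 30L, 7L, 70L), 2, 4)
  cm <- make_counts(m)
  md <- tibble::tibble(unit_id = paste0("u", 1:4),
                       sample_id = c("s1", "s1", "s1", "s2"),
                       group = "HC",
                       segment = c("PT", "PT", "PT", "PT"))
  pb <- pseudobulk(cm, md)
  expect_equal(as.vector(pb$counts$counts[, "s1.PT"]), c(1 + 2 + 3, 10 + 20 + 30))
  # a unit with a single member cell equals that cell
  expect_equal(as.vector(pb$counts$counts[, "s2.PT"]), c(7, 70))
  expect_equal(sum(pb$counts$counts), sum(cm$counts))
  expect_equal(pb$counts$unit_kind, "sample")
  expect_equal(sort(pb$metadata$n_cells), c(1L, 3L))

  # combinations with zero cells are omitted with a warning
  md2 <- md
  md2$segment <- c("PT", "PT", "PT", "DTL")
  cm2 <- subset_counts(cm, units = 1:3)
  expect_warning(pseudobulk(cm2, md2), "no cells")
})

test_that("fraction_expressing counts expressing cells per stratum", {
  m <- matrix(0L, 2, 8)
  m[1, 1:3] <- 1L          # gene g1 in 3 of 8 cells
  m[2, ] <- 1L             # gene g2 in all
  cm <- make_counts(m)
  md <- tibble::tibble(unit_id = paste0("u", 1:8), sample_id = "s1",
                       group = "HC", segment = "PT")
  out <- fraction_expressing(cm, md, "g1")
  expect_equal(out$fraction, 3 / 8)
  expect_equal(fraction_expressing(cm, md, "g2")$fraction, 1)
  m0 <- m; m0[1, ] <- 0L
  expect_equal(fraction_expressing(make_counts(m0), md, "g1")$fraction, 0)
  expect_error(fraction_expressing(cm, md, "absent"), "not present")
  # empty stratum: no row reported
  expect_equal(nrow(fraction_expressing(cm, md, "g1", group = "T2Di_plus")), 0)
})
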