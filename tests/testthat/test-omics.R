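test_that("feature stats match the textbook t-test oracle", {
  sim <- simulate_abundance(omics_sim_params(n_features = 50, frac_up = 0.1,
                                             frac_down = 0.1, noise_cv = 0.2,
                                             seed = 21))
  st <- compute_feature_stats(sim$table)
  tab <- sim$table
  for (i in seq_len(50)) {
    ctrl <- tab$values[i, tab$groups == "control"]
    trt <- tab$values[i, tab$groups == "treatment"]
    ref <- stats::t.test(trt, ctrl, var.equal = TRUE)
    expect_equal(st$p[i], ref$p.value, tolerance = 1e-12)
    expect_equal(st$fc[i], mean(trt) / mean(ctrl), tolerance = 1e-12)
  }
  expect_equal(st$p_adj, stats::p.adjust(st$p, "BH"))
  expect_true(all(st$p_adj >= st$p - 1e-15))

  # Welch variant against its oracle
  stw <- compute_feature_stats(sim$table, var_equal = FALSE)
  for (i in c(1, 17, 50)) {
    ctrl <- tab$values[i, tab$groups == "control"]
    trt <- tab$values[i, tab$groups == "treatment"]
    expect_equal(stw$p[i], stats::t.test(trt, ctrl)$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate and null features are handled per contract", {
  # identical replicates: fc = 1, p = 1 (zero variance, equal means, flagged)
  tab <- abundance_table(c("a", "b"),
                         rbind(c(1, 2, 3, 1, 2, 3),
                               c(10, 10, 10, 20, 20, 20)),
                         rep(c("control", "treatment"), each = 3))
  st <- compute_feature_stats(tab)
  expect_equal(st$fc[1], 1)
  expect_equal(st$p[1], 1)
  expect_false(st$degenerate[1])
  # constant but different groups: fc = 2, degenerate, p = 0
  expect_equal(st$fc[2], 2)
  expect_true(st$degenerate[2])
  expect_equal(st$p[2], 0)
})

test_that("classification implements the printed threshold rules", {
  thr <- screen_preset("proteomic")
  st <- data.frame(feature_id = c("a", "b", "c", "d", "e"),
                   mean_ctrl = 1, mean_trt = 1,
                   fc = c(1.2, 0.95, 1.2, 0.85, 1.05),
                   p = c(0.01, 0.001, 0.2, 0.04, 0.001),
                   p_adj = c(0.05, 0.005, 0.4, 0.08, 0.005),
                   degenerate = FALSE, cls = NA_character_)
  cls <- classify_features(st, thr)$cls
  expect_equal(cls, c("up",   # fc 1.2 > 1.1, p < 0.05
                      "ns",   # 0.95 not < 0.9 despite tiny p
                      "ns",   # fails alpha
                      "down", # 0.85 < 0.9, p < 0.05
                      "ns"))  # 1.05 inside (0.9, 1.1)
  # bh_adjusted mode switches the compared p
  thr_bh <- screen_thresholds(1.1, 0.9, 0.05, "bh_adjusted")
  expect_equal(classify_features(st, thr_bh)$cls[4], "ns")  # p_adj 0.08
})

test_that("counts are conserved and thresholds act monotonically", {
  sim <- simulate_abundance(omics_sim_params(n_features = 400, frac_up = 0.1,
                                             frac_down = 0.1, noise_cv = 0.1,
                                             seed = 5))
  st <- compute_feature_stats(sim$table)
  cl <- classify_features(st, screen_preset("proteomic"))
  expect_equal(sum(cl$cls == "up") + sum(cl$cls == "down") +
                 sum(cl$cls == "ns"), nrow(cl))
  n_dep <- function(thr) {
    x <- classify_features(st, thr)
    sum(x$cls != "ns")
  }
  # shrinking alpha never increases DEP counts
  a_counts <- vapply(c(0.2, 0.1, 0.05, 0.01, 0.001),
                     function(a) n_dep(screen_thresholds(1.1, 0.9, a)),
                     numeric(1))
  expect_true(all(diff(a_counts) <= 0))
  # widening the fc window never increases DEP counts
  f_counts <- vapply(list(c(1.05, 0.95), c(1.1, 0.9), c(1.3, 0.75), c(2, 0.5)),
                     function(fb) n_dep(screen_thresholds(fb[1], fb[2], 0.05)),
                     numeric(1))
  expect_true(all(diff(f_counts) <= 0))
})

test_that("noiseless planted effects are recovered exactly", {
  sim <- simulate_abundance(omics_sim_params(n_features = 200, frac_up = 0.1,
                                             frac_down = 0.1, effect_fc = 2,
                                             noise_cv = 0, seed = 3))
  st <- compute_feature_stats(sim$table)
  # noiseless groups are exactly constant: p = 0 for planted, 1 for null
  cl <- classify_features(st, screen_preset("proteomic"))
  expect_equal(unname(cl$cls), unname(ifelse(sim$truth == "null", "ns",
                                             sim$truth)))
})

test_that("screen summaries reproduce the worked percentage arithmetic", {
  s <- summarize_screen(7190, n_up = 157, n_down = 114)
  expect_identical(s$pct_up, 2.18)
  expect_identical(s$pct_down, 1.59)
  expect_identical(s$n_total_dep, 271)
  s2 <- summarize_screen(2012, n_up = 345, n_down = 163)
  expect_identical(s2$pct_up, 17.15)
  expect_identical(s2$pct_down, 8.10)
  s3 <- summarize_screen(100, n_up = 0, n_down = 0)
  expect_identical(s3$pct_up, 0)
  expect_identical(s3$n_total_dep, 0)
  expect_error(summarize_screen(10, n_up = 7, n_down = 4),
               class = "photomics_param_error")
  # from a classified table
  df <- data.frame(cls = c("up", "up", "down", "ns"))
  s4 <- summarize_screen(df)
  expect_equal(s4$n_identified, 4)
  expect_equal(s4$pct_up, 50)
})

test_that("gene-set intersection matches brute force and is symmetric", {
  a <- with_seed_test(7L, sample(sprintf("gene%04d", 1:2000), 500))
  b <- with_seed_test(8L, sample(sprintf("gene%04d", 1:2000), 661))
  r <- intersect_gene_sets(a, b)
  # brute-force double loop
  brute <- 0L
  an <- normalize_ids(a); bn <- normalize_ids(b)
  for (x in an) for (y in bn) if (x == y) brute <- brute + 1L
  expect_equal(r$count, brute)
  expect_equal(intersect_gene_sets(b, a)$count, r$count)
  expect_equal(intersect_gene_sets(b, a)$ids, r$ids)
  # subset / disjoint / empty / normalization
  expect_equal(intersect_gene_sets(c("x1", "x2"), c("y1", "y2"))$count, 0)
  expect_equal(intersect_gene_sets(c("x1", "x2"), c("x1", "x2", "x3"))$count, 2)
  expect_equal(intersect_gene_sets(character(0), c("x1"))$count, 0)
  expect_equal(intersect_gene_sets("Gpx4", gene_set("s", "GPX4"))$count, 1)
  expect_equal(intersect_gene_sets("ENSMUSG01.4", c("ensmusg01"))$count, 1)
})

test_that("hypergeometric enrichment matches enumeration and edge cases", {
  # spot configuration from the closed-form oracle
  r <- enrichment_test(sprintf("d%d", 1:5),
                       gene_set("pw", c("d1", "d2", "d3", "b1")),
                       c(sprintf("d%d", 1:5), sprintf("b%d", 1:5)))
  expect_equal(r$k, 3); expect_equal(r$M, 4); expect_equal(r$n, 5)
  expect_equal(r$N, 10)
  expect_equal(r$p_hyper, hyper_tail_oracle(3, 4, 10, 5), tolerance = 1e-12)
  expect_equal(r$enrichment_factor, 3 / 4)

  # pathway entirely inside the DEP set
  r1 <- enrichment_test(c("a", "b", "c"), gene_set("pw", c("a", "b")),
                        c("a", "b", "c", "d"))
  expect_equal(r1$enrichment_factor, 1)
  # empty overlap
  r0 <- enrichment_test(c("a", "b"), gene_set("pw", c("x")),
                        c("a", "b", "x", "y"))
  expect_equal(r0$enrichment_factor, 0)
  expect_equal(r0$p_hyper, 1)
  # pathway absent from background: factor 0, flagged
  rM0 <- enrichment_test(c("a"), gene_set("pw", c("zz")), c("a", "b"))
  expect_true(rM0$empty_pathway)
  expect_equal(rM0$enrichment_factor, 0)
  # dep must be a subset of background
  expect_error(enrichment_test(c("q"), gene_set("pw", "a"), c("a", "b")),
               class = "photomics_data_error")
})

test_that("hub ranking equals a brute-force degree recount", {
  net <- simulate_network(25, 60, planted_hubs = c(g003 = 15L), seed = 13)
  rk <- rank_hubs(net, top_k = 25)
  deg <- sapply(net$nodes, function(v) {
    sum(net$edges$from == v) + sum(net$edges$to == v)
  })
  o <- order(-deg, names(deg))
  expect_equal(rk$id, names(deg)[o])
  expect_equal(rk$degree, unname(deg[o]))
  expect_equal(rk$id[1], "g003")
  expect_equal(rk$degree[1], 15)

  # star graph: center first
  star <- interaction_network(rep("c", 4), c("a", "b", "d", "e"))
  expect_equal(rank_hubs(star, 1)$id, "c")
  expect_equal(rank_hubs(star, 1)$degree, 4)
  # empty graph: all degrees 0, lexicographic order
  empty <- interaction_network(character(0), character(0),
                               nodes = c("b", "a", "c"))
  rk0 <- rank_hubs(empty, 3)
  expect_equal(rk0$id, c("a", "b", "c"))
  expect_equal(rk0$degree, c(0, 0, 0))
  # over-long request truncates with a warning
  expect_warning(rank_hubs(star, 99), "truncat")
})
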