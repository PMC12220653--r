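test_that("coverage filter applies strict thresholds on both medians", {
  cfg <- filter_config()
  alt_good <- mk_hits(c(0.95, 0.95), query_id = "a1")
  expect_true(coverage_filter(mk_hits(c(0.45, 0.45, 0.5)), alt_good, cfg)$pass)
  # exactly 60% reference median fails the strict '<'
  expect_false(coverage_filter(mk_hits(c(0.6, 0.6)), alt_good, cfg)$pass)
  expect_true(coverage_filter(mk_hits(c(0.599, 0.599)), alt_good, cfg)$pass)
  # exactly 70% alternate median fails the strict '>'
  expect_false(coverage_filter(mk_hits(c(0.45)), mk_hits(0.70, query_id = "a1"), cfg)$pass)
  expect_true(coverage_filter(mk_hits(c(0.45)), mk_hits(0.701, query_id = "a1"), cfg)$pass)
  # missing hits on either side fail with NA medians recorded
  res <- coverage_filter(mk_hits(numeric()), alt_good, cfg)
  expect_false(res$pass)
  expect_true(is.na(res$ref_median_cov))
})

test_that("subset filter requires alternate targets to be contained in reference targets", {
  ref <- mk_hits(c(0.5, 0.5, 0.5), target_ids = c("T1", "T2", "T3"))
  expect_true(subset_filter(ref, mk_hits(c(0.9, 0.9), query_id = "a",
                                         target_ids = c("T1", "T3"))))
  expect_false(subset_filter(mk_hits(0.5, target_ids = "T1"),
                             mk_hits(c(0.9, 0.9), query_id = "a",
                                     target_ids = c("T1", "T4"))))
  expect_true(subset_filter(ref, mk_hits(c(0.9, 0.9, 0.9), query_id = "a",
                                         target_ids = c("T1", "T2", "T3"))))
  expect_false(subset_filter(ref, mk_hits(numeric(), query_id = "a")))
})

test_that("interval shrinking removes floor(L*f/2) from each end and preserves degenerate intervals", {
  expect_equal(shrink_interval(100L, 300L, 0.10), data.table(start = 110L, end = 290L))
  expect_equal(shrink_interval(5L, 6L, 0.10), data.table(start = 5L, end = 6L))
  expect_equal(shrink_interval(1L, 1L, 0.10), data.table(start = 1L, end = 1L))
  # collapse to the midpoint residue when shrinking would empty the interval
  expect_equal(shrink_interval(10L, 13L, 1.2), data.table(start = 11L, end = 11L))
})

test_that("interval clustering merges transitively overlapping intervals but not abutting ones", {
  cl <- cluster_intervals(c(1L, 90L, 400L), c(100L, 200L, 500L))
  expect_equal(nrow(cl$clusters), 2L)
  expect_equal(cl$clusters$span_start, c(1L, 400L))
  expect_equal(cl$clusters$span_end, c(200L, 500L))
  expect_equal(cl$membership, c(1L, 1L, 2L))
  abut <- cluster_intervals(c(1L, 11L), c(10L, 20L))
  expect_equal(nrow(abut$clusters), 2L)
  expect_equal(nrow(cluster_intervals(5L, 50L)$clusters), 1L)
  expect_equal(nrow(cluster_intervals(integer(), integer())$clusters), 0L)
})

test_that("interval clustering agrees with a brute-force transitive-overlap oracle", {
  set.seed(1234)
  for (rep in 1:1000) {
    n <- sample(1:20, 1)
    s <- sample(1:480, n, replace = TRUE)
    e <- pmin(500L, s + sample(0:60, n, replace = TRUE))
    got <- cluster_intervals(as.integer(s), as.integer(e))
    want <- brute_clusters(s, e)
    expect_equal(nrow(got$clusters), want$count)
    expect_equal(got$clusters[, .(span_start, span_end)], want$spans)
  }
})

test_that("increasing the shrink fraction never decreases the cluster count", {
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(2:15, 1)
    s <- sample(1:400, n, replace = TRUE)
    e <- pmin(500L, s + sample(5:120, n, replace = TRUE))
    counts <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), function(f) {
      shr <- shrink_interval(as.integer(s), as.integer(e), f)
      nrow(cluster_intervals(shr$start, shr$end)$clusters)
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("clustering filter demands two clusters and strict >50% union coverage of unshrunk hits", {
  cfg <- filter_config()
  two <- mk_interval_hits(c(1L, 310L), c(290L, 600L), q_len = 600L)
  res <- clustering_filter(two, 600L, cfg)
  expect_true(res$pass)
  expect_equal(res$cluster_count, 2L)
  expect_equal(res$total_query_cov, (290 + 291) / 600)
  one <- mk_interval_hits(c(1L, 20L), c(250L, 240L), q_len = 600L)
  res1 <- clustering_filter(one, 600L, cfg)
  expect_false(res1$pass)
  expect_equal(res1$cluster_count, 1L)
  # exactly 50% union coverage fails the strict '>'
  half <- mk_interval_hits(c(1L, 401L), c(150L, 550L), q_len = 600L)
  resh <- clustering_filter(half, 600L, cfg)
  expect_equal(resh$cluster_count, 2L)
  expect_equal(resh$total_query_cov, 0.5)
  expect_false(resh$pass)
})

test_that("the scan recovers planted chimeras exactly with correct component counts", {
  b <- simulate_bundle(simulation_config(seed = 42, n_genes = 60, n_chimeras = 10))
  calls <- scan_chimeras(b$ref, b$alt, b$ref_hits, b$alt_hits)
  truth <- b$truth[is_chimera == TRUE]
  cand <- calls[verdict == "candidate"]
  expect_setequal(cand$ref_gene_id, truth$ref_gene_id)
  m <- merge(cand, truth, by = "ref_gene_id")
  expect_equal(m$cluster_count, m$component_count)
  s <- attr(calls, "summary")
  expect_equal(s$assessed, s$candidates + Reduce(`+`, s$rejected))
})

test_that("every planted component count from 2 to 6 is recovered as the cluster count", {
  for (k in 2:6) {
    cfg <- simulation_config(seed = 100 + k, n_genes = 12, n_chimeras = 3,
                             component_count_weights = setNames(1, as.character(k)))
    b <- simulate_bundle(cfg)
    calls <- scan_chimeras(b$ref, b$alt, b$ref_hits, b$alt_hits)
    cand <- calls[verdict == "candidate"]
    expect_setequal(cand$ref_gene_id, b$truth[is_chimera == TRUE, ref_gene_id])
    expect_equal(sort(unique(cand$cluster_count)), k)
  }
})

test_that("a gene is a candidate iff it passes all three filters, independent of evaluation order", {
  b <- simulate_bundle(simulation_config(seed = 8, n_genes = 40, n_chimeras = 8,
                                         coverage_noise_sd = 0.02))
  cfg <- filter_config()
  links <- link_annotations(b$ref, b$alt)
  calls <- scan_chimeras(b$ref, b$alt, b$ref_hits, b$alt_hits, links, cfg)
  for (i in seq_len(nrow(calls))) {
    gid <- calls$ref_gene_id[i]
    rh <- b$ref_hits[query_id == gid]
    ah <- b$alt_hits[query_id %in% links[ref_gene_id == gid, alt_gene_id]]
    p1 <- coverage_filter(rh, ah, cfg)$pass
    p2 <- subset_filter(rh, ah)
    p3 <- clustering_filter(rh, rh$q_len[1], cfg)$pass
    expect_equal(calls$verdict[i] == "candidate", p1 && p2 && p3)
  }
})

test_that("hits naming unknown proteins abort the scan", {
  b <- simulate_bundle(simulation_config(seed = 2, n_genes = 8, n_chimeras = 1))
  bad <- copy(as.data.table(b$ref_hits))
  bad$query_id[1] <- "not_a_gene"
  expect_error(scan_chimeras(b$ref, b$alt, hit_table(bad), b$alt_hits),
               "absent from reference", class = "cs_data_error")
})
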