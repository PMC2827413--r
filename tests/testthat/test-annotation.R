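test_that("functional composition arithmetic is exact", {
  ann <- tibble::tibble(
    feature = paste0("f", 1:10),
    category = c(rep("metabolism", 5), rep("storage protein", 2),
                 "transcription factor", "unknown", "unknown")
  )
  sm <- summarize_function(paste0("f", 1:10), ann)
  expect_equal(sm$percent[sm$category == "metabolism"], 50)
  expect_equal(sum(sm$percent), 100)
  # all features one category
  one <- summarize_function(paste0("f", 1:5), ann)
  expect_equal(one$percent[one$category == "metabolism"], 100)
  # unannotated features fall back to unknown
  extra <- summarize_function(c("f1", "not_on_array"), ann)
  expect_equal(extra$count[extra$category == "unknown"], 1L)
  expect_error(summarize_function(character(), ann), "empty")
})

test_that("planted TF fraction is recovered within binomial error", {
  sim <- generate_expression(expression_sim_spec(seed = 18))
  planted <- sim$truth$planted
  sm <- summarize_function(planted, sim$annotation)
  tf_pct <- sm$percent[sm$category == "transcription factor"]
  # tf_fraction 0.06 of 150 planted members; binomial 3-sigma band
  expect_lt(abs(tf_pct / 100 - 0.06), 3 * sqrt(0.06 * 0.94 / 150))
})

test_that("marker-bearing clusters are selected and ranked", {
  pm <- planted_profile_matrix(n_per_group = 20, noise_sd = 0.05, seed = 19)
  cl <- cluster_profiles(pm$x, k = 3, seed = 3)
  # markers concentrated in group 1 plus one in group 2
  markers <- c(rownames(pm$x)[1:5], "g2_f01")
  sel <- select_clusters(cl, markers)
  expect_equal(nrow(sel), 2L)
  expect_equal(sel$n_markers, c(5L, 1L))
  expect_equal(sel$cluster[1], unname(cl$assignment["g1_f01"]))
  # fraction gate drops the weak cluster
  strict <- select_clusters(cl, markers, min_fraction = 0.5)
  expect_equal(nrow(strict), 1L)
  # disjoint markers: empty selection with a warning
  expect_warning(empty <- select_clusters(cl, "absent_feature"), "no marker")
  expect_equal(nrow(empty), 0L)
  expect_error(select_clusters(cl, character()), "non-empty")
})

test_that("markers spread over three of five clusters select exactly those", {
  sim <- generate_expression(expression_sim_spec(seed = 20))
  chain <- run_selection_chain(sim)
  mk <- intersect(sim$truth$markers, chain$venn$common)
  sel <- select_clusters(chain$clusters, mk)
  marker_clusters <- unique(unname(chain$clusters$assignment[mk]))
  expect_setequal(sel$cluster, marker_clusters)
})

test_that("TF candidates are ranked by correlation with the marker profile", {
  # one TF tracking the markers, one anti-correlated
  t <- seq_len(12)
  prof <- sin(2 * pi * t / 12)
  withr::with_seed(21, {
    x <- rbind(
      m1 = prof + rnorm(12, sd = 0.05), m2 = prof + rnorm(12, sd = 0.05),
      m3 = prof + rnorm(12, sd = 0.05),
      tf_up = prof + rnorm(12, sd = 0.05),
      tf_down = -prof + rnorm(12, sd = 0.05)
    )
  })
  colnames(x) <- sprintf("s%02d", t)
  cl <- cluster_profiles(x, k = 1, seed = 1)
  ann <- tibble::tibble(
    feature = rownames(x),
    category = c(rep("metabolism", 3), rep("transcription factor", 2))
  )
  cand <- extract_tf_candidates(cl, ann, markers = c("m1", "m2", "m3"))
  expect_equal(cand$feature, c("tf_up", "tf_down"))
  expect_gt(cand$correlation_to_markers[1], 0.9)
  expect_lt(cand$correlation_to_markers[2], -0.9)
})

test_that("no TF annotation in the selection gives an empty candidate list", {
  pm <- planted_profile_matrix(n_per_group = 5, seed = 22)
  cl <- cluster_profiles(pm$x, k = 3, seed = 1)
  ann <- tibble::tibble(feature = rownames(pm$x), category = "metabolism")
  cand <- extract_tf_candidates(cl, ann, markers = rownames(pm$x)[1:3])
  expect_equal(nrow(cand), 0L)
})

test_that("planted co-regulated TFs surface as candidates across seeds", {
  hits <- vapply(1:10, function(s) {
    sim <- generate_expression(expression_sim_spec(noise_sd = 0.2, seed = s))
    chain <- run_selection_chain(sim, cluster_seed = s)
    mean(sim$truth$tf_features %in% chain$candidates$feature)
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
})
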