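two_group_design <- function(n_rep, experiment = "exp1",
                             conditions = c("A", "B")) {
  tibble::tibble(
    sample = paste0(rep(conditions, each = n_rep), seq_len(n_rep)),
    experiment = experiment,
    condition = rep(conditions, each = n_rep),
    replicate = rep(seq_len(n_rep), 2)
  )
}

noise_free_matrix <- function(values_a, values_b, n_rep) {
  m <- cbind(matrix(rep(values_a, n_rep), ncol = n_rep),
             matrix(rep(values_b, n_rep), ncol = n_rep))
  dimnames(m) <- list(paste0("f", seq_along(values_a)),
                      two_group_design(n_rep)$sample)
  m
}

test_that("fold change is the orientation-free mean ratio", {
  m <- noise_free_matrix(c(1, 2, 3), c(4, 2, 0.5), 2)
  de <- select_differential(m, two_group_design(2), "exp1", pair = c("A", "B"))
  expect_equal(de$fold_change, c(4, 1, 6))
  # identical feature: no change, cannot pass
  expect_false(de$passes[2])
  expect_equal(de$p_value[2], 1)
})

test_that("swapping the condition pair changes nothing but the sign", {
  withr::with_seed(4, {
    m <- matrix(2^rnorm(80, 5, 1), 10, 8,
                dimnames = list(paste0("f", 1:10),
                                two_group_design(4)$sample))
  })
  des <- two_group_design(4)
  ab <- select_differential(m, des, "exp1", pair = c("A", "B"))
  ba <- select_differential(m, des, "exp1", pair = c("B", "A"))
  expect_equal(ab$fold_change, ba$fold_change)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$passes, ba$passes)
  expect_equal(ab$log2_fc, -ba$log2_fc)
})

test_that("BH correction is gated on the replicate count", {
  withr::with_seed(5, {
    m2 <- matrix(2^rnorm(40, 5, 0.3), 10, 4,
                 dimnames = list(paste0("f", 1:10), two_group_design(2)$sample))
    m4 <- matrix(2^rnorm(80, 5, 0.3), 10, 8,
                 dimnames = list(paste0("f", 1:10), two_group_design(4)$sample))
  })
  de2 <- select_differential(m2, two_group_design(2), "exp1", pair = c("A", "B"))
  expect_false(attr(de2, "corrected"))
  expect_true(all(is.na(de2$adjusted_p)))
  de4 <- select_differential(m4, two_group_design(4), "exp1", pair = c("A", "B"))
  expect_true(attr(de4, "corrected"))
  expect_true(all(de4$adjusted_p >= de4$p_value))
  expect_equal(de4$adjusted_p, bh_adjust_oracle(de4$p_value))
  # explicit override beats the gate
  de2f <- select_differential(m2, two_group_design(2), "exp1",
                              pair = c("A", "B"), correct = "bh")
  expect_true(attr(de2f, "corrected"))
})

test_that("BH equals the brute-force step-up oracle on short grid vectors", {
  grid <- seq(0.01, 0.99, by = 0.01)
  # exhaustive over a coarse sub-grid for lengths 1..3
  coarse <- c(0.01, 0.05, 0.2, 0.5, 0.99)
  for (len in 1:3) {
    combos <- as.matrix(expand.grid(rep(list(coarse), len)))
    for (i in seq_len(nrow(combos))) {
      p <- unname(combos[i, ])
      expect_equal(p.adjust(p, "BH") <= 0.05, bh_select_oracle(p, 0.05))
      expect_equal(unname(p.adjust(p, "BH")), bh_adjust_oracle(p))
    }
  }
  # random fine-grid vectors up to length 8
  withr::with_seed(6, {
    for (i in 1:300) {
      p <- sample(grid, sample(1:8, 1), replace = TRUE)
      expect_equal(unname(p.adjust(p, "BH")), bh_adjust_oracle(p))
      expect_equal(p.adjust(p, "BH") <= 0.05, bh_select_oracle(p, 0.05))
    }
  })
})

test_that("adjusted p-values are monotone in the raw p ranking", {
  withr::with_seed(7, {
    for (i in 1:20) {
      p <- runif(8)
      adj <- p.adjust(p, "BH")
      o <- order(p)
      expect_true(all(diff(adj[o]) >= -1e-15))
    }
  })
})

test_that("the extreme-pair convenience mode contrasts min vs max condition", {
  sim <- generate_expression(expression_sim_spec(n_features = 200, seed = 8))
  norm <- normalize_expression(sim$matrix)
  de_auto <- select_differential(norm, sim$design, "growth_velocity")
  expect_setequal(attr(de_auto, "pair"), c("growing", "nongrowing"))
})

test_that("invalid contrasts are rejected", {
  m <- noise_free_matrix(c(1, 2), c(2, 4), 2)
  des <- two_group_design(2)
  expect_error(select_differential(m, des, "nope", pair = c("A", "B")),
               "not found")
  expect_error(select_differential(m, des, "exp1", pair = c("A", "C")),
               "conditions")
  des1 <- des[des$replicate == 1 | des$condition == "A", ]
  expect_error(select_differential(m[, des1$sample], des1, "exp1",
                                   pair = c("A", "B")), "2 replicates")
  mz <- noise_free_matrix(c(0, 1), c(1, 1), 2)
  expect_error(select_differential(mz, des, "exp1", pair = c("A", "B")),
               "zero")
})

test_that("under a complete null the raw false-positive rate is ~alpha", {
  withr::with_seed(9, {
    fp <- vapply(1:10, function(i) {
      m <- matrix(2^rnorm(1000 * 8, 5, 0.25), 1000, 8,
                  dimnames = list(sprintf("f%04d", 1:1000),
                                  two_group_design(4)$sample))
      de <- select_differential(m, two_group_design(4), "exp1",
                                pair = c("A", "B"), correct = "none")
      mean(de$p_value <= 0.05)
    }, numeric(1))
  })
  expect_lt(abs(mean(fp) - 0.05), 0.01)
})

test_that("volcano autoplot returns a ggplot", {
  m <- noise_free_matrix(c(1, 2, 8), c(4, 2, 1), 2)
  de <- select_differential(m, two_group_design(2), "exp1", pair = c("A", "B"))
  expect_s3_class(autoplot(de), "ggplot")
})
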