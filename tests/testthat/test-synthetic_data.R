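test_that("generator is deterministic and respects its invariants", {
  cfg <- sponge_sim_config(seed = 5L)
  s1 <- simulate_sponge_data(cfg)
  s2 <- simulate_sponge_data(cfg)
  expect_identical(s1, s2)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_sponge_dataset(s1, d1)
  p2 <- write_sponge_dataset(s2, d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }

  # planted ids exist in the generated matrices
  expect_true(all(s1$truth$x_id %in% rownames(s1$rna)))
  expect_true(all(s1$truth$y_id %in% rownames(s1$rna)))
  expect_true(all(stats::na.omit(s1$truth$z_id) %in% rownames(s1$mirna)))
  # planted sponge interactions are in the target table
  sp <- s1$truth[s1$truth$kind == "sponge", ]
  expect_true(all(has_target(s1$target_map, sp$z_id, sp$x_id)))
  expect_true(all(has_target(s1$target_map, sp$z_id, sp$y_id)))
  # raw scale, positive where observed
  expect_identical(expr_scale(s1$rna), "raw")
  expect_true(all(unclass(s1$rna) > 0, na.rm = TRUE))

  expect_error(sponge_sim_config(n_sponge_triplets = 30),
               "n_sponge_triplets")
  expect_error(sponge_sim_config(missing_rate = 1), "missing_rate")
})

test_that("null generator (no sponges) yields an empty truth table and no recoveries", {
  sim <- simulate_sponge_data(
    sponge_sim_config(n_sponge_triplets = 0L, seed = 2L))
  expect_identical(sum(sim$truth$kind == "sponge"), 0L)
  tr <- make_triplets("a", "b", "z", s = 0.9)
  expect_warning(ev <- evaluate_recovery(tr, sim$truth, k = 5),
                 "no planted sponges")
  expect_identical(ev$precision_at_k, 0)
})

test_that("planted sponge pair correlation matches the closed form of the linear model", {
  cfg <- sponge_sim_config(n_samples = 500L, seed = 11L,
                           missing_rate = 0)
  sim <- simulate_sponge_data(cfg)
  lg <- log2_transform(sim$rna)
  b2 <- cfg$mirna_effect^2
  want <- b2 / (b2 + cfg$noise_sd^2)        # ~ 0.917
  for (i in seq_len(cfg$n_sponge_triplets)) {
    got <- cor(lg[sim$truth$x_id[i], ], lg[sim$truth$y_id[i], ])
    expect_lt(abs(got - want), 0.1)
  }
})

test_that("planted seed sites are recoverable by de-novo scanning", {
  sim <- simulate_sponge_data(sponge_sim_config(seed = 8L))
  tm_scan <- build_target_map_from_sequences(sim$mirna_seqs,
                                             sim$transcript_seqs)
  planted <- target_pairs(sim$target_map)
  found <- has_target(tm_scan, planted$mirna_id, planted$gene_id)
  expect_true(all(found))                   # sites were embedded
})

test_that("recovery evaluation ranks by sensitivity and scores against truth", {
  truth <- data.frame(x_id = c("x1", "x2"), y_id = c("y1", "y2"),
                      z_id = c("z1", "z2"), kind = "sponge",
                      stringsAsFactors = FALSE)
  tr <- make_triplets(c("x1", "x2", "x9"), c("y1", "y2", "y9"),
                      c("z1", "z2", "z9"), s = c(0.9, 0.8, 0.7))
  ev <- evaluate_recovery(tr, truth, k = 2)
  expect_identical(ev$precision_at_k, 1)
  expect_identical(ev$recall_at_k, 1)
  # pair orientation must not matter
  tr_sw <- make_triplets(c("y1", "x2"), c("x1", "y2"), c("z1", "z2"),
                         s = c(0.9, 0.8))
  expect_identical(evaluate_recovery(tr_sw, truth, 2)$precision_at_k, 1)
  # random scores give precision near the planted fraction
  set.seed(13)
  n <- 200L
  frac <- numeric(100)
  for (r in 1:100) {
    pool <- make_triplets(paste0("x", 1:n), paste0("y", 1:n),
                          paste0("z", 1:n), s = runif(n))
    truth_r <- data.frame(x_id = paste0("x", 1:20),
                          y_id = paste0("y", 1:20),
                          z_id = paste0("z", 1:20), kind = "sponge",
                          stringsAsFactors = FALSE)
    frac[r] <- evaluate_recovery(pool, truth_r, k = 50)$precision_at_k
  }
  expect_lt(abs(mean(frac) - 20 / n), 0.03)
})
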