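# Feature assembly, boosted-tree engine, nested CV, threshold choice,
# persistence and partner prediction.

small_grid <- expand.grid(max_depth = 3L, eta = c(0.1, 0.3), nrounds = 60L)

# assemble a consistent triple-source fixture for n complexes
triple_source <- function(n = 12, n_open = 2, seed = 3) {
  set.seed(seed)
  ids <- sprintf("cx%02d", seq_len(n))
  structural <- data.frame(
    complex_id = ids,
    e2 = sprintf("E2_%02d", seq_len(n)), e3 = sprintf("E3_%02d", seq_len(n)),
    label = rep(c("pair", "nonpair"), length.out = n),
    conformation = c(rep("Open", n_open), rep("Closed", n - n_open)),
    ile44_helix_dist = runif(n, 5, 9), tail_cys_dist = runif(n, 3, 8),
    linchpin_flag = rbinom(n, 1, 0.5), n_e3_loops = rpois(n, 2),
    n_e3_loop_residues = rpois(n, 8), stringsAsFactors = FALSE
  )
  confidence <- expand.grid(complex_id = ids,
                            interface = c("UB-E2", "UB-E3", "E2-E3"),
                            stringsAsFactors = FALSE)
  for (m in c("ipsae", "iptm", "pdockq", "pdockq2")) {
    confidence[[m]] <- runif(nrow(confidence))
  }
  energetics <- make_energetics_table(ids, is_pair = structural$label == "pair",
                                      seed = seed)
  list(structural = structural, confidence = confidence, energetics = energetics)
}

test_that("assemble_features builds the 38-column schema and drops Open rows", {
  src <- triple_source(12, n_open = 2)
  tab <- assemble_features(src$structural, src$confidence, src$energetics)
  expect_equal(nrow(tab), 10L)
  expect_true(all(feature_schema() %in% names(tab)))
  expect_length(feature_schema(), 38L)          # 3 x 11 + 5
  expect_false(any(grepl("mean_interface_pae", names(tab))))
  expect_false(any(tab$conformation == "Open"))
  # a feature with > 20% missingness is a schema error naming the column
  src2 <- triple_source(12, n_open = 0)
  src2$confidence$ipsae[src2$confidence$interface == "UB-E3"][1:5] <- NA
  expect_error(assemble_features(src2$structural, src2$confidence, src2$energetics),
               "ub_e3_ipsae")
})

test_that("class balancing tops up non-pairs deterministically", {
  ft <- make_feature_table(feature_table_spec(n_pairs = 60, n_nonpairs = 40,
                                              seed = 5))$table
  pool <- make_feature_table(feature_table_spec(n_pairs = 1, n_nonpairs = 50,
                                                seed = 6))$table
  pool <- pool[pool$label == "nonpair", ]
  pool$complex_id <- paste0("pool_", pool$complex_id)
  bal <- balance_classes(ft, pool, seed = 11)
  expect_equal(sum(bal$label == "pair"), sum(bal$label == "nonpair"))
  expect_identical(balance_classes(ft, pool, seed = 11), bal)
  expect_equal(balance_classes(bal, pool, seed = 12), bal,
               ignore_attr = TRUE)                     # already balanced
})

test_that("the boosted-tree engine separates a planted signal deterministically", {
  set.seed(21)
  x <- matrix(rnorm(300 * 6), 300)
  colnames(x) <- paste0("f", 1:6)
  y <- as.numeric(x[, 1] + 0.8 * x[, 2] > 0)
  m1 <- gbt_fit(x, y, nrounds = 80)
  m2 <- gbt_fit(x, y, nrounds = 80)
  expect_identical(predict(m1, x), predict(m2, x))
  expect_gte(roc_auc(predict(m1, x), y), 0.99)
  # informative features dominate the gain importance
  expect_gt(min(m1$importance[c("f1", "f2")]), max(m1$importance[c("f4", "f5", "f6")]))
  expect_error(gbt_fit(cbind(x, NA), y), "missing")
})

test_that("threshold choice equals the brute-force F-beta scan", {
  set.seed(23)
  for (k in 1:20) {
    n <- 60
    labels <- rbinom(n, 1, 0.5)
    probs <- round(runif(n), 2)        # force ties
    if (length(unique(labels)) < 2) next
    expect_equal(choose_threshold(probs, labels, beta = 0.75),
                 oracle_fbeta_threshold(probs, labels, 0.75))
  }
  # limiting behaviour: large beta maximises recall, small beta precision
  probs <- c(0.1, 0.2, 0.4, 0.6, 0.8, 0.9)
  labels <- c(0, 1, 0, 1, 1, 1)
  t_recall <- choose_threshold(probs, labels, beta = 100)
  expect_equal(sum(probs >= t_recall & labels == 1), sum(labels == 1))
  t_prec <- choose_threshold(probs, labels, beta = 0.01)
  cm_pos <- probs >= t_prec
  expect_equal(sum(cm_pos & labels == 0), 0L)
  expect_error(choose_threshold(probs, rep(1, 6)), "single class")
})

test_that("nested CV partitions cleanly and reports coherent metrics", {
  ft <- make_feature_table(feature_table_spec(n_pairs = 60, n_nonpairs = 60,
                                              effect_size = 1.5, seed = 31))$table
  cv <- nested_cv(ft, training_config(seed = 7, grid = small_grid,
                                      n_inner_folds = 2L))
  expect_equal(sum(cv$confusion), nrow(ft))
  expect_true(all(is.finite(cv$oof_probabilities)))
  expect_true(all(cv$per_fold$roc_auc >= 0 & cv$per_fold$roc_auc <= 1))
  expect_gte(cv$mean[["roc_auc"]], 0.8)
  expect_length(cv$selected_features, 5L)
  # too-small classes refuse to stratify
  tiny <- ft[c(1:5, 61:65), ]
  expect_error(nested_cv(tiny, training_config(seed = 1)), ">= 10 rows")
})

test_that("final models persist, reload and reproduce predictions exactly", {
  ft <- make_feature_table(feature_table_spec(n_pairs = 50, n_nonpairs = 50,
                                              effect_size = 1.5, seed = 41))$table
  model <- train_final(ft, training_config(seed = 9, grid = small_grid),
                       threshold = 0.5)
  dir <- withr::local_tempdir()
  save_classifier(model, dir)
  back <- load_classifier(dir)
  x <- ft
  expect_equal(predict(back$model, as.matrix(x[, back$features])),
               predict(model$model, as.matrix(x[, model$features])),
               tolerance = 1e-12)
  expect_equal(back$threshold, model$threshold)
  model2 <- train_final(ft, training_config(seed = 9, grid = small_grid),
                        threshold = 0.5)
  expect_identical(predict(model$model, as.matrix(x[, model$features])),
                   predict(model2$model, as.matrix(x[, model2$features])))
  # planted pairs get higher mean probability than planted non-pairs
  p <- predict(model$model, as.matrix(x[, model$features]))
  expect_gt(mean(p[ft$label == "pair"]), mean(p[ft$label == "nonpair"]))
})

test_that("partner prediction prefilters, scores and flags unique E2s", {
  ft <- make_feature_table(feature_table_spec(n_pairs = 80, n_nonpairs = 80,
                                              effect_size = 2, seed = 51))$table
  model <- train_final(ft, training_config(seed = 3, grid = small_grid),
                       threshold = 0.5)
  cand <- make_feature_table(feature_table_spec(n_pairs = 10, n_nonpairs = 30,
                                                effect_size = 2, seed = 52))$table
  cand$e3 <- rep(sprintf("T3_%02d", 1:8), each = 5)
  cand$e2 <- rep(sprintf("T2_%02d", 1:5), times = 8)
  cand$iptm <- pmax(cand$iptm, 0.6)     # keep the planted failures unambiguous
  cand$ptm <- pmax(cand$ptm, 0.6)
  cand$conformation[1] <- "Open"
  cand$iptm[2] <- 0.45
  cand$ptm[3] <- 0.30
  cand$ring_engagement[4] <- 0
  res <- predict_partners(model, cand)
  expect_equal(nrow(res$predictions), nrow(cand) - 4)
  expect_false(any(res$predictions$iptm < 0.5))
  expect_equal(unname(res$filtered),
               c(1L, 1L, 1L, 1L))
  # an E3 with exactly one predicted E2 is flagged unique
  if (any(res$per_e3$n_predicted == 1)) {
    u <- res$per_e3[res$per_e3$n_predicted == 1, ]
    expect_true(all(u$unique_prediction))
    expect_false(any(grepl(",", u$predicted_e2s)))
  }
  # everything filtered -> empty result with reason counts
  cand2 <- cand
  cand2$iptm <- 0.2
  res2 <- predict_partners(model, cand2)
  expect_equal(nrow(res2$predictions), 0L)
  expect_gt(sum(res2$filtered), 0)
})
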