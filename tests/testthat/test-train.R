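test_that("train_config validates and exposes the reduced profile", {
  cfg <- train_config()
  expect_equal(cfg$stage1_epochs, 150)
  expect_equal(cfg$stage2_epochs, 80)
  expect_equal(cfg$stage1_lr, 1e-4)
  red <- train_config(profile = "reduced")
  expect_equal(red$stage1_epochs, 15)
  expect_equal(red$stage2_epochs, 8)
  expect_error(train_config(stage1_epochs = 0), "epochs")
})

test_that("zero learning rate is a null update", {
  ds <- make_tiny_cpd_dataset(2, seed = 1)
  model <- ttm_init(tiny_ttm_cfg(), seed = 2)
  res <- train_stage1(model, ds,
                      train_config(stage1_epochs = 2, stage1_lr = 0,
                                   batch_size = 16, seed = 1))
  expect_identical(serialize(res$model$params, NULL),
                   serialize(model$params, NULL))
  # same for stage 2
  g <- build_graph()
  nf <- extract_node_features(model, ds)
  sg <- sgcm_init(sgcm_config(), d_in = 8, seed = 3)
  res2 <- train_stage2(sg, nf, g,
                       train_config(stage2_epochs = 2, stage2_lr = 0,
                                    batch_size = 8, seed = 1))
  expect_identical(serialize(res2$model$params, NULL),
                   serialize(sg$params, NULL))
})

test_that("stage 2 never mutates frozen stage-1 weights", {
  ds <- make_tiny_cpd_dataset(2, seed = 5)
  model <- ttm_init(tiny_ttm_cfg(), seed = 6)
  s1 <- train_stage1(model, ds, train_config(stage1_epochs = 1,
                                             batch_size = 16, seed = 2))
  frozen <- serialize(s1$model, NULL)
  nf <- extract_node_features(s1$model, ds)
  sg <- sgcm_init(sgcm_config(), d_in = 8, seed = 3)
  s2 <- train_stage2(sg, nf, build_graph(),
                     train_config(stage2_epochs = 2, batch_size = 8,
                                  seed = 2))
  expect_identical(serialize(s1$model, NULL), frozen)   # bit-identical
  expect_false(identical(serialize(s2$model$params, NULL),
                         serialize(sg$params, NULL)))
})

test_that("training loss decreases on separable data; single class is degenerate", {
  ds <- make_tiny_cpd_dataset(3, seed = 8)
  model <- ttm_init(tiny_ttm_cfg(), seed = 9)
  res <- train_stage1(model, ds,
                      train_config(stage1_epochs = 10, stage1_lr = 1e-3,
                                   batch_size = 16, seed = 3))
  expect_lt(tail(res$loss, 1), head(res$loss, 1))
  expect_true(all(res$channel_accuracy$accuracy > 1 / 3))  # beats chance
  # single-class dataset: accuracy 1 and loss trending to 0
  ds1 <- make_tiny_cpd_dataset(2, seed = 10, classes = "control")
  m1 <- ttm_init(tiny_ttm_cfg(n_classes = 1), seed = 11)
  r1 <- train_stage1(m1, ds1,
                     train_config(stage1_epochs = 5, stage1_lr = 1e-3,
                                  batch_size = 16, seed = 4),
                     classes = "control")
  expect_equal(r1$channel_accuracy$accuracy, rep(1, 16))
  expect_lt(tail(r1$loss, 1), head(r1$loss, 1) + 1e-12)
  expect_error(train_stage1(model, ds, test_subjects =
                              unique(ds$meta$subject_id)),
               "no training samples")
})

test_that("node features align with the electrode graph order", {
  ds <- make_tiny_cpd_dataset(1, seed = 12)
  model <- ttm_init(tiny_ttm_cfg(), seed = 13)
  nf <- extract_node_features(model, ds)
  expect_length(nf$features, 3)
  expect_equal(dim(nf$features[[1]]), c(16, 8))
  # row i of the feature matrix is the TTM feature of channel i's map
  seg1 <- which(ds$meta$segment_key == nf$meta$segment_key[1])
  ch <- montage_scalp16()[4]
  idx <- seg1[ds$meta$channel[seg1] == ch]
  direct <- ttm_forward(model, ds$inputs[[idx]])$features
  expect_equal(nf$features[[1]][4, ], as.numeric(direct), tolerance = 1e-12)
  # a segment missing a channel map is rejected
  ds2 <- ds
  drop <- which(ds$meta$channel == "C3")[1]
  ds2$inputs <- ds2$inputs[-drop]
  ds2$meta <- ds2$meta[-drop, ]
  expect_error(extract_node_features(model, ds2), "lacks feature")
})

test_that("run_experiment produces consistent, deterministic reports", {
  ds <- make_tiny_cpd_dataset(4, seed = 20, strength = 4)
  tcfg <- train_config(stage1_epochs = 2, stage2_epochs = 2, batch_size = 16,
                       stage1_lr = 1e-3, stage2_lr = 1e-3)
  spec <- experiment_spec(class_labels(), dataset = ds,
                          ttm_cfg = tiny_ttm_cfg(), train_cfg = tcfg,
                          k = 4, folds = 1, seed = 6)
  res <- run_experiment(spec)
  expect_equal(dim(res$confusion), c(3, 3))
  expect_equal(sum(res$confusion),
               length(unique(ds$meta$segment_key[ds$meta$subject_id %in%
                 res$fold_results[[1]]$test_subjects])))
  expect_length(res$auc, 3)
  # subject exclusivity: no test subject contributed training maps
  f1 <- res$fold_results[[1]]
  expect_length(intersect(f1$test_subjects,
                          setdiff(names(res$fold_plan$assignments),
                                  f1$test_subjects)), 0)
  res2 <- run_experiment(spec)
  expect_identical(res$mean_metrics, res2$mean_metrics)
  expect_identical(res$confusion, res2$confusion)
  # pairwise experiment yields a binary report
  spec2 <- experiment_spec(c("control", "viral"), dataset = ds,
                           ttm_cfg = tiny_ttm_cfg(n_classes = 2),
                           train_cfg = tcfg, k = 4, folds = 1, seed = 6)
  res_pw <- run_experiment(spec2)
  expect_equal(dim(res_pw$confusion), c(2, 2))
  expect_equal(res_pw$classes, c("control", "viral"))
  expect_error(experiment_spec(c("control", "control"), dataset = ds),
               "distinct")
})
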