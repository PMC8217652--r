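test_that("SMOTE balances classes and leaves majority rows untouched", {
  ds <- make_separable_dataset(n_participants = 4, per_class = 25)
  # unbalance it: keep 12 lie rows
  lie_idx <- which(ds$labels == "lie")
  keep <- sort(c(which(ds$labels == "truth"), lie_idx[1:12]))
  small <- fearleak:::new_frame_dataset(ds$features[keep, ],
                                        ds$labels[keep], ds$groups[keep])
  bal <- smote_oversample(small, k = 5, seed = 3)
  expect_equal(unname(table(bal$labels)[["lie"]]),
               unname(table(bal$labels)[["truth"]]))
  # original rows first and unchanged
  expect_equal(bal$features[seq_along(keep), ], small$features)

  # already balanced -> unchanged
  expect_identical(smote_oversample(ds, seed = 1), ds)

  tiny <- fearleak:::new_frame_dataset(ds$features[1:104, ],
                                       factor(c(rep("lie", 4),
                                                rep("truth", 100)),
                                              levels = c("lie", "truth")),
                                       ds$groups[1:104])
  expect_error(smote_oversample(tiny, k = 5), class = "TooFewMinority")
})

test_that("every SMOTE point lies on a parent-to-neighbour segment", {
  ds <- make_separable_dataset(n_participants = 2, per_class = 15)
  lie_idx <- which(ds$labels == "lie")
  keep <- sort(c(which(ds$labels == "truth"), lie_idx[1:10]))
  small <- fearleak:::new_frame_dataset(ds$features[keep, ],
                                        ds$labels[keep], ds$groups[keep])
  bal <- smote_oversample(small, k = 3, seed = 5)
  n_orig <- length(keep)
  synth <- bal$features[-seq_len(n_orig), , drop = FALSE]
  Xm <- small$features[small$labels == "lie", , drop = FALSE]
  nn <- FNN::get.knn(Xm, k = 3)$nn.index
  # geometric audit: distance to the closest admissible segment is ~0
  seg_dist <- function(s, p, q) {
    v <- q - p
    u <- sum((s - p) * v) / sum(v * v)
    if (!is.finite(u)) u <- 0
    u <- min(max(u, 0), 1)
    sqrt(sum((s - (p + u * v))^2))
  }
  for (i in seq_len(nrow(synth))) {
    d <- min(unlist(lapply(seq_len(nrow(Xm)), function(pi)
      vapply(nn[pi, ], function(qi)
        seg_dist(synth[i, ], Xm[pi, ], Xm[qi, ]), numeric(1)))))
    expect_lt(d, 1e-10)
  }
})

test_that("classification metrics reproduce hand-worked values", {
  lv <- c("lie", "truth")
  # perfect predictions
  y <- factor(rep(lv, c(10, 30)), levels = lv)
  perfect <- classification_metrics(y, y)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$tp_rate, 1)

  # constant majority prediction on a 90/10 split: accuracy 90, kappa 0
  y <- factor(rep(lv, c(10, 90)), levels = lv)
  pred <- factor(rep("truth", 100), levels = lv)
  const <- classification_metrics(y, pred)
  expect_equal(const$accuracy, 90)
  expect_equal(const$kappa, 0)
  # weighted TP rate equals accuracy / 100 (cited tool's convention)
  expect_equal(const$tp_rate, const$accuracy / 100)
  # zero-division convention: precision of the never-predicted class is 0
  expect_equal(const$precision, 0.9 * (90 / 100) + 0.1 * 0)

  # confusion matrix [[40,10],[5,45]]: accuracy 85, hand-computed weights
  y <- factor(rep(lv, c(50, 50)), levels = lv)
  pred <- factor(c(rep("lie", 40), rep("truth", 10),
                   rep("lie", 5), rep("truth", 45)), levels = lv)
  m <- classification_metrics(y, pred)
  expect_equal(m$accuracy, 85)
  expect_equal(m$precision, 0.5 * (40 / 45) + 0.5 * (45 / 55))
  expect_equal(m$recall, 0.5 * (40 / 50) + 0.5 * (45 / 50))
  expect_equal(m$tp_rate, m$accuracy / 100)

  expect_error(classification_metrics(y, pred[-1]), class = "LengthMismatch")
})

test_that("weighted TP rate equals accuracy on random predictions", {
  set.seed(12)
  lv <- c("lie", "truth")
  for (i in 1:10) {
    y <- factor(sample(lv, 200, replace = TRUE, prob = c(0.2, 0.8)),
                levels = lv)
    pred <- factor(sample(lv, 200, replace = TRUE), levels = lv)
    m <- classification_metrics(y, pred)
    expect_equal(m$tp_rate, m$accuracy / 100, tolerance = 1e-12)
    expect_true(m$kappa <= 1)
  }
})

test_that("train/eval split respects participants and learns separable data", {
  ds <- make_separable_dataset(n_participants = 8, per_class = 30)
  ids <- unique(ds$groups)
  for (cf in c("random_forest", "knn", "bagging")) {
    rep <- train_eval_split(ds, ids[1:6], cf, seed = 1, n_trees = 25)
    expect_gte(rep$accuracy, 95)
    expect_gte(rep$prc_area, 0.9)
  }
  expect_error(train_eval_split(ds, ids, "knn"),
               class = "ParticipantOverlap")
  expect_error(train_eval_split(ds, c(ids[1:3], "nobody"), "knn"),
               class = "ParticipantOverlap")
})

test_that("leave-one-person-out yields one clean fold per participant", {
  ds <- make_separable_dataset(n_participants = 5, per_class = 20)
  loo <- leave_one_person_out(ds, "knn", seed = 2)
  expect_equal(nrow(loo$per_fold), 5)
  expect_setequal(loo$per_fold$participant, unique(ds$groups))
  # every participant's frames are all in the test fold exactly once
  expect_equal(sum(loo$per_fold$n_frames), nrow(ds$features))
  expect_gte(loo$mean_accuracy, 90)

  solo <- fearleak:::new_frame_dataset(ds$features[ds$groups == "P01", ],
                                       ds$labels[ds$groups == "P01"],
                                       ds$groups[ds$groups == "P01"])
  expect_error(leave_one_person_out(solo, "knn"),
               class = "SingleParticipant")
})

test_that("frame-level CV runs in paper and leak-safe modes", {
  ds <- make_separable_dataset(n_participants = 4, per_class = 20)
  lie_idx <- which(ds$labels == "lie")
  keep <- sort(c(which(ds$labels == "truth"), lie_idx[1:30]))
  unb <- fearleak:::new_frame_dataset(ds$features[keep, ],
                                      ds$labels[keep], ds$groups[keep])
  paper <- frame_cv(unb, "knn", folds = 5, seed = 3, mode = "paper")
  safe <- frame_cv(unb, "knn", folds = 5, seed = 3, mode = "leak_safe")
  expect_gte(paper$accuracy, 90)
  expect_gte(safe$accuracy, 90)
})
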