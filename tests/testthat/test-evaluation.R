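test_that("micro metrics agree with a brute-force slot-by-slot tally", {
  set.seed(5)
  yt <- random_labels(50)
  expect_equal(mlc_metrics(yt, yt),
               structure(list(precision = 1, recall = 1, f1 = 1, hamming = 0),
                         class = "mlc_metrics"))
  # complement prediction on single-label rows: F1 = 0
  comp <- as_label_matrix(lapply(label_sets(yt), function(s)
    if (length(s) == 1L) setdiff(0:1, s)[1] else integer(0)))
  single <- rowSums(yt) == 1L & yt[, 5] == 0L
  if (any(single)) {
    m0 <- suppressWarnings(mlc_metrics(yt[single, , drop = FALSE],
                                       comp[single, , drop = FALSE]))
    expect_equal(m0$f1, 0)
  }
  # random prediction pairs vs an explicit counting oracle
  for (k in 1:25) {
    a <- random_labels(40); b <- random_labels(40)
    tp <- fp <- fn <- 0
    for (i in 1:40) for (j in 1:5) {
      if (a[i, j] == 1 && b[i, j] == 1) tp <- tp + 1
      if (a[i, j] == 0 && b[i, j] == 1) fp <- fp + 1
      if (a[i, j] == 1 && b[i, j] == 0) fn <- fn + 1
    }
    m <- mlc_metrics(a, b)
    expect_equal(m$precision, tp / (tp + fp))
    expect_equal(m$recall, tp / (tp + fn))
    expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
    expect_equal(m$hamming, (fp + fn) / 200)
  }
  expect_error(mlc_metrics(yt, yt[-1, ]), "shape")
})

test_that("micro-F1 survives frame permutation; degenerate identities hold", {
  set.seed(6)
  a <- random_labels(80); b <- random_labels(80)
  p <- sample(80)
  expect_equal(mlc_metrics(a, b)$f1, mlc_metrics(a[p, ], b[p, ])$f1)
  # Hamming 0 iff exact match
  expect_true(mlc_metrics(a, a)$hamming == 0)
  expect_true(mlc_metrics(a, b)$hamming > 0 || identical(a, b))
  # single-label data: micro precision = recall = accuracy
  sets <- lapply(1:60, function(i) if (i %% 3 == 0) integer(0) else (i %% 4))
  truth <- as_label_matrix(sets)
  pred_sets <- lapply(1:60, function(i) if (i %% 5 == 0) integer(0) else (i %% 4))
  pred <- as_label_matrix(pred_sets)
  m <- mlc_metrics(truth, pred)
  acc <- mean(vapply(1:60, function(i) all(truth[i, ] == pred[i, ]), logical(1)))
  expect_equal(m$precision, m$recall)
  expect_equal(m$precision, acc)
})

test_that("dataset statistics follow their definitions", {
  sets <- c(replicate(100, integer(0), simplify = FALSE),
            replicate(50, 2L, simplify = FALSE),
            replicate(25, 0L, simplify = FALSE))
  st <- dataset_stats(as_label_matrix(sets))
  expect_equal(unname(st$irlbl[c("Normal", "SE", "TF")]), c(1, 2, 4))
  expect_true(all(is.na(st$irlbl[c("TR", "O")])))
  expect_equal(st$p_min, 1)
  # 3 of 4 samples single-labelled
  st2 <- dataset_stats(as_label_matrix(list(0L, 1L, c(0L, 2L), integer(0))))
  expect_equal(1 - st2$p_min, 0.25)
  # all Normal
  st3 <- dataset_stats(as_label_matrix(replicate(5, integer(0),
                                                 simplify = FALSE)))
  expect_equal(st3$p_min, 1)
  expect_equal(unname(st3$irlbl["Normal"]), 1)
  expect_error(dataset_stats(as_label_matrix(list())), "empty")
})

test_that("LOSO folds partition the data and expose out-of-subject error", {
  set.seed(11)
  trials <- lapply(1:9, function(i) {
    list(subject = paste0("P", (i - 1) %/% 3 + 1), id = i,
         labels = random_labels(30))
  })
  seen <- new.env()
  cv <- loso_cv(trials,
                fit = function(train) {
                  ids <- vapply(train, `[[`, numeric(1), "id")
                  assign(paste(sort(ids), collapse = ","), TRUE, envir = seen)
                  ids
                },
                predict_fn = function(model, trial) trial$labels)
  expect_equal(nrow(cv$folds), 3)
  expect_equal(cv$summary$mean[cv$summary$metric == "f1"], 1)
  # every fold trained on exactly the 6 other trials
  expect_length(ls(seen), 3)
  expect_error(loso_cv(trials[1:3], function(x) x, function(m, t) t$labels),
               "2 subjects")

  # memorizing classifier: perfect in-sample, imperfect out-of-subject
  lookup_fit <- function(train) {
    key <- do.call(rbind, lapply(train, `[[`, "features"))
    val <- do.call(rbind, lapply(train, `[[`, "labels"))
    list(key = key, val = val)
  }
  lookup_predict <- function(model, trial) {
    t(apply(trial$features, 1, function(x) {
      hit <- which(apply(model$key, 1, function(k) all(k == x)))[1]
      if (is.na(hit)) c(0L, 0L, 0L, 0L, 1L) else model$val[hit, ]
    }))
  }
  trials2 <- lapply(1:4, function(i) {
    list(subject = paste0("S", i),
         features = cbind(rep(i * 1.0, 20), 1:20),  # unique per frame
         labels = random_labels(20))
  })
  cv2 <- loso_cv(trials2, lookup_fit, lookup_predict)
  ins <- mlc_metrics(trials2[[1]]$labels,
                     lookup_predict(lookup_fit(trials2[1]), trials2[[1]]))
  expect_equal(ins$f1, 1)
  expect_lt(cv2$summary$mean[cv2$summary$metric == "f1"], 1)
})

test_that("LOEO uses two folds and rejects mismatched scenarios", {
  set.seed(12)
  mk <- function(ex, scn, n = 4) lapply(1:n, function(i)
    list(subject = paste0(ex, i), exercise = ex, scenario = scn,
         labels = random_labels(25)))
  e1 <- mk("E1", "S1"); e2 <- mk("E2", "S1")
  cv <- loeo_cv(e1, e2, fit = function(train) NULL,
                predict_fn = function(model, trial) trial$labels)
  expect_equal(nrow(cv$folds), 2)
  expect_setequal(cv$folds$fold, c("test_E1", "test_E2"))
  expect_error(loeo_cv(e1, mk("E3", "S2"), function(x) NULL,
                       function(m, t) t$labels), "scenario")
})
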