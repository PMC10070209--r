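# Curation, K-means relabeling, the two classifiers, evaluation, rules.

toy_table <- function(E, A = rep(2, length(E)), label, ...) {
  data.frame(id = paste0("r", seq_along(E)), E = E, A = A, label = label,
             ..., stringsAsFactors = FALSE)
}

test_that("curate drops R-factor >= threshold (boundary excluded) and
           honours the error-free flag", {
  tab <- toy_table(E = c(1.9, 2.0, 2.1), label = c("II", "III", "IV"),
                   r_factor = c(0.05, 0.075, 0.10),
                   error_free = c(TRUE, TRUE, FALSE))
  out <- curate(tab, max_r_factor = 0.075)
  expect_equal(out$id, "r1")
  out2 <- curate(tab, max_r_factor = NULL, require_error_free = TRUE)
  expect_equal(out2$id, c("r1", "r2"))
  expect_equal(nrow(curate(tab[0, , drop = FALSE])), 0L)
  expect_error(curate(tab[, setdiff(names(tab), "r_factor")]),
               "'r_factor' is absent")
  # filter oracle on random tables
  set.seed(2)
  big <- toy_table(E = runif(100, 1.8, 2.3), label = sample(
    c("II", "III", "IV"), 100, replace = TRUE),
    r_factor = runif(100, 0, 0.15))
  expect_equal(nrow(curate(big)), sum(big$r_factor < 0.075))
  expect_equal(curate(big)$id, big$id[big$r_factor < 0.075])  # order kept
})

test_that("kmeans_relabel recovers tight blobs at the oxidation-class
           centers and maps them II/III/IV by descending E + A", {
  tab <- gen_feature_table(counts = c(II = 120, III = 90, IV = 60),
                           sigma = 0.005, mislabel_rate = 0.2, seed = 5)
  rl <- kmeans_relabel(tab, seed = 5)
  centers <- default_cluster_centers()
  expect_lt(max(abs(rl$model$centers - centers)), 0.01)
  expect_equal(rownames(rl$model$centers), c("II", "III", "IV"))
  # relabeling recovers ground truth despite 20% visible-label corruption
  expect_gt(mean(rl$table$label == tab$truth), 0.99)
})

test_that("K-means is a fixed point and relabeling is idempotent", {
  tab <- gen_feature_table(counts = c(II = 150, III = 100, IV = 50),
                           sigma = 0.03, mislabel_rate = 0.1, seed = 8)
  rl <- kmeans_relabel(tab, seed = 8)
  x <- as.matrix(tab[, c("E", "A")])
  centers <- rl$model$centers
  # each point is nearest its own center, each center is its cluster's mean
  d2 <- vapply(rownames(centers), function(cl) {
    rowSums(sweep(x, 2, centers[cl, ])^2)
  }, numeric(nrow(x)))
  nearest <- rownames(centers)[max.col(-d2)]
  expect_equal(nearest, rl$table$label)
  for (cl in rownames(centers)) {
    expect_equal(colMeans(x[rl$table$label == cl, , drop = FALSE]),
                 centers[cl, ], tolerance = 1e-12)
  }
  rl2 <- kmeans_relabel(rl$table, seed = 8)
  expect_equal(rl2$table$label, rl$table$label)
  expect_error(kmeans_relabel(toy_table(E = c(1, 1), A = c(1, 1),
                                        label = c("II", "II"))),
               "distinct")
})

test_that("GNB: symmetric boundary, normalized posterior, variance floor", {
  tab <- toy_table(E = c(0.99, 1.0, 1.01, 1.99, 2.0, 2.01),
                   A = c(2, 2.01, 1.99, 2, 2.01, 1.99),
                   label = rep(c("II", "IV"), each = 3))
  m <- fit_gnb(tab)
  expect_equal(predict(m, c(1.4, 2.0)), "II")
  expect_equal(predict(m, c(1.6, 2.0)), "IV")
  post <- predict(m, data.frame(E = c(1.2, 1.8), A = c(2, 2)),
                  type = "posterior")
  expect_equal(rowSums(post), c(1, 1), tolerance = 1e-12)
  zero_var <- toy_table(E = c(1, 1, 2, 2.02), A = c(2, 2, 2, 2.01),
                        label = c("II", "II", "IV", "IV"))
  expect_message(mz <- fit_gnb(zero_var), "floored")
  expect_true(all(mz$vars > 0))
  expect_error(fit_gnb(toy_table(E = c(1, 2), label = c("II", "III"))),
               ">= 2 rows")
})

test_that("GNB class means on a fully relabeled table equal the cluster
           centers to 1e-9", {
  tab <- gen_feature_table(counts = c(II = 500, III = 300, IV = 80),
                           sigma = 0.03, mislabel_rate = 0.15, seed = 17)
  rl <- kmeans_relabel(tab, seed = 17)
  g <- fit_gnb(rl$table)
  expect_lt(max(abs(g$means[rownames(rl$model$centers), ] -
                    rl$model$centers)), 1e-9)
})

test_that("decision tree: separable toy set, memorization, single class", {
  tab <- toy_table(E = c(rep(1.9, 5), rep(2.2, 5)),
                   label = rep(c("IV", "II"), each = 5))
  m <- fit_dt(tab)
  expect_false(m$tree$leaf)
  expect_equal(m$tree$feature, "E")
  expect_equal(m$tree$threshold, 2.05, tolerance = 1e-9)
  expect_equal(mean(predict(m, tab) == tab$label), 1.0)
  # no contradictory duplicates -> unlimited depth memorizes
  set.seed(3)
  big <- toy_table(E = runif(200, 1.8, 2.3), A = runif(200, 1.9, 2.4),
                   label = sample(c("II", "III", "IV"), 200, replace = TRUE))
  mb <- fit_dt(big)
  expect_equal(mean(predict(mb, big) == big$label), 1.0)
  single <- toy_table(E = c(1.9, 2.0), label = c("III", "III"))
  ms <- fit_dt(single)
  expect_true(ms$tree$leaf)
  expect_equal(predict(ms, c(5, 5)), "III")
})

test_that("both classifiers predict the printed cluster centers as their
           own class", {
  fx <- fixture_model()
  gnb <- fit_gnb(fx$table)
  centers <- default_cluster_centers()
  for (cl in rownames(centers)) {
    expect_equal(predict(fx$model, centers[cl, ]), cl)
    expect_equal(predict(gnb, centers[cl, ]), cl)
  }
})

test_that("predictions agree with brute-force posterior / tree-walk
           evaluation on a grid", {
  fx <- fixture_model()
  gnb <- fit_gnb(fx$table)
  grid <- expand.grid(E = seq(1.8, 2.4, length.out = 40),
                      A = seq(1.8, 2.4, length.out = 40))
  # independent GNB evaluation
  ll <- sapply(gnb$classes, function(cl) {
    log(gnb$priors[[cl]]) +
      dnorm(grid$E, gnb$means[cl, "E"], sqrt(gnb$vars[cl, "E"]), log = TRUE) +
      dnorm(grid$A, gnb$means[cl, "A"], sqrt(gnb$vars[cl, "A"]), log = TRUE)
  })
  expect_equal(predict(gnb, grid), gnb$classes[apply(ll, 1, which.max)])
  # independent recursive tree walk
  walk <- function(node, e, a) {
    if (node$leaf) return(node$label)
    if ((if (node$feature == "E") e else a) <= node$threshold) {
      walk(node$left, e, a)
    } else {
      walk(node$right, e, a)
    }
  }
  expect_equal(predict(fx$model, grid),
               mapply(walk, e = grid$E, a = grid$A,
                      MoreArgs = list(node = fx$model$tree)))
})

test_that("evaluate: diagonal confusion for a memorizing model, conservation,
           kfold fold stats", {
  fx <- fixture_model()
  tab <- fx$table
  self_eval <- evaluate(function(t) fit_dt(t), tab,
                        holdout_scheme(0.25), seed = 1)
  n_test <- sum(self_eval$confusion)
  expect_equal(n_test, round(0.25 * nrow(tab)))
  cv <- evaluate("gnb", tab, kfold_scheme(5), seed = 2)
  expect_length(cv$fold_scores, 5L)
  expect_equal(cv$mean, mean(cv$fold_scores))
  expect_equal(sum(cv$confusion), nrow(tab))
  # a truly memorizing model evaluated on its own training rows
  memorizer <- fit_dt(tab)
  pred <- predict(memorizer, tab)
  conf <- table(tab$label, pred)
  expect_true(all(conf[row(conf) != col(conf)] == 0))
  expect_error(evaluate("gnb", tab, kfold_scheme(nrow(tab) + 1)), "kfold")
})

test_that("rule export round-trips through the parser", {
  fx <- fixture_model()
  rules <- export_dt_rules(fx$model)
  expect_match(rules[1], "^if [EA] <= ")
  reparsed <- parse_dt_rules(rules)
  set.seed(4)
  pts <- data.frame(E = runif(1e4, 1.7, 2.5), A = runif(1e4, 1.7, 2.5))
  expect_equal(predict(reparsed, pts), predict(fx$model, pts))
  # degenerate and one-split trees
  leaf <- fit_dt(toy_table(E = c(1, 2), label = c("III", "III")))
  expect_equal(export_dt_rules(leaf), "predict III")
  one <- fit_dt(toy_table(E = c(rep(1.9, 5), rep(2.2, 5)),
                          label = rep(c("IV", "II"), each = 5)))
  r1 <- export_dt_rules(one)
  expect_equal(parse_dt_rules(r1)$tree$threshold, one$tree$threshold,
               tolerance = 1e-9)
})

test_that("models serialize to JSON and back without behaviour change", {
  fx <- fixture_model()
  gnb <- fit_gnb(fx$table)
  gnb$clusters <- fx$clusters
  pd <- withr::local_tempfile(fileext = ".json")
  pg <- withr::local_tempfile(fileext = ".json")
  write_model(fx$model, pd)
  write_model(gnb, pg)
  md <- read_model(pd)
  mg <- read_model(pg)
  pts <- data.frame(E = runif(200, 1.7, 2.5), A = runif(200, 1.7, 2.5))
  expect_equal(predict(md, pts), predict(fx$model, pts))
  expect_equal(predict(mg, pts), predict(gnb, pts))
  expect_equal(mg$means, gnb$means, tolerance = 1e-12)
  expect_equal(mg$clusters$centers, fx$clusters$centers, tolerance = 1e-12)
  not_model <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(foo = 1), not_model, auto_unbox = TRUE)
  expect_error(read_model(not_model), "not an mnoxstate model")
})
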