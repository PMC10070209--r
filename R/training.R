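# Training pipeline: feature-table curation, K-means label correction, and
# the two oxidation-state classifiers (Gaussian naive Bayes; entropy
# decision tree), with holdout / k-fold evaluation and rule export.

assert_feature_table <- function(table) {
  need <- c("id", "E", "A", "label")
  missing <- setdiff(need, names(table))
  if (length(missing) > 0L) {
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyNA(table$E) || anyNA(table$A)) stop("feature table has missing E/A")
  if (anyDuplicated(table$id)) stop("feature table ids are not unique")
  bad <- !table$label %in% OXIDATION_LEVELS
  if (any(bad)) {
    stop("labels outside {II, III, IV}: ",
         paste(unique(table$label[bad]), collapse = ", "))
  }
  invisible(table)
}

#' Curate a labeled feature table by crystallographic quality filters
#'
#' Drops rows whose R-factor is at or above the threshold (the curation rule
#' is "R-factor >= 0.075 removed", so the boundary itself is excluded) and,
#' optionally, rows not flagged error-free at the 0.05 A coordinate level.
#' Row order is preserved.
#'
#' @param table Feature table (`id`, `E`, `A`, `label`, plus metadata
#'   columns `r_factor` / `error_free` as required by the filters).
#' @param max_r_factor Removal threshold; rows with `r_factor >=` this value
#'   are dropped. `NULL` disables the filter.
#' @param require_error_free Drop rows with `error_free` FALSE.
#' @return The filtered table.
#' @export
curate <- function(table, max_r_factor = 0.075, require_error_free = FALSE) {
  assert_feature_table(table)
  keep <- rep(TRUE, nrow(table))
  if (!is.null(max_r_factor)) {
    if (!"r_factor" %in% names(table)) {
      stop("R-factor filter requested but column 'r_factor' is absent")
    }
    keep <- keep & table$r_factor < max_r_factor
  }
  if (isTRUE(require_error_free)) {
    if (!"error_free" %in% names(table)) {
      stop("error-free filter requested but column 'error_free' is absent")
    }
    keep <- keep & as.logical(table$error_free)
  }
  table[keep, , drop = FALSE]
}

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centers with
# probability proportional to squared distance from the nearest chosen one.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in 2:k) {
    probs <- d2 / sum(d2)
    centers[j, ] <- x[sample.int(n, 1L, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' Correct oxidation labels by K-means clustering in (E, A) space
#'
#' Runs k = 3 K-means (k-means++ seeding, Lloyd iterations, `nstart`
#' restarts keeping the lowest inertia) on the two bond-length features and
#' relabels every row by its cluster. Clusters are mapped to oxidation
#' states by descending `E + A` of their centers: bonds contract with
#' oxidation, so the longest-bond cluster is Mn(II) and the shortest is
#' Mn(IV).
#'
#' @param table Feature table.
#' @param seed Integer seed (k-means++ sampling).
#' @param nstart Number of restarts.
#' @return List with `model` (class `cluster_model`: `centers` matrix with
#'   rows named by mapped label, `mapping`, `inertia`) and `table` (the
#'   input with `label` replaced by cluster labels).
#' @export
kmeans_relabel <- function(table, seed = NULL, nstart = 10L) {
  assert_feature_table(table)
  x <- as.matrix(table[, c("E", "A")])
  if (nrow(unique(x)) < 3L) stop("need >= 3 distinct (E, A) points")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(nstart)) {
    init <- kmeanspp_init(x, 3L)
    fit <- suppressWarnings(
      stats::kmeans(x, centers = init, iter.max = 200L, algorithm = "Lloyd")
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  # recompute centers as exact per-cluster feature means so downstream
  # class statistics reproduce them bit-for-bit
  centers <- t(vapply(1:3, function(cl) {
    colMeans(x[best$cluster == cl, , drop = FALSE])
  }, numeric(2)))
  colnames(centers) <- c("E", "A")
  ord <- order(rowSums(centers), decreasing = TRUE)
  mapping <- character(3)
  mapping[ord] <- OXIDATION_LEVELS
  rownames(centers) <- mapping
  centers <- centers[OXIDATION_LEVELS, , drop = FALSE]
  model <- structure(
    list(centers = centers, mapping = mapping, inertia = best$tot.withinss),
    class = "cluster_model"
  )
  out <- table
  out$label <- mapping[best$cluster]
  list(model = model, table = out)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> k = 3, inertia =", format(x$inertia), "\n")
  print(round(x$centers, 4))
  invisible(x)
}

#' Fit a Gaussian naive Bayes oxidation-state classifier
#'
#' Per class and feature, stores the class feature mean and (maximum
#' likelihood) variance plus the class frequency prior. Prediction takes the
#' class maximizing `log prior + sum_f log Normal(x_f | mean, var)` under
#' feature independence.
#'
#' @param table Feature table; every class present needs >= 2 rows.
#' @param var_floor Lower bound applied to variances (a zero-variance
#'   class/feature is floored here and a message emitted).
#' @return Object of class `mn_gnb` (also `oxidation_model`).
#' @export
fit_gnb <- function(table, var_floor = 1e-9) {
  assert_feature_table(table)
  classes <- intersect(OXIDATION_LEVELS, unique(table$label))
  counts <- vapply(classes, function(cl) sum(table$label == cl), integer(1))
  if (any(counts < 2L)) {
    stop("each class needs >= 2 rows; got ",
         paste(paste0(classes, "=", counts), collapse = ", "))
  }
  means <- vars <- matrix(NA_real_, length(classes), 2,
                          dimnames = list(classes, c("E", "A")))
  for (cl in classes) {
    sub <- as.matrix(table[table$label == cl, c("E", "A")])
    means[cl, ] <- colMeans(sub)
    v <- colMeans(sweep(sub, 2, colMeans(sub))^2)
    if (any(v < var_floor)) {
      message("fit_gnb: variance floored at ", var_floor, " for class ", cl)
      v <- pmax(v, var_floor)
    }
    vars[cl, ] <- v
  }
  structure(
    list(kind = "gnb", classes = classes,
         priors = counts / sum(counts), means = means, vars = vars,
         n_train = nrow(table)),
    class = c("mn_gnb", "oxidation_model")
  )
}

#' @rdname predict.mn_dt
#' @export
predict.mn_gnb <- function(object, newdata, type = c("class", "posterior"),
                           ...) {
  type <- match.arg(type)
  x <- features_matrix(newdata)
  logp <- vapply(object$classes, function(cl) {
    log(object$priors[[cl]]) +
      stats::dnorm(x[, "E"], object$means[cl, "E"],
                   sqrt(object$vars[cl, "E"]), log = TRUE) +
      stats::dnorm(x[, "A"], object$means[cl, "A"],
                   sqrt(object$vars[cl, "A"]), log = TRUE)
  }, numeric(nrow(x)))
  logp <- matrix(logp, nrow = nrow(x),
                 dimnames = list(NULL, object$classes))
  if (type == "posterior") {
    post <- exp(logp - apply(logp, 1, max))
    return(post / rowSums(post))
  }
  object$classes[max.col(logp, ties.method = "first")]
}

features_matrix <- function(newdata) {
  if (inherits(newdata, "octa_features")) {
    return(matrix(c(newdata$E, newdata$A), 1,
                  dimnames = list(NULL, c("E", "A"))))
  }
  if (is.numeric(newdata) && length(newdata) == 2L) {
    return(matrix(newdata, 1, dimnames = list(NULL, c("E", "A"))))
  }
  m <- as.matrix(as.data.frame(newdata)[, c("E", "A")])
  colnames(m) <- c("E", "A")
  m
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Fit an entropy decision tree on the (E, A) features
#'
#' Greedy binary tree: each node tests `feature <= threshold`, choosing the
#' split that maximizes the information gain (reduction in Shannon entropy).
#' Thresholds are midpoints between consecutive observed feature values;
#' ties are broken toward the smaller threshold with feature `E` preferred
#' over `A`. Leaves carry the majority class. With unlimited depth and no
#' contradictory duplicate rows the tree memorizes the training set.
#'
#' @param table Feature table.
#' @param criterion Split criterion; only `"entropy"` is implemented.
#' @param max_depth Maximum tree depth (`Inf` = unlimited).
#' @return Object of class `mn_dt` (also `oxidation_model`).
#' @export
fit_dt <- function(table, criterion = "entropy", max_depth = Inf) {
  criterion <- match.arg(criterion, "entropy")
  assert_feature_table(table)
  x <- as.matrix(table[, c("E", "A")])
  y <- table$label
  grow <- function(idx, depth) {
    counts <- vapply(OXIDATION_LEVELS, function(cl) sum(y[idx] == cl),
                     numeric(1))
    majority <- OXIDATION_LEVELS[which.max(counts)]
    leaf <- list(leaf = TRUE, label = majority, counts = counts)
    if (length(unique(y[idx])) == 1L || depth >= max_depth) return(leaf)
    h0 <- entropy_bits(counts)
    n <- length(idx)
    best <- list(gain = 0, feature = NA, threshold = NA)
    for (f in c("E", "A")) {
      ord <- order(x[idx, f])
      xs <- x[idx, f][ord]
      ys <- y[idx][ord]
      cut <- which(diff(xs) > 0)           # split after position i
      if (length(cut) == 0L) next
      cum <- apply(vapply(OXIDATION_LEVELS, function(cl) ys == cl,
                          logical(n)), 2, cumsum)
      left <- cum[cut, , drop = FALSE]
      right <- rep(counts, each = length(cut)) - left
      hrow <- function(m) {
        tot <- rowSums(m)
        p <- m / tot
        -rowSums(ifelse(p > 0, p * log2(p), 0))
      }
      gains <- h0 - (cut * hrow(left) + (n - cut) * hrow(right)) / n
      gbest <- which.max(gains)            # first max: smaller threshold wins
      if (gains[gbest] > best$gain + 1e-12) {
        best <- list(gain = gains[gbest], feature = f,
                     threshold = (xs[cut[gbest]] + xs[cut[gbest] + 1L]) / 2)
      }
    }
    if (best$gain <= 1e-12) return(leaf)
    left_idx <- idx[x[idx, best$feature] <= best$threshold]
    right_idx <- setdiff(idx, left_idx)
    list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
         gain = best$gain, counts = counts,
         left = grow(left_idx, depth + 1),
         right = grow(right_idx, depth + 1))
  }
  structure(
    list(kind = "dt", tree = grow(seq_len(nrow(x)), 0), criterion = criterion,
         max_depth = max_depth, n_train = nrow(x)),
    class = c("mn_dt", "oxidation_model")
  )
}

#' Predict oxidation labels from fitted models
#'
#' @param object A fitted `mn_gnb` or `mn_dt` model.
#' @param newdata An `octa_features` object, a length-2 numeric `(E, A)`, or
#'   a data frame with columns `E` and `A`.
#' @param type For GNB, `"class"` (default) or `"posterior"` (3-column
#'   matrix summing to 1 per row).
#' @param ... Ignored.
#' @return Character vector of labels in `{II, III, IV}` (or a posterior
#'   matrix).
#' @export
predict.mn_dt <- function(object, newdata, ...) {
  x <- features_matrix(newdata)
  walk <- function(node, e, a) {
    while (!node$leaf) {
      v <- if (node$feature == "E") e else a
      node <- if (v <= node$threshold) node$left else node$right
    }
    node$label
  }
  vapply(seq_len(nrow(x)), function(i) walk(object$tree, x[i, "E"], x[i, "A"]),
         character(1))
}

#' @export
print.mn_gnb <- function(x, ...) {
  cat("<mn_gnb> Gaussian naive Bayes,", x$n_train, "training rows\n")
  cat("priors:", paste(sprintf("%s=%.3f", x$classes, x$priors),
                       collapse = " "), "\n")
  print(round(cbind(mean = x$means, var = x$vars), 5))
  invisible(x)
}

#' @export
print.mn_dt <- function(x, ...) {
  cat("<mn_dt> entropy decision tree,", x$n_train, "training rows\n")
  cat(export_dt_rules(x), sep = "\n")
  invisible(x)
}

#' Export a fitted decision tree as human-readable rules
#'
#' Depth-first rendering, e.g. `if E <= 2.0650:` with indented branches and
#' `predict III` at the leaves; the left branch is taken when the condition
#' holds. [parse_dt_rules()] inverts the rendering exactly.
#'
#' @param model A fitted `mn_dt`.
#' @param digits Threshold formatting precision (thresholds are emitted at
#'   full precision via `format`, `digits` significant digits).
#' @return Character vector of rule lines.
#' @export
export_dt_rules <- function(model, digits = 17) {
  stopifnot(inherits(model, "mn_dt"))
  render <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      return(paste0(pad, "predict ", node$label))
    }
    c(paste0(pad, "if ", node$feature, " <= ",
             format(node$threshold, digits = digits), ":"),
      render(node$left, indent + 1),
      paste0(pad, "else:"),
      render(node$right, indent + 1))
  }
  render(model$tree, 0)
}

#' Parse exported decision-tree rules back into a model
#'
#' @param lines Character vector produced by [export_dt_rules()].
#' @return An `mn_dt` whose predictions are identical to the original
#'   model's on any input.
#' @export
parse_dt_rules <- function(lines) {
  pos <- 1L
  parse_node <- function(indent) {
    line <- lines[pos]
    pad <- strrep("  ", indent)
    body <- substring(line, nchar(pad) + 1L)
    pos <<- pos + 1L
    if (startsWith(body, "predict ")) {
      label <- sub("^predict ", "", body)
      return(list(leaf = TRUE, label = label, counts = NULL))
    }
    m <- regmatches(body, regexec("^if ([EA]) <= (.+):$", body))[[1]]
    if (length(m) != 3L) stop("cannot parse rule line: ", line)
    left <- parse_node(indent + 1L)
    pos <<- pos + 1L  # skip "else:"
    right <- parse_node(indent + 1L)
    list(leaf = FALSE, feature = m[2], threshold = as.numeric(m[3]),
         left = left, right = right)
  }
  structure(
    list(kind = "dt", tree = parse_node(0L), criterion = "entropy",
         max_depth = Inf, n_train = NA_integer_),
    class = c("mn_dt", "oxidation_model")
  )
}

#' Evaluate a classifier by holdout split or k-fold cross-validation
#'
#' @param kind `"gnb"` or `"dt"`, or a fitting function
#'   `function(table) -> model`.
#' @param table Feature table.
#' @param scheme `holdout_scheme(test_fraction)` or `kfold_scheme(k)`.
#' @param seed Integer seed for the random split.
#' @return List with `accuracy` (pooled trace/total), `confusion` (3x3,
#'   rows true / columns predicted, class order II/III/IV), `fold_scores`,
#'   `mean`, `sd` and `scheme`.
#' @export
evaluate <- function(kind, table, scheme = holdout_scheme(), seed = NULL) {
  assert_feature_table(table)
  fit_fun <- if (is.function(kind)) {
    kind
  } else {
    switch(match.arg(kind, c("gnb", "dt")), gnb = fit_gnb, dt = fit_dt)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(table)
  if (n == 0L) stop("empty table")
  folds <- if (scheme$type == "holdout") {
    test <- sample.int(n, size = max(1L, round(scheme$test_fraction * n)))
    list(test)
  } else {
    k <- scheme$k
    if (k < 2L || k > n) stop("kfold requires 2 <= k <= nrow(table)")
    split(sample.int(n), rep_len(seq_len(k), n))
  }
  confusion <- matrix(0L, 3, 3,
                      dimnames = list(true = OXIDATION_LEVELS,
                                      predicted = OXIDATION_LEVELS))
  fold_scores <- numeric(length(folds))
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    model <- fit_fun(table[-test_idx, , drop = FALSE])
    pred <- predict(model, table[test_idx, , drop = FALSE])
    truth <- table$label[test_idx]
    for (i in seq_along(pred)) {
      confusion[truth[i], pred[i]] <- confusion[truth[i], pred[i]] + 1L
    }
    fold_scores[f] <- mean(pred == truth)
  }
  list(
    accuracy = sum(diag(confusion)) / sum(confusion),
    confusion = confusion,
    fold_scores = fold_scores,
    mean = mean(fold_scores),
    sd = stats::sd(fold_scores),
    scheme = scheme
  )
}

#' @rdname evaluate
#' @param test_fraction Held-out fraction (default 0.25, i.e. a 75/25
#'   train/test split).
#' @export
holdout_scheme <- function(test_fraction = 0.25) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  list(type = "holdout", test_fraction = test_fraction)
}

#' @rdname evaluate
#' @param k Number of folds.
#' @export
kfold_scheme <- function(k = 10L) {
  list(type = "kfold", k = as.integer(k))
}

# --- model / table serialization --------------------------------------------

#' Read or write feature tables and fitted models
#'
#' Feature tables travel as CSV with header `id,E,A,label[,r_factor,
#' error_free,truth]`; lines starting with `#` are provenance comments and
#' are skipped on read. Models are serialized to JSON with all parameters
#' and provenance (format version, kind).
#'
#' @param table Feature table.
#' @param path File path.
#' @param provenance Optional character vector written as `#` comment lines.
#' @return `read_feature_table` the table; `read_model` the model;
#'   writers return the path invisibly.
#' @export
write_feature_table <- function(table, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.csv(table, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  assert_feature_table(tab)
  tab
}

#' @rdname write_feature_table
#' @param model A fitted `oxidation_model` (GNB or decision tree), with an
#'   optional `cluster_model` stored in `model$clusters`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "oxidation_model"))
  payload <- list(format = "mnoxstate-model-1", kind = model$kind)
  if (model$kind == "gnb") {
    payload$gnb <- list(
      classes = model$classes, priors = as.numeric(model$priors),
      means = model$means, vars = model$vars, n_train = model$n_train
    )
  } else {
    payload$dt <- list(tree = model$tree, n_train = model$n_train)
  }
  if (!is.null(model$clusters)) {
    payload$clusters <- list(centers = model$clusters$centers,
                             inertia = model$clusters$inertia)
  }
  if (!is.null(model$provenance)) payload$provenance <- model$provenance
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  if (is.null(p$format) || !startsWith(p$format, "mnoxstate-model")) {
    stop("not an mnoxstate model file: ", path)
  }
  model <- if (p$kind == "gnb") {
    g <- p$gnb
    means <- matrix(unlist(g$means), length(g$classes), 2,
                    dimnames = list(g$classes, c("E", "A")))
    vars <- matrix(unlist(g$vars), length(g$classes), 2,
                   dimnames = list(g$classes, c("E", "A")))
    structure(
      list(kind = "gnb", classes = g$classes,
           priors = stats::setNames(as.numeric(g$priors), g$classes),
           means = means, vars = vars, n_train = g$n_train),
      class = c("mn_gnb", "oxidation_model")
    )
  } else if (p$kind == "dt") {
    relist_node <- function(nd) {
      if (isTRUE(nd$leaf)) {
        return(list(leaf = TRUE, label = nd$label,
                    counts = unlist(nd$counts)))
      }
      list(leaf = FALSE, feature = nd$feature,
           threshold = as.numeric(nd$threshold),
           left = relist_node(nd$left), right = relist_node(nd$right))
    }
    structure(
      list(kind = "dt", tree = relist_node(p$dt$tree), criterion = "entropy",
           max_depth = Inf, n_train = p$dt$n_train),
      class = c("mn_dt", "oxidation_model")
    )
  } else {
    stop("unknown model kind: ", p$kind)
  }
  if (!is.null(p$clusters)) {
    centers <- matrix(unlist(p$clusters$centers), 3, 2,
                      dimnames = list(OXIDATION_LEVELS, c("E", "A")))
    model$clusters <- structure(
      list(centers = centers, mapping = OXIDATION_LEVELS,
           inertia = p$clusters$inertia),
      class = "cluster_model"
    )
  }
  if (!is.null(p$provenance)) model$provenance <- p$provenance
  model
}
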