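# Balanced random-forest regression protocol: two sets of repeated
# train/test splits (the dominant hotspot forced into or out of training),
# regression forests scored by correlation/RMSD, and node-impurity (RSS
# decrease) feature importances aggregated to percent.

#' Forest protocol configuration
#'
#' @param n_trees Trees per forest (default 40; more does not improve the
#'   predictor at this problem size).
#' @param mtry Variables sampled as split candidates at each node
#'   (default 4 of the 7 features).
#' @param n_runs Train/test repetitions per set (default 100).
#' @param train_fraction Fraction of each frequency stratum used for
#'   training (default 0.7).
#' @param hotspot Mutation id whose training-set membership distinguishes
#'   the two protocol sets (default `"V600E"`). Set to `NA` to disable
#'   forcing.
#' @return Object of class `forest_config` (a list).
#' @export
forest_config <- function(n_trees = 40L, mtry = 4L, n_runs = 100L,
                          train_fraction = 0.7, hotspot = "V600E") {
  stopifnot(mtry >= 1L, mtry <= length(FEATURE_NAMES),
            train_fraction > 0, train_fraction < 1,
            n_trees >= 1L, n_runs >= 1L)
  structure(list(n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 n_runs = as.integer(n_runs),
                 train_fraction = train_fraction, hotspot = hotspot),
            class = "forest_config")
}

#' Balanced train/test split
#'
#' Samples the training set independently from the low-frequency stratum
#' (count 0) and the high-frequency stratum (count > 0), taking
#' `floor(train_fraction * n)` of each, so rare and common mutations are both
#' represented in every training set. The hotspot row, when given, is forced
#' into the training set (`include_hotspot = TRUE`) or kept out of it.
#' Consumes the session RNG; seed at the protocol level for reproducibility.
#'
#' @param count Integer vector of mutation counts (defines the strata).
#' @param cfg [forest_config()].
#' @param hotspot_index Row index of the hotspot mutation, or `NA`.
#' @param include_hotspot Force the hotspot into (TRUE) or out of (FALSE)
#'   the training set.
#' @return List with integer vectors `train` and `test` (disjoint,
#'   covering all rows).
#' @export
balanced_split <- function(count, cfg = forest_config(),
                           hotspot_index = NA_integer_,
                           include_hotspot = TRUE) {
  low <- which(count == 0)
  high <- which(count > 0)
  if (length(low) < 2L || length(high) < 2L)
    stop("each frequency stratum (count 0 / count > 0) needs >= 2 mutations",
         call. = FALSE)
  train <- integer()
  for (stratum in list(low, high)) {
    n_train <- floor(cfg$train_fraction * length(stratum))
    if (!is.na(hotspot_index) && hotspot_index %in% stratum) {
      rest <- setdiff(stratum, hotspot_index)
      if (include_hotspot) {
        train <- c(train, hotspot_index,
                   sample(rest, max(n_train - 1L, 0L)))
      } else {
        train <- c(train, sample(rest, min(n_train, length(rest))))
      }
    } else {
      train <- c(train, sample(stratum, n_train))
    }
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(count), train))
}

#' Fit one regression forest
#'
#' A thin wrapper around [randomForest::randomForest()] fixing the protocol's
#' parameters and extracting per-feature node-impurity importance: the total
#' decrease in residual sum of squares over all splits that use the feature,
#' summed across all trees (`IncNodePurity`) — not permutation importance.
#' A constant training response admits no impurity decrease; the fit then
#' degenerates to the training mean with all importances zero (warning).
#'
#' @param x Training feature matrix / data.frame (columns = features).
#' @param y Training response vector.
#' @param cfg [forest_config()].
#' @return Object of class `pocket_forest`: list with `forest` (or `NULL`
#'   when degenerate), `importance` (named, non-negative) and `y_mean`.
#' @export
fit_forest <- function(x, y, cfg = forest_config()) {
  stopifnot(nrow(x) == length(y), nrow(x) >= 2L, ncol(x) >= cfg$mtry)
  if (stats::var(y) == 0) {
    warning("constant training response: returning degenerate forest ",
            "with zero importances")
    imp <- stats::setNames(numeric(ncol(x)), colnames(x))
    return(structure(list(forest = NULL, importance = imp, y_mean = mean(y)),
                     class = "pocket_forest"))
  }
  fit <- randomForest::randomForest(x = x, y = y, ntree = cfg$n_trees,
                                    mtry = cfg$mtry)
  imp <- fit$importance[, "IncNodePurity"]
  structure(list(forest = fit, importance = imp, y_mean = mean(y)),
            class = "pocket_forest")
}

#' @export
predict.pocket_forest <- function(object, newdata, ...) {
  if (is.null(object$forest))
    return(rep(object$y_mean, nrow(newdata)))
  unname(stats::predict(object$forest, newdata, ...))
}

#' @export
print.pocket_forest <- function(x, ...) {
  cat("Regression forest (", if (is.null(x$forest)) "degenerate"
      else paste0(x$forest$ntree, " trees"), ")\n", sep = "")
  cat("Node-impurity importance:\n")
  print(round(x$importance, 3))
  invisible(x)
}

#' Evaluate a fitted forest on held-out mutations
#'
#' Pearson correlation between predicted and real responses, the root mean
#' square deviation of the predictions, and their ratio
#' (correlation / RMSD) as the run's performance indicator.
#'
#' @param fit `pocket_forest` from [fit_forest()].
#' @param x_test,y_test Held-out features and responses (>= 3 rows).
#' @return List with `correlation`, `rmsd`, `performance` (`Inf` when
#'   RMSD is exactly 0).
#' @export
evaluate_run <- function(fit, x_test, y_test) {
  if (nrow(x_test) < 3L) stop("need >= 3 test rows", call. = FALSE)
  pred <- predict(fit, x_test)
  rmsd <- sqrt(mean((pred - y_test)^2))
  if (stats::sd(pred) == 0 || stats::sd(y_test) == 0)
    stop("undefined correlation: constant predictions or responses",
         call. = FALSE)
  r <- stats::cor(pred, y_test)
  list(correlation = r, rmsd = rmsd,
       performance = if (rmsd == 0) Inf else r / rmsd)
}

#' Run the balanced forest importance protocol
#'
#' The package's model-fitting entry point. Two sets of `n_runs` balanced
#' train/test splits are drawn: in the first the hotspot mutation is always
#' part of the training set, in the second it never is (a regression forest
#' cannot extrapolate beyond its training range, so where the dominant
#' hotspot sits changes what the model can learn from it). Each run fits a
#' forest, records test-set correlation, RMSD and performance, and the seven
#' node-impurity importances; per set, mean importances are normalized to
#' percentages.
#'
#' @param features Assembled matrix from [build_feature_matrix()] (needs the
#'   seven feature columns plus `count`, `response`, `mutation`).
#' @param cfg [forest_config()].
#' @param seed Master seed; the whole protocol is reproducible from it.
#' @return Object of class `forest_protocol`: list with `runs` (per-run
#'   data.frame: set, run, correlation, rmsd, performance), `importance`
#'   (list of two n_runs x 7 matrices), `mean_importance_pct` (2 x 7 matrix,
#'   rows `with_hotspot` / `without_hotspot`, each summing to 100),
#'   `cfg` and `seed`.
#' @export
run_protocol <- function(features, cfg = forest_config(), seed = 1L) {
  stopifnot(all(FEATURE_NAMES %in% names(features)),
            all(c("count", "response") %in% names(features)))
  x <- features[, FEATURE_NAMES]
  y <- features$response
  hotspot_index <- if (is.na(cfg$hotspot)) NA_integer_ else
    match(cfg$hotspot, features$mutation)

  set.seed(seed)
  sets <- c(with_hotspot = TRUE, without_hotspot = FALSE)
  runs <- list(); imps <- list()
  for (set_name in names(sets)) {
    imp <- matrix(NA_real_, cfg$n_runs, length(FEATURE_NAMES),
                  dimnames = list(NULL, FEATURE_NAMES))
    tab <- vector("list", cfg$n_runs)
    for (run in seq_len(cfg$n_runs)) {
      split <- balanced_split(features$count, cfg, hotspot_index,
                              include_hotspot = sets[[set_name]])
      fit <- fit_forest(x[split$train, ], y[split$train], cfg)
      ev <- evaluate_run(fit, x[split$test, ], y[split$test])
      imp[run, ] <- fit$importance
      tab[[run]] <- data.frame(set = set_name, run = run,
                               correlation = ev$correlation, rmsd = ev$rmsd,
                               performance = ev$performance,
                               stringsAsFactors = FALSE)
    }
    runs[[set_name]] <- do.call(rbind, tab)
    imps[[set_name]] <- imp
  }
  mean_imp <- t(vapply(imps, function(m) {
    cm <- colMeans(m)
    if (sum(cm) == 0) cm else 100 * cm / sum(cm)
  }, numeric(length(FEATURE_NAMES))))

  structure(list(runs = do.call(rbind, runs), importance = imps,
                 mean_importance_pct = mean_imp, cfg = cfg, seed = seed),
            class = "forest_protocol")
}

#' @export
print.forest_protocol <- function(x, ...) {
  cat("Balanced random-forest importance protocol\n")
  cat(sprintf("  %d runs per set, %d trees, mtry %d, train fraction %.2f\n",
              x$cfg$n_runs, x$cfg$n_trees, x$cfg$mtry, x$cfg$train_fraction))
  cat(sprintf("  hotspot: %s\n", x$cfg$hotspot))
  cat("\nMean feature importance (% of total node-impurity decrease):\n")
  print(round(x$mean_importance_pct, 1))
  invisible(x)
}

#' @export
#' @method summary forest_protocol
summary.forest_protocol <- function(object, ...) {
  perf <- do.call(rbind, lapply(split(object$runs, object$runs$set),
    function(d) data.frame(
      set = d$set[1],
      mean_correlation = mean(d$correlation),
      mean_rmsd = mean(d$rmsd),
      median_performance = stats::median(d$performance))))
  rownames(perf) <- NULL
  out <- list(performance = perf,
              mean_importance_pct = object$mean_importance_pct,
              top_feature = colnames(object$mean_importance_pct)[
                apply(object$mean_importance_pct, 1, which.max)])
  class(out) <- "summary.forest_protocol"
  out
}

#' @export
print.summary.forest_protocol <- function(x, ...) {
  cat("Per-set test performance:\n"); print(x$performance)
  cat("\nMean importance (%):\n"); print(round(x$mean_importance_pct, 1))
  cat("\nTop feature per set:", paste(x$top_feature, collapse = ", "), "\n")
  invisible(x)
}

#' Plot a fitted forest protocol
#'
#' Left: mean percent importance of the seven features, side by side for the
#' two sets. Right: per-run RMSD against correlation.
#'
#' @param x `forest_protocol` object.
#' @param ... Unused.
#' @export
#' @method plot forest_protocol
plot.forest_protocol <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(x$mean_importance_pct, beside = TRUE, las = 2,
                    ylab = "mean importance (%)",
                    legend.text = rownames(x$mean_importance_pct),
                    args.legend = list(x = "topright", bty = "n"))
  cols <- c(with_hotspot = "black", without_hotspot = "grey50")
  graphics::plot(x$runs$correlation, x$runs$rmsd,
                 col = cols[x$runs$set], pch = 19,
                 xlab = "test correlation", ylab = "test RMSD")
  invisible(x)
}
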