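# Classification: ECD labelling and linear-SVM evaluation over repeated
# randomized train/test splits (Monte Carlo cross-validation), with
# vertically averaged ROC curves.

#' Endothelial integrity class from cell density
#'
#' Intact if and only if ECD is strictly greater than 3000 cells/mm^2.
#'
#' @param ecd endothelial cell density (cells/mm^2, > 0); vector ok
#' @param threshold class boundary (cells/mm^2)
#' @return factor with levels `damaged`, `intact`
#' @export
label_from_ecd <- function(ecd, threshold = 3000) {
  if (any(ecd <= 0)) stop("ECD must be positive")
  factor(ifelse(ecd > threshold, "intact", "damaged"),
         levels = c("damaged", "intact"))
}

# stratified (or plain) train/test split; returns train indices
draw_split <- function(y, train_fraction, stratify, max_retries = 100) {
  n <- length(y)
  if (stratify) {
    idx <- unlist(lapply(levels(y), function(lv) {
      who <- which(y == lv)
      ntr <- round(train_fraction * length(who))
      ntr <- min(max(ntr, 1L), length(who) - 1L)
      sample(who, ntr)
    }))
    return(sort(idx))
  }
  for (. in seq_len(max_retries)) {
    idx <- sample.int(n, round(train_fraction * n))
    if (nlevels(droplevels(y[idx])) == 2 &&
        nlevels(droplevels(y[-idx])) == 2) return(sort(idx))
  }
  stop("could not draw a split with both classes in train and test")
}

# decision scores oriented so larger = more 'intact'
svm_scores <- function(fit, newdata) {
  dv <- attr(stats::predict(fit, newdata, decision.values = TRUE),
             "decision.values")
  s <- dv[, 1]
  # e1071 names the column '<first>/<second>'; positive means first class
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  if (first == "intact") s else -s
}

# grid-search the cost parameter by k-fold CV accuracy on the training split
tune_cost <- function(x, y, cost_grid, folds) {
  n <- nrow(x)
  fold_id <- integer(n)
  for (lv in levels(y)) { # class-balanced fold assignment
    who <- which(y == lv)
    fold_id[who] <- sample(rep_len(seq_len(folds), length(who)))
  }
  acc <- vapply(cost_grid, function(cst) {
    hits <- 0L
    for (fd in unique(fold_id)) {
      tr <- fold_id != fd
      if (nlevels(droplevels(y[tr])) < 2) next
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                        cost = cst, scale = FALSE)
      hits <- hits + sum(stats::predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
    }
    hits / n
  }, numeric(1))
  cost_grid[which.max(acc)] # ties resolve to the smallest cost
}

# TPR at a fixed FPR grid from a pROC roc object: linear interpolation of
# the empirical curve, with the origin pinned at (0, 0) — the usual
# convention for vertically averaged mean ROC curves.
tpr_at_fpr <- function(roc_obj, fpr_grid) {
  fpr <- 1 - roc_obj$specificities
  tpr <- roc_obj$sensitivities
  o <- order(fpr, tpr)
  y <- stats::approx(c(0, fpr[o], 1), c(0, tpr[o], 1), xout = fpr_grid,
                     ties = max)$y
  y[fpr_grid == 0] <- 0
  y
}

#' Linear-SVM classification over repeated randomized splits
#'
#' The package's core evaluation model. For each of `n_iter` iterations a
#' randomized train/test split is drawn (stratified by class by default),
#' predictors are z-scored with training-split statistics, the SVM cost
#' parameter is grid-searched by k-fold cross-validation on the training
#' split (scored by accuracy), a linear SVM is fitted, and the test-split
#' ROC and its AUC are computed from the decision function. ROC curves are
#' vertically averaged on a fixed 101-point FPR grid; the headline statistic
#' is the AUC mean and standard deviation over iterations.
#'
#' @param formula model formula, e.g. `class ~ S_Elev_ps + S_Phys_ps`; the
#'   response must be a two-level factor with levels `damaged`, `intact`
#'   (see [label_from_ecd()])
#' @param data data.frame holding the response and predictors
#' @param n_iter number of randomized splits (default 300)
#' @param train_fraction training fraction (default 0.7)
#' @param cost_grid SVM margin-penalty grid (default `10^(-3:3)`)
#' @param cv_folds folds for the cost grid search (default 5)
#' @param stratify stratify splits by class (default TRUE)
#' @param kernel SVM kernel (default `"linear"`)
#' @param seed master integer seed; iteration `i` uses `seed + i`
#' @param keep_scores retain each iteration's test-set decision scores and
#'   labels (for score-level diagnostics)
#' @return an object of class `thz_svm` with elements `aucs`
#'   (per-iteration test AUC), `auc_mean`, `auc_sd`, `roc`
#'   (`fpr`, `tpr_mean`, `tpr_sd`), `predictor_set`, `best_costs`, `call`,
#'   and (if requested) `scores`
#' @export
thz_svm <- function(formula, data, n_iter = 300, train_fraction = 0.7,
                    cost_grid = 10^seq(-3, 3), cv_folds = 5,
                    stratify = TRUE, kernel = "linear", seed = 1L,
                    keep_scores = FALSE) {
  stopifnot(n_iter >= 1, train_fraction > 0, train_fraction < 1,
            length(cost_grid) >= 1)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!is.factor(y) || nlevels(y) != 2)
    stop("response must be a two-level factor")
  y <- factor(y, levels = c("damaged", "intact"))
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  if (ncol(x) == 0) stop("empty predictor set")
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  fpr_grid <- seq(0, 1, by = 0.01)
  aucs <- numeric(n_iter)
  best_costs <- numeric(n_iter)
  tprs <- matrix(NA_real_, n_iter, length(fpr_grid))
  scores <- if (keep_scores) vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    set.seed(as.integer(seed) + i)
    tr <- draw_split(y, train_fraction, stratify)
    mu <- colMeans(x[tr, , drop = FALSE])
    sg <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    z <- sweep(sweep(x, 2, mu), 2, sg, "/")
    cst <- tune_cost(z[tr, , drop = FALSE], y[tr], cost_grid, cv_folds)
    best_costs[i] <- cst
    fit <- e1071::svm(z[tr, , drop = FALSE], y[tr], kernel = kernel,
                      cost = cst, scale = FALSE)
    sc <- svm_scores(fit, z[-tr, , drop = FALSE])
    roc_i <- pROC::roc(response = y[-tr], predictor = sc,
                       levels = c("damaged", "intact"), direction = "<",
                       quiet = TRUE)
    aucs[i] <- as.numeric(pROC::auc(roc_i))
    tprs[i, ] <- tpr_at_fpr(roc_i, fpr_grid)
    if (keep_scores)
      scores[[i]] <- data.frame(iteration = i, score = sc,
                                label = y[-tr])
  }
  structure(list(
    aucs = aucs, auc_mean = mean(aucs), auc_sd = stats::sd(aucs),
    roc = list(fpr = fpr_grid, tpr_mean = colMeans(tprs),
               tpr_sd = apply(tprs, 2, stats::sd)),
    predictor_set = paste(colnames(x), collapse = "+"),
    best_costs = best_costs,
    scores = if (keep_scores) do.call(rbind, scores),
    n_iter = n_iter, train_fraction = train_fraction, seed = seed,
    call = match.call()), class = "thz_svm")
}

#' @export
print.thz_svm <- function(x, ...) {
  cat(sprintf("Linear-SVM Monte Carlo cross-validation (%d x %d/%d splits)\n",
              x$n_iter, round(100 * x$train_fraction),
              round(100 * (1 - x$train_fraction))))
  cat(sprintf("  predictors: %s\n", x$predictor_set))
  cat(sprintf("  test ROC-AUC: %.2f +/- %.2f\n", x$auc_mean, x$auc_sd))
  invisible(x)
}

#' @export
summary.thz_svm <- function(object, ...) {
  print(object)
  cat("  per-iteration AUC quantiles:\n")
  print(round(stats::quantile(object$aucs, c(0.05, 0.25, 0.5, 0.75, 0.95)), 3))
  cat(sprintf("  modal tuned cost: %g\n",
              as.numeric(names(which.max(table(object$best_costs))))))
  invisible(object)
}

#' Plot the averaged ROC curve of a `thz_svm` fit
#'
#' @param x a `thz_svm` object
#' @param ... further arguments passed to [graphics::plot()]
#' @export
plot.thz_svm <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr_mean, type = "l", lwd = 2,
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("%s  (AUC %.2f +/- %.2f)", x$predictor_set,
                                x$auc_mean, x$auc_sd), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Evaluate the four standard predictor sets
#'
#' Runs [thz_svm()] for each of `S_Start`, `S_Elev`, `S_Phys` alone and the
#' combined `S_Elev + S_Phys` model on a joined feature/label table.
#'
#' @param features feature table (see [feature_table()])
#' @param labels labels table (`sample_id, ecd_cells_per_mm2`, see
#'   [cohort_labels()])
#' @param config classification parameter list (see `default_config()$classify`)
#' @param seed master seed
#' @return named list of `thz_svm` objects
#' @export
evaluate_predictor_sets <- function(features, labels,
                                    config = default_config()$classify,
                                    seed = 1L) {
  dat <- merge(features, labels[, c("sample_id", "ecd_cells_per_mm2")],
               by = "sample_id")
  dat$class <- label_from_ecd(dat$ecd_cells_per_mm2)
  sets <- list("S_Start" = class ~ S_Start_ps,
               "S_Elev" = class ~ S_Elev_ps,
               "S_Phys" = class ~ S_Phys_ps,
               "S_Elev+S_Phys" = class ~ S_Elev_ps + S_Phys_ps)
  out <- lapply(sets, function(fm)
    thz_svm(fm, dat, n_iter = config$n_iterations,
            train_fraction = config$train_fraction,
            cost_grid = config$cost_grid, cv_folds = config$cv_folds,
            stratify = config$stratify, seed = seed))
  for (nm in names(out)) out[[nm]]$predictor_set <- nm
  out
}

#' Linear relation between the elevated and recovery slopes
#'
#' Ordinary least-squares fit of `S_Phys` on `S_Elev`; the recovery-period
#' slope is causally downstream of the elevated-period slope, so a strong
#' linear relation is expected when endothelial damage is persistent.
#'
#' @param features feature table with `S_Elev_ps` and `S_Phys_ps`
#' @return list with `slope`, `intercept`, `r_squared`, `n`
#' @export
correlation_report <- function(features) {
  if (nrow(features) < 3) stop("need at least 3 samples")
  if (stats::sd(features$S_Elev_ps) == 0)
    stop("zero variance in S_Elev")
  fit <- stats::lm(S_Phys_ps ~ S_Elev_ps, data = features)
  y <- features$S_Phys_ps
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n = nrow(features))
}
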