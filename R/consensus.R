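# METEORE-style consensus of per-read scores from two or more callers:
# min-max scaling, intersection join across tools, random-forest or ridge
# consensus, and cross-validated ROC/PR curves.

.KEY_COLS <- c("read_id", "chrom", "pos", "strand")

#' Min-max scaling constants per tool
#'
#' Fits per-tool (min, max) on training scores so that the training range
#' maps onto `[0, 1]`; at prediction time values outside the training range
#' are clipped.
#'
#' @param x Numeric matrix or data.frame of per-tool scores (columns = tools).
#' @return A `minmax_scaler`: list with `min` and `max` named by tool.
#' @export
fit_minmax <- function(x) {
  x <- as.matrix(x)
  mins <- apply(x, 2, min, na.rm = TRUE)
  maxs <- apply(x, 2, max, na.rm = TRUE)
  flat <- maxs <= mins
  if (any(flat))
    stop("constant score column for tool(s): ",
         paste(colnames(x)[flat], collapse = ", "))
  structure(list(min = mins, max = maxs), class = "minmax_scaler")
}

#' @rdname fit_minmax
#' @param scaler A fitted `minmax_scaler`.
#' @export
apply_minmax <- function(scaler, x) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  x <- as.matrix(x)
  stopifnot(identical(colnames(x), names(scaler$min)))
  out <- sweep(sweep(x, 2, scaler$min, "-"), 2,
               scaler$max - scaler$min, "/")
  pmin(pmax(out, 0), 1)
}

#' Intersection-join per-read calls across tools
#'
#' Inner join on (read_id, chrom, pos, strand): only reads scored by every
#' tool survive, mirroring the consensus requirement for prediction scores
#' from all inputs. Per-tool retention fractions are attached as the
#' `retention` attribute. If the tables carry a `label` column it is joined
#' through (and must agree across tools).
#'
#' @param tables Named list (>= 2) of standardized per-read call tables.
#' @return A score matrix `data.table`: key columns plus one score column per
#'   tool (named by tool), plus `label` when available.
#' @export
join_reads_across_tools <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2, !is.null(names(tables)))
  tools <- names(tables)
  slim <- lapply(tools, function(tl) {
    dt <- as.data.table(tables[[tl]])
    keep <- c(.KEY_COLS, "score", intersect("label", names(dt)))
    dt <- dt[, ..keep]
    data.table::setnames(dt, "score", tl)
    dt
  })
  out <- Reduce(function(a, b) {
    merge(a, b, by = intersect(names(a), names(b)), all = FALSE)
  }, slim)
  if (nrow(out) == 0) stop("no reads shared by all tools (empty intersection)")
  retention <- vapply(seq_along(tools), function(i)
    nrow(out) / nrow(unique(slim[[i]], by = .KEY_COLS)), numeric(1))
  names(retention) <- tools
  data.table::setattr(out, "tools", tools)
  data.table::setattr(out, "retention", retention)
  out[]
}

.matrix_tools <- function(m) {
  tl <- attr(m, "tools")
  if (is.null(tl)) tl <- setdiff(names(m), c(.KEY_COLS, "label"))
  tl
}

# closed-form ridge with unpenalized intercept and no standardization
# (scores are already min-max scaled to [0, 1])
.ridge_fit <- function(X, y, lambda) {
  xbar <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2, xbar)
  A <- crossprod(Xc) + diag(lambda, ncol(X))
  beta <- solve(A, crossprod(Xc, y - ybar))
  list(coef = drop(beta), intercept = ybar - sum(xbar * beta))
}

.ridge_cv <- function(X, y, lambda_grid, k = 5, seed = 42) {
  n <- nrow(X)
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  mse <- vapply(lambda_grid, function(lam) {
    errs <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      fit <- .ridge_fit(X[tr, , drop = FALSE], y[tr], lam)
      pred <- X[!tr, , drop = FALSE] %*% fit$coef + fit$intercept
      mean((y[!tr] - pred)^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  lambda_grid[which.min(mse)]
}

#' Train a consensus model over joined per-read scores
#'
#' Scores are min-max scaled per tool (constants fitted on the training
#' data), then either a small random forest (`kind = "rf"`, default
#' `max_depth = 3`, `n_trees = 10`) or a ridge regression on the 0/1 labels
#' (`kind = "reg"`, penalty chosen by internal fivefold cross-validation over
#' the fixed grid 0.01, 0.1, 1, 10, 100) is fitted. Training is deterministic
#' given `seed`.
#'
#' @param m Score matrix from [join_reads_across_tools()].
#' @param labels 0/1 truth labels (1 = methylated); defaults to the matrix's
#'   `label` column.
#' @param kind `"rf"` or `"reg"`.
#' @param max_depth,n_trees Random-forest capacity (sklearn-style defaults
#'   used in the consensus: depth 3, 10 trees).
#' @param lambda_grid Ridge penalty grid.
#' @param seed Seed controlling forest growth and CV fold assignment.
#' @return A `consensus_model` with the decision threshold fixed at 0.5.
#' @export
train_consensus <- function(m, labels = NULL, kind = c("rf", "reg"),
                            max_depth = 3, n_trees = 10,
                            lambda_grid = c(0.01, 0.1, 1, 10, 100),
                            seed = 42) {
  kind <- match.arg(kind)
  m <- as.data.table(m)
  tools <- .matrix_tools(m)
  stopifnot(length(tools) >= 2)
  if (is.null(labels)) {
    if (!"label" %in% names(m)) stop("no labels supplied and no label column")
    labels <- m$label
  }
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("training labels contain a single class")
  X <- as.matrix(m[, ..tools])
  scaler <- fit_minmax(X)
  Xs <- apply_minmax(scaler, X)
  if (kind == "rf") {
    df <- data.frame(Xs, check.names = FALSE)
    df$.label <- factor(labels, levels = c(0, 1))
    fit <- ranger::ranger(dependent.variable.name = ".label", data = df,
                          num.trees = n_trees, max.depth = max_depth,
                          probability = TRUE, seed = seed, num.threads = 1)
    params <- list(max_depth = max_depth, n_trees = n_trees)
  } else {
    lambda <- .ridge_cv(Xs, labels, lambda_grid, k = 5, seed = seed)
    fit <- .ridge_fit(Xs, labels, lambda)
    params <- list(lambda = lambda, lambda_grid = lambda_grid)
  }
  structure(list(kind = kind, tools = tools, scaler = scaler, fit = fit,
                 params = params, seed = seed, threshold = 0.5),
            class = "consensus_model")
}

#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf("consensus_model (%s) over tools: %s\n",
              toupper(x$kind), paste(x$tools, collapse = ", ")))
  if (x$kind == "reg")
    cat(sprintf("  ridge lambda = %g; coefficients: %s; intercept %.4f\n",
                x$params$lambda,
                paste(sprintf("%s=%.4f", x$tools, x$fit$coef), collapse = ", "),
                x$fit$intercept))
  else
    cat(sprintf("  %d trees, max depth %d, seed %d\n",
                x$params$n_trees, x$params$max_depth, x$seed))
  invisible(x)
}

#' Predict per-read consensus scores and binary calls
#'
#' The consensus score is the forest's methylated-class probability or the
#' (clipped) ridge prediction, always in `[0, 1]`. Calls follow the strict
#' 0.5 rule: methylated if > 0.5, unmethylated if < 0.5, and a prediction of
#' exactly 0.5 is discarded (counted in the `n_discarded` attribute).
#'
#' @param model A `consensus_model`.
#' @param m Score matrix with the same tool set as the model.
#' @return `m` with `consensus_score` and `consensus_state` columns appended.
#' @export
predict_consensus <- function(model, m) {
  stopifnot(inherits(model, "consensus_model"))
  m <- as.data.table(m)
  tools <- .matrix_tools(m)
  if (!setequal(tools, model$tools))
    stop("tool-set mismatch: model has {", paste(model$tools, collapse = ", "),
         "}, matrix has {", paste(tools, collapse = ", "), "}")
  X <- as.matrix(m[, model$tools, with = FALSE])
  Xs <- apply_minmax(model$scaler, X)
  if (model$kind == "rf") {
    pr <- predict(model$fit, data.frame(Xs, check.names = FALSE),
                  num.threads = 1)$predictions
    score <- pr[, "1"]
  } else {
    score <- drop(Xs %*% model$fit$coef + model$fit$intercept)
    score <- pmin(pmax(score, 0), 1)
  }
  out <- copy(m)
  out[, consensus_score := score]
  out[, consensus_state := fifelse(score > model$threshold, "meth",
                                   fifelse(score < model$threshold,
                                           "unmeth", "discard"))]
  n_disc <- sum(out$consensus_state == "discard")
  if (n_disc > 0)
    message(n_disc, " predictions at exactly ", model$threshold, " discarded")
  data.table::setattr(out, "tools", tools)
  data.table::setattr(out, "n_discarded", n_disc)
  out[]
}

.stratified_folds <- function(labels, k, seed) {
  if (min(table(labels)) < k)
    stop("a class has fewer than k = ", k, " members; cannot stratify")
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# step-function value of the (fpr, tpr) path on a fixed grid
.roc_on_grid <- function(path, grid) {
  vapply(grid, function(g) {
    ok <- path$fpr <= g
    if (any(ok)) max(path$tpr[ok]) else 0
  }, numeric(1))
}

.pr_on_grid <- function(pc, grid) {
  vapply(grid, function(g) {
    ok <- pc$recall >= g
    if (any(ok)) max(pc$precision[ok]) else pc$precision[which.max(pc$recall)]
  }, numeric(1))
}

#' Cross-validated consensus ROC and PR curves
#'
#' Stratified k-fold cross-validation under `seed`: per fold, the consensus
#' model (including its scaling constants) is fitted on the training folds
#' only and evaluated on the held-out fold; the per-fold curves are
#' vertically averaged on a fixed 101-point FPR (resp. recall) grid, and the
#' mean of the per-fold areas is reported.
#'
#' @param m Score matrix with labels available.
#' @param labels 0/1 truth labels; defaults to the `label` column.
#' @param k Number of folds (default 10).
#' @param seed Seed for fold assignment and model training.
#' @param ... Passed to [train_consensus()] (e.g. `kind`).
#' @return List with `fpr_grid`, `mean_tpr`, `recall_grid`, `mean_precision`,
#'   `auc_roc_folds`, `auc_pr_folds`, `mean_auc_roc`, `mean_auc_pr`, `folds`.
#' @export
cross_validated_curves <- function(m, labels = NULL, k = 10, seed = 42, ...) {
  stopifnot(k >= 2)
  m <- as.data.table(m)
  tools <- .matrix_tools(m)
  if (is.null(labels)) {
    if (!"label" %in% names(m)) stop("no labels supplied and no label column")
    labels <- m$label
  }
  labels <- as.integer(labels)
  folds <- .stratified_folds(labels, k, seed)
  grid <- seq(0, 1, length.out = 101)
  tpr_mat <- matrix(NA_real_, k, length(grid))
  prec_mat <- matrix(NA_real_, k, length(grid))
  aucs <- numeric(k); aucs_pr <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    model <- train_consensus(m[tr], labels[tr], seed = seed, ...)
    pred <- predict_consensus(model, m[!tr])
    path <- rate_path(pred$consensus_score, labels[!tr])
    aucs[f] <- auc_roc(path)
    tpr_mat[f, ] <- .roc_on_grid(path, grid)
    pc <- pr_curve(pred$consensus_score, labels[!tr])
    aucs_pr[f] <- auc_pr(pred$consensus_score, labels[!tr])
    prec_mat[f, ] <- .pr_on_grid(pc, grid)
  }
  list(fpr_grid = grid, mean_tpr = colMeans(tpr_mat),
       recall_grid = grid, mean_precision = colMeans(prec_mat),
       auc_roc_folds = aucs, auc_pr_folds = aucs_pr,
       mean_auc_roc = mean(aucs), mean_auc_pr = mean(aucs_pr),
       folds = folds)
}
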