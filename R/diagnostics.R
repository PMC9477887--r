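# Evaluation battery: dissimilarities, PERMANOVA R2, per-taxon association
# testing with BH-FDR, cross-validated random-forest prediction, PCoA.

#' Bray-Curtis dissimilarity matrix
#'
#' `d(a, b) = 1 - 2 sum min(a_i, b_i) / (sum a_i + sum b_i)` on raw counts
#' (computed through vegan). A pair involving an all-zero sample has no
#' defined overlap and is assigned distance 1, with a message.
#'
#' @param table a [count_table()].
#' @return symmetric matrix with attribute `metric = "bray_curtis"`.
#' @export
bray_curtis_matrix <- function(table) {
  stopifnot(inherits(table, "count_table"))
  d <- as.matrix(vegan::vegdist(table$counts, method = "bray"))
  if (any(table$libsize == 0)) {
    message("all-zero sample(s); their distances set to 1")
    zero <- table$libsize == 0
    d[zero, ] <- 1
    d[, zero] <- 1
    diag(d) <- 0
  }
  dimnames(d) <- list(table$sample_ids, table$sample_ids)
  attr(d, "metric") <- "bray_curtis"
  d
}

#' Aitchison (CLR-Euclidean) dissimilarity matrix
#'
#' Counts plus a pseudocount are closed to relative abundances, centred
#' log-ratio transformed per sample, and compared by Euclidean distance.
#'
#' @param table a [count_table()].
#' @param pseudocount positive offset added to every count before closure
#'   (default 0.5, the simulator's Dirichlet prior, reused for coherence).
#' @export
aitchison_matrix <- function(table, pseudocount = 0.5) {
  stopifnot(inherits(table, "count_table"), pseudocount > 0)
  x <- table$counts + pseudocount
  lx <- log(x / rowSums(x))
  clr <- lx - rowMeans(lx)
  d <- as.matrix(stats::dist(clr))
  dimnames(d) <- list(table$sample_ids, table$sample_ids)
  attr(d, "metric") <- "aitchison"
  d
}

#' PERMANOVA R-squared of a variable
#'
#' Fraction of the distance-matrix sum of squares explained by a grouping
#' or numeric variable, from the Gower-centred inner-product decomposition
#' (`R2 = tr(H G H) / tr(G)` with `G` the centred `-d^2/2` matrix and `H`
#' the hat matrix of the variable). Computed from sums of squares directly;
#' no permutations are involved because R2 is used descriptively and as a
#' tuning criterion, not for testing.
#'
#' @param dist symmetric distance matrix.
#' @param variable factor/character grouping or numeric covariate, aligned
#'   with the rows of `dist`.
#' @return R2 in `[0, 1]`.
#' @export
permanova_r2 <- function(dist, variable) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (length(variable) != n) stop("variable not aligned with distances")
  if (is.character(variable)) variable <- factor(variable)
  if (is.factor(variable) && nlevels(droplevels(variable)) < 2)
    stop("variable has a single level")
  if (is.numeric(variable) && stats::var(variable) == 0)
    stop("variable is constant")
  G <- -0.5 * d^2
  G <- sweep(G, 1L, rowMeans(G))
  G <- sweep(G, 2L, colMeans(G))
  M <- model.matrix(~variable)
  H <- M %*% solve(crossprod(M), t(M))
  r2 <- sum(H * G) / sum(diag(G))  # tr(HG), H symmetric idempotent
  max(0, min(1, r2))
}

#' Per-taxon association testing with BH false-discovery control
#'
#' Ordinary linear regression of each taxon's relative abundance
#' (count / library size of the analysed table) on the key variable, with
#' optional covariate adjustment; the key-coefficient p-values are
#' Benjamini-Hochberg adjusted. With a truth set, reports observed FDR
#' (`FP / max(positive calls, 1)`, so zero discoveries give FDR 0) and
#' sensitivity (`TP / |truth|`).
#'
#' @param table a [count_table()].
#' @param meta a [sample_metadata()] aligned with it.
#' @param key key variable column name (defaults to the first key column).
#' @param covariates covariate column names to adjust for.
#' @param alpha BH level (default 0.05).
#' @param truth optional integer indices (or taxon IDs) of truly
#'   differentially abundant taxa.
#' @return list with `pvalues`, `padj`, `discoveries` (taxon indices),
#'   `observed_fdr`, `sensitivity` (the latter two `NULL` without truth).
#' @export
association_fdr <- function(table, meta, key = NULL,
                            covariates = character(), alpha = 0.05,
                            truth = NULL) {
  stopifnot(inherits(table, "count_table"),
            inherits(meta, "sample_metadata"), alpha > 0, alpha < 1)
  key <- key %||% meta$key_cols[1L]
  ls <- table$libsize
  ls[ls == 0] <- 1
  rel <- table$counts / ls
  df <- meta$data[, c(key, covariates), drop = FALSE]
  for (nm in names(df))
    if (is.character(df[[nm]]) || is.logical(df[[nm]]))
      df[[nm]] <- factor(df[[nm]])
  M <- model.matrix(~., data = df)
  key_col <- which(attr(M, "assign") == 1L)[1L]
  n <- nrow(M)
  p <- ncol(M)
  XtXinv <- chol2inv(chol(crossprod(M)))
  B <- XtXinv %*% crossprod(M, rel)      # coefficients, all taxa at once
  res <- rel - M %*% B
  dfree <- n - p
  rss <- colSums(res^2)
  se <- sqrt(rss / dfree * XtXinv[key_col, key_col])
  tstat <- B[key_col, ] / se
  pvals <- 2 * pt(abs(tstat), dfree, lower.tail = FALSE)
  constant <- apply(rel, 2L, function(yj) stats::var(yj) == 0)
  pvals[constant | rss < 1e-30 | !is.finite(pvals)] <- 1  # uninformative
  padj <- p.adjust(pvals, method = "BH")
  disc <- which(padj <= alpha)
  out <- list(pvalues = pvals, padj = padj, discoveries = disc,
              observed_fdr = NULL, sensitivity = NULL)
  if (!is.null(truth)) {
    if (is.character(truth)) truth <- match(truth, table$taxon_ids)
    tp <- sum(disc %in% truth)
    out$observed_fdr <- (length(disc) - tp) / max(length(disc), 1)
    out$sensitivity <- tp / length(truth)
  }
  out
}

# Area under the ROC curve by the rank (Mann-Whitney) identity.
.auc <- function(labels, scores) {
  pos <- labels == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated random-forest prediction of the key variable
#'
#' How much of the key variable the (corrected) taxa counts explain,
#' assessed with a 500-tree random forest under 5-fold cross-validation:
#' pooled ROC-AUC for a binary key, RMSE for a continuous one,
#' cross-entropy for a polytomous one. Folds are stratified for
#' categorical keys and reproducible by seed; a fold whose training split
#' misses a class triggers a re-draw with an incremented seed.
#'
#' @param table a [count_table()]. @param meta aligned metadata.
#' @param key key column name (default: first key column).
#' @param folds number of folds. @param seed fold-assignment seed.
#' @param ntree forest size.
#' @return list with `metric` (`"auc"`, `"rmse"` or `"cross_entropy"`) and
#'   `value`.
#' @export
predict_key_cv <- function(table, meta, key = NULL, folds = 5L, seed = 1L,
                           ntree = 500L) {
  stopifnot(inherits(table, "count_table"),
            inherits(meta, "sample_metadata"))
  key <- key %||% meta$key_cols[1L]
  yv <- meta$data[[key]]
  x <- table$counts
  colnames(x) <- make.names(colnames(x), unique = TRUE)
  categorical <- is.factor(yv) || is.character(yv) || is.logical(yv) ||
    (is.numeric(yv) && length(unique(yv)) <= 2L)
  n <- length(yv)
  draw_folds <- function(s) {
    with_seed(substream_seed(s, "folds"), {
      f <- integer(n)
      if (categorical) {
        for (lv in unique(yv)) {
          idx <- which(yv == lv)
          f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
        }
      } else f <- sample(rep_len(seq_len(folds), n))
      f
    })
  }
  if (categorical) yv <- factor(yv)
  for (attempt in 0:9) {
    fold <- draw_folds(seed + attempt)
    ok <- !categorical ||
      all(vapply(seq_len(folds), function(k)
        nlevels(droplevels(yv[fold != k])) == nlevels(yv), logical(1)))
    if (ok) break
    message("fold without all classes; re-drawing with incremented seed")
  }
  preds <- if (categorical)
    matrix(NA_real_, n, nlevels(yv), dimnames = list(NULL, levels(yv)))
  else rep(NA_real_, n)
  for (k in seq_len(folds)) {
    tr <- fold != k
    rf <- with_seed(substream_seed(seed, "folds", k),
      randomForest::randomForest(x[tr, , drop = FALSE], yv[tr],
                                 ntree = ntree))
    if (categorical)
      preds[!tr, ] <- predict(rf, x[!tr, , drop = FALSE], type = "prob")
    else preds[!tr] <- predict(rf, x[!tr, , drop = FALSE])
  }
  if (!categorical)
    return(list(metric = "rmse",
                value = sqrt(mean((preds - yv)^2))))
  if (nlevels(yv) == 2L)
    return(list(metric = "auc",
                value = .auc(as.integer(yv) - 1L, preds[, 2L])))
  pr <- pmax(preds[cbind(seq_len(n), as.integer(yv))], 1e-15)
  list(metric = "cross_entropy", value = -mean(log(pr)))
}

#' Principal-coordinate export for external plotting
#'
#' Classical multidimensional scaling of a distance matrix; plumbing for
#' ordination plots, no figure is rendered.
#'
#' @param dist distance matrix. @param k number of axes.
#' @return matrix of coordinates (samples x k).
#' @export
pcoa_coords <- function(dist, k = 2L) {
  stats::cmdscale(stats::as.dist(dist), k = k)
}
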