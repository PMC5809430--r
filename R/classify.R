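#' Amino-acid presence features for hexapeptides
#'
#' Global mode: 20 binary indicators, residue X present anywhere in the
#' peptide. Positional mode: 120 indicators `X@k`, residue X at position k.
#' Constant columns (all 0 or all 1 over the input) carry no information and
#' are dropped with a message.
#'
#' @param peptides Character vector of 6-residue peptides.
#' @param mode `"global"` or `"positional"`.
#' @return Binary matrix, rows = peptides, named feature columns.
#' @export
build_features <- function(peptides, mode = c("global", "positional")) {
  mode <- match.arg(mode)
  if (length(peptides) == 0L) stop("empty peptide set")
  stopifnot(all(nchar(peptides) == 6L))
  aa <- amino_acids()
  if (mode == "global") {
    X <- vapply(aa, function(a) grepl(a, peptides, fixed = TRUE),
                logical(length(peptides)))
    X <- matrix(as.numeric(X), ncol = 20L, dimnames = list(peptides, aa))
  } else {
    cols <- vector("list", 120L)
    nm <- character(120L)
    j <- 0L
    for (k in 1:6) {
      res_k <- substr(peptides, k, k)
      for (a in aa) {
        j <- j + 1L
        cols[[j]] <- as.numeric(res_k == a)
        nm[j] <- paste0(a, "@", k)
      }
    }
    X <- do.call(cbind, cols)
    dimnames(X) <- list(peptides, nm)
  }
  const <- apply(X, 2L, function(v) length(unique(v)) == 1L)
  if (any(const)) {
    message("dropping ", sum(const), " constant feature(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  X
}

#' Sample negative peptides from the neutral pool
#'
#' Draws uniformly without replacement from peptides labeled neutral
#' (neither significantly cleaved nor significantly depleted), size-matched
#' to the positive class by default.
#'
#' @param records Enrichment records with `peptide` and `label`.
#' @param n Number of negatives; defaults to the number of cleaved peptides.
#' @param seed Optional integer seed for a reproducible draw.
#' @return Character vector of peptides.
#' @export
sample_negatives <- function(records, n = NULL, seed = NULL) {
  pool <- records$peptide[records$label == "neutral"]
  if (is.null(n)) n <- sum(records$label == "cleaved")
  if (length(pool) < n) stop("neutral pool smaller than requested sample")
  draw <- function() sample(pool, n)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Probability that a random positive outscores a random negative, with
#' ties counted 1/2; computed from ranks, so it is invariant to strictly
#' monotone transformations of the scores.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary labels (1/TRUE = positive).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## logistic fit that tolerates separation: plain IRLS first, ridge
## (penalty lambda on non-intercept coefficients) when it degenerates
.logistic_fit <- function(X, y, ridge = 1e-4) {
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(stats::glm.fit(Xi, y, family = stats::binomial()))
  beta <- fit$coefficients
  separated <- !fit$converged || anyNA(beta) || any(abs(beta) > 15) ||
    any(fit$fitted.values < 1e-10) || any(fit$fitted.values > 1 - 1e-10)
  if (separated) {
    beta <- .ridge_logistic(Xi, y, lambda = ridge)
    attr(beta, "ridged") <- TRUE
  }
  beta
}

## Newton-Raphson for ridge-penalized logistic log-likelihood; the penalty
## (lambda/2)||beta_-intercept||^2 caps coefficients under perfect separation
.ridge_logistic <- function(Xi, y, lambda = 1e-4, maxit = 100L, tol = 1e-10) {
  p <- ncol(Xi)
  pen <- c(0, rep(lambda, p - 1L))
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(Xi %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    g <- drop(crossprod(Xi, y - mu)) - pen * beta
    H <- crossprod(Xi * w, Xi) + diag(pen, p)
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  names(beta) <- colnames(Xi)
  beta
}

#' Forward-stepwise logistic regression ranked by AUROC
#'
#' Starting from an intercept-only model, each step refits a logistic model
#' with every remaining candidate feature added, keeps the one maximizing
#' in-sample AUROC, and stops when the best improvement falls below `tol`
#' or `max_features` is reached. The trajectory is non-decreasing by
#' construction. Perfect separation is stabilized with a ridge penalty
#' (`ridge`), and such steps are flagged.
#'
#' @param X Feature matrix from [build_features()].
#' @param y Binary labels (1 = cleaved).
#' @param tol Minimum AUROC improvement to accept a step (default 0.001).
#' @param max_features Cap on selected features (default 20).
#' @param ridge Ridge penalty used on separation (default 1e-4).
#' @return A `stepwise_result` list: `path` data frame (step, feature, sign,
#'   auroc, ridged), `coefficients` of the final model, `auroc` final value.
#' @export
forward_stepwise <- function(X, y, tol = 0.001, max_features = 20L,
                             ridge = 1e-4) {
  stopifnot(nrow(X) == length(y))
  y <- as.numeric(y)
  selected <- character(0)
  remaining <- colnames(X)
  auc_cur <- 0.5  # intercept-only: constant score, all ties
  path <- NULL
  beta_final <- c(`(Intercept)` = stats::qlogis(max(min(mean(y), 1 - 1e-12), 1e-12)))
  while (length(selected) < max_features && length(remaining) > 0L) {
    aucs <- vapply(remaining, function(f) {
      b <- .logistic_fit(X[, c(selected, f), drop = FALSE], y, ridge)
      sc <- drop(cbind(1, X[, c(selected, f), drop = FALSE]) %*% b)
      auroc(sc, y)
    }, numeric(1L))
    best <- names(which.max(aucs))
    if (aucs[best] - auc_cur < tol) break
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    beta_final <- .logistic_fit(X[, selected, drop = FALSE], y, ridge)
    auc_cur <- aucs[best]
    path <- rbind(path, data.frame(
      step = length(selected), feature = best,
      sign = ifelse(beta_final[best] >= 0, "+", "-"),
      auroc = unname(auc_cur),
      ridged = isTRUE(attr(beta_final, "ridged")),
      stringsAsFactors = FALSE))
  }
  structure(list(path = path, coefficients = beta_final,
                 auroc = auc_cur), class = "stepwise_result")
}
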