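# Multiple imputation by chained equations (fully conditional specification)
# with five per-variable fill rules: deterministic regression prediction
# (norm_predict), a single deterministic column-order sweep (col), Bayesian
# linear regression (norm), predictive mean matching (pmm), and random-forest
# donor sampling (rf).

#' Build a predictor matrix with correlation-based pruning
#'
#' Strongly correlated predictor pairs destabilize the per-variable
#' regressions of chained equations (multicollinearity), so predictor `j` is
#' excluded for target `i` whenever the absolute pairwise-complete
#' correlation exceeds `r_threshold`. The diagonal is always excluded and the
#' exclusion is symmetric.
#'
#' @param x Matrix (with or without `NA`s) or [lab_matrix()].
#' @param r_threshold Correlation bound in `(0, 1]`; default 0.85.
#' @return Binary variable x variable matrix: entry `(i, j)` is 1 when `j`
#'   may predict `i`.
#' @export
build_predictor_matrix <- function(x, r_threshold = 0.85) {
  if (r_threshold <= 0 || r_threshold > 1)
    stop("`r_threshold` must lie in (0, 1]", call. = FALSE)
  v <- lab_values(x)
  cc <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs"))
  cc[is.na(cc)] <- 0
  pred <- (abs(cc) <= r_threshold) * 1
  diag(pred) <- 0
  dimnames(pred) <- list(colnames(v), colnames(v))
  pred
}

# Least squares with a ridge fallback (relative penalty 1e-6) for singular
# designs; the fallback is reported via message().
ls_coef <- function(X, y, context = "") {
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  tryCatch(list(beta = solve(XtX, Xty), V = solve(XtX)),
           error = function(e) {
             message("singular design", if (nzchar(context)) paste0(" (", context, ")"),
                     "; using ridge fallback")
             pen <- diag(1e-6 * mean(diag(XtX)) + 1e-12, ncol(X))
             list(beta = solve(XtX + pen, Xty), V = solve(XtX + pen))
           })
}

# Draw regression parameters from the standard normal-inverse-chi-squared
# posterior of the least-squares fit.
norm_draw <- function(X, y, context = "") {
  fit <- ls_coef(X, y, context)
  resid <- y - X %*% fit$beta
  df <- max(length(y) - ncol(X), 1)
  sigma2 <- sum(resid^2) / stats::rchisq(1, df)
  Vs <- (fit$V + t(fit$V)) / 2
  R <- tryCatch(chol(Vs), error = function(e) {
    chol(Vs + diag(1e-10 * (max(diag(Vs)) + 1), ncol(Vs)))
  })
  beta_dot <- fit$beta + t(R) %*% stats::rnorm(ncol(X)) * sqrt(sigma2)
  list(beta_hat = fit$beta, beta_dot = beta_dot, sigma = sqrt(sigma2))
}

#' Predictive mean matching fill
#'
#' Fits a linear regression on the observed cases with a Bayesian parameter
#' draw, computes predicted means (with the drawn parameters) for observed
#' and missing cases, and imputes each missing case with the observed value
#' of a donor drawn uniformly from the `d` cases with nearest predicted
#' means. Imputations therefore always lie in the observed-value support.
#'
#' @param y_obs Observed target values.
#' @param X_obs,X_mis Design matrices (including an intercept column) for the
#'   observed and the missing cases.
#' @param d Donor-pool size (default 5); lowered with a message when fewer
#'   observed cases exist.
#' @return Imputed values, one per row of `X_mis`.
#' @export
pmm_fill <- function(y_obs, X_obs, X_mis, d = 5) {
  n_obs <- length(y_obs)
  if (d > n_obs) {
    message("pmm: donor pool reduced from ", d, " to ", n_obs)
    d <- n_obs
  }
  dr <- norm_draw(X_obs, y_obs, context = "pmm")
  yhat_obs <- drop(X_obs %*% dr$beta_dot)
  yhat_mis <- drop(X_mis %*% dr$beta_dot)
  vapply(yhat_mis, function(mu) {
    donors <- order(abs(yhat_obs - mu))[seq_len(d)]
    y_obs[donors[sample.int(d, 1)]]
  }, numeric(1))
}

#' Random-forest fill by terminal-node donor sampling
#'
#' Fits a random forest of the target on the predictors over the observed
#' cases; each missing case draws one tree uniformly and then one observed
#' target value uniformly from that tree's terminal node for the case.
#'
#' @param y_obs Observed target values.
#' @param df_obs,df_mis Predictor data.frames for observed and missing cases.
#' @param num_trees Trees in the forest (default 10).
#' @return Imputed values, one per row of `df_mis`.
#' @export
rf_fill <- function(y_obs, df_obs, df_mis, num_trees = 10) {
  if (length(unique(y_obs)) == 1) return(rep(y_obs[1], nrow(df_mis)))
  res <- tryCatch({
    fit <- ranger::ranger(y = y_obs, x = df_obs, num.trees = num_trees,
                          min.node.size = 5, num.threads = 1,
                          seed = sample.int(.Machine$integer.max, 1))
    nodes_obs <- stats::predict(fit, df_obs, type = "terminalNodes",
                                num.threads = 1)$predictions
    nodes_mis <- stats::predict(fit, df_mis, type = "terminalNodes",
                                num.threads = 1)$predictions
    vapply(seq_len(nrow(df_mis)), function(i) {
      tr <- sample.int(num_trees, 1)
      pool <- y_obs[nodes_obs[, tr] == nodes_mis[i, tr]]
      if (!length(pool)) pool <- y_obs
      pool[sample.int(length(pool), 1)]
    }, numeric(1))
  }, error = function(e) NULL)
  if (is.null(res)) {
    message("rf fill degenerate; falling back to pmm")
    X_obs <- cbind(1, as.matrix(df_obs))
    X_mis <- cbind(1, as.matrix(df_mis))
    res <- pmm_fill(y_obs, X_obs, X_mis, d = min(5, length(y_obs)))
  }
  res
}

#' Chained-equations imputation engine
#'
#' Runs fully conditional specification: missing cells are initialized
#' (stochastic methods: random draws from each variable's observed values;
#' deterministic methods: column means, so all copies coincide exactly), then
#' for each of `iterations` cycles the incomplete variables are visited in
#' ascending order of missingness, each regressed on its allowed predictors'
#' current completed values, and its missing cells refilled by the method's
#' rule. `m` independent chains give `m` completed copies. The `col` method
#' is a single deterministic sweep in column order.
#'
#' @param v Matrix with `NA` for missing cells.
#' @param method One of `"norm_predict"`, `"norm"`, `"pmm"`, `"rf"`, `"col"`.
#' @param m Number of chains/copies.
#' @param iterations Cycles per chain (default 10).
#' @param predictor_matrix Optional binary predictor matrix; default built by
#'   [build_predictor_matrix()] at `r_threshold`.
#' @param r_threshold Correlation pruning bound (default 0.85).
#' @param seed Integer seed.
#' @param d Donor-pool size for `pmm`.
#' @param num_trees Trees for `rf`.
#' @return List with `imputations` (list of `m` complete matrices) and
#'   `convergence` (per-chain matrix of per-iteration mean absolute change of
#'   the imputed cells).
#' @export
chained_equations <- function(v, method = c("norm_predict", "norm", "pmm",
                                            "rf", "col"),
                              m = 5, iterations = 10, predictor_matrix = NULL,
                              r_threshold = 0.85, seed = 1, d = 5,
                              num_trees = 10) {
  method <- match.arg(method)
  mask <- is.na(v)
  if (!any(mask))
    return(list(imputations = rep(list(v), m), convergence = NULL))
  if (is.null(predictor_matrix))
    predictor_matrix <- build_predictor_matrix(v, r_threshold)
  deterministic <- method %in% c("norm_predict", "col")
  n_chains <- if (deterministic) 1L else m

  incomplete <- which(colSums(mask) > 0)
  visit <- if (method == "col") {
    incomplete
  } else {
    incomplete[order(colSums(mask)[incomplete])]
  }
  n_iter <- if (method == "col") 1L else iterations

  chains <- vector("list", n_chains)
  conv <- vector("list", n_chains)
  for (chain in seq_len(n_chains)) {
    set.seed(derive_seed(seed, "ce", method, chain))
    filled <- v
    for (j in incomplete) {
      obs <- v[!mask[, j], j]
      filled[mask[, j], j] <- if (deterministic) mean(obs)
        else obs[sample.int(length(obs), sum(mask[, j]), replace = TRUE)]
    }
    changes <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      before <- filled[mask]
      for (j in visit) {
        preds <- which(predictor_matrix[colnames(v)[j], ] == 1)
        obs_i <- !mask[, j]
        y <- v[obs_i, j]
        Xall <- cbind(`(Intercept)` = 1, filled[, preds, drop = FALSE])
        X_obs <- Xall[obs_i, , drop = FALSE]
        X_mis <- Xall[!obs_i, , drop = FALSE]
        ctx <- colnames(v)[j]
        filled[!obs_i, j] <- switch(
          method,
          norm_predict = ,
          col = drop(X_mis %*% ls_coef(X_obs, y, ctx)$beta),
          norm = {
            dr <- norm_draw(X_obs, y, ctx)
            drop(X_mis %*% dr$beta_dot) + stats::rnorm(nrow(X_mis)) * dr$sigma
          },
          pmm = pmm_fill(y, X_obs, X_mis, d = d),
          rf = rf_fill(y, as.data.frame(Xall[obs_i, -1, drop = FALSE]),
                       as.data.frame(Xall[!obs_i, -1, drop = FALSE]),
                       num_trees = num_trees)
        )
      }
      changes[it] <- mean(abs(filled[mask] - before))
    }
    chains[[chain]] <- filled
    conv[[chain]] <- changes
  }
  if (deterministic) {
    chains <- rep(chains, m)
    conv <- rep(conv, m)
  }
  list(imputations = chains, convergence = do.call(rbind, conv))
}
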