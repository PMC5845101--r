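# Imputation dispatcher and the non-chained methods: simple fills, k-nearest
# neighbours, and iterative low-rank (truncated / soft-thresholded SVD)
# matrix completion. The chained-equations engine lives in mice.R.

#' Imputation method name sets
#'
#' Methods whose completed copies are always identical (zero
#' between-imputation variance) versus methods whose copies are independent
#' draws, suitable for multiple imputation.
#'
#' @format Character vectors of method names accepted by [impute()].
#' @export
DETERMINISTIC_METHODS <- c("mean", "median", "knn", "svd_iterative",
                           "soft_impute", "ce_norm_predict", "ce_col")

#' @rdname DETERMINISTIC_METHODS
#' @export
STOCHASTIC_METHODS <- c("random_sample", "ce_norm", "ce_pmm", "ce_rf")

#' @rdname DETERMINISTIC_METHODS
#' @export
IMPUTE_METHODS <- c(DETERMINISTIC_METHODS, STOCHASTIC_METHODS)

new_completed_set <- function(imputations, mask, method, m, params,
                              convergence = NULL, warning_flag = FALSE) {
  structure(list(imputations = imputations, mask = mask, method = method,
                 m = m, params = params, convergence = convergence,
                 warning_flag = warning_flag),
            class = "completed_set")
}

#' @export
print.completed_set <- function(x, ...) {
  cat("<completed_set> method ", x$method, ": ", x$m, " completed ",
      nrow(x$imputations[[1]]), " x ", ncol(x$imputations[[1]]),
      " matrices (", sum(x$mask), " imputed cells each)\n", sep = "")
  invisible(x)
}

#' Impute a masked matrix
#'
#' Fills every missing cell of a masked matrix by one of eleven methods and
#' returns `m` completed copies. Deterministic methods (`mean`, `median`,
#' `knn`, `svd_iterative`, `soft_impute`, `ce_norm_predict`, `ce_col`)
#' produce `m` identical copies; stochastic methods (`random_sample`,
#' `ce_norm`, `ce_pmm`, `ce_rf`) produce independent copies suitable for
#' multiple imputation. Observed cells always pass through unmodified.
#'
#' @param masked A `masked_dataset` or a matrix with `NA` for missing cells.
#' @param method One of `"mean"`, `"median"`, `"random_sample"`, `"knn"`,
#'   `"svd_iterative"`, `"soft_impute"`, `"ce_norm_predict"`, `"ce_norm"`,
#'   `"ce_pmm"`, `"ce_rf"`, `"ce_col"`.
#' @param m Number of completed copies (default 5).
#' @param seed Integer seed governing all stochastic methods.
#' @param k Neighbour count for `knn` (default 5).
#' @param d Donor-pool size for `ce_pmm` (default 5).
#' @param lambda Soft-threshold level for `soft_impute`; default: 1/50 of the
#'   largest singular value of the mean-filled centered matrix.
#' @param rank Target rank for `svd_iterative`; default
#'   `min(10, min(dim) - 1)`.
#' @param iterations Chained-equation cycles (default 10).
#' @param r_threshold Predictor-pruning correlation bound for the
#'   chained-equation methods (default 0.85); see [build_predictor_matrix()].
#' @param predictor_matrix Optional explicit predictor matrix overriding
#'   `r_threshold`.
#' @param tol,max_iter Convergence tolerance and iteration cap for the
#'   low-rank methods (defaults 1e-4, 100).
#' @param num_trees Trees per forest in `ce_rf` (default 10).
#' @return A `completed_set`: list with `imputations` (list of `m` complete
#'   matrices), `mask` (logical, `TRUE` at imputed cells), `method`, `m`,
#'   `params`, `convergence` (per-iteration change norms where applicable)
#'   and `warning_flag` (low-rank non-convergence).
#' @export
impute <- function(masked, method = IMPUTE_METHODS, m = 5, seed = 1,
                   k = 5, d = 5, lambda = NULL, rank = NULL,
                   iterations = 10, r_threshold = 0.85,
                   predictor_matrix = NULL, tol = 1e-4, max_iter = 100,
                   num_trees = 10) {
  method <- match.arg(method)
  v <- lab_values(masked)
  mask <- is.na(v)
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  fully_missing <- colnames(v)[colSums(!mask) == 0]
  if (length(fully_missing))
    stop("variable(s) with no observed cell: ",
         paste(fully_missing, collapse = ", "), call. = FALSE)
  params <- list(seed = seed, k = k, d = d, lambda = lambda, rank = rank,
                 iterations = iterations, r_threshold = r_threshold)

  if (!any(mask)) {
    return(new_completed_set(rep(list(v), m), mask, method, m, params))
  }

  if (method %in% c("mean", "median")) {
    stat <- if (method == "mean") {
      apply(v, 2, mean, na.rm = TRUE)
    } else {
      apply(v, 2, stats::median, na.rm = TRUE)
    }
    filled <- v
    for (j in which(colSums(mask) > 0)) filled[mask[, j], j] <- stat[j]
    return(new_completed_set(rep(list(filled), m), mask, method, m, params))
  }

  if (method == "random_sample") {
    imps <- vector("list", m)
    for (i in seq_len(m)) {
      set.seed(derive_seed(seed, "random_sample", i))
      filled <- v
      for (j in which(colSums(mask) > 0)) {
        obs <- v[!mask[, j], j]
        filled[mask[, j], j] <- obs[sample.int(length(obs), sum(mask[, j]),
                                               replace = TRUE)]
      }
      imps[[i]] <- filled
    }
    return(new_completed_set(imps, mask, method, m, params))
  }

  if (method == "knn") {
    filled <- knn_impute(v, k = k)
    return(new_completed_set(rep(list(filled), m), mask, method, m, params))
  }

  if (method %in% c("svd_iterative", "soft_impute")) {
    res <- lowrank_impute(v, variant = method, lambda = lambda, rank = rank,
                          tol = tol, max_iter = max_iter)
    return(new_completed_set(rep(list(res$filled), m), mask, method, m,
                             params, convergence = res$change,
                             warning_flag = res$warning_flag))
  }

  # Chained equations.
  fill_method <- sub("^ce_", "", method)
  res <- chained_equations(v, method = fill_method, m = m,
                           iterations = iterations,
                           predictor_matrix = predictor_matrix,
                           r_threshold = r_threshold, seed = seed, d = d,
                           num_trees = num_trees)
  new_completed_set(res$imputations, mask, method, m, params,
                    convergence = res$convergence)
}

# k-nearest-neighbour fill. Row-to-row distance is the root-mean-square
# difference over jointly observed variables (euclidean scaled by the square
# root of the shared-variable count); a missing cell is the mean of the k
# nearest rows that carry the variable, extending the pool past neighbours
# that lack it. Rows sharing no variable are at infinite distance.
knn_impute <- function(v, k = 5) {
  n <- nrow(v)
  W <- !is.na(v)
  X0 <- v
  X0[!W] <- 0
  Wn <- W * 1
  sq <- X0^2
  shared <- Wn %*% t(Wn)
  d2 <- sq %*% t(Wn) + Wn %*% t(sq) - 2 * X0 %*% t(X0)
  d2[d2 < 0] <- 0
  dist <- sqrt(d2 / pmax(shared, 1))
  dist[shared == 0] <- Inf
  diag(dist) <- Inf

  filled <- v
  for (i in which(rowSums(!W) > 0)) {
    ord <- order(dist[i, ])
    ord <- ord[is.finite(dist[i, ord])]
    for (j in which(!W[i, ])) {
      donors <- ord[W[ord, j]]
      if (!length(donors)) {
        message("knn: no neighbour carries '", colnames(v)[j],
                "' for row ", rownames(v)[i] %||% i,
                "; falling back to the variable mean")
        filled[i, j] <- mean(v[, j], na.rm = TRUE)
      } else {
        filled[i, j] <- mean(v[utils::head(donors, k), j])
      }
    }
  }
  filled
}

# Iterative low-rank completion. Variables are centered on their observed
# cells; missing cells start at zero (the column mean) and are refilled from
# a truncated (fixed-rank) or soft-thresholded SVD until the relative change
# in the filled cells drops below tol. Started cold from the mean fill, the
# plain fixed-point iteration is prone to stalling in spurious local fixed
# points, so both variants warm start with a soft-threshold annealing phase
# (the threshold decreases geometrically from half the top singular value)
# before iterating at the target threshold or rank. After the soft iteration
# converges, a debias polish re-runs the hard-truncation iteration at the
# effective rank the threshold selected, removing the shrinkage bias of the
# nuclear-norm penalty.
lowrank_impute <- function(v, variant, lambda = NULL, rank = NULL,
                           tol = 1e-4, max_iter = 100) {
  mask <- is.na(v)
  mu <- colMeans(v, na.rm = TRUE)
  x <- sweep(v, 2, mu)
  x[mask] <- 0
  p <- min(dim(v))

  sv1 <- svd(x, nu = 0, nv = 0)$d[1]
  if (variant == "svd_iterative" && is.null(rank))
    rank <- max(1L, min(10L, p - 1L))
  if (variant == "soft_impute" && is.null(lambda)) lambda <- sv1 / 50

  n_anneal <- min(30L, max_iter %/% 2L)
  lambda_floor <- if (variant == "soft_impute") max(lambda, 1e-12) else sv1 / 1000
  lambda_path <- if (lambda_floor < sv1 / 2)
    exp(seq(log(sv1 / 2), log(lambda_floor), length.out = n_anneal))
  else rep(lambda_floor, n_anneal)

  step <- function(x, lam, r) {
    s <- svd(x)
    dvals <- if (is.null(r)) pmax(s$d - lam, 0)
             else c(s$d[seq_len(r)], rep(0, length(s$d) - r))
    recon <- s$u %*% (dvals * t(s$v))
    x[mask] <- recon[mask]
    # effective rank: components carrying non-negligible thresholded energy
    list(x = x, rank_used = sum(dvals > 0.01 * max(dvals, 0)))
  }

  change <- numeric(0)
  warning_flag <- FALSE
  rank_conv <- 0L
  for (it in seq_len(max_iter)) {
    warming <- it <= n_anneal
    old <- x[mask]
    st <- if (warming) step(x, lambda_path[it], NULL)
          else if (variant == "soft_impute") step(x, lambda, NULL)
          else step(x, NULL, rank)
    x <- st$x
    rank_conv <- st$rank_used
    delta <- sqrt(sum((x[mask] - old)^2)) / max(sqrt(sum(old^2)), 1e-12)
    change <- c(change, delta)
    if (!warming && delta < tol) break
    if (it == max_iter) {
      warning_flag <- TRUE
      warning("low-rank imputation did not converge in ", max_iter,
              " iterations (relative change ", signif(delta, 3), ")",
              call. = FALSE)
    }
  }

  if (variant == "soft_impute" && rank_conv > 0) {
    # the low-rank basin is already identified, so the hard iteration is
    # cheap and stable; run it tighter than the soft phase
    tol_polish <- min(tol, 1e-8)
    for (it in seq_len(max(max_iter, 300L))) {
      old <- x[mask]
      x <- step(x, lam = NULL, r = rank_conv)$x
      delta <- sqrt(sum((x[mask] - old)^2)) / max(sqrt(sum(old^2)), 1e-12)
      if (delta < tol_polish) break
    }
  }

  filled <- sweep(x, 2, mu, "+")
  filled[!mask] <- v[!mask]
  list(filled = filled, change = change, warning_flag = warning_flag)
}
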