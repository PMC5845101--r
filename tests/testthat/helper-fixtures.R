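# Fixtures built in code: correlated Gaussian matrices and small toy tables.

# Equicorrelated multivariate-normal matrix (single-factor construction),
# standard normal marginals.
gaussian_truth <- function(n, V, rho = 0, seed = 1, prefix = "V") {
  set.seed(seed)
  f <- rnorm(n)
  e <- matrix(rnorm(n * V), n, V)
  m <- sqrt(rho) * f + sqrt(1 - rho) * e
  dimnames(m) <- list(sprintf("P%05d", seq_len(n)), paste0(prefix, seq_len(V)))
  m
}

# Two-panel correlated matrix with a panel map, for tests needing panel
# structure (presence prediction excludes the target's panel).
panelled_truth <- function(n, seed = 1, rho_within = 0.6, rho_cross = 0.25,
                           v_per_panel = c(a = 4, b = 4)) {
  set.seed(seed)
  panels <- rep(names(v_per_panel), v_per_panel)
  V <- length(panels)
  sigma <- matrix(rho_cross, V, V)
  for (p in unique(panels)) {
    idx <- panels == p
    sigma[idx, idx] <- rho_within
  }
  diag(sigma) <- 1
  m <- matrix(rnorm(n * V), n, V) %*% chol(sigma)
  vars <- paste0(panels, sequence(v_per_panel))
  dimnames(m) <- list(sprintf("P%05d", seq_len(n)), vars)
  lab_matrix(m, panel_map = data.frame(loinc = vars, panel = panels,
                                       stringsAsFactors = FALSE))
}

# Minimal demographics table for matching tests.
demo_table <- function(ids, sex, age, bmi) {
  data.frame(patient_id = ids, sex = sex, age = age, bmi = bmi,
             stringsAsFactors = FALSE)
}

# Brute-force AUROC oracle: concordant-pair fraction over label-discordant
# pairs, ties counting one half.
auroc_pairs <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}
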