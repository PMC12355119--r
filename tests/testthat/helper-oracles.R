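# Independent oracles and small fixtures shared across test files.

# Bivariate normal rectangle probability via the one-dimensional integral
# identity Phi2(h, k, rho) = Phi(h) Phi(k) + int_0^rho phi2(h, k, r) dr;
# independent of the package's Gauss-Legendre implementation.
phi2_oracle <- function(h, k, rho) {
  if (!is.finite(h) || !is.finite(k)) {
    if (h == -Inf || k == -Inf) return(0)
    if (h == Inf) return(pnorm(k))
    return(pnorm(h))
  }
  f <- function(r) {
    exp(-(h^2 - 2 * r * h * k + k^2) / (2 * (1 - r^2))) /
      (2 * pi * sqrt(1 - r^2))
  }
  base <- pnorm(h) * pnorm(k)
  if (rho == 0) return(base)
  base + stats::integrate(Vectorize(f), 0, rho, rel.tol = 1e-11)$value
}

# Log-likelihood of a 2x2 ordinal table under the bivariate-normal model,
# thresholds fixed at the two-step marginal estimates, cells from the
# oracle CDF. Brute-force grid search over rho, staged coarse-then-fine
# (the profile likelihood is unimodal): final resolution 5e-4.
tetrachoric_grid_oracle <- function(x, y) {
  tab <- table(x, y)
  stopifnot(dim(tab) == c(2, 2))
  tx <- qnorm(sum(tab[1, ]) / sum(tab))
  ty <- qnorm(sum(tab[, 1]) / sum(tab))
  loglik <- function(r) {
    p00 <- phi2_oracle(tx, ty, r)
    p0y <- pnorm(tx) - p00
    px0 <- pnorm(ty) - p00
    p11 <- 1 - pnorm(tx) - pnorm(ty) + p00
    ps <- pmax(c(p00, p0y, px0, p11), 1e-12)
    sum(c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]) * log(ps))
  }
  coarse <- seq(-0.99, 0.99, by = 0.01)
  r0 <- coarse[which.max(vapply(coarse, loglik, numeric(1)))]
  fine <- seq(max(-0.995, r0 - 0.02), min(0.995, r0 + 0.02), by = 5e-4)
  fine[which.max(vapply(fine, loglik, numeric(1)))]
}

# All 25 DAGs on 3 nodes, as logical adjacency matrices ([i, j] = i -> j).
all_dags_3 <- function() {
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  out <- list()
  for (s1 in 0:2) for (s2 in 0:2) for (s3 in 0:2) {
    a <- matrix(FALSE, 3, 3)
    st <- c(s1, s2, s3)
    for (k in 1:3) {
      if (st[k] == 1) a[pairs[k, 1], pairs[k, 2]] <- TRUE
      if (st[k] == 2) a[pairs[k, 2], pairs[k, 1]] <- TRUE
    }
    m <- a + 0
    reach <- m
    for (i in 1:3) reach <- ((reach %*% m) > 0) | (reach > 0)
    if (!any(diag(reach) > 0)) out[[length(out) + 1]] <- a
  }
  out
}

# Independent Gaussian-BIC score of a DAG: per-node lm() fits.
dag_score_oracle <- function(data, amat) {
  n <- nrow(data)
  sum(vapply(seq_len(ncol(amat)), function(j) {
    pa <- which(amat[, j])
    fit <- if (length(pa) == 0) {
      stats::lm(data[, j] ~ 1)
    } else {
      stats::lm(data[, j] ~ data[, pa, drop = FALSE])
    }
    sigma2 <- mean(stats::residuals(fit)^2)
    ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
    ll - (length(pa) + 2) / 2 * log(n)
  }, numeric(1)))
}

# Exact 2-node Ising distribution (0/1 coding) by state enumeration.
ising2_exact <- function(tau, beta) {
  states <- expand.grid(x1 = 0:1, x2 = 0:1)
  logw <- tau[1] * states$x1 + tau[2] * states$x2 +
    beta * states$x1 * states$x2
  w <- exp(logw) / sum(exp(logw))
  list(p = w, states = states,
       mean = c(sum(w * states$x1), sum(w * states$x2)),
       agree = sum(w[states$x1 == states$x2]))
}

# Small deterministic ordinal matrix for scoring tests.
toy_items <- function(n = 8, items, seed = 1, max_val = 4) {
  set.seed(seed)
  m <- matrix(sample(0:max_val, n * length(items), replace = TRUE), n,
              dimnames = list(NULL, items))
  m
}

# Linear chain A -> B -> C with strong coefficients.
chain_data <- function(n, seed) {
  set.seed(seed)
  a <- rnorm(n)
  b <- 0.8 * a + rnorm(n, sd = 0.6)
  c <- 0.8 * b + rnorm(n, sd = 0.6)
  cbind(A = a, B = b, C = c)
}

# A small strong-structure generator used by several module tests.
small_strong_spec <- function(seed = 3, n = 1000) {
  generator_spec(n_nodes = c(3, 3), seed = seed, n_respondents = n,
                 edges = data.frame(i = c(1, 4, 2), j = c(2, 5, 4),
                                    weight = c(0.4, 0.3, 0.25)))
}
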