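# Shared fixtures, memoized so expensive simulations run once per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the reference scenario: 500 cells, 20 planted links at w = 1.5, seed 13
default_sim <- function() memo("default_sim", simulate_dataset(sim_config(seed = 13L)))

default_qc <- function() memo("default_qc", apply_qc(default_sim()$dataset))

# small clean simulation for cheap structural tests
small_sim <- function() memo("small_sim", {
  simulate_dataset(sim_config(n_cells = 120L, n_genes = 300L, n_links = 5L,
                              decoys_in_window = 5L, doublet_rate = 0,
                              lowq_rate = 0, seed = 5L))
})

# a tiny deterministic count matrix with ids
toy_counts <- function() {
  m <- matrix(c(3L, 0L, 1L,
                0L, 2L, 0L,
                5L, 1L, 4L), nrow = 3, byrow = TRUE,
              dimnames = list(c("c1", "c2", "c3"), c("gA", "gB", "MT-1")))
  count_matrix(m, "rna")
}

# exhaustive two-sided rank-sum p by enumerating group assignments
perm_rank_sum_p <- function(v, g1) {
  r <- rank(v)
  n <- length(v); n1 <- sum(g1)
  W <- sum(r[g1])
  combs <- utils::combn(n, n1)
  dist <- colSums(matrix(r[combs], nrow = n1))
  mu <- mean(dist)
  mean(abs(dist - mu) >= abs(W - mu) - 1e-9)
}

# binomial log-likelihood of a logistic model, maximized by direct
# numerical optimization (independent of glm's IRLS)
optim_logistic_ll <- function(X, y) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  -fit$value
}
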