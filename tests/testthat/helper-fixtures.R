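# Shared helpers for the test suite. All fixtures are generated in code.

sample_skewness <- function(x) {
  mean((x - mean(x))^3) / stats::sd(x)^3
}

# Scattered sample points with a smooth deterministic surface plus noise.
toy_points <- function(n = 30, seed = 1, noise_sd = 0.05,
                       extent = 1000) {
  set.seed(seed)
  pts <- data.frame(id = seq_len(n),
                    x = stats::runif(n, 0, extent),
                    y = stats::runif(n, 0, extent))
  pts$z <- sin(pts$x / 300) + cos(pts$y / 400) +
    stats::rnorm(n, 0, noise_sd)
  pts
}

# A perfectly consistent pairwise matrix a_ij = w_i / w_j.
consistent_matrix <- function(w) {
  pairwise_matrix(outer(w, w, "/"),
                  labels = paste0("C", seq_along(w)))
}

# Independent brute-force LOOCV for IDW: explicit fold enumeration with a
# plain weighted mean, no shared code with the package implementation.
bruteforce_idw_loocv <- function(pts, power) {
  res <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    rest <- pts[-i, ]
    d <- sqrt((rest$x - pts$x[i])^2 + (rest$y - pts$y[i])^2)
    if (any(d < 1e-9)) {
      pred <- rest$z[which(d < 1e-9)[1]]
    } else {
      w <- 1 / d^power
      pred <- sum(w * rest$z) / sum(w)
    }
    res[i] <- pred - pts$z[i]
  }
  sqrt(mean(res^2))
}
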