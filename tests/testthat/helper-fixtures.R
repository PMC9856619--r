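# Shared fixtures, all generated in code.

# The published outcome-by-cluster counts (ascending risk order A, C, B)
# and the merged two-group counts (O, B), used across statistics tests.
table_three <- function() {
  matrix(c(4, 16, 50, 41, 77, 106), nrow = 2, byrow = TRUE,
         dimnames = list(c("presence", "absence"),
                         c("cluster_A", "cluster_C", "cluster_B")))
}
table_two <- function() {
  matrix(c(20, 50, 118, 106), nrow = 2, byrow = TRUE,
         dimnames = list(c("presence", "absence"), c("cluster_O", "cluster_B")))
}

# Two tight, well-separated Gaussian blobs in the plane.
two_blobs <- function(n_per = 100, dist = 10, sd = 1, seed = 1) {
  set.seed(seed)
  coords <- rbind(
    cbind(rnorm(n_per, 0, sd), rnorm(n_per, 0, sd)),
    cbind(rnorm(n_per, dist, sd), rnorm(n_per, dist, sd))
  )
  tibble::tibble(x = coords[, 1], y = coords[, 2],
                 label = rep(1:2, each = n_per))
}

three_blobs <- function(n_per = 60, dist = 12, sd = 0.8, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(dist, 0), c(dist / 2, dist))
  coords <- do.call(rbind, lapply(1:3, function(k) {
    cbind(rnorm(n_per, centers[k, 1], sd), rnorm(n_per, centers[k, 2], sd))
  }))
  tibble::tibble(x = coords[, 1], y = coords[, 2],
                 label = rep(1:3, each = n_per))
}

# A small planted two-cluster fuzzy graph: strong edges inside each half,
# none across.
planted_two_cluster_graph <- function(n_per = 15) {
  n <- 2 * n_per
  w <- matrix(0, n, n)
  w[1:n_per, 1:n_per] <- 0.9
  w[(n_per + 1):n, (n_per + 1):n] <- 0.9
  diag(w) <- 0
  bcrlmap:::new_fuzzy_graph(w)
}

# Brute-force O(n^2) silhouette oracle, independent of the implementation.
silhouette_oracle <- function(coords, labels) {
  y <- as.matrix(coords[, c("x", "y")])
  n <- nrow(y)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(sqrt(rowSums((y[own, , drop = FALSE] -
                              matrix(y[i, ], length(own), 2, byrow = TRUE))^2)))
    b <- Inf
    for (g in setdiff(unique(labels), labels[i])) {
      oth <- which(labels == g)
      b <- min(b, mean(sqrt(rowSums((y[oth, , drop = FALSE] -
                                       matrix(y[i, ], length(oth), 2, byrow = TRUE))^2))))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Independent recursive Freeman-Halton oracle for 2 x c tables: loops the
# first row directly (no shared code with the implementation).
ffh_oracle_2xc <- function(m) {
  rs <- rowSums(m); cs <- colSums(m)
  logp <- function(tab) {
    sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
      lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
  }
  lp_obs <- logp(m)
  cc <- ncol(m)
  total <- 0
  grid <- expand.grid(lapply(cs[-cc], function(cj) 0:min(rs[1], cj)))
  for (r in seq_len(nrow(grid))) {
    top <- as.numeric(grid[r, ])
    last <- rs[1] - sum(top)
    if (last < 0 || last > cs[cc]) next
    tab <- rbind(c(top, last), cs - c(top, last))
    if (any(tab < 0)) next
    lp <- logp(tab)
    if (lp <= lp_obs + 1e-7) total <- total + exp(lp)
  }
  min(total, 1)
}

# A tiny valid cohort data frame covering all 23 schema variables.
toy_cohort_df <- function(n = 3) {
  sch <- default_bcrl_schema()
  df <- tibble::tibble(patient_id = sprintf("T%02d", seq_len(n)))
  set.seed(99)
  for (i in seq_len(nrow(sch))) {
    nm <- sch$name[i]
    df[[nm]] <- if (sch$vtype[i] == "continuous") {
      round(runif(n, 30, 70), 1)
    } else {
      sample(sch$codes[[i]], n, replace = TRUE)
    }
  }
  df$BCRL <- rep_len(c(0L, 1L), n)
  df
}
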