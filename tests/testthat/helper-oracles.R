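# Independent brute-force oracles used to cross-check the vectorised
# implementations.  These deliberately use naive enumeration (explicit
# walks over voxels, lines and patient pairs) and survival::survdiff, so
# they share no code path with the package internals they verify.

# Co-occurrence oracle: loop over every masked voxel and compare its
# position against all other masked voxels to find pairs at `offset`.
oracle_glcm <- function(grid, mask, G, offset, symmetric = TRUE) {
  pos <- which(mask, arr.ind = TRUE)
  counts <- matrix(0, G, G)
  for (a in seq_len(nrow(pos))) {
    d <- sweep(pos, 2, pos[a, ] + offset, "-")
    hit <- which(rowSums(abs(d)) == 0)
    for (b in hit) {
      i <- grid[matrix(pos[a, ], 1)]; j <- grid[matrix(pos[b, ], 1)]
      counts[i, j] <- counts[i, j] + 1
      if (symmetric) counts[j, i] <- counts[j, i] + 1
    }
  }
  if (sum(counts) == 0) return(NULL)
  counts / sum(counts)
}

oracle_cluster_shade <- function(P) {
  G <- nrow(P)
  mux <- sum(seq_len(G) * rowSums(P))
  muy <- sum(seq_len(G) * colSums(P))
  s <- 0
  for (i in seq_len(G)) for (j in seq_len(G))
    s <- s + (i + j - mux - muy)^3 * P[i, j]
  s
}

# Run-length oracle: walk every line in direction `d` voxel by voxel.
oracle_runs <- function(grid, mask, d) {
  dims <- dim(mask)
  level <- integer(0); len <- integer(0)
  inside <- function(p) all(p >= 1) && all(p <= dims)
  at <- function(p) mask[matrix(p, 1)]
  pos <- which(mask, arr.ind = TRUE)
  for (a in seq_len(nrow(pos))) {
    p <- pos[a, ]
    prev <- p - d
    if (inside(prev) && at(prev)) next     # not a line start
    # walk the line from p
    cur <- p
    run_lv <- grid[matrix(cur, 1)]; run_ln <- 1L
    repeat {
      nxt <- cur + d
      if (!inside(nxt) || !at(nxt)) {
        level <- c(level, run_lv); len <- c(len, run_ln)
        break
      }
      lv <- grid[matrix(nxt, 1)]
      if (lv == run_lv) run_ln <- run_ln + 1L
      else {
        level <- c(level, run_lv); len <- c(len, run_ln)
        run_lv <- lv; run_ln <- 1L
      }
      cur <- nxt
    }
  }
  list(level = level, length = len)
}

oracle_lgre <- function(runs) {
  mean(1 / as.numeric(runs$level)^2)
}

# Harrell C-index oracle: explicit double loop over ordered pairs.
oracle_c_index <- function(scores, time, event) {
  conc <- 0; comp <- 0
  n <- length(scores)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    comparable <- (time[i] < time[j] && event[i] == 1) ||
      (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (!comparable) next
    comp <- comp + 1
    if (scores[i] > scores[j]) conc <- conc + 1
    else if (scores[i] == scores[j]) conc <- conc + 0.5
  }
  conc / comp
}

# Brute-force maximally selected log-rank scan via survival::survdiff.
oracle_cutpoint <- function(scores, time, event, min_group_frac = 0.1) {
  n <- length(scores)
  s <- sort(unique(scores))
  cand <- (s[-1] + s[-length(s)]) / 2
  best <- NULL
  for (cc in cand) {
    lo <- sum(scores <= cc)
    if (lo < min_group_frac * n || (n - lo) < min_group_frac * n) next
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ I(scores > cc))
    if (is.null(best) || sd_$chisq > best$stat + 1e-12 ||
        (abs(sd_$chisq - best$stat) <= 1e-12 &&
         abs(lo - n / 2) < abs(best$lo - n / 2))) {
      best <- list(cut = cc, stat = sd_$chisq, lo = lo)
    }
  }
  best
}

# small random survival data set
random_surv <- function(n, seed, cens = 0.3) {
  set.seed(seed)
  list(time = round(rexp(n, 0.2), 2) + 0.01,
       event = as.integer(runif(n) > cens),
       scores = rnorm(n))
}

# random quantised grid fixture
random_quantized <- function(seed, max_dim = 8, G = 4) {
  set.seed(seed)
  dims <- sample(2:max_dim, 3, replace = TRUE)
  vol <- array(runif(prod(dims)), dim = dims)
  mask <- array(runif(prod(dims)) < 0.8, dim = dims)
  if (!any(mask)) mask[1, 1, 1] <- TRUE
  quantize(vol, mask, G)
}
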