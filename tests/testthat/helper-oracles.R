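# Independent brute-force oracles used to validate the fast implementations.
# Each one derives the quantity by a different route than the package code.

# exact Hardy-Weinberg p by enumerating absolute configuration probabilities
oracle_hwe <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na <- 2 * n2 + n1
  nr <- min(na, 2 * n - na)
  hets <- seq(nr %% 2, nr, by = 2)
  pr <- vapply(hets, function(h) {
    homr <- (nr - h) / 2
    homc <- n - h - homr
    exp(lfactorial(n) - lfactorial(homr) - lfactorial(h) - lfactorial(homc) +
          h * log(2) + lfactorial(nr) + lfactorial(2 * n - nr) -
          lfactorial(2 * n))
  }, 0)
  obs <- pr[hets == n1]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# Tajima's D with every constant recomputed from its definition
oracle_tajima <- function(n, S, pi) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# two-population variance components through R's one-way ANOVA machinery
oracle_wc_fst <- function(n1, ac1, n2, ac2) {
  y <- c(rep(1, ac1), rep(0, n1 - ac1), rep(1, ac2), rep(0, n2 - ac2))
  pop <- factor(rep(c("a", "b"), c(n1, n2)))
  ms <- stats::anova(stats::aov(y ~ pop))$`Mean Sq`
  N <- n1 + n2
  nc <- N - (n1^2 + n2^2) / N
  a <- (ms[1] - ms[2]) / nc
  a / (a + ms[2])
}

# EHH by pasting haplotype strings and counting identical pairs
oracle_ehh <- function(haps, pos, core, mode, max_gap = Inf) {
  n <- nrow(haps)
  members <- if (mode == 2) seq_len(n) else which(haps[, core] == mode)
  d0 <- sum(choose(table(haps[members, core]), 2))
  prof_dir <- function(idxs) {
    res <- data.frame(pos = pos[core], ehh = 1)
    prev <- pos[core]
    span <- core
    for (j in idxs) {
      if (abs(pos[j] - prev) > max_gap) break
      span <- c(span, j)
      key <- apply(haps[members, span, drop = FALSE], 1, paste, collapse = "")
      res <- rbind(res, data.frame(pos = pos[j],
                                   ehh = sum(choose(table(key), 2)) / d0))
      prev <- pos[j]
    }
    res
  }
  list(left = prof_dir(rev(seq_len(core - 1))),
       right = prof_dir(if (core < ncol(haps)) (core + 1):ncol(haps)
                        else integer(0)),
       d0 = d0, n_core = length(members))
}

# iHH by dense-grid numeric integration with a root-found cutoff crossing
oracle_ihh <- function(profile, cutoff = 0.05) {
  side <- function(df) {
    d <- abs(df$pos - df$pos[1])
    e <- df$ehh
    if (length(d) < 2) return(0)
    f <- stats::approxfun(d, e)
    below <- which(e < cutoff)
    end <- if (length(below)) {
      j <- below[1]
      stats::uniroot(function(x) f(x) - cutoff, c(d[j - 1], d[j]),
                     tol = 1e-13)$root
    } else max(d)
    xs <- sort(unique(c(d[d <= end], end, seq(0, end, length.out = 4001))))
    sum(diff(xs) * (utils::head(f(xs), -1) + utils::tail(f(xs), -1)) / 2)
  }
  side(profile$left) + side(profile$right)
}

# weighted block-jackknife SE by explicit delete-one recomputation
oracle_jackknife_se <- function(contrib, block) {
  blocks <- unique(block)
  g <- length(blocks)
  n <- length(contrib)
  est <- mean(contrib)
  theta <- vapply(blocks, function(b) mean(contrib[block != b]), 0)
  m <- vapply(blocks, function(b) sum(block == b), 0)
  h <- n / m
  theta_dot <- g * est - sum((1 - m / n) * theta)
  tau <- h * est - (h - 1) * theta
  sqrt(mean((tau - theta_dot)^2 / (h - 1)))
}

# random small haplotype instance for property tests
rand_hap_instance <- function(seed) {
  set.seed(seed)
  n <- sample(4:32, 1)
  S <- sample(8:64, 1)
  list(haps = matrix(rbinom(n * S, 1, stats::runif(1, 0.2, 0.8)), n, S),
       pos = sort(sample.int(1e5, S)))
}
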