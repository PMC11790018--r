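# Shared fixtures: a small, fast cohort configuration and independent
# statistical oracles used to cross-check package computations.

tiny_config <- function(seed = 1, ...) {
  args <- list(n_pediatric = 14, n_adult = 6,
               n_background_cpgs = 30, n_genes_expression = 25,
               library_spec = list(n_targets = 20, guides_per_gene = 4,
                                   n_essential = 6, n_nontargeting = 40,
                                   n_nt_genes = 2),
               n_effect_genes = 5, n_mutation_genes = 8, n_cnv_genes = 8,
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(truth_config, args)
}

# brute-force Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- prev
  }
  adj
}

# closed-form equal-variance two-sample t-test
t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), nx + ny - 2))
}

# closed-form Pearson correlation (no cor())
pearson_oracle <- function(x, y) {
  xm <- x - sum(x) / length(x)
  ym <- y - sum(y) / length(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# brute-force grid search over the full 4PL parameter space, minimizing
# the same least-squares objective as the fitter; the RSS is affine in
# (top, bottom) given the logistic base, which keeps a dense grid cheap
grid_search_4pl <- function(doses_uM, viability) {
  nz <- doses_uM > 0
  d <- doses_uM[nz] * 1000
  v <- viability[nz]
  lg <- seq(log10(min(d)), log10(max(d)) + 1, length.out = 400)
  hills <- seq(0.4, 3, by = 0.2)
  tops <- seq(0.9, 1.1, by = 0.02)
  bottoms <- seq(0, 0.2, by = 0.02)
  s_vv <- sum(v^2)
  s_v <- sum(v)
  n <- length(v)
  best <- list(ic50 = NA_real_, rss = Inf, lg = NA_real_)
  for (h in hills) {
    # base[i, j] = 1 / (1 + (d_i / ic50_j)^h)
    base <- 1 / (1 + outer(d, 10^lg, "/")^h)
    s_b <- colSums(base)
    s_bb <- colSums(base^2)
    s_vb <- colSums(v * base)
    for (t in tops) for (bo in bottoms) {
      a <- t - bo
      rss <- s_vv - 2 * bo * s_v - 2 * a * s_vb + bo^2 * n +
        2 * bo * a * s_b + a^2 * s_bb
      j <- which.min(rss)
      if (rss[j] < best$rss)
        best <- list(ic50 = 10^lg[j], rss = rss[j], lg = lg[j])
    }
  }
  best[c("ic50", "rss")]
}

# exhaustive two-sided Fisher test by direct enumeration of all tables
# with the observed margins, point probabilities from choose()
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - r2):min(r1, c1)
  pr <- vapply(support, function(a)
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1), numeric(1))
  p_obs <- pr[support == tab[1, 1]]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}
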