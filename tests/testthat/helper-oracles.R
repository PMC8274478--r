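# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: brute-force enumeration, closed forms, and
# hand-rolled geometry.

# brute-force Wilcoxon signed-rank: enumerate all 2^n sign patterns
brute_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  M <- n * (n + 1) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.numeric(signs %*% r)
  p_le <- mean(Vs <= V + 1e-12)
  p_ge <- mean(Vs >= V - 1e-12)
  list(W = min(V, M - V), V = V, p = min(1, 2 * min(p_le, p_ge)))
}

# brute-force cloud diameter: explicit pairwise 3-D distances on the helix
brute_cloud_diameter <- function(ks, r = 1, h = sqrt(2 / 15)) {
  ks <- unique(ks)
  if (length(ks) == 1L) return(0)
  pos <- lapply(ks, function(k) {
    c(r * sin(k * pi / 2), r * cos(k * pi / 2), k * h)
  })
  dmax <- 0
  for (i in seq_along(pos)) {
    for (j in seq_along(pos)) {
      if (j <= i) next
      dd <- sqrt(sum((pos[[i]] - pos[[j]])^2))
      if (dd > dmax) dmax <- dd
    }
  }
  dmax / sqrt(2 * r^2 + h^2)
}

# line-of-fifths index computed from first principles (sharpward fifths
# from C, sweeping the letter cycle F C G D A E B)
brute_fifths <- function(step, alter) {
  cycle <- c("F", "C", "G", "D", "A", "E", "B")
  (match(step, cycle) - 2L) + 7L * alter
}

make_timeline <- function(n_bars, bar_dur = 2, piece = "p") {
  bar_timeline(seq(0, by = bar_dur, length.out = n_bars),
               n_bars * bar_dur, piece = piece)
}

const_baseline <- function(level = 4, dur = 60, fs = 60,
                           subject = "s", occasion = "b") {
  t <- seq(0, dur - 1e-9, by = 1 / fs)
  baseline_stats(pupil_trace(t, rep(level, length(t)), rep(level, length(t)),
                             subject = subject, trial = occasion))
}

# latent AR(1)+iid bar-level series with known groups, for model oracles
sim_bar_data <- function(n_subj, n_piece, n_bars, beta, rho, sigma_ar,
                         sigma_e, sigma_subject = 0, sigma_piece = 0,
                         seed = 1) {
  set.seed(seed)
  subs <- sprintf("s%d", seq_len(n_subj))
  pcs <- sprintf("p%d", seq_len(n_piece))
  u_s <- stats::setNames(rnorm(n_subj, 0, sigma_subject), subs)
  u_p <- stats::setNames(rnorm(n_piece, 0, sigma_piece), pcs)
  out <- list()
  for (s in subs) {
    for (p in pcs) {
      X <- matrix(rnorm(n_bars * length(beta)), n_bars)
      colnames(X) <- names(beta)
      ar <- numeric(n_bars)
      if (sigma_ar > 0) {
        ar[1] <- rnorm(1, 0, sigma_ar)
        for (b in 2:n_bars) {
          ar[b] <- rho * ar[b - 1] + rnorm(1, 0, sigma_ar * sqrt(1 - rho^2))
        }
      }
      y <- as.numeric(X %*% beta) + u_s[[s]] + u_p[[p]] + ar +
        rnorm(n_bars, 0, sigma_e)
      out[[paste(s, p)]] <- data.frame(subject = s, piece = p,
                                       bar = seq_len(n_bars), pupil = y, X)
    }
  }
  bar_table(do.call(rbind, c(out, list(make.row.names = FALSE))))
}
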