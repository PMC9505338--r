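# Independent brute-force oracles, coded directly from the descriptor and
# metric definitions with plain loops; deliberately share no code path with
# the package implementations (only the published constant tables).

AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(len, prob = NULL) {
  paste(sample(AAS, len, replace = TRUE, prob = prob), collapse = "")
}

oracle_aac <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  out <- numeric(20)
  names(out) <- AAS
  for (a in AAS) {
    n <- 0
    for (c in ch) if (c == a) n <- n + 1
    out[a] <- n / length(ch)
  }
  out
}

oracle_dpc <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  out <- numeric(0)
  for (a in AAS) for (b in AAS) {
    n <- 0
    for (i in 1:(L - 1)) if (ch[i] == a && ch[i + 1] == b) n <- n + 1
    out[paste0(a, b)] <- n / (L - 1)
  }
  out
}

# explicit window enumeration over the boundary-padded sequence
oracle_wdc <- function(seq, window = 21) {
  ch <- c("#", strsplit(seq, "")[[1]], "#")
  lp <- length(ch)
  alpha <- c(AAS, "#")
  counts <- matrix(0, 21, 21, dimnames = list(alpha, alpha))
  starts <- if (lp <= window) 1 else 1:(lp - window + 1)
  for (s in starts) {
    e <- min(s + window - 1, lp)
    if (e > s) for (i in s:(e - 1)) {
      counts[ch[i], ch[i + 1]] <- counts[ch[i], ch[i + 1]] + 1
    }
  }
  out <- numeric(0)
  for (a in alpha) for (b in alpha) out[paste0(a, b)] <- counts[a, b]
  out
}

oracle_group_features <- function(seq, groups) {
  ch <- strsplit(seq, "")[[1]]
  counts <- numeric(length(groups))
  names(counts) <- names(groups)
  for (g in names(groups)) counts[g] <- sum(ch %in% groups[[g]])
  c(counts, counts / length(ch))
}

# CTD oracle per the published definition (3-class partition `groups`)
oracle_ctd_one <- function(seq, groups) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  cls <- integer(L)
  for (k in 1:3) for (i in 1:L) if (ch[i] %in% groups[[k]]) cls[i] <- k
  comp <- c(sum(cls == 1), sum(cls == 2), sum(cls == 3)) / L
  t12 <- t13 <- t23 <- 0
  for (i in 1:(L - 1)) {
    pr <- sort(c(cls[i], cls[i + 1]))
    if (pr[1] == 1 && pr[2] == 2) t12 <- t12 + 1
    if (pr[1] == 1 && pr[2] == 3) t13 <- t13 + 1
    if (pr[1] == 2 && pr[2] == 3) t23 <- t23 + 1
  }
  trans <- c(t12, t13, t23) / (L - 1)
  distr <- numeric(0)
  for (k in 1:3) {
    pos <- which(cls == k)
    n <- length(pos)
    if (n == 0) distr <- c(distr, rep(0, 5))
    else {
      idx <- c(1, max(1, round(0.25 * n)), max(1, round(0.5 * n)),
               max(1, round(0.75 * n)), n)
      distr <- c(distr, pos[idx] / L)
    }
  }
  c(comp, trans, distr)
}

std20 <- function(scale) {
  x <- scale[AAS]
  (x - mean(x)) / sd(x)
}

oracle_autocorr <- function(seq, scale, nlag, kind) {
  p <- std20(scale)[strsplit(seq, "")[[1]]]
  L <- length(p)
  pbar <- mean(p)
  out <- numeric(nlag)
  for (d in 1:nlag) {
    if (kind == "moreau_broto") {
      s <- 0
      for (i in 1:(L - d)) s <- s + p[i] * p[i + d]
      out[d] <- s / (L - d)
    } else if (kind == "moran") {
      num <- 0
      for (i in 1:(L - d)) num <- num + (p[i] - pbar) * (p[i + d] - pbar)
      den <- sum((p - pbar)^2) / L
      out[d] <- if (den == 0) 0 else (num / (L - d)) / den
    } else {
      num <- 0
      for (i in 1:(L - d)) num <- num + (p[i] - p[i + d])^2
      den <- sum((p - pbar)^2) / (L - 1)
      out[d] <- if (den == 0) 0 else (num / (2 * (L - d))) / den
    }
  }
  out
}

oracle_socn <- function(seq, dmat, nlag) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  out <- numeric(nlag)
  for (d in 1:nlag) {
    s <- 0
    for (i in 1:(L - d)) s <- s + dmat[ch[i], ch[i + d]]^2
    out[d] <- s
  }
  out
}

oracle_qso <- function(seq, dmat, nlag, w) {
  ch <- strsplit(seq, "")[[1]]
  tau <- oracle_socn(seq, dmat, nlag)
  f <- numeric(20)
  names(f) <- AAS
  for (a in AAS) f[a] <- sum(ch == a)
  c(f, w * tau) / (length(ch) + w * sum(tau))
}

paac_norm20 <- function(scale) {
  x <- scale[AAS]
  (x - mean(x)) / sqrt(sum((x - mean(x))^2) / 20)
}

oracle_paac <- function(seq, lambda, w, h1, h2, h3) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  p1 <- paac_norm20(h1)[ch]; p2 <- paac_norm20(h2)[ch]
  p3 <- paac_norm20(h3)[ch]
  theta <- numeric(lambda)
  for (d in 1:lambda) {
    s <- 0
    for (i in 1:(L - d)) {
      s <- s + ((p1[i] - p1[i + d])^2 + (p2[i] - p2[i + d])^2 +
                  (p3[i] - p3[i + d])^2) / 3
    }
    theta[d] <- s / (L - d)
  }
  f <- numeric(20); names(f) <- AAS
  for (a in AAS) f[a] <- sum(ch == a) / L
  c(f, w * theta) / (1 + w * sum(theta))
}

oracle_apaac <- function(seq, lambda, w, h1, h2) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  p1 <- paac_norm20(h1)[ch]; p2 <- paac_norm20(h2)[ch]
  tau <- numeric(2 * lambda)
  for (d in 1:lambda) {
    s1 <- s2 <- 0
    for (i in 1:(L - d)) {
      s1 <- s1 + p1[i] * p1[i + d]
      s2 <- s2 + p2[i] * p2[i + d]
    }
    tau[2 * d - 1] <- s1 / (L - d)
    tau[2 * d] <- s2 / (L - d)
  }
  f <- numeric(20); names(f) <- AAS
  for (a in AAS) f[a] <- sum(ch == a) / L
  c(f, w * tau) / (1 + w * sum(tau))
}

oracle_conjoint <- function(seq, classes) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  cls <- integer(L)
  for (k in seq_along(classes)) for (i in 1:L) {
    if (ch[i] %in% classes[[k]]) cls[i] <- k
  }
  out <- numeric(0)
  for (a in 1:7) for (b in 1:7) for (c in 1:7) {
    n <- 0
    for (i in 1:(L - 2)) {
      if (cls[i] == a && cls[i + 1] == b && cls[i + 2] == c) n <- n + 1
    }
    out[paste0(a, b, c)] <- n
  }
  out
}

# metric oracles: explicit summation loops over the paper-style formulas
oracle_metrics <- function(y_pred, y_true) {
  n <- length(y_true)
  sse <- sae <- 0
  for (i in 1:n) {
    sse <- sse + (y_pred[i] - y_true[i])^2
    sae <- sae + abs(y_pred[i] - y_true[i])
  }
  mx <- sum(y_pred) / n
  my <- sum(y_true) / n
  sxy <- sxx <- syy <- sstot <- 0
  for (i in 1:n) {
    sxy <- sxy + (y_pred[i] - mx) * (y_true[i] - my)
    sxx <- sxx + (y_pred[i] - mx)^2
    syy <- syy + (y_true[i] - my)^2
    sstot <- sstot + (y_true[i] - my)^2
  }
  list(pcc = (sxy / n) / (sqrt(sxx / n) * sqrt(syy / n)),
       rmse = sqrt(sse / n), mse = sse / n, mae = sae / n,
       r2 = 1 - sse / sstot)
}
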