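# Brute-force reference implementations, written independently of the
# package internals (explicit double loops, textbook formulas). They are
# deliberately slow and only run on tiny inputs.

# Exhaustive largest all-TRUE rectangle: enumerate every row pair, find the
# longest run of full columns between them.
oracle_max_rect_area <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  best <- 0
  for (r0 in 1:H) for (r1 in r0:H) {
    full <- colSums(mask[r0:r1, , drop = FALSE]) == (r1 - r0 + 1)
    run <- 0
    for (c in 1:W) {
      run <- if (full[c]) run + 1 else 0
      best <- max(best, (r1 - r0 + 1) * run)
    }
  }
  best
}

# Pair enumeration GLCM (symmetrized, normalized, averaged over directions).
oracle_glcm <- function(q, d, directions = c(0, 45, 90, 135)) {
  G <- if (!is.null(attr(q, "levels"))) attr(q, "levels") else max(q) + 1
  offs <- list(`0` = c(0, d), `45` = c(-d, d), `90` = c(-d, 0), `135` = c(-d, -d))
  mats <- lapply(directions, function(ang) {
    off <- offs[[as.character(ang)]]
    cnt <- matrix(0, G, G)
    for (r in seq_len(nrow(q))) for (c in seq_len(ncol(q))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        i <- q[r, c] + 1; j <- q[r2, c2] + 1
        cnt[i, j] <- cnt[i, j] + 1
        cnt[j, i] <- cnt[j, i] + 1
      }
    }
    cnt / sum(cnt)
  })
  Reduce(`+`, mats) / length(mats)
}

# Textbook Haralick formulas, written with explicit loops (0-based levels,
# base-2 logs, 0 log 0 = 0).
oracle_glcm_features <- function(p) {
  G <- nrow(p)
  lg <- function(v) if (v > 0) log2(v) else 0
  px <- rowSums(p); py <- colSums(p)
  mux <- 0; muy <- 0
  for (i in 1:G) { mux <- mux + (i - 1) * px[i]; muy <- muy + (i - 1) * py[i] }
  sx <- 0; sy <- 0
  for (i in 1:G) { sx <- sx + (i - 1 - mux)^2 * px[i]; sy <- sy + (i - 1 - muy)^2 * py[i] }
  sx <- sqrt(sx); sy <- sqrt(sy)
  asm <- 0; con <- 0; cor0 <- 0; vari <- 0; idm <- 0; ent <- 0; dis <- 0; aut <- 0
  for (i in 1:G) for (j in 1:G) {
    v <- p[i, j]; di <- (i - 1) - (j - 1)
    asm <- asm + v^2
    con <- con + di^2 * v
    cor0 <- cor0 + (i - 1) * (j - 1) * v
    vari <- vari + (i - 1 - mux)^2 * v
    idm <- idm + v / (1 + di^2)
    ent <- ent - v * lg(v)
    dis <- dis + abs(di) * v
    aut <- aut + (i - 1) * (j - 1) * v
  }
  correlation <- if (sx > 0 && sy > 0) (cor0 - mux * muy) / (sx * sy) else 0
  psum <- numeric(2 * G - 1)
  pdif <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    psum[i + j - 1] <- psum[i + j - 1] + p[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p[i, j]
  }
  sa <- sum((0:(2 * G - 2)) * psum)
  sv <- sum(((0:(2 * G - 2)) - sa)^2 * psum)
  se <- -sum(sapply(seq_along(psum), function(k) psum[k] * lg(psum[k])))
  da <- sum((0:(G - 1)) * pdif)
  dv <- sum(((0:(G - 1)) - da)^2 * pdif)
  de <- -sum(sapply(seq_along(pdif), function(k) pdif[k] * lg(pdif[k])))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:G) for (j in 1:G) {
    hxy1 <- hxy1 - p[i, j] * lg(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  hx <- -sum(sapply(1:G, function(i) px[i] * lg(px[i])))
  hy <- -sum(sapply(1:G, function(j) py[j] * lg(py[j])))
  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - 2^(-2 * (hxy2 - ent))))
  c(asm = asm, contrast = con, correlation = correlation, variance = vari,
    idm = idm, sum_average = sa, sum_variance = sv, sum_entropy = se,
    entropy = ent, diff_variance = dv, diff_entropy = de, imc1 = imc1,
    imc2 = imc2, dissimilarity = dis, autocorrelation = aut, max_prob = max(p))
}

# Scan-line run enumeration for one direction.
oracle_runs <- function(q, angle) {
  step <- switch(as.character(angle),
                 `0` = c(0, 1), `90` = c(1, 0), `45` = c(-1, 1), `135` = c(1, 1))
  H <- nrow(q); W <- ncol(q)
  starts <- list()
  for (r in 1:H) for (c in 1:W) {
    pr <- r - step[1]; pc <- c - step[2]
    if (pr < 1 || pr > H || pc < 1 || pc > W)
      starts[[length(starts) + 1]] <- c(r, c)
  }
  lv <- c(); ll <- c()
  for (s in starts) {
    r <- s[1]; c <- s[2]
    cur <- q[r, c]; len <- 0
    while (r >= 1 && r <= H && c >= 1 && c <= W) {
      if (q[r, c] == cur) len <- len + 1
      else { lv <- c(lv, cur); ll <- c(ll, len); cur <- q[r, c]; len <- 1 }
      r <- r + step[1]; c <- c + step[2]
    }
    lv <- c(lv, cur); ll <- c(ll, len)
  }
  data.frame(level = lv, length = ll)
}

oracle_glrlm_features <- function(q, directions = c(0, 45, 90, 135)) {
  per <- lapply(directions, function(ang) {
    runs <- oracle_runs(q, ang)
    g <- runs$level + 1; l <- runs$length; nr <- nrow(runs); np <- length(q)
    gl_counts <- table(g); rl_counts <- table(l)
    c(glrlm_sre = sum(1 / l^2) / nr, glrlm_lre = sum(l^2) / nr,
      glrlm_gln = sum(as.numeric(gl_counts)^2) / nr,
      glrlm_rln = sum(as.numeric(rl_counts)^2) / nr,
      glrlm_rp = nr / np, glrlm_lgre = sum(1 / g^2) / nr,
      glrlm_hgre = sum(g^2) / nr, glrlm_srlge = sum(1 / (l * g)^2) / nr,
      glrlm_srhge = sum(g^2 / l^2) / nr, glrlm_lrlge = sum(l^2 / g^2) / nr,
      glrlm_lrhge = sum((l * g)^2) / nr)
  })
  Reduce(`+`, per) / length(per)
}

oracle_glds_features <- function(q) {
  G <- max(q) + 1
  diffs <- c()
  for (off in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    for (r in seq_len(nrow(q))) for (c in seq_len(ncol(q))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q))
        diffs <- c(diffs, abs(q[r, c] - q[r2, c2]))
    }
  }
  p <- sapply(0:(G - 1), function(d) mean(diffs == d))
  lg <- function(v) if (v > 0) log2(v) else 0
  mu <- sum((0:(G - 1)) * p)
  c(glds_mean = mu,
    glds_variance = sum(((0:(G - 1)) - mu)^2 * p),
    glds_entropy = -sum(sapply(p, function(v) v * lg(v))),
    glds_asm = sum(p^2),
    glds_contrast = sum((0:(G - 1))^2 * p))
}

# Direct per-pixel population moments.
oracle_moments <- function(x) {
  n <- length(x); m <- sum(x) / n
  v <- sum((x - m)^2) / n
  s <- sqrt(v)
  c(mean = m, variance = v, std = s,
    skewness = if (s > 0) sum((x - m)^3) / n / s^3 else 0,
    kurtosis = if (s > 0) sum((x - m)^4) / n / s^4 - 3 else 0)
}

# Direct 3x3 valid convolution.
oracle_conv3x3 <- function(img, k) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H - 2, W - 2)
  for (r in 2:(H - 1)) for (c in 2:(W - 1)) {
    acc <- 0
    for (dr in -1:1) for (dc in -1:1)
      acc <- acc + k[dr + 2, dc + 2] * img[r + dr, c + dc]
    out[r - 1, c - 1] <- acc
  }
  out
}
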