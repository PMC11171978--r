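# Independent brute-force oracles. Everything here is written as plain
# loops over definitions, deliberately sharing no code with the package.

rand_region <- function(nr, nc, seed, max_val = 255L) {
  set.seed(seed)
  matrix(sample(0L:max_val, nr * nc, replace = TRUE), nr, nc)
}

# direction -> (dr, dc), matching the documented angle convention
oracle_offset <- function(angle, distance = 1L) {
  switch(as.character(angle),
         "0"   = c(0L, distance),
         "45"  = c(-distance, distance),
         "90"  = c(-distance, 0L),
         "135" = c(-distance, -distance))
}

# explicit pair enumeration: count, symmetrize, normalize, average angles
oracle_glcm <- function(region, ng, distance = 1L,
                        angles = c(0, 45, 90, 135)) {
  acc <- matrix(0, ng, ng)
  used <- 0
  for (a in angles) {
    off <- oracle_offset(a, distance)
    counts <- matrix(0, ng, ng)
    for (r in seq_len(nrow(region))) {
      for (c in seq_len(ncol(region))) {
        r2 <- r + off[1]; c2 <- c + off[2]
        if (r2 >= 1 && r2 <= nrow(region) && c2 >= 1 && c2 <= ncol(region)) {
          i <- region[r, c] + 1L; j <- region[r2, c2] + 1L
          counts[i, j] <- counts[i, j] + 1
          counts[j, i] <- counts[j, i] + 1
        }
      }
    }
    if (sum(counts) > 0) {
      acc <- acc + counts / sum(counts)
      used <- used + 1
    }
  }
  acc / used
}

# naive double-sum Haralick features of a probability matrix p (levels 0..ng-1)
oracle_glcm_features <- function(p) {
  ng <- nrow(p)
  contrast <- 0; idm <- 0; sijp <- 0
  psum <- numeric(2 * ng - 1)   # index k+1, k = i+j in 0..2ng-2
  pdif <- numeric(ng)           # index k+1, k = |i-j|
  for (i in 0:(ng - 1)) for (j in 0:(ng - 1)) {
    v <- p[i + 1, j + 1]
    contrast <- contrast + (i - j)^2 * v
    idm <- idm + v / (1 + (i - j)^2)
    sijp <- sijp + i * j * v
    psum[i + j + 1] <- psum[i + j + 1] + v
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + v
  }
  px <- rowSums(p)
  mu <- sum((0:(ng - 1)) * px)
  sig2 <- sum(((0:(ng - 1)) - mu)^2 * px)
  sum_avg <- sum((0:(2 * ng - 2)) * psum)
  ssq <- 0
  for (i in 0:(ng - 1)) for (j in 0:(ng - 1))
    ssq <- ssq + (i - mu)^2 * p[i + 1, j + 1]
  mud <- sum((0:(ng - 1)) * pdif)
  dvar <- sum(((0:(ng - 1)) - mud)^2 * pdif)
  corr <- if (sig2 <= 0) NA_real_ else (sijp - mu^2) / sig2
  c(glcm_contrast = contrast, glcm_sum_average = sum_avg,
    glcm_ssq_variance = ssq, glcm_difference_variance = dvar,
    glcm_correlation = corr, glcm_idm = idm)
}

oracle_glds <- function(region, ng,
                        disps = list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))) {
  counts <- numeric(ng)
  for (d in disps) {
    for (r in seq_len(nrow(region))) {
      for (c in seq_len(ncol(region))) {
        r2 <- r + d[1]; c2 <- c + d[2]
        if (r2 >= 1 && r2 <= nrow(region) && c2 >= 1 && c2 <= ncol(region)) {
          k <- abs(region[r, c] - region[r2, c2])
          counts[k + 1] <- counts[k + 1] + 1
        }
      }
    }
  }
  counts / sum(counts)
}

oracle_glds_features <- function(q) {
  hom <- 0; con <- 0; asm <- 0; ent <- 0; mn <- 0
  for (k in seq_along(q) - 1) {
    v <- q[k + 1]
    hom <- hom + v / (1 + k^2)
    con <- con + k^2 * v
    asm <- asm + v^2
    if (v > 0) ent <- ent - v * log(v)
    mn <- mn + k * v
  }
  c(glds_homogeneity = hom, glds_contrast = con, glds_asm = asm,
    glds_entropy = ent, glds_mean = mn)
}

# direct 2x2 block filtering: averages and differences over one level
oracle_haar <- function(region) {
  nr <- nrow(region) - nrow(region) %% 2
  nc <- ncol(region) - ncol(region) %% 2
  coefs <- c()
  for (r in seq(1, nr, 2)) {
    for (c in seq(1, nc, 2)) {
      a <- region[r, c]; b <- region[r, c + 1]
      d <- region[r + 1, c]; e <- region[r + 1, c + 1]
      coefs <- c(coefs,
                 (a - b + d - e) / 2,   # horizontal detail
                 (a + b - d - e) / 2,   # vertical detail
                 (a - b - d + e) / 2)   # diagonal detail
    }
  }
  v <- abs(coefs)
  c(haar_mean = mean(v), haar_variance = mean((v - mean(v))^2))
}

# exhaustive concordant-pair AUC (ties count one half)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# weighted kappa straight from the printed weight/count tables
oracle_weighted_kappa <- function(s1, s2, k = 4) {
  n <- length(s1)
  o <- matrix(0, k, k)
  for (t in seq_len(n)) o[s1[t] + 1, s2[t] + 1] <- o[s1[t] + 1, s2[t] + 1] + 1
  o <- o / n
  pr <- rowSums(o); pc <- colSums(o)
  num <- 0; den <- 0
  for (i in 1:k) for (j in 1:k) {
    w <- ((i - j) / (k - 1))^2
    num <- num + w * o[i, j]
    den <- den + w * pr[i] * pc[j]
  }
  if (den <= 0) NA_real_ else 1 - num / den
}

# midranks computed by hand (no rank()), then the tie-corrected W formula
oracle_kendall_w <- function(x) {
  n <- nrow(x); m <- ncol(x)
  midrank <- function(col) {
    r <- numeric(n)
    for (i in seq_len(n)) r[i] <- sum(col < col[i]) + (1 + sum(col == col[i])) / 2
    r
  }
  ranks <- sapply(seq_len(m), function(j) midrank(x[, j]))
  s <- sum(rowSums(ranks)^2)
  tt <- 0
  for (j in seq_len(m)) {
    for (v in unique(x[, j])) {
      t <- sum(x[, j] == v)
      tt <- tt + t^3 - t
    }
  }
  (12 * s - 3 * m^2 * n * (n + 1)^2) / (m^2 * n * (n^2 - 1) - m * tt)
}

oracle_shoelace <- function(v) {
  n <- nrow(v); s <- 0
  for (i in seq_len(n)) {
    j <- i %% n + 1
    s <- s + v[i, 1] * v[j, 2] - v[j, 1] * v[i, 2]
  }
  abs(s) / 2
}

# marching-squares boundary length of a binary mask (0.5-level contour,
# midpoint interpolation) - independent of the Moore contour tracer
oracle_marching_squares_perimeter <- function(mask) {
  m <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  len <- 0
  h <- sqrt(0.5^2 + 0.5^2)
  for (r in seq_len(nrow(m) - 1)) {
    for (c in seq_len(ncol(m) - 1)) {
      sq <- c(m[r, c], m[r, c + 1], m[r + 1, c + 1], m[r + 1, c])
      k <- sum(sq)
      if (k == 1 || k == 3) len <- len + h          # one corner cut
      else if (k == 2) {
        if (all(sq == c(1, 1, 0, 0)) || all(sq == c(0, 0, 1, 1)) ||
            all(sq == c(1, 0, 0, 1)) || all(sq == c(0, 1, 1, 0)))
          len <- len + 1                             # straight edge
        else len <- len + 2 * h                      # saddle: two cuts
      }
    }
  }
  len
}

# dense vertical-ray-casting width oracle for a polygon made of two chains
oracle_widths_raycast <- function(poly_vertices, xs) {
  # at each x, intersect the vertical line with every polygon edge and take
  # the span of intersection ys
  v <- poly_vertices
  n <- nrow(v)
  sapply(xs, function(x) {
    ys <- c()
    for (i in seq_len(n)) {
      j <- i %% n + 1
      x1 <- v[i, 1]; x2 <- v[j, 1]
      if ((x1 <= x && x <= x2) || (x2 <= x && x <= x1)) {
        if (x1 == x2) ys <- c(ys, v[i, 2], v[j, 2])
        else ys <- c(ys, v[i, 2] + (x - x1) / (x2 - x1) * (v[j, 2] - v[i, 2]))
      }
    }
    max(ys) - min(ys)
  })
}
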