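# Independent brute-force oracles for the texture matrices, the MIC grid
# search, and small fixture builders. Each oracle takes a different route
# than the implementation (pairwise enumeration instead of directional
# scans, label propagation instead of BFS, exhaustive cut enumeration
# instead of dynamic programming).

# all 26-neighbour offsets
all_offsets <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
}

# GLCM oracle: count every ordered pair of in-mask voxels at Chebyshev
# distance 1.
oracle_glcm <- function(levels, n_gray) {
  w <- which(levels > 0, arr.ind = TRUE)
  M <- matrix(0, n_gray, n_gray)
  n <- nrow(w)
  for (p in seq_len(n)) for (q in seq_len(n)) {
    if (p == q) next
    d <- abs(w[p, ] - w[q, ])
    if (max(d) == 1) {
      M[levels[w[p, , drop = FALSE]], levels[w[q, , drop = FALSE]]] <-
        M[levels[w[p, , drop = FALSE]], levels[w[q, , drop = FALSE]]] + 1
    }
  }
  M
}

# GLRLM oracle: for each direction, walk every full grid line and rle it.
oracle_glrlm <- function(levels, n_gray) {
  dm <- dim(levels)
  dirs <- rbind(c(1,0,0), c(0,1,0), c(0,0,1),
                c(1,1,0), c(1,-1,0), c(1,0,1), c(1,0,-1), c(0,1,1), c(0,1,-1),
                c(1,1,1), c(1,1,-1), c(1,-1,1), c(1,-1,-1))
  M <- matrix(0, n_gray, max(dm))
  inside <- function(v) all(v >= 1) && all(v <= dm)
  for (r in seq_len(nrow(dirs))) {
    d <- dirs[r, ]
    starts <- which(array(TRUE, dm), arr.ind = TRUE)
    starts <- starts[!apply(starts, 1, function(v) inside(v - d)), ,
                     drop = FALSE]
    for (s in seq_len(nrow(starts))) {
      v <- starts[s, ]
      seqv <- integer(0)
      while (inside(v)) {
        seqv <- c(seqv, levels[v[1], v[2], v[3]])
        v <- v + d
      }
      rl <- rle(seqv)
      keep <- rl$values > 0
      for (i in which(keep))
        M[rl$values[i], rl$lengths[i]] <- M[rl$values[i], rl$lengths[i]] + 1
    }
  }
  M
}

# GLSZM oracle: zone sizes by iterative min-label propagation over the
# 26-neighbourhood within constant-level voxels.
oracle_glszm_zones <- function(levels) {
  w <- which(levels > 0, arr.ind = TRUE)
  n <- nrow(w)
  lab <- seq_len(n)
  offs <- all_offsets()
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  idx_of <- setNames(seq_len(n), key(w))
  lev <- levels[w]
  repeat {
    changed <- FALSE
    for (p in seq_len(n)) {
      nb <- sweep(offs, 2, as.numeric(w[p, ]), "+")
      hit <- idx_of[key(nb)]
      hit <- hit[!is.na(hit)]
      hit <- hit[lev[hit] == lev[p]]
      if (length(hit) > 0) {
        m <- min(lab[p], lab[hit])
        if (any(c(lab[p], lab[hit]) != m)) {
          lab[p] <- m
          lab[hit] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  z <- table(lab)
  data.frame(level = lev[as.integer(names(z))], size = as.integer(z))
}

# NGTDM oracle: direct neighbour enumeration per voxel.
oracle_ngtdm <- function(levels, n_gray) {
  w <- which(levels > 0, arr.ind = TRUE)
  dm <- dim(levels)
  offs <- all_offsets()
  s <- numeric(n_gray)
  cnt <- integer(n_gray)
  for (p in seq_len(nrow(w))) {
    nb <- sweep(offs, 2, as.numeric(w[p, ]), "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    nb <- nb[ok, , drop = FALSE]
    vals <- levels[nb]
    vals <- vals[vals > 0]
    if (length(vals) == 0) next
    g <- levels[w[p, , drop = FALSE]]
    s[g] <- s[g] + abs(g - mean(vals))
    cnt[g] <- cnt[g] + 1L
  }
  list(s = s, n = cnt)
}

# MIC oracle: exhaustive enumeration of all cut subsets of the free axis
# (both orientations) over the same admissible grid family searched by the
# implementation (equal-probability bins on the fixed axis, grid bound
# k * l <= max(4, n^0.6)), with mutual information computed from plain
# contingency tables.
oracle_mic <- function(x, y, alpha = 0.6) {
  n <- length(x)
  B <- max(4, n^alpha)
  equip <- function(v, l) {
    r <- rank(v, ties.method = "max")
    b <- pmin(pmax(ceiling(l * r / n), 1), l)
    as.integer(factor(b))
  }
  mi_bits <- function(rows, cols) {
    tab <- table(rows, cols) / n
    hr <- -sum(ifelse(rowSums(tab) > 0, rowSums(tab) * log2(rowSums(tab)), 0))
    hc <- -sum(ifelse(colSums(tab) > 0, colSums(tab) * log2(colSums(tab)), 0))
    hj <- -sum(ifelse(tab > 0, tab * log2(tab), 0))
    hr + hc - hj
  }
  best <- 0
  for (orient in 1:2) {
    vfix <- if (orient == 1) y else x
    vfree <- if (orient == 1) x else y
    for (l in 2:max(2, floor(B / 2))) {
      if (2 * l > B) next
      rows <- equip(vfix, l)
      nr <- length(unique(rows))
      if (nr < 2) next
      kmax <- floor(B / nr)
      if (kmax < 2) next
      ord <- order(vfree)
      sv <- vfree[ord]
      cutpos <- which(diff(sv) != 0) # cuts between distinct values
      for (k in 2:kmax) {
        ncuts <- min(k - 1, length(cutpos))
        for (nc in 1:ncuts) {
          combos <- utils::combn(cutpos, nc, simplify = FALSE)
          for (cs in combos) {
            colid <- integer(n)
            colid[ord] <- findInterval(seq_len(n), cs + 0.5) + 1
            val <- mi_bits(rows, colid) / log2(min(k, nr))
            best <- max(best, val)
          }
        }
      }
    }
  }
  min(best, 1)
}

# small random in-mask level array fixture
random_levels <- function(dim3, n_gray, density = 0.7, seed = 1) {
  set.seed(seed)
  a <- array(0L, dim3)
  inmask <- runif(prod(dim3)) < density
  a[inmask] <- sample.int(n_gray, sum(inmask), replace = TRUE)
  a
}

tiny_table <- function(n_pos = 16, n_neg = 35, p = 12, informative = 1:3,
                       effect = 2, seed = 1, prefix = "f") {
  generate_feature_table(table_spec(n_pos = n_pos, n_neg = n_neg,
                                    p_features = p,
                                    informative_idx = informative,
                                    effect_size = effect, seed = seed,
                                    prefix = prefix))
}
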