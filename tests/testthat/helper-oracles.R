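# Independent brute-force oracles used to cross-check the implementation.

# AUC as the explicit mean over all positive-negative pairs.
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# Maximum pairwise distance over *all* mask voxels (no boundary shortcut).
oracle_diameter <- function(mask, spacing = c(1, 1, 1)) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) < 2) return(0)
  pts <- sweep(idx - 1, 2, spacing, "*")
  mx <- 0
  for (i in seq_len(nrow(pts) - 1)) {
    d2 <- (pts[(i + 1):nrow(pts), 1] - pts[i, 1])^2 +
          (pts[(i + 1):nrow(pts), 2] - pts[i, 2])^2 +
          (pts[(i + 1):nrow(pts), 3] - pts[i, 3])^2
    mx <- max(mx, max(d2))
  }
  sqrt(mx)
}

# Coverage as an explicit voxel loop.
oracle_coverage <- function(activation, mask, threshold) {
  n_in <- 0; n_hit <- 0
  for (i in seq_along(mask)) {
    if (mask[i] != 0) {
      n_in <- n_in + 1
      if (activation[i] >= threshold) n_hit <- n_hit + 1
    }
  }
  n_hit / n_in
}

# Exhaustive threshold scan: maximise specificity s.t. sensitivity >= target,
# ties toward the larger threshold, over the same candidate family.
oracle_threshold <- function(scores, labels, target) {
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  best <- NULL; best_spec <- -1
  for (t in cand) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    if (sens >= target &&
        (spec > best_spec || (spec == best_spec && t > best)))  {
      best <- t; best_spec <- spec
    }
  }
  best
}

# Random blob-like binary mask with at most `max_vox` voxels.
random_mask <- function(dim = c(12, 12, 12), max_vox = 500) {
  m <- array(0L, dim = dim)
  n_seed <- sample(1:3, 1)
  ctr <- matrix(runif(3 * n_seed, 3, dim[1] - 2), ncol = 3)
  rad <- runif(n_seed, 1, 4)
  g <- as.matrix(expand.grid(x = 1:dim[1], y = 1:dim[2], z = 1:dim[3]))
  for (k in seq_len(n_seed)) {
    d <- sqrt(colSums((t(g) - ctr[k, ])^2))
    m[g[d <= rad[k], , drop = FALSE]] <- 1L
  }
  if (sum(m) == 0) m[ctr[1, 1], ctr[1, 2], ctr[1, 3]] <- 1L
  if (sum(m) > max_vox) {
    keep <- which(m == 1L)
    m[keep[-seq_len(max_vox)]] <- 0L
  }
  m
}

# 6-connectivity check: TRUE when every mask voxel reaches a voxel adjacent
# to the wall region through face-connected mask steps.
mask_connected_to_wall <- function(mask, wall) {
  idx <- which(mask != 0)
  if (length(idx) == 0) return(FALSE)
  d <- dim(mask)
  coord <- arrayInd(idx, d)
  key <- function(m) (m[, 1] - 1) + d[1] * ((m[, 2] - 1) + d[2] * (m[, 3] - 1))
  in_mask <- new.env(hash = TRUE)
  for (k in key(coord)) assign(as.character(k), FALSE, envir = in_mask)
  # seeds: mask voxels with a face neighbour in the wall
  shifts <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  touches_wall <- rep(FALSE, nrow(coord))
  for (s in seq_len(6)) {
    nb <- sweep(coord, 2, shifts[s, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    hit <- rep(FALSE, nrow(coord))
    hit[ok] <- wall[nb[ok, , drop = FALSE]] != 0
    touches_wall <- touches_wall | hit
  }
  if (!any(touches_wall)) return(FALSE)
  # BFS over the mask from the wall-adjacent seeds
  visited <- rep(FALSE, nrow(coord))
  lookup <- match(key(coord), key(coord))
  keymap <- new.env(hash = TRUE)
  kk <- key(coord)
  for (i in seq_along(kk)) assign(as.character(kk[i]), i, envir = keymap)
  queue <- which(touches_wall)
  visited[queue] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    for (s in seq_len(6)) {
      nb <- coord[i, ] + shifts[s, ]
      if (any(nb < 1) || any(nb > d)) next
      k <- as.character((nb[1] - 1) + d[1] * ((nb[2] - 1) + d[2] * (nb[3] - 1)))
      j <- keymap[[k]]
      if (!is.null(j) && !visited[j]) {
        visited[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  all(visited)
}
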