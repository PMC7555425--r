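# Independent brute-force oracles. Deliberately naive (explicit loops,
# all-pairs distances) and kept free of any code path they are used to check.

bf_surface <- function(vox) {
  dm <- dim(vox)
  out <- array(FALSE, dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (vox[i, j, k] == 1) {
      nb <- c(
        if (i > 1) vox[i - 1, j, k] else 0, if (i < dm[1]) vox[i + 1, j, k] else 0,
        if (j > 1) vox[i, j - 1, k] else 0, if (j < dm[2]) vox[i, j + 1, k] else 0,
        if (k > 1) vox[i, j, k - 1] else 0, if (k < dm[3]) vox[i, j, k + 1] else 0)
      if (any(nb == 0) || length(nb) < 6) out[i, j, k] <- TRUE
    }
  }
  out
}

bf_directed_dists <- function(pa, pb) {
  apply(pa, 1, function(a) {
    sqrt(min(colSums((t(pb) - a)^2)))
  })
}

bf_surface_points <- function(mask) {
  sv <- which(bf_surface(mask$voxels), arr.ind = TRUE)
  sweep(sv, 2, mask$spacing, `*`)
}

bf_hd95 <- function(a, b) {
  pa <- bf_surface_points(a); pb <- bf_surface_points(b)
  dab <- bf_directed_dists(pa, pb); dba <- bf_directed_dists(pb, pa)
  max(quantile(dab, 0.95, names = FALSE, type = 7),
      quantile(dba, 0.95, names = FALSE, type = 7))
}

bf_asd <- function(a, b) {
  pa <- bf_surface_points(a); pb <- bf_surface_points(b)
  dab <- bf_directed_dists(pa, pb); dba <- bf_directed_dists(pb, pa)
  mean(c(dab, dba))
}

bf_dice <- function(a, b) {
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0) return(1)
  2 * sum(a$voxels == 1 & b$voxels == 1) / (na + nb)
}

all_offsets_26 <- function() {
  g <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  g[!(g$x == 0 & g$y == 0 & g$z == 0), ]
}

half_directions_13 <- function() {
  g <- all_offsets_26()
  keep <- g$x > 0 | (g$x == 0 & g$y > 0) | (g$x == 0 & g$y == 0 & g$z > 0)
  g[keep, ]
}

in_grid <- function(q, dm) all(q >= 1) && all(q <= dm)

bf_glcm <- function(L, d, levels) {
  dm <- dim(L)
  n <- length(levels)
  C <- matrix(0, n, n, dimnames = list(levels, levels))
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (L[i, j, k] > 0) {
      q <- c(i, j, k) + d
      if (in_grid(q, dm) && L[q[1], q[2], q[3]] > 0) {
        a <- match(L[i, j, k], levels); b <- match(L[q[1], q[2], q[3]], levels)
        C[a, b] <- C[a, b] + 1
        C[b, a] <- C[b, a] + 1  # symmetric
      }
    }
  }
  C
}

bf_glrlm <- function(L, d, levels) {
  dm <- dim(L)
  runs <- list()
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    v <- L[i, j, k]
    if (v > 0) {
      prev <- c(i, j, k) - d
      is_start <- !(in_grid(prev, dm) && L[prev[1], prev[2], prev[3]] == v)
      if (is_start) {
        len <- 1
        q <- c(i, j, k) + d
        while (in_grid(q, dm) && L[q[1], q[2], q[3]] == v) {
          len <- len + 1
          q <- q + d
        }
        runs[[length(runs) + 1]] <- c(v, len)
      }
    }
  }
  rr <- do.call(rbind, runs)
  maxlen <- max(rr[, 2])
  P <- matrix(0, length(levels), maxlen, dimnames = list(levels, seq_len(maxlen)))
  for (r in seq_len(nrow(rr)))
    P[match(rr[r, 1], levels), rr[r, 2]] <- P[match(rr[r, 1], levels), rr[r, 2]] + 1
  P
}

bf_glszm <- function(L, levels) {
  dm <- dim(L)
  seen <- array(FALSE, dm)
  offs <- all_offsets_26()
  zones <- list()
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (L[i, j, k] > 0 && !seen[i, j, k]) {
      lev <- L[i, j, k]
      stack <- list(c(i, j, k))
      seen[i, j, k] <- TRUE
      size <- 0
      while (length(stack)) {
        cur <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        size <- size + 1
        for (o in seq_len(nrow(offs))) {
          q <- cur + as.numeric(offs[o, ])
          if (in_grid(q, dm) && !seen[q[1], q[2], q[3]] &&
              L[q[1], q[2], q[3]] == lev) {
            seen[q[1], q[2], q[3]] <- TRUE
            stack[[length(stack) + 1]] <- q
          }
        }
      }
      zones[[length(zones) + 1]] <- c(lev, size)
    }
  }
  zz <- do.call(rbind, zones)
  maxs <- max(zz[, 2])
  P <- matrix(0, length(levels), maxs, dimnames = list(levels, seq_len(maxs)))
  for (r in seq_len(nrow(zz)))
    P[match(zz[r, 1], levels), zz[r, 2]] <- P[match(zz[r, 1], levels), zz[r, 2]] + 1
  P
}

bf_gldm <- function(L, levels) {
  dm <- dim(L)
  offs <- all_offsets_26()
  deps <- list()
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    v <- L[i, j, k]
    if (v > 0) {
      cnt <- 1  # the centre voxel
      for (o in seq_len(nrow(offs))) {
        q <- c(i, j, k) + as.numeric(offs[o, ])
        if (in_grid(q, dm) && L[q[1], q[2], q[3]] == v) cnt <- cnt + 1
      }
      deps[[length(deps) + 1]] <- c(v, cnt)
    }
  }
  dd <- do.call(rbind, deps)
  maxd <- max(dd[, 2])
  P <- matrix(0, length(levels), maxd, dimnames = list(levels, seq_len(maxd)))
  for (r in seq_len(nrow(dd)))
    P[match(dd[r, 1], levels), dd[r, 2]] <- P[match(dd[r, 1], levels), dd[r, 2]] + 1
  P
}

bf_ngtdm <- function(L, levels) {
  dm <- dim(L)
  offs <- all_offsets_26()
  n_i <- setNames(numeric(length(levels)), levels)
  s_i <- setNames(numeric(length(levels)), levels)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    v <- L[i, j, k]
    if (v > 0) {
      nb <- c()
      for (o in seq_len(nrow(offs))) {
        q <- c(i, j, k) + as.numeric(offs[o, ])
        if (in_grid(q, dm) && L[q[1], q[2], q[3]] > 0)
          nb <- c(nb, L[q[1], q[2], q[3]])
      }
      if (length(nb)) {
        a <- match(v, levels)
        n_i[a] <- n_i[a] + 1
        s_i[a] <- s_i[a] + abs(v - mean(nb))
      }
    }
  }
  list(n = as.numeric(n_i), s = as.numeric(s_i))
}
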