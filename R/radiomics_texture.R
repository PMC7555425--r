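GLCM_NAMES <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy",
  "MaximumProbability", "Mcc", "SumAverage", "SumEntropy", "SumSquares")

GLRLM_NAMES <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
  "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
  "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
  "ShortRunLowGrayLevelEmphasis")

GLSZM_NAMES <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
  "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "ZoneEntropy", "ZonePercentage", "ZoneVariance")

GLDM_NAMES <- c(
  "DependenceEntropy", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "DependenceVariance",
  "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
  "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
  "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis")

NGTDM_NAMES <- c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")

#' Build the five texture-matrix families for a discretized ROI
#'
#' Gray-level co-occurrence (GLCM) and run-length (GLRLM) matrices are built
#' per direction along the 13 unique directions of the 26-neighbourhood at
#' distance 1; size-zone (GLSZM) zones are 26-connected iso-intensity
#' components (direction-free); dependence (GLDM) counts use the full
#' 26-neighbourhood at distance 1 with similarity tolerance 0 (the
#' dependence of a voxel is 1 + the number of equal-level neighbours);
#' the neighbouring gray-tone difference matrix (NGTDM) averages the 26
#' in-mask neighbours. Gray levels are the sorted distinct labels present
#' in the ROI.
#'
#' @param disc A [discretize()] result.
#' @return List with `glcm` (13 symmetric count matrices, `NULL` where a
#'   direction has no voxel pairs), `glrlm` (13 level-by-run-length count
#'   matrices), `glszm`, `gldm`, `ngtdm` (list `n`, `s`, plus voxel counts),
#'   `levels`, `n_voxels`.
#' @export
texture_matrices <- function(disc) {
  stopifnot(inherits(disc, "discretized_roi"))
  L <- disc$labels
  levels <- disc$levels
  dirs <- directions_13()
  list(glcm = lapply(dirs, function(d) glcm_direction(L, d, levels)),
       glrlm = lapply(dirs, function(d) glrlm_direction(L, d, levels)),
       glszm = glszm_matrix(L, levels),
       gldm = gldm_matrix(L, levels),
       ngtdm = ngtdm_tables(L, levels),
       levels = levels, n_voxels = disc$n_voxels)
}

glcm_direction <- function(L, d, levels) {
  sh <- shift_array(L, d)
  sel <- L > 0L & sh > 0L
  if (!any(sel)) return(NULL)
  li <- factor(L[sel], levels = levels)
  lj <- factor(sh[sel], levels = levels)
  C <- unclass(table(li, lj))
  C + t(C)  # symmetric co-occurrences
}

glrlm_direction <- function(L, d, levels) {
  dm <- dim(L)
  prev <- shift_array(L, -d)
  starts <- which(L > 0L & prev != L)
  lev <- L[starts]
  coord <- arrayInd(starts, dm)
  len <- rep(1L, length(starts))
  active <- seq_along(starts)
  cur <- coord
  while (length(active)) {
    nxt <- cur[active, , drop = FALSE] +
      matrix(d, length(active), 3, byrow = TRUE)
    inb <- nxt[, 1] >= 1L & nxt[, 1] <= dm[1] &
           nxt[, 2] >= 1L & nxt[, 2] <= dm[2] &
           nxt[, 3] >= 1L & nxt[, 3] <= dm[3]
    val <- rep(0L, length(active))
    if (any(inb)) val[inb] <- L[nxt[inb, , drop = FALSE]]
    alive <- val == lev[active]
    keep <- active[alive]
    if (length(keep)) {
      len[keep] <- len[keep] + 1L
      cur[keep, ] <- nxt[alive, , drop = FALSE]
    }
    active <- keep
  }
  maxlen <- max(len)
  unclass(table(factor(lev, levels = levels),
                factor(len, levels = seq_len(maxlen))))
}

glszm_matrix <- function(L, levels) {
  dm <- dim(L)
  idx <- which(L > 0L)
  vid <- array(0L, dm)
  vid[idx] <- seq_along(idx)
  edges <- integer(0)
  for (d in directions_13()) {
    shL <- shift_array(L, d)
    shV <- shift_array(vid, d)
    sel <- L > 0L & shL > 0L & L == shL
    if (any(sel)) edges <- c(edges, rbind(vid[sel], shV[sel]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  zone_level <- tapply(L[idx], comp$membership, function(v) v[1])
  zone_size <- comp$csize
  unclass(table(factor(zone_level, levels = levels),
                factor(zone_size, levels = seq_len(max(zone_size)))))
}

gldm_matrix <- function(L, levels) {
  eq <- array(0L, dim(L))
  for (o in offsets_26()) {
    sh <- shift_array(L, o)
    eq <- eq + as.integer(sh > 0L & sh == L)
  }
  sel <- L > 0L
  dep <- 1L + eq[sel]  # the centre voxel always depends on itself
  unclass(table(factor(L[sel], levels = levels),
                factor(dep, levels = seq_len(max(dep)))))
}

ngtdm_tables <- function(L, levels) {
  nsum <- array(0, dim(L))
  ncnt <- array(0L, dim(L))
  for (o in offsets_26()) {
    sh <- shift_array(L, o)
    nsum <- nsum + sh
    ncnt <- ncnt + as.integer(sh > 0L)
  }
  sel <- L > 0L & ncnt > 0L
  A <- nsum[sel] / ncnt[sel]
  lv <- L[sel]
  n_i <- vapply(levels, function(i) sum(lv == i), numeric(1))
  s_i <- vapply(levels, function(i) sum(abs(i - A[lv == i])), numeric(1))
  list(n = n_i, s = s_i, n_valid = length(A), levels = levels)
}

xlogx2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

glcm_features_one <- function(C, levels) {
  p <- C / sum(C)
  n <- length(levels)
  lv <- as.numeric(levels)
  I <- matrix(lv, n, n)
  J <- t(I)
  px <- rowSums(p); py <- colSums(p)
  ux <- sum(lv * px); uy <- sum(lv * py)
  sx <- sqrt(sum((lv - ux)^2 * px)); sy <- sqrt(sum((lv - uy)^2 * py))
  ks <- as.numeric(names(ps <- tapply(p, I + J, sum)))
  kd <- as.numeric(names(pd <- tapply(p, abs(I - J), sum)))
  da <- sum(kd * pd)
  hxy <- xlogx2(p)
  sel <- p > 0
  hxy1 <- -sum(p[sel] * log2((px[row(p)] * py[col(p)])[sel]))
  pxpy <- outer(px, py)
  hxy2 <- xlogx2(pxpy)
  hx <- xlogx2(px)
  present <- px > 0
  mcc <- if (sum(present) < 2) 1 else {
    pp <- p[present, present, drop = FALSE]
    pxp <- px[present]; pyp <- py[present]
    # Q[i,j] = sum_k p(i,k) p(j,k) / (px(i) py(k))
    Q <- (pp / pxp) %*% (t(pp) / pyp)
    evq <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(evq[2], 0))
  }
  offdiag <- abs(I - J) > 0
  stats::setNames(c(
    sum(I * J * p),                              # Autocorrelation
    sum((I + J - ux - uy)^4 * p),                # ClusterProminence
    sum((I + J - ux - uy)^3 * p),                # ClusterShade
    sum((I + J - ux - uy)^2 * p),                # ClusterTendency
    sum((I - J)^2 * p),                          # Contrast
    if (sx * sy > 0) (sum(I * J * p) - ux * uy) / (sx * sy) else 1,
    da,                                          # DifferenceAverage
    xlogx2(pd),                                  # DifferenceEntropy
    sum((kd - da)^2 * pd),                       # DifferenceVariance
    sum(p / (1 + abs(I - J))),                   # Id
    sum(p / (1 + (I - J)^2)),                    # Idm
    sum(p / (1 + (I - J)^2 / n^2)),              # Idmn
    sum(p / (1 + abs(I - J) / n)),               # Idn
    if (hx > 0) (hxy - hxy1) / hx else 0,        # Imc1 (HX = HY by symmetry)
    sqrt(max(1 - exp(-2 * (hxy2 - hxy)), 0)),    # Imc2
    sum(p[offdiag] / ((I - J)^2)[offdiag]),      # InverseVariance
    ux,                                          # JointAverage
    sum(p^2),                                    # JointEnergy
    hxy,                                         # JointEntropy
    max(p),                                      # MaximumProbability
    mcc,                                         # Mcc
    sum(ks * ps),                                # SumAverage
    xlogx2(ps),                                  # SumEntropy
    sum((I - ux)^2 * p)                          # SumSquares
  ), GLCM_NAMES)
}

# Shared run-length / size-zone / dependence feature family: counts matrix P
# with rows = gray levels, columns = run length / zone size / dependence.
rl_family_features <- function(P, levels, Np) {
  Ns <- sum(P)
  lv <- as.numeric(levels)
  jv <- seq_len(ncol(P))
  Im <- matrix(lv, length(lv), length(jv))
  Jm <- matrix(jv, length(lv), length(jv), byrow = TRUE)
  p <- P / Ns
  mu_i <- sum(Im * p); mu_j <- sum(Jm * p)
  vals <- c(
    SE = sum(P / Jm^2) / Ns,
    LE = sum(P * Jm^2) / Ns,
    GLN = sum(rowSums(P)^2) / Ns,
    GLNN = sum(rowSums(P)^2) / Ns^2,
    SN = sum(colSums(P)^2) / Ns,
    SNN = sum(colSums(P)^2) / Ns^2,
    PCT = Ns / Np,
    GLV = sum(p * (Im - mu_i)^2),
    SV = sum(p * (Jm - mu_j)^2),
    ENT = xlogx2(p),
    LGL = sum(P / Im^2) / Ns,
    HGL = sum(P * Im^2) / Ns,
    SLGL = sum(P / (Im^2 * Jm^2)) / Ns,
    SHGL = sum(P * Im^2 / Jm^2) / Ns,
    LLGL = sum(P * Jm^2 / Im^2) / Ns,
    LHGL = sum(P * Im^2 * Jm^2) / Ns
  )
  vals
}

glrlm_features_one <- function(P, levels, Np) {
  v <- rl_family_features(P, levels, Np)
  stats::setNames(
    c(v["GLN"], v["GLNN"], v["GLV"], v["HGL"], v["LE"], v["LHGL"], v["LLGL"],
      v["LGL"], v["ENT"], v["SN"], v["SNN"], v["PCT"], v["SV"], v["SE"],
      v["SHGL"], v["SLGL"]),
    GLRLM_NAMES)
}

glszm_features <- function(P, levels, Np) {
  v <- rl_family_features(P, levels, Np)
  stats::setNames(
    c(v["GLN"], v["GLNN"], v["GLV"], v["HGL"], v["LE"], v["LHGL"], v["LLGL"],
      v["LGL"], v["SN"], v["SNN"], v["SE"], v["SHGL"], v["SLGL"], v["ENT"],
      v["PCT"], v["SV"]),
    GLSZM_NAMES)
}

gldm_features <- function(P, levels, Np) {
  v <- rl_family_features(P, levels, Np)
  stats::setNames(
    c(v["ENT"], v["SN"], v["SNN"], v["SV"], v["GLN"], v["GLV"], v["HGL"],
      v["LE"], v["LHGL"], v["LLGL"], v["LGL"], v["SE"], v["SHGL"], v["SLGL"]),
    GLDM_NAMES)
}

ngtdm_features <- function(tab) {
  n_i <- tab$n; s_i <- tab$s
  lv <- as.numeric(tab$levels)
  N <- sum(n_i)
  if (N == 0) return(stats::setNames(rep(0, 5), NGTDM_NAMES))
  p_i <- n_i / N
  pos <- p_i > 0
  ngp <- sum(pos)
  lp <- lv[pos]; pp <- p_i[pos]; sp <- s_i[pos]
  coarse_den <- sum(pp * sp)
  coarseness <- if (coarse_den > 0) min(1 / coarse_den, 1e6) else 1e6
  contrast <- if (ngp > 1)
    sum(outer(pp, pp) * outer(lp, lp, `-`)^2) / (ngp * (ngp - 1)) *
      sum(s_i) / N else 0
  busy_den <- sum(abs(outer(lp * pp, lp * pp, `-`)))  # all ordered pairs
  busyness <- if (busy_den > 0) coarse_den / busy_den else 0
  complexity <- sum(abs(outer(lp, lp, `-`)) *
                      (outer(pp * sp, pp * sp, `+`)) /
                      outer(pp, pp, `+`)) / N
  strength <- if (sum(s_i) > 0)
    sum(outer(pp, pp, `+`) * outer(lp, lp, `-`)^2) / sum(s_i) else 0
  stats::setNames(c(busyness, coarseness, complexity, contrast, strength),
                  NGTDM_NAMES)
}

#' Texture features (75) from the five matrix families
#'
#' GLCM (24) and GLRLM (16) features are computed per direction and averaged
#' over the 13 directions (directions without any voxel pair are excluded
#' from the average); GLSZM (16) is direction-free; GLDM (14) and NGTDM (5)
#' are computed once from their 26-neighbourhood matrices. Degenerate
#' matrices (e.g. a single-voxel ROI with no GLCM pairs) yield 0 for the
#' affected family.
#'
#' @param mats A [texture_matrices()] result.
#' @return Named numeric vector of 75 features, names prefixed by family
#'   (`glcm_`, `glrlm_`, `glszm_`, `gldm_`, `ngtdm_`).
#' @export
texture_features <- function(mats) {
  avg_over_dirs <- function(mat_list, fun, names_out) {
    per_dir <- Filter(Negate(is.null), mat_list)
    if (!length(per_dir))
      return(stats::setNames(rep(0, length(names_out)), names_out))
    rowMeans(vapply(per_dir, fun, numeric(length(names_out))))
  }
  glcm <- avg_over_dirs(mats$glcm,
                        function(C) glcm_features_one(C, mats$levels),
                        GLCM_NAMES)
  glrlm <- avg_over_dirs(mats$glrlm,
                         function(P) glrlm_features_one(P, mats$levels,
                                                        mats$n_voxels),
                         GLRLM_NAMES)
  glszm <- glszm_features(mats$glszm, mats$levels, mats$n_voxels)
  gldm <- gldm_features(mats$gldm, mats$levels, mats$n_voxels)
  ngtdm <- ngtdm_features(mats$ngtdm)
  c(stats::setNames(glcm, paste0("glcm_", GLCM_NAMES)),
    stats::setNames(glrlm, paste0("glrlm_", GLRLM_NAMES)),
    stats::setNames(glszm, paste0("glszm_", GLSZM_NAMES)),
    stats::setNames(gldm, paste0("gldm_", GLDM_NAMES)),
    stats::setNames(ngtdm, paste0("ngtdm_", NGTDM_NAMES)))
}
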