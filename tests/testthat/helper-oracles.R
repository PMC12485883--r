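# Independent oracles used across the test files. These deliberately share
# no code with the package internals: brute-force neighborhood scans and
# from-scratch component searches, recomputed per candidate.

# Pearson correlation from raw sums (textbook formula).
direct_pcc <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# --- exhaustive prominence oracle -------------------------------------------
# Semantics under test: a plateau of value v is a reported maximum iff the
# 8-connected component of {pixels >= v - tol} containing it (i) holds no
# pixel strictly above v and (ii) holds no other v-valued plateau whose
# representative pixel precedes it lexicographically. Representative pixel =
# plateau member closest to the plateau centroid, (row, col) ties ascending.

oracle_neighbors <- function(i, j, nr, nc) {
  out <- NULL
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ii <- i + di; jj <- j + dj
    if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
      out <- rbind(out, c(ii, jj))
  }
  out
}

# All plateau maxima of a matrix: list of (value, members kxn matrix, rep).
oracle_plateaus <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  seen <- matrix(FALSE, nr, nc)
  res <- list()
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (seen[i, j]) next
    v <- px[i, j]
    # grow the equal-value component by repeated scanning
    comp <- matrix(c(i, j), 1)
    seen[i, j] <- TRUE
    k <- 1
    while (k <= nrow(comp)) {
      nb <- oracle_neighbors(comp[k, 1], comp[k, 2], nr, nc)
      for (q in seq_len(nrow(nb))) {
        qi <- nb[q, 1]; qj <- nb[q, 2]
        if (!seen[qi, qj] && px[qi, qj] == v) {
          seen[qi, qj] <- TRUE
          comp <- rbind(comp, c(qi, qj))
        }
      }
      k <- k + 1
    }
    # plateau is a candidate maximum iff no member has a higher neighbor
    # and it does not span the whole image
    is_max <- nrow(comp) < nr * nc
    if (is_max) for (k in seq_len(nrow(comp))) {
      nb <- oracle_neighbors(comp[k, 1], comp[k, 2], nr, nc)
      if (any(px[nb] > v)) { is_max <- FALSE; break }
    }
    if (is_max) {
      d2 <- (comp[, 1] - mean(comp[, 1]))^2 + (comp[, 2] - mean(comp[, 2]))^2
      cand <- which(d2 == min(d2))
      cand <- cand[order(comp[cand, 1], comp[cand, 2])][1]
      res[[length(res) + 1]] <- list(value = v, members = comp,
                                     rep = comp[cand, ])
    }
  }
  res
}

# 0-based (row, col) positions of the maxima surviving tolerance `tol`.
oracle_find_maxima <- function(px, tol) {
  nr <- nrow(px); nc <- ncol(px)
  plats <- oracle_plateaus(px)
  if (length(plats) == 0) return(matrix(integer(0), 0, 2))
  reps <- t(vapply(plats, function(p) p$rep, numeric(2)))
  vals <- vapply(plats, function(p) p$value, numeric(1))
  accepted <- NULL
  for (pi in seq_along(plats)) {
    v <- vals[pi]
    # from-scratch component of pixels >= v - tol around this plateau
    inc <- matrix(FALSE, nr, nc)
    comp <- plats[[pi]]$members
    inc[comp] <- TRUE
    k <- 1
    higher <- FALSE
    while (k <= nrow(comp)) {
      nb <- oracle_neighbors(comp[k, 1], comp[k, 2], nr, nc)
      for (q in seq_len(nrow(nb))) {
        qi <- nb[q, 1]; qj <- nb[q, 2]
        if (!inc[qi, qj] && px[qi, qj] >= v - tol) {
          inc[qi, qj] <- TRUE
          comp <- rbind(comp, c(qi, qj))
          if (px[qi, qj] > v) higher <- TRUE
        }
      }
      k <- k + 1
    }
    if (higher) next
    # equal-valued plateaus sharing the component: lexicographic first wins
    rivals <- which(vals == v & seq_along(plats) != pi)
    beaten <- FALSE
    for (ri in rivals) {
      rrep <- plats[[ri]]$rep
      if (inc[rrep[1], rrep[2]]) {
        mine <- plats[[pi]]$rep
        if (rrep[1] < mine[1] || (rrep[1] == mine[1] && rrep[2] < mine[2]))
          beaten <- TRUE
      }
    }
    if (!beaten) accepted <- rbind(accepted, plats[[pi]]$rep - 1)
  }
  if (is.null(accepted)) matrix(integer(0), 0, 2) else accepted
}

# canonical string form of a 0-based position set, for set comparisons
position_key <- function(m) {
  if (nrow(m) == 0) return(character(0))
  sort(paste(m[, 1], m[, 2], sep = ","))
}

# direct 2D kernel-sum convolution at one pixel (for the blur oracle)
direct_gauss_center_weight <- function(sigma) {
  r <- max(1, ceiling(4 * sigma))
  k <- dnorm(-r:r, sd = sigma); k <- k / sum(k)
  k2 <- outer(k, k)
  k2[r + 1, r + 1]
}

# closed-form two-sided t interval for a mean
t_interval <- function(x, level = 0.95) {
  n <- length(x)
  m <- mean(x)
  half <- qt(1 - (1 - level) / 2, n - 1) * sd(x) / sqrt(n)
  c(m - half, m + half)
}
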