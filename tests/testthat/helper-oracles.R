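# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks: grid/derivative-free search instead of SVD, explicit
# enumeration instead of closed forms.

quaternion_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), 3, byrow = TRUE)
}

# deterministic rotation grid: Fibonacci-sphere axes x angle sweep
rotation_grid <- function(n_axes = 60L, n_angles = 36L) {
  golden <- pi * (3 - sqrt(5))
  axes <- t(vapply(seq_len(n_axes), function(i) {
    z <- 1 - 2 * (i - 0.5) / n_axes
    r <- sqrt(max(1 - z^2, 0))
    th <- golden * (i - 1)
    c(r * cos(th), r * sin(th), z)
  }, numeric(3)))
  angles <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  qs <- list()
  for (i in seq_len(n_axes)) {
    for (a in angles) {
      qs[[length(qs) + 1L]] <- c(cos(a / 2), sin(a / 2) * axes[i, ])
    }
  }
  qs
}

# minimum superposed RMSD by rotation-grid search + Nelder-Mead polish
oracle_min_rmsd <- function(mobile, target) {
  mc <- scale(mobile, scale = FALSE)
  tc <- scale(target, scale = FALSE)
  f <- function(q) {
    r <- quaternion_rotation(q)
    sqrt(mean(rowSums((mc %*% t(r) - tc)^2)))
  }
  grid <- rotation_grid()
  vals <- vapply(grid, f, numeric(1))
  best <- order(vals)[1:5]
  res <- vapply(best, function(i) {
    optim(grid[[i]], f, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-14))$value
  }, numeric(1))
  min(res)
}

# maximum TM-score over rigid transforms: dense rotation grid, translations
# seeded both at centroid match and at every single-pair coincidence (the
# score's narrow peaks often align a few atoms far from the centroids),
# then 7-parameter Nelder-Mead polish of the best candidates
oracle_max_tm <- function(p, q, l, d0) {
  score <- function(par) {
    r <- quaternion_rotation(par[1:4])
    qt <- sweep(q %*% t(r), 2, -par[5:7])
    di2 <- rowSums((qt - p)^2)
    sum(1 / (1 + di2 / d0^2)) / l
  }
  grid <- rotation_grid()
  cands <- list()
  for (qq in grid) {
    r <- quaternion_rotation(qq)
    qr <- q %*% t(r)
    cands[[length(cands) + 1L]] <- c(qq, colMeans(p) - colMeans(qr))
    for (i in seq_len(nrow(p))) {
      cands[[length(cands) + 1L]] <- c(qq, p[i, ] - qr[i, ])
    }
  }
  vals <- vapply(cands, score, numeric(1))
  best <- order(-vals)[1:30]
  res <- vapply(best, function(i) {
    -optim(cands[[i]], function(par) -score(par), method = "Nelder-Mead",
           control = list(maxit = 5000, reltol = 1e-15))$value
  }, numeric(1))
  max(res)
}

# exact two-sided Wilcoxon rank-sum p-value by enumerating every assignment
# of the pooled observations to the first sample
oracle_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  ranks <- rank(pooled)
  combs <- combn(length(pooled), nx)
  sums <- apply(combs, 2, function(idx) sum(ranks[idx]))
  obs <- sum(ranks[seq_len(nx)])
  p_le <- mean(sums <= obs)
  p_ge <- mean(sums >= obs)
  min(1, 2 * min(p_le, p_ge))
}

# median/MAD from explicit sorted-order statistics
oracle_median_mad <- function(x) {
  s <- sort(x)
  n <- length(s)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  d <- sort(abs(x - med))
  mad <- if (n %% 2 == 1) d[(n + 1) / 2] else (d[n / 2] + d[n / 2 + 1]) / 2
  c(median = med, mad = mad)
}

# exhaustive global-alignment oracle: enumerate every alignment (no
# double-gap columns), score with BLOSUM62 + affine gaps (open + ext * len
# per maximal gap run), return the identity values of all optimal alignments
oracle_identity_set <- function(a, b, open = 11, ext = 1) {
  bl <- blosum_matrix()
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  results <- new.env()
  results$best <- -Inf
  results$idents <- numeric(0)

  recur <- function(i, j, cols_a, cols_b) {
    if (i > length(ac) && j > length(bc)) {
      sc <- 0
      runs <- rle(cols_a == "-")
      sc <- sc - sum(ifelse(runs$values, open + ext * runs$lengths, 0))
      runs <- rle(cols_b == "-")
      sc <- sc - sum(ifelse(runs$values, open + ext * runs$lengths, 0))
      both <- cols_a != "-" & cols_b != "-"
      if (any(both)) {
        sc <- sc + sum(bl[cbind(cols_a[both], cols_b[both])])
      }
      ident <- sum(cols_a == cols_b & cols_a != "-") / length(cols_a)
      if (sc > results$best + 1e-9) {
        results$best <- sc
        results$idents <- ident
      } else if (abs(sc - results$best) <= 1e-9) {
        results$idents <- unique(c(results$idents, ident))
      }
      return(invisible())
    }
    if (i <= length(ac) && j <= length(bc)) {
      recur(i + 1, j + 1, c(cols_a, ac[i]), c(cols_b, bc[j]))
    }
    if (i <= length(ac)) recur(i + 1, j, c(cols_a, ac[i]), c(cols_b, "-"))
    if (j <= length(bc)) recur(i, j + 1, c(cols_a, "-"), c(cols_b, bc[j]))
  }
  recur(1, 1, character(0), character(0))
  results$idents
}

blosum_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# angle (degrees) of the relative rotation between two coordinate sets
oracle_rotation_angle <- function(from, to) {
  sp <- kabsch_superpose(from, to)
  acos(min(1, max(-1, (sum(diag(sp$rotation)) - 1) / 2))) * 180 / pi
}
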