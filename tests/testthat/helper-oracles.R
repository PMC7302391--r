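# Independent brute-force oracles used to cross-check the vectorised
# implementations. Deliberately written as naive per-pixel loops.

bf_potts <- function(lab, beta, neighbourhood = 8L) {
  offs <- if (neighbourhood == 4L) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    expand.grid(dr = -1:1, dc = -1:1) |>
      (\(g) g[!(g$dr == 0 & g$dc == 0), ])() |>
      (\(g) lapply(seq_len(nrow(g)), \(r) c(g$dr[r], g$dc[r])))()
  }
  out <- matrix(0, nrow(lab), ncol(lab))
  for (i in seq_len(nrow(lab))) {
    for (j in seq_len(ncol(lab))) {
      for (off in offs) {
        ii <- i + off[1]; jj <- j + off[2]
        if (ii >= 1 && ii <= nrow(lab) && jj >= 1 && jj <= ncol(lab) &&
            lab[ii, jj] != lab[i, j]) {
          out[i, j] <- out[i, j] + beta
        }
      }
    }
  }
  out
}

bf_region_means <- function(u, phi, epsilon) {
  H <- 0.5 * (1 + (2 / pi) * atan(phi / epsilon))
  num1 <- 0; den1 <- 0; num2 <- 0; den2 <- 0
  for (i in seq_along(u)) {
    num1 <- num1 + u[i] * H[i];       den1 <- den1 + H[i]
    num2 <- num2 + u[i] * (1 - H[i]); den2 <- den2 + (1 - H[i])
  }
  list(f1 = num1 / den1, f2 = num2 / den2)
}

bf_total_energy <- function(phi, u, S, lambda1, lambda2, mu, nu, epsilon) {
  M <- nrow(phi); N <- ncol(phi)
  f <- bf_region_means(u, phi, epsilon)
  H <- 0.5 * (1 + (2 / pi) * atan(phi / epsilon))
  d <- (epsilon / pi) / (epsilon^2 + phi^2)
  tot <- 0
  for (i in seq_len(M)) {
    for (j in seq_len(N)) {
      # central differences in the interior, one-sided at the borders
      iu <- max(i - 1, 1); id <- min(i + 1, M)
      jl <- max(j - 1, 1); jr <- min(j + 1, N)
      gr <- (phi[id, j] - phi[iu, j]) / (id - iu)
      gc <- (phi[i, jr] - phi[i, jl]) / (jr - jl)
      gn <- sqrt(gr^2 + gc^2)
      tot <- tot + lambda1 * (u[i, j] - f$f1)^2 * H[i, j] +
        lambda2 * (u[i, j] - f$f2)^2 * (1 - H[i, j]) +
        mu * S[i, j] * d[i, j] * gn +
        nu * 0.5 * (gn - 1)^2
    }
  }
  tot
}

bf_signed_distance <- function(mask) {
  M <- nrow(mask); N <- ncol(mask)
  fg <- which(mask == 1, arr.ind = TRUE)
  bg <- which(mask == 0, arr.ind = TRUE)
  out <- matrix(0, M, N)
  for (i in seq_len(M)) {
    for (j in seq_len(N)) {
      ref <- if (mask[i, j] == 1) bg else fg
      d <- sqrt(min((ref[, 1] - i)^2 + (ref[, 2] - j)^2))
      out[i, j] <- if (mask[i, j] == 1) d else -d
    }
  }
  out
}

bf_iou_sets <- function(a, b) {
  ia <- which(a == 1); ib <- which(b == 1)
  length(intersect(ia, ib)) / length(union(ia, ib))
}

rand_mask <- function(M, N, p = 0.3) {
  matrix(rbinom(M * N, 1, p), M, N)
}

# mean interior central-difference gradient magnitude
grad_norm_stat <- function(phi) {
  M <- nrow(phi); N <- ncol(phi)
  up <- phi[c(1, seq_len(M - 1)), ]
  down <- phi[c(seq_len(M - 1) + 1, M), ]
  left <- phi[, c(1, seq_len(N - 1))]
  right <- phi[, c(seq_len(N - 1) + 1, N)]
  gn <- sqrt(((down - up) / 2)^2 + ((right - left) / 2)^2)
  mean(gn[2:(M - 1), 2:(N - 1)])
}
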